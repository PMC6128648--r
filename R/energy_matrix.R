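## Import of externally computed ddG energy terms and assembly of the
## modelling matrix from descriptor blocks.
##
## Energy descriptors never come from this package: molecular-mechanics
## suites export, per mutant, a final ddG value (totE) and its individual
## functional terms (indE); tiE is the *union* of the two descriptor sets
## (the total column plus every individual-term column), not an arithmetic
## sum.

mutant_key <- function(df) {
  paste(df$pdb_id, df$chain, df$position, toupper(df$wt), toupper(df$mut),
        sep = "_")
}

#' Load a per-mutant energy-term table
#'
#' @param path tabular text file (TSV/CSV autodetected by extension) with
#'   the mutant key columns `pdb_id, chain, position, wt, mut`, one `totE`
#'   column (final ddG, kcal/mol) and zero or more individual-term
#'   columns.
#' @param package label of the originating package (e.g. `"BL"`,
#'   `"Cart"`, `"DS"`, `"MOE"`, `"Mono"`).
#' @param mutants optional mutant table (see [load_mutants()]); rows of
#'   the energy table not present in it are dropped with a warning.
#' @return an `energy_table`: data frame keyed by mutant with columns
#'   `totE` and the term columns; attributes `package` and `terms`.
#' @export
load_energy_table <- function(path, package = "energy", mutants = NULL) {
  df <- read_tabular(path)
  need <- c("pdb_id", "chain", "position", "wt", "mut")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("energy table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"totE" %in% names(df)) stop("energy table has no 'totE' column")
  key <- mutant_key(df)
  if (anyDuplicated(key)) {
    stop("duplicate mutant keys in energy table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  terms <- setdiff(names(df), c(need, "totE"))
  if (!is.null(mutants)) {
    known <- key %in% mutant_key(mutants)
    if (any(!known)) {
      warning(sum(!known), " energy row(s) for mutants absent from the ",
              "mutant table were ignored")
      df <- df[known, , drop = FALSE]
      key <- key[known]
    }
  }
  out <- df[, c(need, "totE", terms), drop = FALSE]
  rownames(out) <- key
  structure(out, class = c("energy_table", "data.frame"),
            package = package, terms = terms)
}

read_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## ---- descriptor matrix ----------------------------------------------------

new_descriptor_matrix <- function(x, mutants, response) {
  stopifnot(nrow(x) == nrow(mutants), nrow(x) == length(response))
  rownames(x) <- mutant_key(mutants)
  structure(list(x = x, mutants = mutants, response = response),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d mutants x %d descriptors\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$x)

subset_descriptor_matrix <- function(dm, rows) {
  new_descriptor_matrix(dm$x[rows, , drop = FALSE],
                        dm$mutants[rows, , drop = FALSE],
                        dm$response[rows])
}

#' Assemble a descriptor matrix from blocks
#'
#' Joins the requested descriptor blocks for the mutants of a mutant table
#' into one numeric matrix (one row per mutant, in mutant-table order)
#' with block-namespaced column names (`A.`, `L.`, `G.`, `totE.`,
#' `indE.`).  `tiE` expands to the union of `totE` and `indE`.  Mutants
#' with any missing requested descriptor are dropped with a warning, never
#' imputed.
#'
#' @param mutants mutant table from [load_mutants()] (provides the `dTm`
#'   response).
#' @param blocks character subset of `c("A", "L", "G", "totE", "indE",
#'   "tiE")`.
#' @param a,l,g data frames of per-mutant computed blocks, rows keyed by
#'   mutant (as produced by [compute_descriptors()]).
#' @param energy an `energy_table` (required for `totE`/`indE`/`tiE`).
#' @return a `descriptor_matrix`.
#' @export
assemble <- function(mutants, blocks, a = NULL, l = NULL, g = NULL,
                     energy = NULL) {
  blocks <- unique(blocks)
  valid <- c("A", "L", "G", "totE", "indE", "tiE")
  if (length(blocks) == 0) stop("empty block request")
  bad <- setdiff(blocks, valid)
  if (length(bad)) stop("unknown block(s): ", paste(bad, collapse = ", "))
  if ("tiE" %in% blocks) blocks <- unique(c(setdiff(blocks, "tiE"),
                                            "totE", "indE"))
  ## keep canonical order
  blocks <- valid[valid %in% blocks]

  keys <- mutant_key(mutants)
  pieces <- list()
  for (b in blocks) {
    tab <- switch(b,
      A = a, L = l, G = g,
      totE = energy_cols(energy, "totE"),
      indE = energy_cols(energy, "indE"))
    if (is.null(tab)) stop("block '", b, "' requested but not supplied")
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("block '", b, "' contains non-numeric columns")
    colnames(m) <- paste0(b, ".", colnames(m))
    pieces[[b]] <- m[match(keys, rownames(tab)), , drop = FALSE]
  }
  x <- do.call(cbind, pieces)
  complete <- stats::complete.cases(x) & is.finite(mutants$dTm)
  if (any(!complete)) {
    warning(sum(!complete), " mutant(s) dropped: missing descriptor values")
  }
  constant <- apply(x[complete, , drop = FALSE], 2,
                    function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warning("constant descriptor column(s) kept: ",
            paste(colnames(x)[constant], collapse = ", "))
  }
  new_descriptor_matrix(x[complete, , drop = FALSE],
                        mutants[complete, , drop = FALSE],
                        mutants$dTm[complete])
}

energy_cols <- function(energy, which) {
  if (is.null(energy)) return(NULL)
  terms <- attr(energy, "terms")
  cols <- if (which == "totE") "totE" else terms
  if (which == "indE" && length(cols) == 0) {
    stop("energy table has no individual term columns")
  }
  out <- as.data.frame(energy)[, cols, drop = FALSE]
  rownames(out) <- rownames(energy)
  out
}

#' Compute A/L/G descriptor blocks for a mutant table
#'
#' Runs the descriptor pipeline over all mutants: validates each mutant's
#' wild-type residue against its structure, computes per-structure SASA
#' and secondary structure once, then the per-mutant blocks.
#'
#' @param mutants mutant table ([load_mutants()]).
#' @param structures named list of stripped `protein_structure`s, names =
#'   `pdb_id` values.
#' @param blocks subset of `c("A", "L", "G")`.
#' @param property_table for the A block.
#' @param probe_radius,n_points SASA parameters.
#' @return named list of data frames (`a`, `l`, `g` as requested), rows
#'   keyed by mutant, ready for [assemble()].
#' @export
compute_descriptors <- function(mutants, structures,
                                blocks = c("A", "L"),
                                property_table = load_property_table(),
                                probe_radius = 1.4, n_points = 960) {
  blocks <- match.arg(blocks, c("A", "L", "G"), several.ok = TRUE)
  keys <- mutant_key(mutants)
  need_struct <- any(c("L", "G") %in% blocks)
  cache <- list()
  get_ctx <- function(pdb_id) {
    if (is.null(cache[[pdb_id]])) {
      s <- structures[[pdb_id]]
      if (is.null(s)) stop("no structure supplied for pdb_id '", pdb_id, "'")
      cache[[pdb_id]] <<- list(
        structure = s,
        sasa = compute_sasa(s, probe_radius = probe_radius,
                            n_points = n_points),
        ss = assign_secondary_structure(s))
    }
    cache[[pdb_id]]
  }

  out <- list()
  if ("A" %in% blocks) {
    rows <- t(mapply(function(w, m) a_block(w, m, property_table),
                     mutants$wt, mutants$mut))
    out$a <- as.data.frame(rows, row.names = keys)
  }
  if ("L" %in% blocks) {
    rows <- t(vapply(seq_len(nrow(mutants)), function(i) {
      ctx <- get_ctx(mutants$pdb_id[i])
      validate_mutant_residue(ctx$structure, mutants$chain[i],
                              mutants$position[i], mutants$wt[i])
      lb <- local_block(ctx$structure, mutants$chain[i], mutants$position[i],
                        sasa = ctx$sasa, ss = ctx$ss)
      local_block_row(lb)
    }, numeric(9)))
    out$l <- as.data.frame(rows, row.names = keys)
  }
  if ("G" %in% blocks) {
    rows <- t(vapply(seq_len(nrow(mutants)), function(i) {
      ctx <- get_ctx(mutants$pdb_id[i])
      validate_mutant_residue(ctx$structure, mutants$chain[i],
                              mutants$position[i], mutants$wt[i])
      mu <- build_naive_mutant(ctx$structure, mutants$chain[i],
                               mutants$position[i], mutants$mut[i])
      g_block(ctx$structure, mu, probe_radius = probe_radius,
              n_points = n_points)
    }, numeric(14)))
    out$g <- as.data.frame(rows, row.names = keys)
  }
  if (need_struct) invisible(NULL)
  out
}
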