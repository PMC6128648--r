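## Benchmark mutant tables and dataset-composition diagnostics: stability
## class counts, the wild-type x mutant substitution grid, protein-family
## composition, coverage of the possible mutant types and
## buriedness-stratified dTm medians.

## Residue-type grouping used for grouped substitution reports; the
## grouping is a package default (configurable), so grouped results are
## approximate.
RESIDUE_GROUPS <- list(
  apolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C"),
  polar = c("S", "T", "N", "Q", "Y", "H"),
  charged = c("D", "E", "K", "R")
)

## Fraction-buried strata (as fractions; text reports use percent edges
## 71 and 91): <= 0.71, (0.71, 0.91], > 0.91.
BURIED_BIN_EDGES <- c(0.71, 0.91)

#' Load a mutant table
#'
#' @param path tabular text file (TSV/CSV by extension) with columns
#'   `pdb_id, chain, position, wt, mut, dTm`; an optional
#'   `protein_family` column and any extra numeric columns (treated as
#'   precomputed descriptors) are carried along.
#' @return validated data frame of mutant records (class `mutant_table`).
#' @export
load_mutants <- function(path) {
  df <- read_tabular(path)
  need <- c("pdb_id", "chain", "position", "wt", "mut", "dTm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutant table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$wt <- toupper(df$wt); df$mut <- toupper(df$mut)
  df$dTm <- suppressWarnings(as.numeric(df$dTm))
  bad <- which(!is.finite(df$dTm))
  if (length(bad)) stop("unparsable dTm in row(s): ",
                        paste(bad, collapse = ", "))
  same <- which(df$wt == df$mut)
  if (length(same)) stop("wt equals mut in row(s): ",
                         paste(same, collapse = ", "))
  badaa <- which(!is_standard_aa1(df$wt) | !is_standard_aa1(df$mut))
  if (length(badaa)) stop("non-standard amino acid in row(s): ",
                          paste(badaa, collapse = ", "))
  key <- mutant_key(df)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    rows <- which(key %in% dup)
    stop("duplicate mutant record(s) in row(s): ",
         paste(rows, collapse = ", "))
  }
  structure(df, class = c("mutant_table", "data.frame"))
}

#' Dataset-composition diagnostics
#'
#' @param records a mutant table ([load_mutants()] or equivalent data
#'   frame with `wt`, `mut`, `dTm`).
#' @param fraction_buried optional per-record fraction buried (in
#'   \[0, 1\]) of the wild-type residue, enabling the buriedness-stratified
#'   medians.
#' @return a `dataset_summary`: list with
#'   `class_counts` (stabilizing/neutral/destabilizing, three-class),
#'   `type_grid` (20 x 20 wt x mut counts, zero diagonal),
#'   `type_mean_dTm` (mean dTm per observed type),
#'   `group_grid` (apolar/polar/charged wt x mut counts),
#'   `family_fractions` (percent per `protein_family`, when present),
#'   `coverage_percent` (percent of the 19*19 = 361 possible mutant types
#'   observed), and `buried_median_dTm` (median dTm within the
#'   fraction-buried strata <= 0.71, (0.71, 0.91], > 0.91; `NULL` with a
#'   note when `fraction_buried` is absent).
#' @export
summarize_mutants <- function(records, fraction_buried = NULL) {
  stopifnot(nrow(records) > 0)
  cls <- classify_stability(records$dTm, "three_class")
  class_counts <- c(stabilizing = sum(cls == "stabilizing"),
                    neutral = sum(cls == "neutral"),
                    destabilizing = sum(cls == "destabilizing"))

  wt <- factor(records$wt, levels = AA1)
  mut <- factor(records$mut, levels = AA1)
  type_grid <- table(wt = wt, mut = mut)

  type <- paste0(records$wt, ">", records$mut)
  type_mean <- tapply(records$dTm, type, mean)

  grp <- function(a) {
    out <- rep(NA_character_, length(a))
    for (g in names(RESIDUE_GROUPS)) out[a %in% RESIDUE_GROUPS[[g]]] <- g
    factor(out, levels = names(RESIDUE_GROUPS))
  }
  group_grid <- table(wt = grp(records$wt), mut = grp(records$mut))

  family_fractions <- NULL
  if ("protein_family" %in% names(records)) {
    family_fractions <- sort(100 * table(records$protein_family) /
                               nrow(records), decreasing = TRUE)
  }

  coverage <- 100 * length(unique(type)) / (19 * 19)

  buried_median <- NULL
  if (!is.null(fraction_buried)) {
    stopifnot(length(fraction_buried) == nrow(records))
    bin <- cut(fraction_buried,
               breaks = c(-Inf, BURIED_BIN_EDGES, Inf),
               labels = c("<=0.71", "(0.71,0.91]", ">0.91"))
    buried_median <- tapply(records$dTm, bin, stats::median)
  }

  structure(list(n = nrow(records),
                 class_counts = class_counts,
                 type_grid = type_grid,
                 type_mean_dTm = type_mean,
                 group_grid = group_grid,
                 family_fractions = family_fractions,
                 coverage_percent = coverage,
                 buried_median_dTm = buried_median),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d mutants\n", x$n))
  cat("  classes:", paste(names(x$class_counts), x$class_counts,
                          sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mutant-type coverage: %.1f%% of 361\n", x$coverage_percent))
  if (!is.null(x$buried_median_dTm)) {
    cat("  median dTm by fraction buried:",
        paste(names(x$buried_median_dTm),
              round(x$buried_median_dTm, 2), sep = "=", collapse = ", "), "\n")
  } else {
    cat("  (fraction buried not supplied: buriedness medians omitted)\n")
  }
  invisible(x)
}

#' Training-set representation of query mutant types
#'
#' For each distinct (wt, mut) substitution type in the query set, counts
#' its occurrences in the training set and bins the types into
#' unseen (0), rare (< 5) and common (>= 5).
#'
#' @param training,query mutant tables (data frames with `wt` and `mut`).
#' @return list with `counts` (named per query type) and `bins`
#'   (unseen / rare / common type counts).
#' @export
query_overlap <- function(training, query) {
  stopifnot(nrow(training) > 0, nrow(query) > 0)
  ttype <- paste0(training$wt, ">", training$mut)
  qtype <- unique(paste0(query$wt, ">", query$mut))
  counts <- vapply(qtype, function(t) sum(ttype == t), numeric(1))
  bins <- c(unseen = sum(counts == 0),
            rare = sum(counts > 0 & counts < 5),
            common = sum(counts >= 5))
  list(counts = counts, bins = bins)
}
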