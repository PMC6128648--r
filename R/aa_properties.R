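## Amino-acid property scales and the A descriptor block.
##
## Eighteen per-residue scales are shipped as an editable tab-separated
## table (inst/extdata/aa_properties.tsv).  The shipped values are
## documented literature scales chosen to play the roles the model needs:
## Chou-Fasman helix/sheet/turn propensities, ring-count aromaticity,
## C-beta branching, Zimmerman bulkiness and polarity2, formal charge at
## pH 7, Fauchere-Pliska octanol->water transfer free energy (and a
## derived logD surrogate), Bhaskaran-Ponnuswamy flexibility,
## Kyte-Doolittle hydrophobicity, free amino-acid molecular weight, Dayhoff
## relative mutability, isoelectric point, Grantham polarity, side-chain
## van der Waals volume, and the Eisenberg consensus hydrophobicity.  Any
## scale can be overridden from a user table.

PROPERTY_SCALES <- c(
  "alpha_propensity", "beta_propensity", "coil_propensity", "aromaticity",
  "branchness", "bulkiness", "charge", "dG_octanol_water", "flexibility",
  "hydrophobicity", "logD", "molecular_weight", "mutability", "pI",
  "polarity", "polarity2", "vdw_volume", "consensus_hydrophobicity"
)

#' Load an amino-acid property table
#'
#' @param path `"default"` for the shipped table, or a path to a
#'   tab-separated file with an `aa` column (one-letter codes) and one
#'   column per scale.  A user table may cover only a subset of scales;
#'   the remaining scales are taken from the shipped defaults, but every
#'   provided scale must cover all 20 amino acids.
#' @return a `property_table`: named list of 18 scales, each a named
#'   numeric vector over the 20 standard amino acids.
#' @export
load_property_table <- function(path = "default") {
  default_path <- system.file("extdata", "aa_properties.tsv",
                              package = "thermoforest")
  tab <- read_property_file(default_path)
  if (!identical(path, "default")) {
    user <- read_property_file(path, require_all_scales = FALSE)
    for (sc in names(user)) tab[[sc]] <- user[[sc]]
  }
  validate_property_table(tab)
  structure(tab, class = "property_table")
}

read_property_file <- function(path, require_all_scales = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"aa" %in% names(df)) stop("property table must have an 'aa' column")
  scales <- setdiff(names(df), "aa")
  unknown <- setdiff(scales, PROPERTY_SCALES)
  if (length(unknown)) {
    stop("unknown property scale(s): ", paste(unknown, collapse = ", "))
  }
  if (require_all_scales) {
    missing <- setdiff(PROPERTY_SCALES, scales)
    if (length(missing)) {
      stop("property table missing scale(s): ",
           paste(missing, collapse = ", "))
    }
  }
  lapply(stats::setNames(scales, scales), function(sc) {
    stats::setNames(df[[sc]], toupper(df$aa))
  })
}

validate_property_table <- function(tab) {
  for (sc in names(tab)) {
    missing <- setdiff(AA1, names(tab[[sc]]))
    if (length(missing)) {
      stop("scale '", sc, "' missing amino acid(s): ",
           paste(missing, collapse = ", "))
    }
    if (anyNA(tab[[sc]][AA1])) {
      stop("scale '", sc, "' has missing values")
    }
  }
  invisible(tab)
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d scales x %d amino acids\n",
              length(x), length(x[[1]])))
  invisible(x)
}

#' Amino-acid (A) descriptor block for one mutation
#'
#' For each of the 18 property scales the block carries the wild-type
#' value (`_first`), the mutant value (`_second`) and the change
#' (`_diff` = second - first): 54 descriptors in fixed column order
#' (scales in shipped-table order, first/second/diff within each scale).
#'
#' @param wt,mut one-letter wild-type and mutant amino acids.
#' @param table a `property_table`; defaults to the shipped scales.
#' @return named numeric vector of length 54.
#' @examples
#' b <- a_block("G", "W")
#' b["molecular_weight_diff"]
#' @export
a_block <- function(wt, mut, table = load_property_table()) {
  wt <- toupper(wt); mut <- toupper(mut)
  if (!is_standard_aa1(wt)) stop("non-standard wild-type amino acid: ", wt)
  if (!is_standard_aa1(mut)) stop("non-standard mutant amino acid: ", mut)
  out <- numeric(0)
  for (sc in PROPERTY_SCALES) {
    v1 <- unname(table[[sc]][wt])
    v2 <- unname(table[[sc]][mut])
    vals <- c(v1, v2, v2 - v1)
    names(vals) <- paste0(sc, c("_first", "_second", "_diff"))
    out <- c(out, vals)
  }
  out
}
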