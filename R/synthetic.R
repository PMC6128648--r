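## Synthetic fixtures: ideal secondary-structure elements with known
## geometry and simulated mutant datasets with a known descriptor -> dTm
## relationship.  Everything here is first-class, seeded and reproducible;
## the generated data emulate the statistical shape of a mutant benchmark
## (descriptor matrix plus a continuous response), not protein energetics.

#' Ideal alpha-helix fixture
#'
#' Backbone built at phi = -57, psi = -47 with ideal bond lengths and
#' angles; side chains from the idealized templates.
#'
#' @param n_residues number of residues (>= 4).
#' @param sequence one-letter sequence, a single amino acid to repeat, or
#'   `NULL` for poly-alanine.
#' @param chain,id passed to [build_peptide()].
#' @return a `protein_structure`.
#' @export
make_ideal_helix <- function(n_residues, sequence = "A", chain = "A",
                             id = "ideal_helix") {
  stopifnot(n_residues >= 4)
  seq1 <- expand_sequence(sequence, n_residues)
  build_peptide(seq1, phi = -57, psi = -47, chain = chain, id = id)
}

#' Ideal two-strand antiparallel beta-sheet fixture
#'
#' Two extended strands (chains A and B) placed at hydrogen-bonding
#' register.  The placement is a deterministic geometric search: the
#' second strand is the first rotated to run antiparallel, and its
#' in-plane offset and register shift are chosen to maximise the number
#' of backbone hydrogen bonds under the electrostatic criterion.
#'
#' @param n_per_strand residues per strand (>= 3).
#' @param sequence one-letter sequence for each strand (repeated single
#'   amino acid allowed; default poly-valine).
#' @return a `protein_structure` with chains A and B.
#' @export
make_beta_hairpin <- function(n_per_strand, sequence = "V") {
  stopifnot(n_per_strand >= 3)
  seq1 <- expand_sequence(sequence, n_per_strand)
  s1 <- build_peptide(seq1, phi = -139, psi = 135, chain = "A",
                      id = "strand1")
  ## strand axis and sheet frame from the CA trace
  ca <- s1$atoms[s1$atoms$elety == "CA", c("x", "y", "z")]
  ca <- as.matrix(ca)
  axis <- unit(ca[nrow(ca), ] - ca[1, ])
  centroid <- colMeans(ca)

  s2_base <- build_peptide(seq1, phi = -139, psi = 135, chain = "B",
                           id = "strand2")
  s2_base <- transform_structure(s2_base, t = -centroid)

  best <- NULL
  best_n <- -1L
  ## flip strand 2 about an axis perpendicular to the strand; search the
  ## perpendicular direction, inter-strand offset and register shift
  perp0 <- pick_perpendicular(axis)
  for (gamma in seq(0, 150, by = 30)) {
    perp <- as.vector(rotation_matrix(axis, gamma) %*% perp0)
    R <- rotation_matrix(perp, 180)
    flipped <- transform_structure(s2_base, R = R)
    for (offset in seq(4.2, 5.4, by = 0.3)) {
      for (shift in seq(-3.5, 3.5, by = 0.5)) {
        s2 <- transform_structure(
          flipped, t = centroid + offset * perp + shift * axis)
        ## reject sterically clashing placements before counting H-bonds
        cb <- as.matrix(s2$atoms[s2$atoms$elety == "CA", c("x", "y", "z")])
        if (min(as.matrix(stats::dist(rbind(ca, cb)))[
          seq_len(nrow(ca)), nrow(ca) + seq_len(nrow(cb))]) < 4.0) next
        both <- combine_structures(s1, s2, id = "beta_sheet")
        nhb <- sum(hbond_matrix(both)$hb)
        if (nhb > best_n) { best_n <- nhb; best <- both }
      }
    }
  }
  best
}

pick_perpendicular <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(cross3(axis, ref))
}

combine_structures <- function(a, b, id = "combined") {
  new_structure(rbind(a$atoms, b$atoms), id = id)
}

expand_sequence <- function(sequence, n) {
  if (is.null(sequence)) sequence <- "A"
  if (length(sequence) == 1 && nchar(sequence) == 1) {
    rep(sequence, n)
  } else {
    s <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
    if (length(s) != n) stop("sequence length ", length(s),
                             " does not match n = ", n)
    s
  }
}

## ---- simulated mutant datasets -------------------------------------------

#' Specification of a simulated descriptor -> dTm effect
#'
#' @param coefficients named numeric vector: linear coefficient of each
#'   active descriptor (descriptors are independent standard normal).
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   dTm (degrees C).
#' @param n number of simulated mutants.
#' @param n_noise additional pure-noise descriptors with zero
#'   coefficient.
#' @param seed integer seed.
#' @return an `effect_spec` list; its `attainable_r2` is the analytic
#'   ceiling var(signal) / (var(signal) + noise_sd^2) for any model.
#' @export
effect_spec <- function(coefficients, noise_sd = 1, n = 500, n_noise = 0,
                        seed = 1L) {
  stopifnot(length(coefficients) >= 1, !is.null(names(coefficients)),
            noise_sd >= 0, n >= 1, n_noise >= 0)
  var_signal <- sum(coefficients^2)
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 n = as.integer(n), n_noise = as.integer(n_noise),
                 seed = as.integer(seed),
                 attainable_r2 = if (var_signal + noise_sd^2 > 0) {
                   var_signal / (var_signal + noise_sd^2)
                 } else 0),
            class = "effect_spec")
}

#' Simulate a mutant dataset with known structure
#'
#' Draws independent standard-normal descriptors, sets
#' dTm = sum(coef * descriptor) + N(0, noise_sd), and packages the result
#' as a `descriptor_matrix` ready for training, plus synthetic mutant
#' bookkeeping columns.
#'
#' @param spec an [effect_spec()].
#' @param shift optional numeric: added to every descriptor (used to
#'   create distribution-shifted query sets for applicability-domain
#'   experiments).
#' @param scale optional numeric: multiplies every descriptor before the
#'   shift (scale > 1 gives a wide, sparsely populated cloud).
#' @return a `descriptor_matrix` with attribute `attainable_r2`.
#' @export
simulate_dataset <- function(spec, shift = 0, scale = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(spec$seed)
  p_active <- length(spec$coefficients)
  p <- p_active + spec$n_noise
  x <- matrix(stats::rnorm(spec$n * p), spec$n, p) * scale + shift
  noise_names <- if (spec$n_noise > 0) {
    paste0("noise", seq_len(spec$n_noise))
  } else character(0)
  colnames(x) <- c(names(spec$coefficients), noise_names)
  signal <- as.vector(x[, seq_len(p_active), drop = FALSE] %*%
                        spec$coefficients)
  dtm <- signal + stats::rnorm(spec$n, 0, spec$noise_sd)
  mutants <- data.frame(
    pdb_id = "SYN", chain = "A", position = seq_len(spec$n),
    wt = "A", mut = "G", dTm = dtm, stringsAsFactors = FALSE)
  dm <- new_descriptor_matrix(x, mutants, dtm)
  attr(dm, "attainable_r2") <- spec$attainable_r2
  dm
}

#' Stack simulated datasets
#'
#' Row-binds two or more simulated `descriptor_matrix` objects with
#' identical descriptor columns (positions are renumbered to keep mutant
#' keys unique).  Used to build heterogeneous training sets, e.g. a dense
#' core plus a sparse wide tail for applicability-domain experiments.
#'
#' @param ... `descriptor_matrix` objects.
#' @return a combined `descriptor_matrix`.
#' @export
combine_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "descriptor_matrix")))
  cols <- colnames(parts[[1]]$x)
  for (p in parts) {
    if (!identical(colnames(p$x), cols)) {
      stop("datasets have different descriptor columns")
    }
  }
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  mutants <- do.call(rbind, lapply(parts, `[[`, "mutants"))
  mutants$position <- seq_len(nrow(mutants))
  new_descriptor_matrix(x, mutants, unlist(lapply(parts, `[[`, "response")))
}
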