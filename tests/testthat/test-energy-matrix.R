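# Energy-term import and descriptor-matrix assembly.

energy_fixture <- function(terms = c("solv_gb", "selfcont", "lipo", "vdw",
                                     "ref", "hbond", "coulomb", "packing",
                                     "covalent", "solv_sa"),
                           n = 6, extra_row = FALSE) {
  set.seed(9)
  df <- data.frame(pdb_id = "1ABC", chain = "A", position = seq_len(n),
                   wt = "A", mut = "G", totE = rnorm(n))
  for (t in terms) df[[t]] <- rnorm(n)
  if (extra_row) {
    df <- rbind(df, df[n, ])
    df$position[n + 1] <- 999
  }
  df
}

mutants_fixture <- function(n = 6) {
  structure(data.frame(pdb_id = "1ABC", chain = "A", position = seq_len(n),
                       wt = "A", mut = "G", dTm = seq_len(n) - 3),
            class = c("mutant_table", "data.frame"))
}

write_fixture <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("an energy file with ten term columns yields ten named indE terms", {
  et <- load_energy_table(write_fixture(energy_fixture()), package = "BL")
  expect_equal(length(attr(et, "terms")), 10)
  expect_true(all(c("solv_gb", "solv_sa") %in% attr(et, "terms")))
  expect_equal(attr(et, "package"), "BL")
})

test_that("a totE-only file has empty indE; rows for unknown mutants drop", {
  df <- energy_fixture(terms = character(0), extra_row = TRUE)
  expect_warning(
    et <- load_energy_table(write_fixture(df), mutants = mutants_fixture()),
    "ignored")
  expect_length(attr(et, "terms"), 0)
  expect_equal(nrow(et), 6)
})

test_that("duplicate keys and missing totE are rejected", {
  df <- energy_fixture()
  expect_error(load_energy_table(write_fixture(rbind(df, df[1, ]))),
               "duplicate")
  df$totE <- NULL
  expect_error(load_energy_table(write_fixture(df)), "totE")
})

test_that("assembled block widths follow the definitions", {
  mt <- mutants_fixture()
  et <- load_energy_table(write_fixture(energy_fixture()), package = "BL")
  a <- as.data.frame(t(vapply(seq_len(nrow(mt)),
                              function(i) a_block(mt$wt[i], mt$mut[i]),
                              numeric(54))))
  rownames(a) <- thermoforest:::mutant_key(mt)

  ## the single-type fixture makes every A column constant; assemble warns
  expect_equal(ncol(suppressWarnings(assemble(mt, "A", a = a))$x), 54)
  ## totE + indE = 1 + 10 columns
  dm <- suppressWarnings(assemble(mt, c("totE", "indE"), energy = et))
  expect_equal(ncol(dm$x), 11)
  ## tiE is the union of totE and indE, column for column
  dm_tie <- suppressWarnings(assemble(mt, "tiE", energy = et))
  expect_identical(colnames(dm_tie$x), colnames(dm$x))
  expect_identical(dm_tie$x, dm$x)
})

test_that("row order matches the mutant table and assembly is pure", {
  mt <- mutants_fixture()
  et <- load_energy_table(write_fixture(energy_fixture()), package = "BL")
  d1 <- suppressWarnings(assemble(mt, c("totE", "indE"), energy = et))
  d2 <- suppressWarnings(assemble(mt, c("indE", "totE"), energy = et))
  expect_identical(d1$x, d2$x)
  expect_identical(rownames(d1$x), thermoforest:::mutant_key(mt))
  expect_identical(d1$response, mt$dTm)
})

test_that("empty or unknown block requests error; missing rows drop with warning", {
  mt <- mutants_fixture()
  expect_error(assemble(mt, character(0)), "empty")
  expect_error(assemble(mt, "Z"), "unknown block")
  ## an incomplete A table drops the uncovered mutant
  a <- as.data.frame(t(vapply(1:5, function(i) a_block(mt$wt[i], mt$mut[i]),
                              numeric(54))))
  rownames(a) <- thermoforest:::mutant_key(mt[1:5, ])
  suppressWarnings(expect_warning(dm <- assemble(mt, "A", a = a), "dropped"))
  expect_equal(nrow(dm$x), 5)
})

test_that("the L block from the pipeline has 9 columns including one-hot classes", {
  hx <- helix15()
  mt <- structure(data.frame(pdb_id = "HX", chain = "A",
                             position = c(5, 8, 11), wt = "A", mut = "G",
                             dTm = c(1, -2, 0)),
                  class = c("mutant_table", "data.frame"))
  blk <- compute_descriptors(mt, list(HX = hx), blocks = c("A", "L"),
                             n_points = 120)
  expect_equal(ncol(blk$l), 9)
  expect_setequal(colnames(blk$l),
                  c("totalArea", "buriedArea", "hydrophobicArea",
                    "hydrophobicRatio", "fractionBuried",
                    "ss_helix", "ss_beta", "ss_coil", "ss_turn"))
  ## one-hot: exactly one class active per row
  expect_equal(unname(rowSums(blk$l[, c("ss_helix", "ss_beta", "ss_coil",
                                        "ss_turn")])), rep(1, 3))
  dm <- suppressWarnings(assemble(mt, c("A", "L"), a = blk$a, l = blk$l))
  expect_equal(ncol(dm$x), 63)
})
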