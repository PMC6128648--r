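# Shared fixtures, built in code.  Expensive ones are computed once per
# test run and reused across files.

# Write one PDB-format atom line.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", occ = 1, alt = "", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, alt, resname, chain, resno,
          x, y, z, occ, 0, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Minimal one-residue alanine (5 heavy atoms), coordinates roughly ideal.
minimal_ala_pdb <- function() {
  write_pdb_text(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.009, 1.420, 0.000),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 1.251, 2.390, 0.000),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.988, -0.773, -1.199)
  ))
}

# Single-atom / few-atom structures assembled directly.
atoms_structure <- function(x, y, z, element = "C", resid = "ALA",
                            elety = NULL, resno = NULL, chain = "A",
                            id = "toy") {
  n <- length(x)
  if (is.null(elety)) elety <- rep("CB", n)
  if (is.null(resno)) resno <- seq_len(n)
  thermoforest:::new_structure(
    data.frame(chain = chain, resno = resno, insert = "",
               resid = resid, elety = elety, element = element,
               x = x, y = y, z = z, het = FALSE,
               stringsAsFactors = FALSE),
    id = id)
}

# Cached expensive fixtures ------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

helix15 <- function() cached("helix15", make_ideal_helix(15, "A"))

helix15_sasa <- function() {
  cached("helix15_sasa", compute_sasa(helix15(), n_points = 240))
}

hairpin6 <- function() cached("hairpin6", make_beta_hairpin(6))

# Simulated signal dataset shared by forest / evaluation / AD tests.
signal_dm <- function() {
  cached("signal_dm",
         simulate_dataset(effect_spec(c(x1 = 3, x2 = 2), noise_sd = 2,
                                      n = 400, n_noise = 3, seed = 42)))
}

# Mutant-table text fixture.
mutant_table_text <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
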