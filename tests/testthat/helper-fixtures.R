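# Shared fixtures: reference parameter sets, a small PDB text fixture,
# and a Monte-Carlo rejection-sampling oracle for accessible surface
# area (independent of the deterministic lattice the package uses).

apo_params <- function() two_state_params(62.5, 111.6, 96.3)
camp_params <- function() two_state_params(71.0, 120.4, 139.9)
g325d_params <- function() two_state_params(52.1, 111.6, 96.3)

# Table of structure-derived energetics inputs and printed outputs used
# by the reproduction tests: dASA_ap, dASA_pol, Tm and the published
# dCp / dH60 / dH(Tm) values per structure.
energetics_table <- function() {
  data.frame(
    name = c("1RGS", "1RL3", "2QCS"),
    dasa_ap = c(18746, 19535, 19938),
    dasa_pol = c(10598, 11526, 12194),
    tm = c(71, 62.5, 62.5),
    dcp = c(5.7, 5.8, 5.8),
    dh60 = c(174.5, 197.0, 214.6),
    dhtm = c(236, 212, 230))
}

pdb_line <- function(rec, serial, name, alt, resn, chain, resno,
                     x, y, z, occ = 1, elem) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# Ala-Gly dipeptide with an altloc pair on CA (occupancies 0.4/0.6), a
# tied altloc pair on CB (0.5/0.5), one hydrogen, a nucleotide-like
# HETATM group and a water.
pdb_fixture_text <- function() {
  paste(c(
    pdb_line("ATOM", 1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line("ATOM", 2, "CA", "A", "ALA", "A", 1, 1.458, 0, 0, 0.4, "C"),
    pdb_line("ATOM", 3, "CA", "B", "ALA", "A", 1, 1.558, 0, 0, 0.6, "C"),
    pdb_line("ATOM", 4, "C", " ", "ALA", "A", 1, 2.0, 1.4, 0, 1, "C"),
    pdb_line("ATOM", 5, "O", " ", "ALA", "A", 1, 1.4, 2.4, 0, 1, "O"),
    pdb_line("ATOM", 6, "CB", "A", "ALA", "A", 1, 2.0, -1.2, 0.9, 0.5, "C"),
    pdb_line("ATOM", 7, "CB", "B", "ALA", "A", 1, 2.1, -1.3, 1.0, 0.5, "C"),
    pdb_line("ATOM", 8, "HB1", " ", "ALA", "A", 1, 2.5, -1.9, 1.5, 1, "H"),
    pdb_line("ATOM", 9, "N", " ", "GLY", "A", 2, 3.3, 1.5, 0.1, 1, "N"),
    pdb_line("ATOM", 10, "CA", " ", "GLY", "A", 2, 4.1, 2.7, 0.2, 1, "C"),
    pdb_line("ATOM", 11, "C", " ", "GLY", "A", 2, 5.6, 2.5, 0.3, 1, "C"),
    pdb_line("ATOM", 12, "O", " ", "GLY", "A", 2, 6.2, 1.4, 0.3, 1, "O"),
    pdb_line("HETATM", 13, "P", " ", "CMP", "A", 401, 10, 10, 10, 1, "P"),
    pdb_line("HETATM", 14, "O1", " ", "CMP", "A", 401, 11, 10, 10, 1, "O"),
    pdb_line("HETATM", 15, "O", " ", "HOH", "A", 501, 20, 20, 20, 1, "O"),
    "END"), collapse = "\n")
}

# Monte-Carlo rejection-sampling ASA oracle: uniform random directions
# on each atom's solvent-expanded sphere, counting points outside every
# other expanded sphere.
mc_asa <- function(structure, probe = 1.4, n_samples = 1e5, seed = 1) {
  at <- structure$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- at$radius + probe
  set.seed(seed)
  per <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * rexp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= rexp[j]^2
    }
    per[i] <- 4 * pi * rexp[i]^2 * mean(acc)
  }
  list(per_atom = per, total = sum(per))
}

# Random compact atom cluster for ASA property tests.
random_cluster <- function(n_atoms, seed, box = 6) {
  set.seed(seed)
  structure_model(data.frame(
    element = sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE),
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    radius = NA_real_, resname = "UNK", resno = seq_len(n_atoms),
    chain = "A", stringsAsFactors = FALSE) |>
      transform(radius = vdw_radius(element)))
}
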