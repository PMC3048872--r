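# PDB parsing, Shrake-Rupley surface areas, polarity classes, and the
# unfolded-state reference.

test_that("PDB parsing keeps protein heavy atoms and resolves altlocs", {
  mod <- parse_structure(pdb_fixture_text())
  at <- mod$atoms
  # 5 ALA heavy atoms (one CA, one CB) + 4 GLY atoms; no H, no HETATM
  expect_equal(nrow(at), 9)
  expect_false(any(at$element == "H"))
  expect_false(any(at$resname %in% c("CMP", "HOH")))
  # highest occupancy wins (CA altloc B at x = 1.558)
  ca <- at[at$resname == "ALA" & at$element == "C" &
             abs(at$x - 1.558) < 1e-6, ]
  expect_equal(nrow(ca), 1)
  # occupancy tie resolved toward altloc A (CB at x = 2.0)
  expect_true(any(abs(at$x - 2.0) < 1e-6 & abs(at$y + 1.2) < 1e-6))
  expect_false(any(abs(at$x - 2.1) < 1e-6 & abs(at$y + 1.3) < 1e-6))
  expect_identical(unname(mod$sequence["A"]), "AG")
  # ligand atoms come back only on request; waters never do
  het <- parse_structure(pdb_fixture_text(), include_hetatm = TRUE)
  expect_equal(nrow(het$atoms), 11)
  expect_false(any(het$atoms$resname == "HOH"))
  # chain selection drops everything else
  none <- parse_structure(pdb_fixture_text(), chains = "B")
  expect_equal(nrow(none$atoms), 0)
})

test_that("single atoms match the analytic sphere area and distant atoms do not occlude", {
  iso <- shrake_rupley_asa(toy_structure("single_atom"))
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(iso$total, analytic, tolerance = 5e-3)
  expect_equal(iso$apolar, iso$total)
  expect_equal(iso$polar, 0)
  pair <- shrake_rupley_asa(toy_structure("far_pair"))
  expect_equal(pair$total, 2 * iso$total, tolerance = 1e-12)
  # monotone in probe radius, exactly 4 pi (r + rp)^2 for an isolated atom
  probes <- c(0.5, 1.0, 1.4, 2.0)
  areas <- sapply(probes, function(rp) {
    shrake_rupley_asa(toy_structure("single_atom"), probe_radius = rp)$total
  })
  expect_equal(areas, 4 * pi * (1.70 + probes)^2, tolerance = 1e-12)
  expect_error(shrake_rupley_asa(toy_structure("single_atom"),
                                 n_points = 50),
               class = "dscfit_invalid_input")
})

test_that("a caged atom is buried and the per-atom areas sum consistently", {
  caged <- shrake_rupley_asa(toy_structure("caged_atom"))
  expect_lt(caged$per_atom[1], 0.5)
  expect_equal(sum(caged$per_atom), caged$apolar + caged$polar,
               tolerance = 1e-9)
})

test_that("lattice ASA agrees with a Monte-Carlo rejection oracle on clusters", {
  # one deeper check on a 5-atom cluster with many samples, then a sweep
  cl5 <- random_cluster(5, seed = 101)
  sr <- shrake_rupley_asa(cl5)
  mc <- mc_asa(cl5, n_samples = 1e6, seed = 1)
  expect_equal(sr$total, mc$total, tolerance = 0.02)
  for (seed in 102:105) {
    n <- 5 + (seed %% 4) * 5  # 5-20 atoms
    cl <- random_cluster(n, seed = seed)
    sr <- shrake_rupley_asa(cl)
    mc <- mc_asa(cl, n_samples = 2e4, seed = seed)
    expect_equal(sr$total, mc$total, tolerance = 0.02)
  }
})

test_that("ASA is additive over well-separated chains and bit-reproducible", {
  two <- toy_structure("two_chain")
  one <- toy_structure("mini_helix")
  a_two <- shrake_rupley_asa(two)
  a_one <- shrake_rupley_asa(one)
  expect_equal(a_two$total, 2 * a_one$total, tolerance = 1e-6)
  expect_equal(a_two$apolar, 2 * a_one$apolar, tolerance = 1e-6)
  expect_identical(shrake_rupley_asa(one)$per_atom, a_one$per_atom)
})

test_that("polarity classes follow the C,S apolar / N,O polar convention", {
  expect_identical(classify_polarity(c("C", "O", "N", "S")),
                   c("apolar", "polar", "polar", "apolar"))
  expect_error(classify_polarity("X"), class = "dscfit_invalid_input")
})

test_that("the unfolded reference is additive over the sequence table", {
  empty <- unfolded_reference_asa("")
  expect_equal(empty$total, 0)
  g1 <- unfolded_reference_asa("G")
  gg <- unfolded_reference_asa("GG")
  expect_equal(gg$apolar, 2 * g1$apolar)
  expect_equal(gg$polar, 2 * g1$polar)
  # independent summation oracle over the shipped table
  tab <- read.delim(system.file("extdata", "unfolded_reference_asa.tsv",
                                package = "dscfit"),
                    comment.char = "#", header = FALSE,
                    col.names = c("aa1", "aa3", "apolar", "polar"))
  seq_all <- paste(tab$aa1, collapse = "")
  ref <- unfolded_reference_asa(seq_all)
  expect_equal(ref$apolar, sum(tab$apolar))
  expect_equal(ref$polar, sum(tab$polar))
  expect_error(unfolded_reference_asa("AXB"),
               class = "dscfit_invalid_input")
  expect_warning(skipped <- unfolded_reference_asa("AXA", "skip"))
  expect_equal(skipped$total, unfolded_reference_asa("AA")$total)
})

test_that("unfolding a compact helix exposes both surface classes", {
  helix <- toy_structure("mini_helix")
  folded <- shrake_rupley_asa(helix)
  unfolded <- unfolded_reference_asa(helix$sequence)
  d <- delta_asa(folded, unfolded)
  expect_gt(d$dasa_ap, 0)
  expect_gt(d$dasa_pol, 0)
  # identical inputs give a zero change; a zero folded state gives the totals
  expect_equal(delta_asa(folded, folded), list(dasa_ap = 0, dasa_pol = 0))
  none <- asa_breakdown(0, 0)
  expect_equal(delta_asa(none, unfolded),
               list(dasa_ap = unfolded$apolar, dasa_pol = unfolded$polar))
})

test_that("energetics correlations are linear and reproduce the published table", {
  expect_equal(predict_dcp(0, 0), 0)
  expect_equal(predict_dh60(0, 0), 0)
  a <- c(12000, 7000); b <- c(5000, 3000)
  expect_equal(predict_dcp(a[1] + b[1], a[2] + b[2]),
               predict_dcp(a[1], a[2]) + predict_dcp(b[1], b[2]))
  expect_equal(predict_dh60(a[1] + b[1], a[2] + b[2]),
               predict_dh60(a[1], a[2]) + predict_dh60(b[1], b[2]))
  expect_equal(dh_at_temperature(174.5, 5.7, 60), 174.5)
  tab <- energetics_table()
  for (i in seq_len(nrow(tab))) {
    pred <- predict_energetics(tab$dasa_ap[i], tab$dasa_pol[i], tab$tm[i])
    expect_equal(round(pred$dcp_calc, 1), tab$dcp[i])
    expect_equal(pred$dh_calc_60, tab$dh60[i], tolerance = 3e-3)
    expect_equal(pred$dh_calc_at_tm, tab$dhtm[i], tolerance = 6e-3)
    expect_equal(pred$dh_calc_at_tm,
                 pred$dh_calc_60 + pred$dcp_calc * (tab$tm[i] - 60))
  }
  # residual-structure index: printed experimental over predicted values
  expect_equal(residual_structure_index(120.4, 236), 0.51, tolerance = 0.01)
  expect_equal(residual_structure_index(111.6, 212), 0.53, tolerance = 0.01)
  expect_equal(residual_structure_index(100, 100), 1.0)
  expect_error(residual_structure_index(100, -5),
               class = "dscfit_invalid_input")
})
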