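# Seeded generators for every input the analysis consumes: DSC
# thermograms with chemical baselines, CD melts, Tm-titration series, and
# toy coordinate sets for ASA validation. Generators are pure functions
# of their arguments and seed; the injected ground truth travels with the
# output as an attribute. Defaults mirror the acquisition conditions of
# the study the models target: a 15-95 degC scan at 1.5 K/min, low
# micromolar protein in a 0.527 mL cell, and instrument noise small
# relative to the ~12 kcal/mol/K unfolding peak.

#' Simulate a DSC thermogram
#'
#' Evaluates the two-state excess heat-capacity model on a temperature
#' grid, adds an optional chemical baseline (linear folded and unfolded
#' trends joined smoothly through the transition in proportion to the
#' unfolded fraction) and iid Gaussian noise.
#'
#' @param params a [two_state_params()] object (degC, kcal/mol).
#' @param grid numeric length 3: start, stop, step in degC (default
#'   15-95 degC at 0.1 degC).
#' @param noise_sd Gaussian noise standard deviation, kcal mol^-1 K^-1
#'   (default 0.1).
#' @param baseline `NULL` for none (the output is `excess` stage), or a
#'   list with numeric length-2 elements `pre` and `post` (intercept,
#'   slope per degC) giving the folded and unfolded heat-capacity
#'   trends; the output is then `molar` stage.
#' @param seed RNG seed (default 0).
#' @param scan_rate,conc,cell_volume acquisition metadata recorded in the
#'   output (defaults 1.5 K/min, 4e-6 M, 5.27e-4 L).
#' @return A [thermogram()] with attribute `truth` (list of `params`,
#'   `baseline`, `noise_sd`, `seed`).
#' @examples
#' apo <- two_state_params(62.5, 111.6, 96.3)
#' tg <- simulate_thermogram(apo, noise_sd = 0)
#' @export
simulate_thermogram <- function(params, grid = c(15, 95, 0.1),
                                noise_sd = 0.1, baseline = NULL,
                                seed = 0, scan_rate = 1.5,
                                conc = 4e-6, cell_volume = 5.27e-4) {
  stopifnot(length(grid) == 3, grid[3] > 0, noise_sd >= 0)
  tt <- seq(grid[1], grid[2], by = grid[3])
  cp <- two_state_excess_cp(tt, params)
  stage <- "excess"
  if (!is.null(baseline)) {
    theta <- unfolded_fraction(tt, params)
    pre <- baseline$pre[1] + baseline$pre[2] * tt
    post <- baseline$post[1] + baseline$post[2] * tt
    cp <- cp + (1 - theta) * pre + theta * post
    stage <- "molar"
  }
  if (noise_sd > 0) {
    cp <- cp + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  }
  tg <- thermogram(tt, cp, scan_rate = scan_rate, conc = conc,
                   cell_volume = cell_volume, stage = stage)
  attr(tg, "truth") <- list(params = params, baseline = baseline,
                            noise_sd = noise_sd, seed = seed)
  tg
}

#' Simulate a CD thermal melt
#'
#' @param params a [cd_melt_params()] object.
#' @param grid start, stop, step in degC (default 20-95 at 0.5).
#' @param noise_sd Gaussian noise SD in signal units (default 0).
#' @param seed RNG seed (default 0).
#' @return A data frame of class `melt_curve` with columns `temperature`
#'   and `signal`, attribute `truth`.
#' @export
simulate_cd_melt <- function(params, grid = c(20, 95, 0.5),
                             noise_sd = 0, seed = 0) {
  stopifnot(length(grid) == 3, grid[3] > 0, noise_sd >= 0)
  tt <- seq(grid[1], grid[2], by = grid[3])
  sig <- cd_two_state_signal(tt, params)
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  }
  out <- data.frame(temperature = tt, signal = sig)
  class(out) <- c("melt_curve", "data.frame")
  attr(out, "truth") <- list(params = params, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Simulate a Tm titration series
#'
#' Evaluates the single-site linkage model at each ligand concentration
#' and adds Gaussian noise to the melting temperatures.
#'
#' @param params a [linkage_params()] object.
#' @param concs non-negative ligand concentrations, mol/L.
#' @param noise_sd_tm Gaussian noise SD on Tm, K (default 0).
#' @param seed RNG seed (default 0).
#' @return Data frame of class `titration_series` with columns `conc` and
#'   `tm`, attribute `truth`.
#' @export
simulate_titration <- function(params, concs, noise_sd_tm = 0, seed = 0) {
  stopifnot(noise_sd_tm >= 0)
  tm <- ligand_shifted_tm(concs, params)
  if (noise_sd_tm > 0) {
    tm <- tm + with_seed(seed, stats::rnorm(length(tm), 0, noise_sd_tm))
  }
  out <- data.frame(conc = concs, tm = tm)
  class(out) <- c("titration_series", "data.frame")
  attr(out, "truth") <- list(params = params, noise_sd_tm = noise_sd_tm,
                             seed = seed)
  out
}

#' Deterministic toy structures for ASA validation
#'
#' Small coordinate sets with known surface-area behaviour:
#' \describe{
#'   \item{single_atom}{one carbon at the origin (analytic sphere area).}
#'   \item{far_pair}{two carbons 100 angstrom apart (no occlusion).}
#'   \item{caged_atom}{a carbon enclosed by 26 neighbours on a 2.5
#'     angstrom lattice shell (near-zero accessibility).}
#'   \item{mini_helix}{an ideal 20-residue poly-alanine alpha-helix
#'     (backbone N, CA, C, O plus CB; 100 degrees twist, 1.5 angstrom
#'     rise).}
#'   \item{two_chain}{two copies of `mini_helix` in chains A and B,
#'     60 angstrom apart (per-chain additivity).}
#' }
#'
#' @param kind one of the names above.
#' @return A [structure_model()].
#' @export
toy_structure <- function(kind = c("single_atom", "far_pair",
                                   "caged_atom", "mini_helix",
                                   "two_chain")) {
  kind <- match.arg(kind)
  atom_row <- function(element, x, y, z, resname = "UNK", resno = 1,
                       chain = "A") {
    data.frame(element = element, x = x, y = y, z = z,
               radius = vdw_radius(element), resname = resname,
               resno = resno, chain = chain, stringsAsFactors = FALSE)
  }
  if (kind == "single_atom") {
    return(structure_model(atom_row("C", 0, 0, 0)))
  }
  if (kind == "far_pair") {
    return(structure_model(rbind(atom_row("C", 0, 0, 0),
                                 atom_row("C", 100, 0, 0))))
  }
  if (kind == "caged_atom") {
    off <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    off <- off[!(off$x == 0 & off$y == 0 & off$z == 0), ]
    cage <- atom_row("C", 2.5 * off$x, 2.5 * off$y, 2.5 * off$z,
                     resno = 2)
    return(structure_model(rbind(atom_row("C", 0, 0, 0), cage)))
  }
  helix <- function(chain, shift) {
    rows <- list()
    # idealized alpha-helix: per-residue twist 100 deg, rise 1.5 A;
    # backbone atoms placed on coaxial cylinders with fixed phase offsets
    spec <- list(N = c(r = 1.55, dphi = -28, dz = -0.7),
                 CA = c(r = 2.30, dphi = 0, dz = 0),
                 C = c(r = 1.65, dphi = 27, dz = 0.8),
                 O = c(r = 2.00, dphi = 24, dz = 1.9),
                 CB = c(r = 3.30, dphi = -8, dz = -0.3))
    elem <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
    for (i in seq_len(20)) {
      base_phi <- (i - 1) * 100 * pi / 180
      base_z <- (i - 1) * 1.5
      for (a in names(spec)) {
        s <- spec[[a]]
        phi <- base_phi + s[["dphi"]] * pi / 180
        rows[[length(rows) + 1]] <- atom_row(
          elem[[a]],
          s[["r"]] * cos(phi) + shift,
          s[["r"]] * sin(phi),
          base_z + s[["dz"]],
          resname = "ALA", resno = i, chain = chain)
      }
    }
    do.call(rbind, rows)
  }
  if (kind == "mini_helix") {
    return(structure_model(helix("A", 0),
                           sequence = c(A = strrep("A", 20))))
  }
  structure_model(rbind(helix("A", 0), helix("B", 60)),
                  sequence = c(A = strrep("A", 20),
                               B = strrep("A", 20)))
}
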