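# Structure handling: PDB parsing, van der Waals radii, Shrake-Rupley
# accessible surface area, atom polarity classes, and the extended
# unfolded-state reference.

# cached constants tables (read once per session from inst/extdata)
.dscfit_cache <- new.env(parent = emptyenv())

read_constants_table <- function(file, col_names) {
  key <- file
  if (!is.null(.dscfit_cache[[key]])) return(.dscfit_cache[[key]])
  path <- system.file("extdata", file, package = "dscfit")
  if (path == "") path <- file.path("inst", "extdata", file)
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          col.names = col_names,
                          stringsAsFactors = FALSE)
  .dscfit_cache[[key]] <- df
  df
}

#' Van der Waals radius lookup
#'
#' Heavy-atom radii used by the ASA engine (C 1.70, N 1.55, O 1.52,
#' S 1.80 angstrom), read from the package's plain-text constants table.
#'
#' @param element character vector of element symbols.
#' @return Numeric radii, NA for unknown elements.
#' @export
vdw_radius <- function(element) {
  tab <- read_constants_table("vdw_radii.tsv", c("element", "radius"))
  tab$radius[match(toupper(element), tab$element)]
}

#' Build a structure model from atoms
#'
#' Low-level constructor used by [parse_structure()] and
#' [toy_structure()].
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`,
#'   `radius`, `resname`, `resno`, `chain`.
#' @param sequence named character vector of one-letter sequences per
#'   chain (may be empty for toy models).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, sequence = character()) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z", "radius",
                  "resname", "resno", "chain") %in% names(atoms)))
  if (nrow(atoms) > 0) {
    stopifnot_positive(atoms$radius, "radius")
    if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
      dscfit_stop("atom coordinates must be finite", "dscfit_invalid_input")
    }
  }
  structure(list(atoms = atoms, sequence = sequence),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d chain(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Parse a PDB file into a structure model
#'
#' Reads ATOM records (first model only) via `bio3d::read.pdb`. By
#' default HETATM records (ligands, waters) and hydrogens are excluded,
#' so only the protein heavy atoms enter downstream ASA calculations;
#' bound nucleotides therefore never contribute to the folded surface.
#' Alternate-location duplicates are resolved by highest occupancy, ties
#' by altloc `'A'` (then alphabetical).
#'
#' @param input path to a PDB file, or a character string/vector of PDB
#'   text.
#' @param include_hetatm keep non-water HETATM records (default FALSE).
#' @param chains optional character vector restricting to the given chain
#'   identifiers (e.g. to drop a bound partner chain).
#' @param on_unknown what to do with atoms whose element has no radius:
#'   `"skip"` (drop with a warning, default) or `"fail"`.
#' @return A [structure_model()] with per-chain one-letter sequences.
#' @export
parse_structure <- function(input, include_hetatm = FALSE, chains = NULL,
                            on_unknown = c("skip", "fail")) {
  on_unknown <- match.arg(on_unknown)
  path <- input
  if (length(input) > 1 || grepl("\n", input[1], fixed = TRUE) ||
      grepl("^(ATOM|HETATM|HEADER|MODEL)", input[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(input, "\n", fixed = TRUE)), path)
    on.exit(unlink(path))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]          # waters never kept
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  # element symbol: PDB column if present, else first letter of atom name
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[miss])), 1, 1)
  keep_h <- elem != "H" & elem != "D"                  # heavy atoms only
  at <- at[keep_h, , drop = FALSE]
  elem <- elem[keep_h]
  # resolve altlocs: highest occupancy wins, ties go to 'A'/alphabetical
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]
  radius <- vdw_radius(elem)
  if (anyNA(radius)) {
    bad <- unique(elem[is.na(radius)])
    if (on_unknown == "fail") {
      dscfit_stop(sprintf("unknown element(s): %s",
                          paste(bad, collapse = ", ")),
                  "dscfit_invalid_input")
    }
    warning(sprintf("skipping atoms with unknown element(s): %s",
                    paste(bad, collapse = ", ")))
    ok <- !is.na(radius)
    at <- at[ok, , drop = FALSE]
    elem <- elem[ok]
    radius <- radius[ok]
  }
  atoms <- data.frame(element = elem, x = at$x, y = at$y, z = at$z,
                      radius = radius, resname = at$resid,
                      resno = at$resno, chain = at$chain,
                      stringsAsFactors = FALSE)
  # one-letter sequence per chain from the ATOM residues
  seqs <- character()
  prot <- atoms[atoms$resname %in% names(.AA321), , drop = FALSE]
  for (ch in unique(prot$chain)) {
    sub <- prot[prot$chain == ch, , drop = FALSE]
    res <- sub[!duplicated(sub$resno), , drop = FALSE]
    seqs[ch] <- paste(.AA321[res$resname], collapse = "")
  }
  structure_model(atoms, sequence = seqs)
}

.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Deterministic golden-spiral lattice of n points on the unit sphere.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley accessible surface area
#'
#' Solvent-accessible surface area by the Shrake-Rupley point-counting
#' method: each atom's solvent-expanded sphere (van der Waals radius plus
#' probe radius) is covered with a deterministic golden-spiral lattice of
#' test points, and the accessible area is the expanded-sphere area times
#' the fraction of points not buried inside any neighbouring atom's
#' expanded sphere. The lattice is fixed, so results are reproducible
#' bit-for-bit.
#'
#' @param structure a [structure_model()].
#' @param probe_radius solvent probe radius, angstrom (default 1.4).
#' @param n_points number of lattice points per atom (default 960,
#'   minimum 100).
#' @return An object of class `asa_breakdown`: list with `apolar` and
#'   `polar` totals (angstrom^2), the `per_atom` vector and `total`.
#' @examples
#' iso <- toy_structure("single_atom")
#' shrake_rupley_asa(iso)$total   # 4*pi*(1.70+1.4)^2
#' @export
shrake_rupley_asa <- function(structure, probe_radius = 1.4,
                              n_points = 960) {
  if (n_points < 100) {
    dscfit_stop("n_points must be at least 100", "dscfit_invalid_input")
  }
  at <- structure$atoms
  n <- nrow(at)
  pts <- sphere_lattice(n_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rexp <- at$radius + probe_radius
  area <- numeric(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      # candidate occluders: expanded spheres that can reach atom i's shell
      d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
        (xyz[, 3] - xyz[i, 3])^2
      nb <- which(d2 < (rexp[i] + rexp)^2 & seq_len(n) != i)
      p <- pts * rexp[i]
      p[, 1] <- p[, 1] + xyz[i, 1]
      p[, 2] <- p[, 2] + xyz[i, 2]
      p[, 3] <- p[, 3] + xyz[i, 3]
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
          (p[acc, 3] - xyz[j, 3])^2
        acc[acc] <- dj2 >= rexp[j]^2
      }
      area[i] <- 4 * pi * rexp[i]^2 * sum(acc) / n_points
    }
  }
  pol <- classify_polarity(at$element)
  asa_breakdown(apolar = sum(area[pol == "apolar"]),
                polar = sum(area[pol == "polar"]),
                per_atom = area)
}

#' ASA breakdown container
#'
#' @param apolar apolar (carbon, sulfur) area, angstrom^2.
#' @param polar polar (nitrogen, oxygen) area, angstrom^2.
#' @param per_atom optional per-atom (or per-residue) areas whose sum
#'   must equal `apolar + polar`.
#' @return Object of class `asa_breakdown`.
#' @export
asa_breakdown <- function(apolar, polar, per_atom = NULL) {
  if (apolar < 0 || polar < 0) {
    dscfit_stop("areas must be non-negative", "dscfit_invalid_input")
  }
  if (!is.null(per_atom) &&
      abs(sum(per_atom) - (apolar + polar)) > 1e-6) {
    dscfit_stop("per_atom areas do not sum to apolar + polar",
                "dscfit_invalid_input")
  }
  structure(list(apolar = apolar, polar = polar, per_atom = per_atom,
                 total = apolar + polar),
            class = "asa_breakdown")
}

#' @export
print.asa_breakdown <- function(x, ...) {
  cat(sprintf("ASA: apolar %.1f + polar %.1f = %.1f A^2\n",
              x$apolar, x$polar, x$total))
  invisible(x)
}

#' Polarity class of a heavy atom
#'
#' Standard structure-energetics convention: carbon and sulfur surface is
#' apolar, nitrogen and oxygen surface is polar. Hydrogens are absent
#' under the heavy-atom convention.
#'
#' @param element character vector of element symbols.
#' @return Character vector, `"apolar"` or `"polar"`.
#' @export
classify_polarity <- function(element) {
  el <- toupper(element)
  out <- ifelse(el %in% c("C", "S"), "apolar",
                ifelse(el %in% c("N", "O"), "polar", NA_character_))
  if (anyNA(out)) {
    dscfit_stop(sprintf("no polarity class for element(s): %s",
                        paste(unique(el[is.na(out)]), collapse = ", ")),
                "dscfit_invalid_input")
  }
  out
}

#' Unfolded-state reference surface area of a sequence
#'
#' The unfolded state is modelled as fully solvated residues with the
#' accessibility each amino acid has as the central residue of an
#' extended Gly-X-Gly tripeptide; the per-residue apolar/polar areas are
#' read from the package's plain-text reference table and summed over the
#' sequence.
#'
#' @param sequence one-letter amino-acid string (or character vector of
#'   strings, summed together).
#' @param on_nonstandard `"fail"` (default) or `"skip"` unknown letters.
#' @return An [asa_breakdown()] with per-residue areas in `$per_atom`.
#' @export
unfolded_reference_asa <- function(sequence,
                                   on_nonstandard = c("fail", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  tab <- read_constants_table(
    "unfolded_reference_asa.tsv", c("aa1", "aa3", "apolar", "polar"))
  letters1 <- strsplit(toupper(paste(sequence, collapse = "")), "")[[1]]
  idx <- match(letters1, tab$aa1)
  if (anyNA(idx)) {
    bad <- unique(letters1[is.na(idx)])
    if (on_nonstandard == "fail") {
      dscfit_stop(sprintf("non-standard residue(s): %s",
                          paste(bad, collapse = ", ")),
                  "dscfit_invalid_input")
    }
    warning(sprintf("skipping non-standard residue(s): %s",
                    paste(bad, collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  ap <- tab$apolar[idx]
  po <- tab$polar[idx]
  asa_breakdown(apolar = sum(ap), polar = sum(po), per_atom = ap + po)
}

#' Surface-area change upon unfolding
#'
#' @param folded [asa_breakdown()] of the folded structure.
#' @param unfolded [asa_breakdown()] of the unfolded reference (e.g.
#'   [unfolded_reference_asa()]).
#' @return List with `dasa_ap` and `dasa_pol` (unfolded minus folded,
#'   angstrom^2); both positive for compact folds.
#' @export
delta_asa <- function(folded, unfolded) {
  list(dasa_ap = unfolded$apolar - folded$apolar,
       dasa_pol = unfolded$polar - folded$polar)
}
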