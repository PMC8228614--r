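#' Template alignment specification
#'
#' The shared rigid scaffold of all phthalate esters is the
#' benzene-1,2-dicarboxylate core (12 heavy atoms: ring + two carboxylate
#' carbons and four oxygens). All compounds are superposed onto the
#' template molecule (DMP by default) by least squares over this core.
#'
#' The carboxylate ester linkage has two near-degenerate twist states;
#' letting every compound keep its global energy minimum can split a
#' homologous series into two misaligned core clusters. With
#' `conformer_select = "best_core_fit"` (the default) each compound
#' picks, among its minimized conformers within `energy_window`
#' kcal/mol of its minimum, the one whose core superposes best on the
#' template; `"lowest_energy"` always keeps the global minimum.
#'
#' @param template abbreviation of the template compound
#' @param min_core_atoms minimum number of matched core atoms accepted
#' @param conformer_select `"best_core_fit"` or `"lowest_energy"`
#' @param energy_window kcal/mol window above the per-compound minimum
#'   inside which conformers are eligible for core-fit selection
#' @return a `pae_alignment_spec`
#' @export
alignment_spec <- function(template = "DMP", min_core_atoms = 8L,
                           conformer_select = c("best_core_fit",
                                                "lowest_energy"),
                           energy_window = 5.0) {
  structure(list(template = template,
                 min_core_atoms = as.integer(min_core_atoms),
                 conformer_select = match.arg(conformer_select),
                 energy_window = energy_window),
            class = "pae_alignment_spec")
}

# Kabsch: least-squares rotation (proper, det +1) + translation mapping
# point set P onto Q (both n x 3). Returns the transform applied to P.
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_from = cp, center_to = cq)
}

apply_rigid <- function(X, tr) {
  sweep(sweep(X, 2, tr$center_from) %*% t(tr$R), 2, tr$center_to, "+")
}

rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# Canonical reference core ordering of a molecule: the lexicographically
# smallest of its symmetry-equivalent core matches.
reference_core <- function(mol) {
  if (!length(mol$core_matches)) {
    stop(mol$abbrev, ": no phthalate core match; cannot align", call. = FALSE)
  }
  keys <- vapply(mol$core_matches,
                 function(m) paste(sprintf("%05d", m), collapse = ","), "")
  mol$core_matches[[order(keys)[1L]]]
}

#' Rigidly align a molecule onto the template via the phthalate core
#'
#' Finds the least-squares rigid superposition of the molecule's core
#' atoms onto the template's, trying every symmetry-equivalent core
#' mapping (the two ester arms are interchangeable) and keeping the one
#' with the smallest core RMSD; ties break on the canonical (sorted)
#' match order. All atoms are carried by the chosen rigid transform.
#'
#' If the molecule carries its minimized conformer set (see
#' [embed_compounds()]) and the spec asks for `"best_core_fit"`, the
#' conformer used is the one -- within the spec's energy window above
#' the compound's minimum -- whose core RMSD to the template is
#' smallest.
#'
#' @param mol,template `pae_molecule` objects carrying `core_matches`
#' @param spec an [alignment_spec()]
#' @return `mol` with transformed coordinates and attributes
#'   `core_rmsd` (Angstrom) and `core_match` (atom indices used)
#' @export
align_to_template <- function(mol, template, spec = alignment_spec()) {
  tref <- reference_core(template)
  if (length(tref) < spec$min_core_atoms) {
    stop("template core smaller than min_core_atoms", call. = FALSE)
  }
  tmat <- coords(template)[tref, , drop = FALSE]
  if (!length(mol$core_matches)) {
    stop(mol$abbrev, ": no phthalate core match; cannot align", call. = FALSE)
  }
  keys <- vapply(mol$core_matches,
                 function(m) paste(sprintf("%05d", m), collapse = ","), "")
  matches <- mol$core_matches[order(keys)]

  candidates <- list(coords(mol))
  energies <- 0
  if (spec$conformer_select == "best_core_fit" &&
      length(mol$conformers %||% list()) > 1L) {
    e <- vapply(mol$conformers, `[[`, 0, "energy_post")
    # extended-mode conformers are the deliberate ester-twist variants
    # of one sketch: all are eligible regardless of energy
    keep <- if (identical(mol$provenance$mode, "extended")) {
      rep(TRUE, length(e))
    } else {
      e <= min(e) + spec$energy_window
    }
    candidates <- lapply(mol$conformers[keep], `[[`, "xyz")
    energies <- e[keep]
  }

  best <- NULL
  for (ci in seq_along(candidates)) {
    xyz <- candidates[[ci]]
    for (m in matches) {
      if (length(m) != length(tref)) next
      tr <- kabsch(xyz[m, , drop = FALSE], tmat)
      r <- rmsd(apply_rigid(xyz[m, , drop = FALSE], tr), tmat)
      if (is.null(best) || r < best$r - 1e-12) {
        best <- list(tr = tr, r = r, m = m, xyz = xyz,
                     energy = energies[ci])
      }
    }
  }
  if (is.null(best)) {
    stop(mol$abbrev, ": no core mapping of matching size", call. = FALSE)
  }
  coords(mol) <- apply_rigid(best$xyz, best$tr)
  attr(mol, "core_rmsd") <- best$r
  attr(mol, "core_match") <- best$m
  mol
}

#' Align a set of molecules onto a common template
#'
#' @param mols named list of `pae_molecule`
#' @param spec an [alignment_spec()]; the template molecule must be
#'   present in `mols` (it is aligned onto itself, a no-op up to
#'   round-off)
#' @return the list with all coordinates superposed; per-molecule core
#'   RMSDs in `attr(, "core_rmsd")`
#' @export
align_ensemble <- function(mols, spec = alignment_spec()) {
  if (!spec$template %in% names(mols)) {
    stop("template ", spec$template, " not among molecules", call. = FALSE)
  }
  template <- mols[[spec$template]]
  out <- lapply(mols, align_to_template, template = template, spec = spec)
  attr(out, "core_rmsd") <- vapply(out, function(m) attr(m, "core_rmsd"), 0)
  out
}

#' Write molecules as a multi-record V2000 SDF
#'
#' Coordinates in Angstrom; Gasteiger charges, hydrophobicity weights and
#' donor/acceptor flags as SDF data fields (one value per atom line).
#' Bond blocks are omitted (atom-only records): the downstream field
#' calculations use atoms, charges and coordinates only.
#'
#' @param mols named list of `pae_molecule`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms
    writeLines(c(mol$abbrev, "  paeqsar aligned ensemble", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), 0L), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    writeLines("M  END", con)
    writeLines(c("> <GASTEIGER_CHARGES>",
                 paste(sprintf("%.6f", at$charge), collapse = " "), ""), con)
    if (!is.null(at$hydro)) {
      writeLines(c("> <HYDROPHOBICITY>",
                   paste(sprintf("%.6f", at$hydro), collapse = " "), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
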