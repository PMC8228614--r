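#' @noRd
python_binary <- function() {
  py <- Sys.getenv("PAEQSAR_PYTHON", Sys.which("python"))
  if (!nzchar(py)) {
    stop("no 'python' on PATH; an RDKit-enabled Python is required ",
         "for conformer generation", call. = FALSE)
  }
  py
}

new_pae_molecule <- function(abbrev, atoms, provenance,
                             core_matches = list(),
                             energy = c(pre = NA_real_, post = NA_real_)) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  structure(list(abbrev = abbrev, atoms = atoms, provenance = provenance,
                 core_matches = core_matches, energy = energy),
            class = "pae_molecule")
}

#' @export
print.pae_molecule <- function(x, ...) {
  cat(sprintf("<pae_molecule %s> %d atoms (%d heavy)",
              x$abbrev, nrow(x$atoms), sum(x$atoms$element != "H")))
  if (is.finite(x$energy[["post"]])) {
    cat(sprintf(", E = %.2f kcal/mol", x$energy[["post"]]))
  }
  cat("\n")
  invisible(x)
}

#' @noRd
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' @noRd
`coords<-` <- function(mol, value) {
  mol$atoms[, c("x", "y", "z")] <- value
  mol
}

#' Embed and minimize a batch of compounds (one Python call)
#'
#' Generates minimized 3D structures by distance-geometry embedding
#' followed by MMFF94 minimization (gradient tolerance 0.005
#' kcal/(mol*A), at most 1000 iterations -- the published optimization
#' settings; MMFF94 stands in for the unavailable Tripos force field).
#' Gasteiger charges stand in for Gasteiger-Huckel; Crippen atomic logP
#' contributions provide the CoMSIA hydrophobicity weights; O/N atoms
#' are hydrogen-bond acceptors and O-H/N-H donors. Deterministic: the
#' same (smiles, seed, mode) always yields identical coordinates.
#'
#' Two conformer strategies:
#' * `mode = "extended"` (default): one starting geometry with every
#'   acyclic torsion set to 180 degrees, then locally minimized. This
#'   emulates building each ester from a sketch and running a local
#'   optimizer -- chains stay extended, so a homologous series stays
#'   conformationally consistent.
#' * `mode = "ensemble"`: `n_confs` stochastic conformers are embedded
#'   and all minimized; the lowest-energy one provides the default
#'   coordinates and the full set is kept on the molecule for
#'   energy-window/core-fit selection at alignment time.
#'
#' @param smiles named character vector (names = compound abbreviations)
#' @param seed integer random seed for the distance-geometry embed
#' @param max_iter iteration cap for minimization
#' @param force_tol gradient termination threshold, kcal/(mol*A)
#' @param n_confs conformers embedded per compound in `"ensemble"` mode
#' @param mode conformer strategy, see above
#' @return named list of `pae_molecule` objects. Each carries the atom
#'   table (element, x/y/z in Angstrom, Gasteiger charge in e, `hydro`,
#'   `donor`, `acceptor`), MMFF energies before/after minimization, and
#'   all symmetry-equivalent matches of the phthalate diester core
#'   (1-based atom indices) when present.
#' @export
embed_compounds <- function(smiles, seed = 42L, max_iter = 1000L,
                            force_tol = 0.005, n_confs = 60L,
                            mode = c("extended", "ensemble")) {
  mode <- match.arg(mode)
  stopifnot(length(smiles) >= 1, !is.null(names(smiles)),
            all(nzchar(names(smiles))))
  job <- list(
    compounds = lapply(seq_along(smiles), function(i) {
      list(abbrev = names(smiles)[i], smiles = unname(smiles[i]))
    }),
    seed = as.integer(seed), max_iter = as.integer(max_iter),
    force_tol = force_tol, n_confs = as.integer(n_confs),
    mode = mode
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(job, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(python_binary(),
                    c(pae_file("python", "embed_pae.py"), fin, fout),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout)) {
    stop("embedding backend failed (exit status ", status, ")",
         call. = FALSE)
  }
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  mols <- lapply(res, function(r) {
    if (!is.null(r$error)) {
      stop("embedding failed for ", r$abbrev, ": ", r$error, call. = FALSE)
    }
    atoms <- do.call(rbind, lapply(r$atoms, function(a) {
      data.frame(element = a$element, x = a$x, y = a$y, z = a$z,
                 charge = a$charge, hydro = a$hydro,
                 donor = as.logical(a$donor), acceptor = as.logical(a$acceptor),
                 stringsAsFactors = FALSE)
    }))
    conformers <- lapply(r$conformers, function(cf) {
      xyz <- do.call(rbind, lapply(cf$coords, unlist))
      list(xyz = xyz, energy_pre = cf$energy_pre,
           energy_post = cf$energy_post,
           converged = as.logical(cf$converged))
    })
    mol <- new_pae_molecule(
      abbrev = r$abbrev, atoms = atoms,
      provenance = list(smiles = r$smiles, seed = as.integer(seed),
                        max_iter = as.integer(max_iter),
                        force_tol = force_tol,
                        n_confs = as.integer(n_confs), mode = mode,
                        converged = as.logical(r$converged),
                        backend = "rdkit/ETKDGv3+MMFF94",
                        formal_charge = r$formal_charge),
      core_matches = lapply(r$core_matches, function(m) unlist(m) + 1L),
      energy = c(pre = r$energy_pre, post = r$energy_post)
    )
    mol$conformers <- conformers   # sorted by minimized energy
    check_charge_sum(mol)
    mol
  })
  setNames(mols, vapply(mols, `[[`, "", "abbrev"))
}

#' Embed and minimize a single compound
#'
#' Convenience wrapper around [embed_compounds()].
#'
#' @param smiles a single SMILES string
#' @param seed integer seed
#' @param abbrev compound label used in messages and downstream tables
#' @param ... passed to [embed_compounds()]
#' @return a `pae_molecule`
#' @export
embed_and_minimize <- function(smiles, seed = 42L, abbrev = "MOL", ...) {
  embed_compounds(setNames(smiles, abbrev), seed = seed, ...)[[1L]]
}

check_charge_sum <- function(mol, tol = 1e-3) {
  total <- sum(mol$atoms$charge)
  formal <- mol$provenance$formal_charge %||% 0
  if (abs(total - formal) > tol) {
    stop(sprintf("%s: partial charges sum to %.4f, formal charge %d",
                 mol$abbrev, total, formal), call. = FALSE)
  }
  invisible(mol)
}

# Fallback hydrophobicity weights (rough Crippen-like atomic logP
# contributions) used only for molecules built by hand in R.
DEFAULT_HYDRO <- c(C = 0.14, H = 0.03, O = -0.25, N = -0.60, S = 0.25,
                   F = 0.22, Cl = 0.64, Br = 0.81, P = -0.5)

#' Ensure a molecule carries the CoMSIA atom-property weights
#'
#' Validates Gasteiger charges (must sum to the formal molecular charge
#' within 1e-3 e) and fills in any missing hydrophobicity weights or
#' H-bond donor/acceptor flags using simple element rules: O and N are
#' acceptors; O-H and N-H (explicit H neighbor information is not kept,
#' so a `has_h` column or backend flags are used) are donors. Molecules
#' from [embed_compounds()] already carry backend-derived annotations and
#' pass through unchanged apart from validation.
#'
#' @param mol a `pae_molecule` with at least `element` and `charge`
#' @return the annotated molecule
#' @export
assign_atom_weights <- function(mol) {
  at <- mol$atoms
  if (is.null(at$charge)) {
    stop(mol$abbrev, ": no partial charges; embed first", call. = FALSE)
  }
  unknown <- setdiff(unique(at$element), c(names(DEFAULT_HYDRO)))
  if (is.null(at$hydro)) {
    if (length(unknown)) {
      stop("no hydrophobicity parameters for element(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    at$hydro <- unname(DEFAULT_HYDRO[at$element])
  }
  if (is.null(at$acceptor)) at$acceptor <- at$element %in% c("O", "N")
  if (is.null(at$donor)) {
    has_h <- if (!is.null(at$has_h)) at$has_h else FALSE
    at$donor <- at$element %in% c("O", "N") & has_h
  }
  mol$atoms <- at
  check_charge_sum(mol)
  mol
}
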