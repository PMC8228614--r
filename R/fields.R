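# Lennard-Jones parameters per element (Tripos-style): van der Waals
# radius R (Angstrom) and well depth eps (kcal/mol). Unlisted elements
# raise an error rather than defaulting silently.
LJ_PARAMS <- data.frame(
  element = c("C", "H", "O", "N", "S", "P", "F", "Cl", "Br"),
  r       = c(1.70, 1.50, 1.52, 1.55, 1.80, 1.80, 1.47, 1.75, 1.85),
  eps     = c(0.107, 0.042, 0.116, 0.095, 0.314, 0.314, 0.109, 0.314, 0.434),
  stringsAsFactors = FALSE
)

lj_lookup <- function(elements) {
  idx <- match(elements, LJ_PARAMS$element)
  if (anyNA(idx)) {
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  LJ_PARAMS[idx, ]
}

#' Probe specification for field evaluation
#'
#' The CoMFA probe is an sp3 carbon with +1 e charge; the CoMSIA probe
#' carries unit weight in every property. `alpha` is the CoMSIA Gaussian
#' attenuation factor (1/Angstrom^2) and `cutoff` the CoMFA energy
#' truncation (kcal/mol).
#'
#' @param steric_r,steric_eps probe LJ radius (A) and well depth (kcal/mol)
#' @param charge probe charge, e
#' @param hydro,donor,acceptor CoMSIA probe weights
#' @param alpha CoMSIA attenuation, default 0.3
#' @param cutoff CoMFA truncation, default 30
#' @return a `pae_probe_spec`
#' @export
probe_spec <- function(steric_r = 1.70, steric_eps = 0.107, charge = 1,
                       hydro = 1, donor = 1, acceptor = 1,
                       alpha = 0.3, cutoff = 30) {
  stopifnot(alpha > 0, cutoff > 0)
  structure(list(steric_r = steric_r, steric_eps = steric_eps,
                 charge = charge, hydro = hydro, donor = donor,
                 acceptor = acceptor, alpha = alpha, cutoff = cutoff),
            class = "pae_probe_spec")
}

#' Build a rectangular grid enclosing an aligned ensemble
#'
#' The box is the union of atom bounding boxes expanded by `margin` on
#' every side, snapped outward to multiples of `spacing`. Grid points are
#' enumerated in fixed lexicographic order with x varying fastest, then
#' y, then z.
#'
#' @param mols list of aligned `pae_molecule` (or a single molecule)
#' @param spacing grid step, Angstrom (default 2.0)
#' @param margin box padding, Angstrom (default 4.0)
#' @return a `pae_grid` with `origin`, `spacing`, `dims`
#' @export
build_grid <- function(mols, spacing = 2.0, margin = 4.0) {
  if (inherits(mols, "pae_molecule")) mols <- list(mols)
  if (!length(mols)) stop("build_grid() needs at least one molecule",
                          call. = FALSE)
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- unname(floor((apply(xyz, 2, min) - margin) / spacing)) * spacing
  hi <- unname(ceiling((apply(xyz, 2, max) + margin) / spacing)) * spacing
  dims <- as.integer(round((hi - lo) / spacing)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "pae_grid")
}

#' Grid point coordinates in canonical order
#'
#' @param grid a `pae_grid`
#' @return n_points x 3 matrix; row order is x fastest, then y, then z
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k) {
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1L)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  pts
}

#' @export
print.pae_grid <- function(x, ...) {
  cat(sprintf("<pae_grid> %d x %d x %d points, spacing %.2f A, origin (%.1f, %.1f, %.1f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# squared distances between grid points (n_g x 3) and atoms (n_a x 3)
dist2_grid_atoms <- function(G, A) {
  d2 <- outer(rowSums(G^2), rowSums(A^2), "+") - 2 * G %*% t(A)
  pmax(d2, 0)
}

#' CoMFA steric and electrostatic fields of one molecule
#'
#' Steric: sum over atoms of the 6-12 Lennard-Jones interaction with an
#' sp3 carbon probe, truncated at +/- cutoff; points whose untruncated
#' steric energy reaches the cutoff are "sterically excluded".
#' Electrostatic: Coulomb term 332.0 * q_probe * q_i / (eps(r) * r) with
#' distance-dependent dielectric eps(r) = r, i.e. 332 q q / r^2; at
#' excluded points the returned electrostatic value is replaced by the
#' mean over this molecule's non-excluded points (the raw values and the
#' exclusion mask are also returned so an ensemble assembly can apply
#' the across-compound column-mean convention instead).
#'
#' @param mol a `pae_molecule` with coordinates and charges
#' @param grid a `pae_grid`
#' @param probe a [probe_spec()]
#' @return list with numeric vectors `steric`, `electrostatic`,
#'   `electrostatic_raw` and logical `excluded`, all of length
#'   `prod(grid$dims)`
#' @export
comfa_fields <- function(mol, grid, probe = probe_spec()) {
  G <- grid_points(grid)
  A <- coords(mol)
  lj <- lj_lookup(mol$atoms$element)
  d2 <- dist2_grid_atoms(G, A)
  r <- sqrt(d2)

  Rij <- matrix(lj$r + probe$steric_r, nrow(G), nrow(A), byrow = TRUE)
  epsij <- matrix(sqrt(lj$eps * probe$steric_eps), nrow(G), nrow(A),
                  byrow = TRUE)
  # guard r = 0 (probe on top of an atom): ratio -> Inf, truncated below
  rr <- pmax(r, 1e-6)
  frac6 <- (Rij / rr)^6
  steric_raw <- rowSums(epsij * (frac6^2 - 2 * frac6))
  excluded <- steric_raw >= probe$cutoff
  steric <- pmin(pmax(steric_raw, -probe$cutoff), probe$cutoff)

  q <- mol$atoms$charge
  relec <- pmax(r, 0.1)           # floor keeps near-contact terms finite
  elec_raw <- 332.0 * probe$charge * as.vector((1 / relec^2) %*% q)
  # electrostatics are truncated at +/- cutoff like the steric field,
  # then overwritten inside the steric envelope
  elec_raw <- pmin(pmax(elec_raw, -probe$cutoff), probe$cutoff)
  elec <- elec_raw
  if (any(excluded)) {
    fill <- if (all(excluded)) 0 else mean(elec_raw[!excluded])
    elec[excluded] <- fill
  }
  list(steric = steric, electrostatic = elec,
       electrostatic_raw = elec_raw, excluded = excluded)
}

#' CoMSIA similarity-index fields of one molecule
#'
#' For each property F and grid point q, the index is
#' A_F(q) = -sum_i w_probe * w_i * exp(-alpha * r_iq^2): a smooth,
#' everywhere-finite Gaussian overlap needing no cutoff. Property
#' weights: steric uses atomic volume (vdW radius cubed), electrostatic
#' the Gasteiger charge, hydrophobic the atomic logP contribution, and
#' donor/acceptor the 0/1 flags.
#'
#' @inheritParams comfa_fields
#' @return list of numeric vectors `S`, `E`, `H`, `D`, `A`
#' @export
comsia_fields <- function(mol, grid, probe = probe_spec()) {
  at <- mol$atoms
  need <- c("charge", "hydro", "donor", "acceptor")
  if (!all(need %in% names(at))) {
    stop(mol$abbrev, ": missing atom annotations (",
         paste(setdiff(need, names(at)), collapse = ", "),
         "); run assign_atom_weights()", call. = FALSE)
  }
  G <- grid_points(grid)
  d2 <- dist2_grid_atoms(G, coords(mol))
  K <- exp(-probe$alpha * d2)     # n_g x n_a Gaussian kernel
  lj <- lj_lookup(at$element)
  w <- list(S = probe$steric_eps^0 * lj$r^3,   # volume-like weight
            E = at$charge,
            H = at$hydro,
            D = as.numeric(at$donor),
            A = as.numeric(at$acceptor))
  pw <- c(S = 1, E = probe$charge, H = probe$hydro,
          D = probe$donor, A = probe$acceptor)
  out <- lapply(names(w), function(f) -pw[[f]] * as.vector(K %*% w[[f]]))
  setNames(out, names(w))
}

new_field_block <- function(kind, values, mask = NULL) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(kind = kind, values = values,
                 mask = mask %||% rep(TRUE, ncol(values)),
                 scale = NA_real_),
            class = "pae_field_block")
}

#' @export
print.pae_field_block <- function(x, ...) {
  cat(sprintf("<pae_field_block %s> %d compounds x %d points (%d retained)\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Evaluate CoMFA field blocks for an aligned ensemble
#'
#' Electrostatic values at sterically excluded points are replaced by the
#' across-compound column mean of the non-excluded values (0 where every
#' compound is excluded), so that buried grid points do not inject huge
#' Coulomb terms into the PLS.
#'
#' @param mols named list of aligned `pae_molecule`
#' @inheritParams comfa_fields
#' @return named list of `pae_field_block`: `CoMFA_S`, `CoMFA_E`
#' @export
comfa_blocks <- function(mols, grid, probe = probe_spec()) {
  per <- lapply(mols, comfa_fields, grid = grid, probe = probe)
  S <- do.call(rbind, lapply(per, `[[`, "steric"))
  E <- do.call(rbind, lapply(per, `[[`, "electrostatic_raw"))
  X <- do.call(rbind, lapply(per, `[[`, "excluded"))
  rownames(S) <- rownames(E) <- names(mols)
  for (j in seq_len(ncol(E))) {
    excl <- X[, j]
    if (any(excl)) {
      E[excl, j] <- if (all(excl)) 0 else mean(E[!excl, j])
    }
  }
  list(CoMFA_S = new_field_block("CoMFA_S", S),
       CoMFA_E = new_field_block("CoMFA_E", E))
}

#' Evaluate CoMSIA field blocks for an aligned ensemble
#'
#' @param mols named list of aligned, annotated `pae_molecule`
#' @param fields subset of `c("S","E","H","D","A")`
#' @inheritParams comfa_fields
#' @return named list of `pae_field_block` (`CoMSIA_S`, ...)
#' @export
comsia_blocks <- function(mols, grid, probe = probe_spec(),
                          fields = c("S", "E", "H", "D", "A")) {
  fields <- match.arg(fields, several.ok = TRUE)
  per <- lapply(mols, comsia_fields, grid = grid, probe = probe)
  out <- lapply(fields, function(f) {
    M <- do.call(rbind, lapply(per, `[[`, f))
    rownames(M) <- names(mols)
    new_field_block(paste0("CoMSIA_", f), M)
  })
  setNames(out, paste0("CoMSIA_", fields))
}

#' Default minimum-sigma column filter threshold per field kind
#'
#' 2.0 (kcal/mol) for CoMFA energies, 0.1 for the dimensionless CoMSIA
#' similarity indices.
#' @param kind field kind string
#' @return numeric threshold
#' @export
default_min_sigma <- function(kind) {
  if (startsWith(kind, "CoMFA")) 2.0 else 0.1
}

#' Mask low-variance descriptor columns
#'
#' Columns whose standard deviation across compounds falls below
#' `min_sigma` are masked out of the modeling matrix (the mask is kept so
#' contour values can be mapped back to the full grid).
#'
#' @param block a `pae_field_block`
#' @param min_sigma threshold; `NULL` uses [default_min_sigma()]
#' @return the block with its `mask` updated
#' @export
filter_columns <- function(block, min_sigma = NULL) {
  min_sigma <- min_sigma %||% default_min_sigma(block$kind)
  sds <- apply(block$values, 2, sd)
  mask <- sds >= min_sigma   # min_sigma = 0 retains everything
  if (!any(mask)) {
    stop(block$kind, ": every column masked at min_sigma = ", min_sigma,
         "; lower the threshold", call. = FALSE)
  }
  block$mask <- mask
  block
}

#' Assemble filtered field blocks into one descriptor matrix
#'
#' Retained columns of each block are concatenated; each block is divided
#' by the overall standard deviation of its retained entries (CoMFA-style
#' block scaling, so no field dominates purely by variance). The index
#' map is a bijection from descriptor columns to (field kind, grid point).
#'
#' @param blocks named list of filtered `pae_field_block` sharing grid
#'   and compound order
#' @param scale logical; divide each block by its overall sd
#' @return a `pae_descriptors`: `X` (compounds x columns), `map`
#'   (data.frame column/field/point), `scales`, `masks`
#' @export
assemble_descriptors <- function(blocks, scale = TRUE) {
  rows <- lapply(blocks, function(b) rownames(b$values))
  if (length(unique(vapply(rows, paste, "", collapse = "|"))) != 1L) {
    stop("blocks disagree on compound order", call. = FALSE)
  }
  pieces <- list(); maps <- list(); scales <- numeric(0)
  for (b in blocks) {
    vals <- b$values[, b$mask, drop = FALSE]
    sc <- if (scale) sd(as.vector(vals)) else 1
    if (!is.finite(sc) || sc == 0) sc <- 1
    pieces[[b$kind]] <- vals / sc
    scales[b$kind] <- sc
    maps[[b$kind]] <- data.frame(field = b$kind, point = which(b$mask),
                                 stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, pieces)
  map <- do.call(rbind, maps)
  map$column <- seq_len(nrow(map))
  rownames(map) <- NULL
  colnames(X) <- sprintf("%s.%d", map$field, map$point)
  structure(list(X = X, map = map, scales = scales,
                 masks = lapply(blocks, `[[`, "mask"),
                 compounds = rows[[1L]]),
            class = "pae_descriptors")
}

#' @export
print.pae_descriptors <- function(x, ...) {
  cat(sprintf("<pae_descriptors> %d compounds x %d columns (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(names(x$scales), collapse = ", ")))
  invisible(x)
}

#' Write one field's grid values in the plain-text grid-map format
#'
#' Three comment header lines (origin, spacing, dims) followed by one
#' value per line in the canonical lexicographic point order.
#'
#' @param values numeric vector, length `prod(grid$dims)`
#' @param grid a `pae_grid`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_grid_map <- function(values, grid, path) {
  stopifnot(length(values) == prod(grid$dims))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin: %.6f %.6f %.6f", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("# spacing: %.6f", grid$spacing),
               sprintf("# dims: %d %d %d", grid$dims[1], grid$dims[2],
                       grid$dims[3]),
               sprintf("%.10g", values)), con)
  invisible(path)
}

#' @rdname write_grid_map
#' @export
read_grid_map <- function(path) {
  lines <- readLines(path)
  origin <- as.numeric(strsplit(sub("# origin: ", "", lines[1]), " ")[[1]])
  spacing <- as.numeric(sub("# spacing: ", "", lines[2]))
  dims <- as.integer(strsplit(sub("# dims: ", "", lines[3]), " ")[[1]])
  grid <- structure(list(origin = origin, spacing = spacing, dims = dims),
                    class = "pae_grid")
  list(grid = grid, values = as.numeric(lines[-(1:3)]))
}

#' Export a descriptor matrix with its JSON sidecar
#'
#' The matrix goes to gzip-compressed CSV; grid, probe, per-block masks
#' and scales go to a JSON sidecar next to it.
#'
#' @param desc a `pae_descriptors`
#' @param grid,probe the grid and probe used to build it
#' @param path output `.csv.gz` path; sidecar is `path` + `.json`
#' @return `path`, invisibly
#' @export
write_descriptors <- function(desc, grid, probe, path) {
  con <- gzfile(path, "w")
  write.csv(data.frame(compound = desc$compounds, desc$X,
                       check.names = FALSE),
            con, row.names = FALSE)
  close(con)
  sidecar <- list(grid = unclass(grid), probe = unclass(probe),
                  scales = as.list(desc$scales),
                  masks = lapply(desc$masks, which))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
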