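# Shared fixtures. Embedding goes through the RDKit backend once per
# test run and is memoized here; everything else is built in code.

.pae_cache <- new.env(parent = emptyenv())

# aligned ensemble of all 14 registry compounds (seed 42, defaults)
pae_test_ensemble <- function() {
  if (is.null(.pae_cache$ensemble)) {
    reg <- load_pae_registry()
    mols <- embed_compounds(setNames(reg$smiles, reg$abbrev), seed = 42L)
    .pae_cache$ensemble <- align_ensemble(mols)
  }
  .pae_cache$ensemble
}

pae_test_mol <- function(abbrev) pae_test_ensemble()[[abbrev]]

# hand-built molecule (no backend): coordinates + annotations supplied
toy_mol <- function(xyz, elements = rep("C", nrow(xyz)),
                    charge = rep(0, nrow(xyz)),
                    hydro = rep(0.1, nrow(xyz)),
                    donor = rep(FALSE, nrow(xyz)),
                    acceptor = rep(FALSE, nrow(xyz)),
                    abbrev = "TOY") {
  atoms <- data.frame(element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charge, hydro = hydro,
                      donor = donor, acceptor = acceptor,
                      stringsAsFactors = FALSE)
  structure(list(abbrev = abbrev, atoms = atoms,
                 provenance = list(formal_charge = round(sum(charge))),
                 core_matches = list(),
                 energy = c(pre = NA_real_, post = NA_real_)),
            class = "pae_molecule")
}

# minimal fitted-model stand-in for contour arithmetic tests
fake_pls <- function(coef, x_sd, colnames = NULL) {
  structure(list(n_components = 1L, coef = coef,
                 intercept = 0, x_center = rep(0, length(coef)),
                 y_mean = 0, x_sd = x_sd, colnames = colnames),
            class = "pae_pls")
}

# |value - printed| within half a unit of the printed precision
# (tables print between 2 and 4 decimals per entry)
matches_printed <- function(value, printed, max_decimals = 4L) {
  ok <- logical(length(value))
  for (i in seq_along(value)) {
    d <- max_decimals
    for (cand in 0:max_decimals) {
      if (round(printed[i], cand) == printed[i]) { d <- cand; break }
    }
    ok[i] <- abs(value[i] - printed[i]) <= 0.5 * 10^(-d)
  }
  ok
}

# independent least-squares oracle (normal equations with intercept)
ols_fit <- function(X, y) {
  Xi <- cbind(1, X)
  as.vector(Xi %*% solve(crossprod(Xi), crossprod(Xi, y)))
}
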