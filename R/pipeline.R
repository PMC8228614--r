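#' Run the full 3D-QSAR chain on an arbitrary compound set
#'
#' conformers -> alignment -> grid -> fields -> column filter ->
#' block-scaled assembly -> component selection by LOO q2 -> PLS fit ->
#' statistics, predictions, external validation and applicability
#' domain. [build_qsar_model()] is the packaged-dataset front end;
#' this function also accepts synthetic series (e.g. from
#' [gen_homologous_series()]).
#'
#' @param compounds data.frame with `abbrev` and `smiles`
#' @param y named numeric responses (modeling scale), names = abbrev
#' @param roles named character `"train"`/`"test"` per compound
#' @param template abbrev of the alignment template (embedded and
#'   aligned even if it carries no response)
#' @param method `"CoMFA"` or `"CoMSIA"`
#' @param comsia_fields CoMSIA property subset (ignored for CoMFA)
#' @param seed integer seed for conformer embedding
#' @param spacing,margin grid geometry, Angstrom
#' @param probe a [probe_spec()]
#' @param min_sigma column filter threshold; `NULL` = per-kind default
#' @param max_components cap for LOO component selection
#' @param n_components fixed latent-variable count; `NULL` (default)
#'   selects it by maximum LOO q2. Pass the published model size (3 for
#'   the reported PAE models) when reproducing a literature model whose
#'   component count is known.
#' @return a `pae_qsar_run` (model, grid, descriptors, predictions,
#'   stats, contributions, tropsha report, AD table, aligned molecules)
#' @export
run_qsar_pipeline <- function(compounds, y, roles, template,
                              method = c("CoMFA", "CoMSIA"),
                              comsia_fields = c("S", "E", "H", "D", "A"),
                              seed = 42L, spacing = 2.0, margin = 4.0,
                              probe = probe_spec(), min_sigma = NULL,
                              max_components = 5L, n_components = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("abbrev", "smiles") %in% names(compounds)),
            all(names(y) %in% compounds$abbrev),
            identical(sort(names(y)), sort(names(roles))))
  modeled <- names(y)

  embed_set <- unique(c(template, modeled))
  smiles <- setNames(compounds$smiles, compounds$abbrev)[embed_set]
  if (anyNA(smiles)) {
    stop("compounds missing from the registry: ",
         paste(embed_set[is.na(smiles)], collapse = ", "), call. = FALSE)
  }
  mols <- embed_compounds(smiles, seed = seed)
  aligned <- align_ensemble(mols, alignment_spec(template = template))
  used <- aligned[modeled]

  grid <- build_grid(used, spacing = spacing, margin = margin)
  blocks <- if (method == "CoMFA") {
    comfa_blocks(used, grid, probe)
  } else {
    comsia_blocks(used, grid, probe, fields = comsia_fields)
  }

  zero_fields <- character(0)
  kept <- list()
  for (b in blocks) {
    fb <- tryCatch(filter_columns(b, min_sigma),
                   error = function(e) NULL)
    if (is.null(fb)) zero_fields <- c(zero_fields, b$kind)
    else kept[[fb$kind]] <- fb
  }
  if (!length(kept)) {
    stop("all field blocks were filtered out; lower min_sigma",
         call. = FALSE)
  }
  desc <- assemble_descriptors(kept)

  is_train <- roles[desc$compounds] == "train"
  X_train <- desc$X[is_train, , drop = FALSE]
  y_all <- y[desc$compounds]
  y_train <- y_all[is_train]

  selected <- select_components(X_train, y_train, max_components)
  ncomp <- as.integer(n_components %||% selected)
  model <- fit_pls(X_train, y_train, ncomp)
  q2 <- if (ncomp <= length(attr(selected, "q2"))) {
    attr(selected, "q2")[ncomp]
  } else {
    as.numeric(loo_q2(X_train, y_train, ncomp))
  }
  stats <- c(q2 = q2, model_stats(model, X_train, y_train),
             n_components = model$n_components)
  model$stats <- stats

  pred <- predict(model, desc$X)
  predictions <- data.frame(
    abbrev = desc$compounds,
    role = unname(roles[desc$compounds]),
    exp = unname(y_all),
    pred = pred,
    res = residual(unname(y_all), pred),
    stringsAsFactors = FALSE)

  tropsha <- NULL
  if (sum(!is_train) >= 2) {
    tropsha <- tryCatch(
      tropsha_criteria(y_all[!is_train], pred[!is_train], mean(y_train)),
      error = function(e) {
        warning("Tropsha battery not computable: ", conditionMessage(e))
        NULL
      })
  }
  ad <- ad_analysis(model, desc$X, y_all, abbrev = desc$compounds)

  config <- list(method = method, comsia_fields = comsia_fields,
                 template = template, seed = as.integer(seed),
                 spacing = spacing, margin = margin,
                 min_sigma = min_sigma, max_components = max_components,
                 n_components = n_components, probe = unclass(probe))
  structure(list(
    config = config, config_hash = config_hash(config),
    model = model, grid = grid, probe = probe, descriptors = desc,
    zero_fields = zero_fields,
    stats = stats,
    q2_by_components = attr(selected, "q2"),
    contributions = field_contributions(model, desc$map, zero_fields),
    predictions = predictions, tropsha = tropsha, ad = ad,
    molecules = aligned),
    class = "pae_qsar_run")
}

#' Build a QSAR model for one packaged toxicity endpoint
#'
#' Loads the packaged registry and endpoint table, uses the published
#' train/test split, aligns every compound onto DMP, and runs
#' [run_qsar_pipeline()].
#'
#' @param endpoint one of `PAE_ENDPOINTS`
#' @param ... passed on to [run_qsar_pipeline()] (method, seed, grid
#'   geometry, ...)
#' @return a `pae_qsar_run`
#' @examples
#' \dontrun{
#' run <- build_qsar_model("LD50", method = "CoMFA", seed = 42)
#' run$stats
#' }
#' @export
build_qsar_model <- function(endpoint = PAE_ENDPOINTS, ...) {
  endpoint <- match.arg(endpoint)
  ds <- load_pae_dataset()
  tab <- ds$endpoints[[endpoint]]
  run <- run_qsar_pipeline(
    compounds = ds$registry,
    y = setNames(tab$transformed_value, tab$abbrev),
    roles = setNames(tab$role, tab$abbrev),
    template = "DMP", ...)
  run$endpoint <- endpoint
  run
}

#' @export
print.pae_qsar_run <- function(x, ...) {
  cat(sprintf("<pae_qsar_run%s> %s, %d compounds, %d descriptors\n",
              if (is.null(x$endpoint)) "" else paste0(" ", x$endpoint),
              x$config$method, nrow(x$predictions),
              ncol(x$descriptors$X)))
  cat(sprintf("  ncomp = %d  q2 = %.3f  r2 = %.4f  SEE = %.4f  F = %.2f\n",
              x$stats["n_components"], x$stats["q2"], x$stats["r2"],
              x$stats["SEE"], x$stats["F"]))
  contr <- paste(sprintf("%s %.1f%%", names(x$contributions),
                         x$contributions), collapse = "  ")
  cat("  contributions:", contr, "\n")
  if (!is.null(x$tropsha)) {
    cat(sprintf("  external validation: %s\n",
                if (x$tropsha$pass) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Predict new compounds with a finished run
#'
#' Embeds the new SMILES with the run's seed, aligns them onto the
#' run's template, evaluates the same fields on the stored grid, applies
#' the stored column masks and block scales, and predicts.
#'
#' @param run a `pae_qsar_run`
#' @param compounds data.frame with `abbrev` and `smiles`
#' @return data.frame `abbrev`, `pred`
#' @export
predict_new_compounds <- function(run, compounds) {
  template <- run$molecules[[run$config$template]]
  smiles <- setNames(compounds$smiles, compounds$abbrev)
  mols <- embed_compounds(smiles, seed = run$config$seed)
  aligned <- lapply(mols, align_to_template, template = template,
                    spec = alignment_spec(template = run$config$template))
  blocks <- if (run$config$method == "CoMFA") {
    comfa_blocks(aligned, run$grid, run$probe)
  } else {
    comsia_blocks(aligned, run$grid, run$probe,
                  fields = run$config$comsia_fields)
  }
  pieces <- lapply(names(run$descriptors$scales), function(kind) {
    mask <- run$descriptors$masks[[kind]]
    blocks[[kind]]$values[, mask, drop = FALSE] /
      run$descriptors$scales[[kind]]
  })
  Xnew <- do.call(cbind, pieces)
  colnames(Xnew) <- run$model$colnames
  data.frame(abbrev = compounds$abbrev,
             pred = predict(run$model, Xnew),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a fitted PLS model as JSON
#'
#' Stores coefficients against the descriptor column names together
#' with everything needed to predict and to project scores.
#'
#' @param model a `pae_pls`
#' @param path JSON file
#' @return `write_model_json()`: `path`, invisibly;
#'   `read_model_json()`: a `pae_pls`
#' @export
write_model_json <- function(model, path) {
  payload <- list(n_components = model$n_components,
                  coef = model$coef, intercept = model$intercept,
                  x_center = model$x_center, y_mean = model$y_mean,
                  x_sd = model$x_sd,
                  W = model$W, P = model$P, q = model$q,
                  colnames = model$colnames,
                  stats = as.list(model$stats %||% NULL))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  W <- as.matrix(p$W)
  P <- as.matrix(p$P)
  model <- structure(list(
    n_components = p$n_components,
    coef = as.numeric(p$coef), intercept = p$intercept,
    W = W, P = P, q = as.numeric(p$q),
    projection = W %*% solve(crossprod(P, W)),
    scores = NULL,
    x_center = as.numeric(p$x_center), y_mean = p$y_mean,
    x_sd = as.numeric(p$x_sd),
    colnames = p$colnames,
    stats = unlist(p$stats)), class = "pae_pls")
  model
}

#' Write the human-facing artifacts of a run to a directory
#'
#' Produces `run.json` (config, hash, grid, masks, scales, column map),
#' `model.json`, `stats.csv` (one row: q2, r2, SEE, F plus per-field
#' contribution percentages), `predictions.csv` (Exp/Pred/Res per
#' compound), `williams.csv`, and `aligned.sdf`.
#'
#' @param run a `pae_qsar_run`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(endpoint = run$endpoint, config = run$config,
               config_hash = run$config_hash,
               package_version = as.character(utils::packageVersion("paeqsar")),
               grid = unclass(run$grid),
               zero_fields = run$zero_fields,
               scales = as.list(run$descriptors$scales),
               masks = lapply(run$descriptors$masks, which),
               map = run$descriptors$map,
               q2_by_components = run$q2_by_components)
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  write_model_json(run$model, file.path(dir, "model.json"))
  stats_row <- data.frame(t(c(run$stats, run$contributions)),
                          check.names = FALSE)
  write.csv(stats_row, file.path(dir, "stats.csv"), row.names = FALSE)
  write.csv(run$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE, quote = FALSE)
  write_ad_csv(run$ad, file.path(dir, "williams.csv"))
  write_sdf(run$molecules, file.path(dir, "aligned.sdf"))
  write_descriptors(run$descriptors, run$grid, run$probe,
                    file.path(dir, "descriptors.csv.gz"))
  if (!is.null(run$tropsha)) {
    jsonlite::write_json(
      list(stats = run$tropsha[c("R2", "Rcvext2", "R02", "R02_prime",
                                 "k", "k_prime")],
           criteria = as.list(run$tropsha$criteria),
           pass = run$tropsha$pass),
      file.path(dir, "tropsha.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
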