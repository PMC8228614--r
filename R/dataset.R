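#' Endpoint identifiers used throughout the package
#'
#' `"LD50"` is rat acute oral LD50 in mg/kg (modeled as lg = log10),
#' `"IC50_72h"` is the 72-hour HepG2 IC50 in micromolar (modeled as lg),
#' and `"Nrf2"` is relative Nrf2 protein content (dimensionless ratio,
#' modeled untransformed).
#' @export
PAE_ENDPOINTS <- c("LD50", "IC50_72h", "Nrf2")

endpoint_file_stub <- function(endpoint) {
  switch(match.arg(endpoint, PAE_ENDPOINTS),
         LD50 = "ld50", IC50_72h = "ic50", Nrf2 = "nrf2")
}

#' Load the packaged phthalate ester registry
#'
#' Fourteen dialkyl/diaryl esters of benzene-1,2-dicarboxylic acid with
#' SMILES reconstructed from their common names. Branched homologues
#' (DIBP, DIOP, DIDP, DEHP, DPHP) use the conventional single
#' representative isomer, noted in the `full_name` column.
#'
#' @return data.frame with columns `abbrev`, `full_name`, `smiles`
#' @export
load_pae_registry <- function() {
  reg <- read.delim(pae_file("extdata", "pae_registry.tsv"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(reg$abbrev)) {
    stop("registry abbreviations are not unique", call. = FALSE)
  }
  reg
}

#' Load one packaged endpoint table
#'
#' @param endpoint one of `PAE_ENDPOINTS`
#' @return data.frame (`pae_endpoint_table`) with columns `abbrev`,
#'   `raw_value`, `transformed_value`, `role` (`"train"`/`"test"`) and an
#'   `endpoint` attribute. For the two lg-modeled endpoints
#'   `transformed_value` is log10 of `raw_value`; for Nrf2 it equals the
#'   raw ratio.
#' @export
load_endpoint_table <- function(endpoint = PAE_ENDPOINTS) {
  endpoint <- match.arg(endpoint)
  path <- pae_file("extdata",
                   paste0("endpoints_", endpoint_file_stub(endpoint), ".csv"))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("abbrev", "raw_value", "transformed_value", "role")
                %in% names(tab)),
            all(tab$role %in% c("train", "test")))
  attr(tab, "endpoint") <- endpoint
  class(tab) <- c("pae_endpoint_table", "data.frame")
  tab
}

#' Load the published per-compound model predictions for one endpoint
#'
#' These are the reference predictions of the original CoMFA/CoMSIA
#' models, kept for desk-checking residual arithmetic and external
#' validation statistics; they are not produced by this package.
#'
#' @inheritParams load_endpoint_table
#' @return data.frame with columns `abbrev`, `model`, `exp`, `pred`, `res`
#' @export
load_reference_predictions <- function(endpoint = PAE_ENDPOINTS) {
  endpoint <- match.arg(endpoint)
  path <- pae_file("extdata",
                   paste0("predictions_", endpoint_file_stub(endpoint), ".csv"))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load the full phthalate ester dataset
#'
#' @return list with `registry` (see [load_pae_registry()]) and
#'   `endpoints`, a named list of the three endpoint tables. Every
#'   compound in an endpoint table is checked against the registry.
#' @examples
#' ds <- load_pae_dataset()
#' nrow(ds$endpoints$LD50)  # 13
#' @export
load_pae_dataset <- function() {
  registry <- load_pae_registry()
  endpoints <- setNames(lapply(PAE_ENDPOINTS, load_endpoint_table),
                        PAE_ENDPOINTS)
  for (tab in endpoints) {
    missing <- setdiff(tab$abbrev, registry$abbrev)
    if (length(missing)) {
      stop("endpoint compounds missing from registry: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  list(registry = registry, endpoints = endpoints)
}

#' Base-10 log transform of a positive endpoint value
#'
#' The lg transform used for LD50 (mg/kg) and IC50 (uM); reported tables
#' print it to 4 decimals.
#'
#' @param raw positive numeric vector
#' @return log10(raw)
#' @examples
#' lg_transform(6800)  # 3.8325 at 4 decimals
#' @export
lg_transform <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)) || any(raw <= 0)) {
    stop("lg_transform() requires finite positive values", call. = FALSE)
  }
  log10(raw)
}

#' Signed residual between experimental and predicted values
#'
#' @param exp,pred numeric vectors on the modeling (transformed) scale
#' @return `exp - pred`
#' @export
residual <- function(exp, pred) {
  if (any(!is.finite(exp)) || any(!is.finite(pred))) {
    stop("residual() requires finite inputs", call. = FALSE)
  }
  exp - pred
}

#' Flag reference-prediction rows whose printed residual is inconsistent
#'
#' Some published rows print a residual that does not equal
#' `exp - pred` (the IC50 CoMSIA column appears row-shifted). This check
#' recomputes `exp - pred` and flags rows where it differs from the
#' printed `res` by more than `tol`. Nothing is corrected; the flags are
#' a data-quality record.
#'
#' @param pred_table output of [load_reference_predictions()]
#' @param tol absolute tolerance on the printed residual
#' @return the table with logical column `res_inconsistent` added
#' @export
flag_residual_anomalies <- function(pred_table, tol = 1e-4) {
  recomputed <- residual(pred_table$exp, pred_table$pred)
  pred_table$res_inconsistent <- abs(recomputed - pred_table$res) > tol
  pred_table
}

#' Write / read an endpoint table as CSV (lossless round trip)
#'
#' @param tab a `pae_endpoint_table`
#' @param path file path
#' @return `write_endpoint_csv()` returns `path` invisibly;
#'   `read_endpoint_csv()` returns the table with its `endpoint`
#'   attribute restored from the embedded comment header.
#' @export
write_endpoint_csv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# endpoint: %s", attr(tab, "endpoint") %||% "unknown"),
             con)
  write.csv(as.data.frame(tab), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_csv
#' @export
read_endpoint_csv <- function(path) {
  first <- readLines(path, n = 1L)
  endpoint <- sub("^# endpoint: ", "", first)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(tab, "endpoint") <- endpoint
  class(tab) <- c("pae_endpoint_table", "data.frame")
  tab
}

#' Export the full dataset (registry + endpoint tables) as JSON
#'
#' @param path output file
#' @return `path`, invisibly
#' @export
export_dataset_json <- function(path) {
  ds <- load_pae_dataset()
  out <- list(
    registry = ds$registry,
    endpoints = lapply(ds$endpoints, as.data.frame)
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.pae_endpoint_table <- function(x, ...) {
  cat(sprintf("<pae_endpoint_table: %s> %d compounds (%d train / %d test)\n",
              attr(x, "endpoint"), nrow(x),
              sum(x$role == "train"), sum(x$role == "test")))
  print(as.data.frame(x), ...)
  invisible(x)
}
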