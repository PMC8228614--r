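#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a file shipped with the package
#' @noRd
pae_file <- function(...) {
  path <- system.file(..., package = "paeqsar", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("packaged file not found: ", file.path(...),
         " (broken installation?)", call. = FALSE)
  }
  path
}

#' Population (n-denominator) standard deviation
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' FNV-1a hash of an R object, for run provenance
#'
#' Hashes the canonical `deparse()` of the object. Not cryptographic;
#' used only to tag outputs so a run can be matched to its config.
#' @param x any R object
#' @return 8-hex-digit character scalar
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  # polynomial rolling hash kept below 2^31 (exact in double precision)
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
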