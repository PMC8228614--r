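#' Leverage (hat value) of samples in a score space
#'
#' h = x (X'X)^-1 x' for each query row, with X the reference (training)
#' score matrix. In this package leverages are computed in the PLS
#' latent-score space -- the raw descriptor matrix has far more columns
#' than compounds, so X'X would be singular there; in score space k (the
#' "variable term" of the h* = 3k/n threshold) is the number of latent
#' variables.
#'
#' @param score_matrix reference matrix (samples x k), full column rank
#' @param query optional matrix of rows to evaluate (default: the
#'   reference itself, giving the hat-matrix diagonal)
#' @return numeric vector of leverages
#' @export
leverage <- function(score_matrix, query = NULL) {
  S <- as.matrix(score_matrix)
  Q <- if (is.null(query)) S else as.matrix(query)
  XtX <- crossprod(S)
  inv <- tryCatch(solve(XtX),
                  error = function(e) {
                    stop("X'X is rank deficient; use fewer components",
                         call. = FALSE)
                  })
  if (rcond(XtX) < 1e-12) {
    stop("X'X is numerically singular; use fewer components", call. = FALSE)
  }
  rowSums((Q %*% inv) * Q)
}

#' Leverage warning threshold h* = 3k/n
#'
#' @param k number of model variables (latent components, plus one if an
#'   intercept column is part of the score matrix)
#' @param n number of samples
#' @return 3k/n
#' @examples
#' h_star(3, 13)  # 0.6923..., printed as 0.692
#' @export
h_star <- function(k, n) {
  stopifnot(k >= 1, n >= 1)
  3 * k / n
}

#' Williams-plot classification of compounds
#'
#' Standardized residual = residual / population (n-denominator) SD of
#' the residuals. A compound is an X outlier iff its leverage strictly
#' exceeds `h_star`, and a Y outlier iff |standardized residual|
#' strictly exceeds `y_bound` (2.5 by convention here).
#'
#' @param leverages,residuals equal-length numeric vectors
#' @param h_star leverage threshold (see [h_star()])
#' @param y_bound standardized-residual bound, default 2.5
#' @param abbrev optional compound labels
#' @return a `pae_ad_result` data.frame: `abbrev`, `leverage`,
#'   `std_residual`, `class` in {in_domain, X_outlier, Y_outlier, both};
#'   thresholds kept as attributes
#' @export
williams_classify <- function(leverages, residuals, h_star, y_bound = 2.5,
                              abbrev = NULL) {
  stopifnot(length(leverages) == length(residuals))
  s <- pop_sd(residuals)
  if (s == 0) stop("residuals have zero spread; cannot standardize",
                   call. = FALSE)
  std <- residuals / s
  x_out <- leverages > h_star          # strict: h = h* is in-domain
  y_out <- abs(std) > y_bound
  cls <- ifelse(x_out & y_out, "both",
         ifelse(x_out, "X_outlier",
         ifelse(y_out, "Y_outlier", "in_domain")))
  out <- data.frame(
    abbrev = abbrev %||% paste0("cmp", seq_along(leverages)),
    leverage = leverages, std_residual = std, class = cls,
    stringsAsFactors = FALSE)
  attr(out, "h_star") <- h_star
  attr(out, "y_bound") <- y_bound
  class(out) <- c("pae_ad_result", "data.frame")
  out
}

#' Full applicability-domain analysis of a fitted QSAR model
#'
#' Projects all compounds (training and test) into the model's latent
#' score space, computes leverages over the combined set, h* = 3k/n with
#' k the component count and n the combined sample count, and classifies
#' each compound on the Williams plot.
#'
#' @param model a `pae_pls`
#' @param X descriptor matrix for all compounds (training layout)
#' @param y observed responses
#' @param abbrev compound labels
#' @return a `pae_ad_result` (see [williams_classify()]) with `role`
#'   columns preserved when provided via names
#' @export
ad_analysis <- function(model, X, y, abbrev = NULL) {
  scores <- pls_scores(model, X)
  h <- leverage(scores)
  res <- y - predict(model, X)
  williams_classify(h, res,
                    h_star(model$n_components, nrow(as.matrix(X))),
                    abbrev = abbrev)
}

#' Write an applicability-domain table as CSV
#'
#' @param ad a `pae_ad_result`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ad_csv <- function(ad, path) {
  df <- as.data.frame(ad)
  df$h_star <- attr(ad, "h_star")
  df$y_bound <- attr(ad, "y_bound")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
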