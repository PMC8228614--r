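#' Synthetic descriptor data with a planted low-rank latent structure
#'
#' X = T P' + E and y = T c + e, the generative model a linear latent-
#' variable QSAR assumes: a few orthogonal-ish latent factors drive both
#' the (many, collinear) descriptor columns and the response. Gaussian
#' i.i.d. noise; the response noise SD is set from `snr` as
#' sd(T c) / sqrt(snr).
#'
#' @param n samples
#' @param p descriptor columns
#' @param factors number of latent factors
#' @param snr signal-to-noise ratio of the response (variance ratio);
#'   `Inf` gives a noise-free response
#' @param x_noise_sd SD of the descriptor noise (default 0.1)
#' @param seed integer seed; the generator is bit-reproducible
#' @return list: `X`, `y`, and `truth` (T, P, c, the implied coefficient
#'   vector beta = P (P'P)^-1 c, and the noise SDs)
#' @export
gen_latent_pls_data <- function(n, p, factors, snr = 10, x_noise_sd = 0.1,
                                seed = 1L) {
  if (n <= factors) stop("need n > factors", call. = FALSE)
  if (p < factors) stop("need p >= factors", call. = FALSE)
  set.seed(as.integer(seed))
  # Orthonormal factor scores with a geometric variance ladder across
  # factors (amplitudes 2^(f-1) .. 1) and response coefficients scaled
  # inversely to the ladder: every factor contributes comparably to y,
  # but the low-variance factors are reached only by later latent
  # components, so "f factors" genuinely means f recoverable PLS
  # components (a flat ladder lets a single component blend them all).
  amp <- 2^(seq.int(factors, 1) - 1)
  Tm <- qr.Q(qr(matrix(rnorm(n * factors), n, factors))) * sqrt(n)
  P <- qr.Q(qr(matrix(rnorm(p * factors), p, factors))) %*%
    diag(amp, factors)
  cvec <- sample(c(-1, 1), factors, replace = TRUE) *
    runif(factors, 0.7, 1.3) / amp
  signal <- as.vector(Tm %*% cvec)
  y_noise_sd <- if (is.finite(snr)) sd(signal) / sqrt(snr) else 0
  X <- Tm %*% t(P) + x_noise_sd * matrix(rnorm(n * p), n, p)
  y <- signal + y_noise_sd * rnorm(n)
  beta <- P %*% solve(crossprod(P), cvec)
  list(X = X, y = y,
       truth = list(T = Tm, P = P, c = cvec, beta = as.vector(beta),
                    y_noise_sd = y_noise_sd, x_noise_sd = x_noise_sd,
                    seed = as.integer(seed)))
}

#' Homologous dialkyl phthalate series with a chain-length endpoint
#'
#' Linear di-n-alkyl phthalates with both ester chains of length
#' `min_chain` .. `max_chain` carbons (chain 1 is dimethyl phthalate),
#' paired with a synthetic endpoint a + b*k that rises with chain
#' length -- the direction the measured lgLD50 series follows from DMP
#' up through the C10 esters. Defaults a = 3.5, b = 0.1 put the values
#' in the observed lgLD50 range.
#'
#' @param min_chain,max_chain chain lengths, 1..12
#' @param a,b intercept and slope of the synthetic endpoint
#' @return data.frame: `abbrev`, `chain`, `smiles`, `endpoint`
#' @export
gen_homologous_series <- function(min_chain = 1L, max_chain = 8L,
                                  a = 3.5, b = 0.1) {
  stopifnot(min_chain >= 1, max_chain <= 12, min_chain <= max_chain)
  k <- seq.int(min_chain, max_chain)
  chain <- vapply(k, function(i) strrep("C", i), "")
  data.frame(
    abbrev = sprintf("PAE_C%d", k),
    chain = k,
    smiles = sprintf("%sOC(=O)c1ccccc1C(=O)O%s", chain, chain),
    endpoint = a + b * k,
    stringsAsFactors = FALSE)
}

#' Score/residual fixture with planted Williams-plot outliers
#'
#' Generates an n x k latent-score matrix with well-behaved rows plus,
#' optionally, one or more planted X outliers (rows pushed away from the
#' centroid until their leverage, computed over the full set, exceeds
#' h* = 3k/n by at least 20%) and Y outliers (residuals inflated until
#' their standardized value exceeds the 2.5 bound by at least 20%).
#'
#' @param n rows (needs n > 3.6 k to leave room above h*, since
#'   leverages over the full set are bounded by 1)
#' @param k score columns
#' @param n_x_outliers,n_y_outliers planted counts
#' @param seed integer seed
#' @return list: `scores`, `residuals`, `x_outliers`, `y_outliers`
#'   (planted row indices), `h_star`
#' @export
gen_ad_fixture <- function(n, k, n_x_outliers = 0L, n_y_outliers = 0L,
                           seed = 1L) {
  if (n <= k) stop("need n > k", call. = FALSE)
  hs <- h_star(k, n)
  if (n_x_outliers > 0 && 1.2 * hs >= 1) {
    stop("n too small to plant an X outlier above 1.2 * h* (< 1 needed)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  S <- matrix(rnorm(n * k, sd = 1), n, k)
  res <- rnorm(n, sd = 0.5)
  x_idx <- if (n_x_outliers > 0) seq_len(n_x_outliers) else integer(0)
  y_idx <- if (n_y_outliers > 0) n - seq_len(n_y_outliers) + 1L
           else integer(0)
  # tame chance outliers among the background rows so that only the
  # planted ones cross the thresholds
  for (iter in 1:60) {
    h <- leverage(S)
    wild <- setdiff(which(h > 0.9 * hs), x_idx)
    if (!length(wild)) break
    S[wild, ] <- S[wild, ] * 0.8
  }
  for (iter in 1:60) {
    z <- res / pop_sd(res)
    wild <- setdiff(which(abs(z) > 2), y_idx)
    if (!length(wild)) break
    res[wild] <- res[wild] * 0.8
  }
  for (i in x_idx) {
    for (iter in 1:60) {
      if (leverage(S)[i] > 1.2 * hs) break
      S[i, ] <- S[i, ] * 1.5
    }
    if (leverage(S)[i] <= 1.2 * hs) {
      stop("failed to plant X outlier at row ", i, call. = FALSE)
    }
  }
  for (i in y_idx) {
    for (iter in 1:60) {
      if (abs(res[i] / pop_sd(res)) > 1.2 * 2.5) break
      res[i] <- if (res[i] == 0) 1 else res[i] * 1.5
    }
    # one inflated residual also inflates the pooled SD; with very few
    # rows the standardized value saturates near sqrt(n) and may never
    # clear the bound -- refuse rather than return a bad fixture
    if (abs(res[i] / pop_sd(res)) <= 1.2 * 2.5) {
      stop("failed to plant Y outlier at row ", i,
           " (n too small: |z| saturates near sqrt(n))", call. = FALSE)
    }
  }
  list(scores = S, residuals = res, x_outliers = x_idx,
       y_outliers = y_idx, h_star = hs)
}
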