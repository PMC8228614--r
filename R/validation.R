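origin_slope <- function(x, y) sum(x * y) / sum(x * x)

# R^2 of a through-origin regression of response on regressor,
# relative to the response's own mean-centered variation.
origin_r2 <- function(regressor, response) {
  k <- origin_slope(regressor, response)
  1 - sum((response - k * regressor)^2) /
      sum((response - mean(response))^2)
}

#' External-set model acceptance battery (Tropsha criteria)
#'
#' Evaluates the seven acceptance conditions on an external test set:
#' R2 > 0.6; Rcvext2 > 0.5; (R2 - R02)/R2 < 0.1; (R2 - R'02)/R2 < 0.1;
#' |R02 - R'02| < 0.3; 0.85 <= k <= 1.15; 0.85 <= k' <= 1.15.
#' R2 is the squared Pearson correlation of predicted and observed;
#' R02 and k come from the through-origin regression of predicted on
#' observed, R'02 and k' from the reverse orientation; Rcvext2 is
#' 1 - sum((obs-pred)^2) / sum((obs - train_mean)^2) (the Q2F1
#' convention, with the training-set mean in the denominator).
#'
#' @param y_obs_test,y_pred_test observed and predicted test-set values
#' @param y_train_mean mean of the training-set responses
#' @return a `pae_tropsha_report`: statistics, per-criterion logicals,
#'   and overall pass flag
#' @export
tropsha_criteria <- function(y_obs_test, y_pred_test, y_train_mean) {
  obs <- as.numeric(y_obs_test)
  pred <- as.numeric(y_pred_test)
  if (length(obs) < 2 || length(obs) != length(pred)) {
    stop("need >= 2 matched test pairs", call. = FALSE)
  }
  if (any(!is.finite(c(obs, pred, y_train_mean)))) {
    stop("non-finite inputs", call. = FALSE)
  }
  if (sd(obs) == 0 || sd(pred) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  R2 <- cor(obs, pred)^2
  R02 <- origin_r2(obs, pred)    # predicted vs observed
  R02p <- origin_r2(pred, obs)   # observed vs predicted
  k <- origin_slope(obs, pred)
  kp <- origin_slope(pred, obs)
  Rcvext2 <- external_q2(obs, pred, y_train_mean)

  crit <- c(
    R2_gt_0.6        = R2 > 0.6,
    Rcvext2_gt_0.5   = Rcvext2 > 0.5,
    R2_R02_ratio     = (R2 - R02) / R2 < 0.1,
    R2_R02p_ratio    = (R2 - R02p) / R2 < 0.1,
    absdiff_R02      = abs(R02 - R02p) < 0.3,
    k_in_band        = k >= 0.85 && k <= 1.15,
    kp_in_band       = kp >= 0.85 && kp <= 1.15
  )
  structure(list(R2 = R2, Rcvext2 = Rcvext2, R02 = R02, R02_prime = R02p,
                 k = k, k_prime = kp, criteria = crit,
                 pass = all(crit)),
            class = "pae_tropsha_report")
}

#' @export
print.pae_tropsha_report <- function(x, ...) {
  cat(sprintf("<tropsha report> %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  R2 = %.4f  Rcvext2 = %.4f  R02 = %.4f  R'02 = %.4f  k = %.3f  k' = %.3f\n",
              x$R2, x$Rcvext2, x$R02, x$R02_prime, x$k, x$k_prime))
  for (nm in names(x$criteria)) {
    cat(sprintf("  [%s] %s\n", if (x$criteria[[nm]]) "ok" else "FAIL", nm))
  }
  invisible(x)
}

#' External predictive squared correlation (Q2F1)
#'
#' 1 - sum((obs - pred)^2) / sum((obs - y_train_mean)^2). Equals 1 iff
#' predictions are exact; 0 when predictions are no better than the
#' training mean.
#'
#' @inheritParams tropsha_criteria
#' @return scalar <= 1
#' @export
external_q2 <- function(y_obs_test, y_pred_test, y_train_mean) {
  obs <- as.numeric(y_obs_test)
  pred <- as.numeric(y_pred_test)
  if (length(obs) < 1 || length(obs) != length(pred)) {
    stop("need >= 1 matched test pair", call. = FALSE)
  }
  denom <- sum((obs - y_train_mean)^2)
  if (denom == 0) {
    stop("test responses all equal the training mean; Q2F1 undefined",
         call. = FALSE)
  }
  1 - sum((obs - pred)^2) / denom
}

#' Y-randomization (response permutation) control
#'
#' Refits the model on seeded random permutations of the response and
#' reports the null distribution of LOO q2 and training r2. A sound
#' model's real q2 should sit above essentially all permuted ones. The
#' empirical p-value uses the (1 + exceed) / (n_perm + 1) correction.
#'
#' @param X descriptor matrix
#' @param y response
#' @param n_perm number of permutations (>= 10)
#' @param seed integer seed
#' @param n_components latent variables per refit (default: selected on
#'   the real response)
#' @return list: `real_q2`, `perm_q2`, `perm_r2`, `p_value`
#' @export
y_randomization <- function(X, y, n_perm = 100L, seed = 1L,
                            n_components = NULL) {
  if (n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  X <- as.matrix(X)
  n_components <- n_components %||% as.integer(select_components(X, y))
  real_q2 <- as.numeric(loo_q2(X, y, n_components))
  rng <- local({
    set.seed(as.integer(seed))
    replicate(n_perm, sample.int(length(y)), simplify = FALSE)
  })
  perm_q2 <- perm_r2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- y[rng[[b]]]
    perm_q2[b] <- as.numeric(loo_q2(X, yp, n_components))
    fitp <- fit_pls(X, yp, n_components)
    perm_r2[b] <- unname(model_stats(fitp, X, yp)["r2"])
  }
  list(real_q2 = real_q2, perm_q2 = perm_q2, perm_r2 = perm_r2,
       p_value = (1 + sum(perm_q2 >= real_q2)) / (n_perm + 1))
}
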