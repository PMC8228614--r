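#' Fit a PLS1 regression (NIPALS)
#'
#' Columns are centered by their training means; the response is
#' centered by its mean; no autoscaling of y (block scaling is done
#' upstream when descriptors are assembled). Components are extracted by
#' the NIPALS sequence -- weight w = X'y normalized, score t = Xw,
#' loading p = X't/t't, y-loading q = y't/t't, deflation -- which for a
#' single response converges in one pass per component. With
#' `n_components = rank(X)` the fit reproduces least squares.
#'
#' @param X numeric matrix (samples x descriptors)
#' @param y numeric response vector
#' @param n_components number of latent variables (>= 1)
#' @return a `pae_pls` model: `coef` (regression vector on the input
#'   column scale), `intercept`, weights `W`, loadings `P`, y-loadings
#'   `q`, training scores `scores`, centers, and training column sds
#'   (used for field contributions and contour values)
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (sd(y) == 0) stop("zero-variance response", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(n - 1L, ncol(X))) {
    stop("n_components must be in [1, min(n-1, ncol(X))]", call. = FALSE)
  }

  x_center <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_mean

  W <- P <- matrix(0, ncol(X), n_components)
  Tm <- matrix(0, n, n_components)
  qv <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("X exhausted after ", a - 1L,
           " components; reduce n_components", call. = FALSE)
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - qa * t
    W[, a] <- w
    P[, a] <- p
    Tm[, a] <- t
    qv[a] <- qa
  }
  # projection R maps centered X to scores: T = Xc R; beta = R q
  R <- W %*% solve(crossprod(P, W))
  beta <- as.vector(R %*% qv)
  structure(list(n_components = n_components,
                 coef = beta,
                 intercept = y_mean - sum(x_center * beta),
                 W = W, P = P, q = qv, projection = R,
                 scores = Tm,
                 x_center = x_center, y_mean = y_mean,
                 x_sd = apply(X, 2, sd),
                 colnames = colnames(X)),
            class = "pae_pls")
}

#' @export
print.pae_pls <- function(x, ...) {
  cat(sprintf("<pae_pls> %d component(s), %d descriptor columns\n",
              x$n_components, length(x$coef)))
  if (!is.null(x$stats)) {
    cat(sprintf("  q2 = %.3f  r2 = %.4f  SEE = %.4f  F = %.2f\n",
                x$stats["q2"], x$stats["r2"], x$stats["SEE"], x$stats["F"]))
  }
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a `pae_pls`
#' @param newdata matrix with the same columns (order and meaning) as
#'   the training matrix
#' @param ... unused
#' @return numeric vector of predictions
#' @export
predict.pae_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coef)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coef), call. = FALSE)
  }
  if (!is.null(object$colnames) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$colnames)) {
    stop("newdata column names do not match the training matrix",
         call. = FALSE)
  }
  as.vector(newdata %*% object$coef) + object$intercept
}

#' Project samples into the latent-score space of a fitted model
#'
#' T = (X - center) W (P'W)^-1; training rows reproduce `model$scores`.
#'
#' @param model a `pae_pls`
#' @param X matrix on the training column layout
#' @return samples x n_components score matrix
#' @export
pls_scores <- function(model, X) {
  X <- as.matrix(X)
  sweep(X, 2, model$x_center) %*% model$projection
}

#' Leave-one-out cross-validated q2
#'
#' Each sample is held out in turn, the model (including centering) is
#' refit on the remainder, and the held-out response predicted.
#' q2 = 1 - PRESS / SS with SS taken about the mean of the retained
#' (n-1) training responses of each fold. `loo_q2_naive()` is an
#' independent re-implementation (explicit NIPALS inlined per fold,
#' no model objects) kept as a cross-check oracle.
#'
#' @inheritParams fit_pls
#' @return q2 (scalar, <= 1), with attribute `"predictions"`
#' @export
loo_q2 <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("LOO needs at least 3 samples", call. = FALSE)
  preds <- numeric(n)
  ss <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (sd(yi) == 0) stop("fold ", i, ": zero-variance response",
                          call. = FALSE)
    fit <- fit_pls(X[-i, , drop = FALSE], yi, n_components)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
    ss[i] <- (y[i] - mean(yi))^2
  }
  q2 <- 1 - sum((y - preds)^2) / sum(ss)
  attr(q2, "predictions") <- preds
  q2
}

#' @rdname loo_q2
#' @export
loo_q2_naive <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("LOO needs at least 3 samples", call. = FALSE)
  preds <- numeric(n)
  ss <- numeric(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    if (sd(yt) == 0) stop("fold ", i, ": zero-variance response",
                          call. = FALSE)
    xc <- colMeans(Xt)
    ym <- mean(yt)
    E <- sweep(Xt, 2, xc)
    f <- yt - ym
    W <- P <- matrix(0, ncol(X), n_components)
    qv <- numeric(n_components)
    for (a in seq_len(n_components)) {
      w <- crossprod(E, f)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) stop("X exhausted after ", a - 1L,
                           " components; reduce n_components",
                           call. = FALSE)
      w <- w / nw
      t <- as.vector(E %*% w)
      tt <- sum(t^2)
      p <- crossprod(E, t) / tt
      qa <- sum(f * t) / tt
      E <- E - tcrossprod(t, p)
      f <- f - qa * t
      W[, a] <- w
      P[, a] <- p
      qv[a] <- qa
    }
    beta <- as.vector((W %*% solve(crossprod(P, W))) %*% qv)
    preds[i] <- as.vector(X[i, , drop = FALSE] %*% beta) +
      (ym - sum(xc * beta))
    ss[i] <- (y[i] - mean(yt))^2
  }
  1 - sum((y - preds)^2) / sum(ss)
}

#' Choose the number of PLS components by leave-one-out q2
#'
#' Evaluates q2 for 1..max_components latent variables (capped at n-2 so
#' every fold remains fittable) and returns the smallest count whose q2
#' comes within `parsimony` (relative) of the best -- the CoMFA-standard
#' "5 percent rule": a q2 gain smaller than LOO resampling noise does
#' not buy an extra latent variable. `parsimony = 0` reduces to the
#' strict maximum with ties going to the smaller model.
#'
#' @inheritParams fit_pls
#' @param max_components upper bound on components tried (default 5,
#'   sized for training sets as small as 5 compounds)
#' @param parsimony relative q2 margin within which the smaller model
#'   wins (default 0.05)
#' @return chosen component count (integer) with attribute `"q2"`, the
#'   vector of per-count q2 values
#' @export
select_components <- function(X, y, max_components = 5L,
                              parsimony = 0.05) {
  X <- as.matrix(X)
  n <- length(y)
  cap <- min(as.integer(max_components), n - 2L, ncol(X))
  if (cap < 1) stop("too few samples/columns to cross-validate",
                    call. = FALSE)
  q2s <- numeric(0)
  for (a in seq_len(cap)) {
    q <- tryCatch(as.numeric(loo_q2(X, y, a)), error = function(e) NULL)
    if (is.null(q)) break     # X exhausted (exact low rank): stop scan
    q2s[a] <- q
  }
  if (!length(q2s)) stop("no component count could be cross-validated",
                         call. = FALSE)
  best_val <- max(q2s)
  chosen <- min(which(q2s >= best_val - parsimony * abs(best_val)))
  structure(as.integer(chosen), q2 = q2s)
}

#' Training-set statistics of a fitted PLS model
#'
#' r2 = 1 - SSE/SST; SEE = sqrt(SSE / (n - c - 1)); F is the explained-
#' to-residual variance ratio ((SST-SSE)/c) / (SSE/(n-c-1)), with c the
#' number of latent variables.
#'
#' @param model a `pae_pls`
#' @param X,y the training data
#' @return named numeric: `r2`, `SEE`, `F`
#' @export
model_stats <- function(model, X, y) {
  n <- length(y)
  cc <- model$n_components
  if (n - cc - 1 <= 0) {
    stop("n - c - 1 <= 0: too many components for these statistics",
         call. = FALSE)
  }
  fitted <- predict(model, X)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  see <- sqrt(sse / (n - cc - 1))
  fstat <- if (sse == 0) Inf else ((sst - sse) / cc) / (sse / (n - cc - 1))
  c(r2 = r2, SEE = see, F = fstat)
}

#' Percent contribution of each field to the PLS model
#'
#' Field f's share is sum over its columns of |b_j| * sd(X_j),
#' normalized to 100 across fields. Fields whose blocks were entirely
#' filtered out can be passed in `zero_fields` and are reported as 0.
#'
#' @param model a `pae_pls`
#' @param map index map from [assemble_descriptors()] (`field` per column)
#' @param zero_fields character vector of field kinds to report as 0
#' @return named numeric percentages summing to 100
#' @export
field_contributions <- function(model, map, zero_fields = character(0)) {
  stopifnot(nrow(map) == length(model$coef))
  w <- abs(model$coef) * model$x_sd
  raw <- tapply(w, factor(map$field, levels = unique(map$field)), sum)
  raw <- c(raw, setNames(rep(0, length(zero_fields)), zero_fields))
  if (sum(raw) == 0) return(raw)
  100 * raw / sum(raw)
}
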