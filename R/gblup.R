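#' REML-based GBLUP
#'
#' Fits the mixed model `y = 1 mu + Z u + e`, `u ~ N(0, U sg2)`,
#' `e ~ N(0, I se2)` by restricted maximum likelihood, profiled over the
#' variance ratio `lambda = se2 / sg2` via one eigendecomposition of the
#' training-set relationship matrix. The profile is maximized by a
#' bracketing log-grid over `lambda` in `[1e-6, 1e6]` followed by
#' golden-section refinement, then `mu` is the GLS intercept at the
#' optimum and BLUPs are propagated to every individual in `U` through
#' `u_hat = sg2 U Z' V^{-1} (y - 1 mu)`.
#'
#' @param y_train named numeric vector of training phenotypes (adjusted
#'   means), or a vector aligned with `train_ids`.
#' @param U relationship matrix with dimnames covering training and
#'   prediction individuals; must be PSD up to a small jitter.
#' @param train_ids ids of the training individuals (default
#'   `names(y_train)`).
#' @param lambda_range search range for `lambda`.
#' @param tol relative tolerance of the golden-section refinement.
#' @return an object of class `gblup_fit` with elements `mu`, `sigma_g2`,
#'   `sigma_e2`, `lambda`, `u` (BLUPs for all ids in `U`), `train_ids`,
#'   `loglik` (restricted log-likelihood at the optimum).
#' @export
reml_fit <- function(y_train, U, train_ids = names(y_train),
                     lambda_range = c(1e-6, 1e6), tol = 1e-8) {
  if (is.null(train_ids)) stop("training ids are required")
  stopifnot(length(y_train) == length(train_ids))
  ids <- rownames(U)
  if (is.null(ids)) stop("U needs dimnames")
  if (!all(train_ids %in% ids)) stop("U does not cover all training ids")
  n <- length(train_ids)
  if (n < 10) stop("need at least 10 training individuals")
  y <- as.numeric(y_train)
  if (stats::var(y) == 0) stop("degenerate y: zero variance")
  K <- U[train_ids, train_ids]
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  jit_tol <- 1e-8 * mean(diag(K))
  if (min(d) < -jit_tol)
    stop("relationship matrix is not PSD (min eigenvalue ", signif(min(d), 3), ")")
  if (min(d) < 0) d <- d + jit_tol  # numerical jitter for tiny negatives
  Q <- eg$vectors
  yt <- drop(crossprod(Q, y))
  xt <- drop(crossprod(Q, rep(1, n)))
  # restricted log-likelihood profiled over sg2 and mu, up to a constant
  rll <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- d + lam
    w <- 1 / v
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    r <- yt - xt * mu
    sg2 <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(sg2) + sum(log(v)) + log(sxx) + (n - 1))
  }
  lg <- seq(log(lambda_range[1]), log(lambda_range[2]), length.out = 41)
  vals <- vapply(lg, rll, numeric(1))
  i <- which.max(vals)
  lo <- lg[max(1, i - 1)]; hi <- lg[min(length(lg), i + 1)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = tol)
  lam <- exp(opt$maximum)
  v <- d + lam
  w <- 1 / v
  sxx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / sxx
  r <- yt - xt * mu
  sg2 <- sum(w * r^2) / (n - 1)
  se2 <- lam * sg2
  # u_hat = U[, train] (K + lam I)^{-1} (y - mu) for every individual
  alpha <- Q %*% (w * drop(crossprod(Q, y - mu)))
  u <- drop(U[, train_ids, drop = FALSE] %*% alpha)
  names(u) <- ids
  structure(list(mu = mu, sigma_g2 = sg2, sigma_e2 = se2, lambda = lam,
                 u = u, train_ids = train_ids, loglik = opt$objective),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> n_train=", length(x$train_ids),
      "  mu=", signif(x$mu, 4),
      "  sigma_g2=", signif(x$sigma_g2, 4),
      "  sigma_e2=", signif(x$sigma_e2, 4),
      "  h2_model=", signif(x$sigma_g2 / (x$sigma_g2 + x$sigma_e2), 3),
      "\n", sep = "")
  invisible(x)
}

#' Predict genetic values for unphenotyped individuals
#'
#' @param object a [reml_fit()] result.
#' @param predict_ids ids covered by the fit's relationship matrix and
#'   disjoint from the training set.
#' @param ... unused.
#' @return named numeric vector of BLUPs for `predict_ids`.
#' @export
predict.gblup_fit <- function(object, predict_ids, ...) {
  if (!all(predict_ids %in% names(object$u)))
    stop("prediction ids not covered by the relationship matrix")
  if (any(predict_ids %in% object$train_ids))
    stop("prediction ids overlap the training set")
  object$u[predict_ids]
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genetic values and observed
#' phenotypes, divided by the square root of the prediction set's
#' heritability.
#'
#' @param predicted,observed numeric vectors (>= 3 pairs, non-constant).
#' @param h2 heritability of the trait in the prediction set, in (0, 1].
#' @return scalar accuracy.
#' @export
prediction_accuracy <- function(predicted, observed, h2) {
  stopifnot(h2 > 0, h2 <= 1, length(predicted) == length(observed),
            length(predicted) >= 3)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("accuracy undefined for a constant vector")
  stats::cor(predicted, observed) / sqrt(h2)
}
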