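# Lag covariance of a Brownian predictor in the optimum.
#
# For an OU response tracking a BM predictor g (evolutionary slope beta =
# k * rho, optimal slope k), the GLS residual of species i is
#   k L_i + OU-noise - beta ghat_i,
# with L_i = alpha * int_0^Ti (g(t) - g0) e^{-alpha (Ti - t)} dt and ghat_i
# the observed tip deviation. Using min(t, t', s) = int_0^s 1[w<t] 1[w<t'] dw,
#   Cov(L_i, L_j)   = sg2 * int_0^s (1 - e^{-a(Ti - w)})(1 - e^{-a(Tj - w)}) dw
#   Cov(L_i, ghat_j)= sg2 * int_0^s (1 - e^{-a(Ti - w)}) dw
# which integrate to the closed forms below. In the trend limit (a -> 0 with
# beta fixed) L_i / a -> M_i = int (g - g0) dt and the diagonal reduces to the
# Brownian-bridge integral variance sg2/12 (a classic check). Certified
# against the Monte-Carlo simulator oracle in the test suite.
bm_lag_cov <- function(s, depths, alpha, beta, sg2) {
  Ti <- outer(depths, rep(1, length(depths)))
  Tj <- t(Ti)
  if (alpha > 0) {
    a <- alpha
    rho <- 1 - (1 - exp(-a * depths)) / (a * depths)
    k <- beta / mean(rho)
    e_i <- (exp(-a * (Ti - s)) - exp(-a * Ti)) / a
    e_j <- (exp(-a * (Tj - s)) - exp(-a * Tj)) / a
    C_LL <- sg2 * (s - e_i - e_j +
                     (exp(-a * (Ti + Tj - 2 * s)) - exp(-a * (Ti + Tj))) / (2 * a))
    C_Lg_ij <- sg2 * (s - e_i)
    C_Lg_ji <- sg2 * (s - e_j)
    k^2 * C_LL - k * beta * (C_Lg_ij + C_Lg_ji) + beta^2 * sg2 * s
  } else {
    # trend limit: response drifts at rate c * (g - g0), beta = c * T / 2
    Tm <- mean(depths)
    cc <- 2 * beta / Tm
    C_MM <- sg2 * (s * Ti * Tj - (Ti + Tj) * s^2 / 2 + s^3 / 3)
    C_Mg_ij <- sg2 * (Ti * s - s^2 / 2)
    C_Mg_ji <- sg2 * (Tj * s - s^2 / 2)
    cc^2 * C_MM - cc * beta * (C_Mg_ij + C_Mg_ji) + beta^2 * sg2 * s
  }
}

#' Residual covariance of the OU/trend GLS model
#'
#' Assembles the phylogenetic residual covariance: the OU kernel
#' \code{Vy (1 - exp(-2 alpha s)) exp(-alpha d)} for a finite half-life, or
#' the Brownian kernel \code{Vy s} in the trend limit; plus diagonal
#' observation variance in the response; plus \code{b^2} times the
#' observation variance of each direct-effect predictor; plus the lag
#' covariance contributed by each Brownian predictor in the optimum.
#'
#' @param s Shared-time matrix (from \code{\link{phylo_matrices}}).
#' @param d Distance matrix.
#' @param depths Root-to-tip depths.
#' @param t_half Phylogenetic half-life in tree-height units (\code{Inf} for
#'   the trend limit).
#' @param vy Stationary variance (trend limit: diffusion variance per unit
#'   tree height); must be > 0.
#' @param y_obs_var Response observation variances (scalar or vector).
#' @param direct_slope Current direct-effect slope estimate(s).
#' @param direct_obs_var Matrix (n x p) of predictor observation variances
#'   matching \code{direct_slope}.
#' @param random_beta Current evolutionary slope estimate(s) for the
#'   Brownian predictor(s).
#' @param random_sg2 Brownian variance(s) of those predictors (per unit tree
#'   height).
#' @return The n x n covariance matrix.
#' @export
residual_covariance <- function(s, d, depths, t_half, vy,
                                y_obs_var = 0,
                                direct_slope = numeric(0), direct_obs_var = NULL,
                                random_beta = numeric(0), random_sg2 = numeric(0)) {
  stopifnot(t_half > 0, vy > 0)
  n <- nrow(s)
  alpha <- if (is.infinite(t_half)) 0 else log(2) / t_half
  V <- if (alpha > 0) vy * (1 - exp(-2 * alpha * s)) * exp(-alpha * d) else vy * s
  diag(V) <- diag(V) + rep_len(y_obs_var, n)
  if (length(direct_slope)) {
    ev <- as.matrix(direct_obs_var)
    for (p in seq_along(direct_slope))
      diag(V) <- diag(V) + direct_slope[p]^2 * ev[, p]
  }
  if (length(random_beta)) {
    for (q in seq_along(random_beta))
      V <- V + bm_lag_cov(s, depths, alpha, random_beta[q], random_sg2[q])
  }
  V
}

#' Generalized least squares via Cholesky factorization
#'
#' Solves \code{beta = (X' V^-1 X)^-1 X' V^-1 y} by whitening with the
#' Cholesky factor of \code{V} (never an explicit inverse), and returns the
#' coefficient covariance, the GLS residual sum of squares
#' \code{(y - X beta)' V^-1 (y - X beta)}, and \code{log|V|}.
#'
#' @param X Design matrix (full column rank).
#' @param V Positive-definite covariance.
#' @param y Response vector.
#' @return List with \code{beta}, \code{cov}, \code{rss}, \code{logdet},
#'   \code{fitted}.
#' @export
gls_solve <- function(X, V, y) {
  R <- tryCatch(chol(V), error = function(e)
    stop("residual covariance is not positive definite (condition estimate ",
         format(tryCatch(kappa(V), error = function(e2) NA), digits = 3), ")"))
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) {
    aliased <- colnames(Xs)[qx$pivot[(qx$rank + 1):ncol(Xs)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, ys)
  fitted_s <- qr.fitted(qx, ys)
  rss <- sum((ys - fitted_s)^2)
  ci <- chol2inv(qr.R(qx))
  covb <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  covb[qx$pivot, qx$pivot] <- ci
  list(beta = stats::setNames(as.vector(beta), colnames(X)),
       cov = covb, rss = rss,
       logdet = 2 * sum(log(diag(R))),
       fitted = as.vector(X %*% beta))
}

# ML Brownian-motion moments of a predictor on the tree: GLS mean and the
# ML variance rate (used for the lag term's sg2).
bm_ml <- function(x, s) {
  n <- length(x)
  R <- chol(s)
  ones <- backsolve(R, rep(1, n), transpose = TRUE)
  xs <- backsolve(R, x, transpose = TRUE)
  mu <- sum(ones * xs) / sum(ones^2)
  sg2 <- sum((xs - mu * ones)^2) / n
  list(mu = mu, sg2 = sg2)
}
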