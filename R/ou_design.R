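#' Convert between the adaptation rate and the phylogenetic half-life
#'
#' \code{t_half = ln(2) / alpha}; an infinite half-life is the Brownian
#' (trend) limit \code{alpha = 0}. When \code{original_height} is given the
#' half-life is also expressed in original time units.
#'
#' @param alpha Adaptation rate per unit tree height (give one of
#'   \code{alpha}/\code{t_half}).
#' @param t_half Phylogenetic half-life in tree-height units.
#' @param original_height Optional tree height in time units (e.g. myr).
#' @return List with \code{alpha}, \code{t_half}, and (when requested)
#'   \code{t_half_time}.
#' @export
convert_half_life <- function(alpha = NULL, t_half = NULL, original_height = NULL) {
  if (is.null(alpha) == is.null(t_half))
    stop("give exactly one of alpha or t_half")
  if (is.null(alpha)) {
    stopifnot(t_half > 0)
    alpha <- if (is.infinite(t_half)) 0 else log(2) / t_half
  } else {
    stopifnot(alpha >= 0)
    t_half <- if (alpha == 0) Inf else log(2) / alpha
  }
  out <- list(alpha = alpha, t_half = t_half)
  if (!is.null(original_height)) out$t_half_time <- t_half * original_height
  out
}

#' Adaptation weights of a lineage history
#'
#' Under an OU model with rate \code{alpha}, the expected trait at the tip is
#' a weighted sum of the ancestral state and the regime optima, the weight of
#' regime \code{r} being the integral of \code{alpha * exp(-alpha (T - t))}
#' over the time spent in \code{r}. The weights sum to one. In the trend
#' limit (\code{alpha = 0}) the ancestral weight is 1 and each regime weight
#' is the total time spent in it (tree-height units).
#'
#' @param history A \code{lineage_history} (see \code{\link{lineage_epochs}}).
#' @param alpha Adaptation rate (>= 0); 0 selects the trend limit.
#' @param levels Optional regime level set for the output order.
#' @return List with \code{ancestral} (scalar weight) and \code{regime}
#'   (named vector over \code{levels}).
#' @export
regime_weights <- function(history, alpha, levels = NULL) {
  stopifnot(alpha >= 0)
  Tt <- attr(history, "T")
  if (is.null(levels)) levels <- sort(unique(history$regime))
  w <- stats::setNames(numeric(length(levels)), levels)
  if (alpha == 0) {
    tm <- tapply(history$end - history$start, history$regime, sum)
    w[names(tm)] <- tm
    return(list(ancestral = 1, regime = w))
  }
  contrib <- exp(-alpha * (Tt - history$end)) - exp(-alpha * (Tt - history$start))
  cc <- tapply(contrib, history$regime, sum)
  w[names(cc)] <- cc
  list(ancestral = exp(-alpha * Tt), regime = w)
}

# Regime-weight design block for all tips: n x R matrix, plus the ancestral
# weight column. `histories` is a named list in row order.
regime_weight_matrix <- function(histories, alpha, levels) {
  W <- matrix(vapply(histories, function(h)
    regime_weights(h, alpha, levels)$regime, numeric(length(levels))),
    nrow = length(histories), ncol = length(levels), byrow = TRUE)
  colnames(W) <- levels
  anc <- vapply(histories, function(h) regime_weights(h, alpha, levels)$ancestral, 0)
  list(W = W, ancestral = anc)
}

#' Build the GLS design matrix for an OU/trend model
#'
#' Columns are the regime-weight columns (with the ancestral-state weight
#' absorbed into the root regime's column for finite \code{alpha}; in the
#' trend limit the constant ancestral column is dropped and trends are
#' estimated relative to the confounded root state), followed by one column
#' per direct-effect predictor and one per Brownian predictor, both holding
#' observed values. Without regimes a plain intercept column is used.
#'
#' @param histories Named list of \code{lineage_history} in data row order
#'   (or \code{NULL} for no regimes).
#' @param alpha Adaptation rate (0 = trend limit).
#' @param root_regime Regime at the root of the painting (needed for finite
#'   \code{alpha} with regimes).
#' @param direct Numeric matrix (or vector) of direct-effect predictors.
#' @param random Numeric matrix (or vector) of Brownian predictors.
#' @param levels Regime level set.
#' @return Design matrix with named columns; attribute
#'   \code{"regime_cols"} marks which columns are regime levels.
#' @export
build_design <- function(histories, alpha, root_regime = NULL,
                         direct = NULL, random = NULL, levels = NULL) {
  n <- if (!is.null(histories)) length(histories)
       else max(NROW(direct), NROW(random))
  if (!is.null(histories)) {
    if (is.null(levels))
      levels <- sort(unique(unlist(lapply(histories, function(h) h$regime))))
    rb <- regime_weight_matrix(histories, alpha, levels)
    X <- rb$W
    if (alpha > 0) {
      if (is.null(root_regime)) stop("root_regime required for finite alpha")
      X[, root_regime] <- X[, root_regime] + rb$ancestral
    }
    tot <- colSums(X)
    if (any(tot <= 1e-12)) {
      attr(X, "inestimable") <- levels[tot <= 1e-12]
      X <- X[, tot > 1e-12, drop = FALSE]
    }
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  regime_cols <- colnames(X)
  add <- function(X, v, prefix) {
    if (is.null(v)) return(X)
    v <- as.matrix(v)
    if (is.null(colnames(v))) colnames(v) <- paste0(prefix, seq_len(ncol(v)))
    cbind(X, v)
  }
  X2 <- add(add(X, direct, "direct"), random, "random")
  attr(X2, "regime_cols") <- if (!is.null(histories)) regime_cols else character(0)
  attr(X2, "inestimable") <- attr(X, "inestimable")
  X2
}

#' Attenuation factor between evolutionary and optimal regression
#'
#' For an OU response tracking a Brownian predictor, the regression slope
#' among extant species (the evolutionary slope) equals the slope of the
#' optimum times \code{rho = 1 - (1 - exp(-alpha T)) / (alpha T)}. The
#' optimal slope is therefore the evolutionary slope divided by \code{rho},
#' reported only for finite half-lives (\code{rho -> 0} in the trend limit).
#'
#' @param alpha Adaptation rate (>= 0; \code{Inf} allowed).
#' @param T Elapsed time (tree heights), default 1.
#' @return \code{rho} in \code{[0, 1]}.
#' @export
rho_factor <- function(alpha, T = 1) {
  stopifnot(alpha >= 0, T > 0)
  if (alpha == 0) return(0)
  if (is.infinite(alpha)) return(1)
  1 - (1 - exp(-alpha * T)) / (alpha * T)
}

#' Transform log-scale effects to published scales
#'
#' @param value Effect on the natural-log scale (a contrast, trend, or
#'   slope).
#' @param kind \code{"fold"} = \code{exp(value)};
#'   \code{"percent_change"} = \code{100 (exp(value) - 1)} for increases and
#'   \code{100 (1 - exp(value))} (a "percent downward" shift) for decreases;
#'   \code{"doubling_effect"} = \code{100 (1 - exp(value ln 2))}, the percent
#'   decrease per doubling of the predictor for a negative slope.
#' @return Transformed value(s); \code{percent_change} carries a
#'   \code{"direction"} attribute.
#' @export
effect_transform <- function(value, kind = c("fold", "percent_change",
                                             "doubling_effect")) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(value)))
  switch(kind,
    fold = exp(value),
    percent_change = {
      out <- ifelse(value >= 0, 100 * (exp(value) - 1), 100 * (1 - exp(value)))
      attr(out, "direction") <- ifelse(value >= 0, "up", "down")
      out
    },
    doubling_effect = 100 * (1 - exp(value * log(2)))
  )
}
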