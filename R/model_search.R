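#' Enumerate admissible predictor combinations
#'
#' Builds all subsets of the candidate predictor pool, always retaining the
#' direct-effect body-mass term, always including the allometric-only
#' baseline (the empty subset), and dropping any subset that contains two or
#' more members of an exclusion set (mutually incompatible predictors, e.g.
#' alternative codings of sociality).
#'
#' @param pool Named list describing candidate predictors; each element is a
#'   list with \code{type} = \code{"categorical"} or \code{"random"}.
#' @param exclusions List of character vectors; within each vector at most
#'   one member may appear in a model.
#' @param direct Direct-effect predictor column(s) present in every model.
#' @param response Response column.
#' @param response_var,direct_var Observation-variance columns (see
#'   \code{\link{model_spec}}).
#' @return List of \code{model_spec}s; the first is the baseline.
#' @export
enumerate_models <- function(pool, exclusions = list(), direct = "log_body_mass",
                             response = "log_ecv", response_var = NULL,
                             direct_var = NULL) {
  if (!length(pool)) stop("empty predictor pool")
  nm <- names(pool)
  if (is.null(nm) || any(nm == "")) stop("pool must be a named list")
  for (ex in exclusions) {
    if (anyDuplicated(ex)) stop("contradictory exclusions: a predictor is excluded with itself")
    if (!all(ex %in% nm)) stop("exclusion names predictors outside the pool: ",
                               paste(setdiff(ex, nm), collapse = ", "))
  }
  subsets <- lapply(0:(2^length(nm) - 1), function(mask)
    nm[bitwAnd(mask, bitwShiftL(1, seq_along(nm) - 1)) > 0])
  ok <- vapply(subsets, function(ss)
    !any(vapply(exclusions, function(ex) sum(ex %in% ss) >= 2, TRUE)), TRUE)
  subsets <- subsets[ok]
  # deterministic order: by size then lexicographic
  key <- vapply(subsets, function(ss) paste(sort(ss), collapse = "+"), "")
  subsets <- subsets[order(lengths(subsets), key)]
  lapply(subsets, function(ss) {
    types <- vapply(pool[ss], function(p) p$type, "")
    model_spec(response = response, direct = direct,
               random = if (any(types == "random")) ss[types == "random"] else NULL,
               categorical = if (any(types == "categorical")) ss[types == "categorical"] else NULL,
               response_var = response_var, direct_var = direct_var)
  })
}

#' Fit a list of model specifications
#'
#' @param specs List of \code{model_spec}s (e.g. from
#'   \code{\link{enumerate_models}}).
#' @param data,tree,paintings,... Passed to \code{\link{profile_fit}}.
#' @return List of \code{ou_fit}s (failed fits are kept as \code{NULL} with
#'   a warning).
#' @export
fit_models <- function(specs, data, tree, paintings = NULL, ...) {
  lapply(specs, function(sp) {
    tryCatch(profile_fit(data, tree, sp, paintings, ...),
             error = function(e) {
               warning("fit failed for ", format(sp), ": ", conditionMessage(e))
               NULL
             })
  })
}

#' Rank fitted models by AICc
#'
#' @param fits List of \code{ou_fit}s; the baseline (allometric-only) fit is
#'   taken to be the one whose spec has no categorical or random predictors,
#'   unless \code{baseline} is given.
#' @param baseline Optional index of the baseline fit.
#' @return Data frame sorted by AICc (ties broken by fewer parameters) with
#'   model formula, k, logLik, AICc, delta-AICc against the best model and
#'   against the baseline, R2 and residual R2 (percent).
#' @export
rank_models <- function(fits, baseline = NULL) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no successful fits to rank")
  if (is.null(baseline)) {
    is_base <- vapply(fits, function(f)
      !length(f$spec$categorical) && !length(f$spec$random), TRUE)
    baseline <- which(is_base)[1]
  }
  if (is.na(baseline)) stop("no allometric baseline fit found")
  base <- fits[[baseline]]
  df <- data.frame(
    model = vapply(fits, function(f) format(f$spec), ""),
    kind = vapply(fits, function(f) f$kind, ""),
    k = vapply(fits, function(f) f$k, 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    AICc = vapply(fits, function(f) f$AICc, 0),
    R2_pct = vapply(fits, function(f) 100 * f$R2, 0),
    t_half = vapply(fits, function(f) f$t_half, 0),
    stringsAsFactors = FALSE)
  df$dAICc_baseline <- df$AICc - base$AICc
  df$resid_R2_pct <- residual_r2_percent(df$R2_pct, 100 * base$R2)
  o <- order(df$AICc, df$k)
  df <- df[o, ]
  df$dAICc_best <- df$AICc - df$AICc[1]
  rownames(df) <- NULL
  df
}
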