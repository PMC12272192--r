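# Sample-wise paired t-maps with FDR control, per-event change summaries,
# and the random-slope linear mixed-effects models.

#' Sample-wise paired t-test map
#'
#' At every time-frequency(-channel) sample, a paired t-test across events of
#' event minus baseline log10 amplitude. Samples with fewer than two complete
#' pairs are undefined and masked. Adding any per-event constant to both
#' members of a pair leaves the map unchanged.
#'
#' @param event_arr,baseline_arr arrays whose first dimension indexes events
#'   (event x time x frequency (x channel)), identical shape; NAs allowed
#'   (e.g. rejected channels).
#' @param q FDR level for the significance mask.
#' @return object of class \code{"tmap"}: arrays \code{t}, \code{p},
#'   \code{n_pairs}, logical \code{significant} (BH at \code{q}), and
#'   \code{q}.
#' @export
ttest_map <- function(event_arr, baseline_arr, q = 0.01) {
  if (!identical(dim(event_arr), dim(baseline_arr)))
    stop("ttest_map: shape mismatch")
  d <- event_arr - baseline_arr
  dm <- dim(d)
  n_ev <- dm[1]
  mat <- matrix(d, nrow = n_ev)
  np <- colSums(!is.na(mat))
  m <- colMeans(mat, na.rm = TRUE)
  s <- apply(mat, 2, stats::sd, na.rm = TRUE)
  tt <- ifelse(np >= 2, m / (s / sqrt(np)), NA_real_)
  # degenerate samples: zero spread means t = 0 (no difference) or +/-Inf
  zero_s <- np >= 2 & s == 0
  tt[zero_s] <- sign(m[zero_s]) * ifelse(m[zero_s] == 0, 0, Inf)
  pp <- ifelse(np >= 2, 2 * stats::pt(-abs(tt), np - 1), NA_real_)
  shape <- dm[-1]
  out <- list(t = array(tt, shape), p = array(pp, shape),
              n_pairs = array(np, shape),
              significant = array(fdr_mask(pp, q), shape),
              q = q, n_events = n_ev)
  class(out) <- "tmap"
  out
}

#' @export
print.tmap <- function(x, ...) {
  ok <- !is.na(x$p)
  cat(sprintf("Paired t-map: %d events, %d samples, %.2f%% significant (FDR q = %g)\n",
              x$n_events, sum(ok),
              100 * mean(x$significant[ok]), x$q))
  invisible(x)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control applied jointly over all samples of a
#' map: a sample is rejected when its BH-adjusted p-value is at most
#' \code{q}. NAs are never rejected.
#'
#' @param p p-values in [0, 1] (vector or array; NAs allowed).
#' @param q FDR level.
#' @return logical mask, same shape as \code{p}.
#' @export
fdr_mask <- function(p, q = 0.01) {
  if (length(p) == 0) return(logical(0))
  adj <- stats::p.adjust(as.vector(p), method = "BH")
  mask <- !is.na(adj) & adj <= q
  if (!is.null(dim(p))) dim(mask) <- dim(p)
  mask
}

#' Per-event scalar EEG amplitude change
#'
#' Averages an end-locked change map over the time samples inside
#' \code{window}, all frequencies, and all retained channels (rejected
#' channels enter as NA and are excluded). The default window of -5 to +5 s
#' around the pause end is where the suppression is maximal.
#'
#' @param cm change-map array (time x frequency x channel) with a
#'   \code{time_s} attribute, or a list of them (one per event).
#' @param window time window in seconds relative to the lock point.
#' @return scalar per event (NA when every channel was rejected).
#' @export
summarize_change <- function(cm, window = c(-5, 5)) {
  one <- function(a) {
    tt <- attr(a, "time_s")
    if (is.null(tt)) stop("summarize_change: change map lacks a time axis")
    sel <- tt >= window[1] & tt < window[2]
    v <- a[sel, , , drop = FALSE]
    if (all(is.na(v))) return(NA_real_)
    mean(v, na.rm = TRUE)
  }
  if (is.list(cm)) vapply(cm, one, numeric(1)) else one(cm)
}

#' Fit a random-slope linear mixed-effects model
#'
#' Relates the per-event EEG amplitude change to a single covariate with a
#' fixed intercept and slope and per-infant random intercept and slope:
#' \deqn{Y_n = \beta_0 + \beta_1 X_{n,1} + \gamma_1 Z_{n,1} + \epsilon_n.}
#' Fitted by REML via \pkg{lme4}; the slope p-value uses Satterthwaite
#' degrees of freedom (\pkg{lmerTest}). If the random-effects covariance is
#' singular, the model is refitted with a random intercept only and flagged.
#' A categorical covariate (sleep state) enters as a factor and \code{p}
#' is the joint Satterthwaite F-test of its fixed effect.
#'
#' @param data data frame with the response, covariate and grouping columns.
#' @param covariate name of the fixed covariate column.
#' @param response name of the response column.
#' @param group name of the infant/grouping column.
#' @return object of class \code{"pause_lmm"}.
#' @export
fit_lmm <- function(data, covariate, response = "eeg_change",
                    group = "infant_id") {
  stopifnot(all(c(response, covariate, group) %in% names(data)))
  d <- data[stats::complete.cases(data[c(response, covariate, group)]), ]
  d$.y <- d[[response]]
  d$.x <- d[[covariate]]
  d$.g <- factor(d[[group]])
  categorical <- is.factor(d$.x) || is.character(d$.x)
  if (categorical) d$.x <- factor(d$.x)
  if (!categorical && stats::var(d$.x) == 0)
    stop("fit_lmm: covariate has zero variance")
  if (nlevels(d$.g) < 5)
    warning("fit_lmm: fewer than 5 infants; estimates will be unstable")

  quiet <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  # lmerTest provides Satterthwaite dfs; on numerically degenerate fits
  # (e.g. zero residual variance) it can fail where plain lme4 succeeds,
  # in which case p-values fall back to the normal approximation.
  fit_formula <- function(fml) {
    fit <- tryCatch(quiet(lmerTest::lmer(fml, data = d, REML = TRUE)),
                    error = function(e)
                      tryCatch(quiet(lme4::lmer(fml, data = d, REML = TRUE)),
                               error = function(e2)
                                 stop("fit_lmm: model failed to converge: ",
                                      conditionMessage(e2), call. = FALSE)))
    fit
  }

  fit <- fit_formula(.y ~ .x + (1 + .x | .g))
  structure_used <- "intercept+slope"
  if (lme4::isSingular(fit, tol = 1e-5) && !categorical) {
    fit <- fit_formula(.y ~ .x + (1 | .g))
    structure_used <- "intercept-only (singular random slope)"
  }
  satt <- inherits(fit, "lmerModLmerTest")
  df_method <- if (satt) "Satterthwaite" else "normal approximation"

  # degenerate fits (zero residual variance) can break vcov(); fall back to
  # point estimates with undefined standard errors
  ct <- tryCatch(stats::coef(suppressWarnings(summary(fit))),
                 error = function(e) {
                   fe <- lme4::fixef(fit)
                   m <- cbind(Estimate = fe, "Std. Error" = NA_real_)
                   rownames(m) <- names(fe)
                   m
                 })
  wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))
  if (categorical) {
    beta1 <- ct[-1, "Estimate"]
    se1 <- ct[-1, "Std. Error"]
    p1 <- tryCatch({
      if (!satt) stop("no Satterthwaite")
      suppressWarnings(stats::anova(fit, type = 2))[["Pr(>F)"]][1]
    }, error = function(e)
      stats::pchisq(sum((beta1 / se1)^2), df = length(beta1),
                    lower.tail = FALSE))
  } else {
    beta1 <- ct[".x", "Estimate"]
    se1 <- ct[".x", "Std. Error"]
    p1 <- if (satt) ct[".x", "Pr(>|t|)"] else wald_p(beta1, se1)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(beta0 = unname(ct["(Intercept)", "Estimate"]),
              beta1 = unname(beta1), se_beta1 = unname(se1),
              p_beta1 = unname(p1),
              df_method = df_method,
              covariate = covariate, categorical = categorical,
              random_structure = structure_used,
              varcor = vc,
              random_effects = lme4::ranef(fit)$.g,
              residuals = stats::residuals(fit),
              n_events = nrow(d), n_infants = nlevels(d$.g),
              model = fit)
  class(out) <- "pause_lmm"
  out
}

#' @export
print.pause_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model: eeg_change ~ %s + (random %s per infant)\n",
              x$covariate, x$random_structure))
  cat(sprintf("  n = %d events, %d infants\n", x$n_events, x$n_infants))
  if (x$categorical) {
    cat("  level effects:", paste(sprintf("%.4g", x$beta1), collapse = ", "),
        "\n")
    cat(sprintf("  joint fixed-effect p = %.4g (%s)\n", x$p_beta1, x$df_method))
  } else {
    cat(sprintf("  beta0 = %.4g, beta1 = %.4g (SE %.3g), p = %.4g (%s)\n",
                x$beta0, x$beta1, x$se_beta1, x$p_beta1, x$df_method))
  }
  invisible(x)
}

#' @export
summary.pause_lmm <- function(object, ...) {
  print(object)
  cat("  variance components:\n")
  vc <- object$varcor
  for (i in seq_len(nrow(vc)))
    cat(sprintf("    %s %s: sd = %.4g\n", vc$grp[i],
                paste(stats::na.omit(c(vc$var1[i], vc$var2[i])), collapse = ":"),
                vc$sdcor[i]))
  invisible(object)
}

#' @export
coef.pause_lmm <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
residuals.pause_lmm <- function(object, ...) object$residuals

#' @export
predict.pause_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  stats::predict(object$model, newdata = newdata, ...)
}

#' Simulate data from the random-slope mixed model
#'
#' Draws per-infant random intercepts and slopes and i.i.d. residuals from
#' the model that [fit_lmm()] estimates; used for parameter-recovery
#' validation.
#'
#' @param n_infants,n_per_infant design size.
#' @param beta0,beta1 fixed effects.
#' @param intercept_sd,slope_sd random-effect SDs.
#' @param resid_sd residual SD.
#' @param x_mean,x_sd covariate distribution.
#' @param seed RNG seed.
#' @return data frame with \code{eeg_change}, \code{x}, \code{infant_id}.
#' @export
simulate_lmm_data <- function(n_infants = 60, n_per_infant = 20,
                              beta0 = 0, beta1 = 0.001,
                              intercept_sd = 0.02, slope_sd = 0.0005,
                              resid_sd = 0.05,
                              x_mean = -20, x_sd = 10, seed = 1) {
  set.seed(seed)
  b0 <- stats::rnorm(n_infants, 0, intercept_sd)
  b1 <- stats::rnorm(n_infants, 0, slope_sd)
  g <- rep(seq_len(n_infants), each = n_per_infant)
  x <- stats::rnorm(length(g), x_mean, x_sd)
  y <- beta0 + b0[g] + (beta1 + b1[g]) * x +
    stats::rnorm(length(g), 0, resid_sd)
  data.frame(eeg_change = y, x = x,
             infant_id = sprintf("inf%03d", g))
}
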