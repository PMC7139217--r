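# Nonlinear curve fits for steady-state kinetics: Michaelis-Menten activation
# (ATPase rate vs microtubule concentration) and the three-parameter Hill
# inhibition curve used for inhibitor titrations.

#' Fit a Michaelis-Menten curve
#'
#' Nonlinear least squares of `v = Vmax * S / (K + S)`. Initialization is
#' deterministic: `Vmax0 = max(rate)` and `K0` is the concentration at
#' half-maximal rate by linear interpolation.
#'
#' @param conc activator/substrate concentrations (>= 3 distinct values).
#' @param rate observed velocities (non-negative).
#' @param weights optional per-point weights (e.g. 1/SD^2 of replicate means);
#'   unweighted by default.
#' @return object of class `mm_fit` with elements `vmax`, `k_half`, `se`
#'   (named standard errors), `rss`, `r_squared`, `fit` (the `nls` object).
#' @examples
#' s <- c(2, 5, 10, 20, 50, 100)
#' f <- fit_michaelis_menten(s, 2 * s / (10 + s))
#' c(f$vmax, f$k_half)
#' @export
fit_michaelis_menten <- function(conc, rate, weights = NULL) {
  conc <- as.numeric(conc)
  rate <- as.numeric(rate)
  if (length(conc) != length(rate)) stop("conc and rate lengths differ")
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (any(rate < 0)) stop("rates must be non-negative")
  if (all(rate == 0))
    stop("fit-failure: all rates are zero (Vmax at boundary)")
  vmax0 <- max(rate)
  k0 <- .half_point(conc, rate, vmax0 / 2, increasing = TRUE)
  df <- data.frame(S = conc, v = rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (K + S), data = df,
                      start = list(Vmax = vmax0, K = k0),
                      lower = c(Vmax = 0, K = 1e-12),
                      weights = weights %||% rep(1, nrow(df)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit-failure: Michaelis-Menten fit did not converge (",
           conditionMessage(e), ")"))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, K = NA_real_))
  rss <- deviance(fit)
  tss <- sum((rate - mean(rate))^2)
  structure(list(vmax = unname(est["Vmax"]), k_half = unname(est["K"]),
                 se = c(vmax = unname(se["Vmax"]), k_half = unname(se["K"])),
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g +/- %.2g, K1/2 = %.4g +/- %.2g (RSS %.3g)\n",
              x$vmax, x$se["vmax"], x$k_half, x$se["k_half"], x$rss))
  invisible(x)
}

#' Fit a three-parameter inhibition (IC50/Hill) curve
#'
#' Least squares of `y = a / (1 + (x/b)^c)` where `a` is the uninhibited
#' level, `b` the IC50 and `c` the Hill coefficient; by construction the
#' fitted curve equals `a/2` at `x = b`. Zero concentrations are handled on
#' the linear axis (the model value at `x = 0` is `a` for `c > 0`).
#' All three parameters are free.
#'
#' @param conc inhibitor concentrations (>= 0).
#' @param activity response, typically percent of the uninhibited rate.
#' @param weights optional per-point weights.
#' @return object of class `ic50_fit` with elements `a`, `b` (IC50), `c`
#'   (Hill coefficient), `se`, `rss`, `r_squared`, `fit`.
#' @export
fit_ic50 <- function(conc, activity, weights = NULL) {
  conc <- as.numeric(conc)
  activity <- as.numeric(activity)
  if (length(conc) != length(activity)) stop("conc and activity lengths differ")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (length(unique(activity)) == 1L)
    stop("fit-failure: all activities identical; no midpoint to fit")
  a0 <- max(activity)
  b0 <- .half_point(conc, activity, a0 / 2, increasing = FALSE)
  df <- data.frame(x = conc, y = activity)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + (x / b)^c), data = df,
                      start = list(a = a0, b = b0, c = 1),
                      lower = c(a = 0, b = 1e-12, c = 0.01),
                      upper = c(a = Inf, b = Inf, c = 100),
                      weights = weights %||% rep(1, nrow(df)),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      stop("fit-failure: IC50 fit did not converge (",
           conditionMessage(e), ")"))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), c("a", "b", "c")))
  rss <- deviance(fit)
  tss <- sum((activity - mean(activity))^2)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = unname(est["c"]),
                 se = c(a = unname(se["a"]), b = unname(se["b"]),
                        c = unname(se["c"])),
                 rss = rss, r_squared = 1 - rss / tss, fit = fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit y = a/(1+(x/b)^c): a = %.4g, IC50 = %.4g, Hill c = %.3g (R^2 = %.4f)\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Evaluate a fitted inhibition curve
#'
#' @param object an `ic50_fit`.
#' @param x concentrations at which to evaluate.
#' @param ... unused.
#' @return fitted activities.
#' @export
predict.ic50_fit <- function(object, x, ...) {
  object$a / (1 + (x / object$b)^object$c)
}

#' @export
predict.mm_fit <- function(object, x, ...) {
  object$vmax * x / (object$k_half + x)
}

# concentration where the response crosses `target`, by interpolation along
# the concentration axis; falls back to the nearest observed point
.half_point <- function(conc, resp, target, increasing = TRUE) {
  ord <- order(conc)
  cs <- conc[ord]
  rs <- resp[ord]
  cross <- if (increasing) which(rs >= target) else which(rs <= target)
  est <- if (length(cross) && cross[1] > 1L) {
    i <- cross[1]
    r1 <- rs[i - 1]; r2 <- rs[i]
    if (r2 != r1)
      cs[i - 1] + (target - r1) / (r2 - r1) * (cs[i] - cs[i - 1])
    else cs[i]
  } else {
    cs[which.min(abs(rs - target))]
  }
  max(est, min(cs[cs > 0], na.rm = TRUE) * 1e-3, 1e-9)
}
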