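#' Ordinary nonparametric bootstrap of the mean velocity
#'
#' Resamples the per-molecule velocities with replacement and records the
#' mean of each resample, approximating the sampling distribution of the
#' cohort mean from the 10-18 molecules a typical single-molecule cohort
#' contains.
#'
#' @param velocities Numeric vector of per-molecule velocities (bp/s).
#' @param resamples Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `bootstrap_mean`: `means` (one per resample),
#'   `mean`, `sd`, `resamples`, `n`, `sample_mean`, `sample_sd`, `seed`.
#' @export
bootstrap_mean <- function(velocities, resamples = 100, seed = NULL) {
  n <- length(velocities)
  if (n < 2) stop("need at least 2 velocities to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(resamples), function(i) {
    mean(sample(velocities, n, replace = TRUE))
  }, numeric(1))
  structure(list(means = means, mean = mean(means), sd = sd(means),
                 resamples = resamples, n = n,
                 sample_mean = mean(velocities),
                 sample_sd = sd(velocities), seed = seed),
            class = "bootstrap_mean")
}

#' @export
print.bootstrap_mean <- function(x, ...) {
  cat("<bootstrap_mean> ", x$resamples, " resamples of n = ", x$n,
      ": mean ", signif(x$mean, 4), " +/- ", signif(x$sd, 3),
      " bp/s (sample ", signif(x$sample_mean, 4), " +/- ",
      signif(x$sample_sd, 3), ")\n", sep = "")
  invisible(x)
}

#' Percentile interval of a bootstrap distribution
#' @param x A `bootstrap_mean`.
#' @param level Coverage (default 0.95).
#' @return Two-element vector (lower, upper).
#' @export
bootstrap_ci <- function(x, level = 0.95) {
  stopifnot(inherits(x, "bootstrap_mean"))
  a <- (1 - level) / 2
  quantile(x$means, c(a, 1 - a), names = FALSE)
}

#' Fit Michaelis-Menten kinetics to the ATP dependence
#'
#' Fits `v = Vmax * S / (Km + S)` by bounded nonlinear least squares
#' (initialised at `Vmax = max(v)`, `Km = median(S)`). With exactly two
#' distinct substrate concentrations the hyperbola is inverted algebraically.
#'
#' @param S Substrate (ATP) concentrations (mM).
#' @param v Velocities (bp/s), same length as `S`.
#' @param weights Optional fit weights (e.g. `1/sd^2`); unweighted by
#'   default.
#' @return An object of class `mm_fit`: `Vmax` (bp/s), `Km` (mM), `points`,
#'   `fit` (the `nls` object, or `NULL` for the two-point solve),
#'   `converged`. Supports `print()`, `coef()` and `predict()`.
#' @examples
#' S <- c(0.25, 0.5, 1.0, 2.5, 5.0)
#' fit <- fit_michaelis_menten(S, 4.69 * S / (1.03 + S))
#' coef(fit)
#' @export
fit_michaelis_menten <- function(S, v, weights = NULL) {
  stopifnot(length(S) == length(v))
  if (any(v < 0)) stop("velocities must be >= 0")
  nS <- length(unique(S))
  if (nS < 2) stop("need at least 2 distinct substrate concentrations")
  if (nS == 2 && length(S) == 2) {
    # exact inversion of the hyperbola through two points
    Km <- S[1] * S[2] * (v[1] - v[2]) / (v[2] * S[1] - v[1] * S[2])
    Vmax <- v[1] * (Km + S[1]) / S[1]
    if (!is.finite(Km) || Km <= 0 || Vmax <= 0)
      stop("two-point solve gives non-positive parameters")
    out <- list(Vmax = Vmax, Km = Km,
                points = data.frame(S = S, v = v), fit = NULL,
                converged = TRUE)
    class(out) <- "mm_fit"
    return(out)
  }
  dat <- data.frame(S = S, v = v)
  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fit <- minpack.lm::nls.lm(
    par = c(Vmax = max(v), Km = unname(median(S))),
    lower = c(Vmax = 1e-12, Km = 1e-12),
    fn = function(p) sqrt(w) * (v - p[1] * S / (p[2] + S)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("Michaelis-Menten fit did not converge: ", fit$message)
  structure(list(Vmax = unname(fit$par["Vmax"]), Km = unname(fit$par["Km"]),
                 points = dat, fit = fit, converged = TRUE),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Vmax = ", signif(x$Vmax, 4), " bp/s, Km = ",
      signif(x$Km, 4), " mM (", nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(Vmax = object$Vmax, Km = object$Km)
}

#' @export
predict.mm_fit <- function(object, S = NULL, ...) {
  if (is.null(S)) S <- object$points$S
  object$Vmax * S / (object$Km + S)
}

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$points$S, x$points$v, xlab = "[ATP] (mM)",
       ylab = "unwinding velocity (bp/s)", ...)
  Sg <- seq(0, max(x$points$S) * 1.05, length.out = 200)
  lines(Sg, predict(x, Sg), col = "red")
  invisible(x)
}

#' ATPase rate from a coupled-assay absorbance trace
#'
#' In the NADH-coupled assay the ATP hydrolysis rate is proportional to the
#' rate of absorbance decrease at 340 nm:
#' `rate (uM/min) = |dA340/dt| (1/s) * 9820`. The constant embeds the NADH
#' extinction coefficient and path length and is taken as given.
#'
#' @param t_s Times (s).
#' @param a340 Absorbance values at 340 nm.
#' @param window Optional two-element time range (s) delimiting the linear
#'   section used for the slope.
#' @return An object of class `atpase_rate`: `slope_A340` (1/s, magnitude of
#'   the decrease), `rate` (uM/min), `n`.
#' @examples
#' t <- 0:120
#' atpase_rate(t, 1 - 3.318e-3 * t) # ~32.6 uM/min
#' @export
atpase_rate <- function(t_s, a340, window = NULL) {
  stopifnot(length(t_s) == length(a340))
  if (!is.null(window)) {
    sel <- t_s >= window[1] & t_s <= window[2]
    t_s <- t_s[sel]
    a340 <- a340[sel]
  }
  if (length(t_s) < 2) stop("need at least 2 points in the fit window")
  slope <- unname(coef(lm(a340 ~ t_s))[2])
  tol <- 1e-12 * max(abs(a340), 1)
  if (slope > tol) {
    warning("A340 increases over the window; reporting rate 0")
    slope <- 0
  } else if (slope > 0) {
    slope <- 0
  }
  structure(list(slope_A340 = abs(slope), rate = abs(slope) * 9820,
                 n = length(t_s)),
            class = "atpase_rate")
}

#' @export
print.atpase_rate <- function(x, ...) {
  cat("<atpase_rate> |dA340/dt| = ", signif(x$slope_A340, 4),
      " 1/s -> ", signif(x$rate, 4), " uM/min\n", sep = "")
  invisible(x)
}

#' Normalised gel-shift unwinding percentage
#'
#' `%Unwound = (%Us - %U0) / (%U100 - %U0) * 100`, where `Us` is the sample
#' lane, `U0` the unreacted control and `U100` the heat-denatured control.
#'
#' @param Us,U0,U100 Percent single-stranded signal of the sample, unreacted
#'   and boiled lanes.
#' @return Normalised percentage. Carries attribute `out_of_range = TRUE`
#'   when outside \[0, 100\] (the value itself is not clipped).
#' @examples
#' percent_unwound(50, 10, 90) # 50
#' @export
percent_unwound <- function(Us, U0, U100) {
  if (U100 == U0) stop("U100 must differ from U0")
  out <- (Us - U0) / (U100 - U0) * 100
  if (out < 0 || out > 100) attr(out, "out_of_range") <- TRUE
  out
}

#' Fold change relative to a reference
#'
#' @param value,reference Positive measurements (e.g. velocities or
#'   efficiencies); `reference > 0`.
#' @return `value / reference`.
#' @examples
#' fold_change(7.50, 3.58) # ~2.09
#' @export
fold_change <- function(value, reference) {
  if (reference <= 0) stop("reference must be > 0")
  value / reference
}

#' Tether-disappearance time course
#'
#' The cumulative percentage of beads lost versus reaction time directly
#' reports the progress of unwinding across the field of view. The empirical
#' curve is fitted with a saturating exponential; the default amplitude form
#' is `y = y0 + A * (1 - exp(-x/t))`. A variant with the amplitude tied to
#' `1/t` is available as `model = "verbatim"`, but its prefactor is
#' dimensionally inconsistent with a percent axis and the amplitude form is
#' the default.
#'
#' @param times Bead-loss times (s).
#' @param total Total number of beads observed (>= number of losses).
#' @param model `"amplitude"` or `"verbatim"`.
#' @return An object of class `disappearance_curve`: `times`, `fraction`
#'   (cumulative percent lost at each loss time), `total`, `fit` (`NULL` when
#'   no losses or the fit is skipped), `coef`, `model`.
#' @export
disappearance_curve <- function(times, total,
                                model = c("amplitude", "verbatim")) {
  model <- match.arg(model)
  if (total < length(times)) stop("total must be >= number of events")
  times <- sort(times)
  k <- length(times)
  frac <- if (k > 0) 100 * seq_len(k) / total else numeric(0)
  out <- list(times = times, fraction = frac, total = total, fit = NULL,
              coef = NULL, model = model)
  class(out) <- "disappearance_curve"
  if (k < 4 || length(unique(times)) < 3) return(out)
  dat <- data.frame(x = times, y = frac)
  form <- if (model == "amplitude")
    y ~ y0 + A * (1 - exp(-x / tc)) else y ~ y0 + (1 - (1 / tc) * exp(-x / tc))
  start <- if (model == "amplitude")
    list(y0 = 0, A = max(frac), tc = unname(median(times))) else
    list(y0 = mean(frac), tc = unname(median(times)))
  fit <- try(minpack.lm::nlsLM(form, data = dat, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    out$fit <- fit
    out$coef <- coef(fit)
  }
  out
}

#' @export
print.disappearance_curve <- function(x, ...) {
  cat("<disappearance_curve> ", length(x$times), "/", x$total,
      " beads lost", sep = "")
  if (!is.null(x$coef)) {
    cat(" | fit (", x$model, "): ",
        paste(names(x$coef), signif(x$coef, 4), sep = " = ",
              collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.disappearance_curve <- function(x, ...) {
  plot(stats::stepfun(x$times, c(0, x$fraction)), do.points = FALSE,
       xlab = "time (s)", ylab = "beads disappeared (%)", main = "", ...)
  if (!is.null(x$fit)) {
    xg <- seq(0, max(x$times) * 1.05, length.out = 200)
    lines(xg, predict(x$fit, newdata = data.frame(x = xg)), col = "red")
  }
  invisible(x)
}
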