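#' Fit an equilibrium dissociation constant from an anisotropy curve
#'
#' Nonlinear least-squares fit of the hyperbolic saturation model
#' `y = A_free + (A_bound - A_free) * P / (Kd + P)` (the standard
#' anisotropy form when the labeled probe concentration is well below the
#' dissociation constant, so ligand depletion is negligible). A quadratic
#' ligand-depletion variant using the probe concentration is available via
#' `model = "quadratic"`. Initialisation is multi-start over a geometric
#' grid of candidate Kd values; the best-converged fit by residual sum of
#' squares is kept.
#'
#' @param conc protein concentrations in nM (>= 5 distinct values).
#' @param y anisotropy measurements, matched length.
#' @param probe_conc labeled-probe concentration in nM (used only by the
#'   quadratic model; typical experiments use 0.5 nM).
#' @param model `"hyperbolic"` (default) or `"quadratic"`.
#' @param n_boot residual-bootstrap replicates for the stderr (0 = use the
#'   asymptotic standard error from the fit's local curvature).
#' @param seed seed for the bootstrap.
#' @return an object of class `c("kd_fit", "binding_fit")`: list with
#'   `param` (Kd, nM), `stderr`, `floor`, `ceiling`, `residual_ss`,
#'   `converged`, `n_boot`, `model`, and the data.
#' @export
fit_kd <- function(conc, y, probe_conc = 0.5,
                   model = c("hyperbolic", "quadratic"),
                   n_boot = 0L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(y), all(conc >= 0))
  if (length(unique(conc)) < 5L)
    stop("need at least 5 distinct concentrations")
  dat <- data.frame(P = conc, y = y)
  fb <- function(P, Kd) P / (Kd + P)
  if (model == "quadratic") {
    R <- probe_conc
    fb <- function(P, Kd)
      ((Kd + P + R) - sqrt((Kd + P + R)^2 - 4 * P * R)) / (2 * R)
  }
  fit_one <- function(kd0) {
    tryCatch(
      minpack.lm::nlsLM(y ~ Af + (Ab - Af) * fb(P, Kd), data = dat,
                        start = list(Af = min(y), Ab = max(y), Kd = kd0),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- exp(seq(log(max(min(conc[conc > 0]), 1e-3)),
                    log(max(conc)), length.out = 7L))
  fits <- Filter(Negate(is.null), lapply(starts, fit_one))
  if (length(fits) == 0L) {
    return(structure(list(param = NA_real_, stderr = NA_real_,
                          floor = NA_real_, ceiling = NA_real_,
                          residual_ss = NA_real_, converged = FALSE,
                          n_boot = 0L, model = model, data = dat,
                          message = "no start converged"),
                     class = c("kd_fit", "binding_fit")))
  }
  ss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(ss)]]
  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients["Kd", "Std. Error"],
                 error = function(e) NA_real_)
  if (n_boot > 0L) {
    res <- stats::resid(best)
    fitted_y <- stats::fitted(best)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      yb <- fitted_y + sample(res, replace = TRUE)
      db <- data.frame(P = dat$P, y = yb)
      fb2 <- tryCatch(
        minpack.lm::nlsLM(y ~ Af + (Ab - Af) * fb(P, Kd), data = db,
                          start = as.list(est), lower = c(-Inf, -Inf, 1e-12)),
        error = function(e) NULL)
      if (is.null(fb2)) NA_real_ else stats::coef(fb2)[["Kd"]]
    }, numeric(1)))
    se <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(param = unname(est["Kd"]), stderr = unname(se),
                 floor = unname(est["Af"]), ceiling = unname(est["Ab"]),
                 residual_ss = min(ss), converged = TRUE,
                 n_boot = as.integer(n_boot), model = model, data = dat),
            class = c("kd_fit", "binding_fit"))
}

#' Normalise a decay curve to percent remaining
#'
#' Intensities are expressed as a percentage of the intensity at time
#' zero.
#'
#' @param time time points in hours, sorted ascending with `time[1] == 0`.
#' @param intensity matched nonnegative intensities with `intensity[1] > 0`.
#' @return data frame with columns `time` and `percent_remaining`.
#' @export
percent_remaining <- function(time, intensity) {
  stopifnot(length(time) == length(intensity), !is.unsorted(time))
  if (time[1L] != 0) stop("the first time point must be 0")
  if (intensity[1L] <= 0) stop("intensity at time zero must be positive")
  data.frame(time = time, percent_remaining = 100 * intensity / intensity[1L])
}

#' Fit an RNA half-life from a decay time course
#'
#' Fit of `y = y0 * 2^(-t / t_half)`. Under the default absolute error
#' model, nonlinear least squares on the raw scale, seeded by the
#' log-linear regression of `log(y)` on `t` and never returning a worse
#' raw-scale residual sum than that seed. Under `error_model = "relative"`
#' — appropriate when measurement error scales with the signal, as in gel
#' densitometry — the fit minimises squared error of `log(y)`, which is
#' the maximum-likelihood estimator for constant-CV noise (and there the
#' log-linear solution is itself the optimum). When the series shows no
#' identifiable decay (no observation below 90 percent of the initial
#' intensity), a censored lower bound on the half-life — the span of the
#' observation window — is reported instead of a point estimate, the
#' appropriate summary for chemically stabilised RNAs whose decay is not
#' measurable within the experiment.
#'
#' @param time time points in hours (>= 4, sorted ascending, first = 0;
#'   replicate observations may share time points).
#' @param intensity matched nonnegative intensities.
#' @param error_model `"absolute"` (raw-scale least squares) or
#'   `"relative"` (log-scale least squares, constant-CV noise).
#' @return an object of class `c("halflife_fit", "binding_fit")`: list with
#'   `param` (half-life, h; `NA` when censored), `lower_bound` (h; `NA`
#'   when a point estimate exists), `stderr`, `y0`, `residual_ss`
#'   (raw scale), `converged`, `censored`, and the data.
#' @export
fit_half_life <- function(time, intensity,
                          error_model = c("absolute", "relative")) {
  error_model <- match.arg(error_model)
  stopifnot(length(time) == length(intensity))
  if (length(time) < 4L) stop("need at least 4 time points")
  if (is.unsorted(time)) stop("time must be sorted ascending")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  dat <- data.frame(t = time, y = intensity)
  y0_obs <- mean(intensity[time == min(time)])
  if (y0_obs <= 0) stop("intensity at the first time point must be positive")
  if (min(intensity) >= 0.9 * y0_obs) {
    return(structure(list(param = NA_real_, lower_bound = max(time),
                          stderr = NA_real_, y0 = y0_obs,
                          residual_ss = NA_real_, converged = FALSE,
                          censored = TRUE, data = dat),
                     class = c("halflife_fit", "binding_fit")))
  }
  ## log-linear solution on the positive observations
  posi <- intensity > 0
  fitl <- stats::lm(log(y) ~ t, data = dat[posi, ])
  slope <- stats::coef(fitl)[["t"]]
  th0 <- if (slope < 0) -log(2) / slope else max(time)
  y00 <- exp(stats::coef(fitl)[["(Intercept)"]])
  if (error_model == "relative") {
    se_slope <- tryCatch(
      suppressWarnings(summary(fitl)$coefficients["t", "Std. Error"]),
      error = function(e) NA_real_)
    est <- c(y0 = y00, th = th0)
    ssq <- sum((intensity - y00 * 2^(-time / th0))^2)
    se <- if (is.finite(se_slope) && slope < 0) log(2) * se_slope / slope^2
          else NA_real_
  } else {
    seed_ss <- sum((intensity - y00 * 2^(-time / th0))^2)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y0 * 2^(-t / th), data = dat,
                        start = list(y0 = y00, th = th0),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || sum(stats::resid(fit)^2) > seed_ss) {
      ## fall back to the log-linear solution (never worse than the seed)
      est <- c(y0 = y00, th = th0)
      ssq <- seed_ss
      se <- NA_real_
    } else {
      est <- stats::coef(fit)
      ssq <- sum(stats::resid(fit)^2)
      se <- tryCatch(summary(fit)$coefficients["th", "Std. Error"],
                     error = function(e) NA_real_)
    }
  }
  structure(list(param = unname(est[["th"]]), lower_bound = NA_real_,
                 stderr = unname(se), y0 = unname(est[["y0"]]),
                 residual_ss = ssq, converged = TRUE, censored = FALSE,
                 data = dat),
            class = c("halflife_fit", "binding_fit"))
}

#' @export
print.binding_fit <- function(x, ...) {
  if (inherits(x, "kd_fit")) {
    if (!x$converged) cat("Kd fit failed:", x$message, "\n")
    else cat("Kd = ", signif(x$param, 4), " nM (stderr ", signif(x$stderr, 3),
             "), floor ", signif(x$floor, 3), ", ceiling ", signif(x$ceiling, 3),
             ", RSS ", signif(x$residual_ss, 3), "\n", sep = "")
  } else {
    if (x$censored)
      cat("Half-life not identifiable within the observation window: ",
          "t1/2 > ", x$lower_bound, " h (censored bound)\n", sep = "")
    else cat("Half-life = ", signif(x$param, 4), " h (stderr ",
             signif(x$stderr, 3), "), y0 ", signif(x$y0, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method stats::coef
coef.binding_fit <- function(object, ...) {
  if (inherits(object, "kd_fit"))
    c(Kd = object$param, floor = object$floor, ceiling = object$ceiling)
  else c(t_half = object$param, y0 = object$y0)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (inherits(object, "kd_fit")) {
    P <- if (is.null(newdata)) object$data$P else newdata
    object$floor + (object$ceiling - object$floor) * P / (object$param + P)
  } else {
    t <- if (is.null(newdata)) object$data$t else newdata
    object$y0 * 2^(-t / object$param)
  }
}

#' @exportS3Method stats::residuals
residuals.binding_fit <- function(object, ...) {
  obs <- if (inherits(object, "kd_fit")) object$data$y else object$data$y
  obs - predict(object)
}

#' @exportS3Method graphics::plot
plot.binding_fit <- function(x, ...) {
  if (inherits(x, "kd_fit")) {
    graphics::plot(x$data$P, x$data$y, log = "x",
                   xlab = "protein (nM)", ylab = "anisotropy", ...)
    P <- exp(seq(log(min(x$data$P[x$data$P > 0])), log(max(x$data$P)),
                 length.out = 200))
    graphics::lines(P, predict(x, P))
  } else {
    graphics::plot(x$data$t, x$data$y, xlab = "time (h)", ylab = "intensity", ...)
    if (!x$censored) {
      t <- seq(min(x$data$t), max(x$data$t), length.out = 200)
      graphics::lines(t, predict(x, t))
    }
  }
  invisible(x)
}
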