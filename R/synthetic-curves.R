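#' Configuration for simulated binding or decay curves
#'
#' @param true_param ground-truth parameter: equilibrium dissociation
#'   constant in nM (binding) or half-life in hours (decay).
#' @param x_values protein concentrations (nM) or time points (h);
#'   strictly positive for binding, nonnegative sorted for decay.
#' @param y_floor,y_ceiling free and bound anisotropy (binding), or
#'   `y_ceiling` the initial intensity (decay; `y_floor` unused).
#' @param noise_sd Gaussian noise scale: the standard deviation on y
#'   (`noise_type = "additive"`) or the coefficient of variation
#'   (`noise_type = "proportional"`, the realistic model for densitometry
#'   readouts whose error grows with the signal).
#' @param noise_type `"additive"` or `"proportional"`.
#' @param n_replicates replicate curves drawn per call.
#' @param seed integer seed.
#' @return an object of class `curve_config`.
#' @export
curve_config <- function(true_param, x_values, y_floor = 0.05,
                         y_ceiling = 0.25, noise_sd = 0,
                         noise_type = c("additive", "proportional"),
                         n_replicates = 1L, seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(true_param > 0, noise_sd >= 0, n_replicates >= 1)
  if (any(diff(x_values) <= 0)) stop("x_values must be sorted strictly ascending")
  structure(list(true_param = true_param, x_values = x_values,
                 y_floor = y_floor, y_ceiling = y_ceiling,
                 noise_sd = noise_sd, noise_type = noise_type,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "curve_config")
}

add_noise <- function(mu, config) {
  if (config$noise_type == "proportional")
    mu * (1 + stats::rnorm(length(mu), 0, config$noise_sd))
  else mu + stats::rnorm(length(mu), 0, config$noise_sd)
}

#' Simulate a fluorescence-anisotropy binding curve
#'
#' In the no-depletion regime (probe concentration well below the
#' dissociation constant) the anisotropy follows the hyperbolic saturation
#' `y = floor + (ceiling - floor) * x / (Kd + x)`, with additive Gaussian
#' noise.
#'
#' @param config a [curve_config()] whose `true_param` is the dissociation
#'   constant in nM; `x_values` must be strictly positive.
#' @return data frame with columns `conc`, `anisotropy`, `replicate`.
#' @export
simulate_binding_curve <- function(config) {
  stopifnot(inherits(config, "curve_config"))
  if (any(config$x_values <= 0))
    stop("binding-curve concentrations must be strictly positive")
  with_seed(config$seed, {
    mu <- config$y_floor + (config$y_ceiling - config$y_floor) *
      config$x_values / (config$true_param + config$x_values)
    do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      data.frame(conc = config$x_values,
                 anisotropy = add_noise(mu, config),
                 replicate = r)
    }))
  })
}

#' Simulate an RNA stability (decay) time course
#'
#' Exponential decay in half-life parameterisation,
#' `y = y0 * 2^(-t / t_half)`, with additive Gaussian noise clipped at 0.
#'
#' @param config a [curve_config()] whose `true_param` is the half-life in
#'   hours and `y_ceiling` the initial intensity `y0`; `x_values` are time
#'   points in hours (may include 0).
#' @return data frame with columns `time`, `intensity`, `replicate`.
#' @export
simulate_decay <- function(config) {
  stopifnot(inherits(config, "curve_config"))
  if (any(config$x_values < 0)) stop("time points must be nonnegative")
  with_seed(config$seed, {
    mu <- config$y_ceiling * 2^(-config$x_values / config$true_param)
    do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      data.frame(time = config$x_values,
                 intensity = pmax(add_noise(mu, config), 0),
                 replicate = r)
    }))
  })
}

#' Simulate a two-channel colocalization image
#'
#' Builds two intensity matrices in which channel-A objects overlap
#' channel-B objects in exactly the requested pixel fraction, so the true
#' Manders M1 coefficient is known by construction.
#'
#' @param shape integer 2-vector, image dimensions in pixels.
#' @param overlap_fraction requested fraction in `[0, 1]` of channel-A
#'   object pixels that also carry channel-B signal (quantized to whole
#'   pixels; the achieved value is returned).
#' @param n_object_px object size in pixels per channel.
#' @param signal,background object and background intensities.
#' @param seed integer seed.
#' @return list with matrices `a`, `b`, a logical `roi` mask covering both
#'   objects, and `m1_true`, the achieved overlap fraction.
#' @export
simulate_colocalization_image <- function(shape = c(64L, 64L),
                                          overlap_fraction,
                                          n_object_px = 400L,
                                          signal = 100, background = 10,
                                          seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  npix <- prod(shape)
  stopifnot(n_object_px >= 1, 2 * n_object_px <= npix, signal > background)
  with_seed(seed, {
    n_ov <- round(overlap_fraction * n_object_px)
    idx_a <- sample.int(npix, n_object_px)
    overlap <- sample(idx_a, n_ov)
    outside <- setdiff(seq_len(npix), idx_a)
    idx_b <- c(overlap, sample(outside, n_object_px - n_ov))
    a <- matrix(background, shape[1], shape[2])
    b <- matrix(background, shape[1], shape[2])
    a[idx_a] <- signal
    b[idx_b] <- signal
    roi <- matrix(FALSE, shape[1], shape[2])
    roi[c(idx_a, idx_b)] <- TRUE
    list(a = a, b = b, roi = roi, m1_true = n_ov / n_object_px)
  })
}
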