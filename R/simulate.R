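#' Simulation configuration for synthetic impregnation experiments
#'
#' Bundles every knob of the synthetic-data generator: the true effective
#' diffusivity driving the forward models, the sample geometry, the imaging
#' grid, the sampling times, and the noise/texture/shrinkage parameters.
#' The defaults describe a 1.2 cm cube (half-edge \code{L0 = 0.00609} m)
#' impregnated at a boundary concentration of 1, sampled at the immersion
#' times used for desk-scale osmotic dehydration kinetics (0 to 810 min),
#' with moderate shrinkage to 75 % of the initial volume.
#'
#' @param D_true true effective diffusivity in m^2/s (> 0).
#' @param L0 characteristic half-length of the cube in m (> 0).
#' @param grid_n pixels per side of the simulated cross-section (>= 16).
#' @param t_samples strictly increasing, nonnegative sampling times in s.
#' @param boundary_value dimensionless boundary concentration (default 1).
#' @param noise_sigma standard deviation of additive pixel noise, in gray
#'   levels.
#' @param texture_scale correlation length (Gaussian smoothing sigma, in
#'   pixels) of the tissue texture field.
#' @param texture_amp amplitude (standard deviation, in gray levels) of the
#'   smoothed texture field added to rendered images.
#' @param shrink_final asymptotic dimensionless volume V/V0, in (0, 1].
#' @param shrink_rate first-order shrinkage rate in 1/s (>= 0).
#' @param seed integer RNG seed; fixes every random draw of a run.
#'
#' @return An object of class \code{"simulation_config"} (a validated list).
#' @examples
#' cfg <- simulation_config(t_samples = c(0, 600, 3600), grid_n = 32)
#' cfg$D_true
#' @export
simulation_config <- function(D_true = 2e-10,
                              L0 = 0.00609,
                              grid_n = 96L,
                              t_samples = 60 * c(0, 5, 10, 15, 30, 60, 120,
                                                 180, 240, 360, 480, 600,
                                                 720, 810),
                              boundary_value = 1.0,
                              noise_sigma = 2,
                              texture_scale = 3,
                              texture_amp = 12,
                              shrink_final = 0.75,
                              shrink_rate = 1e-4,
                              seed = 1L) {
  stopifnot(is.numeric(D_true), length(D_true) == 1L, D_true > 0)
  stopifnot(is.numeric(L0), length(L0) == 1L, L0 > 0)
  grid_n <- as.integer(grid_n)
  if (grid_n < 16L) stop("'grid_n' must be at least 16")
  t_samples <- as.numeric(t_samples)
  if (length(t_samples) < 1L || any(t_samples < 0) ||
      any(diff(t_samples) <= 0)) {
    stop("'t_samples' must be nonnegative and strictly increasing")
  }
  stopifnot(boundary_value > 0, boundary_value <= 1)
  stopifnot(noise_sigma >= 0, texture_scale > 0, texture_amp >= 0)
  if (shrink_final <= 0 || shrink_final > 1) {
    stop("'shrink_final' must lie in (0, 1]")
  }
  stopifnot(shrink_rate >= 0)
  structure(
    list(D_true = D_true, L0 = L0, grid_n = grid_n, t_samples = t_samples,
         boundary_value = boundary_value, noise_sigma = noise_sigma,
         texture_scale = texture_scale, texture_amp = texture_amp,
         shrink_final = shrink_final, shrink_rate = shrink_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic impregnation run\n")
  cat(sprintf("  D_true  %.3g m^2/s on a %d x %d grid (half-length %.4g m)\n",
              x$D_true, x$grid_n, x$grid_n, x$L0))
  cat(sprintf("  %d sampling times, %g to %g s\n", length(x$t_samples),
              min(x$t_samples), max(x$t_samples)))
  cat(sprintf("  shrinkage -> %.2f V/V0 at rate %.3g 1/s; seed %d\n",
              x$shrink_final, x$shrink_rate, x$seed))
  invisible(x)
}

#' Simulate dimensionless shrinkage of a sample
#'
#' First-order relaxation of the dimensionless volume toward its plateau:
#' \deqn{V/V_0(t) = v_f + (1 - v_f)\, e^{-r t}}
#' with \code{v_f = shrink_final} and \code{r = shrink_rate}. The curve is
#' exactly 1 at t = 0 and monotone, matching the qualitative shape of
#' measured osmotic-dehydration shrinkage (a fast early contraction that
#' levels off near equilibrium).
#'
#' @param config a [simulation_config()].
#' @return A [shrinkage_series()] on \code{config$t_samples}.
#' @examples
#' s <- generate_shrinkage(simulation_config(t_samples = c(0, 1e4, 5e4)))
#' s$v_ratio
#' @export
generate_shrinkage <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  v <- config$shrink_final +
    (1 - config$shrink_final) * exp(-config$shrink_rate * config$t_samples)
  shrinkage_series(times = config$t_samples, v_ratio = v)
}

# Exact dimensionless-volume function used by the kinetic forward model
# (continuous in t, identical to generate_shrinkage at the sample times).
shrink_fun <- function(config) {
  function(t) {
    config$shrink_final +
      (1 - config$shrink_final) * exp(-config$shrink_rate * t)
  }
}

# Cumulative shrinkage-corrected Fourier number tau*(t) = D int_0^t L(u)^-2 du
# evaluated by composite trapezoid on a fine grid, then interpolated.
tau_star_curve <- function(times, D, L0, v_fun, n_grid = 4000L) {
  t_max <- max(times)
  if (t_max == 0) return(rep(0, length(times)))
  tg <- seq(0, t_max, length.out = n_grid)
  integrand <- D / (L0 * v_fun(tg)^(1 / 3))^2
  ct <- c(0, cumsum((integrand[-1] + integrand[-n_grid]) / 2 * diff(tg)))
  stats::approx(tg, ct, xout = times)$y
}

#' Simulate time-series images of boundary-driven impregnation
#'
#' Solves the diffusion equation \eqn{\partial C/\partial t = D \nabla^2 C}
#' on a square cross-section with Dirichlet boundary
#' \code{C = boundary_value} and initial \code{C = 0}, by explicit
#' forward-time centered-space (FTCS) finite differences with a stable step
#' \code{dt = 0.2 dx^2 / D}, and renders each requested time as an 8-bit
#' grayscale image: staining darkens the tissue, so intensity is
#' \code{255 (1 - C)}, to which a fixed smoothed Gaussian texture field
#' (shared by all times of a run, emulating tissue structure; strictly
#' darkening, with mean \code{-2.5 texture_amp}, so unstained tissue is an
#' unclipped Gaussian field just below white) and independent per-image
#' pixel noise are added before rounding and clipping to [0, 255]. The
#' foreground mask is the full square.
#'
#' @param config a [simulation_config()].
#' @param dt optional override of the integration step in s; rejected if it
#'   violates the 2-D FTCS stability bound \code{D dt / dx^2 <= 0.25}.
#' @return A list of [gray_image()] objects, one per \code{t_samples},
#'   with the sampling times attached as \code{attr(, "times")}.
#' @examples
#' cfg <- simulation_config(grid_n = 24, t_samples = c(0, 2000),
#'                          noise_sigma = 0, texture_amp = 0)
#' imgs <- generate_impregnation_images(cfg)
#' imgs[[1]]$pixels[12, 12]  # centre still unstained: 255
#' @export
generate_impregnation_images <- function(config, dt = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$grid_n
  dx <- 2 * config$L0 / (n - 1)
  if (is.null(dt)) dt <- 0.2 * dx^2 / config$D_true
  alpha <- config$D_true * dt / dx^2
  if (alpha > 0.25 + 1e-12) {
    stop(sprintf(
      "unstable FTCS step: D*dt/dx^2 = %.3f exceeds the 2-D bound 0.25",
      alpha))
  }

  set.seed(config$seed)
  # Tissue texture: white noise smoothed to correlation length texture_scale,
  # rescaled to the requested gray-level amplitude. One field per run.
  # The field is anchored 2.5 amplitudes below zero so that it darkens the
  # rendered tissue: unstained tissue then sits just below the white point
  # as an unclipped Gaussian field, which is what gives early-time ECCs
  # their double-peak structure (clipping at 255 would destroy the bright
  # peak).
  if (config$texture_amp > 0) {
    w <- matrix(rnorm(n * n), n, n)
    tex <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(w),
                                             sigma = config$texture_scale))
    tex <- tex / stats::sd(tex) * config$texture_amp - 2.5 * config$texture_amp
  } else {
    tex <- matrix(0, n, n)
  }

  C <- matrix(0, n, n)
  C[1, ] <- C[n, ] <- config$boundary_value
  C[, 1] <- C[, n] <- config$boundary_value

  render <- function(C) {
    pix <- 255 * (1 - C) + tex
    if (config$noise_sigma > 0) {
      pix <- pix + matrix(rnorm(n * n, sd = config$noise_sigma), n, n)
    }
    gray_image(pmin(pmax(round(pix), 0), 255),
               mask = matrix(TRUE, n, n))
  }

  step_to <- function(C, t_from, t_to) {
    remaining <- t_to - t_from
    idx <- 2:(n - 1)
    while (remaining > 1e-12) {
      h <- min(dt, remaining)
      a <- config$D_true * h / dx^2
      lap <- C[idx - 1, idx] + C[idx + 1, idx] +
        C[idx, idx - 1] + C[idx, idx + 1] - 4 * C[idx, idx]
      C[idx, idx] <- C[idx, idx] + a * lap
      remaining <- remaining - h
    }
    C
  }

  out <- vector("list", length(config$t_samples))
  t_prev <- 0
  for (k in seq_along(config$t_samples)) {
    t_k <- config$t_samples[k]
    if (t_k > t_prev) C <- step_to(C, t_prev, t_k)
    out[[k]] <- render(C)
    t_prev <- t_k
  }
  attr(out, "times") <- config$t_samples
  out
}

#' Simulate an uptake kinetic series from the Fickian forward model
#'
#' Generates the mass-transfer increase Y(t) of a substance that diffuses
#' into a shrinking cube. The shrinkage-corrected Fourier number
#' \eqn{\tau^*(t) = \int_0^t D/L(u)^2\,du} (with
#' \eqn{L(u) = L_0 (V/V_0)^{1/3}}) drives the diagonal series solution
#' [psi_model()]; because that series equals 8/15 rather than 1 at
#' \eqn{\tau^* = 0}, the unaccomplished ratio is normalized by its initial
#' value so that Y(0) = 0 exactly:
#' \deqn{Y(t) = Y_e \left(1 - \Psi(\tau^*(t)) / \Psi(0)\right).}
#' Optional additive and/or multiplicative Gaussian noise is applied under
#' the configuration seed, so identical seeds give identical series.
#'
#' @param config a [simulation_config()].
#' @param Y_e equilibrium increase of the substance (> 0), in its own units.
#' @param substance label for the series (e.g. "water loss").
#' @param noise_sd additive Gaussian noise standard deviation, in substance
#'   units (default 0).
#' @param noise_rel multiplicative noise: each Y is scaled by
#'   \code{1 + N(0, noise_rel)} (default 0).
#' @return A [kinetic_series()].
#' @examples
#' cfg <- simulation_config(shrink_final = 1)
#' k <- generate_kinetics(cfg, Y_e = 0.436, substance = "water loss")
#' all(diff(k$values) >= 0)
#' @export
generate_kinetics <- function(config, Y_e, substance = "water loss",
                              noise_sd = 0, noise_rel = 0) {
  stopifnot(inherits(config, "simulation_config"))
  stopifnot(is.numeric(Y_e), length(Y_e) == 1L, Y_e > 0)
  stopifnot(noise_sd >= 0, noise_rel >= 0)
  tau <- tau_star_curve(config$t_samples, config$D_true, config$L0,
                        shrink_fun(config))
  psi0 <- psi_model(0)
  psi_norm <- psi_model(tau) / psi0
  y <- Y_e * (1 - psi_norm)
  if (noise_sd > 0 || noise_rel > 0) {
    set.seed(config$seed)
    m <- length(y)
    if (noise_rel > 0) y <- y * (1 + rnorm(m, sd = noise_rel))
    if (noise_sd > 0) y <- y + rnorm(m, sd = noise_sd)
  }
  kinetic_series(substance = substance, times = config$t_samples, values = y)
}
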