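#' Kinetic series of a mass-transfer increase
#'
#' Timestamped increases \eqn{Y_j(t) = w_{j}(t) - w_{j}(0)} of a diffusing
#' substance: water loss, solute gain, or a bioactive compound
#' (antioxidant activity, total phenolics, monomeric anthocyanins), in the
#' substance's own units.
#'
#' @param substance label of the diffusing substance.
#' @param times sampling times in s, strictly increasing, first >= 0.
#' @param values increases at each time, in substance units.
#' @return An object of class \code{"kinetic_series"}.
#' @export
kinetic_series <- function(substance, times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length")
  }
  if (length(times) == 0L || times[1] < 0 || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing and nonnegative")
  }
  structure(list(substance = as.character(substance), times = times,
                 values = values),
            class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("kinetic_series '%s': %d points, t in [%g, %g] s, Y in [%g, %g]\n",
              x$substance, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Shrinkage series of a sample
#'
#' Dimensionless volume V/V0 over time. Must start at (or very near) 1.
#'
#' @param times sampling times in s.
#' @param v_ratio dimensionless volume at each time, > 0.
#' @param tol tolerance on \code{v_ratio[times == 0] == 1} (default 0.05).
#' @return An object of class \code{"shrinkage_series"}.
#' @export
shrinkage_series <- function(times, v_ratio, tol = 0.05) {
  times <- as.numeric(times); v_ratio <- as.numeric(v_ratio)
  if (length(times) != length(v_ratio)) {
    stop("'times' and 'v_ratio' must have equal length")
  }
  if (any(v_ratio <= 0)) stop("'v_ratio' must be positive")
  if (any(times == 0) && abs(v_ratio[times == 0][1] - 1) > tol) {
    stop("'v_ratio' at time 0 must equal 1 within tolerance")
  }
  structure(list(times = times, v_ratio = v_ratio),
            class = "shrinkage_series")
}

#' Dimensionless volume of a rectangular sample
#'
#' Product ratio of current to initial edge lengths,
#' \eqn{(L_1 L_2 L_3)/(L_{1,0} L_{2,0} L_{3,0})}.
#'
#' @param L1,L2,L3 current edge lengths in m (> 0).
#' @param L1_0,L2_0,L3_0 initial edge lengths in m (> 0).
#' @return Dimensionless V/V0.
#' @examples
#' dimensionless_volume(1, 2, 3, 2, 2, 3)  # 0.5
#' @export
dimensionless_volume <- function(L1, L2, L3, L1_0, L2_0, L3_0) {
  v <- c(L1, L2, L3, L1_0, L2_0, L3_0)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all lengths must be positive")
  (L1 * L2 * L3) / (L1_0 * L2_0 * L3_0)
}

#' Convert moisture content from wet basis to dry basis
#'
#' \code{wb / (1 - wb)}: g water per g dry solids from g water per g fresh
#' sample.
#'
#' @param wb moisture on wet basis, in [0, 1).
#' @return Moisture on dry basis.
#' @examples
#' wet_to_dry_basis(0.84)  # 5.25
#' @export
wet_to_dry_basis <- function(wb) {
  if (any(wb < 0) || any(wb >= 1)) stop("'wb' must lie in [0, 1)")
  wb / (1 - wb)
}

#' Water loss of an osmotically treated sample
#'
#' \eqn{WL = (m_{p0} M_0 - m_{OP} M_{OP}) / m_{p0}}: grams of water lost
#' per gram of fresh product, from sample masses and wet-basis moisture
#' fractions before and after treatment.
#'
#' @param m_p0 fresh sample mass in g (> 0).
#' @param m_OP treated sample mass in g (> 0).
#' @param M0 fresh moisture mass fraction, wet basis, in [0, 1).
#' @param M_OP treated moisture mass fraction, wet basis, in [0, 1).
#' @return Water loss in g water / g fresh product.
#' @examples
#' water_loss(10, 8, 0.84, 0.75)  # 0.24
#' @export
water_loss <- function(m_p0, m_OP, M0, M_OP) {
  check_mass_fraction(m_p0, m_OP, M0, M_OP)
  (m_p0 * M0 - m_OP * M_OP) / m_p0
}

#' Solute gain of an osmotically treated sample
#'
#' \eqn{SG = (m_{OP}(1 - M_{OP}) - m_{p0}(1 - M_0)) / m_{p0}}: grams of
#' solutes gained per gram of fresh product. Together with [water_loss()]
#' it satisfies the mass balance
#' \code{WL - (m_p0 - m_OP)/m_p0 - SG = 0}.
#'
#' @inheritParams water_loss
#' @return Solute gain in g solutes / g fresh product.
#' @examples
#' solute_gain(10, 8, 0.84, 0.75)  # 0.04
#' @export
solute_gain <- function(m_p0, m_OP, M0, M_OP) {
  check_mass_fraction(m_p0, m_OP, M0, M_OP)
  (m_OP * (1 - M_OP) - m_p0 * (1 - M0)) / m_p0
}

check_mass_fraction <- function(m_p0, m_OP, M0, M_OP) {
  if (any(m_p0 <= 0) || any(m_OP <= 0)) stop("masses must be positive")
  if (any(M0 < 0) || any(M0 >= 1) || any(M_OP < 0) || any(M_OP >= 1)) {
    stop("moisture fractions must lie in [0, 1)")
  }
  invisible(TRUE)
}

#' Peleg sorption model
#'
#' The two-parameter hyperbolic uptake model
#' \eqn{Y(t) = Y_0 + t / (k_1 + k_2 t)}: \code{k1} (s per substance unit)
#' is the reciprocal initial rate and \code{k2} (1 per substance unit) the
#' capacity constant, whose reciprocal is the total equilibrium increase.
#'
#' @param t time in s.
#' @param Y0 initial value in substance units.
#' @param k1 reciprocal rate constant, s per substance unit (> 0).
#' @param k2 capacity constant, 1 per substance unit (> 0).
#' @return Model value Y(t).
#' @examples
#' peleg_model(c(0, 1e6), Y0 = 0, k1 = 6753.13, k2 = 2.29)
#' @export
peleg_model <- function(t, Y0, k1, k2) {
  Y0 + ifelse(t == 0, 0, t / (k1 + k2 * t))
}

#' Fit the Peleg model to a kinetic series
#'
#' Nonlinear least squares of \eqn{Y = Y_0 + t/(k_1 + k_2 t)} with
#' \eqn{Y_0} fixed to the t = 0 observation (0 for water loss and solute
#' gain series started from fresh tissue). Starting values come from
#' ordinary least squares on the linearization
#' \eqn{t/(Y - Y_0) = k_1 + k_2 t}; the nonlinear refinement uses
#' Levenberg-Marquardt. Reports \eqn{R^2 = 1 - SSE/SST}, RMSE, and
#' Jacobian-based standard errors for \code{k1} and \code{k2}.
#'
#' @param series a [kinetic_series()] with at least 4 points.
#' @param Y0 fixed initial value; defaults to the observation at t = 0
#'   (required to be present if \code{Y0} is not given).
#' @return An object of class \code{"peleg_fit"} with fields \code{Y0},
#'   \code{k1}, \code{k2}, \code{Ye}, \code{r_squared}, \code{rmse},
#'   \code{se_k1}, \code{se_k2}.
#' @examples
#' t <- c(0, 600, 1800, 3600, 7200, 21600, 48600)
#' y <- peleg_model(t, 0, 6753.13, 2.29)
#' fit <- peleg_fit(kinetic_series("water loss", t, y))
#' fit$k2
#' @export
peleg_fit <- function(series, Y0 = NULL) {
  stopifnot(inherits(series, "kinetic_series"))
  t <- series$times; y <- series$values
  if (length(t) < 4L) stop("need at least 4 points to fit the Peleg model")
  if (diff(range(y)) == 0) {
    stop("degenerate input: constant series, k2 is unidentifiable")
  }
  if (is.null(Y0)) {
    if (t[1] != 0) {
      stop("no t = 0 observation; supply 'Y0' explicitly")
    }
    Y0 <- y[1]
  }

  pos <- t > 0 & (y - Y0) > 0
  if (sum(pos) < 3L) {
    stop("degenerate input: too few points with uptake above Y0")
  }
  lin <- lm(I(t[pos] / (y[pos] - Y0)) ~ t[pos])
  k1_0 <- unname(coef(lin)[1]); k2_0 <- unname(coef(lin)[2])
  if (!is.finite(k2_0) || k2_0 <= 0) {
    stop("non-Peleg data: linearized capacity constant k2 is not positive")
  }
  if (!is.finite(k1_0) || k1_0 <= 0) k1_0 <- t[pos][1] / (y[pos][1] - Y0)

  dat <- data.frame(t = t[t > 0], y = y[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Y0 + t / (k1 + k2 * t), data = dat,
                      start = list(k1 = k1_0, k2 = k2_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # perfectly linearizable data can defeat the LM step; fall back
    k1 <- k1_0; k2 <- k2_0
    se <- c(NA_real_, NA_real_)
  } else {
    cf <- coef(fit)
    k1 <- unname(cf["k1"]); k2 <- unname(cf["k2"])
    se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                   error = function(e) c(NA_real_, NA_real_))
  }
  if (k2 <= 0) stop("non-Peleg data: fitted k2 is not positive")

  yhat <- peleg_model(t, Y0, k1, k2)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(substance = series$substance, Y0 = Y0, k1 = k1, k2 = k2,
                 Ye = Y0 + 1 / k2,
                 r_squared = 1 - sse / sst,
                 rmse = sqrt(mean((y - yhat)^2)),
                 se_k1 = unname(se[1]), se_k2 = unname(se[2]),
                 n = length(t)),
            class = "peleg_fit")
}

#' @export
print.peleg_fit <- function(x, ...) {
  cat(sprintf("Peleg fit '%s' (n = %d)\n", x$substance, x$n))
  cat(sprintf("  k1 = %.6g +/- %.2g   k2 = %.6g +/- %.2g\n",
              x$k1, x$se_k1, x$k2, x$se_k2))
  cat(sprintf("  Ye = %.6g   R2 = %.4f   RMSE = %.4g\n",
              x$Ye, x$r_squared, x$rmse))
  invisible(x)
}

#' Equilibrium value of a Peleg fit
#'
#' The t -> Inf limit of the Peleg model, \eqn{Y_e = Y_0 + 1/k_2}.
#'
#' @param fit a [peleg_fit()], or any list with elements \code{Y0} and
#'   \code{k2}.
#' @return Equilibrium value in substance units.
#' @examples
#' equilibrium_value(list(Y0 = 0, k2 = 2.29))
#' @export
equilibrium_value <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$Y0), !is.null(fit$k2))
  if (fit$k2 <= 0) stop("'k2' must be positive")
  fit$Y0 + 1 / fit$k2
}
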