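# Temperature-law analysis of fitted dynamical parameters: Arrhenius and
# Vogel-Fulcher-Tammann fits with small-sample-corrected information
# criterion selection, the pseudo-diffusion coefficient of internal motions,
# MSD-slope resilience, and piecewise-linear breakpoint detection.

#' Arrhenius fit of a rate or time observable
#'
#' Weighted linear fit of ln y versus 1/T. For \code{sign_mode = "rate"}
#' (e.g. a Lorentzian HWHM) the law is y = y0 exp(-EA / (R T)); for
#' \code{sign_mode = "time"} (a residence or relaxation time,
#' tau = hbar / Gamma) the exponent sign is reversed:
#' y = y0 exp(+EA / (R T)).
#'
#' @param temperature Temperatures in K (>= 3 points).
#' @param y Positive observable (meV for rates, ps for times).
#' @param sigma Optional 1-sigma errors on y; default unweighted.
#' @param sign_mode "rate" or "time".
#' @return An object of class \code{arrhenius_fit} with activation energy in
#'   kJ/mol and kcal/mol, the prefactor, uncertainties from linear theory
#'   and the weighted R^2.
#' @export
fit_arrhenius <- function(temperature, y, sigma = NULL,
                          sign_mode = c("rate", "time")) {
  sign_mode <- match.arg(sign_mode)
  if (length(temperature) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(y <= 0)) stop("observable must be strictly positive", call. = FALSE)
  if (any(temperature <= 0)) stop("temperatures must be > 0", call. = FALSE)
  w <- if (is.null(sigma)) rep(1, length(y)) else (y / sigma)^2
  x <- 1 / temperature
  fit <- .wls(cbind(1, x), log(y), w)
  slope <- fit$coef[2]
  sgn <- if (sign_mode == "rate") -1 else 1
  ea <- sgn * slope * .const$Rgas                 # kJ/mol
  ea_se <- fit$se[2] * .const$Rgas
  prefactor <- exp(fit$coef[1])
  structure(list(ea_kJ = ea, ea_kcal = ea / .const$kJ_per_kcal,
                 ea_se_kJ = ea_se, prefactor = prefactor,
                 prefactor_se = prefactor * fit$se[1],
                 sign_mode = sign_mode, rsq = fit$rsq,
                 slope = slope, intercept = fit$coef[1], cov = fit$cov,
                 rss_w = fit$rss_w, n = length(y),
                 temperature = temperature, y = y, w = w),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s): EA = %.3f +/- %.3f kJ/mol (%.3f kcal/mol)\n",
              x$sign_mode, x$ea_kJ, x$ea_se_kJ, x$ea_kcal))
  cat(sprintf("  prefactor = %.4g, weighted R^2 = %.4f\n", x$prefactor,
              x$rsq))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...)
  c(ea_kJ = object$ea_kJ, prefactor = object$prefactor)

#' @export
predict.arrhenius_fit <- function(object, temperature = object$temperature,
                                  ...) {
  sgn <- if (object$sign_mode == "rate") -1 else 1
  object$prefactor * exp(sgn * object$ea_kJ /
                           (.const$Rgas * temperature))
}

#' Vogel-Fulcher-Tammann fit of a relaxation time
#'
#' tau(T) = tau0 exp(D T0 / (T - T0)), with fragility index 1/D. The Vogel
#' temperature T0 is profiled over a grid (the conditional fit being linear
#' in ln tau0 and D T0) and then refined by bounded nonlinear least squares.
#' T0 is constrained to [0, min(T) - 20 K] as an identifiability guard; a
#' fit pinned at that bound is flagged.
#'
#' @param temperature Temperatures in K (>= 5 points).
#' @param tau Relaxation times, ps (> 0).
#' @param sigma Optional 1-sigma errors on tau.
#' @return An object of class \code{vft_fit} with tau0 (ps), d_strength (D),
#'   t0 (K), \code{fragility} = 1/D, uncertainties and flags
#'   (\code{t0_at_bound}, \code{reduces_to_arrhenius} when D T0 is
#'   consistent with 0).
#' @export
fit_vft <- function(temperature, tau, sigma = NULL) {
  if (length(temperature) < 5) stop("need at least 5 points", call. = FALSE)
  if (any(tau <= 0)) stop("tau must be strictly positive", call. = FALSE)
  w <- if (is.null(sigma)) rep(1, length(tau)) else (tau / sigma)^2
  z <- log(tau)
  t0_max <- min(temperature) - 20
  if (t0_max <= 0) t0_max <- min(temperature) * 0.5
  t0_grid <- seq(0, t0_max, length.out = 41)
  prof <- vapply(t0_grid, function(t0) {
    .wls(cbind(1, 1 / (temperature - t0)), z, w)$rss_w
  }, numeric(1))
  t0_best <- t0_grid[which.min(prof)]
  lin <- .wls(cbind(1, 1 / (temperature - t0_best)), z, w)
  p0 <- c(exp(lin$coef[1]), max(lin$coef[2], 1e-6), t0_best)
  resid_fn <- function(p)
    sqrt(w) * (z - (log(p[1]) + p[2] / (temperature - p[3])))
  lower <- c(1e-8, 0, 0); upper <- c(1e8, 1e5, t0_max)
  out <- minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  par <- out$par
  dof <- max(length(tau) - 3, 1)
  chisq_red <- out$deviance / dof
  covm <- .lm_covariance(resid_fn, par, chisq_red, lower, upper)
  se <- sqrt(pmax(diag(covm), 0))
  b <- par[2]                      # b = D * T0
  t0 <- par[3]
  t0_at_bound <- t0 >= t0_max - 1e-6
  if (t0_at_bound)
    warning("Vogel temperature pinned at its identifiability bound; ",
            "VFT parameters weakly identifiable", call. = FALSE)
  D <- if (t0 > 0) b / t0 else NA_real_
  # delta-method errors for D = b / t0
  D_se <- if (t0 > 0 && is.finite(D))
    abs(D) * sqrt((se[2] / max(b, 1e-12))^2 + (se[3] / t0)^2) else NA_real_
  reduces <- b <= 2 * se[2]        # D T0 consistent with 0: tau ~ constant
  structure(list(tau0 = par[1], tau0_se = se[1],
                 d_strength = D, d_strength_se = D_se,
                 dt0_product = b, dt0_se = se[2],
                 t0 = t0, t0_se = se[3],
                 fragility = if (is.finite(D) && D > 0) 1 / D else NA_real_,
                 chisq_red = chisq_red, rss_w = out$deviance, n = length(tau),
                 t0_at_bound = t0_at_bound, reduces_to_arrhenius = reduces,
                 temperature = temperature, tau = tau, w = w),
            class = "vft_fit")
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf("VFT fit: tau0 = %.4g ps, D = %.3g, T0 = %.1f K (fragility 1/D = %.3g)\n",
              x$tau0, x$d_strength, x$t0, x$fragility))
  if (x$reduces_to_arrhenius)
    cat("  note: D*T0 consistent with 0 - reduces to a constant/Arrhenius-like law\n")
  if (x$t0_at_bound) cat("  note: T0 at identifiability bound\n")
  invisible(x)
}

#' @export
coef.vft_fit <- function(object, ...)
  c(tau0 = object$tau0, d_strength = object$d_strength, t0 = object$t0)

#' @export
predict.vft_fit <- function(object, temperature = object$temperature, ...)
  object$tau0 * exp(object$dt0_product / (temperature - object$t0))

#' Choose between Arrhenius and VFT temperature laws
#'
#' Fits both laws to tau(T) on the ln scale with shared weights and compares
#' the small-sample-corrected AIC. |delta AICc| < 2 (or too few points for
#' the comparison to be meaningful) yields "indistinguishable".
#'
#' @param temperature Temperatures in K.
#' @param tau Relaxation times, ps.
#' @param sigma Optional errors on tau.
#' @return A list of class \code{thermal_law_selection}: \code{law}
#'   ("arrhenius", "vft" or "indistinguishable"), \code{delta_aicc}
#'   (AICc_arrhenius - AICc_vft), the AICc values and both fits (VFT NULL
#'   when infeasible).
#' @export
select_thermal_law <- function(temperature, tau, sigma = NULL) {
  n <- length(temperature)
  arr <- fit_arrhenius(temperature, tau, sigma, sign_mode = "time")
  k_arr <- 3; k_vft <- 4
  if (n - k_vft - 1 <= 0) {
    warning("too few points to discriminate temperature laws", call. = FALSE)
    return(structure(list(law = "indistinguishable", delta_aicc = NA_real_,
                          aicc_arrhenius = NA_real_, aicc_vft = NA_real_,
                          arrhenius = arr, vft = NULL),
                     class = "thermal_law_selection"))
  }
  vft <- tryCatch(suppressWarnings(fit_vft(temperature, tau, sigma)),
                  error = function(e) NULL)
  if (is.null(vft)) {
    return(structure(list(law = "arrhenius", delta_aicc = NA_real_,
                          aicc_arrhenius = .aicc_ls(arr$rss_w, n, k_arr),
                          aicc_vft = NA_real_, arrhenius = arr, vft = NULL),
                     class = "thermal_law_selection"))
  }
  aicc_arr <- .aicc_ls(arr$rss_w, n, k_arr)
  aicc_vft <- .aicc_ls(vft$rss_w, n, k_vft)
  delta <- aicc_arr - aicc_vft
  # a VFT solution whose T0 is consistent with 0 is the Arrhenius law in
  # disguise (tau0 exp(D T0 / T)); it carries no curvature evidence, so the
  # simpler law wins regardless of the raw AICc difference
  vft_degenerate <- vft$reduces_to_arrhenius ||
    vft$t0 <= max(2 * vft$t0_se, 1e-6)
  law <- if (vft_degenerate) "arrhenius"
  else if (abs(delta) < 2) "indistinguishable"
  else if (delta < 0) "arrhenius" else "vft"
  structure(list(law = law, delta_aicc = delta, aicc_arrhenius = aicc_arr,
                 aicc_vft = aicc_vft, arrhenius = arr, vft = vft),
            class = "thermal_law_selection")
}

#' @export
print.thermal_law_selection <- function(x, ...) {
  cat("Thermal-law selection:", x$law,
      sprintf("(delta AICc = %.2f)\n", x$delta_aicc))
  invisible(x)
}

#' Pseudo-diffusion coefficient of internal jump diffusion
#'
#' D_pseudo = <l>^2 / (2 tau), reported both in Angstrom^2/ps and in
#' 1e-5 cm^2/s (1 Angstrom^2/ps = 10 x 1e-5 cm^2/s).
#'
#' @param jump_len Mean jump length, Angstrom.
#' @param tau Residence time, ps (> 0).
#' @return A list with \code{A2_per_ps} and \code{cm2_per_s_1e5}.
#' @export
pseudo_diffusion <- function(jump_len, tau) {
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  d <- jump_len^2 / (2 * tau)
  list(A2_per_ps = d, cm2_per_s_1e5 = d * 10)
}

#' Resilience (pseudo force constant) from an MSD curve
#'
#' The slope k = d(MSD_total)/dT is obtained by weighted linear fit over the
#' requested temperature window; the protein resilience is reported as the
#' pseudo force constant 2 kB / k with kB in J/K and the slope converted to
#' m^2/K. A non-positive slope gives an infinite resilience with an
#' \code{overflow} flag.
#'
#' @param msd An \code{msd_curve} (from \code{\link{total_msd}}) or a
#'   data.frame with columns \code{temperature} and \code{msd_total}.
#' @param window Optional c(Tmin, Tmax) restriction, K.
#' @param sigma Optional errors on the MSD values.
#' @return A list with \code{slope_A2_per_K}, \code{slope_se},
#'   \code{force_constant_N_per_m} and \code{overflow}.
#' @export
resilience <- function(msd, window = NULL, sigma = NULL) {
  Tv <- msd$temperature; y <- msd$msd_total
  if (!is.null(window)) {
    keep <- Tv >= window[1] & Tv <= window[2]
    Tv <- Tv[keep]; y <- y[keep]
    if (!is.null(sigma)) sigma <- sigma[keep]
  }
  if (length(Tv) < 3) stop("need at least 3 points in the window",
                           call. = FALSE)
  if (is.unsorted(Tv, strictly = TRUE) &&
      is.unsorted(rev(Tv), strictly = TRUE))
    stop("temperatures must be monotone", call. = FALSE)
  w <- if (is.null(sigma)) rep(1, length(y)) else 1 / sigma^2
  fit <- .wls(cbind(1, Tv), y, w)
  slope <- fit$coef[2]
  overflow <- slope <= .Machine$double.eps
  k <- if (overflow) Inf else 2 * .const$kB_J / (slope * 1e-20)  # N/m
  list(slope_A2_per_K = slope, slope_se = fit$se[2],
       force_constant_N_per_m = k, overflow = overflow)
}

#' Detect a slope change in an MSD versus temperature curve
#'
#' Exhaustive search over interior candidate breakpoints of a continuous
#' two-segment piecewise-linear model (hinge regression), compared against
#' the single-line null with an F test (2 extra parameters). The breakpoint
#' is reported only when p < alpha, otherwise the curve is declared linear.
#'
#' @param msd An \code{msd_curve} or data.frame with \code{temperature} and
#'   \code{msd_total} (>= 6 points).
#' @param sigma Optional errors on the MSD values.
#' @param alpha Significance level, default 0.05.
#' @return A list of class \code{breakpoint_result}: \code{linear} flag,
#'   \code{t_star}, \code{slope_low}, \code{slope_high}, \code{p_value}.
#' @export
detect_breakpoint <- function(msd, sigma = NULL, alpha = 0.05) {
  Tv <- msd$temperature; y <- msd$msd_total
  n <- length(Tv)
  if (n < 6) stop("need at least 6 points", call. = FALSE)
  o <- order(Tv); Tv <- Tv[o]; y <- y[o]
  w <- if (is.null(sigma)) rep(1, n) else 1 / sigma[o]^2
  null_fit <- .wls(cbind(1, Tv), y, w)
  cands <- Tv[3:(n - 2)]
  best <- NULL
  for (ts in cands) {
    hinge <- pmax(Tv - ts, 0)
    fit <- .wls(cbind(1, Tv, hinge), y, w)
    if (is.null(best) || fit$rss_w < best$rss_w)
      best <- c(fit, list(t_star = ts))
  }
  dof <- n - 4                       # slope change + breakpoint location
  Fstat <- ((null_fit$rss_w - best$rss_w) / 2) / (best$rss_w / dof)
  p <- stats::pf(Fstat, 2, dof, lower.tail = FALSE)
  significant <- is.finite(p) && p < alpha
  structure(list(linear = !significant,
                 t_star = if (significant) best$t_star else NA_real_,
                 slope_low = best$coef[2],
                 slope_high = best$coef[2] + best$coef[3],
                 p_value = p, f_stat = Fstat,
                 null_slope = null_fit$coef[2]),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (x$linear) {
    cat(sprintf("MSD(T): linear (breakpoint p = %.3g)\n", x$p_value))
  } else {
    cat(sprintf("MSD(T): slope change at T* = %.1f K (p = %.3g); slopes %.4g -> %.4g Ang^2/K\n",
                x$t_star, x$p_value, x$slope_low, x$slope_high))
  }
  invisible(x)
}
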