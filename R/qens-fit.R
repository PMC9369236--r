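# Global fitting of QENS maps: all (q, omega) points fitted at once with the
# Hall-Ross + localized-Lorentzian model convolved with the measured
# resolution. By default A0(q) is fitted per q channel alongside
# (Gamma_loc, tau, <l>) and a Debye-Waller amplitude, with the integrated
# EISF supplying starting values; it can also be held fixed.

# centered running mean with edge fill, used to smooth variance profiles
.smooth_vec <- function(x, k = 21) {
  k <- min(k, length(x))
  if (k < 2) return(x)
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y[is.na(y)] <- mean(x)
  as.vector(y)
}

.qens_starts <- function() {
  expand.grid(tau = c(0.1, 1, 10),          # ps, decades
              jump_len = c(0.3, 1, 3),      # Angstrom
              gamma_loc = c(0.03, 0.3, 3))  # meV
}

#' Global Hall-Ross fit of a QENS map at one condition
#'
#' Weighted least squares over all (q, omega) channels with free residence
#' time tau, mean jump length <l> and localized HWHM Gamma_loc, plus an
#' overall amplitude and a Debye-Waller MSD entering as
#' scale_amp exp(-q^2 dw_msd). With \code{a0_mode = "free"} (the default)
#' one elastic fraction A0 per q channel is fitted jointly with the dynamic
#' parameters, using the supplied EISF curve only as starting values; the
#' window-integrated EISF estimate is biased by the finite elastic window,
#' so letting the global fit determine A0(q) against the full line shape is
#' both unbiased and well-conditioned (a handful of extra parameters against
#' hundreds of channels). With \code{a0_mode = "fixed"} the supplied curve
#' is used as-is. Multi-start over a deterministic 3 x 3 x 3 grid of
#' (tau, <l>, Gamma_loc) decades, ranked by initial cost.
#'
#' @param spectrum A \code{qens_dataset} at one condition (>= 5 q channels)
#'   with its resolution set.
#' @param eisf An \code{eisf_curve} on the same q grid (from
#'   \code{\link{extract_eisf}}), used as A0(q) start (or fixed values).
#' @param a0_mode "free" (fit A0 per q, default) or "fixed".
#' @param fix_dw If TRUE, \code{dw_msd} is frozen at the supplied value
#'   instead of fitted.
#' @param dw_msd Debye-Waller MSD used when \code{fix_dw} is TRUE.
#' @param n_refine Number of ranked starts refined fully, default 6.
#' @param reweight_iter Iteratively-reweighted passes, default 2. Counting
#'   errors estimated from the observed channel contents correlate with the
#'   noise itself (downward fluctuations get overweighted), which biases
#'   chi-square fits at low counts. Each pass rebuilds the per-channel
#'   variance from the fitted model -- var = (model + c(omega)) / k per q
#'   row, with the counts-to-intensity scale k and the smooth background
#'   variance c(omega) estimated from the data -- and refits. Set 0 to fit
#'   with the supplied sigma only.
#' @return An object of class \code{qens_fit} with coefficients (tau,
#'   jump_len, gamma_loc, scale_amp, dw_msd), standard errors, the parameter
#'   covariance (including the tau-<l> correlation), reduced chi^2, the
#'   fitted (or fixed) A0(q) with its errors, and fitted spectra. The
#'   \code{eisf} element is an \code{eisf_curve} built from the fitted
#'   A0(q), suitable for \code{\link{fit_eisf}}.
#' @export
fit_qens <- function(spectrum, eisf, a0_mode = c("free", "fixed"),
                     fix_dw = FALSE, dw_msd = 0, n_refine = 6,
                     reweight_iter = 2) {
  stopifnot(inherits(spectrum, "qens_dataset"),
            inherits(eisf, "eisf_curve"))
  a0_mode <- match.arg(a0_mode)
  if (nrow(spectrum$conditions) != 1)
    stop("fit_qens expects a single condition; use subset_condition()",
         call. = FALSE)
  if (length(spectrum$q) < 5)
    stop("need at least 5 q channels", call. = FALSE)
  a0_start <- stats::approx(eisf$q, eisf$a0, xout = spectrum$q, rule = 2)$y
  a0_start <- pmin(pmax(a0_start, 0), 1)
  q <- spectrum$q; omega <- spectrum$omega
  nq <- length(q)
  S <- spectrum$s_qw[1, , ]; E <- spectrum$sigma[1, , ]
  R <- spectrum$resolution
  free_a0 <- a0_mode == "free"

  # amplitude / Debye-Waller starts from the per-q integrated intensities
  areas <- rowSums(S) * diff(omega)[1]
  afit <- stats::lm.fit(cbind(1, q^2), log(pmax(areas, 1e-12)))
  sc0 <- exp(unname(afit$coefficients[1]))
  dw0 <- if (fix_dw) dw_msd else
    min(max(-unname(afit$coefficients[2]), 0), 3)

  n_dyn <- if (fix_dw) 4L else 5L
  model_of <- function(par) {
    a0 <- if (free_a0) par[n_dyn + seq_len(nq)] else a0_start
    qens_model_convolved(q, omega, a0, par[1], par[2], par[3],
                         par[4], if (fix_dw) dw_msd else par[5], R)
  }
  resid_fn <- function(par) as.vector((S - model_of(par)) / E)
  lower <- c(1e-3, 0.05, 0, 1e-12, if (!fix_dw) 0,
             if (free_a0) rep(0, nq))
  upper <- c(1e3, 10, 10, Inf, if (!fix_dw) 5,
             if (free_a0) rep(1, nq))
  starts <- .qens_starts()
  a0_init <- pmin(pmax(a0_start, 0.02), 0.98)
  mkpar <- function(k) c(starts$tau[k], starts$jump_len[k],
                         starts$gamma_loc[k], sc0, if (!fix_dw) dw0,
                         if (free_a0) a0_init)
  cost0 <- vapply(seq_len(nrow(starts)),
                  function(k) sum(resid_fn(mkpar(k))^2), numeric(1))
  best <- NULL
  for (k in order(cost0)[seq_len(min(n_refine, nrow(starts)))]) {
    out <- tryCatch(
      minpack.lm::nls.lm(mkpar(k), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best))
    stop("QENS global fit failed to converge from any start; diagnostics: ",
         "initial costs ", paste(signif(sort(cost0)[1:3], 3), collapse = ", "),
         call. = FALSE)
  # iteratively-reweighted passes: per q row, estimate the counts-to-
  # intensity scale k = sum(S)/sum(sigma^2) and a smoothed excess variance
  # c(omega) = smooth(k sigma^2 - S), then replace the weights with
  # model-based ones, var = (model + c)/k, decorrelating weights from noise
  E_obs <- E
  for (it in seq_len(max(reweight_iter, 0))) {
    m <- model_of(best$par)
    E_new <- E_obs
    ok <- TRUE
    for (j in seq_len(nq)) {
      denom <- sum(E_obs[j, ]^2)
      if (!is.finite(denom) || denom <= 0 || sum(S[j, ]) <= 0) {
        ok <- FALSE; break
      }
      kj <- sum(S[j, ]) / denom
      cj <- pmax(.smooth_vec(kj * E_obs[j, ]^2 - S[j, ]), 0)
      E_new[j, ] <- sqrt(pmax(m[j, ] + cj, 1e-12) / kj)
    }
    if (!ok) break
    E <- E_new
    out <- tryCatch(
      minpack.lm::nls.lm(best$par, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out)) break
    best <- out
  }
  par <- best$par
  a0 <- if (free_a0) pmin(pmax(par[n_dyn + seq_len(nq)], 0), 1) else a0_start
  dof <- max(length(S) - length(par), 1)
  chisq_red <- best$deviance / dof
  covm <- .lm_covariance(resid_fn, par, chisq_red, lower, upper)
  nm <- c("tau", "jump_len", "gamma_loc", "scale_amp",
          if (!fix_dw) "dw_msd",
          if (free_a0) sprintf("a0_q%d", seq_len(nq)))
  dimnames(covm) <- list(nm, nm)
  se <- sqrt(pmax(diag(covm), 0))
  co <- list(tau = par[1], jump_len = par[2], gamma_loc = par[3],
             scale_amp = par[4],
             dw_msd = if (fix_dw) dw_msd else par[5])
  ses <- list(tau = se[1], jump_len = se[2], gamma_loc = se[3],
              scale_amp = se[4], dw_msd = if (fix_dw) 0 else se[5])
  a0_se <- if (free_a0) se[n_dyn + seq_len(nq)] else
    stats::approx(eisf$q, eisf$sigma, xout = q, rule = 2)$y
  corr_tau_l <- covm["tau", "jump_len"] /
    sqrt(covm["tau", "tau"] * covm["jump_len", "jump_len"])
  fitted <- qens_model_convolved(q, omega, a0, co$tau, co$jump_len,
                                 co$gamma_loc, co$scale_amp, co$dw_msd, R)
  eisf_out <- data.frame(q = q, a0 = a0, sigma = pmax(a0_se, 1e-12),
                         a0_raw = a0)
  attr(eisf_out, "condition") <- spectrum$conditions[1, ]
  class(eisf_out) <- c("eisf_curve", "data.frame")
  structure(list(coefficients = co, se = ses, cov = covm,
                 corr_tau_jump_len = corr_tau_l, chisq_red = chisq_red,
                 a0 = a0, a0_se = a0_se, eisf = eisf_out,
                 a0_mode = a0_mode, q = q, omega = omega, fitted = fitted,
                 condition = spectrum$conditions[1, ],
                 deviance = best$deviance, niter = best$niter),
            class = "qens_fit")
}

#' @export
print.qens_fit <- function(x, ...) {
  cat(sprintf("QENS global fit (T = %g K, P = %g bar)\n",
              x$condition$temperature, x$condition$pressure))
  cat(sprintf("  tau       = %.4g +/- %.2g ps\n", x$coefficients$tau,
              x$se$tau))
  cat(sprintf("  <l>       = %.4g +/- %.2g Ang\n", x$coefficients$jump_len,
              x$se$jump_len))
  cat(sprintf("  Gamma_loc = %.4g +/- %.2g meV\n", x$coefficients$gamma_loc,
              x$se$gamma_loc))
  cat(sprintf("  scale = %.4g, dw_msd = %.4g Ang^2; reduced chi^2 = %.3f\n",
              x$coefficients$scale_amp, x$coefficients$dw_msd, x$chisq_red))
  cat(sprintf("  corr(tau, <l>) = %.3f\n", x$corr_tau_jump_len))
  invisible(x)
}

#' @export
coef.qens_fit <- function(object, ...) unlist(object$coefficients)

#' Joint confidence-region membership for (tau, <l>)
#'
#' Tests whether a point lies inside the elliptical joint confidence region
#' of the residence time and jump length implied by the fit covariance.
#'
#' @param fit A \code{qens_fit}.
#' @param tau,jump_len Candidate point.
#' @param level Region size in sigma units (default 2, i.e. the 95.45
#'   percent joint ellipse).
#' @return Logical.
#' @export
in_tau_l_region <- function(fit, tau, jump_len, level = 2) {
  C <- fit$cov[c("tau", "jump_len"), c("tau", "jump_len")]
  d <- c(tau - fit$coefficients$tau, jump_len - fit$coefficients$jump_len)
  m2 <- tryCatch(drop(t(d) %*% solve(C, d)), error = function(e) Inf)
  m2 <= stats::qchisq(stats::pchisq(level^2, 1), 2)
}

#' Model-free Lorentzian survey of a QENS map
#'
#' Per q channel, fits an explicit resolution-shaped elastic line plus n
#' resolution-convolved Lorentzians for n = 1..max_components, compares the
#' candidate orders with the small-sample-corrected AIC, and classifies the
#' q dependence of each retained component's HWHM as flat (q-independent,
#' localized motions) or saturating (jump diffusion).
#'
#' @param spectrum A \code{qens_dataset} at one condition.
#' @param max_components Maximum number of Lorentzians, 1 to 3.
#' @return An object of class \code{model_free_fit}: chosen order
#'   \code{n_best}, per-order AICc, a per-q table of HWHMs and amplitudes
#'   with uncertainties, and the per-component trend classification.
#' @export
model_free_fit <- function(spectrum, max_components = 3) {
  stopifnot(inherits(spectrum, "qens_dataset"))
  if (!max_components %in% 1:3)
    stop("max_components must be 1, 2 or 3", call. = FALSE)
  if (nrow(spectrum$conditions) != 1)
    stop("model_free_fit expects a single condition", call. = FALSE)
  q <- spectrum$q; omega <- spectrum$omega
  nw <- length(omega)
  aicc_tot <- stats::setNames(numeric(max_components),
                              paste0("n", seq_len(max_components)))
  per_q <- vector("list", max_components)
  failed <- matrix(FALSE, max_components, length(q))
  gamma_starts <- list(0.3, c(0.08, 0.8), c(0.05, 0.3, 1.5))
  for (n in seq_len(max_components)) {
    rows <- NULL
    for (j in seq_along(q)) {
      s <- spectrum$s_qw[1, j, ]; e <- spectrum$sigma[1, j, ]
      r <- spectrum$resolution[j, ]
      area <- sum(s) * diff(omega)[1]
      resid_fn <- function(par) {
        ael <- par[1]
        m <- ael * r
        for (i in seq_len(n)) {
          li <- convolve_resolution(lorentzian(omega, par[1 + 2 * i]),
                                    r, omega)
          m <- m + par[2 * i] * li
        }
        (s - m) / e
      }
      p0 <- c(0.1 * area,
              as.vector(rbind(rep(area / n, n), gamma_starts[[n]])))
      lower <- c(0, rep(c(0, 1e-4), n))
      upper <- c(Inf, rep(c(Inf, 10), n))
      out <- tryCatch(
        minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(out)) { failed[n, j] <- TRUE; next }
      k <- length(p0) + 1
      aicc_tot[n] <- aicc_tot[n] + .aicc_ls(out$deviance, nw, k)
      covm <- .lm_covariance(resid_fn, out$par, out$deviance /
                               max(nw - length(p0), 1), lower, upper)
      se <- sqrt(pmax(diag(covm), 0))
      ordc <- order(out$par[1 + 2 * seq_len(n)])  # narrow to broad
      rows <- rbind(rows, data.frame(
        q = q[j], component = seq_len(n),
        hwhm = out$par[1 + 2 * ordc], hwhm_se = se[1 + 2 * ordc],
        amp = out$par[2 * ordc], amp_se = se[2 * ordc],
        elastic_amp = out$par[1]))
    }
    per_q[[n]] <- rows
  }
  n_best <- unname(which.min(aicc_tot))
  trends <- .classify_width_trends(per_q[[n_best]], n_best)
  structure(list(n_best = n_best, aicc = aicc_tot, components = per_q,
                 trends = trends, failed_q = failed,
                 condition = spectrum$conditions[1, ]),
            class = "model_free_fit")
}

.aicc_ls <- function(rss, n, k) {
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

# flat (weighted mean) vs saturating b (1 - exp(-c q^2)) comparison per
# component, plus a linear slope with its error for significance checks
.classify_width_trends <- function(tab, n) {
  out <- NULL
  for (i in seq_len(n)) {
    sub <- tab[tab$component == i, ]
    w <- 1 / pmax(sub$hwhm_se, 1e-9)^2
    wls <- .wls(cbind(1, sub$q), sub$hwhm, w)
    mu <- sum(w * sub$hwhm) / sum(w)
    rss_flat <- sum(w * (sub$hwhm - mu)^2)
    sat <- tryCatch(minpack.lm::nls.lm(
      c(max(sub$hwhm), 0.5), lower = c(1e-6, 1e-4), upper = c(20, 50),
      fn = function(p) sqrt(w) * (sub$hwhm - p[1] * (1 - exp(-p[2] * sub$q^2)))),
      error = function(e) NULL)
    rss_sat <- if (is.null(sat)) Inf else sat$deviance
    aicc_flat <- .aicc_ls(rss_flat, nrow(sub), 2)
    aicc_sat <- .aicc_ls(rss_sat, nrow(sub), 3)
    out <- rbind(out, data.frame(
      component = i, trend = if (aicc_flat <= aicc_sat) "flat" else "saturating",
      mean_hwhm = mu, slope = wls$coef[2], slope_se = wls$se[2],
      aicc_flat = aicc_flat, aicc_saturating = aicc_sat))
  }
  out
}

#' @export
print.model_free_fit <- function(x, ...) {
  cat("Model-free Lorentzian survey:", x$n_best,
      "component(s) selected by AICc\n")
  print(round(x$aicc, 2))
  cat("Width trends:\n")
  print(x$trends[, c("component", "trend", "mean_hwhm", "slope", "slope_se")],
        digits = 3)
  invisible(x)
}
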