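# Two-state double-well model of elastic scans: hydrogen motions as
# vibrations inside two harmonic wells (Debye-Waller MSD dx0^2) plus jumps
# between the wells, separated by a distance d with free-energy difference
# dG = dH - T dS. Populations follow the Boltzmann ratio; the elastic line
# S(q, 0) = exp(-dx0^2 q^2) [1 - 2 p1 p2 (1 - sinc(q d))].

.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Well populations of the two-state model
#'
#' Population ratio p1/p2 = exp(-dH/(R T) + dS/R) with p1 + p2 = 1. Well 2 is
#' the ground state: p2 >= p1 whenever dG = dH - T dS > 0.
#'
#' @param dH Enthalpy difference, kJ/mol.
#' @param dS Entropy difference, J/(mol K).
#' @param temperature Temperature in K (> 0); vectorized.
#' @return A list with numeric components \code{p1} and \code{p2}.
#' @export
population_fraction <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  dG <- dH - temperature * dS / 1000              # kJ/mol
  r <- exp(-dG / (.const$Rgas * temperature))     # p1/p2
  list(p1 = r / (1 + r), p2 = 1 / (1 + r))
}

#' Elastic intensity of the two-state model
#'
#' S(q, 0) = exp(-dx0^2 q^2) [1 - 2 p1 p2 (1 - sinc(q d))] with
#' sinc(x) = sin(x)/x, sinc(0) = 1. Lies in (0, 1] for all q >= 0.
#'
#' @param q Momentum transfer, 1/Angstrom (>= 0); vectorized.
#' @param dx0_sq Single-well MSD, Angstrom^2 (>= 0).
#' @param d Inter-well distance, Angstrom (>= 0).
#' @param dH Enthalpy difference, kJ/mol.
#' @param dS Entropy difference, J/(mol K).
#' @param temperature Temperature in K.
#' @return Elastic intensities, same length as q.
#' @export
two_state_elastic <- function(q, dx0_sq, d, dH, dS, temperature) {
  if (dx0_sq < 0) stop("dx0_sq must be >= 0", call. = FALSE)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  p <- population_fraction(dH, dS, temperature)
  exp(-dx0_sq * q^2) * (1 - 2 * p$p1 * p$p2 * (1 - .sinc(q * d)))
}

# deterministic multi-start grid; the model is multimodal in (d, dH)
.twostate_starts <- function() {
  expand.grid(d = c(0.5, 1, 1.5, 2, 3),
              dH = c(5, 10, 20, 40),
              dS = c(0, 20, 50))
}

#' Global two-state fit of elastic scans at one pressure
#'
#' Weighted least squares over all (T, q) points jointly, sharing (d, dH, dS)
#' and one overall scale factor across temperatures while leaving the
#' single-well MSD dx0^2 free per temperature. Multi-start over a fixed
#' (d, dH, dS) grid; starts are ranked by initial cost and the best few are
#' refined with bounded Levenberg-Marquardt. Because p1 p2 is invariant
#' under a joint sign flip of (dH, dS) (relabeling the wells), the result is
#' canonicalized to the dH >= 0 branch.
#'
#' @param scans An \code{elastic_scan_set} at a single pressure with at least
#'   3 temperatures and 5 unmasked q points.
#' @param anchor_scale If TRUE the overall scale is fixed at 1 (anchoring
#'   S(q -> 0) = 1) instead of fitted.
#' @param n_refine Number of ranked starts refined fully, default 12.
#' @return An object of class \code{twostate_fit} with components
#'   \code{coefficients} (d, dH, dS, scale and per-temperature dx0_sq),
#'   \code{se}, \code{chisq_red}, \code{temperatures}, \code{pressure},
#'   \code{unidentifiable} (flags for dH/dS when d is degenerate) and the
#'   fitted values.
#' @export
fit_two_state <- function(scans, anchor_scale = FALSE, n_refine = 12) {
  stopifnot(inherits(scans, "elastic_scan_set"))
  P <- unique(scans$conditions$pressure)
  if (length(P) != 1)
    stop("scans must be at a single pressure; split by pressure first",
         call. = FALSE)
  Tv <- scans$conditions$temperature
  if (length(Tv) < 3) stop("need at least 3 temperatures", call. = FALSE)
  if (sum(scans$mask) < 5) stop("need at least 5 unmasked q points",
                                call. = FALSE)
  ord <- order(Tv)
  Tv <- Tv[ord]
  q <- scans$q[scans$mask]
  I <- scans$intensity[ord, scans$mask, drop = FALSE]
  S <- scans$sigma[ord, scans$mask, drop = FALSE]
  nT <- length(Tv)

  # starting dx0^2 and scale from the low-q Debye-Waller slope of log I
  dx0_start <- numeric(nT); sc0 <- 1
  for (i in seq_len(nT)) {
    ok <- I[i, ] > 0
    fitl <- stats::lm.fit(cbind(1, q[ok]^2), log(I[i, ok]))
    dx0_start[i] <- max(-fitl$coefficients[2], 1e-3)
    if (i == 1) sc0 <- exp(min(fitl$coefficients[1], 5))
  }
  if (anchor_scale) sc0 <- 1

  resid_fn <- function(par) {
    d <- par[1]; dH <- par[2]; dS <- par[3]
    sc <- if (anchor_scale) 1 else par[4]
    dx <- par[(if (anchor_scale) 4 else 5):length(par)]
    r <- numeric(0)
    for (i in seq_len(nT)) {
      m <- sc * two_state_elastic(q, dx[i], d, dH, dS, Tv[i])
      r <- c(r, (I[i, ] - m) / S[i, ])
    }
    r
  }

  starts <- .twostate_starts()
  mkpar <- function(k) {
    base <- c(starts$d[k], starts$dH[k], starts$dS[k])
    if (anchor_scale) c(base, dx0_start) else c(base, sc0, dx0_start)
  }
  lower <- c(0, -200, -500, if (!anchor_scale) 1e-8, rep(0, nT))
  upper <- c(10, 200, 500, if (!anchor_scale) Inf, rep(5, nT))
  cost0 <- vapply(seq_len(nrow(starts)),
                  function(k) sum(resid_fn(mkpar(k))^2), numeric(1))
  order_starts <- order(cost0)[seq_len(min(n_refine, nrow(starts)))]
  best <- NULL
  for (k in order_starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(mkpar(k), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best))
    stop("two-state fit failed to converge from any start; ",
         "check data scaling and masks", call. = FALSE)
  par <- best$par
  # p1 p2 is exactly invariant under (dH, dS) -> (-dH, -dS) (swapping the
  # well labels); canonicalize to the dH >= 0 branch
  if (par[2] < 0) { par[2] <- -par[2]; par[3] <- -par[3]; best$par <- par }
  npar <- length(par)
  ndata <- nT * length(q)
  dof <- max(ndata - npar, 1)
  chisq_red <- best$deviance / dof
  covm <- .lm_covariance(resid_fn, par, chisq_red, lower, upper)
  se <- sqrt(pmax(diag(covm), 0))
  iofs <- if (anchor_scale) 3 else 4
  coefs <- list(d = par[1], dH = par[2], dS = par[3],
                scale = if (anchor_scale) 1 else par[4],
                dx0_sq = par[(iofs + 1):npar])
  ses <- list(d = se[1], dH = se[2], dS = se[3],
              scale = if (anchor_scale) 0 else se[4],
              dx0_sq = se[(iofs + 1):npar])
  unident <- c(dH = is.na(ses$dH) || ses$dH > abs(coefs$dH),
               dS = is.na(ses$dS) || ses$dS > abs(coefs$dS),
               d = is.na(ses$d) || ses$d > abs(coefs$d) + 1e-12)
  fitted <- t(vapply(seq_len(nT), function(i)
    coefs$scale * two_state_elastic(q, coefs$dx0_sq[i], coefs$d,
                                    coefs$dH, coefs$dS, Tv[i]),
    numeric(length(q))))
  structure(list(coefficients = coefs, se = ses, chisq_red = chisq_red,
                 temperatures = Tv, pressure = P, q = q,
                 fitted = fitted, data = list(intensity = I, sigma = S),
                 unidentifiable = unident, deviance = best$deviance,
                 niter = best$niter),
            class = "twostate_fit")
}

# finite-difference Jacobian at the solution; pseudo-inverse fallback keeps
# degenerate directions flagged instead of crashing
.lm_covariance <- function(resid_fn, par, chisq_red, lower, upper) {
  n <- length(par)
  r0 <- resid_fn(par)
  J <- matrix(0, length(r0), n)
  for (j in seq_len(n)) {
    h <- max(1e-6 * abs(par[j]), 1e-8)
    pj <- par
    if (!is.null(upper) && par[j] + h > upper[j]) h <- -h
    pj[j] <- par[j] + h
    J[, j] <- (resid_fn(pj) - r0) / h
  }
  A <- crossprod(J)
  covm <- tryCatch(chol2inv(chol(A)) * chisq_red, error = function(e) {
    s <- svd(A)
    tol <- max(s$d) * 1e-10
    inv_d <- ifelse(s$d > tol, 1 / s$d, 1 / tol)
    (s$v %*% (inv_d * t(s$u))) * chisq_red
  })
  covm
}

#' @export
print.twostate_fit <- function(x, ...) {
  cat("Two-state global fit at", x$pressure, "bar (",
      length(x$temperatures), "temperatures x", length(x$q), "q points )\n")
  cat(sprintf("  d  = %.3f +/- %.3f Ang\n", x$coefficients$d, x$se$d))
  cat(sprintf("  dH = %.2f +/- %.2f kJ/mol%s\n", x$coefficients$dH, x$se$dH,
              if (x$unidentifiable["dH"]) "  [unidentifiable]" else ""))
  cat(sprintf("  dS = %.2f +/- %.2f J/(mol K)%s\n", x$coefficients$dS,
              x$se$dS,
              if (x$unidentifiable["dS"]) "  [unidentifiable]" else ""))
  cat(sprintf("  scale = %.4f; reduced chi^2 = %.3f\n",
              x$coefficients$scale, x$chisq_red))
  invisible(x)
}

#' @export
coef.twostate_fit <- function(object, ...) {
  c(d = object$coefficients$d, dH = object$coefficients$dH,
    dS = object$coefficients$dS, scale = object$coefficients$scale,
    stats::setNames(object$coefficients$dx0_sq,
                    paste0("dx0_sq_", format(object$temperatures))))
}

#' @export
summary.twostate_fit <- function(object, ...) {
  print(object)
  msd <- total_msd(object)
  cat("\nTotal MSD (Angstrom^2):\n")
  print(msd, digits = 4)
  invisible(object)
}

#' Predicted elastic intensities from a two-state fit
#'
#' @param object A \code{twostate_fit}.
#' @param q Optional q vector; defaults to the fitted grid.
#' @param ... Unused.
#' @return Matrix [temperature x q] of model intensities.
#' @export
predict.twostate_fit <- function(object, q = object$q, ...) {
  co <- object$coefficients
  t(vapply(seq_along(object$temperatures), function(i)
    co$scale * two_state_elastic(q, co$dx0_sq[i], co$d, co$dH, co$dS,
                                 object$temperatures[i]),
    numeric(length(q))))
}

#' Total mean-square displacement from a two-state fit
#'
#' dx_tot^2(T) = dx0^2(T) + (p1 p2 / 3) d^2, combining the intra-well
#' Debye-Waller term with the inter-well jump contribution.
#'
#' @param params A \code{twostate_fit} (or a list with elements
#'   \code{dx0_sq}, \code{d}, \code{dH}, \code{dS}, \code{temperatures},
#'   \code{pressure}).
#' @return A data.frame of class \code{msd_curve} with columns
#'   \code{temperature}, \code{msd_single}, \code{msd_total} and attribute
#'   \code{pressure}.
#' @export
total_msd <- function(params) {
  if (inherits(params, "twostate_fit")) {
    co <- params$coefficients
    Tv <- params$temperatures; P <- params$pressure
  } else {
    co <- params; Tv <- params$temperatures; P <- params$pressure
  }
  p <- population_fraction(co$dH, co$dS, Tv)
  out <- data.frame(temperature = Tv,
                    msd_single = co$dx0_sq,
                    msd_total = co$dx0_sq + p$p1 * p$p2 * co$d^2 / 3)
  attr(out, "pressure") <- P
  class(out) <- c("msd_curve", "data.frame")
  out
}
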