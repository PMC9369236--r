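# Geometric model of the elastic incoherent structure factor: an immobile
# fraction p, a fraction s of the mobile hydrogens confined in a region of
# radius R (restricted jump diffusion) and the complement undergoing
# three-site methyl jumps of fixed jump distance a_M.

.j0 <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Geometric EISF model
#'
#' A0(q) = p + (1 - p) [s j0^2(q R / 2) + (1 - s) (1/3)(1 + 2 j0(q a_M))],
#' with j0 the zeroth-order spherical Bessel function. With
#' \code{aj_form = "full"} the confinement term uses j0^2(q R) instead
#' (sensitivity switch).
#'
#' @param q Momentum transfer, 1/Angstrom; vectorized.
#' @param p_immobile Fraction of immobile hydrogens, in [0, 1].
#' @param s_confined Fraction of mobile hydrogens confined, in [0, 1].
#' @param radius Confinement radius R, Angstrom (> 0).
#' @param a_methyl Methyl jump distance, Angstrom; default 1.715.
#' @param aj_form "half" (default, j0^2(qR/2)) or "full" (j0^2(qR)).
#' @return A0 values in (0, 1].
#' @export
eisf_model <- function(q, p_immobile, s_confined, radius,
                       a_methyl = 1.715, aj_form = c("half", "full")) {
  aj_form <- match.arg(aj_form)
  if (p_immobile < 0 || p_immobile > 1 || s_confined < 0 || s_confined > 1)
    stop("p_immobile and s_confined must lie in [0, 1]", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  x <- if (aj_form == "half") q * radius / 2 else q * radius
  aj <- .j0(x)^2
  a3 <- (1 + 2 * .j0(q * a_methyl)) / 3
  p_immobile + (1 - p_immobile) * (s_confined * aj + (1 - s_confined) * a3)
}

#' Fit the geometric EISF model to an extracted A0(q) curve
#'
#' Bounded weighted least squares with p, s in [0, 1] and R in (0.5, 20)
#' Angstrom, a_M fixed; multi-start over R. q points exceeding 1 by more
#' than two sigma are rejected with a warning. When s is degenerate (near 0)
#' the radius is flagged unidentifiable.
#'
#' @param curve An \code{eisf_curve} (columns q, a0, sigma) with at least 6
#'   q points.
#' @param a_methyl Methyl jump distance, Angstrom; default 1.715.
#' @param aj_form See \code{\link{eisf_model}}.
#' @param r_starts Multi-start radii, default c(1, 2, 4, 8).
#' @return An object of class \code{eisf_fit} with coefficients
#'   (p_immobile, s_confined, radius), standard errors, chi^2 and an
#'   \code{unidentifiable} flag for the radius.
#' @export
fit_eisf <- function(curve, a_methyl = 1.715, aj_form = c("half", "full"),
                     r_starts = c(1, 2, 4, 8)) {
  aj_form <- match.arg(aj_form)
  stopifnot(is.data.frame(curve), all(c("q", "a0", "sigma") %in% names(curve)))
  keep <- curve$a0 <= 1 + 2 * curve$sigma
  if (any(!keep))
    warning(sum(!keep), " q point(s) with A0 > 1 + 2 sigma rejected",
            call. = FALSE)
  curve <- curve[keep, ]
  if (nrow(curve) < 6)
    stop("need at least 6 usable q points spanning the keep-range",
         call. = FALSE)
  w <- 1 / curve$sigma^2
  resid_fn <- function(par)
    sqrt(w) * (curve$a0 - eisf_model(curve$q, par[1], par[2], par[3],
                                     a_methyl, aj_form))
  lower <- c(0, 0, 0.5); upper <- c(1, 1, 20)
  best <- NULL; diags <- NULL
  for (r0 in r_starts) {
    p0 <- c(max(min(curve$a0), 0.05), 0.5, r0)
    out <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    diags <- rbind(diags, data.frame(r_start = r0,
                                     deviance = if (is.null(out)) NA
                                     else out$deviance))
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) {
    stop("EISF fit failed to converge from all starts; start-point ",
         "diagnostics: ", paste(utils::capture.output(print(diags)),
                                collapse = "\n"), call. = FALSE)
  }
  par <- best$par
  dof <- max(nrow(curve) - 3, 1)
  chisq_red <- best$deviance / dof
  covm <- .lm_covariance(resid_fn, par, chisq_red, lower, upper)
  se <- sqrt(pmax(diag(covm), 0))
  r_unident <- is.na(se[3]) || se[3] > par[3] ||
    par[2] < max(2 * se[2], 0.02)   # s ~ 0: nothing constrains R
  structure(list(coefficients = list(p_immobile = par[1],
                                     s_confined = par[2], radius = par[3]),
                 se = list(p_immobile = se[1], s_confined = se[2],
                           radius = if (r_unident) max(se[3], par[3] * 1.01)
                           else se[3]),
                 chisq_red = chisq_red, a_methyl = a_methyl,
                 aj_form = aj_form, unidentifiable = c(radius = r_unident),
                 curve = curve, condition = attr(curve, "condition")),
            class = "eisf_fit")
}

#' @export
print.eisf_fit <- function(x, ...) {
  cat("EISF geometry fit (a_M =", x$a_methyl, "Ang,", x$aj_form,
      "confinement form)\n")
  cat(sprintf("  p (immobile)  = %.3f +/- %.3f\n", x$coefficients$p_immobile,
              x$se$p_immobile))
  cat(sprintf("  s (confined)  = %.3f +/- %.3f\n", x$coefficients$s_confined,
              x$se$s_confined))
  cat(sprintf("  R (radius)    = %.3f +/- %.3f Ang%s\n",
              x$coefficients$radius, x$se$radius,
              if (x$unidentifiable["radius"]) "  [unidentifiable]" else ""))
  cat(sprintf("  reduced chi^2 = %.3f\n", x$chisq_red))
  invisible(x)
}

#' @export
coef.eisf_fit <- function(object, ...) unlist(object$coefficients)

#' Predicted A0(q) from an EISF geometry fit
#'
#' @param object An \code{eisf_fit}.
#' @param q Optional q vector; defaults to the fitted points.
#' @param ... Unused.
#' @return A0 values.
#' @export
predict.eisf_fit <- function(object, q = object$curve$q, ...) {
  co <- object$coefficients
  eisf_model(q, co$p_immobile, co$s_confined, co$radius,
             object$a_methyl, object$aj_form)
}

#' Radius of the sphere with a given volume
#'
#' Converts a cavity volume to an equivalent radius (3V / 4 pi)^(1/3) for
#' comparison with the QENS confinement radius.
#'
#' @param volume Volume in Angstrom^3 (>= 0); vectorized.
#' @return Radius in Angstrom.
#' @export
equivalent_radius <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0", call. = FALSE)
  (3 * volume / (4 * pi))^(1 / 3)
}
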