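# Quasi-elastic spectral model: an elastic fraction A0(q) times a Lorentzian
# of HWHM Gamma_j(q) (Hall-Ross confined jump diffusion) plus the complement
# times a Lorentzian of HWHM Gamma_j(q) + Gamma_loc (fast localized motions
# convolved with the jump diffusion; Lorentzian HWHMs add under convolution).

#' Hall-Ross jump-diffusion half width
#'
#' Gamma_j(q) = (hbar / tau) [1 - exp(-q^2 <l>^2 / 2)], in meV. Monotone
#' non-decreasing in q, saturating at hbar/tau.
#'
#' @param q Momentum transfer, 1/Angstrom; vectorized.
#' @param tau Residence time between jumps, ps (> 0).
#' @param jump_len Mean jump length <l>, Angstrom.
#' @return HWHM values in meV.
#' @export
hall_ross_hwhm <- function(q, tau, jump_len) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  (.const$hbar / tau) * (1 - exp(-q^2 * jump_len^2 / 2))
}

#' Unit-area Lorentzian
#'
#' @param omega Energy transfer grid, meV.
#' @param hwhm Half width at half maximum, meV (> 0).
#' @return (1/pi) hwhm / (hwhm^2 + omega^2).
#' @export
lorentzian <- function(omega, hwhm) {
  if (hwhm < 0) stop("hwhm must be >= 0", call. = FALSE)
  hwhm / (pi * (hwhm^2 + omega^2))
}

#' Quasi-elastic model spectrum (before resolution convolution)
#'
#' S(q, omega) = A0(q) L(omega; Gamma_j(q)) +
#' (1 - A0(q)) L(omega; Gamma_j(q) + Gamma_loc), with L unit-area
#' Lorentzians, scaled by scale_amp exp(-q^2 dw_msd) (Debye-Waller factor).
#' The unscaled model integrates to 1 over omega for every q.
#'
#' @param q q vector, 1/Angstrom.
#' @param omega Energy grid, meV.
#' @param a0 EISF values A0(q) in [0, 1], one per q.
#' @param tau Residence time, ps.
#' @param jump_len Mean jump length, Angstrom.
#' @param gamma_loc Localized-motion HWHM, meV (>= 0).
#' @param scale_amp Overall amplitude, default 1.
#' @param dw_msd Debye-Waller MSD <u^2>, Angstrom^2, default 0.
#' @return Matrix [q x omega] of intensities.
#' @export
qens_model <- function(q, omega, a0, tau, jump_len, gamma_loc,
                       scale_amp = 1, dw_msd = 0) {
  if (gamma_loc < 0) stop("gamma_loc must be >= 0", call. = FALSE)
  if (any(a0 < 0 | a0 > 1)) stop("a0 must lie in [0, 1]", call. = FALSE)
  gj <- hall_ross_hwhm(q, tau, jump_len)
  out <- matrix(0, length(q), length(omega))
  for (j in seq_along(q)) {
    narrow <- lorentzian(omega, gj[j])
    broad <- lorentzian(omega, gj[j] + gamma_loc)
    out[j, ] <- (a0[j] * narrow + (1 - a0[j]) * broad) *
      scale_amp * exp(-q[j]^2 * dw_msd)
  }
  out
}

#' Convolve a model spectrum with the instrument resolution
#'
#' Discrete linear convolution on the regular omega grid. The model is
#' zero-padded by \code{pad_windows} window-widths on each side before the
#' open convolution, and the central window is returned; with an area-1
#' kernel the discrete area of the model is preserved. For best tail
#' accuracy evaluate the analytic model on an extended grid (see
#' \code{\link{qens_model_convolved}}).
#'
#' @param model Vector or matrix [q x omega] on the same grid as
#'   \code{resolution}.
#' @param resolution Resolution profile(s): vector, or matrix [q x omega],
#'   area-normalized on the grid.
#' @param omega The energy grid, meV (evenly spaced).
#' @param pad_windows Number of window-widths of zero padding, default 3.
#' @return Convolved spectrum, same shape as \code{model}.
#' @export
convolve_resolution <- function(model, resolution, omega, pad_windows = 3) {
  vec_in <- is.null(dim(model))
  if (vec_in) model <- matrix(model, 1)
  if (is.null(dim(resolution)))
    resolution <- matrix(resolution, nrow(model), length(resolution),
                         byrow = TRUE)
  nw <- length(omega)
  if (ncol(model) != nw || ncol(resolution) != nw)
    stop("grid mismatch: model, resolution and omega must share one grid",
         call. = FALSE)
  if (nrow(resolution) != nrow(model))
    stop("grid mismatch: one resolution profile per model row required",
         call. = FALSE)
  dw <- diff(omega)[1]
  i0 <- which.min(abs(omega))       # kernel center (omega = 0 channel)
  npad <- pad_windows * nw
  out <- matrix(0, nrow(model), nw)
  for (j in seq_len(nrow(model))) {
    x <- c(rep(0, npad), model[j, ], rep(0, npad))
    z <- .conv_open(x, resolution[j, ]) * dw
    # alignment: kernel index i0 corresponds to zero shift
    out[j, ] <- z[npad + seq_len(nw) + i0 - 1]
  }
  if (vec_in) out[1, ] else out
}

# open (full) linear convolution via FFT, z[l] = sum_i x[i] k[l - i + 1]
.conv_open <- function(x, k) {
  n <- length(x) + length(k) - 1
  nf <- stats::nextn(n, 2)
  xz <- c(x, rep(0, nf - length(x)))
  kz <- c(k, rep(0, nf - length(k)))
  z <- Re(stats::fft(stats::fft(xz) * stats::fft(kz), inverse = TRUE)) / nf
  z[seq_len(n)]
}

#' Resolution-convolved analytic QENS model on the data grid
#'
#' Evaluates \code{\link{qens_model}} on a grid extended by
#' \code{pad_windows} window-widths per side, convolves with the resolution,
#' and crops to the data window, so Lorentzian tails outside the analysis
#' window are carried correctly.
#'
#' @inheritParams qens_model
#' @param resolution Matrix [q x omega] of area-normalized profiles on the
#'   data grid.
#' @param pad_windows Window extension factor, default 3.
#' @return Matrix [q x omega] of convolved model intensities.
#' @export
qens_model_convolved <- function(q, omega, a0, tau, jump_len, gamma_loc,
                                 scale_amp = 1, dw_msd = 0, resolution,
                                 pad_windows = 3) {
  dw <- diff(omega)[1]
  nw <- length(omega)
  next_lo <- seq(omega[1] - pad_windows * nw * dw, omega[1] - dw, by = dw)
  next_hi <- seq(omega[nw] + dw, omega[nw] + pad_windows * nw * dw, by = dw)
  ext <- c(next_lo, omega, next_hi)
  m_ext <- qens_model(q, ext, a0, tau, jump_len, gamma_loc, scale_amp,
                      dw_msd)
  i0 <- which.min(abs(omega))
  keep <- length(next_lo) + seq_len(nw)
  out <- matrix(0, length(q), nw)
  if (is.null(dim(resolution)))
    resolution <- matrix(resolution, length(q), nw, byrow = TRUE)
  for (j in seq_along(q)) {
    z <- .conv_open(m_ext[j, ], resolution[j, ]) * dw
    out[j, ] <- z[keep + i0 - 1]
  }
  out
}

#' Per-q full width at half maximum of a resolution profile
#'
#' @param resolution Matrix [q x omega] (or vector) of profiles.
#' @param omega Energy grid, meV.
#' @return FWHM per q, meV, by linear interpolation of the half crossings.
#' @export
resolution_fwhm <- function(resolution, omega) {
  if (is.null(dim(resolution))) resolution <- matrix(resolution, 1)
  apply(resolution, 1, function(r) {
    pk <- which.max(r)
    half <- r[pk] / 2
    left <- which(r[seq_len(pk)] >= half)[1]
    right <- pk - 1 + rev(which(r[pk:length(r)] >= half))[1]
    xl <- if (left > 1)
      stats::approx(r[c(left - 1, left)], omega[c(left - 1, left)],
                    xout = half)$y else omega[left]
    xr <- if (right < length(r))
      stats::approx(r[c(right, right + 1)], omega[c(right, right + 1)],
                    xout = half)$y else omega[right]
    xr - xl
  })
}

#' Extract the elastic incoherent structure factor by integration
#'
#' A0(q) = integral of S over |omega| <= w divided by the integral over the
#' full window, per q. The default window half-width w is one resolution
#' FWHM at that q. A raw estimate is always reported; when
#' \code{bias_correct} is TRUE an iteratively window-bias-corrected estimate
#' is returned as \code{a0} (the raw one stays in \code{a0_raw}): the raw
#' ratio mixes the enclosed fractions of the resolution-shaped elastic part
#' (f_el) and of the broadened part (f_b), and the correction inverts
#' raw = A0 f_el + (1 - A0) f_b with f_b re-estimated from the residual
#' broad component.
#'
#' @param spectrum A \code{qens_dataset} at a single condition.
#' @param window_hwidth Optional numeric half-width in meV; default one
#'   resolution FWHM per q.
#' @param bias_correct Apply the window-bias correction, default TRUE.
#' @return A data.frame of class \code{eisf_curve} with columns \code{q},
#'   \code{a0}, \code{sigma}, \code{a0_raw}; condition kept as attribute.
#' @export
extract_eisf <- function(spectrum, window_hwidth = NULL,
                         bias_correct = TRUE) {
  stopifnot(inherits(spectrum, "qens_dataset"))
  if (nrow(spectrum$conditions) != 1)
    stop("extract_eisf expects a single condition; use subset_condition()",
         call. = FALSE)
  omega <- spectrum$omega
  dw <- diff(omega)[1]
  fw <- resolution_fwhm(spectrum$resolution, omega)
  w <- if (is.null(window_hwidth)) fw else rep_len(window_hwidth,
                                                   length(spectrum$q))
  if (any(w > max(omega)))
    stop("elastic window exceeds the data range", call. = FALSE)
  nq <- length(spectrum$q)
  a0_raw <- numeric(nq); sig <- numeric(nq); a0 <- numeric(nq)
  masked <- logical(nq)
  for (j in seq_len(nq)) {
    s <- spectrum$s_qw[1, j, ]
    e <- spectrum$sigma[1, j, ]
    inwin <- abs(omega) <= w[j]
    tot <- sum(s) * dw
    if (tot <= 0) { masked[j] <- TRUE; next }
    el <- sum(s[inwin]) * dw
    a0_raw[j] <- el / tot
    # ratio-of-sums error with the shared channels accounted for
    v <- (1 / tot)^2 * sum(e[inwin]^2) +
      (el / tot^2)^2 * sum(e^2) -
      2 * (el / tot^3) * sum(e[inwin]^2)
    sig[j] <- dw * sqrt(max(v, 0))
    if (bias_correct) {
      a0[j] <- .eisf_window_bias_correct(s, e, spectrum$resolution[j, ],
                                         omega, inwin, a0_raw[j])
    } else a0[j] <- a0_raw[j]
  }
  out <- data.frame(q = spectrum$q[!masked], a0 = pmin(pmax(a0[!masked], 0), 1),
                    sigma = pmax(sig[!masked], 1e-12),
                    a0_raw = a0_raw[!masked])
  attr(out, "condition") <- spectrum$conditions[1, ]
  attr(out, "window_hwidth") <- w
  class(out) <- c("eisf_curve", "data.frame")
  out
}

# Window-bias correction of the integrated EISF. The raw elastic/total ratio
# mixes the enclosed fractions of the narrow (resolution-convolved
# jump-diffusion) and broad components; a quick two-Lorentzian component fit
# per q supplies those fractions, and the mixing relation
#   raw = (A0 e_n + (1-A0) e_b) / (A0 g_n + (1-A0) g_b)
# (e = in-window, g = in-grid enclosed integral of each unit-area convolved
# component) is inverted for A0.
.eisf_window_bias_correct <- function(s, e, r, omega, inwin, raw) {
  dw <- diff(omega)[1]
  area <- sum(s) * dw
  resid_fn <- function(p) {
    m <- p[1] * convolve_resolution(lorentzian(omega, p[2]), r, omega) +
      p[3] * convolve_resolution(lorentzian(omega, p[4]), r, omega)
    (s - m) / e
  }
  p0 <- c(0.6 * area, 0.05, 0.4 * area, 0.5)
  out <- tryCatch(
    minpack.lm::nls.lm(p0, lower = c(0, 1e-4, 0, 1e-4),
                       upper = c(Inf, 5, Inf, 10), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(x) NULL)
  if (is.null(out)) return(raw)
  g <- sort(c(out$par[2], out$par[4]))   # narrow, broad HWHM
  conv_n <- convolve_resolution(lorentzian(omega, g[1]), r, omega)
  conv_b <- convolve_resolution(lorentzian(omega, g[2]), r, omega)
  e_n <- sum(conv_n[inwin]) * dw; g_n <- sum(conv_n) * dw
  e_b <- sum(conv_b[inwin]) * dw; g_b <- sum(conv_b) * dw
  num <- raw * g_b - e_b
  den <- (raw * g_b - e_b) - (raw * g_n - e_n)
  if (abs(den) < 1e-9) return(raw)
  min(max(num / den, 0), 1)
}
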