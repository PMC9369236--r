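# Correction chain turning raw sample / empty-cell / buffer / vanadium
# measurements into fit-ready containers: transmission scaling, background
# subtraction, vanadium (detector-efficiency) normalization, detailed
# balance, temperature binning, hysteresis-checked up/down merging and
# flux-conserving energy rebinning.

.payload_grid_equal <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (!isTRUE(all.equal(a$q, b$q))) return(FALSE)
  if (inherits(a, "qens_dataset") && !isTRUE(all.equal(a$omega, b$omega)))
    return(FALSE)
  TRUE
}

.values <- function(x) if (inherits(x, "qens_dataset")) x$s_qw else x$intensity
.errors <- function(x) if (inherits(x, "qens_dataset")) x$sigma else x$sigma

.rebuild <- function(template, values, sigma) {
  if (inherits(template, "qens_dataset")) {
    qens_dataset(template$q, template$omega, values, sigma,
                 template$resolution, template$resolution_sigma,
                 template$conditions)
  } else {
    elastic_scan_set(template$q, values, sigma, template$conditions,
                     template$mask)
  }
}

#' Subtract empty-cell and buffer backgrounds with transmission scaling
#'
#' Computes (I_s/t_s - I_ec/t_ec) - (1 - f) (I_b/t_b - I_ec/t_ec), where f is
#' the fraction of buffer volume displaced by the protein, with errors
#' propagated in quadrature. Negative results are clipped to zero and the
#' clip count is recorded in the \code{n_clipped} attribute.
#'
#' @param sample,empty_cell,buffer \code{raw_measurement} objects on matching
#'   grids, with transmissions set.
#' @param displaced_fraction Fraction of the buffer displaced by the solute,
#'   in [0, 1). Default 0.0876 (0.120 g/mL protein times a partial specific
#'   volume of 0.73 mL/g).
#' @return A corrected payload of the same class as the sample payload.
#' @export
subtract_backgrounds <- function(sample, empty_cell, buffer,
                                 displaced_fraction = 0.0876) {
  stopifnot(inherits(sample, "raw_measurement"),
            inherits(empty_cell, "raw_measurement"),
            inherits(buffer, "raw_measurement"))
  if (!is.numeric(displaced_fraction) || displaced_fraction < 0 ||
      displaced_fraction >= 1)
    stop("displaced_fraction must be in [0, 1)", call. = FALSE)
  if (!.payload_grid_equal(sample$data, empty_cell$data) ||
      !.payload_grid_equal(sample$data, buffer$data))
    stop("grid mismatch between sample, empty cell and buffer ",
         "(q and omega axes must be identical)", call. = FALSE)
  f <- displaced_fraction
  ts <- sample$transmission; te <- empty_cell$transmission
  tb <- buffer$transmission
  # coefficient of the empty cell collapses to -f/t_ec
  val <- .values(sample$data) / ts -
    (1 - f) * .broadcast_cond(.values(buffer$data), dim(.values(sample$data))) / tb -
    f * .broadcast_cond(.values(empty_cell$data), dim(.values(sample$data))) / te
  sig <- sqrt((.errors(sample$data) / ts)^2 +
                ((1 - f) * .broadcast_cond(.errors(buffer$data),
                                           dim(.values(sample$data))) / tb)^2 +
                (f * .broadcast_cond(.errors(empty_cell$data),
                                     dim(.values(sample$data))) / te)^2)
  n_clipped <- sum(val < 0)
  val[val < 0] <- 0
  out <- .rebuild(sample$data, val, sig)
  attr(out, "n_clipped") <- n_clipped
  out
}

# backgrounds may be measured once (1 condition) and shared across sample
# conditions; replicate along the condition axis when needed
.broadcast_cond <- function(x, target_dim) {
  if (identical(dim(x), target_dim)) return(x)
  if (is.matrix(x) && length(target_dim) == 2 && nrow(x) == 1)
    return(matrix(x, target_dim[1], target_dim[2], byrow = TRUE))
  if (length(dim(x)) == 3 && length(target_dim) == 3 && dim(x)[1] == 1) {
    out <- array(0, target_dim)
    for (i in seq_len(target_dim[1])) out[i, , ] <- x[1, , ]
    return(out)
  }
  stop("grid mismatch: background shape incompatible with sample",
       call. = FALSE)
}

#' Normalize to a vanadium standard (per-detector efficiency removal)
#'
#' Each q channel is divided by the transmission-scaled vanadium elastic
#' intensity (elastic scans) or by the vanadium omega-integral at that q
#' (QENS maps). Channels where vanadium is non-positive are auto-masked with
#' a warning.
#'
#' @param corrected A background-corrected payload.
#' @param vanadium A \code{raw_measurement} of kind "vanadium" on the same
#'   q grid.
#' @return Payload of the same class, vanadium-normalized.
#' @export
normalize_vanadium <- function(corrected, vanadium) {
  stopifnot(inherits(vanadium, "raw_measurement"))
  vd <- vanadium$data
  if (!isTRUE(all.equal(corrected$q, vd$q)))
    stop("grid mismatch: vanadium q axis differs from data", call. = FALSE)
  tv <- vanadium$transmission
  if (inherits(vd, "qens_dataset")) {
    dw <- diff(vd$omega)[1]
    v <- apply(vd$s_qw[1, , , drop = FALSE], 2, sum) * dw / tv
    vs <- sqrt(apply(vd$sigma[1, , , drop = FALSE]^2, 2, sum)) * dw / tv
  } else {
    v <- vd$intensity[1, ] / tv
    vs <- vd$sigma[1, ] / tv
  }
  bad <- !is.finite(v) | v <= 0
  if (any(bad))
    warning(sum(bad), " q channel(s) with non-positive vanadium intensity ",
            "auto-masked", call. = FALSE)
  vsafe <- ifelse(bad, 1, v)
  if (inherits(corrected, "qens_dataset")) {
    val <- corrected$s_qw; sig <- corrected$sigma
    for (j in seq_along(v)) {
      a <- val[, j, ]
      sig[, j, ] <- sqrt((sig[, j, ] / vsafe[j])^2 +
                           (a * vs[j] / vsafe[j]^2)^2)
      val[, j, ] <- a / vsafe[j]
    }
    if (any(bad)) {
      keep <- !bad
      rs <- corrected$resolution_sigma
      if (!is.null(rs)) rs <- rs[keep, , drop = FALSE]
      out <- qens_dataset(corrected$q[keep], corrected$omega,
                          val[, keep, , drop = FALSE],
                          sig[, keep, , drop = FALSE],
                          corrected$resolution[keep, , drop = FALSE],
                          rs, corrected$conditions)
      return(out)
    }
    .rebuild(corrected, val, sig)
  } else {
    a <- corrected$intensity
    sig <- sqrt(sweep(corrected$sigma, 2, vsafe, "/")^2 +
                  sweep(a, 2, vs / vsafe^2, "*")^2)
    val <- sweep(a, 2, vsafe, "/")
    out <- elastic_scan_set(corrected$q, val, sig, corrected$conditions,
                            corrected$mask & !bad)
    out
  }
}

#' Apply the detailed-balance correction to a QENS dataset
#'
#' Multiplies S(q, omega) by exp(-hbar omega / (2 kB T)), turning a spectrum
#' with the exact quantum asymmetry S(-omega) = exp(-hbar omega / kB T)
#' S(omega) into a symmetric one. Positive omega is energy transferred to
#' the sample.
#'
#' @param spectrum A \code{qens_dataset} with condition temperatures set.
#' @return The corrected \code{qens_dataset}.
#' @export
detailed_balance_correct <- function(spectrum) {
  stopifnot(inherits(spectrum, "qens_dataset"))
  Ts <- spectrum$conditions$temperature
  if (any(Ts <= 0)) stop("temperatures must be > 0", call. = FALSE)
  val <- spectrum$s_qw; sig <- spectrum$sigma
  for (i in seq_along(Ts)) {
    fac <- exp(-.const$hbar * spectrum$omega / (2 * .const$kB * Ts[i]))
    fac <- matrix(fac, length(spectrum$q), length(spectrum$omega),
                  byrow = TRUE)
    val[i, , ] <- val[i, , ] * fac
    sig[i, , ] <- sig[i, , ] * fac
  }
  .rebuild(spectrum, val, sig)
}

#' Bin a continuous temperature ramp into fixed-width temperature bins
#'
#' Points are assigned to bins of the given width with edges anchored at the
#' scan-start (minimum) temperature. Each bin holds the error-weighted mean
#' intensity per q, the bin label being the weighted mean temperature of its
#' members. Empty bins are dropped.
#'
#' @param scans An \code{elastic_scan_set} whose conditions carry the
#'   instantaneous temperature of each ramp point (single pressure).
#' @param width Bin width in K, default 10.
#' @return A binned \code{elastic_scan_set}.
#' @export
bin_temperature <- function(scans, width = 10) {
  stopifnot(inherits(scans, "elastic_scan_set"))
  if (!is.numeric(width) || width <= 0)
    stop("bin width must be > 0", call. = FALSE)
  Tv <- scans$conditions$temperature
  anchor <- min(Tv)
  idx <- floor((Tv - anchor) / width)
  bins <- sort(unique(idx))
  nq <- length(scans$q)
  I <- matrix(0, length(bins), nq)
  S <- matrix(0, length(bins), nq)
  Tb <- numeric(length(bins)); Pb <- numeric(length(bins))
  for (k in seq_along(bins)) {
    m <- idx == bins[k]
    w <- 1 / scans$sigma[m, , drop = FALSE]^2
    I[k, ] <- colSums(w * scans$intensity[m, , drop = FALSE]) / colSums(w)
    S[k, ] <- 1 / sqrt(colSums(w))
    wt <- rowSums(w)
    Tb[k] <- sum(wt * Tv[m]) / sum(wt)
    Pb[k] <- scans$conditions$pressure[m][1]
  }
  elastic_scan_set(scans$q, I, S,
                   conditions(Tb, Pb, scans$conditions$sample_id[1]),
                   scans$mask)
}

#' Merge up- and down-scans after a hysteresis check
#'
#' Per (T, q) point the discrepancy |I_up - I_down| / sqrt(s_up^2 + s_down^2)
#' is compared to \code{tolerance_sigma}. If more than
#' \code{max_discrepant_fraction} of the points are discrepant the merge is
#' refused with an error of class \code{piezodyn_hysteresis_error} carrying
#' the logical discrepancy map; otherwise the error-weighted average is
#' returned.
#'
#' @param up,down \code{elastic_scan_set} objects on the same binning grid.
#' @param tolerance_sigma Per-point threshold in units of sigma, default 3.
#' @param max_discrepant_fraction Refusal threshold, default 0.01.
#' @return Merged \code{elastic_scan_set}.
#' @export
merge_updown <- function(up, down, tolerance_sigma = 3,
                         max_discrepant_fraction = 0.01) {
  stopifnot(inherits(up, "elastic_scan_set"),
            inherits(down, "elastic_scan_set"))
  if (!isTRUE(all.equal(up$q, down$q)) ||
      nrow(up$conditions) != nrow(down$conditions) ||
      !isTRUE(all.equal(up$conditions$temperature,
                        down$conditions$temperature, tolerance = 1e-6)))
    stop("grid mismatch: up and down scans must share the binning grid",
         call. = FALSE)
  z <- abs(up$intensity - down$intensity) /
    sqrt(up$sigma^2 + down$sigma^2)
  discrepant <- z > tolerance_sigma
  frac <- mean(discrepant)
  if (frac > max_discrepant_fraction) {
    stop(errorCondition(
      sprintf("hysteresis detected: %.1f%% of points discrepant beyond %g sigma; merge refused",
              100 * frac, tolerance_sigma),
      class = c("piezodyn_hysteresis_error", "error", "condition"),
      discrepant = discrepant, z = z))
  }
  wu <- 1 / up$sigma^2; wd <- 1 / down$sigma^2
  I <- (wu * up$intensity + wd * down$intensity) / (wu + wd)
  S <- 1 / sqrt(wu + wd)
  elastic_scan_set(up$q, I, S, up$conditions, up$mask & down$mask)
}

#' Flux-conserving energy rebinning of a QENS dataset
#'
#' Input channels are treated as piecewise-constant over their widths and
#' integrated over the new bins, so the integral over any shared interval is
#' preserved. q channels outside the keep-range are dropped.
#'
#' @param spectrum A \code{qens_dataset}.
#' @param step New energy step in meV, default 0.02.
#' @param window Two-element analysis window in meV, default c(-1.5, 1.5).
#' @param qrange q keep-range in 1/Angstrom, default c(0.6, 1.8).
#' @return Rebinned \code{qens_dataset}.
#' @export
rebin_energy <- function(spectrum, step = 0.02, window = c(-1.5, 1.5),
                         qrange = c(0.6, 1.8)) {
  stopifnot(inherits(spectrum, "qens_dataset"))
  h <- diff(spectrum$omega)[1]
  lo <- min(spectrum$omega) - h / 2
  hi <- max(spectrum$omega) + h / 2
  if (window[1] - step / 2 < lo - 1e-9 || window[2] + step / 2 > hi + 1e-9)
    stop("requested window lies outside the data range", call. = FALSE)
  new_centers <- seq(window[1], window[2], by = step)
  ov <- .overlap_matrix(spectrum$omega, h, new_centers, step)
  keep <- spectrum$q >= qrange[1] & spectrum$q <= qrange[2]
  if (!any(keep)) stop("no q channels inside qrange", call. = FALSE)
  nc <- nrow(spectrum$conditions); nq <- sum(keep)
  nw <- length(new_centers)
  val <- array(0, c(nc, nq, nw)); sig <- array(0, c(nc, nq, nw))
  qi <- which(keep)
  for (i in seq_len(nc)) for (j in seq_along(qi)) {
    val[i, j, ] <- as.vector(ov %*% spectrum$s_qw[i, qi[j], ]) / step
    sig[i, j, ] <- sqrt(as.vector(ov^2 %*% spectrum$sigma[i, qi[j], ]^2)) / step
  }
  R <- t(apply(spectrum$resolution[keep, , drop = FALSE], 1,
               function(r) as.vector(ov %*% r) / step))
  R <- R / (rowSums(R) * step)   # re-normalize after truncation
  qens_dataset(spectrum$q[keep], new_centers, val, sig, R, NULL,
               spectrum$conditions)
}

.overlap_matrix <- function(old_centers, old_h, new_centers, new_h) {
  ol <- old_centers - old_h / 2; oh <- old_centers + old_h / 2
  nl <- new_centers - new_h / 2; nh <- new_centers + new_h / 2
  ov <- outer(nh, oh, pmin) - outer(nl, ol, pmax)
  ov[ov < 0] <- 0
  ov
}

#' Full elastic reduction chain
#'
#' Background subtraction followed by vanadium normalization.
#'
#' @param sample,empty_cell,buffer,vanadium \code{raw_measurement} objects.
#' @param displaced_fraction See \code{\link{subtract_backgrounds}}.
#' @return An \code{elastic_scan_set} ready for fitting.
#' @export
reduce_elastic <- function(sample, empty_cell, buffer, vanadium,
                           displaced_fraction = 0.0876) {
  corrected <- subtract_backgrounds(sample, empty_cell, buffer,
                                    displaced_fraction)
  normalize_vanadium(corrected, vanadium)
}

#' Full QENS reduction chain
#'
#' Background subtraction, vanadium normalization (detector efficiency),
#' detailed-balance correction, and installation of the vanadium-derived
#' resolution profile.
#'
#' @inheritParams reduce_elastic
#' @return A \code{qens_dataset} ready for fitting, with its resolution set
#'   to the area-normalized vanadium profile.
#' @export
reduce_qens <- function(sample, empty_cell, buffer, vanadium,
                        displaced_fraction = 0.0876) {
  corrected <- subtract_backgrounds(sample, empty_cell, buffer,
                                    displaced_fraction)
  out <- normalize_vanadium(corrected, vanadium)
  out <- detailed_balance_correct(out)
  dw <- diff(out$omega)[1]
  vq <- vanadium$data$s_qw[1, , ]
  R <- vq / (rowSums(vq) * dw)
  keep <- match(out$q, vanadium$data$q)
  qens_dataset(out$q, out$omega, out$s_qw, out$sigma,
               R[keep, , drop = FALSE], NULL, out$conditions)
}
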