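#' Build a table of measurement conditions
#'
#' @param temperature Numeric vector of sample temperatures in K (> 0).
#' @param pressure Numeric vector of hydrostatic pressures in bar (>= 1).
#' @param sample_id Character vector of free-text sample identifiers.
#' @return A data.frame with columns \code{temperature}, \code{pressure},
#'   \code{sample_id}, one row per condition.
#' @export
conditions <- function(temperature, pressure, sample_id = "sample") {
  n <- max(length(temperature), length(pressure))
  temperature <- rep_len(as.numeric(temperature), n)
  pressure <- rep_len(as.numeric(pressure), n)
  sample_id <- rep_len(as.character(sample_id), n)
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("condition temperatures must be finite and > 0", call. = FALSE)
  if (any(!is.finite(pressure)) || any(pressure < 1))
    stop("condition pressures must be finite and >= 1 bar", call. = FALSE)
  data.frame(temperature = temperature, pressure = pressure,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

.check_conditions <- function(cond) {
  if (!is.data.frame(cond) ||
      !all(c("temperature", "pressure", "sample_id") %in% names(cond)))
    stop("conditions must be a data.frame with columns temperature, pressure, sample_id",
         call. = FALSE)
  if (nrow(cond) == 0) stop("condition list is empty", call. = FALSE)
  invisible(conditions(cond$temperature, cond$pressure, cond$sample_id))
}

#' Elastic scan container
#'
#' Holds elastic intensities I(q) for a set of (temperature, pressure)
#' conditions, with 1-sigma counting errors and a per-q mask.
#'
#' @param q Strictly increasing vector of momentum transfers, 1/Angstrom.
#' @param intensity Matrix [condition x q] of elastic intensities
#'   (arbitrary normalized units, >= 0 where unmasked).
#' @param sigma Matrix of the same shape with 1-sigma errors (> 0).
#' @param conditions Condition table, see \code{\link{conditions}}.
#' @param mask Logical vector per q; TRUE keeps the channel. Default all TRUE.
#' @return An object of class \code{elastic_scan_set}.
#' @export
elastic_scan_set <- function(q, intensity, sigma, conditions,
                             mask = rep(TRUE, length(q))) {
  q <- as.numeric(q)
  intensity <- as.matrix(intensity)
  sigma <- as.matrix(sigma)
  cond <- .check_conditions(conditions)
  if (length(q) < 1 || any(diff(q) <= 0))
    stop("q must be strictly increasing", call. = FALSE)
  if (!identical(dim(intensity), dim(sigma)))
    stop("intensity and sigma must have the same shape", call. = FALSE)
  if (nrow(intensity) != nrow(cond) || ncol(intensity) != length(q))
    stop("intensity must be [n_conditions x n_q]", call. = FALSE)
  if (length(mask) != length(q) || !is.logical(mask))
    stop("mask must be a logical vector per q", call. = FALSE)
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("sigma must be strictly positive and finite", call. = FALSE)
  if (any(intensity[, mask, drop = FALSE] < 0))
    stop("intensity must be >= 0 on unmasked channels", call. = FALSE)
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 conditions = cond, mask = mask),
            class = "elastic_scan_set")
}

#' @export
print.elastic_scan_set <- function(x, ...) {
  cat("Elastic scan set:", nrow(x$conditions), "conditions x",
      length(x$q), "q points\n")
  cat("  q: ", format(min(x$q)), "-", format(max(x$q)), "1/Ang;",
      sum(!x$mask), "masked channels\n")
  cat("  T: ", format(min(x$conditions$temperature)), "-",
      format(max(x$conditions$temperature)), "K;  P:",
      paste(unique(x$conditions$pressure), collapse = ", "), "bar\n")
  invisible(x)
}

#' Quasi-elastic dataset container
#'
#' S(q, omega) maps with errors and a matched, area-normalized resolution
#' measurement. Positive omega means energy transferred to the sample.
#'
#' @param q Momentum-transfer vector, 1/Angstrom.
#' @param omega Evenly spaced energy-transfer vector, meV.
#' @param s_qw 3-D array [condition x q x omega] of intensities (>= 0).
#' @param sigma Errors, same shape as \code{s_qw}.
#' @param resolution Matrix [q x omega]; each row must integrate to 1 on the
#'   omega grid (within 1e-6).
#' @param resolution_sigma Optional matrix of resolution errors.
#' @param conditions Condition table.
#' @return An object of class \code{qens_dataset}.
#' @export
qens_dataset <- function(q, omega, s_qw, sigma, resolution,
                         resolution_sigma = NULL, conditions) {
  q <- as.numeric(q); omega <- as.numeric(omega)
  cond <- .check_conditions(conditions)
  if (length(omega) < 3) stop("omega grid too short", call. = FALSE)
  dw <- diff(omega)
  if (max(abs(dw - dw[1])) > 1e-6 * abs(dw[1]))
    stop("omega grid is not evenly spaced (relative deviation > 1e-6)",
         call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  s_qw <- .as_qens_array(s_qw, nrow(cond), length(q), length(omega), "s_qw")
  sigma <- .as_qens_array(sigma, nrow(cond), length(q), length(omega), "sigma")
  resolution <- as.matrix(resolution)
  if (!identical(dim(resolution), c(length(q), length(omega))))
    stop("resolution must be [n_q x n_omega]", call. = FALSE)
  area <- rowSums(resolution) * dw[1]
  if (any(abs(area - 1) > 1e-6))
    stop("each resolution profile must integrate to 1 on its grid (within 1e-6); ",
         "supply a vanadium-derived, area-normalized profile", call. = FALSE)
  if (any(s_qw < 0)) stop("s_qw must be >= 0", call. = FALSE)
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("sigma must be strictly positive and finite", call. = FALSE)
  structure(list(q = q, omega = omega, s_qw = s_qw, sigma = sigma,
                 resolution = resolution, resolution_sigma = resolution_sigma,
                 conditions = cond),
            class = "qens_dataset")
}

.as_qens_array <- function(x, nc, nq, nw, name) {
  if (is.matrix(x) && nc == 1) x <- array(x, dim = c(1, nq, nw))
  x <- as.array(x)
  if (!identical(dim(x), c(nc, nq, nw)))
    stop(name, " must be [n_conditions x n_q x n_omega]", call. = FALSE)
  x
}

#' @export
print.qens_dataset <- function(x, ...) {
  cat("QENS dataset:", nrow(x$conditions), "conditions x", length(x$q),
      "q x", length(x$omega), "omega points\n")
  cat("  omega: ", format(min(x$omega)), "-", format(max(x$omega)),
      "meV (step", format(diff(x$omega)[1]), ")\n")
  cat("  q: ", format(min(x$q)), "-", format(max(x$q)), "1/Ang\n")
  invisible(x)
}

#' Select a single condition from a QENS dataset
#'
#' @param data A \code{qens_dataset}.
#' @param i Condition row index.
#' @return A \code{qens_dataset} restricted to that condition.
#' @export
subset_condition <- function(data, i) {
  stopifnot(inherits(data, "qens_dataset"))
  if (length(i) != 1 || i < 1 || i > nrow(data$conditions))
    stop("condition index out of range", call. = FALSE)
  qens_dataset(data$q, data$omega,
               data$s_qw[i, , , drop = FALSE],
               data$sigma[i, , , drop = FALSE],
               data$resolution, data$resolution_sigma,
               data$conditions[i, , drop = FALSE])
}

#' Raw measurement wrapper for the reduction chain
#'
#' @param kind One of "sample", "empty_cell", "buffer", "vanadium".
#' @param data An \code{elastic_scan_set} or \code{qens_dataset} payload.
#' @param transmission Neutron transmission of the measurement, in (0, 1].
#' @param scan_direction Optional, "up" or "down" for continuous elastic ramps.
#' @return An object of class \code{raw_measurement}.
#' @export
raw_measurement <- function(kind = c("sample", "empty_cell", "buffer", "vanadium"),
                            data, transmission = 1, scan_direction = NULL) {
  kind <- match.arg(kind)
  if (!inherits(data, "elastic_scan_set") && !inherits(data, "qens_dataset"))
    stop("data must be an elastic_scan_set or qens_dataset", call. = FALSE)
  if (!is.numeric(transmission) || length(transmission) != 1 ||
      transmission <= 0 || transmission > 1)
    stop("transmission must be a single value in (0, 1]", call. = FALSE)
  if (!is.null(scan_direction) &&
      !scan_direction %in% c("up", "down"))
    stop("scan_direction must be 'up' or 'down'", call. = FALSE)
  structure(list(kind = kind, data = data, transmission = transmission,
                 scan_direction = scan_direction),
            class = "raw_measurement")
}
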