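# Tabular interchange dialect: UTF-8 TSV, '#'-prefixed metadata header lines,
# one row per (T, P, q[, omega]). Numbers are written with 17 significant
# digits so that write -> read -> write is byte-identical and round-trips are
# exact to double precision.

.fmt_num <- function(x) sprintf("%.17g", x)

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Write an elastic scan set to a TSV table
#'
#' @param data An \code{elastic_scan_set}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_elastic_table <- function(data, path) {
  stopifnot(inherits(data, "elastic_scan_set"))
  cond <- data$conditions
  nq <- length(data$q)
  rows <- data.frame(
    T = rep(cond$temperature, each = nq),
    P = rep(cond$pressure, each = nq),
    sample_id = rep(cond$sample_id, each = nq),
    q = rep(data$q, times = nrow(cond)),
    intensity = as.vector(t(data$intensity)),
    sigma = as.vector(t(data$sigma)),
    mask = rep(as.integer(data$mask), times = nrow(cond)),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# piezodyn elastic v1",
               "# units: q=1/Angstrom T=K P=bar intensity=arb sigma=arb",
               paste(names(rows), collapse = "\t")), con, sep = "\n")
  lines <- paste(.fmt_num(rows$T), .fmt_num(rows$P), rows$sample_id,
                 .fmt_num(rows$q), .fmt_num(rows$intensity),
                 .fmt_num(rows$sigma), rows$mask, sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an elastic scan set from a TSV table
#'
#' Rows are grouped by (temperature, pressure, sample) and q is sorted
#' ascending. Inputs violating the container invariants are rejected.
#'
#' @param path Path to a file written by \code{\link{write_elastic_table}}
#'   or following the same dialect.
#' @return An \code{elastic_scan_set}.
#' @export
read_elastic_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  .require_columns(df, c("q", "intensity", "sigma", "T", "P"), path)
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  if (any(!is.finite(df$sigma)) || any(df$sigma <= 0))
    stop("validation error in '", path,
         "': sigma must be strictly positive", call. = FALSE)
  key <- paste(df$T, df$P, df$sample_id, sep = "\r")
  groups <- split(df, factor(key, levels = unique(key)))
  q <- sort(unique(df$q))
  first <- groups[[1]][order(groups[[1]]$q), ]
  if (!isTRUE(all.equal(first$q, q)))
    stop("format error in '", path,
         "': all conditions must share one q grid", call. = FALSE)
  cond <- do.call(rbind, lapply(groups, function(g)
    data.frame(temperature = g$T[1], pressure = g$P[1],
               sample_id = g$sample_id[1], stringsAsFactors = FALSE)))
  rownames(cond) <- NULL
  I <- t(vapply(groups, function(g) g$intensity[order(g$q)], numeric(length(q))))
  S <- t(vapply(groups, function(g) g$sigma[order(g$q)], numeric(length(q))))
  dimnames(I) <- NULL
  dimnames(S) <- NULL
  mask <- if ("mask" %in% names(df)) {
    g <- groups[[1]][order(groups[[1]]$q), ]
    as.logical(g$mask)
  } else rep(TRUE, length(q))
  elastic_scan_set(q, I, S, cond, mask)
}

#' Write a QENS dataset (spectra plus resolution) to a TSV bundle
#'
#' @param data A \code{qens_dataset}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_qens_store <- function(data, path) {
  stopifnot(inherits(data, "qens_dataset"))
  cond <- data$conditions
  nq <- length(data$q); nw <- length(data$omega); nc <- nrow(cond)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# piezodyn qens v1",
               "# units: q=1/Angstrom omega=meV T=K P=bar S=arb",
               "# omega sign: positive = energy transferred to the sample",
               paste("block", "T", "P", "sample_id", "q", "omega",
                     "value", "sigma", sep = "\t")), con, sep = "\n")
  for (i in seq_len(nc)) {
    v <- as.vector(t(data$s_qw[i, , ]))   # q-major, omega fastest
    s <- as.vector(t(data$sigma[i, , ]))
    lines <- paste("spectrum", .fmt_num(cond$temperature[i]),
                   .fmt_num(cond$pressure[i]), cond$sample_id[i],
                   .fmt_num(rep(data$q, each = nw)),
                   .fmt_num(rep(data$omega, times = nq)),
                   .fmt_num(v), .fmt_num(s), sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  rs <- if (is.null(data$resolution_sigma))
    matrix(0, nq, nw) else data$resolution_sigma
  lines <- paste("resolution", "NA", "NA", "vanadium",
                 .fmt_num(rep(data$q, each = nw)),
                 .fmt_num(rep(data$omega, times = nq)),
                 .fmt_num(as.vector(t(data$resolution))),
                 .fmt_num(as.vector(t(rs))), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a QENS dataset from a TSV bundle
#'
#' The resolution block is re-normalized to unit area on its omega grid on
#' load (the one documented repair); all other invariant violations are
#' rejected.
#'
#' @param path Path to a file written by \code{\link{write_qens_store}}.
#' @return A \code{qens_dataset}.
#' @export
read_qens_store <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA")
  .require_columns(df, c("block", "q", "omega", "value", "sigma"), path)
  res <- df[df$block == "resolution", ]
  if (nrow(res) == 0)
    stop("no resolution block in '", path,
         "': supply a vanadium-derived resolution measurement", call. = FALSE)
  sp <- df[df$block == "spectrum", ]
  if (nrow(sp) == 0) stop("no spectrum block in '", path, "'", call. = FALSE)
  omega <- sort(unique(sp$omega))
  dw <- diff(omega)
  if (max(abs(dw - dw[1])) > 1e-6 * abs(dw[1]))
    stop("format error in '", path,
         "': omega grid not evenly spaced beyond 1e-6 relative", call. = FALSE)
  q <- sort(unique(sp$q))
  key <- paste(sp$T, sp$P, sp$sample_id, sep = "\r")
  groups <- split(sp, factor(key, levels = unique(key)))
  nc <- length(groups); nq <- length(q); nw <- length(omega)
  s_qw <- array(NA_real_, c(nc, nq, nw))
  sig <- array(NA_real_, c(nc, nq, nw))
  cond <- data.frame(temperature = numeric(nc), pressure = numeric(nc),
                     sample_id = character(nc), stringsAsFactors = FALSE)
  for (i in seq_len(nc)) {
    g <- groups[[i]]
    if (nrow(g) != nq * nw)
      stop("parse error in '", path, "': incomplete spectrum block",
           call. = FALSE)
    o <- order(g$q, g$omega)
    s_qw[i, , ] <- matrix(g$value[o], nq, nw, byrow = TRUE)
    sig[i, , ] <- matrix(g$sigma[o], nq, nw, byrow = TRUE)
    cond$temperature[i] <- g$T[1]; cond$pressure[i] <- g$P[1]
    cond$sample_id[i] <- g$sample_id[1]
  }
  if (nrow(res) != nq * nw)
    stop("parse error in '", path, "': incomplete resolution block",
         call. = FALSE)
  o <- order(res$q, res$omega)
  R <- matrix(res$value[o], nq, nw, byrow = TRUE)
  Rs <- matrix(res$sigma[o], nq, nw, byrow = TRUE)
  area <- rowSums(R) * dw[1]
  if (any(area <= 0))
    stop("resolution profile with non-positive area in '", path, "'",
         call. = FALSE)
  R <- R / area          # documented re-normalization on load
  Rs <- Rs / area
  if (all(Rs == 0)) Rs <- NULL
  qens_dataset(q, omega, s_qw, sig, R, Rs, cond)
}
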