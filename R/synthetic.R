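# Forward generator: raw-like and reduced elastic/QENS datasets with known
# ground truth, instrument effects (efficiency, backgrounds, transmission,
# detailed-balance asymmetry, resolution) and counting noise, so every
# pipeline stage is testable end-to-end without measured data.

#' Assemble a ground-truth record for the synthetic generators
#'
#' @param two_state List of per-pressure lists with elements \code{pressure},
#'   \code{d} (Angstrom), \code{dH} (kJ/mol), \code{dS} (J/(mol K)),
#'   \code{dx0_ref} and \code{dx0_slope} (single-well MSD at 283 K and its
#'   linear temperature slope, Angstrom^2 and Angstrom^2/K).
#' @param qens List with \code{law} ("arrhenius" or "vft"), \code{tau0} (ps),
#'   \code{ea_tau} (kJ/mol, Arrhenius), \code{vft} (list tau0, D, T0),
#'   \code{jump_len0}, \code{jump_len_tslope}, \code{jump_len_pslope},
#'   \code{gamma0} (meV), \code{ea_gamma} (kJ/mol), \code{dw_msd},
#'   \code{scale_amp}.
#' @param eisf List with \code{p}, \code{s}, \code{r0} (Angstrom),
#'   \code{r_pslope} (Angstrom/bar), \code{a_methyl}.
#' @param thermal_law "arrhenius" or "vft" (mirrors \code{qens$law}).
#' @param backgrounds List with transmissions \code{t_sample},
#'   \code{t_cell}, \code{t_buffer}, \code{t_vanadium}, levels
#'   \code{cell_level}, \code{buffer_level}, \code{vanadium_level} and
#'   \code{displaced_fraction}.
#' @param resolution_spec List with \code{shape} ("gaussian" or
#'   "lorentzian") and \code{hwhm} (meV).
#' @param noise_spec List with \code{model} ("poisson", "gaussian", "none")
#'   and \code{counts}.
#' @return A list of class \code{ground_truth}.
#' @export
ground_truth <- function(two_state, qens, eisf,
                         thermal_law = qens$law,
                         backgrounds = list(t_sample = 0.9, t_cell = 0.95,
                                            t_buffer = 0.92, t_vanadium = 1,
                                            cell_level = 0.15,
                                            buffer_level = 0.35,
                                            vanadium_level = 1,
                                            displaced_fraction = 0.0876),
                         resolution_spec = list(shape = "gaussian",
                                                hwhm = 0.07),
                         noise_spec = list(model = "poisson",
                                           counts = 1e4)) {
  structure(list(two_state = two_state, qens = qens, eisf = eisf,
                 thermal_law = thermal_law, backgrounds = backgrounds,
                 resolution_spec = resolution_spec, noise_spec = noise_spec),
            class = "ground_truth")
}

#' True QENS parameters at a condition
#'
#' Evaluates the ground truth's thermal laws at (T, P): tau from the
#' Arrhenius or VFT law, Gamma_loc from its Arrhenius law, the jump length
#' and confinement radius from their linear trends.
#'
#' @param truth A \code{ground_truth}.
#' @param temperature K.
#' @param pressure bar.
#' @return List with tau, jump_len, gamma_loc, scale_amp, dw_msd, and the
#'   EISF parameters p, s, radius, a_methyl.
#' @export
true_qens_params <- function(truth, temperature, pressure) {
  qp <- truth$qens
  tau <- if (qp$law == "arrhenius") {
    qp$tau0 * exp(qp$ea_tau / (.const$Rgas * temperature))
  } else {
    qp$vft$tau0 * exp(qp$vft$D * qp$vft$T0 / (temperature - qp$vft$T0))
  }
  gamma_loc <- qp$gamma0 * exp(-qp$ea_gamma / (.const$Rgas * temperature))
  jl <- qp$jump_len0 + qp$jump_len_tslope * (temperature - 283) +
    qp$jump_len_pslope * (pressure - 1)
  ep <- truth$eisf
  list(tau = tau, jump_len = jl, gamma_loc = gamma_loc,
       scale_amp = qp$scale_amp, dw_msd = qp$dw_msd,
       p = ep$p, s = ep$s,
       radius = ep$r0 + ep$r_pslope * (pressure - 1),
       a_methyl = ep$a_methyl)
}

# smooth positive detector-efficiency profile
.efficiency <- function(q) 0.85 + 0.3 * exp(-(q - 0.6 * max(q))^2 / 2)

.add_counting_noise <- function(values, counts_scale, model) {
  if (model == "none")
    return(list(values = values,
                sigma = array(1e-6, dim = dim(values) %||% length(values))))
  if (model == "poisson") {
    cnt <- array(stats::rpois(length(values), values * counts_scale),
                 dim = dim(values) %||% length(values))
    list(values = cnt / counts_scale,
         sigma = sqrt(pmax(cnt, 1)) / counts_scale)
  } else {                      # gaussian high-count limit
    sd <- sqrt(pmax(values, 1e-12) / counts_scale)
    v <- values + array(stats::rnorm(length(values), 0, 1),
                        dim = dim(values) %||% length(values)) * sd
    list(values = pmax(v, 0), sigma = pmax(sd, 1e-12))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic elastic scan campaign with known ground truth
#'
#' The reference is the noiseless two-state elastic model on the requested
#' grids. The raw set multiplies the signal by a detector-efficiency
#' profile, adds empty-cell and buffer backgrounds with their transmissions,
#' and applies counting noise; reducing the raw set with
#' \code{\link{reduce_elastic}} recovers the reference (exactly when
#' noiseless).
#'
#' @param truth A \code{ground_truth}.
#' @param q q grid, default an IN13-like 0.2-4.5 1/Angstrom range.
#' @param temperatures Temperature grid, default 283-363 K in 10 K steps.
#' @param pressures Pressure list, default c(1, 150, 300, 600) bar.
#' @param seed Integer seed; recorded in the output.
#' @param noise "poisson", "gaussian" or "none" (overrides the truth's
#'   noise_spec model when given).
#' @param counts Mean counts at unit intensity for the noise model.
#' @return List with \code{raw} (sample, empty_cell, buffer, vanadium as
#'   \code{raw_measurement}s), \code{reference} (noiseless
#'   \code{elastic_scan_set}), \code{truth}, \code{seed}.
#' @export
generate_elastic_dataset <- function(truth,
                                     q = seq(0.2, 4.5, length.out = 25),
                                     temperatures = seq(283, 363, by = 10),
                                     pressures = c(1, 150, 300, 600),
                                     seed = 1,
                                     noise = truth$noise_spec$model,
                                     counts = truth$noise_spec$counts) {
  set.seed(seed)
  bk <- truth$backgrounds
  eff <- .efficiency(q)
  cell <- bk$cell_level * (1 + 0.05 * q)
  buffer <- bk$buffer_level * (1 - 0.04 * q)
  v0 <- bk$vanadium_level
  f <- bk$displaced_fraction
  cond <- expand.grid(temperature = temperatures, pressure = pressures)
  ts_by_p <- stats::setNames(truth$two_state,
                             vapply(truth$two_state,
                                    function(x) as.character(x$pressure),
                                    character(1)))
  nC <- nrow(cond); nQ <- length(q)
  ref <- matrix(0, nC, nQ)
  for (i in seq_len(nC)) {
    tsp <- ts_by_p[[as.character(cond$pressure[i])]]
    if (is.null(tsp)) stop("no two-state truth for pressure ",
                           cond$pressure[i], call. = FALSE)
    dx0 <- tsp$dx0_ref + tsp$dx0_slope * (cond$temperature[i] - 283)
    ref[i, ] <- two_state_elastic(q, dx0, tsp$d, tsp$dH, tsp$dS,
                                  cond$temperature[i])
  }
  condf <- conditions(cond$temperature, cond$pressure, "synthetic")
  reference <- elastic_scan_set(q, ref, matrix(1e-6, nC, nQ), condf)

  effm <- matrix(eff, nC, nQ, byrow = TRUE)
  cellm <- matrix(cell, nC, nQ, byrow = TRUE)
  bufm <- matrix(buffer, nC, nQ, byrow = TRUE)
  i_s <- bk$t_sample * effm * (ref * v0 + cellm + (1 - f) * bufm)
  i_ec <- bk$t_cell * matrix(eff * cell, 1)
  i_b <- bk$t_buffer * matrix(eff * (cell + buffer), 1)
  i_v <- bk$t_vanadium * matrix(eff * v0, 1)

  mk <- function(vals, kind, transmission, cnd) {
    nz <- .add_counting_noise(vals, counts, noise)
    raw_measurement(kind,
                    elastic_scan_set(q, nz$values, nz$sigma, cnd),
                    transmission)
  }
  aux_cond <- conditions(min(temperatures), min(pressures), "aux")
  raw <- list(
    sample = mk(i_s, "sample", bk$t_sample, condf),
    empty_cell = mk(i_ec, "empty_cell", bk$t_cell, aux_cond),
    buffer = mk(i_b, "buffer", bk$t_buffer, aux_cond),
    vanadium = mk(i_v, "vanadium", bk$t_vanadium, aux_cond))
  list(raw = raw, reference = reference, truth = truth, seed = seed)
}

#' Resolution profile on an energy grid
#'
#' @param omega Energy grid, meV.
#' @param spec List with \code{shape} ("gaussian" or "lorentzian") and
#'   \code{hwhm} in meV.
#' @return Area-normalized profile vector.
#' @export
resolution_profile <- function(omega, spec = list(shape = "gaussian",
                                                  hwhm = 0.07)) {
  r <- switch(spec$shape,
              gaussian = stats::dnorm(omega, 0,
                                      spec$hwhm / sqrt(2 * log(2))),
              lorentzian = lorentzian(omega, spec$hwhm),
              stop("unknown resolution shape: ", spec$shape, call. = FALSE))
  r / (sum(r) * diff(omega)[1])
}

#' Generate a synthetic QENS campaign with known ground truth
#'
#' The reference is the noiseless Hall-Ross + localized-Lorentzian model
#' with the EISF-geometry A0(q), convolved with the resolution. The raw set
#' multiplies signal and backgrounds by the detailed-balance asymmetry
#' exp(+hbar omega / (2 kB T)) and a detector-efficiency profile, adds
#' counting noise, and includes a vanadium measurement (pure resolution);
#' \code{\link{reduce_qens}} recovers the reference (exactly when
#' noiseless).
#'
#' @param truth A \code{ground_truth}.
#' @param q q grid, default an IN5-like 0.6-1.8 1/Angstrom range.
#' @param omega Energy grid, default -1.5 to 1.5 meV in 0.02 meV steps.
#' @param temperatures,pressures Conditions (paired per row of their
#'   expansion).
#' @param seed Integer seed.
#' @param noise,counts Noise model and total counts per q channel
#'   ("poisson": Poisson counts scaled so each q row totals \code{counts}).
#' @return List with \code{raw} measurements, \code{reference}
#'   \code{qens_dataset}, per-condition \code{params} (true tau, jump_len,
#'   gamma_loc, A0), \code{truth}, \code{seed}.
#' @export
generate_qens_dataset <- function(truth,
                                  q = seq(0.6, 1.8, by = 0.2),
                                  omega = seq(-1.5, 1.5, by = 0.02),
                                  temperatures = 300, pressures = 1,
                                  seed = 1,
                                  noise = truth$noise_spec$model,
                                  counts = truth$noise_spec$counts) {
  set.seed(seed)
  bk <- truth$backgrounds
  nQ <- length(q); nW <- length(omega)
  dw <- diff(omega)[1]
  cond <- expand.grid(temperature = temperatures, pressure = pressures)
  nC <- nrow(cond)
  R1 <- resolution_profile(omega, truth$resolution_spec)
  R <- matrix(R1, nQ, nW, byrow = TRUE)
  eff <- .efficiency(q)
  v0 <- bk$vanadium_level
  f <- bk$displaced_fraction
  cellq <- bk$cell_level * (1 + 0.05 * q)
  ref <- array(0, c(nC, nQ, nW))
  params <- vector("list", nC)
  for (i in seq_len(nC)) {
    pp <- true_qens_params(truth, cond$temperature[i], cond$pressure[i])
    a0 <- eisf_model(q, pp$p, pp$s, pp$radius, pp$a_methyl)
    ref[i, , ] <- qens_model_convolved(q, omega, a0, pp$tau, pp$jump_len,
                                       pp$gamma_loc, pp$scale_amp,
                                       pp$dw_msd, R)
    params[[i]] <- c(pp, list(a0 = a0))
  }
  condf <- conditions(cond$temperature, cond$pressure, "synthetic")
  reference <- qens_dataset(q, omega, ref, array(1e-6, c(nC, nQ, nW)),
                            R, NULL, condf)

  # backgrounds: smooth cell (low-order polynomial in omega and q) and a
  # broad buffer Lorentzian; everything but vanadium carries the quantum
  # detailed-balance asymmetry
  cell <- outer(cellq, 0.2 * (1 + 0.1 * omega^2))
  buf <- outer(bk$buffer_level * (1 - 0.04 * q), lorentzian(omega, 1.0))
  i_s <- array(0, c(nC, nQ, nW))
  for (i in seq_len(nC)) {
    asym <- matrix(exp(.const$hbar * omega /
                         (2 * .const$kB * cond$temperature[i])),
                   nQ, nW, byrow = TRUE)
    i_s[i, , ] <- bk$t_sample * eff *
      ((ref[i, , ] * v0 + cell + (1 - f) * buf) * asym)
  }
  # backgrounds measured at every sample condition (their asymmetry factor
  # is temperature dependent, so a single shared measurement would only be
  # consistent at one temperature)
  i_ec <- array(0, c(nC, nQ, nW)); i_b <- array(0, c(nC, nQ, nW))
  for (i in seq_len(nC)) {
    asym <- matrix(exp(.const$hbar * omega /
                         (2 * .const$kB * cond$temperature[i])),
                   nQ, nW, byrow = TRUE)
    i_ec[i, , ] <- bk$t_cell * eff * (cell * asym)
    i_b[i, , ] <- bk$t_buffer * eff * ((cell + buf) * asym)
  }
  i_v <- array(bk$t_vanadium * eff * (v0 * R), c(1, nQ, nW))

  # Poisson: scale each q channel so its omega-total is `counts`
  noisify <- function(vals) {
    if (noise == "none")
      return(list(values = vals, sigma = array(1e-6, dim(vals))))
    out_v <- vals; out_s <- vals
    for (i in seq_len(dim(vals)[1])) for (j in seq_len(dim(vals)[2])) {
      row <- vals[i, j, ]
      cs <- counts / max(sum(row), 1e-12)
      nz <- .add_counting_noise(row, cs, noise)
      out_v[i, j, ] <- nz$values
      out_s[i, j, ] <- nz$sigma
    }
    list(values = out_v, sigma = out_s)
  }
  aux_cond <- conditions(cond$temperature[1], cond$pressure[1], "aux")
  raw <- list(
    sample = {
      nz <- noisify(i_s)
      raw_measurement("sample",
                      qens_dataset(q, omega, nz$values, nz$sigma, R, NULL,
                                   condf), bk$t_sample)
    },
    empty_cell = {
      nz <- noisify(i_ec)
      raw_measurement("empty_cell",
                      qens_dataset(q, omega, nz$values, nz$sigma, R, NULL,
                                   condf), bk$t_cell)
    },
    buffer = {
      nz <- noisify(i_b)
      raw_measurement("buffer",
                      qens_dataset(q, omega, nz$values, nz$sigma, R, NULL,
                                   condf), bk$t_buffer)
    },
    vanadium = {
      nz <- noisify(i_v)
      raw_measurement("vanadium",
                      qens_dataset(q, omega, nz$values, nz$sigma, R, NULL,
                                   aux_cond), bk$t_vanadium)
    })
  list(raw = raw, reference = reference, params = params, truth = truth,
       seed = seed)
}

#' Documented ground-truth presets
#'
#' Two qualitative parameter sets mirroring the contrast between a
#' pressure-adapted (piezophile-like: Arrhenius residence times,
#' pressure-flat well distance and confinement radius) and a
#' pressure-sensitive protein (VFT residence times, pressure-decreasing well
#' distance, pressure-increasing confinement radius). Magnitudes are
#' fabricated defaults for testing, flagged as such in the returned
#' metadata; only the trend directions are meaningful.
#'
#' @param name "piezophile_like" or "piezosensitive_like".
#' @return A \code{ground_truth} with attribute
#'   \code{fabricated_defaults = TRUE}.
#' @export
preset_profiles <- function(name = c("piezophile_like",
                                     "piezosensitive_like")) {
  if (!is.character(name) || !name[1] %in% c("piezophile_like",
                                             "piezosensitive_like"))
    stop("unknown preset '", name[1],
         "'; available: piezophile_like, piezosensitive_like",
         call. = FALSE)
  name <- name[1]
  pressures <- c(1, 150, 300, 600)
  if (name == "piezophile_like") {
    two_state <- lapply(seq_along(pressures), function(k) list(
      pressure = pressures[k], d = 1.4,
      dH = c(14, 11, 11, 11)[k], dS = c(30, 22, 22, 22)[k],
      dx0_ref = 0.04, dx0_slope = 0.0015))
    qens <- list(law = "arrhenius", tau0 = 0.036, ea_tau = 10,
                 vft = NULL, jump_len0 = 1.2, jump_len_tslope = 0.001,
                 jump_len_pslope = 0, gamma0 = 7.4, ea_gamma = 8,
                 dw_msd = 0.5, scale_amp = 1)
    eisf <- list(p = 0.15, s = 0.55, r0 = 3, r_pslope = 0,
                 a_methyl = 1.715)
  } else {
    two_state <- lapply(seq_along(pressures), function(k) list(
      pressure = pressures[k], d = 1.6 - 6e-4 * pressures[k],
      dH = 10 + 0.004 * pressures[k], dS = 20 + 0.01 * pressures[k],
      dx0_ref = 0.045, dx0_slope = 0.0018))
    qens <- list(law = "vft", tau0 = NA, ea_tau = NA,
                 vft = list(tau0 = 0.1, D = 5, T0 = 150),
                 jump_len0 = 1.3, jump_len_tslope = 0.001,
                 jump_len_pslope = 5e-4, gamma0 = 7.4, ea_gamma = 9,
                 dw_msd = 0.5, scale_amp = 1)
    eisf <- list(p = 0.15, s = 0.55, r0 = 3, r_pslope = 0.0015,
                 a_methyl = 1.715)
  }
  gt <- ground_truth(two_state, qens, eisf)
  attr(gt, "fabricated_defaults") <- TRUE
  attr(gt, "preset") <- name
  gt
}
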