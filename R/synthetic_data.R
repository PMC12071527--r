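# Synthetic multi-sensor spoilage data: a seeded generator producing aligned
# FTIR / MSI / MSIF feature tables with a known generative structure, so the
# fusion pipeline can be exercised and validated without instrument data.

#' Bacterial growth-curve parameters
#'
#' Parameters of a three-phase (lag / logistic rise / plateau) growth model
#' for total viable counts (TVC) in log10 CFU/g. The curve is flat at
#' `initial_load` until `lag` hours, then rises along a shifted logistic
#' towards `max_load`. The specific growth rate at temperature T (degrees C)
#' is `rate_at_ref * exp(temp_sensitivity * T) * condition_rate_factor`,
#' with 0 degrees C as the reference temperature.
#'
#' @param initial_load initial TVC, log CFU/g
#' @param max_load stationary-phase TVC, log CFU/g; must exceed `initial_load`
#' @param rate_at_ref growth-rate constant at the 0 degrees C reference, 1/h
#' @param temp_sensitivity exponential rate multiplier per degree C
#' @param lag lag-phase duration, h
#' @param condition_rate_factor packaging-dependent growth slowdown in (0, 1]
#'   (e.g. vacuum packaging < 1, aerobic = 1)
#' @return an object of class `growth_params`
#' @export
#' @examples
#' gp <- growth_params()
#' growth_curve(gp, temperature = 5, times = c(0, 48, 96, 192))
growth_params <- function(initial_load = 5.2, max_load = 9,
                          rate_at_ref = 0.02, temp_sensitivity = 0.1,
                          lag = 12, condition_rate_factor = 1) {
  for (nm in c("initial_load", "max_load", "rate_at_ref", "temp_sensitivity",
               "lag", "condition_rate_factor")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (initial_load >= max_load) {
    stop("`initial_load` must be smaller than `max_load`", call. = FALSE)
  }
  if (rate_at_ref <= 0) stop("`rate_at_ref` must be positive", call. = FALSE)
  if (lag < 0) stop("`lag` must be non-negative", call. = FALSE)
  if (condition_rate_factor <= 0 || condition_rate_factor > 1) {
    stop("`condition_rate_factor` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(initial_load = initial_load, max_load = max_load,
         rate_at_ref = rate_at_ref, temp_sensitivity = temp_sensitivity,
         lag = lag, condition_rate_factor = condition_rate_factor),
    class = "growth_params"
  )
}

#' Expected (noise-free) growth curve
#'
#' Evaluates the deterministic three-phase logistic in log-count space:
#' y(t) = y0 for t <= lag, and
#' y(t) = y0 + (ymax - y0) * tanh(r_eff * (t - lag) / 2) afterwards,
#' where tanh(u/2) is the symmetric logistic 2/(1 + exp(-u)) - 1. The curve
#' equals `initial_load` exactly at the end of lag and approaches `max_load`
#' as a plateau.
#'
#' @param params a [growth_params()] object
#' @param temperature storage temperature, degrees C
#' @param times sampling times, h (non-negative, strictly increasing)
#' @return numeric vector of expected TVC, log CFU/g
#' @export
growth_curve <- function(params, temperature, times) {
  stopifnot(inherits(params, "growth_params"))
  if (length(times) == 0L) stop("`times` must be nonempty", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  r_eff <- params$rate_at_ref * exp(params$temp_sensitivity * temperature) *
    params$condition_rate_factor
  dt <- pmax(0, times - params$lag)
  params$initial_load +
    (params$max_load - params$initial_load) * tanh(r_eff * dt / 2)
}

#' Simulate a TVC trajectory with replicate noise
#'
#' Adds seeded i.i.d. Gaussian replicate noise to the expected growth curve
#' and clips the result to `[0, max_load + 1]`.
#'
#' @inheritParams growth_curve
#' @param seed integer seed for the replicate noise
#' @param noise_sd replicate noise standard deviation, log CFU/g
#' @return numeric vector of simulated TVC values, one per time point
#' @export
simulate_growth <- function(params, temperature, times, seed, noise_sd = 0.25) {
  mu <- growth_curve(params, temperature, times)
  eps <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(times), sd = noise_sd))
  } else {
    rep(0, length(times))
  }
  pmin(pmax(mu + eps, 0), params$max_load + 1)
}

# Band set of a typical industrial MSI platform: 18 wavelengths in 405-970 nm.
default_msi_bands <- function() {
  c(405, 435, 450, 470, 505, 525, 570, 590, 630, 645, 660, 700,
    780, 850, 870, 890, 940, 970)
}

# Default fluorescent MSI band set: 8 wavelengths in the 270-405 nm UV/blue range.
default_msif_bands <- function() {
  c(270, 285, 300, 315, 330, 345, 365, 405)
}

#' FTIR wavenumber grid
#'
#' A uniform wavenumber grid anchored so that the closed fingerprint interval
#' \[900, 2000\] cm-1 contains exactly 1141 grid points (step 1100/1140 cm-1),
#' extended over `range` and returned in descending instrument order.
#' `downsample = k` keeps every k-th point; k must divide 1140 so both
#' fingerprint endpoints remain on the grid.
#'
#' @param range length-2 numeric, wavenumber range in cm-1
#' @param downsample positive integer grid-thinning factor (divisor of 1140)
#' @return numeric vector of wavenumbers, strictly decreasing
#' @export
ftir_grid <- function(range = c(400, 4000), downsample = 1L) {
  downsample <- as.integer(downsample)
  if (downsample < 1L || 1140L %% downsample != 0L) {
    stop("`downsample` must be a positive divisor of 1140", call. = FALSE)
  }
  step <- 1100 / 1140 * downsample
  k_min <- ceiling((min(range) - 900) / step)
  k_max <- floor((max(range) - 900) / step)
  # integer numerator keeps the fingerprint endpoints 900 and 2000 exact
  k <- k_min:k_max
  sort((900 * 1140 + k * 1100 * downsample) / 1140, decreasing = TRUE)
}

#' Generative signal/noise parameters for the simulator
#'
#' Per-modality amplitudes of the TVC-linked spectral signal, the
#' modality-unique interference, a cross-modality shared nuisance factor, and
#' instrument artifacts. The modality-unique interference enters in
#' log-CFU-equivalent units along the same spectral direction as the TVC
#' signal: each modality effectively measures `tvc + unique_sd * u` with `u`
#' drawn independently per modality, so single-sensor models face an
#' irreducible error floor that cross-modality fusion can reduce.
#'
#' @param tvc_amplitude named numeric, absorbance/reflectance units per log CFU/g
#' @param unique_sd named numeric, modality-unique interference sd (log CFU/g
#'   equivalent); set to 0 to remove the modality's unique component
#' @param shared_weight named numeric, amplitude of the shared nuisance factor
#' @param gain_sd sd of the per-row multiplicative gain artifact
#' @param offset_sd sd of the per-row additive offset artifact
#' @param noise_sd named numeric, i.i.d. per-feature measurement noise sd
#' @return a named list of class `signal_params`
#' @export
signal_params <- function(tvc_amplitude = c(ftir = 0.012, msi = 0.02, msif = 0.012),
                          unique_sd = c(ftir = 0.40, msi = 0.35, msif = 0.60),
                          shared_weight = c(ftir = 0.004, msi = 0.006, msif = 0.004),
                          gain_sd = 0.08,
                          offset_sd = 0.04,
                          noise_sd = c(ftir = 0.002, msi = 0.003, msif = 0.003)) {
  mods <- c("ftir", "msi", "msif")
  for (nm in c("tvc_amplitude", "unique_sd", "shared_weight", "noise_sd")) {
    v <- get(nm)
    if (!all(mods %in% names(v))) {
      stop(sprintf("`%s` must be named with ftir, msi, msif", nm), call. = FALSE)
    }
  }
  if (any(unique_sd < 0)) stop("`unique_sd` entries must be non-negative", call. = FALSE)
  structure(
    list(tvc_amplitude = tvc_amplitude[mods], unique_sd = unique_sd[mods],
         shared_weight = shared_weight[mods], gain_sd = gain_sd,
         offset_sd = offset_sd, noise_sd = noise_sd[mods]),
    class = "signal_params"
  )
}

#' Simulation configuration
#'
#' Defines one synthetic spoilage study: storage conditions, isothermal
#' temperatures and their sampling schedules, two sourcing batches, replicate
#' counts, growth kinetics, the spectral grids of the three modalities and
#' the generative signal model. Defaults emulate a chicken storage trial:
#' two packaging conditions, 0/5/10 degrees C, sampling every 24 h, initial
#' TVC ~5.2 log CFU/g rising past the 7-8 log CFU/g spoilage range, and a
#' 0.7 log CFU/g batch offset.
#'
#' @param meat_type sample label used in sample IDs
#' @param conditions character vector of packaging condition labels
#' @param condition_rate_factors named numeric in (0, 1], growth slowdown per condition
#' @param temperatures numeric vector of storage temperatures, degrees C
#' @param sampling_times named list (one entry per temperature, names are the
#'   temperatures) of strictly increasing sampling times in h
#' @param batches number of sourcing batches (2 for batch-on-batch designs)
#' @param replicates_range length-2 integer range; the replicate count of each
#'   (condition, temperature, time, batch) sampling point is drawn uniformly
#'   from this range
#' @param batch_tvc_offset additive TVC shift applied to batch 2, log CFU/g
#' @param batch_gain_shift relative spectral gain shift applied to batch 2
#' @param growth a [growth_params()] object
#' @param tvc_noise_sd replicate TVC noise sd, log CFU/g
#' @param ftir_range,ftir_downsample arguments to [ftir_grid()]
#' @param msi_bands MSI band centres, nm (must lie in 405-970)
#' @param msif_bands fluorescent MSI band centres, nm (must lie in 270-405)
#' @param signal a [signal_params()] object
#' @param seed integer seed; the dataset is a pure function of the config
#' @return an object of class `sim_config`
#' @export
sim_config <- function(meat_type = "chicken",
                       conditions = c("aerobic", "vacuum"),
                       condition_rate_factors = c(aerobic = 1, vacuum = 0.55),
                       temperatures = c(0, 5, 10),
                       sampling_times = list(`0` = seq(0, 216, by = 24),
                                             `5` = seq(0, 216, by = 24),
                                             `10` = seq(0, 120, by = 24)),
                       batches = 2L,
                       replicates_range = c(2L, 10L),
                       batch_tvc_offset = 0.7,
                       batch_gain_shift = 0.03,
                       growth = growth_params(),
                       tvc_noise_sd = 0.25,
                       ftir_range = c(400, 4000),
                       ftir_downsample = 1L,
                       msi_bands = default_msi_bands(),
                       msif_bands = default_msif_bands(),
                       signal = signal_params(),
                       seed = 1L) {
  if (length(conditions) < 1L) stop("need at least one condition", call. = FALSE)
  if (!all(conditions %in% names(condition_rate_factors))) {
    stop("`condition_rate_factors` must name every condition", call. = FALSE)
  }
  if (!all(as.character(temperatures) %in% names(sampling_times))) {
    stop("`sampling_times` must have one entry per temperature", call. = FALSE)
  }
  for (tt in as.character(temperatures)) {
    st <- sampling_times[[tt]]
    if (length(st) == 0L || any(diff(st) <= 0)) {
      stop("each `sampling_times` entry must be nonempty and strictly increasing",
           call. = FALSE)
    }
  }
  if (length(msi_bands) == 0L || any(msi_bands < 405) || any(msi_bands > 970)) {
    stop("`msi_bands` must be nonempty and lie within 405-970 nm", call. = FALSE)
  }
  if (length(msif_bands) == 0L || any(msif_bands < 270) || any(msif_bands > 405)) {
    stop("`msif_bands` must be nonempty and lie within 270-405 nm", call. = FALSE)
  }
  if (min(ftir_range) < 400 - 1e-9 || max(ftir_range) > 4000 + 1e-9) {
    stop("`ftir_range` must lie within 400-4000 cm-1", call. = FALSE)
  }
  stopifnot(inherits(growth, "growth_params"), inherits(signal, "signal_params"))
  batches <- as.integer(batches)
  if (batches < 1L) stop("`batches` must be >= 1", call. = FALSE)
  replicates_range <- as.integer(replicates_range)
  if (length(replicates_range) != 2L || replicates_range[1] < 1L ||
      replicates_range[1] > replicates_range[2]) {
    stop("`replicates_range` must be an increasing pair of positive integers",
         call. = FALSE)
  }
  structure(
    list(meat_type = meat_type, conditions = conditions,
         condition_rate_factors = condition_rate_factors,
         temperatures = temperatures, sampling_times = sampling_times,
         batches = batches, replicates_range = replicates_range,
         batch_tvc_offset = batch_tvc_offset,
         batch_gain_shift = batch_gain_shift, growth = growth,
         tvc_noise_sd = tvc_noise_sd, ftir_range = ftir_range,
         ftir_downsample = as.integer(ftir_downsample),
         msi_bands = sort(msi_bands), msif_bands = sort(msif_bands),
         signal = signal, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic spectral loadings. The TVC loading of the FTIR block is
# concentrated in the 1750-1400 cm-1 amide/fingerprint region; the MSI TVC
# trend sits in the 450-700 nm visible bands; MSIF carries a weaker analogue.
# The shared nuisance loading occupies a different spectral region per
# modality so it is linearly separable from the TVC signal.
gaussian_bump <- function(x, centre, width) exp(-((x - centre) / width)^2)

ftir_loadings <- function(wn) {
  tvc <- gaussian_bump(wn, 1655, 45) + 0.8 * gaussian_bump(wn, 1545, 40) +
    0.5 * gaussian_bump(wn, 1450, 30)
  list(
    baseline = 0.25 + 0.3 * gaussian_bump(wn, 3350, 500) +
      0.2 * gaussian_bump(wn, 1650, 350) + 0.05 * (4000 - wn) / 3600,
    tvc = tvc / max(tvc),
    shared = gaussian_bump(wn, 1100, 150)
  )
}

msi_loadings <- function(bands) {
  tvc_band <- gaussian_bump(bands, 575, 80)
  # per band: mean feature then sd feature; sd trend is 30% of the mean trend
  interleave <- function(mean_part, sd_part) {
    out <- numeric(2L * length(bands))
    out[seq(1L, by = 2L, length.out = length(bands))] <- mean_part
    out[seq(2L, by = 2L, length.out = length(bands))] <- sd_part
    out
  }
  list(
    baseline = interleave(0.5 - 0.25 * gaussian_bump(bands, 550, 120), rep(0.05, length(bands))),
    tvc = interleave(tvc_band, 0.3 * tvc_band),
    shared = interleave(gaussian_bump(bands, 850, 100), rep(0, length(bands)))
  )
}

msif_loadings <- function(bands) {
  tvc_band <- gaussian_bump(bands, 340, 40)
  interleave <- function(mean_part, sd_part) {
    out <- numeric(2L * length(bands))
    out[seq(1L, by = 2L, length.out = length(bands))] <- mean_part
    out[seq(2L, by = 2L, length.out = length(bands))] <- sd_part
    out
  }
  list(
    baseline = interleave(0.3 + 0.001 * (bands - 270), rep(0.04, length(bands))),
    tvc = interleave(tvc_band, 0.3 * tvc_band),
    shared = interleave(gaussian_bump(bands, 290, 30), rep(0, length(bands)))
  )
}

band_stat_names <- function(prefix, bands) {
  as.vector(rbind(sprintf("%s_%g_mean", prefix, bands),
                  sprintf("%s_%g_sd", prefix, bands)))
}

modality_axes <- function(config) {
  wn <- ftir_grid(config$ftir_range, config$ftir_downsample)
  list(
    MSI = list(names = band_stat_names("msi", config$msi_bands),
               loadings = msi_loadings(config$msi_bands)),
    FTIR = list(names = sprintf("%.4f", wn), wavenumbers = wn,
                loadings = ftir_loadings(wn)),
    MSIF = list(names = band_stat_names("msif", config$msif_bands),
                loadings = msif_loadings(config$msif_bands))
  )
}

#' Simulate an aligned multi-sensor spoilage dataset
#'
#' Generates one row per (condition, temperature, time, batch, replicate)
#' with a shared sample-ID scheme
#' `<meat>_<condition>_<tempC>_<timeH>_<batch>_<rep>` across a metadata table
#' and three spectral blocks (MSI, FTIR, MSIF). Each block is
#' `baseline + z * tvc_loading + s * shared_loading`, row-scaled by a
#' multiplicative gain and additive offset artifact (which SNV removes) plus
#' i.i.d. measurement noise, where `z = tvc + unique_sd * u` carries the
#' modality-unique interference and `s` is a shared nuisance factor. Batch 2
#' TVC values are shifted by `batch_tvc_offset` and batch 2 gains by
#' `batch_gain_shift`. The output is a pure function of the config
#' (including its seed).
#'
#' @param config a [sim_config()] object
#' @return a [multimodal_dataset()] with blocks MSI, FTIR, MSIF
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(
#'   conditions = "aerobic", temperatures = 10,
#'   sampling_times = list(`10` = c(0, 48, 96)),
#'   replicates_range = c(2, 2), ftir_downsample = 60, seed = 7
#' ))
#' ds
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  axes <- modality_axes(config)
  withr::with_seed(config$seed, {
    meta <- list()
    for (cond in config$conditions) {
      gp <- config$growth
      gp$condition_rate_factor <- gp$condition_rate_factor *
        config$condition_rate_factors[[cond]]
      for (temp in config$temperatures) {
        times <- config$sampling_times[[as.character(temp)]]
        mu <- growth_curve(gp, temp, times)
        for (b in seq_len(config$batches)) {
          for (i in seq_along(times)) {
            n_rep <- sample(seq(config$replicates_range[1],
                                config$replicates_range[2]), 1L)
            tvc <- mu[i] + stats::rnorm(n_rep, sd = config$tvc_noise_sd) +
              (b - 1L) * config$batch_tvc_offset
            tvc <- pmin(pmax(tvc, 0), gp$max_load + 1 + config$batch_tvc_offset)
            meta[[length(meta) + 1L]] <- data.frame(
              sample_id = sprintf("%s_%s_%g_%g_%d_%d", config$meat_type, cond,
                                  temp, times[i], b, seq_len(n_rep)),
              meat_type = config$meat_type, condition = cond,
              temperature = temp, time = times[i], batch = b,
              replicate = seq_len(n_rep), tvc = tvc,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    meta <- do.call(rbind, meta)
    if (anyDuplicated(meta$sample_id)) {
      stop("duplicate sample IDs generated; check the configuration", call. = FALSE)
    }
    n <- nrow(meta)
    sp <- config$signal
    shared_factor <- stats::rnorm(n)
    blocks <- list()
    for (mod in c("MSI", "FTIR", "MSIF")) {
      key <- tolower(mod)
      ax <- axes[[mod]]
      u <- stats::rnorm(n)
      z <- meta$tvc + sp$unique_sd[[key]] * u
      gain <- 1 + stats::rnorm(n, sd = sp$gain_sd)
      gain <- gain * (1 + (meta$batch - 1L) * config$batch_gain_shift)
      offset <- stats::rnorm(n, sd = sp$offset_sd)
      x <- tcrossprod(rep(1, n), ax$loadings$baseline) +
        tcrossprod(z * sp$tvc_amplitude[[key]], ax$loadings$tvc) +
        tcrossprod(shared_factor * sp$shared_weight[[key]], ax$loadings$shared)
      if (sp$noise_sd[[key]] > 0) {
        x <- x + matrix(stats::rnorm(n * length(ax$names), sd = sp$noise_sd[[key]]),
                        nrow = n)
      }
      x <- x * gain + offset
      dimnames(x) <- list(meta$sample_id, ax$names)
      blocks[[mod]] <- spectral_block(x, modality = mod,
                                      wavenumbers = ax$wavenumbers)
    }
    multimodal_dataset(blocks, meta)
  })
}

#' Ground-truth generative weights of a simulation config
#'
#' Exports the exact per-feature TVC and shared-factor loadings and the
#' per-modality unique-interference standard deviation used by
#' [simulate_dataset()], for signal-recovery tests. Deterministic given the
#' config.
#'
#' @param config a [sim_config()] object
#' @return a data.frame with columns `modality`, `feature`, `tvc_loading`
#'   (response units per log CFU/g), `shared_loading`, `unique_sd`
#' @export
oracle_signal_report <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  axes <- modality_axes(config)
  out <- lapply(c("MSI", "FTIR", "MSIF"), function(mod) {
    key <- tolower(mod)
    ax <- axes[[mod]]
    data.frame(
      modality = mod, feature = ax$names,
      tvc_loading = config$signal$tvc_amplitude[[key]] * ax$loadings$tvc,
      shared_loading = config$signal$shared_weight[[key]] * ax$loadings$shared,
      unique_sd = config$signal$unique_sd[[key]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
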