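#' Simulation configuration for an oddball study
#'
#' Bundles the acquisition parameters (64 channels at 500 Hz, 2000-stimulus
#' oddball sequence with 90/10 standard/deviant split and 500 ms stimulus
#' onset asynchrony) with the generative model of the cohort: a planted DNM
#' subnetwork whose spectral radius `gamma` controls the distance to the
#' bifurcation (criticality), a group-dependent MMN deflection on the DNM
#' channels, and a group-dependent direct-coupling strength among the
#' remaining channels (stable brains show stronger regular causality).
#'
#' @param n_channels number of channels (default 64).
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param n_stimuli number of stimuli per recording (default 2000).
#' @param deviant_fraction proportion of deviant stimuli in (0,1)
#'   (default 0.10).
#' @param soa stimulus onset asynchrony in ms (default 500); `soa *
#'   sampling_rate / 1000` must be an integer.
#' @param epoch_window epoch window in ms relative to stimulus onset,
#'   inclusive start / exclusive end (default `c(-100, 400)`).
#' @param groups data frame with one row per group and columns `group`
#'   (HC/UHR/PD), `n` (subjects), `gamma` (DNM-block spectral radius in
#'   (0,1)), `mmn_amplitude` (uV, negative), `mmn_latency` (ms),
#'   `direct_coupling` (non-DNM nearest-neighbour coupling strength).
#'   Defaults mirror the study cohort: 49 HC (gamma 0.97), 24 UHR (0.8),
#'   29 PD (0.6), with MMN amplitude attenuating from -3 uV (HC) to
#'   -1 uV (PD).
#' @param dnm_members channel indices of the planted DNM block (default 1:8).
#' @param noise_sd standard deviation of the dynamical noise xi in uV
#'   (default 5).
#' @param sensor_noise_sd i.i.d. Gaussian sensor noise SD in uV (default 5).
#' @param erp_amplitude amplitude scale of the standard ERP template in uV
#'   (default 2).
#' @param mmn_width Gaussian width (SD, ms) of the planted MMN deflection
#'   (default 25).
#' @param self_coupling diagonal self-coupling of non-DNM channels
#'   (default 0.25).
#' @param coupling_delay_ms conduction delay of the direct coupling in ms
#'   (default 10).
#' @param no_consecutive_deviants if TRUE (default) no two deviants occur
#'   back to back; the conditional deviant probability is inflated to
#'   `p/(1-p)` so the long-run deviant fraction still equals
#'   `deviant_fraction`.
#' @param seed study-level integer seed; per-subject seeds are derived from
#'   it deterministically.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 64, sampling_rate = 500, n_stimuli = 2000,
                       deviant_fraction = 0.10, soa = 500,
                       epoch_window = c(-100, 400),
                       groups = default_group_specs(),
                       dnm_members = 1:8, noise_sd = 5, sensor_noise_sd = 5,
                       erp_amplitude = 2, mmn_width = 25,
                       self_coupling = 0.25, coupling_delay_ms = 10,
                       no_consecutive_deviants = TRUE, seed = 1) {
  check_scalar_in(deviant_fraction, "deviant_fraction", 0, 1)
  soa_samples <- soa * sampling_rate / 1000
  if (abs(soa_samples - round(soa_samples)) > 1e-9)
    stop_invalid("soa (%g ms) x sampling_rate (%g Hz) is not an integer number of samples",
                 soa, sampling_rate)
  if (n_stimuli < 1L) stop_invalid("n_stimuli must be >= 1")
  if (length(epoch_window) != 2L || epoch_window[1] >= epoch_window[2])
    stop_invalid("epoch_window must be an increasing ms pair")
  req <- c("group", "n", "gamma", "mmn_amplitude", "mmn_latency", "direct_coupling")
  if (!is.data.frame(groups) || !all(req %in% names(groups)))
    stop_invalid("groups must be a data frame with columns %s",
                 paste(req, collapse = ", "))
  if (nrow(groups) == 0L || any(groups$n < 1L))
    stop_invalid("every requested group needs at least one subject")
  for (g in seq_len(nrow(groups)))
    check_scalar_in(groups$gamma[g], paste0("gamma[", groups$group[g], "]"), 0, 1)
  if (length(dnm_members) == 0L || length(dnm_members) >= n_channels ||
      any(dnm_members < 1L | dnm_members > n_channels) ||
      anyDuplicated(dnm_members))
    stop_invalid("dnm_members must be a non-empty strict subset of 1..n_channels")
  structure(list(
    n_channels = n_channels, sampling_rate = sampling_rate,
    n_stimuli = n_stimuli, deviant_fraction = deviant_fraction, soa = soa,
    soa_samples = as.integer(round(soa_samples)),
    epoch_window = epoch_window, groups = groups,
    dnm_members = as.integer(sort(dnm_members)), noise_sd = noise_sd,
    sensor_noise_sd = sensor_noise_sd, erp_amplitude = erp_amplitude,
    mmn_width = mmn_width, self_coupling = self_coupling,
    coupling_delay_ms = coupling_delay_ms,
    no_consecutive_deviants = isTRUE(no_consecutive_deviants),
    seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_group_specs <- function() {
  data.frame(group = c("HC", "UHR", "PD"),
             n = c(49L, 24L, 29L),
             gamma = c(0.97, 0.80, 0.60),
             mmn_amplitude = c(-3, -2, -1),
             mmn_latency = c(170, 175, 180),
             direct_coupling = c(0.10, 0.15, 0.65),
             stringsAsFactors = FALSE)
}

#' Linear network model of the corrected-epoch difference process
#'
#' Builds the linearised difference-process dynamics
#' `z(t+1) = A z(t) + D z(t - delay) + xi(t)`. The planted DNM block (inside
#' `A`) receives uniform all-to-all coupling rescaled so its spectral radius
#' equals `gamma` (`design = "uniform"`), or a gamma-diagonal
#' (`design = "diagonal"`). Non-DNM channels get a weak self-coupling in `A`
#' plus a directed nearest-neighbour coupling ring of strength
#' `direct_coupling` in `D`, acting after a conduction delay of
#' `coupling_delay` samples (axonal/synaptic propagation); this delayed ring
#' is the generative mechanism for the strong regular direct causality of
#' stable (far-from-critical) dynamics at physiological lags. It never
#' touches the DNM block, so the block spectral radius is exactly `gamma`
#' and non-DNM variance does not depend on `gamma`. Stationarity is checked
#' on the companion (stacked-state) form, which brings the delayed system
#' back to first order.
#'
#' @param n_channels number of channels.
#' @param dnm_members channel indices of the DNM block (non-empty strict
#'   subset).
#' @param gamma target spectral radius of the DNM block, in (0,1).
#' @param design `"uniform"` (default) or `"diagonal"` DNM-block design.
#' @param self_coupling diagonal coefficient of non-DNM channels.
#' @param direct_coupling nearest-neighbour directed coupling among non-DNM
#'   channels; `self_coupling + |direct_coupling|` must stay below 1, a
#'   sufficient condition for stationarity of the delayed system.
#' @param coupling_delay conduction delay of the direct coupling in samples
#'   (default 5, i.e. 10 ms at 500 Hz); 0 means the coupling acts at lag 1.
#' @param noise_sd SD of the i.i.d. Gaussian dynamical noise xi (uV).
#' @return an object of class `dnm_model` with elements `n_channels`, `A`,
#'   `D`, `delay`, `dnm_members`, `gamma`, `noise_sd`.
#' @export
make_linear_model <- function(n_channels, dnm_members, gamma,
                              design = c("uniform", "diagonal"),
                              self_coupling = 0.25, direct_coupling = 0.1,
                              coupling_delay = 5, noise_sd = 5) {
  design <- match.arg(design)
  check_scalar_in(gamma, "gamma", 0, 1)
  if (length(dnm_members) == 0L || length(dnm_members) >= n_channels ||
      any(dnm_members < 1L | dnm_members > n_channels) ||
      anyDuplicated(dnm_members))
    stop_invalid("dnm_members must be a non-empty strict subset of 1..n_channels")
  if (self_coupling + abs(direct_coupling) >= 1)
    stop_invalid("self_coupling + |direct_coupling| must be < 1 for stationarity")
  if (coupling_delay < 0L) stop_invalid("coupling_delay must be >= 0 samples")
  dnm_members <- as.integer(sort(dnm_members))
  m <- length(dnm_members)
  A <- matrix(0, n_channels, n_channels)
  D <- matrix(0, n_channels, n_channels)
  if (design == "uniform") {
    # spectral radius of the all-ones m x m matrix is m
    A[dnm_members, dnm_members] <- gamma / m
  } else {
    A[cbind(dnm_members, dnm_members)] <- gamma
  }
  others <- setdiff(seq_len(n_channels), dnm_members)
  if (length(others) > 0L) {
    A[cbind(others, others)] <- self_coupling
    if (length(others) > 1L && direct_coupling != 0) {
      src <- c(others[length(others)], others[-length(others)]) # ring
      D[cbind(others, src)] <- direct_coupling
    }
  }
  if (all(D == 0)) coupling_delay <- 0L
  if (coupling_delay == 0L) {
    A <- A + D
    D <- matrix(0, n_channels, n_channels)
  }
  rho_full <- spectral_radius(companion_matrix(A, D, coupling_delay))
  if (rho_full >= 1)
    stop_invalid("coupling system has spectral radius %.3f >= 1", rho_full)
  structure(list(n_channels = as.integer(n_channels), A = A, D = D,
                 delay = as.integer(coupling_delay),
                 dnm_members = dnm_members, gamma = gamma,
                 design = design, self_coupling = self_coupling,
                 direct_coupling = direct_coupling, noise_sd = noise_sd,
                 spectral_radius = rho_full),
            class = "dnm_model")
}

# First-order companion embedding of z(t+1) = A z(t) + D z(t - delay) + xi.
companion_matrix <- function(A, D, delay) {
  C <- nrow(A)
  if (delay == 0L) return(A + D)
  k <- delay + 1L
  M <- matrix(0, C * k, C * k)
  M[seq_len(C), seq_len(C)] <- A
  M[seq_len(C), (delay * C) + seq_len(C)] <- D
  for (b in seq_len(delay))
    M[(b * C) + seq_len(C), ((b - 1L) * C) + seq_len(C)] <- diag(C)
  M
}

#' Simulate the difference process
#'
#' Iterates z(t+1) = A z(t) + xi(t) from z(0) = 0 with i.i.d. Gaussian
#' noise of SD `model$noise_sd`.
#'
#' @param model a `dnm_model`.
#' @param n_samples number of samples to return (>= 2).
#' @param seed optional integer seed for reproducibility.
#' @return channel x sample matrix.
#' @export
simulate_difference_process <- function(model, n_samples, seed = NULL) {
  if (n_samples < 2L) stop_invalid("n_samples must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  C <- model$n_channels
  z <- matrix(0, C, n_samples)
  if (model$noise_sd == 0) return(z)
  xi <- matrix(stats::rnorm(C * n_samples, sd = model$noise_sd), C, n_samples)
  state <- numeric(C)
  A <- model$A
  delayed <- model$delay > 0L && any(model$D != 0)
  for (t in seq_len(n_samples)) {
    state <- drop(A %*% state) + xi[, t]
    if (delayed && t > model$delay)
      state <- state + drop(model$D %*% z[, t - model$delay])
    z[, t] <- state
  }
  z
}

# Batched difference-process segments: one independent stationary segment per
# deviant epoch, simulated in parallel columns after a burn-in. Uses the
# current RNG stream.
sim_z_segments <- function(model, n_steps, n_segments, burnin = 200L) {
  C <- model$n_channels
  out <- array(0, dim = c(C, n_steps, n_segments))
  if (model$noise_sd == 0 || n_segments == 0L) return(out)
  A <- model$A
  D <- model$D
  delayed <- model$delay > 0L && any(D != 0)
  # circular history buffer for the delayed coupling term
  hist_len <- max(model$delay, 1L)
  hist <- array(0, dim = c(C, n_segments, hist_len))
  Z <- matrix(0, C, n_segments)
  step <- function(Z, t_abs) {
    nz <- A %*% Z + matrix(stats::rnorm(C * n_segments, sd = model$noise_sd),
                           C, n_segments)
    if (delayed) {
      slot <- ((t_abs - 1L - model$delay) %% hist_len) + 1L
      if (t_abs > model$delay) nz <- nz + D %*% hist[, , slot]
    }
    nz
  }
  for (t in seq_len(burnin + n_steps)) {
    Z <- step(Z, t)
    if (delayed) hist[, , ((t - 1L) %% hist_len) + 1L] <- Z
    if (t > burnin) out[, t - burnin, ] <- Z
  }
  out
}

# Standard-response ERP template (uV) on the fronto-central (DNM) channels;
# shape is an N1-P2-like biphasic wave. It cancels exactly in corrected
# epochs, so its precise form is immaterial to the downstream analysis.
standard_erp_template <- function(t_ms, amplitude) {
  amplitude * (-exp(-((t_ms - 100) / 20)^2 / 2) +
                 0.8 * exp(-((t_ms - 200) / 30)^2 / 2))
}

mmn_template <- function(t_ms, amplitude, latency, width) {
  amplitude * exp(-((t_ms - latency) / width)^2 / 2)
}

#' Simulate a single oddball recording
#'
#' Produces a continuous multichannel signal with stimulus events. Standard
#' stimuli evoke a fixed ERP template on the DNM channels; deviant stimuli
#' additionally evoke a negative Gaussian MMN deflection (group-dependent
#' amplitude/latency) on the DNM channels and carry one stationary segment of
#' the difference-process dynamics on all channels, so that corrected epochs
#' (deviant minus mean standard) realise z(t). I.i.d. Gaussian sensor noise
#' is added everywhere.
#'
#' @param config a [sim_config()].
#' @param model a [make_linear_model()] with `n_channels` matching the config.
#' @param subject_id subject identifier string.
#' @param group group label (must appear in `config$groups`).
#' @param seed integer seed.
#' @return an object of class `oddball_recording`: list with `subject_id`,
#'   `group`, `signal` (channel x sample, uV), `sampling_rate`, `events`
#'   (data frame `onset_sample`, `kind`).
#' @export
simulate_oddball_recording <- function(config, model, subject_id, group,
                                       seed = NULL) {
  if (model$n_channels != config$n_channels)
    stop_invalid("model has %d channels but config requests %d",
                 model$n_channels, config$n_channels)
  gi <- match(group, config$groups$group)
  if (is.na(gi)) stop_invalid("unknown group '%s'", group)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  soa_s <- config$soa_samples
  pre_s  <- as.integer(ceiling(-config$epoch_window[1] * fs / 1000)) + 2L
  post_s <- as.integer(ceiling(config$epoch_window[2] * fs / 1000)) + 2L
  n_total <- pre_s + config$n_stimuli * soa_s + post_s
  onsets <- pre_s + (seq_len(config$n_stimuli) - 1L) * soa_s + 1L

  kinds <- draw_oddball_kinds(config$n_stimuli, config$deviant_fraction,
                              config$no_consecutive_deviants)
  C <- config$n_channels
  signal <- matrix(stats::rnorm(C * n_total, sd = config$sensor_noise_sd),
                   C, n_total)

  # evoked responses on the DNM channels
  erp_len <- min(soa_s, as.integer(300 * fs / 1000))
  t_erp <- (seq_len(erp_len) - 1L) * 1000 / fs
  erp <- standard_erp_template(t_erp, config$erp_amplitude)
  mmn <- mmn_template(t_erp, config$groups$mmn_amplitude[gi],
                      config$groups$mmn_latency[gi], config$mmn_width)
  dnm <- config$dnm_members
  dev_idx <- which(kinds == "deviant")
  for (k in seq_len(erp_len)) {
    if (erp[k] != 0)
      signal[dnm, onsets + k - 1L] <- signal[dnm, onsets + k - 1L] + erp[k]
    if (length(dev_idx) > 0L && mmn[k] != 0)
      signal[dnm, onsets[dev_idx] + k - 1L] <-
        signal[dnm, onsets[dev_idx] + k - 1L] + mmn[k]
  }

  # difference-process dynamics injected into deviant responses only
  z_len <- as.integer(round(config$epoch_window[2] * fs / 1000))
  if (length(dev_idx) > 0L && z_len > 0L) {
    zs <- sim_z_segments(model, z_len, length(dev_idx))
    for (e in seq_along(dev_idx)) {
      cols <- onsets[dev_idx[e]] + seq_len(z_len) - 1L
      signal[, cols] <- signal[, cols] + zs[, , e]
    }
  }

  structure(list(subject_id = subject_id, group = group, signal = signal,
                 sampling_rate = fs,
                 events = data.frame(onset_sample = onsets, kind = kinds,
                                     stringsAsFactors = FALSE)),
            class = "oddball_recording")
}

# Deviant/standard sequence. With the no-two-consecutive convention the
# conditional probability after a standard is p/(1-p), which keeps the
# stationary deviant fraction at exactly p.
draw_oddball_kinds <- function(n, p, no_consecutive) {
  if (!no_consecutive) {
    kinds <- ifelse(stats::runif(n) < p, "deviant", "standard")
    return(kinds)
  }
  p_cond <- p / (1 - p)
  u <- stats::runif(n)
  kinds <- character(n)
  prev_dev <- TRUE # first stimulus is always standard
  for (i in seq_len(n)) {
    if (!prev_dev && u[i] < p_cond) {
      kinds[i] <- "deviant"; prev_dev <- TRUE
    } else {
      kinds[i] <- "standard"; prev_dev <- FALSE
    }
  }
  kinds
}

#' Generate a multisubject oddball study
#'
#' Assembles a cohort of simulated recordings according to
#' `config$groups`: one linear network model per group (its `gamma` and
#' `direct_coupling`), per-subject seeds derived deterministically from the
#' study seed.
#'
#' @param config a [sim_config()].
#' @return list of `oddball_recording` objects (class `dnm_recording_set`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  recs <- list()
  idx <- 0L
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    model <- make_linear_model(
      config$n_channels, config$dnm_members, gamma = g$gamma,
      self_coupling = config$self_coupling,
      direct_coupling = g$direct_coupling,
      coupling_delay = as.integer(round(config$coupling_delay_ms *
                                          config$sampling_rate / 1000)),
      noise_sd = config$noise_sd)
    for (s in seq_len(g$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g$group, s)
      recs[[sid]] <- simulate_oddball_recording(
        config, model, sid, g$group, seed = derive_seed(config$seed, idx))
    }
  }
  structure(recs, class = "dnm_recording_set")
}

#' Simulate and preprocess a study one subject at a time
#'
#' Memory-lean equivalent of `preprocess_study(generate_study(config))`:
#' each recording is simulated, epoched and reduced to its corrected epochs
#' before the next subject is touched, so cohort-scale studies never hold
#' all continuous signals at once. Uses the same per-subject seed discipline
#' as [generate_study()], so the result is identical to the two-step path.
#'
#' @param config a [sim_config()].
#' @param preprocess a [preprocess_config()].
#' @return named list of [corrected_epochs()], one per subject.
#' @export
simulate_corrected_study <- function(config,
                                     preprocess = preprocess_config()) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  idx <- 0L
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    model <- make_linear_model(
      config$n_channels, config$dnm_members, gamma = g$gamma,
      self_coupling = config$self_coupling,
      direct_coupling = g$direct_coupling,
      coupling_delay = as.integer(round(config$coupling_delay_ms *
                                          config$sampling_rate / 1000)),
      noise_sd = config$noise_sd)
    for (s in seq_len(g$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g$group, s)
      rec <- simulate_oddball_recording(
        config, model, sid, g$group, seed = derive_seed(config$seed, idx))
      out[[sid]] <- correct_epochs(
        reject_artifacts(extract_epochs(rec, preprocess), preprocess))
    }
  }
  out
}

#' @export
print.oddball_recording <- function(x, ...) {
  cat(sprintf("oddball recording '%s' (%s): %d channels x %d samples @ %g Hz, %d events (%d deviant)\n",
              x$subject_id, x$group, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, nrow(x$events),
              sum(x$events$kind == "deviant")))
  invisible(x)
}

#' @export
print.dnm_recording_set <- function(x, ...) {
  grp <- vapply(x, function(r) r$group, character(1))
  cat(sprintf("simulated oddball study: %d subjects (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                    collapse = ", ")))
  invisible(x)
}
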