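#' One-period PPG pulse template
#'
#' Asymmetric quasi-periodic pulse shape evaluated at phase in \[0, 1):
#' a narrow positive systolic lobe (width about 0.15 of the period, peak +1),
#' a small secondary diastolic bump (<= 0.2), and a broad negative undershoot
#' whose depth is set by `asymmetry` (default 0.5, i.e. swings between about
#' -0.5 and +1). The undershoot width is chosen so the template integrates to
#' approximately zero over a period.
#'
#' @param phase Phase values; taken modulo 1.
#' @param asymmetry Ratio of negative to positive swing (> 0).
#' @return Template amplitude at each phase.
#' @export
pulse_waveform <- function(phase, asymmetry = 0.5) {
  raw <- function(ph) {
    lobe <- function(center, sigma) {
      d <- (ph - center + 0.5) %% 1 - 0.5
      exp(-0.5 * (d / sigma)^2)
    }
    sys_amp <- 1; sys_sig <- 0.055
    dia_amp <- 0.15; dia_sig <- 0.06
    # Undershoot area balances the positive lobes (amp * sig * sqrt(2*pi)
    # each) so the template integrates to ~0 over a period.
    pos_area <- (sys_amp * sys_sig + dia_amp * dia_sig) * sqrt(2 * pi)
    neg_sig <- pos_area / (asymmetry * sqrt(2 * pi))
    sys_amp * lobe(0.2, sys_sig) + dia_amp * lobe(0.45, dia_sig) -
      asymmetry * lobe(0.75, neg_sig)
  }
  # Recenter so the maximum sits exactly at the systolic phase 0.2 (the
  # undershoot tail shifts the raw peak by a few 1e-4) and scale to unit peak.
  opt <- stats::optimize(raw, c(0.1, 0.3), maximum = TRUE, tol = 1e-10)
  raw((phase + opt$maximum - 0.2) %% 1) / opt$objective
}

#' Heart-rate trajectories for the synthetic generator
#'
#' `hr_constant()` holds one rate; `hr_sinusoid()` oscillates around a mean;
#' `hr_bike_protocol()` emulates a stationary-bike session — sedentary rest
#' for the first half, a ramp to moderate effort, a climb to peak effort,
#' then recovery — scaled to the record duration (the canonical 20 min
#' session spends 10 min at rest, 2 min ramping, 3 min at peak and 5 min
#' recovering).
#'
#' @param hr,mean,amp,period_s,rest,moderate,peak,recovery BPM values and
#'   the sinusoid period in seconds.
#' @return A function of time (seconds, vectorized) returning HR in BPM,
#'   with a `name` attribute.
#' @export
hr_constant <- function(hr = 70) {
  structure(function(t) rep(hr, length(t)), name = sprintf("constant(%g)", hr))
}

#' @rdname hr_constant
#' @export
hr_sinusoid <- function(mean = 70, amp = 10, period_s = 120) {
  structure(function(t) mean + amp * sin(2 * pi * t / period_s),
            name = sprintf("sinusoid(%g,%g,%g)", mean, amp, period_s))
}

#' @rdname hr_constant
#' @export
hr_bike_protocol <- function(rest = 75, moderate = 120, peak = 150,
                             recovery = 95) {
  structure(function(t) {
    tmax <- max(t)
    frac <- t / tmax
    approx(x = c(0, 0.5, 0.6, 0.75, 1),
           y = c(rest, rest, moderate, peak, recovery),
           xout = pmin(pmax(frac, 0), 1))$y
  }, name = "bike_protocol")
}

#' Synthetic PPG generator configuration
#'
#' Defaults emulate a 20 min chest-mounted recording at 46.3 Hz: an
#' asymmetric pulse train following the bike-protocol HR trajectory, slow
#' band-limited baseline drift (three random-phase sinusoids below
#' `drift_band` Hz, comparable in amplitude to the pulse), additive white
#' noise, and optional impulsive contact-loss events and a narrowband
#' pedaling-cadence tone. A contact-loss event suppresses the pulse for its
#' duration (0.5-3 s; no blood-flow signal reaches a detached sensor) and
#' adds step transients of `contact_loss_amp` pulse amplitudes with
#' exponential re-baselining (tau = 0.5 s) at both the loss and the
#' re-contact instant — the sharp swings whose transforms smear into
#' broadband spectrogram streaks.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param hr_trajectory A trajectory function from [hr_constant()] etc.
#' @param pulse_asymmetry Negative/positive swing ratio.
#' @param drift_amp Drift amplitude (pulse units).
#' @param drift_band Upper edge of the drift band, Hz (breathing scale).
#' @param contact_loss_rate Poisson rate of contact-loss events, events/s.
#' @param contact_loss_amp Transient amplitude, multiples of pulse amplitude.
#' @param cadence_bpm Optional cadence-artifact frequency in BPM.
#' @param cadence_amp Cadence tone amplitude, fraction of pulse amplitude.
#' @param noise_sd White-noise standard deviation (pulse units).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 46.3, duration_s = 1200,
                         hr_trajectory = hr_bike_protocol(),
                         pulse_asymmetry = 0.5,
                         drift_amp = 1, drift_band = 0.3,
                         contact_loss_rate = 0, contact_loss_amp = 10,
                         cadence_bpm = NULL, cadence_amp = 0,
                         noise_sd = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic PPG record with ground truth
#'
#' Integrates the instantaneous phase of the HR trajectory, evaluates the
#' pulse template, and adds drift, Poisson-scheduled contact-loss
#' transients, an optional cadence tone, and white noise. Ground-truth HR is
#' emitted at 1 Hz, and the true systolic peak times are returned for
#' timing checks.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_ppg`: `record` (a [ppg_record()]),
#'   `truth` (tibble `time_s`, `hr` at 1 Hz), `beat_times` (true systolic
#'   times, seconds), `artifacts` (tibble `onset_s`, `duration_s`, `kind`).
#' @export
synth_ppg <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_synth(config))
}

generate_synth <- function(cf) {
  n <- round(cf$duration_s * cf$fs)
  t <- (seq_len(n) - 1) / cf$fs
  hr <- cf$hr_trajectory(t)
  if (any(hr < 45 | hr > 200)) {
    abort_config("HR trajectory must stay within [45, 200] BPM.")
  }
  phase <- cumsum(hr / 60) / cf$fs
  x <- pulse_waveform(phase, cf$pulse_asymmetry)

  # True systolic times: template peak sits at phase 0.2 (mod 1).
  ks <- seq(ceiling(min(phase) - 0.2), floor(max(phase) - 0.2))
  beat_times <- approx(phase, t, xout = ks + 0.2)$y
  beat_times <- beat_times[!is.na(beat_times)]

  artifacts <- tibble(onset_s = numeric(0), duration_s = numeric(0),
                      kind = character(0))
  if (cf$drift_amp > 0) {
    fr <- runif(3, 0.02, cf$drift_band)
    phs <- runif(3, 0, 2 * pi)
    amps <- cf$drift_amp * c(0.5, 0.3, 0.2)
    for (i in 1:3) x <- x + amps[i] * sin(2 * pi * fr[i] * t + phs[i])
  }
  if (cf$contact_loss_rate > 0) {
    n_ev <- rpois(1, cf$contact_loss_rate * cf$duration_s)
    if (n_ev > 0) {
      onsets <- sort(runif(n_ev, 0, cf$duration_s))
      durations <- runif(n_ev, 0.5, 3)
      tau <- 0.5
      for (j in seq_len(n_ev)) {
        o <- onsets[j]; d <- durations[j]
        # No plethysmographic signal while contact is lost: gate the pulse
        # off over [o, o + d] (sharp ~20 ms edges), and add step transients
        # with exponential re-baselining at loss and at re-contact.
        gate <- 1 - stats::plogis((t - o) / 0.02) *
          stats::plogis((o + d - t) / 0.02)
        x <- x * gate
        s1 <- sample(c(-1, 1), 1)
        s2 <- sample(c(-1, 1), 1)
        i1 <- t >= o
        x[i1] <- x[i1] + s1 * cf$contact_loss_amp * exp(-(t[i1] - o) / tau)
        i2 <- t >= o + d
        x[i2] <- x[i2] + s2 * cf$contact_loss_amp * exp(-(t[i2] - o - d) / tau)
      }
      artifacts <- dplyr::bind_rows(
        artifacts,
        tibble(onset_s = onsets, duration_s = durations, kind = "contact_loss")
      )
    }
  }
  if (!is.null(cf$cadence_bpm)) {
    x <- x + cf$cadence_amp * sin(2 * pi * (cf$cadence_bpm / 60) * t)
    artifacts <- dplyr::bind_rows(
      artifacts,
      tibble(onset_s = 0, duration_s = cf$duration_s, kind = "cadence")
    )
  }
  if (cf$noise_sd > 0) x <- x + rnorm(n, 0, cf$noise_sd)

  truth_t <- seq(0, floor(cf$duration_s - 1))
  structure(
    list(
      record = ppg_record(x, fs = cf$fs,
                          record_id = sprintf("synth_seed%d", cf$seed)),
      truth = tibble(time_s = truth_t, hr = cf$hr_trajectory(truth_t)),
      beat_times = beat_times,
      artifacts = artifacts,
      config = cf
    ),
    class = "synth_ppg"
  )
}

#' @export
print.synth_ppg <- function(x, ...) {
  cat(sprintf(
    "<synth_ppg>  %d samples @ %g Hz, HR trajectory %s, %d artifact(s)\n",
    nrow(x$record), x$config$fs,
    attr(x$config$hr_trajectory, "name") %||% "custom", nrow(x$artifacts)
  ))
  invisible(x)
}

#' Write a fixture suite of synthetic records
#'
#' Writes a deterministic set of CSV records spanning clean, marginal and
#' corrupted conditions, together with per-record ground-truth HR CSVs and a
#' YAML manifest (record ids, paths, designed labels, generator settings).
#' Clean records are labelled good; records corrupted with contact-loss
#' transients are labelled poor.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base RNG seed; per-record seeds are derived from it.
#' @param duration_s Length of each record, seconds.
#' @return The manifest path, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, duration_s = 180) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(paste0("Cannot create directory: ", out_dir))
  }
  specs <- list(
    list(id = "clean_constant", label = "good",
         args = list(hr_trajectory = hr_constant(75))),
    list(id = "clean_bike", label = "good",
         args = list(hr_trajectory = hr_bike_protocol())),
    list(id = "clean_sinusoid", label = "good",
         args = list(hr_trajectory = hr_sinusoid(90, 10, 120))),
    list(id = "marginal_contact", label = "poor",
         args = list(hr_trajectory = hr_constant(80),
                     contact_loss_rate = 0.05)),
    list(id = "corrupted_contact", label = "poor",
         args = list(hr_trajectory = hr_constant(80),
                     contact_loss_rate = 0.15)),
    list(id = "severe_contact", label = "poor",
         args = list(hr_trajectory = hr_constant(80),
                     contact_loss_rate = 0.3))
  )
  records <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cf <- do.call(synth_config, c(sp$args, list(
      duration_s = duration_s, seed = as.integer(seed) + i
    )))
    syn <- synth_ppg(cf)
    rec_path <- file.path(out_dir, paste0(sp$id, ".csv"))
    truth_path <- file.path(out_dir, paste0(sp$id, "_truth.csv"))
    write_ppg_csv(syn$record, rec_path)
    readr::write_csv(syn$truth, truth_path, progress = FALSE)
    records[[i]] <- list(
      record_id = sp$id, path = basename(rec_path),
      truth_path = basename(truth_path), label = sp$label,
      fs = cf$fs, duration_s = cf$duration_s, seed = cf$seed,
      contact_loss_rate = cf$contact_loss_rate
    )
  }
  manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(version = 1L, seed = as.integer(seed),
                        records = records), manifest)
  invisible(manifest)
}
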