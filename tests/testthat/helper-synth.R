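# Shared fixtures built in code.

# Short clean synthetic record (constant HR by default).
quick_synth <- function(hr = 70, duration_s = 120, seed = 1L, ...) {
  synth_ppg(synth_config(hr_trajectory = hr_constant(hr),
                         duration_s = duration_s, seed = seed, ...))
}

# Pure tone record (no pulse structure) for spectral checks.
tone_record <- function(freq_hz, fs = 46.3, duration_s = 120, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ppg_record(amp * sin(2 * pi * freq_hz * t), fs = fs, record_id = "tone")
}

# Write a minimal WFDB-style header + signal pair (format 16 by default).
# `signals` is a named list of integer digital vectors, one per channel;
# gain/baseline apply to all channels.
write_wfdb_fixture <- function(dir, name, signals, fs = 30,
                               gain = 100, baseline = 0, fmt = 16) {
  nsig <- length(signals)
  n <- length(signals[[1]])
  dat <- paste0(name, ".dat")
  hea <- c(
    sprintf("%s %d %g %d", name, nsig, fs, n),
    vapply(names(signals), function(ch) {
      sprintf("%s %d %g(%d)/mV 12 0 0 0 0 %s", dat, fmt, gain, baseline, ch)
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  inter <- as.integer(do.call(rbind, signals)) # interleave channels
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  if (fmt == 16) {
    writeBin(inter, con, size = 2, endian = "little")
  } else if (fmt == 80) {
    writeBin(as.raw(inter + 128L), con)
  } else if (fmt == 212) {
    if (length(inter) %% 2 == 1) inter <- c(inter, 0L)
    u <- ifelse(inter < 0, inter + 4096L, inter)
    s1 <- u[seq(1, length(u), 2)]
    s2 <- u[seq(2, length(u), 2)]
    bytes <- as.raw(rbind(
      s1 %% 256L,
      (s1 %/% 256L) + 16L * (s2 %/% 256L),
      s2 %% 256L
    ))
    writeBin(bytes, con)
  }
  file.path(dir, name)
}
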