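#' Read a PhysioNet-style waveform record
#'
#' Reads the paired header (`.hea`) + signal (`.dat`) layout used by
#' PhysioNet waveform databases (e.g. smartphone PPG collections sampled at
#' 30 Hz, or wrist PPG at 125 Hz). Supported signal encodings: format 16
#' (16-bit little-endian two's complement), format 80 (8-bit offset binary)
#' and format 212 (packed 12-bit pairs). Digital values are converted to
#' physical units via `(adc - baseline) / gain`.
#'
#' @param path Record path without extension (or the `.hea` path).
#' @param channel Channel to extract: an index, a name/regex matched against
#'   the channel descriptions, or `NULL` to pick the first channel whose
#'   description or units mention PPG/PLETH.
#' @param quality_label Optional `"good"`/`"poor"` annotation to attach
#'   (PhysioNet quality annotations live in per-dataset side tables).
#' @return A [ppg_record()] with the record's stated sampling rate.
#' @export
read_physionet_record <- function(path, channel = NULL, quality_label = NULL) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) abort_io(paste0("Header file not found: ", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort_format("Header must declare at least one signal.")
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(hdr) < 3) abort_format("Malformed record line in header.")
  nsig <- suppressWarnings(as.integer(hdr[[2]]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", hdr[[3]])))
  if (is.na(nsig) || is.na(fs) || fs <= 0) {
    abort_format("Could not parse signal count / sampling rate from header.")
  }
  if (length(lines) < 1 + nsig) {
    abort_format("Header declares more signals than it describes.")
  }
  sig <- lapply(lines[2:(1 + nsig)], parse_wfdb_signal_line)
  desc <- vapply(sig, function(s) s$description, character(1))

  idx <- resolve_wfdb_channel(channel, desc)

  # Read every signal file once; channels in one file are interleaved.
  dirn <- dirname(path)
  files <- vapply(sig, function(s) s$file, character(1))
  target <- sig[[idx]]
  in_file <- which(files == target$file)
  fmts <- unique(vapply(sig[in_file], function(s) s$format, numeric(1)))
  if (length(fmts) != 1) {
    abort_format("Mixed signal formats within one signal file are not supported.")
  }
  digital <- read_wfdb_signal_file(file.path(dirn, target$file), fmts)
  nchan <- length(in_file)
  pos <- match(idx, in_file)
  chan <- digital[seq(pos, length(digital), by = nchan)]
  physical <- (chan - target$baseline) / target$gain

  ppg_record(physical, fs = fs, record_id = basename(path),
             quality_label = quality_label)
}

parse_wfdb_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 2) abort_format("Malformed signal line in header.")
  fmt_field <- f[[2]]
  fmt <- suppressWarnings(as.numeric(sub("[x:+].*$", "", fmt_field)))
  if (is.na(fmt)) abort_format(paste0("Unparseable signal format: ", fmt_field))
  if (!fmt %in% c(16, 80, 212)) {
    abort_format(paste0("Unsupported signal format: ", fmt))
  }
  gain_field <- if (length(f) >= 3) f[[3]] else "200"
  units <- if (grepl("/", gain_field)) sub("^[^/]*/", "", gain_field) else ""
  gb <- sub("/.*$", "", gain_field)
  baseline <- NA_real_
  if (grepl("\\(", gb)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gb))
    gb <- sub("\\(.*$", "", gb)
  }
  gain <- suppressWarnings(as.numeric(gb))
  if (is.na(gain) || gain == 0) gain <- 200
  adc_zero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[[5]])) else 0
  if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
  # Description = everything after the 8 numeric fields, when present.
  description <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(file = f[[1]], format = fmt, gain = gain, baseline = baseline,
       units = units, description = description)
}

resolve_wfdb_channel <- function(channel, desc) {
  if (is.null(channel)) {
    hit <- grep("ppg|pleth", desc, ignore.case = TRUE)
    if (length(hit) == 0) {
      abort_data(paste0(
        "No PPG channel found (descriptions: ",
        paste(sprintf("'%s'", desc), collapse = ", "),
        "); pass `channel` to select one explicitly."
      ))
    }
    return(hit[[1]])
  }
  if (is.numeric(channel)) {
    channel <- as.integer(channel)
    if (channel < 1 || channel > length(desc)) {
      abort_config("`channel` index out of range.")
    }
    return(channel)
  }
  hit <- grep(channel, desc, ignore.case = TRUE)
  if (length(hit) == 0) abort_data(paste0("No channel matches '", channel, "'."))
  hit[[1]]
}

read_wfdb_signal_file <- function(path, fmt) {
  if (!file.exists(path)) abort_io(paste0("Signal file not found: ", path))
  nbytes <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (fmt == 16) {
    readBin(con, integer(), n = nbytes / 2, size = 2, signed = TRUE,
            endian = "little")
  } else if (fmt == 80) {
    as.integer(readBin(con, integer(), n = nbytes, size = 1,
                       signed = FALSE)) - 128L
  } else { # 212: 3 bytes hold two 12-bit two's complement samples
    b <- as.integer(readBin(con, integer(), n = nbytes, size = 1,
                            signed = FALSE))
    npair <- length(b) %/% 3
    b <- b[seq_len(npair * 3)]
    b1 <- b[seq(1, length(b), 3)]
    b2 <- b[seq(2, length(b), 3)]
    b3 <- b[seq(3, length(b), 3)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8)
    s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4), 8)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    as.integer(rbind(s1, s2))
  }
}
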