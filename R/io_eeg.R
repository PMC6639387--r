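# ---- plain-CSV dialect: time_s, fp1_uV, fp2_uV ------------------------------

#' Write a recording as two-column CSV
#'
#' Columns `time_s, fp1_uV, fp2_uV`; exact text round-trip with
#' [read_eeg()].
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  as_recording_check(rec)
  fmt <- function(v) sprintf("%.17g", v)   # lossless double round-trip
  d <- data.frame(time_s = fmt((seq_len(n_samples(rec)) - 1) / rec$fs),
                  fp1_uV = fmt(rec$signals[, 1]),
                  fp2_uV = fmt(rec$signals[, 2]))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_eeg_csv <- function(path) {
  d <- read.csv(path)
  names(d) <- tolower(names(d))
  i1 <- grep("fp1", names(d)); i2 <- grep("fp2", names(d))
  if (length(i1) != 1L || length(i2) != 1L)
    stop("missing channel: CSV must contain fp1 and fp2 columns", call. = FALSE)
  if (!"time_s" %in% names(d)) stop("CSV lacks a 'time_s' column", call. = FALSE)
  dt <- median(diff(d$time_s))
  if (!is.finite(dt) || dt <= 0) stop("invalid time axis", call. = FALSE)
  eeg_recording(cbind(Fp1 = d[[i1]], Fp2 = d[[i2]]),
                fs = round(1 / dt, 6),
                subject_id = sub("\\.[^.]*$", "", basename(path)))
}

# ---- minimal 16-bit EDF ----------------------------------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal) followed by
# little-endian int16 samples, record-interleaved per signal.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: 16-bit samples, two signals
#' labelled `EEG Fp1` / `EEG Fp2` with physical dimension uV. One-second
#' data records are used when the sample count divides evenly by the
#' sampling rate, otherwise a single record holds the whole signal.
#' Voltages are quantized to the 16-bit grid spanning the (symmetric)
#' physical range, so a round-trip agrees within half a quantization step.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param phys_max symmetric physical range in microvolts; defaults to the
#'   recording's absolute maximum (at least 1).
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path, phys_max = NULL) {
  as_recording_check(rec)
  n <- n_samples(rec); fs <- rec$fs
  if (n %% fs == 0 && fs == round(fs)) {
    n_rec <- n / fs; rec_dur <- 1; spr <- fs
  } else {
    n_rec <- 1; rec_dur <- n / fs; spr <- n
  }
  pm <- phys_max %||% max(1, max(abs(rec$signals)))
  pm <- signif(pm * 1.000001, 6)
  ns <- 2L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(if (is.na(rec$subject_id)) "X" else rec$subject_id, 80),
    edf_field("Startdate 01-JAN-2020", 80),
    edf_field("01.01.20", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(format(rec_dur, digits = 6), 8),
    edf_field(ns, 4))
  sig_hdr <- paste0(
    edf_field("EEG Fp1", 16), edf_field("EEG Fp2", 16),
    edf_field("AgAgCl electrode", 80), edf_field("AgAgCl electrode", 80),
    edf_field("uV", 8), edf_field("uV", 8),
    edf_field(-pm, 8), edf_field(-pm, 8),
    edf_field(pm, 8), edf_field(pm, 8),
    edf_field(-32768, 8), edf_field(-32768, 8),
    edf_field(32767, 8), edf_field(32767, 8),
    edf_field("", 80), edf_field("", 80),
    edf_field(spr, 8), edf_field(spr, 8),
    edf_field("", 32), edf_field("", 32))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (2 * pm) / (32767 - (-32768))
  dig <- round((rec$signals + pm) / scale) - 32768
  dig <- pmax(pmin(dig, 32767), -32768)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in 1:2)
      writeBin(as.integer(dig[idx, ch]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < w)
      stop("truncated EDF header", call. = FALSE)
    trimws(out)
  }
  rd(8)                                   # version
  subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per_sig <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- per_sig(16); per_sig(80)
  dims <- per_sig(8)
  pmin_ <- as.numeric(per_sig(8)); pmax_ <- as.numeric(per_sig(8))
  dmin_ <- as.numeric(per_sig(8)); dmax_ <- as.numeric(per_sig(8))
  per_sig(80)
  spr <- as.integer(per_sig(8)); per_sig(32)
  i1 <- grep("fp1", labels, ignore.case = TRUE)
  i2 <- grep("fp2", labels, ignore.case = TRUE)
  if (length(i1) != 1L || length(i2) != 1L)
    stop("missing channel: EDF must contain Fp1 and Fp2 signals", call. = FALSE)
  for (i in c(i1, i2))
    if (!grepl("uv", dims[i], ignore.case = TRUE))
      stop("unit mismatch: expected microvolt (uV) signals", call. = FALSE)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) for (i in seq_len(ns)) {
    v <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                 signed = TRUE)
    if (length(v) < spr[i]) stop("truncated EDF data", call. = FALSE)
    raw[[i]][[r]] <- v
  }
  tophys <- function(i) {
    v <- unlist(raw[[i]], use.names = FALSE)
    pmin_[i] + (v - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
  }
  fs <- spr[i1] / rec_dur
  eeg_recording(cbind(Fp1 = tophys(i1), Fp2 = tophys(i2)), fs = fs,
                subject_id = if (nzchar(subject)) subject else
                  sub("\\.[^.]*$", "", basename(path)))
}

#' Read a two-channel EEG recording
#'
#' Reads EDF or the package's two-column CSV dialect; the format defaults
#' to the file extension. Channel labels are matched case-insensitively to
#' Fp1/Fp2 and EDF voltages must be in microvolts.
#'
#' @param path input file.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") read_eeg_edf(path) else read_eeg_csv(path)
}
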