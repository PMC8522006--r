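# Minimal EDF (European Data Format) reader/writer for continuous
# multi-channel recordings: 256-byte ASCII header + 256 bytes per signal,
# then 16-bit little-endian samples in fixed-duration data records.
# Only the plain continuous layout is supported (no annotations channel),
# which is all the pipeline needs as a binary carrier.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

# Represent a physical limit in at most 8 ASCII characters and return the
# value the ASCII actually encodes, so writer and reader agree exactly.
edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = -1)
    if (nchar(s) <= 8 && is.finite(as.numeric(s))) {
      return(list(str = s, value = as.numeric(s)))
    }
  }
  stop_earsleep("cannot represent physical limit in 8 characters",
                "earsleep_format_error")
}

write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop_earsleep("EDF writer requires an integer sampling rate (1 s records)",
                  "earsleep_format_error")
  }
  fs <- as.integer(round(fs))
  n <- nrow(rec$data)
  nsig <- ncol(rec$data)
  nrec <- as.integer(ceiling(n / fs))
  if (nrec < 1L) {
    stop_earsleep("recording has no samples", "earsleep_integrity_error")
  }

  dmin <- -32768L; dmax <- 32767L
  pmin_s <- character(nsig); pmax_s <- character(nsig)
  pmin_v <- numeric(nsig);  pmax_v <- numeric(nsig)
  for (j in seq_len(nsig)) {
    amp <- max(abs(rec$data[, j]), na.rm = TRUE)
    if (!is.finite(amp) || amp == 0) amp <- 1
    lim <- edf_num8(amp * 1.0001)  # headroom so rounding never clips
    pmax_s[j] <- lim$str;            pmax_v[j] <- lim$value
    neg <- edf_num8(-lim$value)
    pmin_s[j] <- neg$str;            pmin_v[j] <- neg$value
  }

  start <- rec$start_time
  if (is.null(start)) {
    date_s <- "01.01.00"; time_s <- "00.00.00"
  } else {
    date_s <- format(start, "%d.%m.%y"); time_s <- format(start, "%H.%M.%S")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad(date_s, 8),
    edf_pad(time_s, 8),
    edf_pad(256L * (1L + nsig), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(nsig, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(
    hdr,
    field(rec$channel_labels, 16),
    field(rep("", nsig), 80),
    field(rep("uV", nsig), 8),
    field(pmin_s, 8),
    field(pmax_s, 8),
    field(rep(dmin, nsig), 8),
    field(rep(dmax, nsig), 8),
    field(rep("", nsig), 80),
    field(rep(fs, nsig), 8),
    field(rep("", nsig), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # digitize; pad the trailing partial second with zeros
  total <- nrec * fs
  dig <- matrix(0L, nrow = total, ncol = nsig)
  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  for (j in seq_len(nsig)) {
    d <- as.integer(round((rec$data[, j] - pmin_v[j]) * scale[j]) + dmin)
    d[d < dmin] <- dmin; d[d > dmax] <- dmax
    zero <- as.integer(round((0 - pmin_v[j]) * scale[j]) + dmin)
    col <- rep.int(zero, total)
    col[seq_len(n)] <- d
    dig[, j] <- col
  }
  # record-major layout: per record, each signal's fs samples in turn
  out <- integer(total * nsig)
  pos <- 0L
  block <- fs * nsig
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    out[(pos + 1L):(pos + block)] <- as.integer(dig[rows, , drop = FALSE])
    pos <- pos + block
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (length(s) == 0L) {
      stop_earsleep("truncated EDF header", "earsleep_format_error")
    }
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") {
    stop_earsleep(sprintf("not an EDF file (version field '%s')", version),
                  "earsleep_format_error")
  }
  rd(80); rd(80)
  date_s <- rd(8); time_s <- rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (is.na(nsig) || nsig < 1L || is.na(nrec) || nrec < 1L ||
      is.na(rec_dur) || rec_dur <= 0) {
    stop_earsleep("malformed EDF header (records/signals/duration)",
                  "earsleep_format_error")
  }
  rdv <- function(w) vapply(seq_len(nsig), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)                    # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)) || any(pmax <= pmin) ||
      any(dmax <= dmin) || any(spr < 1L)) {
    stop_earsleep("malformed EDF signal headers", "earsleep_format_error")
  }
  if (hdr_bytes != 256L * (1L + nsig)) {
    stop_earsleep("EDF header byte count inconsistent with signal count",
                  "earsleep_format_error")
  }
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1L) {
    stop_earsleep("signals with differing sampling rates are not supported",
                  "earsleep_integrity_error")
  }
  per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = nrec * per_rec, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) != nrec * per_rec) {
    stop_earsleep("EDF data section shorter than header declares",
                  "earsleep_integrity_error")
  }
  m <- matrix(raw, nrow = per_rec, ncol = nrec)
  ends <- cumsum(spr)
  starts <- ends - spr + 1L
  data <- matrix(0, nrow = nrec * spr[1L], ncol = nsig)
  for (j in seq_len(nsig)) {
    dig <- as.vector(m[starts[j]:ends[j], , drop = FALSE])
    data[, j] <- (dig - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j]) +
      pmin[j]
  }
  colnames(data) <- labels
  start_time <- tryCatch(
    as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL
  )
  if (!is.null(start_time) && is.na(start_time)) start_time <- NULL
  recording(data, fs = fs[1L], start_time = start_time)
}

# One digitization step of the stored physical range; the worst-case
# absolute round-trip error of write_edf/read_edf per sample.
edf_quantization_step <- function(physical_max, physical_min = -physical_max,
                                  digital_max = 32767, digital_min = -32768) {
  (physical_max - physical_min) / (digital_max - digital_min)
}
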