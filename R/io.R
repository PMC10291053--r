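# On-disk trial formats: delimited long-format time series and a minimal
# EDF (European Data Format) writer/reader. Stream layout on disk:
# rest segment first, film segment after it; the split point is carried
# in the manifest / EDF recording-id field.

# flatten a trial's streams to channel vectors with labels and rates
.trial_channels <- function(trial) {
  out <- list()
  for (snm in names(trial$streams)) {
    s <- trial$streams[[snm]]
    film <- s$film; rest <- s$rest
    if (is.matrix(film)) {
      for (ch in colnames(film))
        out[[paste0(snm, ".", ch)]] <- list(stream = snm, channel = ch,
                                            sfreq = s$sfreq,
                                            x = c(rest[, ch], film[, ch]))
    } else {
      out[[snm]] <- list(stream = snm, channel = snm, sfreq = s$sfreq,
                         x = c(rest, film))
    }
  }
  out
}

.rebuild_trial <- function(chans, meta) {
  streams <- list()
  for (ch in chans) {
    snm <- ch$stream
    nr <- round(meta$rest_duration * ch$sfreq)
    if (is.null(streams[[snm]]))
      streams[[snm]] <- list(sfreq = ch$sfreq, rest = list(), film = list())
    streams[[snm]]$rest[[ch$channel]] <- ch$x[seq_len(nr)]
    streams[[snm]]$film[[ch$channel]] <- ch$x[(nr + 1):length(ch$x)]
  }
  for (snm in names(streams)) {
    s <- streams[[snm]]
    if (length(s$rest) > 1) {
      streams[[snm]]$rest <- do.call(cbind, s$rest)
      streams[[snm]]$film <- do.call(cbind, s$film)
    } else {
      streams[[snm]]$rest <- s$rest[[1]]
      streams[[snm]]$film <- s$film[[1]]
    }
  }
  structure(list(subject_id = meta$subject_id, film_id = meta$film_id,
                 genre = meta$genre, rating = meta$rating,
                 duration = meta$duration, rest_duration = meta$rest_duration,
                 sfreq = lapply(streams, `[[`, "sfreq"), streams = streams),
            class = "trial_recording")
}

#' Write a trial recording to disk
#'
#' `format = "delimited"` writes a tab-separated long-format file with
#' columns `time_s`, `stream`, `channel`, `value` (full double
#' precision; exact round-trip) plus a JSON sidecar `<path>.meta.json`
#' with identifiers, rates and the rest-segment duration.
#' `format = "edf"` writes a minimal EDF file (16-bit; round-trip exact
#' to the per-channel quantization step).
#'
#' @param trial a `trial_recording`.
#' @param path output file path.
#' @param format `"delimited"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  chans <- .trial_channels(trial)
  meta <- trial[c("subject_id", "film_id", "genre", "rating", "duration",
                  "rest_duration")]
  if (format == "delimited") {
    tabs <- lapply(chans, function(ch)
      data.table::data.table(time_s = (seq_along(ch$x) - 1) / ch$sfreq,
                             stream = ch$stream, channel = ch$channel,
                             # %.17g guarantees exact double round-trip
                             value = sprintf("%.17g", ch$x)))
    dt <- data.table::rbindlist(tabs)
    data.table::fwrite(dt, path, sep = "\t")
    meta$sfreq <- lapply(chans, `[[`, "sfreq")
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    .write_edf(chans, meta, path)
  }
  invisible(path)
}

#' Read a trial recording
#'
#' @param path file written by [write_trial()].
#' @param format `"delimited"` or `"edf"`.
#' @param streams optional character vector; error if any named stream
#'   is absent from the file.
#' @return a `trial_recording`.
#' @export
read_trial <- function(path, format = c("delimited", "edf"), streams = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                                simplifyVector = TRUE)
    dt <- data.table::fread(path, sep = "\t")
    need <- c("time_s", "stream", "channel", "value")
    if (!all(need %in% names(dt)))
      stop("malformed delimited trial: missing columns ",
           paste(setdiff(need, names(dt)), collapse = ", "))
    chans <- list()
    for (key in unique(paste(dt$stream, dt$channel, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sel <- dt$stream == parts[1] & dt$channel == parts[2]
      nm <- if (parts[1] == parts[2]) parts[1] else
        paste0(parts[1], ".", parts[2])
      chans[[nm]] <- list(stream = parts[1], channel = parts[2],
                          sfreq = meta$sfreq[[nm]],
                          x = as.numeric(dt$value[sel]))
    }
  } else {
    parsed <- .read_edf(path)
    chans <- parsed$chans
    meta <- parsed$meta
  }
  got <- unique(vapply(chans, `[[`, "", "stream"))
  if (!is.null(streams)) {
    missing_s <- setdiff(streams, got)
    if (length(missing_s) > 0)
      stop("stream(s) missing from file: ", paste(missing_s, collapse = ", "))
  }
  .rebuild_trial(chans, meta)
}

# ---- minimal EDF ---------------------------------------------------------

.pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

# one data record per second; samples per record = per-channel sfreq
.write_edf <- function(chans, meta, path) {
  ns <- length(chans)
  dur_total <- meta$duration + meta$rest_duration
  n_rec <- as.integer(ceiling(dur_total))
  labels <- names(chans)
  spr <- vapply(chans, function(ch) as.integer(round(ch$sfreq)), integer(1))
  pmin_ <- vapply(chans, function(ch) min(ch$x), numeric(1))
  pmax_ <- vapply(chans, function(ch) max(ch$x), numeric(1))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(.pad(s, n)), con)
  wr("0", 8)
  wr(paste("subject", meta$subject_id), 80)
  # recording field carries the metadata needed to rebuild the trial
  wr(sprintf("film=%s genre=%s rating=%d dur=%g rest=%g", meta$film_id,
             meta$genre, meta$rating, meta$duration, meta$rest_duration), 80)
  wr("01.01.21", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmin_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmax_[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(as.character(spr[i]), 8)
  for (i in seq_len(ns)) wr("", 32)
  # digitize
  dig <- lapply(seq_len(ns), function(i) {
    x <- chans[[i]]$x
    n_need <- n_rec * spr[i]
    if (length(x) < n_need) x <- c(x, rep(x[length(x)], n_need - length(x)))
    as.integer(round((x[seq_len(n_need)] - pmin_[i]) /
                       (pmax_[i] - pmin_[i]) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- dig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])]
      writeBin(seg, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)
  subj <- rd(80)
  recfield <- rd(80)
  rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    chunks[[r]] <- lapply(seq_len(ns), function(i)
      readBin(con, "integer", spr[i], size = 2, signed = TRUE,
              endian = "little"))
  }
  buf <- lapply(seq_len(ns), function(i)
    unlist(lapply(chunks, `[[`, i), use.names = FALSE))
  kv <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", recfield)
  meta <- list(subject_id = sub("^subject ", "", subj),
               film_id = kv("film"), genre = kv("genre"),
               rating = as.integer(kv("rating")),
               duration = as.numeric(kv("dur")),
               rest_duration = as.numeric(kv("rest")))
  chans <- list()
  for (i in seq_len(ns)) {
    x <- (buf[[i]] + 32768) / 65535 * (pmax_[i] - pmin_[i]) + pmin_[i]
    n_true <- round((meta$duration + meta$rest_duration) * spr[i] / rec_dur)
    x <- x[seq_len(min(n_true, length(x)))]
    nm <- labels[i]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      chans[[nm]] <- list(stream = parts[1], channel = parts[2],
                          sfreq = spr[i] / rec_dur, x = x)
    } else {
      chans[[nm]] <- list(stream = nm, channel = nm, sfreq = spr[i] / rec_dur,
                          x = x)
    }
  }
  list(chans = chans, meta = meta)
}
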