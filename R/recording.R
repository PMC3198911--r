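#' Canonical SEMG channel names
#'
#' Ordered electrode placement labels for the eight forearm muscles monitored
#' by surface electrodes: four wrist extensors followed by four wrist flexors.
#'
#' @format Character vector of length 8.
#' @export
semg_channels <- c("ECRL", "EDC", "ECU", "ECRB", "FCR", "PL", "FDS", "FCU")

#' Construct a raw multichannel SEMG + torque recording
#'
#' Bundles an M-channel SEMG matrix (volts) with the simultaneously sampled
#' wrist torque series (N·m, flexion positive, extension negative) and the
#' session/posture metadata needed by the experiment harness.
#'
#' @param semg Numeric matrix, samples x channels, in volts.
#' @param torque Numeric vector of wrist torque, N·m, same length as `semg`
#'   rows. Flexion positive, extension negative.
#' @param sample_rate_hz Sampling rate in Hz (nominally 1000).
#' @param channel_names Unique channel labels, one per SEMG column.
#' @param session_id One of `"s1"`, `"s2"`, `"s3"`.
#' @param posture One of `"pronated"`, `"supinated"`.
#' @param subject_id Subject label.
#' @return An object of class `semg_recording`.
#' @export
recording <- function(semg, torque, sample_rate_hz = 1000,
                      channel_names = semg_channels,
                      session_id = "s1", posture = "pronated",
                      subject_id = "subject") {
  semg <- as.matrix(semg)
  torque <- as.numeric(torque)
  if (nrow(semg) < 1L) stop("recording must contain at least one sample")
  if (nrow(semg) != length(torque))
    stop("semg and torque must have the same number of samples")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  if (length(channel_names) != ncol(semg))
    stop("one channel name per SEMG column required")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  session_id <- match.arg(session_id, c("s1", "s2", "s3"))
  posture <- match.arg(posture, c("pronated", "supinated"))
  colnames(semg) <- channel_names
  structure(
    list(semg = semg, torque = torque,
         sample_rate_hz = as.numeric(sample_rate_hz),
         channel_names = channel_names,
         session_id = session_id, posture = posture,
         subject_id = subject_id),
    class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %s / %s / %s: %d samples @ %g Hz, %d channels\n",
              x$subject_id, x$session_id, x$posture,
              nrow(x$semg), x$sample_rate_hz, ncol(x$semg)))
  invisible(x)
}

n_samples <- function(x) length(x$torque)

#' Write a recording to CSV with a JSON sidecar
#'
#' The CSV holds columns `time_s`, `ch1..chM`, `torque_nm`; the sidecar holds
#' `sample_rate_hz`, `subject_id`, `session_id`, `posture` and the ordered
#' `channel_names`.
#'
#' @param rec A `semg_recording`.
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; default replaces the CSV extension with
#'   `.json`.
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(rec, csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- n_samples(rec)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate_hz)
  semg <- rec$semg
  for (j in seq_len(ncol(semg))) df[[paste0("ch", j)]] <- semg[, j]
  df$torque_nm <- rec$torque
  write.csv(df, csv_path, row.names = FALSE)
  meta <- list(sample_rate_hz = rec$sample_rate_hz,
               subject_id = rec$subject_id,
               session_id = rec$session_id,
               posture = rec$posture,
               channel_names = rec$channel_names)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param csv_path CSV path.
#' @param json_path Sidecar path; default replaces the CSV extension.
#' @return A `semg_recording`.
#' @export
read_recording <- function(csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  ch_cols <- ch_cols[order(as.integer(sub("^ch", "", ch_cols)))]
  recording(as.matrix(df[ch_cols]), df$torque_nm,
            sample_rate_hz = meta$sample_rate_hz,
            channel_names = meta$channel_names,
            session_id = meta$session_id,
            posture = meta$posture,
            subject_id = meta$subject_id)
}

#' Construct a processed (envelope) recording
#'
#' Holds per-channel normalized activation envelopes in \[0, 1\], the
#' untouched torque series, and the provenance of applied processing steps.
#'
#' @param envelopes Numeric matrix, samples x channels, values in \[0, 1\].
#' @param torque Torque series, N·m.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param provenance Character vector of applied steps, in order.
#' @param meta Optional metadata list carried over from the raw recording.
#' @return An object of class `processed_recording`.
#' @export
processed_recording <- function(envelopes, torque, sample_rate_hz,
                                provenance = character(), meta = list()) {
  envelopes <- as.matrix(envelopes)
  if (nrow(envelopes) != length(torque))
    stop("envelopes and torque must have the same length")
  if (any(envelopes < -1e-9) || any(envelopes > 1 + 1e-9))
    stop("envelope values must lie in [0, 1]")
  structure(
    list(envelopes = envelopes, torque = as.numeric(torque),
         sample_rate_hz = as.numeric(sample_rate_hz),
         provenance = provenance, meta = meta),
    class = "processed_recording")
}

#' @export
print.processed_recording <- function(x, ...) {
  cat(sprintf("<processed_recording> %d samples @ %g Hz, %d channels [%s]\n",
              nrow(x$envelopes), x$sample_rate_hz, ncol(x$envelopes),
              paste(x$provenance, collapse = " > ")))
  invisible(x)
}

# Contiguous slice of a processed recording (sample index range).
slice_processed <- function(pr, from, to) {
  processed_recording(pr$envelopes[from:to, , drop = FALSE],
                      pr$torque[from:to], pr$sample_rate_hz,
                      pr$provenance, pr$meta)
}

# Column subset by channel name.
subset_channels <- function(pr, channels) {
  missing <- setdiff(channels, colnames(pr$envelopes))
  if (length(missing))
    stop("channels not present in recording: ", paste(missing, collapse = ", "))
  processed_recording(pr$envelopes[, channels, drop = FALSE],
                      pr$torque, pr$sample_rate_hz, pr$provenance, pr$meta)
}
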