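# Tabular and binary I/O: BIDS-style events/channels TSV, per-frame feature
# CSV, raw signal as float32 little-endian binary + JSON sidecar.

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid(what, " ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
  df
}

#' Read and write BIDS-style events TSV
#'
#' Columns: `onset`, `duration`, `trial_type`, `block_index`,
#' `features_present`.
#'
#' @param schedule block schedule `data.frame`.
#' @param path file path.
#' @return `write_events_tsv` the path, invisibly; `read_events_tsv` the
#'   schedule `data.frame`.
#' @export
write_events_tsv <- function(schedule, path) write_tsv_file(schedule, path)

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read_tsv_checked(path, c("onset", "duration", "trial_type",
                                 "block_index", "features_present"),
                         "events TSV")
  df$features_present <- as.logical(df$features_present)
  df
}

#' Read and write BIDS-style channels TSV
#'
#' Columns: `name`, `region` (`DLPFC`/`pSTC`/`other`), `status`
#' (`good`/`bad`); bad channels are excluded from referencing and analysis.
#'
#' @param channels `data.frame` with the three columns above.
#' @param path file path.
#' @export
write_channels_tsv <- function(channels, path) write_tsv_file(channels, path)

#' @rdname write_channels_tsv
#' @export
read_channels_tsv <- function(path)
  read_tsv_checked(path, c("name", "region", "status"), "channels TSV")

#' Read and write per-frame facial-feature CSV
#'
#' Columns: `time_s`, `face_id`, then one column per emotion feature.
#'
#' @param face_table per-frame per-face score table.
#' @param path file path.
#' @param feature_names required feature columns.
#' @export
write_features_csv <- function(face_table, path) {
  utils::write.csv(face_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path,
                              feature_names = emotion_feature_set()$names) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_s", "face_id", feature_names), names(df))
  if (length(missing))
    stop_invalid("features CSV ", path, " is missing column(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
  df
}

#' Write and read a raw recording as float32 binary plus JSON sidecar
#'
#' The `.bin` file holds the `[n_channels x n_samples]` signal in
#' little-endian float32, sample-major (all channels of sample 1, then
#' sample 2, ...). The `.json` sidecar records `fs`, `n_channels`,
#' `n_samples`, `channel_names`, `channel_regions`, `bad_channels`.
#'
#' @param session a [recording_session()].
#' @param path_base path without extension; `.bin` and `.json` are appended.
#' @return `write_raw_binary` the base path, invisibly; `read_raw_binary`
#'   the reconstructed `recording_session` (float32 precision).
#' @export
write_raw_binary <- function(session, path_base) {
  con <- file(paste0(path_base, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(session$signal), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(fs = session$fs, n_channels = nrow(session$signal),
         n_samples = ncol(session$signal),
         channel_names = session$channel_names,
         channel_regions = session$channel_regions,
         bad_channels = session$bad_channels,
         dtype = "float32", byte_order = "little", order = "sample_major"),
    paste0(path_base, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path_base)
}

#' @rdname write_raw_binary
#' @export
read_raw_binary <- function(path_base) {
  meta <- jsonlite::read_json(paste0(path_base, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(path_base, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  sig <- matrix(x, nrow = meta$n_channels, ncol = meta$n_samples)
  recording_session(sig, fs = meta$fs, channel_names = meta$channel_names,
                    channel_regions = meta$channel_regions,
                    bad_channels = as.character(meta$bad_channels %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cohort metadata TSV
#'
#' One row per participant: `id`, `age`, `group`, per-area contact counts.
#'
#' @param metadata metadata `data.frame` (e.g. from [generate_cohort()]).
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) write_tsv_file(metadata, path)

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path)
  read_tsv_checked(path, c("id", "age", "group"), "metadata TSV")
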