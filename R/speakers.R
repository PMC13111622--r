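# Speaker feature tables: per-recording embedding vectors plus speaker
# metadata (gender, mean F0). The canonical container is a long data frame
# with one row per recording and columns
#   speaker_id, gender, mean_f0_hz, recording_id, e0 ... e{D-1}
# which is also the on-disk CSV layout.

#' Assemble a speaker feature table
#'
#' @param speaker_id Character vector, one entry per recording.
#' @param gender Character vector (`"male"`/`"female"`), per recording;
#'   must be constant within speaker.
#' @param mean_f0_hz Numeric vector of speaker mean fundamental frequency
#'   in Hz (> 0), constant within speaker.
#' @param recording_id Character vector of unique recording identifiers.
#' @param embeddings Numeric matrix, one row per recording, `D >= 2`
#'   columns. Unit norm is not required.
#' @return A `data.frame` of class `speaker_features`.
#' @export
speaker_features <- function(speaker_id, gender, mean_f0_hz, recording_id,
                             embeddings) {
  embeddings <- as.matrix(embeddings)
  n <- length(speaker_id)
  stopifnot(length(gender) == n, length(mean_f0_hz) == n,
            length(recording_id) == n, nrow(embeddings) == n)
  df <- data.frame(speaker_id = as.character(speaker_id),
                   gender = as.character(gender),
                   mean_f0_hz = as.numeric(mean_f0_hz),
                   recording_id = as.character(recording_id),
                   stringsAsFactors = FALSE)
  colnames(embeddings) <- paste0("e", seq_len(ncol(embeddings)) - 1L)
  df <- cbind(df, as.data.frame(embeddings))
  class(df) <- c("speaker_features", "data.frame")
  validate_speaker_features(df)
  df
}

embedding_cols <- function(features) {
  grep("^e[0-9]+$", colnames(features), value = TRUE)
}

#' @keywords internal
validate_speaker_features <- function(features) {
  req <- c("speaker_id", "gender", "mean_f0_hz", "recording_id")
  missing_cols <- setdiff(req, colnames(features))
  if (length(missing_cols) > 0)
    abort("feature table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  ecols <- embedding_cols(features)
  if (length(ecols) < 2)
    abort("embeddings must have dimension D >= 2 (found %d embedding column(s))",
          length(ecols))
  emb <- as.matrix(features[, ecols])
  if (!is.numeric(emb) || anyNA(emb))
    abort("embedding columns must be numeric and complete")
  if (anyDuplicated(features$recording_id))
    abort("recording_id values must be unique")
  bad_f0 <- !is.finite(features$mean_f0_hz) | features$mean_f0_hz <= 0
  if (any(bad_f0))
    abort("non-positive or missing mean F0 for speaker(s): %s",
          paste(unique(features$speaker_id[bad_f0]), collapse = ", "))
  # gender and F0 constant within speaker
  for (sp in unique(features$speaker_id)) {
    rows <- features[features$speaker_id == sp, ]
    if (length(unique(rows$gender)) > 1 ||
        length(unique(rows$mean_f0_hz)) > 1)
      abort("gender and mean F0 must be constant within speaker '%s'", sp)
  }
  invisible(features)
}

#' Read a speaker feature table from CSV
#'
#' Expects columns `speaker_id, gender, mean_f0_hz, recording_id,
#' e0..e{D-1}`.
#'
#' @param path Path to a CSV file.
#' @return A `speaker_features` data frame.
#' @export
read_speaker_features <- function(path) {
  if (!file.exists(path))
    abort("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$speaker_id <- as.character(df$speaker_id)
  df$recording_id <- as.character(df$recording_id)
  class(df) <- c("speaker_features", "data.frame")
  validate_speaker_features(df)
  df
}

#' Write a speaker feature table to CSV
#'
#' @param features A `speaker_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speaker_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# per-speaker summary: one row per speaker with gender and mean F0
speaker_summary <- function(features) {
  unique(features[, c("speaker_id", "gender", "mean_f0_hz")])
}
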