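#' Construct a longitudinal multimodal sensing panel
#'
#' A panel holds long-format per-participant, per-week sensor feature
#' observations tagged by modality, plus a weekly ground-truth severity score
#' (PHQ-9-like, integer 0-27). It is the universe every stage of the framework
#' consumes: fusion builds wide matrices from it, the split planners enumerate
#' its (participant, week) slots, and the change-score transform derives the
#' regression target.
#'
#' Participant, time-unit and modality orderings are fixed at construction
#' (order of first appearance in the input) so that every downstream tensor
#' slot address is deterministic.
#'
#' @param features data.frame with columns `participant`, `time_unit`
#'   (1-based integer week), `modality`, `feature`, `value`. An `NA` value
#'   marks a missing observation; an exact 0 is a real (sparse) reading.
#' @param scores data.frame with columns `participant`, `time_unit`, `score`
#'   (integer in 0-27).
#' @param modalities optional character vector restricting/ordering the
#'   allowed modalities; rows with a modality outside this set are an error.
#' @return an object of class `flms_panel`: a list with elements `features`,
#'   `scores`, `participants`, `time_units`, `modalities`, `feature_names`
#'   (named list, modality -> ordered feature names).
#' @export
flms_panel <- function(features, scores, modalities = NULL) {
  req_f <- c("participant", "time_unit", "modality", "feature", "value")
  req_s <- c("participant", "time_unit", "score")
  if (!is.data.frame(features) || !all(req_f %in% names(features)))
    stop("features must be a data.frame with columns ",
         paste(req_f, collapse = ", "))
  if (!is.data.frame(scores) || !all(req_s %in% names(scores)))
    stop("ground truth must be a data.frame with columns ",
         paste(req_s, collapse = ", "))
  if (nrow(features) == 0L) stop("no observations in feature table")

  features <- data.frame(
    participant = as.character(features$participant),
    time_unit   = as.integer(features$time_unit),
    modality    = as.character(features$modality),
    feature     = as.character(features$feature),
    value       = as.numeric(features$value),
    stringsAsFactors = FALSE
  )
  scores <- data.frame(
    participant = as.character(scores$participant),
    time_unit   = as.integer(scores$time_unit),
    score       = scores$score,
    stringsAsFactors = FALSE
  )
  if (anyNA(features$time_unit) || anyNA(scores$time_unit))
    stop("malformed time_unit: not an integer")

  bad <- which(!is.finite(scores$score) | scores$score != round(scores$score) |
                 scores$score < 0 | scores$score > 27)
  if (length(bad))
    stop("ground-truth score outside [0, 27] or non-integer at row ",
         bad[1L], " (score = ", scores$score[bad[1L]], ")")
  scores$score <- as.integer(scores$score)

  key <- paste(features$participant, features$time_unit,
               features$modality, features$feature, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, time_unit, modality, feature) row: ",
         gsub("\r", " / ", key[which(duplicated(key))[1L]]))
  skey <- paste(scores$participant, scores$time_unit, sep = "\r")
  if (anyDuplicated(skey))
    stop("duplicate (participant, time_unit) ground-truth row")

  mods_seen <- unique(features$modality)
  if (is.null(modalities)) {
    modalities <- mods_seen
  } else {
    unknown <- setdiff(mods_seen, modalities)
    if (length(unknown))
      stop("unknown modality in feature table: ",
           paste(unknown, collapse = ", "))
  }

  participants <- unique(c(features$participant, scores$participant))
  time_units <- sort(unique(c(features$time_unit, scores$time_unit)))

  feature_names <- lapply(modalities, function(m) {
    unique(features$feature[features$modality == m])
  })
  names(feature_names) <- modalities

  structure(
    list(features = features, scores = scores,
         participants = participants, time_units = time_units,
         modalities = modalities, feature_names = feature_names),
    class = "flms_panel"
  )
}

#' @export
print.flms_panel <- function(x, ...) {
  cat("<flms_panel> ", length(x$participants), " participants, ",
      length(x$time_units), " time units, ",
      length(x$modalities), " modalities (",
      sum(lengths(x$feature_names)), " features), ",
      nrow(x$scores), " ground-truth scores\n", sep = "")
  invisible(x)
}

#' Read a panel from tidy CSV files
#'
#' @param features_path CSV with columns participant, time_unit, modality,
#'   feature, value.
#' @param ground_truth_path CSV with columns participant, time_unit, score.
#' @param modalities optional allowed modality set (see [flms_panel()]).
#' @return an `flms_panel`.
#' @export
read_panel <- function(features_path, ground_truth_path, modalities = NULL) {
  feats <- utils::read.csv(features_path, stringsAsFactors = FALSE)
  truth <- utils::read.csv(ground_truth_path, stringsAsFactors = FALSE)
  flms_panel(feats, truth, modalities = modalities)
}

#' Write a panel back to tidy CSV files
#'
#' Inverse of [read_panel()]: writing then reading reproduces the panel
#' exactly (values, orderings, missingness).
#'
#' @param panel an `flms_panel`.
#' @param features_path,ground_truth_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, features_path, ground_truth_path) {
  stopifnot(inherits(panel, "flms_panel"))
  utils::write.csv(panel$features, features_path, row.names = FALSE, na = "")
  utils::write.csv(panel$scores, ground_truth_path, row.names = FALSE, na = "")
  invisible(c(features_path, ground_truth_path))
}

#' Week-over-week change scores
#'
#' Derives the regression target: the change in severity score at week m,
#' `score(m) - score(m-1)`, defined only where both weeks are observed and
#' consecutive. The first scored week of a participant yields no change, and
#' changes are never differenced across gaps (a 2-week jump is not a weekly
#' change).
#'
#' @param panel an `flms_panel`.
#' @return data.frame `participant`, `time_unit` (the week m of the change),
#'   `change` (integer in -27..27), ordered by panel participant order then
#'   time. Class `flms_changes`.
#' @export
change_scores <- function(panel) {
  stopifnot(inherits(panel, "flms_panel"))
  sc <- panel$scores
  out <- lapply(panel$participants, function(p) {
    s <- sc[sc$participant == p, , drop = FALSE]
    if (nrow(s) < 2L) return(NULL)
    s <- s[order(s$time_unit), , drop = FALSE]
    consec <- which(diff(s$time_unit) == 1L)
    if (!length(consec)) return(NULL)
    data.frame(participant = p,
               time_unit = s$time_unit[consec + 1L],
               change = s$score[consec + 1L] - s$score[consec],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("no modellable targets: no participant has two consecutive scored weeks")
  rownames(out) <- NULL
  class(out) <- c("flms_changes", "data.frame")
  out
}

# Change scores as a participants x time_units matrix (NA = no target slot).
change_matrix <- function(panel, changes = change_scores(panel)) {
  m <- matrix(NA_real_, length(panel$participants), length(panel$time_units),
              dimnames = list(panel$participants, panel$time_units))
  m[cbind(match(changes$participant, panel$participants),
          match(changes$time_unit, panel$time_units))] <- changes$change
  m
}

#' Modality-level tensor view of a panel
#'
#' Stacks the panel into a Z x participants x weeks array (Z = number of
#' modalities), each cell the mean feature value of that modality for that
#' participant-week, `NA` where unobserved. This is the tensor-form view of
#' the data used by the aggregation and ranking stages.
#'
#' @param panel an `flms_panel`.
#' @return a 3-d numeric array with dimnames (modality, participant, time unit).
#' @export
sensor_tensor <- function(panel) {
  arr <- array(NA_real_,
               dim = c(length(panel$modalities), length(panel$participants),
                       length(panel$time_units)),
               dimnames = list(panel$modalities, panel$participants,
                               panel$time_units))
  f <- panel$features
  agg <- stats::aggregate(value ~ modality + participant + time_unit,
                          data = f, FUN = mean, na.rm = TRUE, na.action = NULL)
  idx <- cbind(match(agg$modality, panel$modalities),
               match(agg$participant, panel$participants),
               match(agg$time_unit, panel$time_units))
  arr[idx] <- ifelse(is.nan(agg$value), NA_real_, agg$value)
  arr
}
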