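#' Mean-aggregate prediction tensors
#'
#' Combines the prediction tensors of several fusion combinations of one
#' strategy into a single tensor by the element-wise mean over the tensors
#' predicting each slot (e.g. the 6 five-modality combinations of a
#' 6-modality study collapse into one aggregate). The output mask is the
#' union of the input masks, and every aggregated value lies within the
#' range of its contributors.
#'
#' @param cubes list of numeric matrices with identical dimensions
#'   (`NA` = unpredicted slot).
#' @return a numeric matrix of the same shape.
#' @export
aggregate_mean <- function(cubes) {
  if (!length(cubes)) stop("no tensors to aggregate")
  d <- dim(cubes[[1L]])
  for (m in cubes)
    if (!identical(dim(m), d)) stop("tensor axis mismatch in aggregation")
  s <- Reduce(`+`, lapply(cubes, function(m) ifelse(is.na(m), 0, m)))
  n <- Reduce(`+`, lapply(cubes, function(m) !is.na(m)))
  out <- s / n
  out[n == 0L] <- NA_real_
  dimnames(out) <- dimnames(cubes[[1L]])
  out
}

#' Encode regressed change to binary labels
#'
#' The classification rule applied to both predictions and ground truth:
#' a regressed (or true) change of zero or a negative value encodes to 0, a
#' positive value to 1. Idempotent on 0/1. `NA` passes through (unmasked
#' slots); non-finite values are an error.
#'
#' @param value numeric vector, matrix, or array.
#' @return integer 0/1 object of the same shape.
#' @export
encode_change <- function(value) {
  v <- value
  bad <- is.nan(v) | (!is.na(v) & !is.finite(v))
  if (any(bad)) stop("cannot encode non-finite prediction value")
  out <- ifelse(is.na(v), NA_integer_, as.integer(v > 0))
  if (!is.null(dim(value))) {
    dim(out) <- dim(value)
    dimnames(out) <- dimnames(value)
  }
  out
}

#' Aggregated hamming distance to ground truth
#'
#' The ranking statistic: the number of masked slots where an encoded
#' prediction tensor disagrees with the encoded truth tensor. Slots the
#' candidate does not predict (`NA`) are excluded.
#'
#' @param encoded 0/1 matrix with `NA` mask.
#' @param truth 0/1 matrix of the same shape.
#' @return nonnegative integer.
#' @export
hamming_distance <- function(encoded, truth) {
  if (!identical(dim(encoded), dim(truth)))
    stop("shape mismatch between prediction and truth tensors")
  ok <- !is.na(encoded) & !is.na(truth)
  sum(encoded[ok] != truth[ok])
}

#' Rank candidate prediction tensors
#'
#' Orders candidates ascending by aggregated hamming distance; ties break by
#' smaller fusion cardinality, then lexicographic scope identity. Within each
#' strategy the minimum-distance candidate is flagged `chosen` — the
#' candidate whose distance sets that strategy's ensemble weight.
#'
#' @param records data.frame with columns `strategy`, `scope` (fusion
#'   identity or `agg:x` cardinality-aggregate label), `cardinality`,
#'   `distance`.
#' @return the data.frame sorted, with `rank` and logical `chosen` columns.
#' @export
rank_candidates <- function(records) {
  req <- c("strategy", "scope", "cardinality", "distance")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) stop("no candidates to rank")
  if (any(records$distance < 0)) stop("negative hamming distance")
  o <- order(records$distance, records$cardinality, records$scope)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$chosen <- FALSE
  for (s in unique(out$strategy)) {
    out$chosen[which(out$strategy == s)[1L]] <- TRUE  # already sorted
  }
  rownames(out) <- NULL
  out
}

#' Strategy weights from minimum hamming distances
#'
#' Converts each strategy's minimum hamming distance into an ensemble
#' weight, strictly decreasing in distance and summing to one. The default
#' is normalized inverse distance, `w_k = (1/(D_k + eps)) / sum_j
#' (1/(D_j + eps))`; `"softmax"` uses a softmax of negative distances.
#'
#' @param min_distances named nonnegative numeric vector, one per strategy.
#' @param weighting `"inverse"` or `"softmax"`.
#' @param epsilon guard added before inversion.
#' @return named weights summing to 1.
#' @export
compute_weights <- function(min_distances, weighting = c("inverse", "softmax"),
                            epsilon = 1e-9) {
  weighting <- match.arg(weighting)
  d <- min_distances
  if (!length(d)) stop("no distances")
  if (any(is.na(d)) || any(d < 0)) stop("distances must be nonnegative")
  w <- switch(weighting,
              inverse = 1 / (d + epsilon),
              softmax = exp(-(d - min(d))))
  w / sum(w)
}

#' Weighted ensemble of per-strategy tensors
#'
#' The final stage: fuses the chosen per-strategy encoded tensors into one
#' fractional tensor `P = sum_k w_k e_k` and re-encodes it to 0/1. Where a
#' strategy predicts no value for a slot (e.g. the forecasting strategy has
#' no early-week predictions) the weights renormalize over the strategies
#' that do; a slot no strategy covers stays unmasked. A fused value of
#' exactly 0.5 resolves by `tie_rule` (`"half_up"` to 1, the default).
#'
#' @param chosen named list of per-strategy tensors (0/1, or raw regression
#'   values when ensembling raw predictions), identical shapes, `NA` mask.
#' @param weights named weights from [compute_weights()] (same names).
#' @param tie_rule `"half_up"` or `"half_down"`.
#' @return list of class `flms_ensemble`: `fused` (fractional tensor),
#'   `final` (0/1 tensor), `weights`, `tie_rule`.
#' @export
weighted_ensemble <- function(chosen, weights, tie_rule = c("half_up", "half_down")) {
  tie_rule <- match.arg(tie_rule)
  if (!length(chosen)) stop("no strategy tensors to ensemble")
  if (is.null(names(chosen)) || !setequal(names(chosen), names(weights)))
    stop("strategy names of tensors and weights must match")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be nonnegative")
  d <- dim(chosen[[1L]])
  for (m in chosen)
    if (!identical(dim(m), d)) stop("tensor axis mismatch in ensemble")
  num <- matrix(0, d[1L], d[2L])
  den <- matrix(0, d[1L], d[2L])
  for (k in names(chosen)) {
    m <- chosen[[k]]
    obs <- !is.na(m)
    num[obs] <- num[obs] + weights[[k]] * m[obs]
    den[obs] <- den[obs] + weights[[k]]
  }
  fused <- num / den
  fused[den == 0] <- NA_real_
  final <- ifelse(is.na(fused), NA_integer_,
                  if (tie_rule == "half_up") as.integer(fused >= 0.5)
                  else as.integer(fused > 0.5))
  dim(final) <- d
  dimnames(fused) <- dimnames(final) <- dimnames(chosen[[1L]])
  structure(list(fused = fused, final = final, weights = weights,
                 tie_rule = tie_rule), class = "flms_ensemble")
}
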