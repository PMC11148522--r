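new_split_plan <- function(strategy, splits, slots) {
  structure(list(strategy = strategy, splits = splits, slots = slots),
            class = "flms_split_plan")
}

#' @export
print.flms_split_plan <- function(x, ...) {
  cat("<flms_split_plan> ", x$strategy, ": ", length(x$splits),
      " splits over ", nrow(x$slots), " target slots\n", sep = "")
  invisible(x)
}

#' Leave-one-participant-out split plan
#'
#' User-agnostic strategy: each split holds out every target slot of one
#' participant and trains on all other participants, reflecting the
#' cold-start case of a new user. The union of predict sets covers every
#' target slot exactly once.
#'
#' @param panel an `flms_panel`.
#' @param slots target-slot table from [change_scores()]; computed if omitted.
#' @return an `flms_split_plan`.
#' @export
plan_lopo <- function(panel, slots = change_scores(panel)) {
  parts <- unique(slots$participant)
  if (length(parts) < 2L) stop("LOPO requires >= 2 participants with targets")
  splits <- lapply(parts, function(p) {
    te <- which(slots$participant == p)
    list(train = setdiff(seq_len(nrow(slots)), te), test = te)
  })
  new_split_plan("LOPO", splits, slots)
}

#' Leave-time-unit-X-out split plan
#'
#' User-agnostic strategy: each split holds out one time unit across all
#' participants and trains on the remaining units, probing the impact of
#' time-specific segments on prediction.
#'
#' @inheritParams plan_lopo
#' @return an `flms_split_plan`.
#' @export
plan_ltxo <- function(panel, slots = change_scores(panel)) {
  units <- sort(unique(slots$time_unit))
  if (length(units) < 2L) stop("LTXO requires >= 2 time units with targets")
  splits <- lapply(units, function(u) {
    te <- which(slots$time_unit == u)
    list(train = setdiff(seq_len(nrow(slots)), te), test = te)
  })
  new_split_plan("LTXO", splits, slots)
}

#' Accumulated-time-unit forecasting split plan
#'
#' Personalized strategy: for each participant an expanding window of their
#' own history forecasts the next unit. With initial window `w0` the first
#' model is trained on the participant's first `w0` target slots and
#' predicts slot `w0 + 1`; each iteration the window grows by `step` units
#' and the slot just past the window is predicted, until the participant's
#' units are exhausted. Training slots always strictly precede the predicted
#' slot in time, so the strategy never sees the future. Participants with
#' `w0` or fewer slots yield no predictions (with a warning).
#'
#' @inheritParams plan_lopo
#' @param w0 initial window length in target slots (>= 1).
#' @param step window growth per iteration (>= 1).
#' @return an `flms_split_plan`.
#' @export
plan_atu <- function(panel, w0 = 2L, step = 1L,
                     slots = change_scores(panel)) {
  stopifnot(w0 >= 1, step >= 1)
  splits <- list()
  skipped <- character()
  for (p in unique(slots$participant)) {
    idx <- which(slots$participant == p)
    idx <- idx[order(slots$time_unit[idx])]
    n <- length(idx)
    if (n <= w0) { skipped <- c(skipped, p); next }
    at <- seq(w0 + 1L, n, by = step)
    for (pos in at) {
      splits[[length(splits) + 1L]] <-
        list(train = idx[seq_len(pos - 1L)], test = idx[pos])
    }
  }
  if (length(skipped))
    warning("ATU: skipped participant(s) with <= w0 target slots: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(splits)) stop("ATU produced no forecasting windows")
  new_split_plan("ATU", splits, slots)
}

#' Leave-one-time-unit-of-participant-out split plan
#'
#' Personalized strategy: for each qualifying participant, every target slot
#' is predicted in turn from all of that participant's remaining slots (past
#' and future), probing the value of cross-time personal data. Participants
#' with fewer than `min_units` slots are skipped with a warning.
#'
#' @inheritParams plan_lopo
#' @param min_units minimum target slots for a participant to qualify (>= 2).
#' @return an `flms_split_plan`.
#' @export
plan_lotpo <- function(panel, min_units = 3L,
                       slots = change_scores(panel)) {
  stopifnot(min_units >= 2)
  splits <- list()
  skipped <- character()
  for (p in unique(slots$participant)) {
    idx <- which(slots$participant == p)
    if (length(idx) < min_units) { skipped <- c(skipped, p); next }
    for (i in idx) {
      splits[[length(splits) + 1L]] <- list(train = setdiff(idx, i), test = i)
    }
  }
  if (length(skipped))
    warning("LOTPO: skipped participant(s) with < ", min_units,
            " target slots: ", paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(splits)) stop("LOTPO produced no splits")
  new_split_plan("LOTPO", splits, slots)
}

plan_strategy <- function(strategy, panel, config, slots) {
  switch(strategy,
         LOPO = plan_lopo(panel, slots),
         LTXO = plan_ltxo(panel, slots),
         ATU = plan_atu(panel, config$atu_w0, config$atu_step, slots),
         LOTPO = plan_lotpo(panel, config$lotpo_min_units, slots),
         stop("unknown strategy: ", strategy))
}

#' Run the modeling suite over a split plan
#'
#' For every split of the plan, fits the preprocessing pipeline on the
#' training slots, transforms both sides, fits each algorithm of the suite
#' and predicts the held-out slots. Identical seeds give identical
#' predictions. Splits with an empty training fold are skipped with a
#' warning, leaving their slots unpredicted.
#'
#' @param x wide feature matrix from [fusion_matrix()] (rows = target slots).
#' @param plan an `flms_split_plan` over the same slot table.
#' @param suite an [flms_suite()] or character vector of algorithm names.
#' @param config an [flms_config()].
#' @return list of class `flms_cubeset`: per algorithm, a numeric vector of
#'   predictions over slots (`NA` where unpredicted), plus `slots`.
#' @export
fit_predict_suite <- function(x, plan, suite = flms_suite(), config = flms_config()) {
  stopifnot(inherits(plan, "flms_split_plan"))
  if (!inherits(suite, "flms_suite")) suite <- flms_suite(suite, config$seed)
  slots <- plan$slots
  if (nrow(x) != nrow(slots)) stop("feature matrix does not align with slots")
  y_all <- slots$change
  preds <- matrix(NA_real_, nrow(slots), length(suite),
                  dimnames = list(NULL, names(suite)))
  pp_global <- if (config$global_preprocessing) fit_preprocessor(x, config)
  for (sp in plan$splits) {
    tr <- sp$train; te <- sp$test
    if (!length(te)) next
    if (!length(tr)) {
      warning("degenerate split with empty training fold; slots left unmasked",
              call. = FALSE)
      next
    }
    if (config$global_preprocessing) {
      xtr <- apply_preprocessor(pp_global, x[tr, , drop = FALSE])
      xte <- apply_preprocessor(pp_global, x[te, , drop = FALSE])
    } else {
      pp <- suppressWarnings(fit_preprocessor(x[tr, , drop = FALSE], config))
      xtr <- apply_preprocessor(pp, x[tr, , drop = FALSE])
      xte <- apply_preprocessor(pp, x[te, , drop = FALSE])
    }
    ytr <- y_all[tr]
    for (a in seq_along(suite)) {
      model <- suite[[a]]$fit(xtr, ytr)
      preds[te, a] <- suite[[a]]$predict(model, xte)
    }
  }
  structure(list(pred = preds, slots = slots, strategy = plan$strategy),
            class = "flms_cubeset")
}

#' Select the per-participant best algorithm
#'
#' Implements minimum-absolute-sum-error model selection: for each
#' participant the algorithm minimizing the sum over that participant's
#' predicted slots of |prediction - actual change| wins, and its predictions
#' are copied into the output cube. Ties break by suite order. With
#' `selection_metric = "accuracy"` the argmin flips to argmax accuracy of
#' the encoded predictions (classification-style selection). With
#' `honest_selection` the error is summed over only the first half of the
#' participant's predicted slots (an inner selection window), though all
#' predictions are retained.
#'
#' @param cubeset result of [fit_predict_suite()].
#' @param config an [flms_config()].
#' @return list of class `flms_cube`: `pred` (numeric vector over slots,
#'   `NA` unmasked), `best_alg` (named character per participant), `slots`,
#'   `strategy`.
#' @export
select_best_model <- function(cubeset, config = flms_config()) {
  stopifnot(inherits(cubeset, "flms_cubeset"))
  slots <- cubeset$slots
  preds <- cubeset$pred
  parts <- unique(slots$participant)
  out <- rep(NA_real_, nrow(slots))
  best <- stats::setNames(rep(NA_character_, length(parts)), parts)
  for (p in parts) {
    idx <- which(slots$participant == p)
    masked <- idx[rowSums(!is.na(preds[idx, , drop = FALSE])) > 0L]
    if (!length(masked)) next
    sel <- masked
    if (config$honest_selection && length(masked) > 1L) {
      o <- masked[order(slots$time_unit[masked])]
      sel <- o[seq_len(ceiling(length(o) / 2))]
    }
    scores <- vapply(seq_len(ncol(preds)), function(a) {
      pa <- preds[sel, a]
      if (all(is.na(pa))) return(Inf)
      if (config$selection_metric == "accuracy") {
        -mean(encode_change(pa[!is.na(pa)]) ==
                encode_change(slots$change[sel][!is.na(pa)]))
      } else {
        sum(abs(pa - slots$change[sel]), na.rm = TRUE)
      }
    }, 0)
    a_star <- which.min(scores)  # ties resolve to the first (suite order)
    out[masked] <- preds[masked, a_star]
    best[p] <- colnames(preds)[a_star]
  }
  structure(list(pred = out, best_alg = best, slots = slots,
                 strategy = cubeset$strategy),
            class = "flms_cube")
}

# Slot-vector -> participants x time_units matrix.
cube_matrix <- function(pred, slots, participants = unique(slots$participant),
                        time_units = sort(unique(slots$time_unit))) {
  m <- matrix(NA_real_, length(participants), length(time_units),
              dimnames = list(participants, time_units))
  m[cbind(match(slots$participant, participants),
          match(slots$time_unit, time_units))] <- pred
  m
}
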