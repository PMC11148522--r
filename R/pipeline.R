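#' Run the full prediction-ranking framework
#'
#' Executes all four stages on a panel: (1) enumerate all nonempty modality
#' fusions and build one preprocessed dataset per subset; (2) run the
#' algorithm suite under each configured cross-validation strategy and keep
#' the per-participant minimum-absolute-sum-error model; (3) mean-aggregate
#' prediction tensors per fusion cardinality, encode predictions to 0/1 and
#' rank every candidate tensor by hamming distance to the encoded truth;
#' (4) fuse each strategy's best tensor through the distance-weighted
#' ensemble into the final binary prediction tensor.
#'
#' @param panel an `flms_panel`.
#' @param config an [flms_config()].
#' @return object of class `flms_result`: list with `panel` (after the
#'   missing-data screen), `slots`, `truth` (encoded truth matrix),
#'   `strategy_cubes` (per strategy, per fusion combination, raw best-model
#'   tensors), `candidates` (ranked candidate table), `chosen` (per-strategy
#'   chosen encoded tensors), `min_distances`, `weights`, `ensemble`
#'   (fused + final tensors), `metrics` (per-user metric summary of the
#'   final tensor), `singular_metrics` (per strategy, metrics of its chosen
#'   tensor), `best_alg` (per strategy, per-participant winning algorithm of
#'   the chosen combination), `config`.
#' @export
run_flms <- function(panel, config = flms_config()) {
  stopifnot(inherits(panel, "flms_panel"))
  panel <- drop_sparse_participants(panel, config$participant_missing_max)
  slots <- change_scores(panel)
  participants <- panel$participants
  time_units <- panel$time_units
  truth <- encode_change(change_matrix(panel, slots))

  subsets <- enumerate_fusions(panel$modalities)
  suite <- flms_suite(config$suite, config$seed)
  plans <- lapply(config$strategies, plan_strategy,
                  panel = panel, config = config, slots = slots)
  names(plans) <- config$strategies

  strategy_cubes <- list()   # strategy -> fusion id -> matrix (raw best preds)
  best_alg <- list()         # strategy -> fusion id -> named chr
  for (strat in config$strategies) {
    cubes <- list()
    balg <- list()
    for (ss in subsets) {
      x <- fusion_matrix(panel, ss, slots)
      cubeset <- suppressWarnings(
        fit_predict_suite(x, plans[[strat]], suite, config))
      best <- select_best_model(cubeset, config)
      id <- fusion_id(ss)
      cubes[[id]] <- cube_matrix(best$pred, slots, participants, time_units)
      balg[[id]] <- best$best_alg
    }
    strategy_cubes[[strat]] <- cubes
    best_alg[[strat]] <- balg
  }

  # ---- stage 3: candidates, encoding, hamming ranking -----------------
  card <- vapply(subsets, length, 0L)
  ids <- vapply(subsets, fusion_id, "")
  rec <- list(); enc_store <- list()
  add_record <- function(strategy, scope, cardinality, raw) {
    enc <- encode_change(raw)
    key <- paste(strategy, scope, sep = "\r")
    enc_store[[key]] <<- if (config$ensemble_on_raw) raw else enc
    rec[[length(rec) + 1L]] <<- data.frame(
      strategy = strategy, scope = scope, cardinality = cardinality,
      distance = hamming_distance(enc, truth), stringsAsFactors = FALSE)
  }
  for (strat in config$strategies) {
    cubes <- strategy_cubes[[strat]]
    if (config$fusion_scope %in% c("per_combination", "both")) {
      for (i in seq_along(ids))
        add_record(strat, ids[i], card[i], cubes[[ids[i]]])
    }
    if (config$fusion_scope %in% c("per_cardinality", "both")) {
      for (x in sort(unique(card))) {
        agg <- aggregate_mean(cubes[ids[card == x]])
        add_record(strat, sprintf("agg:%d-sensor", x), x, agg)
      }
    }
  }
  candidates <- rank_candidates(do.call(rbind, rec))

  chosen_rows <- candidates[candidates$chosen, , drop = FALSE]
  chosen_rows <- chosen_rows[match(config$strategies, chosen_rows$strategy), ,
                             drop = FALSE]
  chosen <- stats::setNames(
    lapply(seq_len(nrow(chosen_rows)), function(i)
      enc_store[[paste(chosen_rows$strategy[i], chosen_rows$scope[i],
                       sep = "\r")]]),
    chosen_rows$strategy)
  min_distances <- stats::setNames(chosen_rows$distance, chosen_rows$strategy)

  # ---- stage 4: weighted ensemble -------------------------------------
  weights <- compute_weights(min_distances, config$weighting, config$epsilon)
  ens <- weighted_ensemble(chosen, weights, config$tie_rule)
  if (config$ensemble_on_raw) ens$final <- encode_change(ens$fused)

  singular_metrics <- lapply(chosen, function(m)
    per_user_metrics(encode_change(m), truth))
  metrics <- per_user_metrics(ens$final, truth)

  structure(list(
    panel = panel, slots = slots, truth = truth,
    strategy_cubes = strategy_cubes, candidates = candidates,
    chosen = chosen, min_distances = min_distances, weights = weights,
    ensemble = ens, metrics = metrics, singular_metrics = singular_metrics,
    best_alg = best_alg, config = config
  ), class = "flms_result")
}

#' @export
print.flms_result <- function(x, ...) {
  cat("<flms_result> ", length(x$panel$participants), " participants, ",
      nrow(x$slots), " target slots\n", sep = "")
  cat("minimum hamming distances:\n")
  print(x$min_distances)
  cat("ensemble weights:\n")
  print(round(x$weights, 4))
  cat("final mean per-user accuracy: ",
      round(x$metrics$summary["accuracy", "mean"], 4), "\n", sep = "")
  invisible(x)
}

#' Write the framework report
#'
#' Writes two files under `dir`: `predictions.csv` (per target slot: the
#' per-strategy encoded contributions, fused fractional value, final 0/1
#' prediction, and encoded truth) and `summary.json` (ensemble weights,
#' minimum hamming distances, the ranked candidate table, and metric
#' summaries). Output is byte-identical across reruns with the same config
#' and seed.
#'
#' @param result an `flms_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_report <- function(result, dir) {
  if (!inherits(result, "flms_result") || is.null(result$ensemble$final))
    stop("incomplete result: no final prediction tensor")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  slots <- result$slots
  idx <- cbind(match(slots$participant, rownames(result$truth)),
               match(as.character(slots$time_unit), colnames(result$truth)))
  df <- data.frame(participant = slots$participant,
                   time_unit = slots$time_unit,
                   stringsAsFactors = FALSE)
  for (s in names(result$chosen)) df[[s]] <- result$chosen[[s]][idx]
  df$fused <- result$ensemble$fused[idx]
  df$final <- result$ensemble$final[idx]
  df$truth <- result$truth[idx]
  pred_path <- file.path(dir, "predictions.csv")
  utils::write.csv(df, pred_path, row.names = FALSE, na = "")

  fmt_metrics <- function(m) list(
    mean = as.list(m$summary[, "mean"]),
    sd = as.list(m$summary[, "sd"]),
    n_users = m$n_users)
  summary <- list(
    weights = as.list(result$weights),
    min_hamming = as.list(result$min_distances),
    candidates = result$candidates,
    metrics = c(list(FLMS = fmt_metrics(result$metrics)),
                lapply(result$singular_metrics, fmt_metrics)),
    tie_rule = result$ensemble$tie_rule,
    seed = result$config$seed
  )
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(c(pred_path, json_path))
}
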