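#' Run configuration for the ranking framework
#'
#' Collects every tunable of the pipeline with validated defaults. Defaults
#' mirror the framework's reference setup: all four modeling strategies, the
#' seven-regressor suite, accumulated-time-unit forecasting with an initial
#' window of 2 weeks growing by 1, KNN imputation with k = 5, a correlated
#' feature drop at |r| > 0.9, inverse-distance ensemble weights and random
#' state 42.
#'
#' @param strategies subset of `c("LOPO","LTXO","ATU","LOTPO")`.
#' @param suite character vector of algorithm names understood by
#'   [flms_suite()].
#' @param fusion_scope which candidate tensors enter the ranking:
#'   `"per_combination"` (one per modality subset), `"per_cardinality"`
#'   (mean-aggregates of all subsets of each size), or `"both"`.
#' @param atu_w0 initial training window (time units) for the
#'   accumulated-time-unit strategy; >= 1.
#' @param atu_step window growth per forecasting iteration; >= 1.
#' @param lotpo_min_units minimum observed target slots for a participant to
#'   enter the leave-one-time-unit-of-participant-out strategy; >= 2.
#' @param impute_k neighbour count for KNN imputation; >= 1.
#' @param corr_threshold drop a feature when its absolute training-fold
#'   correlation with an already-kept feature exceeds this; in (0, 1].
#' @param log_features character vector of feature names given a signed
#'   log1p transform before scaling (for heavily skewed sensors); default none.
#' @param participant_missing_max exclude participants missing more than this
#'   fraction of their sensor data; in (0, 1].
#' @param global_preprocessing if `TRUE`, fit imputation/scaling once on the
#'   full matrix instead of per training fold (mimics a global fit; the
#'   default fold-wise fit avoids leakage).
#' @param honest_selection if `TRUE`, the per-participant best algorithm is
#'   chosen on the first half of that participant's predicted slots only;
#'   default `FALSE` selects on all held-out slots (the reference behaviour).
#' @param selection_metric `"abs_error"` (regression, default) or
#'   `"accuracy"` (classification-style selection on encoded predictions).
#' @param weighting `"inverse"` (1/(D+epsilon), normalized) or `"softmax"`
#'   (softmax of negative distances).
#' @param epsilon guard added to distances before inversion.
#' @param tie_rule how a fused value of exactly 0.5 resolves: `"half_up"`
#'   (to 1, default) or `"half_down"`.
#' @param ensemble_on_raw if `TRUE`, the final ensemble averages raw
#'   regression tensors instead of encoded 0/1 tensors.
#' @param seed integer random state used for every stochastic component.
#' @return a validated list of class `flms_config`.
#' @export
flms_config <- function(strategies = c("LOPO", "LTXO", "ATU", "LOTPO"),
                        suite = c("lr", "enet", "rf", "adaboost",
                                  "extratrees", "gbm", "xgb"),
                        fusion_scope = c("both", "per_combination",
                                         "per_cardinality"),
                        atu_w0 = 2L, atu_step = 1L, lotpo_min_units = 3L,
                        impute_k = 5L, corr_threshold = 0.9,
                        log_features = character(),
                        participant_missing_max = 0.6,
                        global_preprocessing = FALSE,
                        honest_selection = FALSE,
                        selection_metric = c("abs_error", "accuracy"),
                        weighting = c("inverse", "softmax"),
                        epsilon = 1e-9,
                        tie_rule = c("half_up", "half_down"),
                        ensemble_on_raw = FALSE,
                        seed = 42L) {
  strategies <- match.arg(strategies, c("LOPO", "LTXO", "ATU", "LOTPO"),
                          several.ok = TRUE)
  fusion_scope <- match.arg(fusion_scope)
  selection_metric <- match.arg(selection_metric)
  weighting <- match.arg(weighting)
  tie_rule <- match.arg(tie_rule)
  stopifnot(atu_w0 >= 1, atu_step >= 1, lotpo_min_units >= 2, impute_k >= 1,
            corr_threshold > 0, corr_threshold <= 1,
            participant_missing_max > 0, participant_missing_max <= 1,
            epsilon > 0, is.numeric(seed), length(seed) == 1)
  structure(list(
    strategies = strategies, suite = suite, fusion_scope = fusion_scope,
    atu_w0 = as.integer(atu_w0), atu_step = as.integer(atu_step),
    lotpo_min_units = as.integer(lotpo_min_units),
    impute_k = as.integer(impute_k), corr_threshold = corr_threshold,
    log_features = log_features,
    participant_missing_max = participant_missing_max,
    global_preprocessing = isTRUE(global_preprocessing),
    honest_selection = isTRUE(honest_selection),
    selection_metric = selection_metric,
    weighting = weighting, epsilon = epsilon, tie_rule = tie_rule,
    ensemble_on_raw = isTRUE(ensemble_on_raw), seed = as.integer(seed)
  ), class = "flms_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [flms_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return an `flms_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(flms_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  do.call(flms_config, vals)
}
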