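# Builders for small in-code fixtures used across test files.

# Panel from a named list of score vectors (one per participant, consecutive
# weeks starting at start_week); features filled with deterministic values
# for every (participant, week, modality, feature).
make_panel <- function(scores, modalities = c("m1", "m2"),
                       n_features = 2L, start_week = 1L) {
  score_rows <- do.call(rbind, lapply(names(scores), function(p) {
    data.frame(participant = p,
               time_unit = seq(start_week, length.out = length(scores[[p]])),
               score = scores[[p]], stringsAsFactors = FALSE)
  }))
  feat_rows <- do.call(rbind, lapply(names(scores), function(p) {
    weeks <- seq(start_week, length.out = length(scores[[p]]))
    expand <- expand.grid(time_unit = weeks, modality = modalities,
                          feature_i = seq_len(n_features),
                          stringsAsFactors = FALSE)
    data.frame(participant = p, time_unit = expand$time_unit,
               modality = expand$modality,
               feature = paste0("f", expand$feature_i),
               value = as.numeric(expand$time_unit) * expand$feature_i +
                 match(p, names(scores)) +
                 ifelse(expand$modality == modalities[1L], 0, 0.5),
               stringsAsFactors = FALSE)
  }))
  flms_panel(feat_rows, score_rows)
}

# Random masked 0/1 matrix pair for oracle-equivalence property tests.
random_masked_pair <- function(nr, nc, p_mask = 0.3) {
  enc <- matrix(sample(0:1, nr * nc, replace = TRUE), nr, nc)
  enc[matrix(stats::runif(nr * nc) < p_mask, nr, nc)] <- NA
  truth <- matrix(sample(0:1, nr * nc, replace = TRUE), nr, nc)
  list(enc = enc, truth = truth)
}

# Small simulated cohort shared by the heavier tests.
small_cohort <- function(seed = 11, zero_inflation = 0.2) {
  simulate_cohort(
    n_participants = 8L, n_weeks = 10L,
    modalities = data.frame(name = c("a", "b", "c"),
                            n_features = c(4L, 3L, 3L),
                            informative = c(TRUE, TRUE, FALSE)),
    weeks_obs = 6:8, zero_inflation = zero_inflation, seed = seed)
}
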