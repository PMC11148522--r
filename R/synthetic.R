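#' Default modality layout for simulated cohorts
#'
#' Six passive-sensing modalities with realistic feature counts (61 features
#' total): calls (14), location (12), screen (11), conversation (12), fitbit
#' (2) and wifi (10). The smartphone modalities carry signal about the
#' latent symptom trajectory; fitbit and wifi are pure-noise channels, which
#' gives sensor-selection tests a ground truth to recover.
#'
#' @return data.frame with columns `name`, `n_features`, `informative`.
#' @export
default_modalities <- function() {
  data.frame(
    name = c("calls", "location", "screen", "conversation", "fitbit", "wifi"),
    n_features = c(14L, 12L, 11L, 12L, 2L, 10L),
    informative = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multimodal longitudinal sensing cohort
#'
#' Generates a synthetic panel with the statistical structure the framework
#' assumes: each participant follows a latent AR(1) symptom trajectory
#' `u_t = rho * u_(t-1) + e_t` around a participant-specific offset; the
#' weekly PHQ-9-like score is `clamp(round(score_scale * (offset + u_t) +
#' score_base), 0, 27)`. Features of informative modalities load linearly on
#' the latent level `u_t` and on the weekly innovation `e_t` (half of each
#' modality's features each) plus Gaussian noise; non-informative modalities
#' are pure noise. Per-participant multiplicative feature scales emulate
#' device heterogeneity. Zero-inflation replaces feature values by exact 0
#' at rate `zero_inflation` (sparse sensor readings); missingness masks
#' cells at rate `missing_rate`. Each participant contributes one
#' contiguous run of observed weeks whose length is drawn uniformly from
#' `weeks_obs`, emulating staggered adherence. Identical arguments and seed
#' reproduce the panel exactly.
#'
#' @param n_participants number of participants.
#' @param n_weeks study length in weeks.
#' @param modalities data.frame as [default_modalities()].
#' @param rho latent AR(1) coefficient in (0, 1).
#' @param sigma feature observation noise SD.
#' @param tau participant-offset SD (between-person heterogeneity).
#' @param zero_inflation probability a feature cell is zeroed, in \[0, 1).
#' @param missing_rate probability a feature cell is masked, in \[0, 1).
#' @param weeks_obs integer vector of possible observed-run lengths.
#' @param score_scale,score_base linear map from latent state to the 0-27
#'   instrument scale.
#' @param loading_scale SD of feature loadings on the latent signals.
#' @param seed integer random state.
#' @return an `flms_panel`.
#' @export
simulate_cohort <- function(n_participants = 45L, n_weeks = 24L,
                            modalities = default_modalities(),
                            rho = 0.7, sigma = 0.5, tau = 0.8,
                            zero_inflation = 0.35, missing_rate = 0,
                            weeks_obs = 9:14,
                            score_scale = 4, score_base = 10,
                            loading_scale = 1, seed = 42L) {
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0, 1)")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (sigma < 0 || tau < 0) stop("noise scales must be nonnegative")
  stopifnot(n_participants >= 1, n_weeks >= 2,
            all(weeks_obs >= 2), all(weeks_obs <= n_weeks))
  set.seed(as.integer(seed))

  mods <- modalities
  feat_names <- lapply(seq_len(nrow(mods)), function(i)
    sprintf("%s_f%02d", mods$name[i], seq_len(mods$n_features[i])))
  names(feat_names) <- mods$name
  n_feat <- sum(mods$n_features)

  # fixed per-feature structure: loadings on (level u_t, innovation e_t),
  # baseline offset; noise modalities get zero loadings
  loads <- do.call(rbind, lapply(seq_len(nrow(mods)), function(i) {
    nf <- mods$n_features[i]
    on_level <- seq_len(nf) <= ceiling(nf / 2)
    l <- stats::rnorm(nf, 0, loading_scale) +
      sign(stats::rnorm(nf)) * 0.5          # keep loadings away from 0
    if (!mods$informative[i]) l[] <- 0
    data.frame(modality = mods$name[i], feature = feat_names[[i]],
               l_level = ifelse(on_level, l, 0),
               l_innov = ifelse(on_level, 0, l),
               baseline = stats::runif(nf, -1, 3),
               stringsAsFactors = FALSE)
  }))

  participants <- sprintf("P%02d", seq_len(n_participants))
  feat_rows <- vector("list", n_participants)
  score_rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    len <- if (length(weeks_obs) == 1L) weeks_obs else sample(weeks_obs, 1L)
    start <- if (n_weeks == len) 1L else sample.int(n_weeks - len + 1L, 1L)
    weeks <- seq.int(start, start + len - 1L)
    offset <- stats::rnorm(1L, 0, tau)
    innov <- stats::rnorm(len)
    u <- numeric(len)
    u[1L] <- stats::rnorm(1L, 0, 1 / sqrt(1 - rho^2))
    for (t in seq_len(len)[-1L]) u[t] <- rho * u[t - 1L] + innov[t]
    z <- offset + u
    score <- pmin(27L, pmax(0L, as.integer(round(score_scale * z + score_base))))
    score_rows[[i]] <- data.frame(participant = participants[i],
                                  time_unit = weeks, score = score,
                                  stringsAsFactors = FALSE)
    # participant-specific multiplicative scale per feature (heterogeneity)
    pscale <- exp(stats::rnorm(n_feat, 0, 0.3))
    vals <- matrix(NA_real_, len, n_feat)
    for (t in seq_len(len)) {
      signal <- loads$l_level * u[t] + loads$l_innov * innov[t]
      vals[t, ] <- pscale * (loads$baseline + signal +
                               sigma * stats::rnorm(n_feat))
    }
    if (zero_inflation > 0) {
      zmask <- matrix(stats::runif(len * n_feat) < zero_inflation, len, n_feat)
      vals[zmask] <- 0
    }
    if (missing_rate > 0) {
      mmask <- matrix(stats::runif(len * n_feat) < missing_rate, len, n_feat)
      vals[mmask] <- NA_real_
    }
    feat_rows[[i]] <- data.frame(
      participant = participants[i],
      time_unit = rep(weeks, times = n_feat),
      modality = rep(loads$modality, each = len),
      feature = rep(loads$feature, each = len),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
  }
  flms_panel(do.call(rbind, feat_rows), do.call(rbind, score_rows),
             modalities = mods$name)
}

#' Encoded ground-truth change tensor
#'
#' Applies the 0/1 change encoding to the true week-over-week score changes:
#' `truth[i, j] = 1` iff participant i's score rose from week j-1 to week j,
#' `NA` where no consecutive pair exists.
#'
#' @param panel an `flms_panel`.
#' @return integer 0/1 matrix (participants x time units) with `NA` mask.
#' @export
ground_truth_encoding <- function(panel) {
  encode_change(change_matrix(panel))
}
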