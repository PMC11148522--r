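#' Enumerate all nonempty modality fusions
#'
#' Stage 1 of the framework explores the data from every sensor view: for Z
#' modalities it builds one dataset per nonempty subset, 2^Z - 1 in total
#' (63 for the canonical 6-modality setup). Order is deterministic: by
#' cardinality, then lexicographically within a cardinality.
#'
#' @param modalities ordered character vector of modality names.
#' @return list of character vectors, each one modality subset.
#' @export
enumerate_fusions <- function(modalities) {
  if (length(modalities) == 0L) stop("no modalities")
  if (anyDuplicated(modalities)) stop("duplicate modality names")
  z <- length(modalities)
  out <- list()
  for (x in seq_len(z)) {
    combos <- utils::combn(sort(modalities), x, simplify = FALSE)
    ord <- order(vapply(combos, paste, "", collapse = "+"))
    out <- c(out, combos[ord])
  }
  out
}

# Identity string of a fusion subset ("calls+location").
fusion_id <- function(subset) paste(sort(subset), collapse = "+")

#' Exclude participants with excessive missing sensor data
#'
#' Participants whose fraction of missing feature cells (over their scored
#' weeks and the full feature set) exceeds `max_missing` are removed from the
#' panel, mirroring the 60% completeness screen applied before modeling.
#'
#' @param panel an `flms_panel`.
#' @param max_missing maximum tolerated missing fraction, in (0, 1].
#' @return the filtered `flms_panel` (with an attribute `dropped` listing
#'   excluded participants).
#' @export
drop_sparse_participants <- function(panel, max_missing = 0.6) {
  stopifnot(inherits(panel, "flms_panel"))
  n_feat <- sum(lengths(panel$feature_names))
  drop <- character()
  for (p in panel$participants) {
    weeks <- panel$scores$time_unit[panel$scores$participant == p]
    if (!length(weeks)) next
    expected <- length(weeks) * n_feat
    f <- panel$features
    present <- sum(f$participant == p & f$time_unit %in% weeks &
                     !is.na(f$value))
    if (1 - present / expected > max_missing) drop <- c(drop, p)
  }
  if (!length(drop)) {
    attr(panel, "dropped") <- character()
    return(panel)
  }
  keep <- setdiff(panel$participants, drop)
  if (!length(keep)) stop("all participants excluded by missing-data screen")
  out <- flms_panel(panel$features[panel$features$participant %in% keep, ],
                    panel$scores[panel$scores$participant %in% keep, ],
                    modalities = panel$modalities)
  attr(out, "dropped") <- drop
  out
}

#' Wide feature matrix for a fusion subset
#'
#' Builds the modeling matrix of one fused dataset: one row per target slot
#' (a participant-week holding a change score), one column per feature of the
#' selected modalities. Cells absent from the panel are `NA` (to be imputed
#' inside each training fold).
#'
#' @param panel an `flms_panel`.
#' @param subset nonempty character vector of modality names.
#' @param slots target-slot table from [change_scores()]; computed if omitted.
#' @return numeric matrix, rownames `participant@time_unit`, with attribute
#'   `slots`.
#' @export
fusion_matrix <- function(panel, subset, slots = change_scores(panel)) {
  stopifnot(inherits(panel, "flms_panel"))
  if (length(subset) == 0L) stop("empty fusion subset")
  bad <- setdiff(subset, panel$modalities)
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
  subset <- panel$modalities[panel$modalities %in% subset]
  cols <- unlist(lapply(subset, function(m)
    paste(m, panel$feature_names[[m]], sep = ".")), use.names = FALSE)
  f <- panel$features[panel$features$modality %in% subset, , drop = FALSE]
  slot_key <- paste(slots$participant, slots$time_unit, sep = "@")
  X <- matrix(NA_real_, nrow(slots), length(cols),
              dimnames = list(slot_key, cols))
  fk_row <- match(paste(f$participant, f$time_unit, sep = "@"), slot_key)
  fk_col <- match(paste(f$modality, f$feature, sep = "."), cols)
  ok <- !is.na(fk_row) & !is.na(fk_col)
  X[cbind(fk_row[ok], fk_col[ok])] <- f$value[ok]
  attr(X, "slots") <- slots
  X
}

#' K-nearest-neighbour imputation
#'
#' Fills missing cells of `x` using the k nearest complete-enough rows of the
#' reference pool `pool` (defaults to `x` itself): distance is the mean
#' squared difference over mutually observed columns, and the imputed value
#' is the mean of the k nearest pool rows observed in the target column.
#' Present values are never modified; a complete matrix is returned
#' unchanged. When invoked inside a cross-validation fold the pool is the
#' training rows only, so no held-out information leaks in.
#'
#' @param x numeric matrix with `NA`s to fill.
#' @param k neighbour count (>= 1).
#' @param pool reference rows used as neighbours (default `x`).
#' @return `x` with all `NA`s replaced.
#' @export
impute_knn <- function(x, k = 5L, pool = x) {
  stopifnot(is.matrix(x), k >= 1)
  if (!anyNA(x)) return(x)
  if (ncol(x) == 0L) return(x)
  all_na <- colSums(!is.na(pool)) == 0L
  if (any(all_na)) {
    # fall back to the target rows themselves for columns the pool never saw
    all_na_x <- colSums(!is.na(x)) == 0L
    truly_dead <- all_na & all_na_x
    if (any(truly_dead))
      stop("feature observed nowhere, cannot impute: ",
           paste(colnames(x)[truly_dead], collapse = ", "))
  }
  col_fallback <- colMeans(pool, na.rm = TRUE)
  col_fallback[is.nan(col_fallback)] <- colMeans(x, na.rm = TRUE)[is.nan(col_fallback)]
  out <- x
  need <- which(rowSums(is.na(x)) > 0L)
  pool_obs <- !is.na(pool)
  for (i in need) {
    xi <- x[i, ]
    miss <- unname(which(is.na(xi)))
    # mean squared difference on mutually observed columns
    d2 <- rep(NA_real_, nrow(pool))
    obs_i <- !is.na(xi)
    for (j in seq_len(nrow(pool))) {
      shared <- obs_i & pool_obs[j, ]
      if (any(shared)) d2[j] <- mean((xi[shared] - pool[j, shared])^2)
    }
    ord <- order(d2, na.last = NA)
    for (m in miss) {
      donors <- ord[pool_obs[ord, m]]
      if (length(donors)) {
        out[i, m] <- mean(pool[donors[seq_len(min(k, length(donors)))], m])
      } else {
        out[i, m] <- col_fallback[m]
      }
    }
  }
  out
}

#' Fit the stage-1 preprocessor on training rows
#'
#' Learns the preprocessing pipeline on (and only on) the rows given:
#' optional signed log1p for configured skewed features, KNN imputation,
#' per-feature z-scoring, drop of zero-variance features, and greedy removal
#' of correlated features (keeping the first in deterministic column order
#' whenever a pair exceeds the |r| threshold on the fitting rows).
#'
#' @param x_train numeric matrix of fitting rows.
#' @param config an [flms_config()].
#' @return an object of class `flms_preprocessor` to pass to
#'   [apply_preprocessor()].
#' @export
fit_preprocessor <- function(x_train, config = flms_config()) {
  stopifnot(is.matrix(x_train))
  logf <- intersect(colnames(x_train), config$log_features)
  xt <- x_train
  if (length(logf))
    xt[, logf] <- sign(xt[, logf]) * log1p(abs(xt[, logf]))
  xt <- impute_knn(xt, k = config$impute_k)
  mu <- colMeans(xt)
  sd <- apply(xt, 2L, stats::sd)
  keep <- which(is.finite(sd) & sd > 0)
  dropped_const <- setdiff(seq_len(ncol(xt)), keep)
  if (length(dropped_const))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(xt)[dropped_const], collapse = ", "),
            call. = FALSE)
  kept <- keep
  if (length(kept) > 1L && nrow(xt) > 2L) {
    z <- scale(xt[, kept, drop = FALSE], center = mu[kept], scale = sd[kept])
    cm <- abs(suppressWarnings(stats::cor(z)))
    cm[is.na(cm)] <- 0
    sel <- logical(length(kept))
    for (j in seq_along(kept)) {
      if (!any(sel)) { sel[j] <- TRUE; next }
      sel[j] <- all(cm[j, sel] <= config$corr_threshold)
    }
    kept <- kept[sel]
  }
  structure(list(train = xt, k = config$impute_k, log_features = logf,
                 mu = mu, sd = sd, keep = kept,
                 colnames = colnames(x_train)),
            class = "flms_preprocessor")
}

#' Apply a fitted preprocessor to new rows
#'
#' Transforms rows with statistics learned by [fit_preprocessor()]; missing
#' cells are imputed against the fitting rows, so held-out rows never
#' influence the transform (perturbing them leaves transformed training rows
#' unchanged).
#'
#' @param pp an `flms_preprocessor`.
#' @param x numeric matrix with the same columns the preprocessor was fit on.
#' @return transformed matrix restricted to the retained features.
#' @export
apply_preprocessor <- function(pp, x) {
  stopifnot(inherits(pp, "flms_preprocessor"), is.matrix(x))
  if (!identical(colnames(x), pp$colnames))
    stop("column mismatch between preprocessor and matrix")
  if (length(pp$log_features))
    x[, pp$log_features] <- sign(x[, pp$log_features]) *
      log1p(abs(x[, pp$log_features]))
  if (anyNA(x)) x <- impute_knn(x, k = pp$k, pool = pp$train)
  keep <- pp$keep
  out <- x[, keep, drop = FALSE]
  sweep(sweep(out, 2L, pp$mu[keep], "-"), 2L, pp$sd[keep], "/")
}
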