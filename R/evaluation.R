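#' Per-user binary classification metrics
#'
#' Computes, for every user with at least one masked prediction, accuracy,
#' recall and F1 (positive class = 1, an increase in the severity score),
#' then the across-user mean and SD of each. When a user has no positive
#' truths, recall is defined as 0 (and flagged); F1 is 0 whenever precision
#' or recall is undefined or their sum is 0.
#'
#' @param pred 0/1 matrix with `NA` mask (participants x time units).
#' @param truth 0/1 matrix of the same shape.
#' @return list of class `flms_metrics`: `per_user` data.frame (user,
#'   n, accuracy, recall, f1, no_positives flag), `summary` matrix
#'   (metric x mean/sd), `n_users`, `excluded` (users with no predictions).
#' @export
per_user_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between prediction and truth tensors")
  users <- rownames(pred)
  if (is.null(users)) users <- as.character(seq_len(nrow(pred)))
  rows <- list(); excluded <- character()
  for (i in seq_len(nrow(pred))) {
    ok <- !is.na(pred[i, ]) & !is.na(truth[i, ])
    if (!any(ok)) { excluded <- c(excluded, users[i]); next }
    p <- pred[i, ok]; a <- truth[i, ok]
    tp <- sum(p == 1 & a == 1); fp <- sum(p == 1 & a == 0)
    fn <- sum(p == 0 & a == 1)
    acc <- mean(p == a)
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && (prec + rec) > 0)
      2 * prec * rec / (prec + rec) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      user = users[i], n = sum(ok), accuracy = acc, recall = rec, f1 = f1,
      no_positives = (tp + fn) == 0L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no user has any masked prediction")
  per_user <- do.call(rbind, rows)
  summ <- rbind(
    accuracy = c(mean = mean(per_user$accuracy), sd = stats::sd(per_user$accuracy)),
    recall = c(mean = mean(per_user$recall), sd = stats::sd(per_user$recall)),
    f1 = c(mean = mean(per_user$f1), sd = stats::sd(per_user$f1)))
  structure(list(per_user = per_user, summary = summ,
                 n_users = nrow(per_user), excluded = excluded),
            class = "flms_metrics")
}

#' @export
print.flms_metrics <- function(x, ...) {
  cat("<flms_metrics> ", x$n_users, " users\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}

#' Sparsity of a feature matrix
#'
#' The ratio of exact-zero entries to the total number of observed entries;
#' missing (`NA`) cells are excluded from both counts.
#'
#' @param x numeric matrix or vector.
#' @return fraction in \[0, 1\].
#' @export
sparsity <- function(x) {
  if (length(x) == 0L) stop("empty matrix")
  obs <- !is.na(x)
  if (!any(obs)) stop("no observed entries")
  sum(x[obs] == 0) / sum(obs)
}

#' Framework versus singular modeling strategies
#'
#' Experiment harness: runs the full framework once and tabulates its final
#' ensemble metrics next to each cross-validation strategy run singly (that
#' strategy's best-ranked tensor), plus the per-strategy minimum hamming
#' distances and best fusion identities. The default suite is reduced to
#' ordinary least squares to keep the 63-fusion sweep tractable; pass a
#' larger suite for a fuller comparison.
#'
#' @param panel an `flms_panel`.
#' @param config an [flms_config()]; default uses the `"lr"` suite.
#' @return list of class `flms_experiment1`: `table` (one row per approach:
#'   mean/sd accuracy, recall, F1), `hamming` (strategy, best scope,
#'   distance), `result` (the underlying `flms_result`).
#' @export
run_experiment1 <- function(panel, config = flms_config(suite = "lr")) {
  res <- run_flms(panel, config)
  row_of <- function(name, type, m) data.frame(
    approach = name, type = type,
    accuracy_mean = m$summary["accuracy", "mean"],
    accuracy_sd = m$summary["accuracy", "sd"],
    recall_mean = m$summary["recall", "mean"],
    recall_sd = m$summary["recall", "sd"],
    f1_mean = m$summary["f1", "mean"],
    f1_sd = m$summary["f1", "sd"],
    stringsAsFactors = FALSE)
  strat_type <- c(LOPO = "user-agnostic", LTXO = "user-agnostic",
                  ATU = "personalized", LOTPO = "personalized")
  tab <- rbind(
    row_of("FLMS", "user-agnostic + personalized", res$metrics),
    do.call(rbind, lapply(names(res$singular_metrics), function(s)
      row_of(s, strat_type[[s]], res$singular_metrics[[s]]))))
  ch <- res$candidates[res$candidates$chosen, c("strategy", "scope",
                                                "cardinality", "distance")]
  rownames(tab) <- rownames(ch) <- NULL
  structure(list(table = tab, hamming = ch, result = res),
            class = "flms_experiment1")
}

# Leave-one-participant-out classification baselines on encoded targets.
baseline_classifiers <- function(names, seed) {
  fitmat <- function(x) { colnames(x) <- paste0("f", seq_len(ncol(x))); x }
  make <- function(fit, predict) list(fit = fit, predict = predict)
  reg <- list(
    majority = make(
      function(x, y) {
        tab <- table(factor(y, levels = c(0, 1)))
        as.integer(names(tab)[which.max(tab)])   # ties -> 0 (first level)
      },
      function(m, x) rep(m, nrow(x))),
    knn = make(
      function(x, y) list(x = fitmat(x), y = factor(y, levels = c(0, 1))),
      function(m, x) as.integer(as.character(
        class::knn(m$x, fitmat(x), m$y, k = min(5L, nrow(m$x)))))),
    dt = make(
      function(x, y) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), fitmat(x))
        rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(xval = 0L, cp = 0.01))
      },
      function(m, x) as.integer(as.character(
        stats::predict(m, data.frame(fitmat(x)), type = "class")))),
    rf = make(
      function(x, y) ranger::ranger(x = fitmat(x),
                                    y = factor(y, levels = c(0, 1)),
                                    num.trees = 100L, seed = seed,
                                    num.threads = 1L),
      function(m, x) as.integer(as.character(
        stats::predict(m, data = fitmat(x), num.threads = 1L)$predictions))),
    svm = make(
      function(x, y) e1071::svm(fitmat(x), factor(y, levels = c(0, 1))),
      function(m, x) as.integer(as.character(stats::predict(m, fitmat(x))))),
    xgb = make(
      function(x, y) fit_xgb_booster(fitmat(x), y, eta = 0.3, max_depth = 6L,
                                     nrounds = 40L, seed = seed,
                                     objective = "binary:logistic"),
      function(m, x) as.integer(predict_xgb_booster(m, fitmat(x)) >= 0.5)),
    adaboost = make(
      function(x, y) fit_adaboost_r2(fitmat(x), as.numeric(y)),
      function(m, x) as.integer(predict_adaboost_r2(m, fitmat(x)) >= 0.5))
  )
  bad <- setdiff(names, names(reg))
  if (length(bad)) stop("unknown baseline: ", paste(bad, collapse = ", "))
  reg[names]
}

#' Leave-one-out classical baselines
#'
#' Runs classical classifiers under leave-one-participant-out validation on
#' the encoded change targets, using the all-modality fused feature matrix
#' (preprocessed per fold), and reports per-user metrics plus the
#' train-versus-test accuracy gap as an overfitting diagnostic. A
#' `"majority"` baseline (per-fold majority class) gives the floor any
#' learner should beat.
#'
#' @param panel an `flms_panel`.
#' @param baselines character vector among `"majority"`, `"knn"`, `"dt"`,
#'   `"rf"`, `"svm"`, `"xgb"`, `"adaboost"`.
#' @param config an [flms_config()].
#' @return list of class `flms_baselines`: `table` (per baseline: metric
#'   means/SDs, train accuracy, train-test gap), `metrics` (per baseline
#'   `flms_metrics`).
#' @export
run_baselines <- function(panel,
                          baselines = c("majority", "knn", "dt", "rf",
                                        "svm", "xgb"),
                          config = flms_config()) {
  panel <- drop_sparse_participants(panel, config$participant_missing_max)
  slots <- change_scores(panel)
  truth_enc <- encode_change(change_matrix(panel, slots))
  x <- fusion_matrix(panel, panel$modalities, slots)
  plan <- plan_lopo(panel, slots)
  y_enc <- encode_change(slots$change)
  clfs <- baseline_classifiers(baselines, config$seed)
  metrics <- list(); rows <- list()
  for (b in names(clfs)) {
    pred <- rep(NA_integer_, nrow(slots))
    tr_acc <- numeric()
    for (sp in plan$splits) {
      pp <- suppressWarnings(
        fit_preprocessor(x[sp$train, , drop = FALSE], config))
      xtr <- apply_preprocessor(pp, x[sp$train, , drop = FALSE])
      xte <- apply_preprocessor(pp, x[sp$test, , drop = FALSE])
      m <- clfs[[b]]$fit(xtr, y_enc[sp$train])
      pred[sp$test] <- clfs[[b]]$predict(m, xte)
      tr_acc <- c(tr_acc, mean(clfs[[b]]$predict(m, xtr) == y_enc[sp$train]))
    }
    pm <- cube_matrix(pred, slots, panel$participants, panel$time_units)
    met <- per_user_metrics(pm, truth_enc)
    metrics[[b]] <- met
    rows[[b]] <- data.frame(
      baseline = b,
      accuracy_mean = met$summary["accuracy", "mean"],
      accuracy_sd = met$summary["accuracy", "sd"],
      recall_mean = met$summary["recall", "mean"],
      f1_mean = met$summary["f1", "mean"],
      train_accuracy = mean(tr_acc),
      train_test_gap = mean(tr_acc) - met$summary["accuracy", "mean"],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, metrics = metrics), class = "flms_baselines")
}
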