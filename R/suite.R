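#' Regression algorithm suite
#'
#' Builds the pluggable modeling suite used in stage 2. Each entry is a list
#' with `fit(x, y)` and `predict(model, x)` closures behind a common
#' contract; every stochastic learner is seeded so identical seeds give
#' identical predictions. Available algorithms:
#'
#' * `"lr"` — ordinary least squares (rank-deficient-safe),
#' * `"enet"` — elastic net ([glmnet::glmnet()], alpha 0.5, fixed lambda 0.1),
#' * `"rf"` — random forest ([ranger::ranger()], 100 trees),
#' * `"extratrees"` — extremely randomized trees (ranger, extratrees split),
#' * `"gbm"` — gradient boosting ([xgboost::xgboost()], depth 3, eta 0.1),
#' * `"xgb"` — XGBoost (depth 6, eta 0.3),
#' * `"adaboost"` — AdaBoost.R2 boosting of [rpart::rpart()] stumps,
#' * `"mean"` — training-mean predictor (baseline/testing).
#'
#' Degenerate folds are handled uniformly: with no usable features or fewer
#' than two training rows every learner falls back to predicting the
#' training mean (or 0 on an empty fold).
#'
#' @param names character vector of algorithm names (order is the tie-break
#'   order for best-model selection).
#' @param seed integer random state.
#' @return named list of algorithm objects, class `flms_suite`.
#' @export
flms_suite <- function(names = c("lr", "enet", "rf", "adaboost",
                                 "extratrees", "gbm", "xgb"),
                       seed = 42L) {
  known <- c("lr", "enet", "rf", "extratrees", "gbm", "xgb", "adaboost",
             "mean")
  bad <- setdiff(names, known)
  if (length(bad)) stop("unknown algorithm: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names)) stop("duplicate algorithm names in suite")
  algs <- lapply(names, function(nm) make_alg(nm, seed))
  names(algs) <- names
  structure(algs, class = "flms_suite")
}

fit_xgb_booster <- function(x, y, eta, max_depth, nrounds, seed,
                            objective = "reg:squarederror") {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(eta = eta, max_depth = max_depth, objective = objective,
                  nthread = 1L),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
    nrounds = nrounds, verbose = 0L)
}
predict_xgb_booster <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1L))
}

# Fallback for folds too degenerate for a learner.
fit_mean_model <- function(y) {
  structure(list(mu = if (length(y)) mean(y) else 0), class = "flms_mean_model")
}
predict_mean_model <- function(model, x) rep(model$mu, nrow(x))

fit_ols <- function(x, y) {
  xi <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(xi, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(beta = beta), class = "flms_ols")
}
predict_ols <- function(model, x) {
  drop(cbind(1, x) %*% model$beta)
}

# AdaBoost.R2 (linear loss) over depth-limited regression trees, using
# instance weights directly in each weak fit (deterministic variant).
fit_adaboost_r2 <- function(x, y, m_iter = 30L, maxdepth = 3L) {
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list()
  betas <- numeric()
  df <- data.frame(y = y, x, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 2L,
                               minbucket = 1L, cp = 0.001, xval = 0L)
  for (m in seq_len(m_iter)) {
    tree <- rpart::rpart(y ~ ., data = df, weights = w, control = ctrl,
                         method = "anova")
    pred <- stats::predict(tree, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) {          # perfect learner: keep it, stop boosting
      learners[[length(learners) + 1L]] <- tree
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) break    # weak-learner condition violated
    beta <- lbar / (1 - lbar)
    learners[[length(learners) + 1L]] <- tree
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (!length(learners)) {
    learners <- list(rpart::rpart(y ~ ., data = df, control = ctrl,
                                  method = "anova"))
    betas <- 0.5
  }
  structure(list(learners = learners, betas = betas,
                 cols = colnames(x)), class = "flms_adaboost")
}

predict_adaboost_r2 <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- model$cols
  preds <- vapply(model$learners, function(t) stats::predict(t, df),
                  numeric(nrow(df)))
  if (nrow(df) == 1L) preds <- matrix(preds, nrow = 1L)
  lw <- log(1 / model$betas)
  # weighted median of weak predictions per row
  apply(preds, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1L]]
  })
}

make_alg <- function(name, seed) {
  guard_fit <- function(core) {
    function(x, y) {
      if (nrow(x) == 0L) return(fit_mean_model(numeric()))
      if (ncol(x) == 0L || nrow(x) < 2L || stats::var(y) == 0)
        return(fit_mean_model(y))
      core(x, y)
    }
  }
  dispatch_predict <- function(core) {
    function(model, x) {
      if (inherits(model, "flms_mean_model")) return(predict_mean_model(model, x))
      core(model, x)
    }
  }
  switch(
    name,
    mean = list(
      fit = function(x, y) fit_mean_model(y),
      predict = predict_mean_model
    ),
    lr = list(
      fit = guard_fit(fit_ols),
      predict = dispatch_predict(predict_ols)
    ),
    enet = list(
      fit = guard_fit(function(x, y) {
        if (ncol(x) < 2L || nrow(x) < 3L) return(fit_ols(x, y))
        glmnet::glmnet(x, y, alpha = 0.5, lambda = c(1, 0.5, 0.1),
                       standardize = FALSE)
      }),
      predict = dispatch_predict(function(model, x) {
        if (inherits(model, "flms_ols")) return(predict_ols(model, x))
        drop(stats::predict(model, newx = x, s = 0.1))
      })
    ),
    rf = list(
      fit = guard_fit(function(x, y)
        ranger::ranger(x = x, y = y, num.trees = 100L, seed = seed,
                       num.threads = 1L)),
      predict = dispatch_predict(function(model, x)
        stats::predict(model, data = x, num.threads = 1L)$predictions)
    ),
    extratrees = list(
      fit = guard_fit(function(x, y)
        ranger::ranger(x = x, y = y, num.trees = 100L, seed = seed,
                       splitrule = "extratrees", num.random.splits = 1L,
                       num.threads = 1L)),
      predict = dispatch_predict(function(model, x)
        stats::predict(model, data = x, num.threads = 1L)$predictions)
    ),
    gbm = list(
      fit = guard_fit(function(x, y)
        fit_xgb_booster(x, y, eta = 0.1, max_depth = 3L, nrounds = 60L,
                        seed = seed)),
      predict = dispatch_predict(predict_xgb_booster)
    ),
    xgb = list(
      fit = guard_fit(function(x, y)
        fit_xgb_booster(x, y, eta = 0.3, max_depth = 6L, nrounds = 40L,
                        seed = seed)),
      predict = dispatch_predict(predict_xgb_booster)
    ),
    adaboost = list(
      fit = guard_fit(function(x, y) fit_adaboost_r2(x, y)),
      predict = dispatch_predict(predict_adaboost_r2)
    ),
    stop("unknown algorithm: ", name)
  )
}
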