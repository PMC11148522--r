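# Brute-force slot enumeration used to audit every planner's coverage.
all_slots <- function(plan) {
  do.call(rbind, lapply(plan$splits, function(sp)
    plan$slots[sp$test, c("participant", "time_unit")]))
}

test_that("LOPO holds out each participant exactly once", {
  p <- make_panel(list(A = c(5, 7, 7), B = c(3, 4, 2), C = c(9, 9, 8)))
  plan <- plan_lopo(p)
  expect_length(plan$splits, 3L)
  covered <- all_slots(plan)
  slots <- change_scores(p)
  expect_equal(covered[order(covered$participant, covered$time_unit), ],
               slots[order(slots$participant, slots$time_unit),
                     c("participant", "time_unit")],
               ignore_attr = TRUE)
  for (sp in plan$splits) {
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_length(unique(plan$slots$participant[sp$test]), 1L)
  }
  # two participants: each trains on the other
  p2 <- make_panel(list(A = c(5, 7), B = c(3, 4)))
  plan2 <- plan_lopo(p2)
  expect_length(plan2$splits, 2L)
  expect_error(plan_lopo(make_panel(list(A = c(5, 7, 9)))), ">= 2 participants")
})

test_that("LTXO holds out each time unit across all participants", {
  p <- make_panel(list(A = c(5, 7, 7, 4), B = c(3, 4, 2, 2)))
  plan <- plan_ltxo(p)
  slots <- change_scores(p)
  expect_length(plan$splits, length(unique(slots$time_unit)))
  for (sp in plan$splits)
    expect_length(unique(plan$slots$time_unit[sp$test]), 1L)
  # union of predict sets = all target slots
  expect_equal(sort(unlist(lapply(plan$splits, `[[`, "test"))),
               seq_len(nrow(slots)))
  # a unit observed by a single participant still gets its own split
  p2 <- make_panel(list(A = c(5, 7, 7, 4), B = c(3, 4)))
  sizes <- vapply(plan_ltxo(p2)$splits, function(sp) length(sp$test), 0L)
  expect_true(any(sizes == 1L))
})

test_that("ATU forecasting windows grow by the configured step", {
  p <- make_panel(list(A = c(5, 7, 7, 4, 6, 3)))   # 5 target slots
  plan <- plan_atu(p, w0 = 2, step = 1)
  # predict positions 3, 4, 5 of the slot sequence (weeks 4, 5, 6)
  expect_equal(vapply(plan$splits, function(sp)
    plan$slots$time_unit[sp$test], 0L), c(4L, 5L, 6L))
  for (sp in plan$splits)
    expect_true(all(plan$slots$time_unit[sp$train] <
                      plan$slots$time_unit[sp$test]))

  p2 <- make_panel(list(A = c(5, 7, 7, 4, 6, 3, 2)))  # 6 target slots
  plan2 <- plan_atu(p2, w0 = 2, step = 2)
  expect_equal(vapply(plan2$splits, function(sp)
    plan2$slots$time_unit[sp$test], 0L), c(4L, 6L))
  # training always on all prior slots
  expect_equal(plan2$splits[[2]]$train, 1:4)

  # a participant with exactly w0 slots yields nothing
  p3 <- make_panel(list(A = c(5, 7, 6), B = c(1, 2, 3, 4, 5)))
  expect_warning(plan3 <- plan_atu(p3, w0 = 2, step = 1), "skipped")
  expect_false("A" %in% unlist(lapply(plan3$splits, function(sp)
    plan3$slots$participant[sp$test])))
})

test_that("LOTPO predicts each unit from the participant's remaining units", {
  p <- make_panel(list(A = c(5, 7, 7, 4, 6, 3, 2, 8, 9, 1, 2)))  # 10 slots
  plan <- plan_lotpo(p, min_units = 3)
  expect_length(plan$splits, 10L)
  for (sp in plan$splits) {
    expect_length(sp$test, 1L)
    expect_length(sp$train, 9L)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  # min_units = 2 allows training on a single slot
  p2 <- make_panel(list(A = c(5, 7, 6), B = c(5, 7, 6, 8)))
  plan2 <- plan_lotpo(p2, min_units = 2)
  a_splits <- Filter(function(sp)
    all(plan2$slots$participant[sp$test] == "A"), plan2$splits)
  expect_length(a_splits, 2L)
  expect_length(a_splits[[1]]$train, 1L)
  # below the minimum: skipped with warning
  p3 <- make_panel(list(A = c(5, 7), B = c(5, 7, 6, 8)))
  expect_warning(plan3 <- plan_lotpo(p3, min_units = 3), "skipped")
  expect_false("A" %in% unlist(lapply(plan3$splits, function(sp)
    plan3$slots$participant[sp$test])))
})

test_that("each strategy's predicted slots match its defining partition", {
  set.seed(31)
  for (rep in 1:5) {
    n_p <- sample(3:5, 1)
    scores <- stats::setNames(lapply(seq_len(n_p), function(i)
      sample(0:27, sample(4:7, 1), replace = TRUE)), LETTERS[seq_len(n_p)])
    p <- make_panel(scores)
    slots <- change_scores(p)
    # LOPO/LTXO/LOTPO(min 2): every target slot predicted exactly once
    for (plan in list(plan_lopo(p), plan_ltxo(p), plan_lotpo(p, 2))) {
      tested <- unlist(lapply(plan$splits, `[[`, "test"))
      expect_equal(sort(tested), seq_len(nrow(slots)))
    }
    # ATU: exactly the slots after the initial window, per participant
    plan <- plan_atu(p, w0 = 2, step = 1)
    tested <- sort(unlist(lapply(plan$splits, `[[`, "test")))
    oracle <- unlist(lapply(unique(slots$participant), function(pp) {
      idx <- which(slots$participant == pp)
      idx[order(slots$time_unit[idx])][-(1:2)]
    }))
    expect_equal(tested, sort(oracle))
  }
})

test_that("the suite predicts constants on constant targets and is seed-stable", {
  p <- make_panel(list(A = c(5, 5, 5, 5), B = c(3, 3, 3, 3), C = c(2, 2, 2, 2)))
  slots <- change_scores(p)    # all changes 0
  x <- fusion_matrix(p, p$modalities, slots)
  plan <- plan_lopo(p, slots)
  cfg <- flms_config(suite = "mean", seed = 42)
  cubeset <- fit_predict_suite(x, plan, flms_suite("mean", 42), cfg)
  expect_true(all(cubeset$pred[, "mean"] == 0))

  cfg2 <- flms_config(suite = c("lr", "rf", "xgb"), seed = 42)
  p2 <- small_cohort(seed = 2)
  slots2 <- change_scores(p2)
  x2 <- fusion_matrix(p2, p2$modalities, slots2)
  plan2 <- plan_lopo(p2, slots2)
  a <- fit_predict_suite(x2, plan2, flms_suite(cfg2$suite, 42), cfg2)
  b <- fit_predict_suite(x2, plan2, flms_suite(cfg2$suite, 42), cfg2)
  expect_identical(a$pred, b$pred)
})

test_that("a linear algorithm recovers a noiseless linear signal", {
  # y = 3 * x exactly; out-of-fold OLS predictions must be exact
  set.seed(5)
  n <- 12
  sc <- data.frame(participant = rep(c("A", "B", "C"), each = 4),
                   time_unit = rep(1:4, 3),
                   score = rep(10L, n))
  xval <- rnorm(n, sd = 2)
  f <- data.frame(participant = sc$participant, time_unit = sc$time_unit,
                  modality = "m", feature = "f1", value = xval)
  p <- flms_panel(f, sc)
  slots <- change_scores(p)
  xmat <- fusion_matrix(p, "m", slots)
  slots$change <- 3 * xmat[, 1]   # overwrite target with exact linear map
  plan <- plan_lopo(p, slots)
  cfg <- flms_config(suite = "lr", corr_threshold = 1)
  got <- fit_predict_suite(xmat, plan, flms_suite("lr", 1), cfg)
  expect_equal(got$pred[, "lr"], slots$change, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("best-model selection is an exact argmin with suite-order ties", {
  slots <- data.frame(participant = rep("A", 2), time_unit = 2:3,
                      change = c(1, 1))
  preds <- cbind(algA = c(2, 0), algB = c(1, 4))  # both sum |err| = 2
  cubeset <- structure(list(pred = preds, slots = slots, strategy = "LOPO"),
                       class = "flms_cubeset")
  best <- select_best_model(cubeset, flms_config())
  expect_equal(unname(best$best_alg["A"]), "algA")   # tie -> first in suite
  expect_equal(best$pred, preds[, "algA"])

  preds2 <- cbind(algA = c(2, 2), algB = c(1, 1.5))  # B strictly better
  cubeset2 <- structure(list(pred = preds2, slots = slots, strategy = "LOPO"),
                        class = "flms_cubeset")
  expect_equal(unname(select_best_model(cubeset2, flms_config())$best_alg["A"]),
               "algB")
})

test_that("best-model selection matches an exhaustive oracle and never hurts", {
  set.seed(77)
  for (rep in 1:20) {
    n_p <- 4; n_slots <- 6
    slots <- data.frame(
      participant = rep(LETTERS[1:n_p], each = n_slots),
      time_unit = rep(2:(n_slots + 1), n_p),
      change = sample(-5:5, n_p * n_slots, replace = TRUE))
    preds <- matrix(rnorm(nrow(slots) * 3, sd = 3), ncol = 3,
                    dimnames = list(NULL, c("a1", "a2", "a3")))
    cubeset <- structure(list(pred = preds, slots = slots, strategy = "X"),
                         class = "flms_cubeset")
    best <- select_best_model(cubeset, flms_config())
    for (pp in LETTERS[1:n_p]) {
      idx <- slots$participant == pp
      errs <- colSums(abs(preds[idx, ] - slots$change[idx]))
      expect_equal(unname(best$best_alg[pp]), names(errs)[which.min(errs)])
      # chosen error is <= every single-algorithm error
      expect_lte(sum(abs(best$pred[idx] - slots$change[idx])), min(errs) + 1e-12)
    }
  }
})

test_that("honest selection uses only the first half of a participant's slots", {
  slots <- data.frame(participant = rep("A", 4), time_unit = 2:5,
                      change = c(0, 0, 10, 10))
  # algA perfect early, terrible late; algB the reverse
  preds <- cbind(algA = c(0, 0, 0, 0), algB = c(10, 10, 10, 10))
  cubeset <- structure(list(pred = preds, slots = slots, strategy = "X"),
                       class = "flms_cubeset")
  honest <- select_best_model(cubeset, flms_config(honest_selection = TRUE))
  expect_equal(unname(honest$best_alg["A"]), "algA")
  full <- select_best_model(cubeset, flms_config())
  expect_equal(unname(full$best_alg["A"]), "algA")  # tie on all slots -> first
})
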