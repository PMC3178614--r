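test_that("AUC anchors: perfect discrimination, chance, and full ties", {
  expect_equal(compute_auc(c(5, 6, 7), c(1, 2, 3, 4)), 1)
  expect_equal(compute_auc(c(1, 2), c(5, 6, 7)), 0)
  expect_equal(compute_auc(rep(2, 10), rep(2, 25)), 0.5)  # tie convention
  set.seed(4)
  aucs <- replicate(50, compute_auc(rnorm(400), rnorm(400)))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("AUC is invariant under strictly monotone transforms and antisymmetric", {
  set.seed(7)
  p <- runif(30); b <- runif(100)
  a <- compute_auc(p, b)
  expect_equal(compute_auc(exp(3 * p), exp(3 * b)), a)
  expect_equal(compute_auc(qlogis(p), qlogis(b)), a)
  expect_equal(compute_auc(b, p), 1 - a)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(12)
  p <- rnorm(40, 1); b <- rnorm(150)
  ours <- compute_auc(p, b)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 150)), predictor = c(p, b),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("binomial omission p-values match closed forms", {
  # background: half the cells at/above the threshold (a = 0.5)
  surf <- surface_from_scores(c(rep(0.8, 10), rep(0.2, 10)))
  thr <- data.frame(name = "t", value = 0.5)
  # all 10 test presences above the threshold
  tests <- binomial_omission_tests(surf, train_cells = 1:3, test_cells = 1:10,
                                   thresholds = thr)
  te <- tests[tests$partition == "test", ]
  expect_equal(te$area, 0.5)
  expect_equal(te$omission, 0)
  expect_equal(te$p, 0.5^10)

  # a = 1: whole area predicted present -> p = 1 regardless of k
  thr0 <- data.frame(name = "t", value = 0)
  t0 <- binomial_omission_tests(surf, 1:3, 11:15, thresholds = thr0)
  expect_equal(t0$p, c(1, 1))

  # k = 0: P(X >= 0) = 1
  thr9 <- data.frame(name = "t", value = 0.9)
  t9 <- binomial_omission_tests(surf, 11:13, 11:15, thresholds = thr9)
  expect_equal(t9$p, c(1, 1))
  expect_equal(t9$omission, c(1, 1))
})

test_that("the standard threshold battery has 11 members with sane values", {
  set.seed(5)
  sc <- simulate_reconstruction_scenario(seed = 5, n_rows = 20, n_cols = 20,
                                         n_records = 40)
  st <- sc$stack
  f <- expand_features(st, n_presence = 15)
  pres <- sample(which(st$valid), 15)
  m <- fit_maxent(pres, which(st$valid), f)
  surf <- predict(m, f)
  thr <- omission_thresholds(surf, pres[1:9], pres[10:15])
  expect_equal(nrow(thr), 11)
  expect_equal(anyDuplicated(thr$name), 0)
  expect_true(all(thr$value >= 0 & thr$value <= 1))
  expect_equal(thr$value[thr$name == "min_training_presence"],
               min(surf$logistic[pres[1:9]]))
  tests <- binomial_omission_tests(surf, pres[1:9], pres[10:15])
  expect_equal(nrow(tests), 22)  # 11 thresholds x 2 partitions
  expect_true(all(tests$p >= 0 & tests$p <= 1))
  expect_true(all(tests$area >= 0 & tests$area <= 1))
})

test_that("omission p-values are uniform or super-uniform under a random surface", {
  set.seed(31)
  n_bg <- 200
  reject <- replicate(400, {
    surf <- surface_from_scores(runif(n_bg))
    pres <- sample(n_bg, 10)
    thr <- data.frame(name = "t",
                      value = quantile(surf$logistic, 0.6, names = FALSE))
    binomial_omission_tests(surf, pres, pres, thresholds = thr)$p[1] < 0.05
  })
  expect_lte(mean(reject), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("the three-criterion rule accepts and rejects correctly", {
  good <- report_with(train_auc = 0.96, test_auc = 0.93)
  expect_true(evaluate_acceptance(good)$accepted)
  # criterion (iii) on the stated example: gap 3.1% < 5%
  expect_equal(evaluate_acceptance(good)$auc_gap, (0.96 - 0.93) / 0.96,
               tolerance = 1e-12)

  low_auc <- report_with(0.95, 0.89)
  d <- evaluate_acceptance(low_auc)
  expect_false(d$accepted); expect_false(d$criterion_i)

  one_bad_p <- report_with(0.96, 0.93)
  one_bad_p$omission$p[7] <- 0.06
  d <- evaluate_acceptance(one_bad_p)
  expect_false(d$accepted); expect_false(d$criterion_ii)
  expect_true(d$criterion_i); expect_true(d$criterion_iii)

  wide_gap <- report_with(0.99, 0.93)  # 6.1% relative gap
  d <- evaluate_acceptance(wide_gap)
  expect_false(d$accepted); expect_false(d$criterion_iii)
  # absolute interpretation available behind the flag
  expect_true(evaluate_acceptance(report_with(0.99, 0.945),
                                  gap_relative = FALSE)$criterion_iii)
})

test_that("acceptance is monotone: improving AUCs and p never flips accept to reject", {
  set.seed(8)
  for (i in 1:20) {
    tr <- runif(1, 0.85, 1); te <- runif(1, 0.85, tr); p <- runif(1, 0, 0.2)
    base <- evaluate_acceptance(report_with(tr, te, p = p))
    # improve: raise test AUC toward train, shrink p
    better <- evaluate_acceptance(report_with(
      tr, te + 0.5 * (tr - te), p = p / 2))
    if (base$accepted) expect_true(better$accepted)
  }
})

test_that("expert rank aggregation averages, selects top-k, and breaks ties by id", {
  tab <- rbind(c(4, 3, 2, 5), c(5, 3, 2, 4))
  colnames(tab) <- c("m1", "m2", "m3", "m4")
  agg <- aggregate_expert_ranks(tab, top_k = 2)
  expect_equal(unname(agg$mean_ranks["m1"]), 4.5)
  expect_setequal(agg$selected, c("m1", "m4"))

  # two candidates tied at the top both make top_k = 2
  tab2 <- rbind(c(3, 4.5, 4.5, 2), c(3, 4.5, 4.5, 2))
  colnames(tab2) <- c("a", "b", "c", "d")
  expect_setequal(aggregate_expert_ranks(tab2, 2)$selected, c("b", "c"))

  # all tied: first top_k by id, tie flagged
  tab3 <- matrix(3, 2, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  agg3 <- aggregate_expert_ranks(tab3, 2)
  expect_equal(agg3$selected, c("w", "x"))
  expect_true(agg3$tied)

  expect_error(aggregate_expert_ranks(rbind(c(1, NA))), "empty")
  expect_error(aggregate_expert_ranks(rbind(c(0, 6))), "\\[1, 5\\]")
})

test_that("best-model selection is argmax with lexicographic tie-break", {
  expect_equal(select_best_model_per_species(c("3" = 0.9887,
                                               "9" = 0.97))$set_id, "3")
  expect_equal(select_best_model_per_species(c("9" = 0.5))$set_id, "9")
  tie <- select_best_model_per_species(c("9" = 0.95, "3" = 0.95))
  expect_equal(tie$set_id, "3")
  expect_true(tie$tied)
  expect_error(select_best_model_per_species(numeric(0)), "no candidate")
})
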