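auc_pairwise <- oracle_auc_pairwise
ap_stepsum <- oracle_ap_stepsum
youden_scan <- oracle_youden_scan

test_that("AUC-ROC equals the pairwise Mann-Whitney statistic", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")

  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(runif(n), 2))  # rounded to force ties
    expect_equal(auc_roc(scores, labels), auc_pairwise(scores, labels))
  }
})

test_that("AUC-ROC is invariant under strictly monotone transforms", {
  set.seed(5)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  a <- auc_roc(scores, labels)
  expect_equal(auc_roc(exp(scores), labels), a)
  expect_equal(auc_roc(atan(scores), labels), a)
  expect_equal(auc_roc(rank(scores), labels), a)
})

test_that("average precision matches the step-sum oracle", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_error(auc_pr(1:3, c(0, 0, 0)), "no positive")
  set.seed(55)
  for (i in 1:100) {
    n <- 10
    labels <- c(1, rbinom(n - 1, 1, 0.5))
    scores <- runif(n)
    expect_equal(auc_pr(scores, labels), ap_stepsum(scores, labels))
  }
})

test_that("average precision of random scores concentrates near prevalence", {
  set.seed(77)
  n <- 2000
  labels <- rep(c(1, 0), n / 2)
  ap <- auc_pr(runif(n), labels)
  expect_equal(ap, 0.5, tolerance = 0.05)
})

test_that("AUC-ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(120)
  labels <- rbinom(120, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(auc_roc(scores, labels), ref, tolerance = 1e-12)
})

test_that("PPV at k counts positives among the top-scored items", {
  expect_equal(ppv_at_k(c(0.9, 0.1, 0.2), c(1, 0, 0), 1), 1.0)
  expect_equal(ppv_at_k(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 1), 3), 2 / 3)
  expect_error(ppv_at_k(1:3, c(1, 0, 1), 4), "k must be")
  expect_error(ppv_at_k(1:3, c(1, 0, 1), 0), "k must be")
})

test_that("Youden cutoff equals an exhaustive threshold scan", {
  out <- youden_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(out$J, 1)
  expect_gt(out$threshold, 0.2)
  expect_lt(out$threshold, 0.8)
  expect_error(youden_cutoff(1:4, rep(1, 4)), "both classes")
  set.seed(33)
  for (i in 1:100) {
    scores <- round(runif(15), 1)
    labels <- c(1, 0, rbinom(13, 1, 0.5))
    expect_equal(youden_cutoff(scores, labels)$J, youden_scan(scores, labels))
  }
})

test_that("zero-shot partitions are epitope-disjoint under the threshold rule", {
  pairs <- data.frame(
    epitope = rep(c("A", "B"), c(12, 3)),
    cdr3b = random_cdr3b(15, 12, seed = 2), label = 1)
  pairs$epitope <- ifelse(pairs$epitope == "A", "SIINFEKLY", "GILGFVFTL")
  sp <- zero_shot_partition(pairs, min_count = 10L)
  expect_equal(unique(sp$train$epitope), "SIINFEKLY")
  expect_equal(unique(sp$test$epitope), "GILGFVFTL")
  expect_length(intersect(sp$train$epitope, sp$test$epitope), 0)

  # degenerate threshold: everything trains
  sp0 <- zero_shot_partition(pairs, min_count = 0L)
  expect_equal(nrow(sp0$test), 0L)
  expect_error(zero_shot_partition(pairs[0, ]), "empty")

  # strictness: a count exactly at the threshold goes to test
  at <- data.frame(epitope = rep("KVAELVHFL", 10), label = 1)
  expect_equal(nrow(zero_shot_partition(at, min_count = 10L)$train), 0L)

  # property: disjointness for random partitions
  set.seed(3)
  for (i in 1:20) {
    df <- data.frame(epitope = sample(LETTERS[1:8], 60, replace = TRUE))
    sp <- zero_shot_partition(df, min_count = sample(2:12, 1))
    expect_length(intersect(sp$train$epitope, sp$test$epitope), 0)
  }
})

test_that("resampled evaluation is seeded and sized as requested", {
  pos <- data.frame(cdr3b = random_cdr3b(8, 13, seed = 12),
                    epitope = "SIINFEKLY", pseudo = random_pseudo())
  pool <- gen_background_tcrs(500, seed = 13)
  scorer <- function(df) {
    nchar(df$cdr3b) +
      cos(vapply(substr(df$cdr3b, 1, 1), utf8ToInt, numeric(1)))
  }
  rep1 <- resampled_eval(scorer, pos, pool, ratio = 10L, n_sets = 5L,
                         ppv_k = c(5L), seed = 14)
  expect_equal(nrow(rep1$sets), 5L)
  expect_true(all(rep1$sets$auc_roc >= 0 & rep1$sets$auc_roc <= 1))
  rep2 <- resampled_eval(scorer, pos, pool, ratio = 10L, n_sets = 5L,
                         ppv_k = c(5L), seed = 14)
  expect_identical(rep1$sets, rep2$sets)
})
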