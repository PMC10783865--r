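test_that("mapping layers are bias-free rank-1 projections per direction", {
  b <- init_binder(toy_tcr_config(), toy_pmhc_config(), seed = 2L)
  enc <- toy_tcr_encoder()
  tok <- tokenize_tcr("CASSLGQAYEQYF")
  E <- encode(enc, tok)
  v <- map_embeddings(b, E, "tcr")
  expect_length(v$v_len, 32L)
  expect_length(v$v_dim, 32L)
  expect_equal(v$v_len, as.vector(E %*% b$weights$tcr_w_dim))
  expect_equal(v$v_dim, as.vector(t(E) %*% b$weights$tcr_w_len))

  # zero matrix -> zero vectors (linearity, no bias)
  z <- map_embeddings(b, matrix(0, 32, 32), "tcr")
  expect_equal(z$v_len, rep(0, 32))
  expect_equal(z$v_dim, rep(0, 32))

  # pad rows are zero by the encoder contract, so both vectors ignore them
  E2 <- E
  E2[(tok$true_len + 1):32, ] <- 0  # already zero; assert the contract
  expect_equal(E, E2)
  expect_error(map_embeddings(b, E[1:10, ], "tcr"), "expected")
})

test_that("pair scores live strictly inside (-1, 1) and are deterministic", {
  b <- init_binder(toy_tcr_config(), toy_pmhc_config(), seed = 5L)
  tenc <- toy_tcr_encoder(); penc <- toy_pmhc_encoder()
  pseudo <- random_pseudo()
  df <- data.frame(cdr3b = random_cdr3b(5, 14, seed = 9),
                   epitope = "SIINFEKLY", pseudo = pseudo)
  f <- score_pairs(b, tenc, penc, df)
  expect_length(f, 5L)
  expect_true(all(abs(f) < 1))
  expect_identical(f, score_pairs(b, tenc, penc, df))
  f1 <- score_pair(b, tenc, penc, df$cdr3b[1], "SIINFEKLY", pseudo)
  expect_equal(f1, f[1])
})

test_that("contrastive loss matches its closed form and identity", {
  expect_equal(contrast_loss(0, 0), 1.0)
  expect_equal(contrast_loss(1, -1), 0.4)
  expect_equal(contrast_loss(0.9, -0.8), 0.29)
  # identity: loss(f, f) = 1 + 0.4 f^2
  grid <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(contrast_loss(grid, grid), 1 + 0.4 * grid^2)
  expect_true(all(contrast_loss(runif(50, -1, 1), runif(50, -1, 1)) >= 0))
})

test_that("negative sampling preserves the positive pMHC multiset", {
  pos <- data.frame(cdr3b = random_cdr3b(20, 14, seed = 3),
                    epitope = rep(c("SIINFEKLY", "GILGFVFTL"), 10),
                    pseudo = random_pseudo(), label = 1)
  pool <- gen_background_tcrs(100, seed = 4)
  neg <- sample_negatives(pos, pool, ratio = 1, seed = 5)
  expect_equal(nrow(neg), 20L)
  expect_true(all(neg$epitope %in% pos$epitope))
  expect_equal(table(neg$epitope), table(pos$epitope))
  expect_true(all(neg$cdr3b %in% pool))
  expect_false(any(paste(neg$cdr3b, neg$epitope) %in%
                   paste(pos$cdr3b, pos$epitope)))
  expect_identical(neg, sample_negatives(pos, pool, ratio = 1, seed = 5))
  neg3 <- sample_negatives(pos, pool, ratio = 3, seed = 6)
  expect_equal(nrow(neg3), 60L)
  expect_error(sample_negatives(pos, character(0)), "empty")
})

test_that("rank scores use midranks and behave under monotone transforms", {
  bg <- c(0.1, 0.2, 0.2, 0.7)
  expect_equal(rank_from_scores(0.9, bg), 1)
  expect_equal(rank_from_scores(0.05, bg), 0)
  expect_equal(rank_from_scores(0.2, bg), (1 + 0.5 * 2) / 4)
  # monotone non-decreasing in f; invariant to background shuffling;
  # equivariant under strictly monotone transforms
  set.seed(11)
  bg <- rnorm(200)
  f <- sort(rnorm(20))
  r <- rank_from_scores(f, bg)
  expect_true(all(diff(r) >= 0))
  expect_equal(r, rank_from_scores(f, sample(bg)))
  expect_equal(r, rank_from_scores(exp(f), exp(bg)))
})

test_that("rank_score draws the requested ensemble and enforces pool size", {
  b <- init_binder(toy_tcr_config(), toy_pmhc_config(), seed = 7L)
  tenc <- toy_tcr_encoder(); penc <- toy_pmhc_encoder()
  pool <- gen_background_tcrs(60, seed = 12)
  rs <- rank_score(b, tenc, penc, pool[1], "SIINFEKLY", random_pseudo(),
                   pool, n = 50L, seed = 1)
  expect_true(rs$rank >= 0 && rs$rank <= 1)
  expect_equal(rs$n, 50L)
  expect_error(rank_score(b, tenc, penc, pool[1], "SIINFEKLY",
                          random_pseudo(), pool, n = 100L), "smaller")
})

test_that("binder training optimizes the margin and records history", {
  pd <- gen_pair_dataset(n_pos = 150L, n_neg = 0L, seed = 61L,
                         n_test_pos = 10L, n_test_neg = 10L,
                         n_train_epitopes = 6L, n_test_epitopes = 2L)
  pool <- gen_background_tcrs(300L, seed = 62L)
  tenc <- toy_tcr_encoder(); penc <- toy_pmhc_encoder()
  sch <- binder_schedule(max_epochs = 4L, batch_size = 64L, seed = 63L)
  fit <- train_binder(pd$train, pool, tenc, penc, sch)
  expect_s3_class(fit, "binder_model")
  expect_lte(nrow(fit$history), 4L)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$train_loss >= 0))
  # the head received gradient (a few epochs may still sit on the margin
  # loss's initial plateau; full learning is exercised by the end-to-end
  # planted-rule study)
  b0 <- init_binder(toy_tcr_config(), toy_pmhc_config(), seed = sch$seed)
  expect_false(identical(fit$weights$W1, b0$weights$W1))
  expect_error(train_binder(pd$train[pd$train$label == 0, ], pool,
                            tenc, penc, sch), "no positive")
})
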