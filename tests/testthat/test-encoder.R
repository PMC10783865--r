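test_that("configuration defaults match the published architecture", {
  cf <- encoder_config()
  expect_equal(cf$n_layers, 4L)
  expect_equal(cf$dim, 256L)
  expect_equal(cf$n_heads, 8L)
  expect_equal(cf$ff_dim, 1024L)
  expect_error(encoder_config(dim = 65L, n_heads = 8L), "divisible")
})

test_that("initialization is reproducible and counts parameters in closed form", {
  a <- init_encoder(toy_tcr_config(), seed = 3L)
  b <- init_encoder(toy_tcr_config(), seed = 3L)
  expect_identical(a$weights, b$weights)

  # closed-form count: embeddings + embedding LN + per-layer blocks + MLM head
  expected_count <- function(cf, nsp = FALSE) {
    D <- cf$dim; FF <- cf$ff_dim; V <- cf$vocab_size
    emb <- V * D + cf$max_len * D + 2 * D +
      if (cf$n_segments > 0) cf$n_segments * D else 0
    per_layer <- 4 * (D * D + D) + 2 * (2 * D) + D * FF + FF + FF * D + D
    head <- D * V + V
    nsp_head <- if (nsp) (2 * D) * D + D + D + 1 else 0
    emb + cf$n_layers * per_layer + head + nsp_head
  }
  expect_equal(n_params(a), expected_count(toy_tcr_config()))
  p <- init_encoder(toy_pmhc_config(), seed = 1L)
  expect_equal(n_params(p), expected_count(toy_pmhc_config(), nsp = TRUE))
})

test_that("encoding is deterministic with the declared shape", {
  enc <- toy_tcr_encoder()
  tok <- tokenize_tcr("CASSLGQAYEQYF")
  E <- encode(enc, tok)
  expect_equal(dim(E), c(32L, 32L))
  expect_true(all(is.finite(E)))
  expect_identical(E, encode(enc, tok))
  expect_error(encode(enc, tokenize_tcr("CASSLGQAYEQYF", max_len = 40L)),
               "max_len")
})

test_that("outputs at true positions are invariant to pad perturbations", {
  enc <- toy_tcr_encoder()
  tok <- tokenize_tcr("CASSLGQAYEQYF")
  E1 <- encode(enc, tok)
  tok2 <- tok
  # overwrite pad ids with arbitrary residue ids
  tok2$ids[(tok$true_len + 1):tok$max_len] <- 5L
  E2 <- encode(enc, tok2)
  expect_lt(max(abs(E1[seq_len(tok$true_len), ] -
                    E2[seq_len(tok$true_len), ])), 1e-5)
})

test_that("uniform logits give MLM loss ln(vocab) and empty masks give 0", {
  enc <- toy_tcr_encoder()
  enc$weights$mlm_W[] <- 0
  enc$weights$mlm_b[] <- 0
  tok <- tokenize_tcr("CASSLGQAYEQYF")
  set.seed(2)
  ex <- apply_mlm_mask(tok, rate = 0.5)
  expect_gt(length(ex$mask_positions), 0)
  expect_equal(mlm_loss(enc, list(ex)), log(24), tolerance = 1e-3)

  set.seed(2)
  none <- apply_mlm_mask(tok, rate = 0)
  expect_equal(mlm_loss(enc, list(none)), 0)
})

test_that("attention profiles are normalized, per-residue and deterministic", {
  enc <- toy_tcr_encoder()
  s <- "CASSLGQAYEQYF"
  p <- attention_profile(enc, s)
  expect_length(p, nchar(s))
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  expect_equal(as.numeric(p), as.numeric(attention_profile(enc, s)))
  # restricting to a subset of layers still normalizes
  p1 <- attention_profile(enc, s, layers = 1L)
  expect_equal(sum(p1), 1)
})

test_that("learning-rate schedule follows linear warmup and plateau decay", {
  expect_equal(tcrbinder:::lr_at(2000, 5e-4, 4000, 1), 0.5 * 5e-4)
  expect_equal(tcrbinder:::lr_at(4000, 5e-4, 4000, 1), 5e-4)
  expect_equal(tcrbinder:::lr_at(8000, 5e-4, 4000, 1), 5e-4)

  sch <- train_schedule(plateau_factor = 0.3, plateau_patience = 2L,
                        early_stop_patience = 4L)
  tr <- tcrbinder:::plateau_tracker(sch)
  expect_false(tr$update(1.0))  # improvement
  expect_false(tr$update(1.1))  # 1 bad epoch
  expect_false(tr$update(1.2))  # 2 bad epochs -> decay
  expect_equal(tr$mult, 0.3)
  expect_false(tr$update(1.3))  # 3rd bad epoch, counter restarted
  expect_true(tr$update(1.4))   # 4 bad epochs since best -> stop
})

test_that("MLM pretraining reduces validation loss on a structured corpus", {
  # repertoire with conserved motifs gives the model something to learn
  rep <- gen_tcr_repertoire(1200L, planted_rate = 0.8, seed = 21L)
  cf <- toy_tcr_config()
  sch <- train_schedule(peak_lr = 1e-3, batch_size = 128L,
                        warmup_steps = 10L, max_epochs = 2L,
                        val_fraction = 0.05, seed = 21L)
  enc <- pretrain_mlm(rep$sequences, cf, sch)
  init_enc <- init_encoder(cf, seed = sch$seed)
  # compare against the initial model on the same fixed validation mask
  set.seed(99)
  toks <- lapply(sample(rep$sequences, 200), tokenize_tcr)
  exs <- lapply(toks, apply_mlm_mask, rate = 0.15)
  expect_lt(mlm_loss(enc, exs), mlm_loss(init_enc, exs))
  expect_equal(nrow(enc$history), 2L)
  expect_error(pretrain_mlm(character(0), cf, sch), "empty corpus")
})

test_that("pretraining is reproducible per seed", {
  rep <- gen_background_tcrs(300L, seed = 31L)
  cf <- encoder_config(n_layers = 1L, dim = 16L, n_heads = 2L,
                       ff_dim = 32L, max_len = 32L)
  sch <- train_schedule(batch_size = 128L, warmup_steps = 5L,
                        max_epochs = 2L, val_fraction = 0.05, seed = 8L)
  h1 <- pretrain_mlm(rep, cf, sch)
  h2 <- pretrain_mlm(rep, cf, sch)
  expect_identical(h1$history, h2$history)
  expect_identical(h1$weights, h2$weights)
})

test_that("checkpoints round-trip weights, config and history", {
  enc <- toy_tcr_encoder()
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  save_encoder(enc, prefix)
  back <- load_encoder(prefix)
  expect_identical(back$weights, enc$weights)
  expect_equal(back$config, enc$config)
})
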