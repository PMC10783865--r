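# The encoder core ships its own backpropagation; verify it against central
# finite differences on a small configuration, for both the masked-LM path
# and the joint selective-masking + regression path.

fd_check <- function(weights, lossfn, grads, names_to_check, n_per = 3L,
                     eps = 1e-5) {
  worst <- 0
  for (nm in names_to_check) {
    w2 <- weights
    set.seed(utf8ToInt(substr(nm, nchar(nm), nchar(nm))))
    idx <- sample(length(w2[[nm]]), min(n_per, length(w2[[nm]])))
    for (i in idx) {
      w2[[nm]][i] <- weights[[nm]][i] + eps
      up <- lossfn(w2)
      w2[[nm]][i] <- weights[[nm]][i] - eps
      dn <- lossfn(w2)
      w2[[nm]][i] <- weights[[nm]][i]
      num <- (up - dn) / (2 * eps)
      ana <- grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  worst
}

test_that("analytic MLM gradients match finite differences", {
  cfg <- encoder_config(n_layers = 2L, dim = 16L, n_heads = 2L,
                        ff_dim = 32L, max_len = 16L, dropout = 0)
  enc <- init_encoder(cfg, seed = 7L)
  bt <- tcrbinder:::tokenize_tcr_batch(random_cdr3b(2, 12, seed = 1),
                                       max_len = 16L)
  set.seed(1)
  m <- tcrbinder:::mask_ids_batch(bt$ids, bt$lens, 0.4, build_vocab())
  lossfn <- function(w) {
    tcrbinder:::cpp_bert_grad(w, m$input, m$target, bt$segments, bt$lens,
                              rep(NA_real_, 2), cfg$n_layers, cfg$n_heads,
                              FALSE, FALSE, 0, FALSE, FALSE)$ce
  }
  r <- tcrbinder:::cpp_bert_grad(enc$weights, m$input, m$target, bt$segments,
                                 bt$lens, rep(NA_real_, 2), cfg$n_layers,
                                 cfg$n_heads, FALSE, FALSE, 0, FALSE, TRUE)
  worst <- fd_check(enc$weights, lossfn, r$grads,
                    c("tok_emb", "pos_emb", "emb_ln_g", "l1_Wq", "l1_bk",
                      "l1_Wo", "l1_ln1_g", "l1_W1", "l1_b2", "l2_Wv",
                      "l2_ln2_b", "mlm_W", "mlm_b"))
  expect_lt(worst, 1e-3)
})

test_that("analytic joint SMLM + NSP gradients match finite differences", {
  cfg <- pmhc_config(n_layers = 1L, dim = 16L, n_heads = 2L, ff_dim = 32L,
                     max_len = 48L, dropout = 0)
  enc <- init_encoder(cfg, seed = 8L)
  bt <- tcrbinder:::tokenize_pmhc_batch(
    c(random_pseudo(1), random_pseudo(2)), c("SIINFEKLY", "GILGFVFTL"),
    max_len = 48L)
  set.seed(2)
  m <- tcrbinder:::mask_ids_batch(bt$ids, bt$lens, 0.3, build_vocab())
  lab <- c(0.9, 0.1)
  lossfn <- function(w) {
    r <- tcrbinder:::cpp_bert_grad(w, m$input, m$target, bt$segments,
                                   bt$lens, lab, cfg$n_layers, cfg$n_heads,
                                   TRUE, TRUE, 0, FALSE, FALSE)
    r$ce + r$mse
  }
  r <- tcrbinder:::cpp_bert_grad(enc$weights, m$input, m$target, bt$segments,
                                 bt$lens, lab, cfg$n_layers, cfg$n_heads,
                                 TRUE, TRUE, 0, FALSE, TRUE)
  worst <- fd_check(enc$weights, lossfn, r$grads,
                    c("tok_emb", "seg_emb", "l1_Wk", "l1_W2", "nsp_W1",
                      "nsp_b1", "nsp_w", "mlm_W"))
  expect_lt(worst, 1e-3)
})

test_that("binder MLP and mapping gradients match finite differences", {
  tcfg <- encoder_config(n_layers = 1L, dim = 8L, n_heads = 2L, ff_dim = 16L,
                         max_len = 32L)
  pcfg <- pmhc_config(n_layers = 1L, dim = 8L, n_heads = 2L, ff_dim = 16L,
                      max_len = 52L)
  tenc <- init_encoder(tcfg, seed = 2L)
  penc <- init_encoder(pcfg, seed = 3L)
  b <- init_binder(tcfg, pcfg, hidden = c(6L, 5L, 4L), seed = 4L)
  pos <- data.frame(cdr3b = random_cdr3b(3, 13, seed = 5),
                    epitope = "SIINFEKLY", pseudo = random_pseudo())
  neg <- data.frame(cdr3b = random_cdr3b(3, 15, seed = 6),
                    epitope = "SIINFEKLY", pseudo = random_pseudo())
  tbank <- tcrbinder:::embed_bank_tcr(tenc, c(pos$cdr3b, neg$cdr3b))
  pbank <- tcrbinder:::embed_bank_pmhc(penc, pos$pseudo, pos$epitope)
  ti_p <- unname(tbank$index[pos$cdr3b]); ti_n <- unname(tbank$index[neg$cdr3b])
  pi_b <- unname(pbank$index[paste(pos$pseudo, pos$epitope, sep = "|")])

  lossfn <- function(w) {
    Xp <- tcrbinder:::pair_features(w, tbank, pbank, ti_p, pi_b)
    Xn <- tcrbinder:::pair_features(w, tbank, pbank, ti_n, pi_b)
    fp <- tcrbinder:::mlp_forward(w, Xp)$f
    fn <- tcrbinder:::mlp_forward(w, Xn)$f
    mean(contrast_loss(fp, fn))
  }
  w <- b$weights
  Xp <- tcrbinder:::pair_features(w, tbank, pbank, ti_p, pi_b)
  Xn <- tcrbinder:::pair_features(w, tbank, pbank, ti_n, pi_b)
  cp <- tcrbinder:::mlp_forward(w, Xp, keep = TRUE)
  cn <- tcrbinder:::mlp_forward(w, Xn, keep = TRUE)
  act <- (1 + cn$f - cp$f) > 0
  gp <- tcrbinder:::mlp_backward(w, cp, (-1 * act + 0.4 * cp$f) / 3)
  gn <- tcrbinder:::mlp_backward(w, cn, (act + 0.4 * cn$f) / 3)
  grads <- Map(`+`, gp[names(gp) != "dX"], gn[names(gn) != "dX"])
  grads <- c(grads,
             Map(`+`,
                 tcrbinder:::map_grads(gp$dX, tbank, pbank, ti_p, pi_b,
                                       b$dims),
                 tcrbinder:::map_grads(gn$dX, tbank, pbank, ti_n, pi_b,
                                       b$dims)))
  worst <- fd_check(w, lossfn, grads,
                    c("tcr_w_dim", "tcr_w_len", "pmhc_w_dim", "pmhc_w_len",
                      "W1", "b2", "W3", "W4", "b4"), n_per = 4L)
  expect_lt(worst, 1e-3)
})
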