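#' Initialize the TCR-pMHC prediction head
#'
#' Four bias-free mapping layers flatten each modality's embedding matrix to
#' a per-position vector (rows projected onto a learned dimension weighting)
#' and a per-dimension vector (columns projected onto a learned position
#' weighting). Their concatenation feeds an MLP with dense layers of 200,
#' 100 and 50 ReLU units, each followed by dropout 0.4, and a single tanh
#' output unit, so the raw score f lies in (-1, 1).
#'
#' @param tcr_config,pmhc_config The frozen encoders' configurations (fix
#'   the mapping dimensions).
#' @param hidden Dense layer widths.
#' @param dropout Dropout rate after each dense layer (training only).
#' @param seed Seed for reproducible initialization.
#' @return A `binder_model`.
#' @export
init_binder <- function(tcr_config, pmhc_config, hidden = c(200L, 100L, 50L),
                        dropout = 0.4, seed = 1L) {
  stopifnot(inherits(tcr_config, "encoder_config"),
            inherits(pmhc_config, "encoder_config"))
  set.seed(seed)
  Lt <- tcr_config$max_len; Dt <- tcr_config$dim
  Lp <- pmhc_config$max_len; Dp <- pmhc_config$dim
  in_dim <- Lt + Dt + Lp + Dp
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  w <- list(
    tcr_w_dim = rnorm(Dt, sd = 1 / sqrt(Dt)),
    tcr_w_len = rnorm(Lt, sd = 1 / sqrt(Lt)),
    pmhc_w_dim = rnorm(Dp, sd = 1 / sqrt(Dp)),
    pmhc_w_len = rnorm(Lp, sd = 1 / sqrt(Lp)),
    W1 = he(in_dim, hidden[1]), b1 = rep(0, hidden[1]),
    W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
    W3 = he(hidden[2], hidden[3]), b3 = rep(0, hidden[3]),
    W4 = matrix(rnorm(hidden[3], sd = 1 / sqrt(hidden[3])), hidden[3], 1),
    b4 = 0
  )
  structure(
    list(weights = w, dims = list(Lt = Lt, Dt = Dt, Lp = Lp, Dp = Dp),
         hidden = as.integer(hidden), dropout = dropout, history = NULL),
    class = "binder_model"
  )
}

#' @export
print.binder_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<binder_model> mapping %dx%d (TCR) + %dx%d (pMHC) -> MLP %s -> tanh\n",
    d$Lt, d$Dt, d$Lp, d$Dp, paste(x$hidden, collapse = "-")))
  if (!is.null(x$history))
    cat("  trained:", nrow(x$history), "epochs, final val loss",
        signif(utils::tail(x$history$val_loss, 1), 4), "\n")
  invisible(x)
}

#' Apply the mapping layers to an embedding matrix
#'
#' `v_len[i] = <row i of E, w_dim>` and `v_dim[j] = <column j of E, w_len>`;
#' no bias terms. Padding rows of `E` are zero by the encoder contract, so
#' pad perturbations cannot reach either vector.
#'
#' @param binder A `binder_model`.
#' @param E Embedding matrix from [encode()] / [encode_pmhc()].
#' @param modality `"tcr"` or `"pmhc"` (selects the weight pair).
#' @return List with `v_len` (length `max_len`) and `v_dim` (length `dim`).
#' @export
map_embeddings <- function(binder, E, modality = c("tcr", "pmhc")) {
  modality <- match.arg(modality)
  w <- binder$weights
  d <- binder$dims
  expect <- if (modality == "tcr") c(d$Lt, d$Dt) else c(d$Lp, d$Dp)
  if (!all(dim(E) == expect))
    stop("embedding matrix is ", nrow(E), "x", ncol(E), ", expected ",
         expect[1], "x", expect[2])
  if (modality == "tcr")
    list(v_len = as.vector(E %*% w$tcr_w_dim),
         v_dim = as.vector(crossprod(E, w$tcr_w_len)))
  else
    list(v_len = as.vector(E %*% w$pmhc_w_dim),
         v_dim = as.vector(crossprod(E, w$pmhc_w_len)))
}

#' Contrastive margin loss
#'
#' `Relu(1 + f_minus - f_plus) + 0.2 * (f_minus^2 + f_plus^2)`: drives the
#' positive-pair output above the matched negative by a unit margin while
#' shrinking both towards zero.
#'
#' @param f_plus,f_minus Raw scores of the positive and negative pair
#'   (vectorized elementwise).
#' @return Non-negative loss value(s).
#' @examples
#' contrast_loss(0, 0)      # 1
#' contrast_loss(1, -1)     # 0.4
#' @export
contrast_loss <- function(f_plus, f_minus) {
  pmax(1 + f_minus - f_plus, 0) + 0.2 * (f_minus^2 + f_plus^2)
}

# ---- embedding banks --------------------------------------------------------
# Frozen-encoder embeddings for a set of unique sequences, stored in two
# stacked layouts so both mapping directions are single matrix products:
#   Mrow[(u-1)*L + i, ] = E_u[i, ]   ((nU*L) x D)
#   Mcol[(u-1)*D + j, ] = E_u[, j]   ((nU*D) x L)
embed_bank_tcr <- function(enc, seqs, chunk = 512L) {
  seqs <- unique(seqs)
  build_bank(seqs, function(batch) {
    bt <- tokenize_tcr_batch(batch, max_len = enc$config$max_len,
                             vocab = enc$vocab)
    encode_batch(enc, bt$ids, bt$segments, bt$lens)$hidden
  }, enc$config$max_len, enc$config$dim, chunk)
}

embed_bank_pmhc <- function(enc, pseudo, epitope, chunk = 512L) {
  key <- paste(pseudo, epitope, sep = "|")
  keep <- !duplicated(key)
  pseudo <- pseudo[keep]; epitope <- epitope[keep]
  bank <- build_bank(key[keep], function(batch_keys) {
    i <- match(batch_keys, key[keep])
    bt <- tokenize_pmhc_batch(pseudo[i], epitope[i],
                              max_len = enc$config$max_len,
                              vocab = enc$vocab)
    encode_batch(enc, bt$ids, bt$segments, bt$lens)$hidden
  }, enc$config$max_len, enc$config$dim, chunk)
  bank
}

build_bank <- function(keys, encode_fn, L, D, chunk) {
  nU <- length(keys)
  Mrow <- matrix(0, nU * L, D)
  Mcol <- matrix(0, nU * D, L)
  for (start in seq(1L, nU, by = chunk)) {
    idx <- start:min(nU, start + chunk - 1L)
    H <- encode_fn(keys[idx])  # L x D x |idx|
    for (k in seq_along(idx)) {
      u <- idx[k]
      E <- H[, , k]
      Mrow[((u - 1L) * L + 1L):(u * L), ] <- E
      Mcol[((u - 1L) * D + 1L):(u * D), ] <- t(E)
    }
  }
  list(Mrow = Mrow, Mcol = Mcol, index = stats::setNames(seq_len(nU), keys),
       L = L, D = D)
}

bank_rows <- function(u, L) {
  as.vector(vapply(u, function(x) ((x - 1L) * L + 1L):(x * L), integer(L)))
}

# Features for pairs given bank indices; returns n x in_dim matrix.
pair_features <- function(w, tbank, pbank, ti, pi) {
  n <- length(ti)
  vt_len <- t(matrix(tbank$Mrow[bank_rows(ti, tbank$L), ] %*% w$tcr_w_dim,
                     tbank$L, n))
  vt_dim <- t(matrix(tbank$Mcol[bank_rows(ti, tbank$D), ] %*% w$tcr_w_len,
                     tbank$D, n))
  vp_len <- t(matrix(pbank$Mrow[bank_rows(pi, pbank$L), ] %*% w$pmhc_w_dim,
                     pbank$L, n))
  vp_dim <- t(matrix(pbank$Mcol[bank_rows(pi, pbank$D), ] %*% w$pmhc_w_len,
                     pbank$D, n))
  cbind(vt_len, vt_dim, vp_len, vp_dim)
}

# MLP forward; returns f and (when keep = TRUE) the cache for backprop.
mlp_forward <- function(w, X, dropout = 0, training = FALSE, keep = FALSE) {
  dmask <- function(nr, nc) {
    if (!training || dropout <= 0) return(NULL)
    matrix((runif(nr * nc) >= dropout) / (1 - dropout), nr, nc)
  }
  A1 <- sweep(X %*% w$W1, 2, w$b1, "+"); R1 <- pmax(A1, 0)
  m1 <- dmask(nrow(R1), ncol(R1)); D1 <- if (is.null(m1)) R1 else R1 * m1
  A2 <- sweep(D1 %*% w$W2, 2, w$b2, "+"); R2 <- pmax(A2, 0)
  m2 <- dmask(nrow(R2), ncol(R2)); D2 <- if (is.null(m2)) R2 else R2 * m2
  A3 <- sweep(D2 %*% w$W3, 2, w$b3, "+"); R3 <- pmax(A3, 0)
  m3 <- dmask(nrow(R3), ncol(R3)); D3 <- if (is.null(m3)) R3 else R3 * m3
  f <- tanh(as.vector(D3 %*% w$W4) + w$b4)
  if (!keep) return(list(f = f))
  list(f = f, X = X, A1 = A1, D1 = D1, A2 = A2, D2 = D2, A3 = A3, D3 = D3,
       m1 = m1, m2 = m2, m3 = m3)
}

# Backprop df (n) through the MLP; returns grads and dX.
mlp_backward <- function(w, cache, df) {
  dz <- df * (1 - cache$f^2)
  g <- list()
  g$W4 <- crossprod(cache$D3, dz)
  g$b4 <- sum(dz)
  dD3 <- dz %*% t(w$W4)
  if (!is.null(cache$m3)) dD3 <- dD3 * cache$m3
  dA3 <- dD3 * (cache$A3 > 0)
  g$W3 <- crossprod(cache$D2, dA3); g$b3 <- colSums(dA3)
  dD2 <- dA3 %*% t(w$W3)
  if (!is.null(cache$m2)) dD2 <- dD2 * cache$m2
  dA2 <- dD2 * (cache$A2 > 0)
  g$W2 <- crossprod(cache$D1, dA2); g$b2 <- colSums(dA2)
  dD1 <- dA2 %*% t(w$W2)
  if (!is.null(cache$m1)) dD1 <- dD1 * cache$m1
  dA1 <- dD1 * (cache$A1 > 0)
  g$W1 <- crossprod(cache$X, dA1); g$b1 <- colSums(dA1)
  g$dX <- dA1 %*% t(w$W1)
  g
}

# Mapping-layer gradients from dX blocks.
map_grads <- function(dX, tbank, pbank, ti, pi, dims) {
  n <- length(ti)
  Lt <- dims$Lt; Dt <- dims$Dt; Lp <- dims$Lp; Dp <- dims$Dp
  dvt_len <- dX[, 1:Lt, drop = FALSE]
  dvt_dim <- dX[, Lt + (1:Dt), drop = FALSE]
  dvp_len <- dX[, Lt + Dt + (1:Lp), drop = FALSE]
  dvp_dim <- dX[, Lt + Dt + Lp + (1:Dp), drop = FALSE]
  list(
    tcr_w_dim = as.vector(
      crossprod(tbank$Mrow[bank_rows(ti, Lt), ], as.vector(t(dvt_len)))),
    tcr_w_len = as.vector(
      crossprod(tbank$Mcol[bank_rows(ti, Dt), ], as.vector(t(dvt_dim)))),
    pmhc_w_dim = as.vector(
      crossprod(pbank$Mrow[bank_rows(pi, Lp), ], as.vector(t(dvp_len)))),
    pmhc_w_len = as.vector(
      crossprod(pbank$Mcol[bank_rows(pi, Dp), ], as.vector(t(dvp_dim))))
  )
}

#' Score TCR-pMHC pairs with a trained binder
#'
#' Evaluation mode (dropout off): deterministic raw scores in (-1, 1).
#'
#' @param binder A `binder_model`.
#' @param tcr_enc,pmhc_enc The frozen encoders used for training.
#' @param pairs Data frame with columns `cdr3b`, `epitope`, `pseudo`.
#' @return Numeric vector of raw scores f.
#' @export
score_pairs <- function(binder, tcr_enc, pmhc_enc, pairs) {
  tbank <- embed_bank_tcr(tcr_enc, pairs$cdr3b)
  pbank <- embed_bank_pmhc(pmhc_enc, pairs$pseudo, pairs$epitope)
  ti <- tbank$index[pairs$cdr3b]
  pi <- pbank$index[paste(pairs$pseudo, pairs$epitope, sep = "|")]
  X <- pair_features(binder$weights, tbank, pbank, ti, pi)
  mlp_forward(binder$weights, X)$f
}

#' @rdname score_pairs
#' @param cdr3b,epitope,pseudo Single pair.
#' @export
score_pair <- function(binder, tcr_enc, pmhc_enc, cdr3b, epitope, pseudo) {
  score_pairs(binder, tcr_enc, pmhc_enc,
              data.frame(cdr3b = cdr3b, epitope = epitope, pseudo = pseudo))
}

#' Sample negative pairs from a healthy background repertoire
#'
#' Each negative keeps a pMHC drawn from the positives' pMHC multiset and
#' replaces the TCR with a uniform draw from `pool`; draws that collide with
#' a known positive pair are resampled. With `ratio = 1` the negatives are
#' aligned one-to-one with the positives (same pMHC), as required by the
#' contrastive pairing.
#'
#' @param positives Data frame with `cdr3b`, `epitope`, `pseudo`.
#' @param pool Character vector of background CDR3beta sequences.
#' @param ratio Negatives per positive.
#' @param seed Optional seed.
#' @return Data frame of negatives (`label = 0`).
#' @export
sample_negatives <- function(positives, pool, ratio = 1, seed = NULL) {
  if (length(pool) == 0) stop("empty background pool")
  if (!is.null(seed)) set.seed(seed)
  npos <- nrow(positives)
  n <- round(ratio * npos)
  idx <- rep(seq_len(npos), length.out = n)
  tcr <- sample(pool, n, replace = TRUE)
  known <- paste(positives$cdr3b, positives$epitope)
  for (iter in 1:100) {
    bad <- paste(tcr, positives$epitope[idx]) %in% known
    if (!any(bad)) break
    tcr[bad] <- sample(pool, sum(bad), replace = TRUE)
  }
  data.frame(cdr3b = tcr, epitope = positives$epitope[idx],
             pseudo = positives$pseudo[idx], label = 0,
             stringsAsFactors = FALSE)
}

#' Train the TCR-pMHC prediction head with contrastive learning
#'
#' Positive and matched negative pairs pass through two copies of the same
#' model (shared weights); the margin loss [contrast_loss()] is optimized
#' with AdamW (default lr 0.005, batch 256). Both encoders stay frozen:
#' their embeddings are computed once and only the mapping layers and the
#' MLP receive gradient. Negatives are resampled from `pool` every epoch;
#' an epitope-stratified validation split with fixed negatives drives
#' plateau decay and early stopping.
#'
#' @param pairs Data frame with `cdr3b`, `epitope`, `pseudo`, `label`
#'   (positives have label 1; any provided negatives are ignored in favour
#'   of pool-sampled ones).
#' @param pool Healthy background CDR3beta sequences.
#' @param tcr_enc,pmhc_enc Pretrained encoders (never modified).
#' @param schedule A [binder_schedule()].
#' @param binder Optional pre-initialized `binder_model`.
#' @param verbose Print per-epoch losses.
#' @return A trained `binder_model` with `history`.
#' @export
train_binder <- function(pairs, pool, tcr_enc, pmhc_enc,
                         schedule = binder_schedule(), binder = NULL,
                         verbose = FALSE) {
  positives <- pairs[pairs$label == 1, , drop = FALSE]
  if (nrow(positives) == 0) stop("no positive pairs")
  if (length(pool) == 0) stop("empty background pool")
  if (is.null(binder))
    binder <- init_binder(tcr_enc$config, pmhc_enc$config,
                          seed = schedule$seed)
  w <- binder$weights
  dims <- binder$dims
  set.seed(schedule$seed)

  # epitope-stratified validation split
  npos <- nrow(positives)
  by_epi <- split(seq_len(npos), positives$epitope)
  val_idx <- sort(unlist(lapply(by_epi, function(ix) {
    k <- round(schedule$val_fraction * length(ix))
    if (k > 0) sample(ix, k) else integer(0)
  }), use.names = FALSE))
  if (length(val_idx) == 0) val_idx <- sample.int(npos, 1L)
  tr_idx <- setdiff(seq_len(npos), val_idx)
  val_pos <- positives[val_idx, , drop = FALSE]
  tr_pos <- positives[tr_idx, , drop = FALSE]
  val_neg <- sample_negatives(val_pos, pool)

  tbank <- embed_bank_tcr(tcr_enc, c(tr_pos$cdr3b, val_pos$cdr3b, pool))
  pbank <- embed_bank_pmhc(pmhc_enc, positives$pseudo, positives$epitope)
  tix <- function(s) unname(tbank$index[s])
  pix <- function(df) unname(pbank$index[paste(df$pseudo, df$epitope,
                                               sep = "|")])
  val_loss <- function(w) {
    Xp <- pair_features(w, tbank, pbank, tix(val_pos$cdr3b), pix(val_pos))
    Xn <- pair_features(w, tbank, pbank, tix(val_neg$cdr3b), pix(val_neg))
    mean(contrast_loss(mlp_forward(w, Xp)$f, mlp_forward(w, Xn)$f))
  }

  opt <- adamw_init(w)
  tracker <- plateau_tracker(schedule)
  step <- 0L
  hist <- list()
  for (epoch in seq_len(schedule$max_epochs)) {
    neg <- sample_negatives(tr_pos, pool)
    ord <- sample(nrow(tr_pos))
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    tr_loss <- 0
    for (bix in batches) {
      step <- step + 1L
      pos_b <- tr_pos[bix, , drop = FALSE]
      neg_b <- neg[bix, , drop = FALSE]
      tip <- tix(pos_b$cdr3b); pip <- pix(pos_b)
      tin <- tix(neg_b$cdr3b); pin <- pix(neg_b)
      Xp <- pair_features(w, tbank, pbank, tip, pip)
      Xn <- pair_features(w, tbank, pbank, tin, pin)
      fp <- mlp_forward(w, Xp, binder$dropout, TRUE, keep = TRUE)
      fn <- mlp_forward(w, Xn, binder$dropout, TRUE, keep = TRUE)
      nB <- length(bix)
      margin_active <- (1 + fn$f - fp$f) > 0
      dfp <- (-1 * margin_active + 0.4 * fp$f) / nB
      dfn <- (margin_active + 0.4 * fn$f) / nB
      gp <- mlp_backward(w, fp, dfp)
      gn <- mlp_backward(w, fn, dfn)
      grads <- Map(`+`, gp[names(gp) != "dX"], gn[names(gn) != "dX"])
      mg_p <- map_grads(gp$dX, tbank, pbank, tip, pip, dims)
      mg_n <- map_grads(gn$dX, tbank, pbank, tin, pin, dims)
      grads <- c(grads, Map(`+`, mg_p, mg_n))
      lr <- lr_at(step, schedule$peak_lr, schedule$warmup_steps,
                  tracker$mult)
      st <- adamw_step(w, grads, opt, lr,
                       weight_decay = schedule$weight_decay)
      w <- st$weights; opt <- st$state
      tr_loss <- tr_loss +
        mean(contrast_loss(fp$f, fn$f))
    }
    vl <- val_loss(w)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = tr_loss / length(batches),
                                val_loss = vl,
                                lr = lr_at(step, schedule$peak_lr,
                                           schedule$warmup_steps,
                                           tracker$mult))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      tr_loss / length(batches), vl))
    if (tracker$update(vl)) break
  }
  binder$weights <- w
  binder$history <- do.call(rbind, hist)
  rownames(binder$history) <- NULL
  binder
}

#' Percentile rank score against a healthy background ensemble
#'
#' The candidate TCR and `n` background TCRs drawn from `pool` are scored
#' against the same pMHC; the rank is the fraction of background scores
#' below the candidate's, counting ties as one half (midrank).
#'
#' @param binder,tcr_enc,pmhc_enc Trained models.
#' @param cdr3b,epitope,pseudo The candidate pair.
#' @param pool Background CDR3beta sequences (`length(pool) >= n`).
#' @param n Background ensemble size (default 1000).
#' @param seed Optional seed for the background draw.
#' @return A list with `rank` in `[0, 1]`, the raw score `f` and `n`.
#' @export
rank_score <- function(binder, tcr_enc, pmhc_enc, cdr3b, epitope, pseudo,
                       pool, n = 1000L, seed = NULL) {
  if (length(pool) < n)
    stop("background pool (", length(pool), ") smaller than n = ", n)
  if (!is.null(seed)) set.seed(seed)
  bg <- sample(pool, n)
  df <- data.frame(cdr3b = c(cdr3b, bg), epitope = epitope, pseudo = pseudo,
                   stringsAsFactors = FALSE)
  f <- score_pairs(binder, tcr_enc, pmhc_enc, df)
  list(rank = rank_from_scores(f[1], f[-1]), f = f[1], n = as.integer(n))
}

#' Midrank percentile of a score within a background sample
#'
#' @param f Candidate score(s).
#' @param background Background scores.
#' @return `(#\{background < f\} + 0.5 * #\{background = f\}) / n`.
#' @export
rank_from_scores <- function(f, background) {
  n <- length(background)
  vapply(f, function(x) {
    (sum(background < x) + 0.5 * sum(background == x)) / n
  }, numeric(1))
}
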