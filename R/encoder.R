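#' Transformer encoder configuration
#'
#' Defaults follow the published architecture: four encoder layers, 256
#' embedding dimensions, 8 attention heads. The feed-forward width defaults
#' to the standard 4x ratio.
#'
#' @param n_layers Number of encoder layers.
#' @param dim Embedding dimension (must be divisible by `n_heads`).
#' @param n_heads Attention heads per layer.
#' @param ff_dim Feed-forward hidden width (default `4 * dim`).
#' @param max_len Padded input length (32 for TCR, 52 for pMHC inputs).
#' @param dropout Dropout rate used during training (default 0.1).
#' @param vocab_size Token inventory size (default 24).
#' @param n_segments 0 for TCR inputs; 3 (MHC / epitope / padding) enables
#'   the learned segment embedding of the pMHC encoder.
#' @param use_nsp Attach the binding-score regression head (pMHC encoder).
#' @return An `encoder_config`.
#' @export
encoder_config <- function(n_layers = 4L, dim = 256L, n_heads = 8L,
                           ff_dim = 4L * dim, max_len = 32L, dropout = 0.1,
                           vocab_size = 24L, n_segments = 0L,
                           use_nsp = FALSE) {
  if (dim %% n_heads != 0)
    stop("dim (", dim, ") must be divisible by n_heads (", n_heads, ")")
  stopifnot(n_layers >= 1, dim >= n_heads, ff_dim >= 1, max_len >= 2,
            dropout >= 0, dropout < 1, vocab_size >= 21,
            n_segments %in% c(0L, 3L))
  structure(
    list(n_layers = as.integer(n_layers), dim = as.integer(dim),
         n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
         max_len = as.integer(max_len), dropout = dropout,
         vocab_size = as.integer(vocab_size),
         n_segments = as.integer(n_segments), use_nsp = isTRUE(use_nsp)),
    class = "encoder_config"
  )
}

#' pMHC encoder configuration
#'
#' Same stack as [encoder_config()] but sized for pseudo-sequence + epitope
#' inputs, with segment embeddings and the binding-score (NSP) head enabled.
#' @inheritParams encoder_config
#' @export
pmhc_config <- function(n_layers = 4L, dim = 256L, n_heads = 8L,
                        ff_dim = 4L * dim, max_len = 52L, dropout = 0.1,
                        vocab_size = 24L) {
  encoder_config(n_layers, dim, n_heads, ff_dim, max_len, dropout,
                 vocab_size, n_segments = 3L, use_nsp = TRUE)
}

#' Pretraining schedule
#'
#' Defaults follow the published pretraining recipe: AdamW at a peak learning
#' rate of 5e-4, batch size 512, linear warm-up over the first 4000 steps,
#' learning rate multiplied by 0.3 when the validation loss fails to improve
#' for 2 consecutive epochs, early stopping after 4 non-improving epochs, at
#' most 100 epochs. The prediction head uses [binder_schedule()].
#'
#' @param peak_lr Peak learning rate after warm-up.
#' @param batch_size Sequences per optimization step.
#' @param warmup_steps Linear warm-up length in steps.
#' @param plateau_factor Multiplicative learning-rate decay on plateau.
#' @param plateau_patience Non-improving epochs before decay.
#' @param max_epochs Hard epoch cap.
#' @param early_stop_patience Non-improving epochs before stopping.
#' @param min_epochs Epochs that must elapse before early stopping and
#'   plateau decay may trigger (useful for loss surfaces with a long
#'   initial plateau, like the contrastive margin loss).
#' @param val_fraction Fraction of the corpus held out for validation.
#' @param weight_decay AdamW decoupled weight decay (matrices only).
#' @param seed Seed fixing shuffling, masking and the validation split.
#' @return A `train_schedule`.
#' @export
train_schedule <- function(peak_lr = 5e-4, batch_size = 512L,
                           warmup_steps = 4000L, plateau_factor = 0.3,
                           plateau_patience = 2L, max_epochs = 100L,
                           early_stop_patience = 4L, min_epochs = 1L,
                           val_fraction = 0.01,
                           weight_decay = 0.01, seed = 1L) {
  stopifnot(peak_lr > 0, batch_size >= 1, warmup_steps >= 0,
            plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1,
            max_epochs >= 1, early_stop_patience >= 1, min_epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(
    list(peak_lr = peak_lr, batch_size = as.integer(batch_size),
         warmup_steps = as.integer(warmup_steps),
         plateau_factor = plateau_factor,
         plateau_patience = as.integer(plateau_patience),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         min_epochs = as.integer(min_epochs),
         val_fraction = val_fraction, weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "train_schedule"
  )
}

#' @rdname train_schedule
#' @export
binder_schedule <- function(peak_lr = 0.005, batch_size = 256L,
                            warmup_steps = 0L, plateau_factor = 0.3,
                            plateau_patience = 2L, max_epochs = 100L,
                            early_stop_patience = 6L, min_epochs = 1L,
                            val_fraction = 0.05,
                            weight_decay = 0.01, seed = 1L) {
  train_schedule(peak_lr, batch_size, warmup_steps, plateau_factor,
                 plateau_patience, max_epochs, early_stop_patience,
                 min_epochs, val_fraction, weight_decay, seed)
}

#' Initialize an encoder
#'
#' Token, position (and optionally segment) embeddings plus `n_layers`
#' post-norm transformer blocks, an MLM output head and, for pMHC
#' configurations, the binding-score regression head. Weights are drawn
#' N(0, 0.02^2); layer-norm gains start at 1, biases at 0.
#'
#' @param config An `encoder_config`.
#' @param seed Integer seed; identical seeds give bit-identical parameters.
#' @return A `bert_encoder`: list with `weights`, `config`, `vocab`,
#'   and (after pretraining) `history`.
#' @export
init_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  set.seed(seed)
  D <- config$dim; FF <- config$ff_dim; V <- config$vocab_size
  mz <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  w <- list(
    tok_emb = mz(V, D),
    pos_emb = mz(config$max_len, D),
    emb_ln_g = rep(1, D), emb_ln_b = rep(0, D)
  )
  if (config$n_segments > 0) w$seg_emb <- mz(config$n_segments, D)
  for (l in seq_len(config$n_layers)) {
    nm <- function(s) paste0("l", l, "_", s)
    w[[nm("Wq")]] <- mz(D, D); w[[nm("bq")]] <- rep(0, D)
    w[[nm("Wk")]] <- mz(D, D); w[[nm("bk")]] <- rep(0, D)
    w[[nm("Wv")]] <- mz(D, D); w[[nm("bv")]] <- rep(0, D)
    w[[nm("Wo")]] <- mz(D, D); w[[nm("bo")]] <- rep(0, D)
    w[[nm("ln1_g")]] <- rep(1, D); w[[nm("ln1_b")]] <- rep(0, D)
    w[[nm("W1")]] <- mz(D, FF); w[[nm("b1")]] <- rep(0, FF)
    w[[nm("W2")]] <- mz(FF, D); w[[nm("b2")]] <- rep(0, D)
    w[[nm("ln2_g")]] <- rep(1, D); w[[nm("ln2_b")]] <- rep(0, D)
  }
  w$mlm_W <- mz(D, V); w$mlm_b <- rep(0, V)
  if (config$use_nsp) {
    # one-hidden-layer MLP head over the segment-aware pooled
    # representation [whole complex, epitope segment]
    w$nsp_W1 <- matrix(rnorm(2 * D * D, sd = sqrt(1 / D)), 2 * D, D)
    w$nsp_b1 <- rep(0, D)
    w$nsp_w <- rnorm(D, sd = 1 / sqrt(D))
    w$nsp_b <- 0
  }
  structure(list(weights = w, config = config, vocab = build_vocab(),
                 history = NULL),
            class = "bert_encoder")
}

#' @export
print.bert_encoder <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<bert_encoder> %d layers, dim %d, %d heads, max_len %d%s%s\n",
              cf$n_layers, cf$dim, cf$n_heads, cf$max_len,
              if (cf$n_segments > 0) ", segment-aware" else "",
              if (cf$use_nsp) ", NSP head" else ""))
  cat("  parameters:", n_params(x), "\n")
  if (!is.null(x$history))
    cat("  pretrained:", nrow(x$history), "epochs, final val loss",
        signif(utils::tail(x$history$val_loss, 1), 4), "\n")
  invisible(x)
}

#' Total trainable parameter count
#' @param enc A `bert_encoder`.
#' @export
n_params <- function(enc) {
  sum(vapply(enc$weights, length, numeric(1)))
}

#' Contextual embeddings for a tokenized sequence
#'
#' Runs the encoder in evaluation mode (no dropout). Padding positions never
#' enter the computation; their rows in the result are zero.
#'
#' @param enc A `bert_encoder`.
#' @param tok A `tok_seq` whose `max_len` matches the encoder's.
#' @return `max_len x dim` matrix with attribute `true_len`.
#' @export
encode <- function(enc, tok) {
  stopifnot(inherits(enc, "bert_encoder"), inherits(tok, "tok_seq"))
  if (tok$max_len != enc$config$max_len)
    stop("tok max_len (", tok$max_len, ") != encoder max_len (",
         enc$config$max_len, ")")
  out <- encode_batch(enc, matrix(tok$ids, nrow = 1L),
                      matrix(tok$segments, nrow = 1L), tok$true_len)
  E <- out$hidden[, , 1L]
  attr(E, "true_len") <- tok$true_len
  E
}

#' @rdname encode
#' @param pseudo,epitope Convenience wrapper tokenizing a pMHC input first.
#' @export
encode_pmhc <- function(enc, pseudo, epitope) {
  if (enc$config$n_segments == 0)
    stop("encoder has no segment embeddings; build it with pmhc_config()")
  encode(enc, tokenize_pmhc(pseudo, epitope, max_len = enc$config$max_len))
}

# low-level batched forward; ids/segments are B x L (0-based), lens true lens
encode_batch <- function(enc, ids, segments, lens, attention = FALSE) {
  cf <- enc$config
  cpp_encode(enc$weights, ids, segments, as.integer(lens), cf$n_layers,
             cf$n_heads, cf$n_segments > 0, attention)
}

#' Mean MLM cross-entropy over a batch of masked examples
#'
#' Cross-entropy is averaged over masked positions only; a batch with no
#' masked position has loss 0 by convention.
#'
#' @param enc A `bert_encoder`.
#' @param examples A list of `mlm_example` objects (see [apply_mlm_mask()]).
#' @return Non-negative scalar.
#' @export
mlm_loss <- function(enc, examples) {
  if (inherits(examples, "mlm_example")) examples <- list(examples)
  stopifnot(length(examples) > 0)
  ids <- do.call(rbind, lapply(examples, `[[`, "input_ids"))
  tgt <- do.call(rbind, lapply(examples, `[[`, "target_ids"))
  L <- ncol(ids)
  lens <- vapply(examples, function(e) {
    pads <- e$input_ids == pad_id(enc$vocab)
    if (any(pads)) which(pads)[1] - 1L else L
  }, integer(1))
  segs <- matrix(0L, nrow(ids), L)
  cf <- enc$config
  res <- cpp_bert_grad(enc$weights, ids, tgt, segs, as.integer(lens),
                       rep(NA_real_, nrow(ids)), cf$n_layers, cf$n_heads,
                       cf$n_segments > 0, FALSE, 0, FALSE, FALSE)
  res$ce
}

#' Attention-based residue importance
#'
#' Quantifies how much attention each residue receives, summed over queries,
#' averaged over all layers and heads (configurable), with the start token
#' and padding excluded and the result renormalized to sum to 1.
#'
#' @param enc A `bert_encoder`.
#' @param x A residue string (tokenized as TCR input) or a `tok_seq`.
#' @param layers Integer vector of layers to average (default all).
#' @param segment For segment-aware inputs, restrict the profile to one
#'   segment (e.g. `1` for epitope residues); `NULL` keeps all residues.
#' @return An `attention_profile`: numeric vector of non-negative scores
#'   summing to 1, one per retained residue, with attribute `positions`
#'   (1-based positions within the token layout).
#' @export
attention_profile <- function(enc, x, layers = NULL, segment = NULL) {
  tok <- if (inherits(x, "tok_seq")) x else
    tokenize_tcr(x, max_len = enc$config$max_len, vocab = enc$vocab)
  out <- encode_batch(enc, matrix(tok$ids, nrow = 1L),
                      matrix(tok$segments, nrow = 1L), tok$true_len,
                      attention = TRUE)
  cf <- enc$config
  A <- out$attn_received[, , 1L, drop = TRUE]  # max_len x (layers*heads)
  A <- matrix(A, nrow = cf$max_len)
  layers <- layers %||% seq_len(cf$n_layers)
  cols <- as.vector(vapply(layers, function(l) {
    (l - 1L) * cf$n_heads + seq_len(cf$n_heads)
  }, integer(cf$n_heads)))
  received <- rowMeans(A[, cols, drop = FALSE])
  keep <- seq_len(tok$true_len)[-1L]  # residues only, start excluded
  if (!is.null(segment)) keep <- keep[tok$segments[keep] == segment]
  if (length(keep) == 0) stop("no residues left after segment restriction")
  p <- received[keep]
  p <- p / sum(p)
  structure(p, positions = keep, class = "attention_profile")
}

#' @rdname attention_profile
#' @param pseudo,epitope pMHC input; the profile is restricted to epitope
#'   residues (segment 1).
#' @export
epitope_attention_profile <- function(enc, pseudo, epitope, layers = NULL) {
  tok <- tokenize_pmhc(pseudo, epitope, max_len = enc$config$max_len,
                       vocab = enc$vocab)
  attention_profile(enc, tok, layers = layers, segment = 1L)
}
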