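# AdamW optimizer over a named list of parameter arrays. Decoupled weight
# decay is applied to matrices only (embeddings and projections), never to
# biases or layer-norm parameters, following common transformer practice.

adamw_init <- function(weights) {
  list(m = lapply(weights, function(p) p * 0),
       v = lapply(weights, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    # vector parameters may arrive as 1-row/1-column matrices from the core
    if (is.null(dim(weights[[nm]]))) g <- as.vector(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(weights[[nm]]))
      upd <- upd + weight_decay * weights[[nm]]
    weights[[nm]] <- weights[[nm]] - lr * upd
  }
  list(weights = weights, state = state)
}

lr_at <- function(step, peak_lr, warmup_steps, plateau_mult) {
  warm <- if (warmup_steps > 0) min(1, step / warmup_steps) else 1
  peak_lr * warm * plateau_mult
}

# Plateau/early-stop bookkeeping shared by all training loops.
plateau_tracker <- function(schedule) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$since_best <- 0L
  env$since_decay <- 0L
  env$mult <- 1
  env$epoch <- 0L
  env$update <- function(val) {
    env$epoch <- env$epoch + 1L
    if (env$epoch < (schedule$min_epochs %||% 1L)) {
      if (val < env$best - 1e-12) env$best <- val
      return(FALSE)
    }
    if (val < env$best - 1e-12) {
      env$best <- val
      env$since_best <- 0L
      env$since_decay <- 0L
    } else {
      env$since_best <- env$since_best + 1L
      env$since_decay <- env$since_decay + 1L
      if (env$since_decay >= schedule$plateau_patience) {
        env$mult <- env$mult * schedule$plateau_factor
        env$since_decay <- 0L
      }
    }
    env$since_best >= schedule$early_stop_patience  # TRUE -> stop
  }
  env
}

#' Pretrain the TCR encoder with masked language modelling
#'
#' Each epoch shuffles the corpus, corrupts every batch with the 80/10/10
#' masking scheme at `rate`, and optimizes the masked cross-entropy with
#' AdamW under linear warm-up; the learning rate is multiplied by
#' `plateau_factor` when the validation loss stalls, and training stops
#' early per the schedule. A fixed fraction of the corpus (masked once, so
#' the validation loss is comparable across epochs) is held out.
#'
#' @param corpus Character vector of CDR3beta sequences.
#' @param config An `encoder_config` (segment-free).
#' @param schedule A [train_schedule()].
#' @param rate MLM corruption rate (default 0.15).
#' @param verbose Print per-epoch losses.
#' @return A pretrained `bert_encoder` with a `history` data frame
#'   (epoch, train_loss, val_loss, lr).
#' @export
pretrain_mlm <- function(corpus, config = encoder_config(),
                         schedule = train_schedule(), rate = 0.15,
                         verbose = FALSE) {
  if (length(corpus) == 0) stop("empty corpus")
  enc <- init_encoder(config, seed = schedule$seed)
  bt <- tokenize_tcr_batch(corpus, max_len = config$max_len,
                           vocab = enc$vocab)
  run_pretrain(enc, bt, labels = NULL, schedule = schedule, rate = rate,
               mask_rows = NULL, verbose = verbose)
}

#' Jointly pretrain the pMHC encoder (selective MLM + binding regression)
#'
#' Selective masking corrupts residues only in records where epitope-MHC
#' binding occurs (MS label 1, or BA score at or above the 500 nM cutoff on
#' the unit scale); the regression (NSP) head squashes the pooled sequence
#' representation (mean over true positions) through a logistic unit and is
#' fit to every record's label by mean squared error. The combined loss is `ce + mse` and the schedule semantics
#' match [pretrain_mlm()].
#'
#' @param records Data frame in the `pmhc` schema of [read_table()].
#' @param config A [pmhc_config()].
#' @param schedule A [train_schedule()].
#' @param rate Selective-masking rate (default 0.15).
#' @param verbose Print per-epoch losses.
#' @return A pretrained `bert_encoder` with segment embeddings, NSP head and
#'   a `history` data frame (epoch, train_loss, val_loss, ce, mse, lr).
#' @export
pretrain_pmhc <- function(records, config = pmhc_config(),
                          schedule = train_schedule(), rate = 0.15,
                          verbose = FALSE) {
  if (nrow(records) == 0) stop("empty dataset")
  stopifnot(config$n_segments > 0, config$use_nsp)
  enc <- init_encoder(config, seed = schedule$seed)
  bt <- tokenize_pmhc_batch(records$pseudo, records$epitope,
                            max_len = config$max_len, vocab = enc$vocab)
  run_pretrain(enc, bt, labels = records$label, schedule = schedule,
               rate = rate, mask_rows = pmhc_binder_flag(records),
               verbose = verbose)
}

#' Binder flag used for selective masking
#'
#' MS records are binders when their label is 1; BA records when their unit
#' score is at or above the 500 nM convention (about 0.426).
#' @param records Data frame with `assay` and `label` columns.
#' @return Logical vector.
#' @export
pmhc_binder_flag <- function(records) {
  (records$assay == "MS" & records$label >= 1) |
    (records$assay == "BA" & records$label >= BA_BINDER_CUTOFF)
}

# Shared training loop. bt: list(ids, segments, lens). labels: NULL for pure
# MLM, numeric otherwise (enables the NSP head). mask_rows: logical vector
# marking rows eligible for masking (NULL = all).
run_pretrain <- function(enc, bt, labels, schedule, rate, mask_rows,
                         verbose = FALSE) {
  cf <- enc$config
  n <- nrow(bt$ids)
  use_nsp <- !is.null(labels)
  if (is.null(mask_rows)) mask_rows <- rep(TRUE, n)

  set.seed(schedule$seed)
  n_val <- max(1L, min(n - 1L, round(schedule$val_fraction * n)))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)

  # validation batch, masked once so epochs are comparable
  vmask <- mask_ids_batch(bt$ids[val_idx, , drop = FALSE], bt$lens[val_idx],
                          rate, enc$vocab)
  if (!all(mask_rows[val_idx]))
    vmask$target[!mask_rows[val_idx], ] <- -1L
  val_labels <- if (use_nsp) labels[val_idx] else rep(NA_real_, n_val)

  val_loss <- function(w) {
    res <- cpp_bert_grad(w, vmask$input, vmask$target,
                         bt$segments[val_idx, , drop = FALSE],
                         bt$lens[val_idx], val_labels, cf$n_layers,
                         cf$n_heads, cf$n_segments > 0, use_nsp,
                         0, FALSE, FALSE)
    c(ce = res$ce, mse = res$mse)
  }

  opt <- adamw_init(enc$weights)
  tracker <- plateau_tracker(schedule)
  step <- 0L
  hist <- list()
  w <- enc$weights
  for (epoch in seq_len(schedule$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    tr_loss <- 0
    for (bix in batches) {
      step <- step + 1L
      m <- mask_ids_batch(bt$ids[bix, , drop = FALSE], bt$lens[bix], rate,
                          enc$vocab)
      if (!all(mask_rows[bix])) m$target[!mask_rows[bix], ] <- -1L
      lab <- if (use_nsp) labels[bix] else rep(NA_real_, length(bix))
      res <- cpp_bert_grad(w, m$input, m$target,
                           bt$segments[bix, , drop = FALSE], bt$lens[bix],
                           lab, cf$n_layers, cf$n_heads, cf$n_segments > 0,
                           use_nsp, cf$dropout, TRUE, TRUE)
      lr <- lr_at(step, schedule$peak_lr, schedule$warmup_steps,
                  tracker$mult)
      st <- adamw_step(w, res$grads, opt, lr,
                       weight_decay = schedule$weight_decay)
      w <- st$weights; opt <- st$state
      tr_loss <- tr_loss + res$ce + res$mse
    }
    vl <- val_loss(w)
    lr_now <- lr_at(step, schedule$peak_lr, schedule$warmup_steps,
                    tracker$mult)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_loss / length(batches),
      val_loss = sum(vl), ce = vl[["ce"]], mse = vl[["mse"]], lr = lr_now)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2e", epoch,
                      tr_loss / length(batches), sum(vl), lr_now))
    if (tracker$update(sum(vl))) break
  }
  enc$weights <- w
  enc$history <- do.call(rbind, hist)
  rownames(enc$history) <- NULL
  enc
}

#' SMLM and NSP losses for a batch of pMHC records
#'
#' Applies selective masking (binder records only, see [pmhc_binder_flag()])
#' with the current RNG state, and evaluates both loss components in
#' evaluation mode.
#'
#' @param enc A pMHC `bert_encoder`.
#' @param records Data frame in the `pmhc` schema.
#' @param rate Masking rate.
#' @return Named numeric: `ce_smlm`, `mse_nsp`, `total` (= their sum).
#' @export
pmhc_losses <- function(enc, records, rate = 0.15) {
  stopifnot(nrow(records) > 0, enc$config$use_nsp)
  cf <- enc$config
  bt <- tokenize_pmhc_batch(records$pseudo, records$epitope,
                            max_len = cf$max_len, vocab = enc$vocab)
  m <- mask_ids_batch(bt$ids, bt$lens, rate, enc$vocab)
  flag <- pmhc_binder_flag(records)
  if (!all(flag)) m$target[!flag, ] <- -1L
  res <- cpp_bert_grad(enc$weights, m$input, m$target, bt$segments, bt$lens,
                       records$label, cf$n_layers, cf$n_heads, TRUE, TRUE,
                       0, FALSE, FALSE)
  c(ce_smlm = res$ce, mse_nsp = res$mse, total = res$ce + res$mse)
}

#' Predict epitope presentation from the pretrained pMHC encoder
#'
#' The regression (NSP) head that was fit during pretraining doubles as the
#' presentation predictor: no additional training is required. Deterministic
#' (evaluation mode), bounded in `[0, 1]` by the logistic output unit.
#'
#' @param enc A pretrained pMHC `bert_encoder`.
#' @param epitope Character vector of epitopes (8-15 residues).
#' @param pseudo 34-residue pseudo-sequence(s), recycled to match.
#' @return Numeric vector of presentation scores in `[0, 1]`.
#' @export
predict_presentation <- function(enc, epitope, pseudo) {
  stopifnot(enc$config$use_nsp)
  if (length(pseudo) == 1) pseudo <- rep(pseudo, length(epitope))
  stopifnot(length(pseudo) == length(epitope))
  cf <- enc$config
  bt <- tokenize_pmhc_batch(pseudo, epitope, max_len = cf$max_len,
                            vocab = enc$vocab)
  H <- encode_batch(enc, bt$ids, bt$segments, bt$lens)$hidden
  w <- enc$weights
  z <- vapply(seq_len(dim(H)[3]), function(b) {
    E <- H[seq_len(bt$lens[b]), , b, drop = FALSE][, , 1]
    epi <- which(bt$segments[b, seq_len(bt$lens[b])] == 1L)
    pooled <- c(colSums(E) / sqrt(nrow(E)),
                colSums(E[epi, , drop = FALSE]) / sqrt(length(epi)))
    h <- pmax(as.vector(pooled %*% w$nsp_W1) + w$nsp_b1, 0)
    sum(h * w$nsp_w) + w$nsp_b
  }, numeric(1))
  1 / (1 + exp(-z))
}

#' Save or load an encoder checkpoint
#'
#' Weights go to `<prefix>.rds`; a JSON sidecar `<prefix>.json` carries the
#' configuration, a vocabulary fingerprint and the training history.
#'
#' @param enc A `bert_encoder`.
#' @param prefix Path prefix for the two files.
#' @export
save_encoder <- function(enc, prefix) {
  saveRDS(enc$weights, paste0(prefix, ".rds"))
  side <- list(config = unclass(enc$config),
               vocab_hash = vocab_fingerprint(enc$vocab),
               history = enc$history)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cfg <- do.call(encoder_config, side$config[
    c("n_layers", "dim", "n_heads", "ff_dim", "max_len", "dropout",
      "vocab_size", "n_segments", "use_nsp")])
  vocab <- build_vocab()
  if (!identical(vocab_fingerprint(vocab), side$vocab_hash))
    stop("checkpoint was written with a different vocabulary")
  structure(list(weights = readRDS(paste0(prefix, ".rds")), config = cfg,
                 vocab = vocab,
                 history = as.data.frame(side$history %||% list())),
            class = "bert_encoder")
}

vocab_fingerprint <- function(vocab) {
  s <- paste(vocab$tokens, collapse = "|")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% 2147483647)
}
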