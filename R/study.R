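#' Desk-scale configurations for the planted-rule validation study
#'
#' The full-scale architecture (4 layers, 256 dimensions, 8 heads, pretrained
#' on >1e8 sequences) is not reproducible on a single CPU, so the package's
#' end-to-end validation runs a scaled-down study: 2-layer, 64-dimension,
#' 4-head encoders trained on synthetic data with planted ground truth.
#' These helpers freeze those study conditions in one place.
#'
#' @return Configuration or schedule objects.
#' @name desk_study
NULL

#' @rdname desk_study
#' @export
tiny_tcr_config <- function() {
  encoder_config(n_layers = 2L, dim = 64L, n_heads = 4L, ff_dim = 256L,
                 max_len = 32L)
}

#' @rdname desk_study
#' @export
tiny_pmhc_config <- function() {
  pmhc_config(n_layers = 2L, dim = 64L, n_heads = 4L, ff_dim = 256L,
              max_len = 52L)
}

#' @rdname desk_study
#' @param seed Integer seed.
#' @param max_epochs Epoch cap for the scaled-down run.
#' @export
tiny_tcr_schedule <- function(seed = 1L, max_epochs = 2L) {
  # warm-up shortened in proportion to the step budget of the small corpus
  train_schedule(batch_size = 512L, warmup_steps = 100L,
                 max_epochs = max_epochs, val_fraction = 0.02, seed = seed)
}

#' @rdname desk_study
#' @export
tiny_pmhc_schedule <- function(seed = 1L, max_epochs = 3L) {
  # smaller batches buy the regression head enough optimization steps to
  # fit within the short epoch budget
  train_schedule(peak_lr = 2e-3, batch_size = 32L, warmup_steps = 30L,
                 max_epochs = max_epochs, val_fraction = 0.02, seed = seed)
}

#' Run the scaled-down end-to-end validation study
#'
#' Generates synthetic study data with planted ground truth, pretrains both
#' encoders, trains the contrastive prediction head over the frozen
#' embeddings, and evaluates on epitope-disjoint held-out pairs:
#' \enumerate{
#'   \item TCR encoder: masked-language-model pretraining on
#'     `tcr_corpus_n` background CDR3beta sequences (2 epochs).
#'   \item pMHC encoder: joint selective-masking + binding-regression
#'     pretraining on anchor-rule epitope-MHC records (3 epochs), with
#'     held-out presentation AUC.
#'   \item Binder: contrastive training on `n_pos` positive pairs following
#'     a planted TCR-epitope recognition rule (label noise 0.1), negatives
#'     resampled from a healthy background pool each epoch.
#'   \item Zero-shot evaluation: AUC-ROC / AUC-PR and the Youden cutoff on
#'     pairs whose epitopes never occur in training.
#' }
#'
#' @param seed Integer seed driving every random choice.
#' @param tcr_corpus_n Background corpus size for MLM pretraining.
#' @param pmhc_per_allele pMHC records per synthetic allele (4 alleles).
#' @param n_pos Positive training pairs for the binder.
#' @param n_test Held-out positives (and negatives) for zero-shot testing.
#' @param pool_n Healthy background pool size.
#' @param binder_epochs Epoch cap for the prediction head.
#' @param verbose Print progress.
#' @return List with the fitted models (`tcr_enc`, `pmhc_enc`, `binder`),
#'   the data (`pairs`, `pool`, `pmhc`), and `metrics` (presentation_auc,
#'   zero_shot_auc_roc, zero_shot_auc_pr, youden threshold and J).
#' @export
run_planted_study <- function(seed = 1L, tcr_corpus_n = 20000L,
                              pmhc_per_allele = 2500L, n_pos = 4000L,
                              n_test = 500L, pool_n = 4000L,
                              binder_epochs = 60L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("pretraining TCR encoder (MLM) ...")
  corpus <- gen_background_tcrs(tcr_corpus_n, seed = seed)
  tcr_enc <- pretrain_mlm(corpus, tiny_tcr_config(),
                          tiny_tcr_schedule(seed = seed))

  say("pretraining pMHC encoder (SMLM + NSP) ...")
  pm <- gen_pmhc_dataset(n_alleles = 4L, per_allele = pmhc_per_allele,
                         noise = 0.1, seed = seed)
  recs <- pm$records
  set.seed(seed)
  hold <- sample(nrow(recs), max(200L, round(0.1 * nrow(recs))))
  pmhc_enc <- pretrain_pmhc(recs[-hold, ], tiny_pmhc_config(),
                            tiny_pmhc_schedule(seed = seed))
  ho <- recs[hold, ]
  pres <- predict_presentation(pmhc_enc, ho$epitope, ho$pseudo)
  pres_lab <- ifelse(ho$assay == "MS", ho$label,
                     as.numeric(ho$label >= BA_BINDER_CUTOFF))
  presentation_auc <- auc_roc(pres, pres_lab)
  say(sprintf("held-out presentation AUC: %.3f", presentation_auc))

  say("training prediction head (contrastive) ...")
  pd <- gen_pair_dataset(n_pos = n_pos, n_neg = 0L, seed = seed,
                         n_test_pos = n_test, n_test_neg = n_test)
  pool <- gen_background_tcrs(pool_n, seed = seed + 1L)
  # the margin loss spends its first epochs on a flat plateau before the
  # pairwise interaction is found; keep early stopping out of that phase
  binder <- train_binder(pd$train, pool, tcr_enc, pmhc_enc,
                         binder_schedule(max_epochs = binder_epochs,
                                         min_epochs = 30L, seed = seed))

  say("zero-shot evaluation on held-out epitopes ...")
  f <- score_pairs(binder, tcr_enc, pmhc_enc, pd$test)
  yc <- youden_cutoff(f, pd$test$label)
  metrics <- list(
    presentation_auc = presentation_auc,
    zero_shot_auc_roc = auc_roc(f, pd$test$label),
    zero_shot_auc_pr = auc_pr(f, pd$test$label),
    youden_threshold = yc$threshold,
    youden_j = yc$J,
    bayes_auc_bound = auc_roc(as.numeric(pd$test$compatible),
                              pd$test$label)
  )
  say(sprintf("zero-shot AUC-ROC: %.3f (rule-oracle bound %.3f)",
              metrics$zero_shot_auc_roc, metrics$bayes_auc_bound))
  list(tcr_enc = tcr_enc, pmhc_enc = pmhc_enc, binder = binder,
       pairs = pd, pool = pool, pmhc = pm, test_scores = f,
       metrics = metrics)
}
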