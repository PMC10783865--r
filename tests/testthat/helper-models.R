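# Shared fixtures, built in code and memoized so expensive models are
# trained at most once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small architecture for fast structural tests
toy_tcr_config <- function() {
  encoder_config(n_layers = 2L, dim = 32L, n_heads = 4L, ff_dim = 64L,
                 max_len = 32L)
}
toy_pmhc_config <- function() {
  pmhc_config(n_layers = 2L, dim = 32L, n_heads = 4L, ff_dim = 64L,
              max_len = 52L)
}

toy_tcr_encoder <- function() memo("toy_tcr_enc", function() {
  init_encoder(toy_tcr_config(), seed = 11L)
})
toy_pmhc_encoder <- function() memo("toy_pmhc_enc", function() {
  init_encoder(toy_pmhc_config(), seed = 12L)
})

# one full scaled-down study per seed, shared across acceptance blocks
planted_study <- function(seed) {
  memo(paste0("study_", seed), function() run_planted_study(seed = seed))
}

# an MLM-pretrained encoder over a motif-planted repertoire, shared by the
# interpretability checks; long enough for motif co-occurrence to shape
# attention (validation loss drops below the ln 20 background entropy)
motif_pretrained <- function() memo("motif_enc", function() {
  rep <- gen_tcr_repertoire(6000L, planted_rate = 0.5, seed = 91L)
  enc <- pretrain_mlm(rep$sequences, tiny_tcr_config(),
                      train_schedule(peak_lr = 1e-3, batch_size = 128L,
                                     warmup_steps = 50L, max_epochs = 16L,
                                     val_fraction = 0.02, seed = 91L))
  list(rep = rep, enc = enc)
})

# all permutations of 1:n as rows (n! x n), for exhaustive permutation nulls
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

random_pseudo <- function(seed = 5L) {
  set.seed(seed)
  paste(sample(AA_ALPHABET, 34, replace = TRUE), collapse = "")
}

random_cdr3b <- function(n = 1L, len = 14L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}
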