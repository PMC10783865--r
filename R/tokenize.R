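#' Tokenize a CDR3beta sequence
#'
#' Prepends the start token, maps residues to ids and pads to `max_len`.
#' Segment ids are 0 for real tokens and 2 for padding (segment 1 is reserved
#' for epitope positions in pMHC inputs).
#'
#' @param seq Amino-acid string, 10-30 canonical residues.
#' @param max_len Padded length (default 32 = 30 residues + start + 1 spare).
#' @param vocab An `aa_vocab` (built if omitted).
#' @return A `tok_seq`: list with `ids` (0-based, length `max_len`),
#'   `segments`, `true_len` (residues + start token) and `max_len`.
#' @examples
#' tok <- tokenize_tcr("CASSLGQAYEQYF")
#' tok$true_len  # 14
#' @export
tokenize_tcr <- function(seq, max_len = 32L, vocab = build_vocab()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 10L || n > 30L)
    stop("CDR3beta length must be in [10, 30], got ", n)
  if (max_len < n + 1L) stop("max_len too small for sequence")
  ch <- split_residues(seq, "CDR3beta")
  ids <- c(start_id(vocab), vocab_id(vocab, ch),
           rep(pad_id(vocab), max_len - n - 1L))
  segments <- c(rep(0L, n + 1L), rep(2L, max_len - n - 1L))
  new_tok_seq(ids, segments, n + 1L, max_len)
}

#' Tokenize a pMHC input (pseudo-sequence + epitope)
#'
#' Layout is `[start, pseudo (34), epitope, padding]`. Segment ids: 0 for the
#' start token and MHC pseudo-sequence, 1 for the epitope, 2 for padding.
#'
#' @param pseudo 34-residue MHC pseudo-sequence.
#' @param epitope Epitope of 8-15 residues.
#' @param max_len Padded length (default 52 = 1 + 34 + 15 + 2 spare).
#' @inheritParams tokenize_tcr
#' @return A `tok_seq` (see [tokenize_tcr()]).
#' @export
tokenize_pmhc <- function(pseudo, epitope, max_len = 52L,
                          vocab = build_vocab()) {
  pseudo <- toupper(pseudo); epitope <- toupper(epitope)
  if (nchar(pseudo) != 34L)
    stop("MHC pseudo-sequence must have exactly 34 residues, got ",
         nchar(pseudo))
  ne <- nchar(epitope)
  if (ne < 8L || ne > 15L)
    stop("epitope length must be in [8, 15], got ", ne)
  if (max_len < 35L + ne) stop("max_len too small for input")
  pc <- split_residues(pseudo, "pseudo-sequence")
  ec <- split_residues(epitope, "epitope")
  npad <- max_len - 35L - ne
  ids <- c(start_id(vocab), vocab_id(vocab, pc), vocab_id(vocab, ec),
           rep(pad_id(vocab), npad))
  segments <- c(rep(0L, 35L), rep(1L, ne), rep(2L, npad))
  new_tok_seq(ids, segments, 35L + ne, max_len)
}

new_tok_seq <- function(ids, segments, true_len, max_len) {
  structure(
    list(ids = as.integer(ids), segments = as.integer(segments),
         true_len = as.integer(true_len), max_len = as.integer(max_len)),
    class = "tok_seq"
  )
}

#' @export
print.tok_seq <- function(x, ...) {
  cat("<tok_seq> true_len", x$true_len, "of", x$max_len, "\n")
  invisible(x)
}

#' Recover the residue string(s) from a tokenized sequence
#'
#' Drops the start token and padding. For pMHC inputs the pseudo-sequence
#' (segment 0) and epitope (segment 1) are returned as separate elements.
#'
#' @param tok A `tok_seq`.
#' @param vocab An `aa_vocab`.
#' @return Named character vector: `seq` for TCR inputs, `c(pseudo=, epitope=)`
#'   for pMHC inputs.
#' @export
detokenize <- function(tok, vocab = build_vocab()) {
  stopifnot(inherits(tok, "tok_seq"))
  keep <- seq_len(tok$true_len)[-1L]  # drop start; pads lie beyond true_len
  sym <- vocab$tokens[tok$ids[keep] + 1L]
  seg <- tok$segments[keep]
  if (any(seg == 1L)) {
    c(pseudo = paste(sym[seg == 0L], collapse = ""),
      epitope = paste(sym[seg == 1L], collapse = ""))
  } else {
    c(seq = paste(sym, collapse = ""))
  }
}

#' Apply masked-language-model corruption
#'
#' Each true residue position (never the start token or padding) is selected
#' independently with probability `rate`; a selected position is replaced by
#' the mask token (80%), a random amino acid (10%) or left unchanged (10%).
#' Uses the current R random-number state; call `set.seed()` for
#' reproducibility.
#'
#' @param tok A `tok_seq`.
#' @param rate Per-position masking probability (default 0.15).
#' @param vocab An `aa_vocab`.
#' @return An `mlm_example`: `input_ids` (corrupted), `target_ids` (original
#'   id at masked positions, -1 elsewhere) and `mask_positions` (1-based
#'   indices into `ids`).
#' @export
apply_mlm_mask <- function(tok, rate = 0.15, vocab = build_vocab()) {
  stopifnot(inherits(tok, "tok_seq"), rate >= 0, rate <= 1)
  ids <- matrix(tok$ids, nrow = 1L)
  out <- mask_ids_batch(ids, tok$true_len, rate, vocab)
  structure(
    list(input_ids = out$input[1L, ],
         target_ids = out$target[1L, ],
         mask_positions = which(out$target[1L, ] >= 0L)),
    class = "mlm_example"
  )
}

# Vectorized batch corruption. ids: B x L matrix of 0-based ids; lens: true
# lengths (start token included). Returns corrupted input and targets (-1
# where unmasked). Residue positions are columns 2..lens[b].
mask_ids_batch <- function(ids, lens, rate, vocab) {
  B <- nrow(ids); L <- ncol(ids)
  colidx <- matrix(rep(seq_len(L), each = B), nrow = B)
  valid <- colidx > 1L & colidx <= lens
  sel <- valid & (matrix(runif(B * L), nrow = B) < rate)
  target <- matrix(-1L, B, L)
  target[sel] <- ids[sel]
  input <- ids
  if (any(sel)) {
    u <- runif(sum(sel))
    repl <- ids[sel]
    repl[u < 0.8] <- mask_id(vocab)
    rnd <- u >= 0.8 & u < 0.9
    if (any(rnd)) repl[rnd] <- sample.int(20L, sum(rnd), replace = TRUE) - 1L
    input[sel] <- repl
  }
  list(input = input, target = target)
}

# Tokenize many sequences into batch matrices for the C++ core.
tokenize_tcr_batch <- function(seqs, max_len = 32L, vocab = build_vocab()) {
  toks <- lapply(seqs, tokenize_tcr, max_len = max_len, vocab = vocab)
  list(ids = do.call(rbind, lapply(toks, `[[`, "ids")),
       segments = do.call(rbind, lapply(toks, `[[`, "segments")),
       lens = vapply(toks, `[[`, integer(1), "true_len"))
}

tokenize_pmhc_batch <- function(pseudo, epitope, max_len = 52L,
                                vocab = build_vocab()) {
  toks <- Map(tokenize_pmhc, pseudo, epitope,
              MoreArgs = list(max_len = max_len, vocab = vocab))
  list(ids = do.call(rbind, lapply(toks, `[[`, "ids")),
       segments = do.call(rbind, lapply(toks, `[[`, "segments")),
       lens = vapply(toks, `[[`, integer(1), "true_len"))
}
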