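#' Amino-acid vocabulary
#'
#' The token inventory shared by both encoders: the 20 canonical amino
#' acids, a start-of-sequence token, a padding token, a mask token, and a
#' reserved unknown-residue token (never emitted by the tokenizers, which
#' reject non-canonical residues instead). Token ids are 0-based and stable
#' across builds.
#'
#' @return An object of class `aa_vocab` with elements `tokens` (ordered
#'   character vector of length 24) and `id` (named integer vector mapping
#'   token to id 0..23).
#' @examples
#' v <- build_vocab()
#' length(v$tokens)      # 24
#' vocab_id(v, "A")
#' @export
build_vocab <- function() {
  tokens <- c(AA_ALPHABET, "<s>", "<pad>", "<mask>", "<unk>")
  structure(
    list(tokens = tokens,
         id = stats::setNames(seq_along(tokens) - 1L, tokens)),
    class = "aa_vocab"
  )
}

#' The 20 canonical amino acids (one-letter codes, alphabetical)
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Look up token ids
#'
#' @param vocab An `aa_vocab`.
#' @param symbols Character vector of tokens.
#' @return Integer ids (0-based). Unknown symbols are an error: `B`, `J`,
#'   `O`, `U`, `X`, `Z` are not canonical amino acids.
#' @export
vocab_id <- function(vocab, symbols) {
  ids <- vocab$id[symbols]
  if (anyNA(ids)) {
    bad <- unique(symbols[is.na(ids)])
    stop("unknown symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(ids)
}

#' @rdname vocab_id
#' @export
start_id <- function(vocab) unname(vocab$id[["<s>"]])
#' @rdname vocab_id
#' @export
pad_id <- function(vocab) unname(vocab$id[["<pad>"]])
#' @rdname vocab_id
#' @export
mask_id <- function(vocab) unname(vocab$id[["<mask>"]])

# split a residue string into single characters, validating against vocab
split_residues <- function(seq, what = "sequence") {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, AA_ALPHABET)
  if (length(bad) > 0)
    stop(what, " contains non-canonical residue(s): ",
         paste(unique(bad), collapse = ", "))
  ch
}
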