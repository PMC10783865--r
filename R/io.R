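#' Transform an IC50 binding affinity to the unit interval
#'
#' `1 - log(ic50) / log(50000)`, clamped to `[0, 1]`: 1 nM maps to 1,
#' 50000 nM (the conventional non-binder ceiling) and anything weaker map
#' to 0. Strictly decreasing on (0, 50000].
#'
#' @param ic50 Positive affinity in nM (vectorized).
#' @return Scores in `[0, 1]`.
#' @examples
#' ba_to_unit(c(1, 500, 50000))
#' @export
ba_to_unit <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive and finite")
  pmin(pmax(1 - log(ic50) / log(50000), 0), 1)
}

# Conventional 500 nM binder cutoff on the unit scale (~0.4256); records at
# or above it count as binders for selective masking.
BA_BINDER_CUTOFF <- 1 - log(500) / log(50000)

#' Read a delimited table of sequence records
#'
#' Validates one of three schemas and normalizes sequences to upper case.
#' Malformed rows are reported with their line numbers.
#'
#' \describe{
#'   \item{`tcr_corpus`}{column `cdr3b` (10-30 canonical residues).}
#'   \item{`pmhc`}{columns `allele`, `pseudo` (34 residues), `epitope`
#'     (8-15 residues), `assay` (`BA` or `MS`), `label` in `[0, 1]`.}
#'   \item{`pairs`}{columns `cdr3b`, `epitope`, `label` (0/1) and either
#'     `pseudo` or `allele` resolved through `pseudo_map`.}
#' }
#'
#' @param path CSV/TSV file with a header.
#' @param schema One of `"tcr_corpus"`, `"pmhc"`, `"pairs"`.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @param pseudo_map Optional data frame (`allele`, `pseudo`) used to resolve
#'   allele names in the `pairs` schema.
#' @return A data frame of validated records.
#' @export
read_table <- function(path, schema = c("tcr_corpus", "pmhc", "pairs"),
                       sep = NULL, pseudo_map = NULL) {
  schema <- match.arg(schema)
  sep <- sep %||% (if (grepl("\\.tsv$", path)) "\t" else ",")
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- switch(schema,
    tcr_corpus = "cdr3b",
    pmhc = c("allele", "pseudo", "epitope", "assay", "label"),
    pairs = c("cdr3b", "epitope", "label"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) for schema '", schema, "': ",
         paste(missing_cols, collapse = ", "))
  line_of <- function(i) i + 1L  # header is line 1
  fail <- function(i, msg) stop("line ", line_of(i), ": ", msg)

  check_seq <- function(x, col, lo, hi) {
    x <- toupper(x)
    for (i in seq_along(x)) {
      n <- nchar(x[i])
      if (n < lo || n > hi)
        fail(i, sprintf("%s length %d outside [%d, %d]", col, n, lo, hi))
      bad <- setdiff(strsplit(x[i], "")[[1]], AA_ALPHABET)
      if (length(bad) > 0)
        fail(i, sprintf("%s has non-canonical residue(s): %s", col,
                        paste(bad, collapse = "")))
    }
    x
  }

  if (schema == "tcr_corpus") {
    df$cdr3b <- check_seq(df$cdr3b, "cdr3b", 10L, 30L)
    return(df)
  }
  if (schema == "pmhc") {
    df$pseudo <- check_seq(df$pseudo, "pseudo", 34L, 34L)
    df$epitope <- check_seq(df$epitope, "epitope", 8L, 15L)
    df$assay <- toupper(df$assay)
    for (i in seq_len(nrow(df))) {
      if (!df$assay[i] %in% c("BA", "MS"))
        fail(i, paste0("invalid assay kind '", df$assay[i],
                       "' (must be BA or MS)"))
      if (!is.finite(df$label[i]) || df$label[i] < 0 || df$label[i] > 1)
        fail(i, "label must be in [0, 1]")
    }
    return(df)
  }
  # pairs
  if (!"pseudo" %in% names(df)) {
    if (is.null(pseudo_map) || !"allele" %in% names(df))
      stop("pairs schema needs a 'pseudo' column, or an 'allele' column ",
           "plus a pseudo_map")
    idx <- match(df$allele, pseudo_map$allele)
    if (anyNA(idx))
      stop("allele(s) not in pseudo_map: ",
           paste(unique(df$allele[is.na(idx)]), collapse = ", "))
    df$pseudo <- pseudo_map$pseudo[idx]
  }
  df$cdr3b <- check_seq(df$cdr3b, "cdr3b", 10L, 30L)
  df$epitope <- check_seq(df$epitope, "epitope", 8L, 15L)
  df$pseudo <- check_seq(df$pseudo, "pseudo", 34L, 34L)
  for (i in seq_len(nrow(df)))
    if (!df$label[i] %in% c(0, 1)) fail(i, "label must be 0 or 1")
  df
}

#' Read an allele-to-pseudo-sequence mapping file
#'
#' @param path CSV with columns `allele`, `pseudo`.
#' @return Data frame with validated 34-residue pseudo-sequences.
#' @export
read_pseudo_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "pseudo") %in% names(df)))
  df$pseudo <- toupper(df$pseudo)
  if (any(nchar(df$pseudo) != 34L))
    stop("all pseudo-sequences must have 34 residues")
  df
}

#' Read epitopes from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` when available, with a
#' plain-text fallback parser.
#'
#' @param path FASTA file of epitope peptides.
#' @return Character vector of upper-cased sequences, named by record id.
#' @export
read_epitope_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readAAStringSet(path)
    return(stats::setNames(toupper(as.character(s)), names(s)))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[idx])
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(k) {
    paste(lines[(idx[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  stats::setNames(toupper(gsub("\\s", "", seqs)), ids)
}
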