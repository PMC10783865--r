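#' Contrast attention scores inside and outside specificity motifs
#'
#' For each annotated sequence the mean attention over motif residues and
#' over non-motif residues is computed; cluster-level means are compared by
#' a paired Wilcoxon signed-rank test across clusters (motif clusters, e.g.
#' from a GLIPH-style grouping, are the paired units).
#'
#' @param profiles Named list of [attention_profile()] vectors, names are
#'   sequence ids.
#' @param annotations Data frame with columns `seq_id`, `cluster`, `motif`,
#'   `start` (1-based residue position of the motif).
#' @return List with `clusters` (per-cluster mean motif / non-motif
#'   attention and their difference), `p_value`, and the `htest` object.
#' @export
motif_attention_contrast <- function(profiles, annotations) {
  need <- c("seq_id", "cluster", "motif", "start")
  stopifnot(all(need %in% names(annotations)))
  miss <- setdiff(unique(annotations$seq_id), names(profiles))
  if (length(miss) > 0)
    stop("no attention profile for sequence(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  per_seq <- lapply(seq_len(nrow(annotations)), function(i) {
    p <- profiles[[annotations$seq_id[i]]]
    span <- annotations$start[i] + seq_len(nchar(annotations$motif[i])) - 1L
    if (any(span < 1) || any(span > length(p)))
      stop("motif span outside sequence bounds for ", annotations$seq_id[i])
    c(motif = mean(p[span]), non_motif = mean(p[-span]))
  })
  m <- do.call(rbind, per_seq)
  cl <- split(seq_len(nrow(m)), annotations$cluster)
  clusters <- data.frame(
    cluster = names(cl),
    motif_mean = vapply(cl, function(ix) mean(m[ix, "motif"]), numeric(1)),
    non_motif_mean = vapply(cl, function(ix) mean(m[ix, "non_motif"]),
                            numeric(1)),
    row.names = NULL
  )
  clusters$diff <- clusters$motif_mean - clusters$non_motif_mean
  if (nrow(clusters) < 2)
    stop("paired test needs at least 2 motif clusters, got ",
         nrow(clusters))
  if (all(clusters$diff == 0)) {
    test <- NULL
    p <- 1
  } else {
    test <- suppressWarnings(
      wilcox.test(clusters$motif_mean, clusters$non_motif_mean,
                  paired = TRUE))
    p <- test$p.value
  }
  list(clusters = clusters, p_value = p, test = test)
}

#' Residue geometry of a TCR-epitope interface
#'
#' @param tcr,epitope Numeric matrices (n x 3) of representative-atom
#'   coordinates in Angstroms, one row per residue.
#' @return A `residue_geometry`.
#' @export
residue_geometry <- function(tcr, epitope) {
  tcr <- as.matrix(tcr); epitope <- as.matrix(epitope)
  stopifnot(ncol(tcr) == 3, ncol(epitope) == 3,
            all(is.finite(tcr)), all(is.finite(epitope)))
  structure(list(tcr = tcr, epitope = epitope), class = "residue_geometry")
}

#' Read interface geometry from a PDB structure
#'
#' Extracts representative-atom coordinates (default C-alpha) for two chains
#' using the `bio3d` parser.
#'
#' @param path PDB file.
#' @param tcr_chain,epitope_chain Chain identifiers.
#' @param atom Representative atom name (default `"CA"`).
#' @return A `residue_geometry`.
#' @export
read_pdb_geometry <- function(path, tcr_chain, epitope_chain, atom = "CA") {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb_geometry requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  grab <- function(chain) {
    sel <- bio3d::atom.select(pdb, chain = chain, elety = atom)
    xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
    if (nrow(xyz) == 0) stop("no ", atom, " atoms in chain ", chain)
    xyz
  }
  residue_geometry(grab(tcr_chain), grab(epitope_chain))
}

#' Average distance from each TCR residue to the epitope
#'
#' Arithmetic mean of Euclidean distances from a TCR residue's
#' representative atom to every epitope residue's representative atom.
#'
#' @param geom A `residue_geometry`.
#' @return Numeric vector (Angstroms), one value per TCR residue.
#' @export
residue_avg_distance <- function(geom) {
  stopifnot(inherits(geom, "residue_geometry"))
  if (nrow(geom$tcr) == 0 || nrow(geom$epitope) == 0)
    stop("both chains must be non-empty")
  apply(geom$tcr, 1, function(a) {
    mean(sqrt(colSums((t(geom$epitope) - a)^2)))
  })
}

#' Correlate attention with structural proximity
#'
#' Both vectors are min-max normalized per complex (which leaves the
#' Spearman coefficient unchanged) and correlated by Spearman's rho; the
#' two-sided p-value comes from a permutation test with add-one smoothing:
#' `p = (1 + #\{|rho_perm| >= |rho|\}) / (1 + n_perm)`.
#'
#' @param profile Attention scores per TCR residue.
#' @param distances Average distances per TCR residue (same length).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List with `rho`, `p`, and `n`.
#' @export
attention_distance_correlation <- function(profile, distances,
                                           n_perm = 10000L, seed = NULL) {
  profile <- as.numeric(profile)
  stopifnot(length(profile) == length(distances))
  n <- length(profile)
  if (n < 3) stop("need at least 3 residues")
  if (sd(profile) == 0 || sd(distances) == 0)
    stop("constant input vector: correlation undefined")
  minmax <- function(x) (x - min(x)) / (max(x) - min(x))
  a <- minmax(profile); d <- minmax(distances)
  rho <- cor(a, d, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- cor(a[sample.int(n)], d, method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  list(rho = rho, p = (1 + hits) / (1 + n_perm), n = n)
}

#' Read motif annotations from a cluster table
#'
#' Consumes the standard cluster-table output of motif-grouping tools
#' (columns `seq_id`, `cluster`, `motif`, `start`).
#'
#' @param path CSV file.
#' @return Data frame of annotations.
#' @export
read_motif_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "cluster", "motif", "start")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$motif <- toupper(df$motif)
  df$start <- as.integer(df$start)
  df
}
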