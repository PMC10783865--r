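#' Zero-shot train/test partition by epitope occurrence
#'
#' Pairs whose epitope occurs strictly more than `min_count` times in the
#' master set go to training; all remaining pairs form the test set, so the
#' train and test epitope sets are disjoint by construction (asserted).
#'
#' @param pairs Labeled master set with an `epitope` column.
#' @param min_count Occurrence threshold (default 10, strict).
#' @return A `split_spec`: list with `train`, `test` data frames and
#'   `min_count`.
#' @export
zero_shot_partition <- function(pairs, min_count = 10L) {
  if (nrow(pairs) == 0) stop("empty master set")
  counts <- table(pairs$epitope)
  train_epi <- names(counts)[counts > min_count]
  in_train <- pairs$epitope %in% train_epi
  out <- structure(
    list(train = pairs[in_train, , drop = FALSE],
         test = pairs[!in_train, , drop = FALSE],
         min_count = as.integer(min_count)),
    class = "split_spec"
  )
  stopifnot(length(intersect(unique(out$train$epitope),
                             unique(out$test$epitope))) == 0)
  out
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise statistic: the probability that a
#' random positive outscores a random negative, ties counted one half
#' (midrank formulation). Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision summation: precision is accumulated at each
#' positive in descending score order (stable tie-break by input order),
#' with no linear interpolation.
#'
#' @inheritParams auc_roc
#' @return Average precision in `(0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (sum(labels == 1) == 0) stop("no positive examples")
  ord <- order(-scores)  # stable
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Positive predictive value among the top-k predictions
#'
#' @inheritParams auc_roc
#' @param k Number of top-scored items to inspect (stable tie-break).
#' @return Fraction of positives among the k top-scored items.
#' @export
ppv_at_k <- function(scores, labels, k) {
  n <- length(scores)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  labels <- as.integer(as.logical(labels))
  ord <- order(-scores)
  mean(labels[ord[seq_len(k)]])
}

#' Operating threshold by the Youden index
#'
#' Scans midpoints of adjacent distinct scores (plus open ends) and returns
#' the threshold maximizing `J = TPR - FPR`; ties broken toward the lower
#' threshold.
#'
#' @inheritParams auc_roc
#' @return List with `threshold` and `J`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  check_two_classes(labels)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  cand <- c(s[1] - 1, cand, s[length(s)] + 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  J <- vapply(cand, function(th) {
    sum(scores > th & labels == 1) / n1 - sum(scores > th & labels == 0) / n0
  }, numeric(1))
  best <- which.max(J)  # first maximum = lowest threshold
  list(threshold = cand[best], J = J[best])
}

#' Resampled evaluation against rotating negative sets
#'
#' Emulates robustness evaluation at a fixed positive:negative ratio: the
#' positives are scored once, then `n_sets` independent negative draws from
#' the background pool (each of size `ratio * n_positives`, pMHCs taken from
#' the positives' multiset) are scored and summarized. Scores are cached per
#' unique pair, so repeated draws are cheap.
#'
#' @param scorer Function mapping a data frame (`cdr3b`, `epitope`,
#'   `pseudo`) to numeric scores.
#' @param positives Data frame of positive pairs.
#' @param pool Background CDR3beta sequences.
#' @param ratio Negatives per positive (default 100).
#' @param n_sets Number of independent negative draws (default 100).
#' @param ppv_k PPV cutoffs reported per set.
#' @param seed Seed for the draws.
#' @return A `metric_report`: list with per-set data frame `sets`
#'   (auc_roc, auc_pr, ppv columns), and `summary` (median and IQR of AUC).
#' @export
resampled_eval <- function(scorer, positives, pool, ratio = 100L,
                           n_sets = 100L, ppv_k = c(10L, 20L, 30L),
                           seed = 1L) {
  npos <- nrow(positives)
  if (length(pool) < 1) stop("empty background pool")
  set.seed(seed)
  pos_scores <- scorer(positives)
  cache <- new.env(parent = emptyenv())
  score_cached <- function(df) {
    key <- paste(df$cdr3b, df$epitope, sep = "|")
    have <- vapply(key, function(k) !is.null(cache[[k]]), logical(1))
    newk <- unique(key[!have])
    if (length(newk) > 0) {
      i <- match(newk, key)
      sc <- scorer(df[i, , drop = FALSE])
      for (k in seq_along(newk)) cache[[newk[k]]] <- sc[k]
    }
    vapply(key, function(k) cache[[k]], numeric(1))
  }
  rows <- lapply(seq_len(n_sets), function(s) {
    neg <- sample_negatives(positives, pool, ratio = ratio)
    neg_scores <- score_cached(neg)
    sc <- c(pos_scores, neg_scores)
    lb <- c(rep(1, npos), rep(0, nrow(neg)))
    out <- data.frame(set = s, auc_roc = auc_roc(sc, lb),
                      auc_pr = auc_pr(sc, lb))
    for (k in ppv_k) out[[paste0("ppv_at_", k)]] <- ppv_at_k(sc, lb, k)
    out
  })
  sets <- do.call(rbind, rows)
  structure(
    list(sets = sets,
         summary = list(
           auc_roc_median = stats::median(sets$auc_roc),
           auc_roc_iqr = stats::IQR(sets$auc_roc),
           auc_pr_median = stats::median(sets$auc_pr))),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", nrow(x$sets), "resampled sets\n")
  cat(sprintf("  AUC-ROC median %.3f (IQR %.3f), AUC-PR median %.3f\n",
              x$summary$auc_roc_median, x$summary$auc_roc_iqr,
              x$summary$auc_pr_median))
  invisible(x)
}
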