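# Seeded generators producing every input the pipeline consumes, with
# planted ground truth. Residue composition defaults to uniform over the 20
# canonical amino acids, which keeps planted signals clean of compositional
# confounds; all generators are pure functions of (parameters, seed).

rand_aa <- function(n, composition = NULL) {
  if (is.null(composition)) sample(AA_ALPHABET, n, replace = TRUE)
  else sample(AA_ALPHABET, n, replace = TRUE, prob = composition)
}

rand_seqs <- function(n, lens, composition = NULL) {
  lens <- rep(lens, length.out = n)
  chars <- rand_aa(sum(lens), composition)
  stops <- cumsum(lens)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  vapply(seq_len(n), function(i) {
    paste(chars[starts[i]:stops[i]], collapse = "")
  }, character(1))
}

#' Generate a healthy background TCR repertoire
#'
#' CDR3beta lengths are uniform on `[10, 30]`; residues are drawn from a
#' fixed composition (uniform by default). An optional fraction of
#' sequences begins with the canonical `CASS` germline prefix.
#'
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param composition Optional length-20 probability vector over
#'   [AA_ALPHABET].
#' @param cass_prefix_rate Fraction of sequences starting with `CASS`.
#' @return Character vector of CDR3beta sequences.
#' @export
gen_background_tcrs <- function(n, seed = 1L, composition = NULL,
                                cass_prefix_rate = 0) {
  stopifnot(n >= 1)
  set.seed(seed)
  lens <- sample(10:30, n, replace = TRUE)
  seqs <- rand_seqs(n, lens, composition)
  if (cass_prefix_rate > 0) {
    pre <- runif(n) < cass_prefix_rate
    seqs[pre] <- paste0("CASS", substr(seqs[pre], 5L, lens[pre]))
  }
  seqs
}

#' Default specificity-motif library
#'
#' Eight fixed 4-mers used as planted motifs; each defines one cluster.
#' @export
default_motif_library <- function() {
  c("GQGA", "YNEQ", "LWSG", "PDRH", "TFKA", "MVSD", "WQRE", "HEIY")
}

#' Generate a TCR repertoire with planted specificity motifs
#'
#' A `planted_rate` fraction of sequences embeds one library motif at a
#' recorded internal position (never touching the first or last residue);
#' the annotation table is exact, mimicking the cluster-table output of
#' motif-grouping tools.
#'
#' @param n Number of sequences.
#' @param motif_library Character vector of motifs (lengths 3-5).
#' @param planted_rate Fraction of sequences carrying a motif.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `annotations`
#'   (data frame `seq_id`, `cluster`, `motif`, `start`).
#' @export
gen_tcr_repertoire <- function(n, motif_library = default_motif_library(),
                               planted_rate = 0.5, seed = 1L) {
  ml <- nchar(motif_library)
  if (any(ml < 3) || any(ml > 5))
    stop("motifs must have length 3-5")
  set.seed(seed)
  lens <- sample(10:30, n, replace = TRUE)
  seqs <- rand_seqs(n, lens)
  ids <- sprintf("tcr%06d", seq_len(n))
  planted <- which(runif(n) < planted_rate)
  ann <- list()
  for (i in planted) {
    m <- sample.int(length(motif_library), 1L)
    motif <- motif_library[m]
    # keep the motif internal
    start <- sample(2:(lens[i] - nchar(motif)), 1L)
    substr(seqs[i], start, start + nchar(motif) - 1L) <- motif
    ann[[length(ann) + 1L]] <- data.frame(
      seq_id = ids[i], cluster = sprintf("cluster%02d", m), motif = motif,
      start = start, stringsAsFactors = FALSE)
  }
  list(sequences = stats::setNames(seqs, ids),
       annotations = if (length(ann) > 0) do.call(rbind, ann) else
         data.frame(seq_id = character(0), cluster = character(0),
                    motif = character(0), start = integer(0)))
}

#' Default per-allele anchor rules
#'
#' Each synthetic allele gets a random 34-residue pseudo-sequence and an
#' anchor rule: positions 2 and the C-terminus of the epitope must each
#' carry one of three permitted residues.
#'
#' @param n_alleles Number of synthetic alleles.
#' @param seed Integer seed.
#' @return An `anchor_rules` list, one element per allele with fields
#'   `allele`, `pseudo`, `anchor_pos` (2 and -1 = C-terminus), `allowed`.
#' @export
default_anchor_rules <- function(n_alleles = 4L, seed = 1L) {
  set.seed(seed)
  rules <- lapply(seq_len(n_alleles), function(a) {
    list(allele = sprintf("SYN-%02d", a),
         pseudo = rand_seqs(1L, 34L),
         anchor_pos = c(2L, -1L),
         allowed = list(sample(AA_ALPHABET, 3L), sample(AA_ALPHABET, 3L)))
  })
  structure(rules, class = "anchor_rules")
}

anchors_match <- function(epitope, rule) {
  L <- nchar(epitope)
  pos <- ifelse(rule$anchor_pos < 0, L + 1L + rule$anchor_pos,
                rule$anchor_pos)
  all(vapply(seq_along(pos), function(k) {
    substr(epitope, pos[k], pos[k]) %in% rule$allowed[[k]]
  }, logical(1)))
}

#' Generate a labeled epitope-MHC dataset with planted anchor rules
#'
#' Per allele, half of the epitopes are designed to satisfy the anchor rule
#' and half are fully random; the true binder status (anchors match) is
#' flipped with probability `noise` to produce the observed label. Records
#' alternate between binding-affinity (BA: unit-scale score consistent with
#' the label) and mass-spectrometry (MS: binary) assays.
#'
#' @param n_alleles Number of synthetic alleles (ignored when `anchor_rules`
#'   is supplied).
#' @param per_allele Records per allele.
#' @param anchor_rules Optional [default_anchor_rules()] output.
#' @param noise Label-flip rate eta in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param epitope_lengths Candidate epitope lengths.
#' @return List with `records` (pmhc schema plus `binder_true`) and `rules`.
#' @export
gen_pmhc_dataset <- function(n_alleles = 4L, per_allele = 2500L,
                             anchor_rules = NULL, noise = 0.1, seed = 1L,
                             epitope_lengths = 8:11) {
  stopifnot(n_alleles >= 1, noise >= 0, noise < 0.5)
  rules <- anchor_rules %||% default_anchor_rules(n_alleles, seed = seed)
  set.seed(seed + 1L)
  recs <- lapply(rules, function(rule) {
    lens <- sample(epitope_lengths, per_allele, replace = TRUE)
    epi <- rand_seqs(per_allele, lens)
    design <- runif(per_allele) < 0.5
    for (i in which(design)) {
      L <- lens[i]
      pos <- ifelse(rule$anchor_pos < 0, L + 1L + rule$anchor_pos,
                    rule$anchor_pos)
      for (k in seq_along(pos))
        substr(epi[i], pos[k], pos[k]) <- sample(rule$allowed[[k]], 1L)
    }
    binder <- vapply(epi, anchors_match, logical(1), rule = rule)
    label_bin <- xor(binder, runif(per_allele) < noise)
    assay <- rep(c("BA", "MS"), length.out = per_allele)
    label <- ifelse(label_bin, runif(per_allele, 0.55, 1.0),
                    runif(per_allele, 0.0, 0.30))
    label[assay == "MS"] <- as.numeric(label_bin[assay == "MS"])
    data.frame(allele = rule$allele, pseudo = rule$pseudo, epitope = epi,
               assay = assay, label = label, binder_true = binder,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  list(records = do.call(rbind, recs), rules = rules)
}

#' Default TCR-epitope recognition rule
#'
#' A fixed compatibility map from epitope key 3-mers (placed at the epitope
#' centre) to TCR 3-mers (placed at the CDR3beta centre): a pair is
#' compatible when the TCR's central 3-mer belongs to the set mapped from
#' the epitope's central 3-mer. Granularity of 3 keeps the rule learnable
#' by a small transformer while requiring genuine pairwise interaction.
#'
#' @param noise Label-flip rate eta in `[0, 0.5)` (default 0.1, keeping the
#'   Bayes-optimal AUC below 1).
#' @return A `recognition_rule`: list with `map` and `noise`.
#' @export
default_recognition_rule <- function(noise = 0.1) {
  structure(
    list(map = list(AGW = "WFG", DKF = "YRE", ERY = "KDM", HLN = "NHL"),
         noise = noise),
    class = "recognition_rule"
  )
}

rule_center <- function(seq) {
  L <- nchar(seq)
  start <- (L - 3L) %/% 2L + 1L
  substr(seq, start, start + 2L)
}

#' Does a TCR-epitope pair satisfy a recognition rule?
#' @param cdr3b,epitope Sequences (vectorized).
#' @param rule A `recognition_rule`.
#' @return Logical vector.
#' @export
satisfies_rule <- function(cdr3b, epitope, rule) {
  mapply(function(t, e) {
    key <- rule_center(e)
    comp <- rule$map[[key]]
    !is.null(comp) && rule_center(t) %in% comp
  }, cdr3b, epitope, USE.NAMES = FALSE)
}

#' Generate labeled TCR-pMHC pairs with an epitope-disjoint evaluation split
#'
#' Epitopes are 9-mers whose central 3-mer is one of the rule's keys and
#' whose flanks are random, split into disjoint training and held-out sets
#' (unseen epitope strings that follow the same rule family). Positives
#' satisfy the rule except for a `noise` fraction; negatives violate it
#' except for the same fraction, emulating label noise in experimental
#' pair data. Each epitope is assigned a synthetic allele pseudo-sequence.
#'
#' @param rule A [default_recognition_rule()].
#' @param n_pos,n_neg Training pair counts per class.
#' @param seed Integer seed.
#' @param n_test_pos,n_test_neg Held-out pair counts per class.
#' @param n_train_epitopes,n_test_epitopes Epitope inventory sizes.
#' @param n_alleles Number of synthetic alleles providing pseudo-sequences.
#' @return List with `train`, `test` (columns `cdr3b`, `epitope`, `pseudo`,
#'   `allele`, `label`, `compatible`), `rule` and `epitopes`.
#' @export
gen_pair_dataset <- function(rule = default_recognition_rule(),
                             n_pos = 2000L, n_neg = 2000L, seed = 1L,
                             n_test_pos = round(n_pos / 4),
                             n_test_neg = round(n_neg / 4),
                             n_train_epitopes = 24L, n_test_epitopes = 8L,
                             n_alleles = 2L) {
  keys <- names(rule$map)
  if (length(keys) == 0) stop("empty recognition rule")
  set.seed(seed)
  make_epitopes <- function(k) {
    out <- character(0)
    while (length(out) < k) {
      flank <- rand_seqs(2L * k, 3L)
      cand <- paste0(flank[seq_len(k)],
                     sample(keys, k, replace = TRUE),
                     flank[k + seq_len(k)])
      out <- unique(c(out, cand))
    }
    out[seq_len(k)]
  }
  all_epi <- unique(make_epitopes(n_train_epitopes + n_test_epitopes + 16L))
  if (length(all_epi) < n_train_epitopes + n_test_epitopes)
    stop("could not build enough distinct epitopes")
  train_epi <- all_epi[seq_len(n_train_epitopes)]
  test_epi <- all_epi[n_train_epitopes + seq_len(n_test_epitopes)]

  pseudos <- rand_seqs(n_alleles, 34L)
  alleles <- sprintf("SYN-%02d", seq_len(n_alleles))
  epi_allele <- stats::setNames(
    sample.int(n_alleles, length(all_epi), replace = TRUE), all_epi)

  all_motifs <- unique(unlist(rule$map))
  make_tcr <- function(epitope, compatible) {
    comp <- rule$map[[rule_center(epitope)]]
    repeat {
      L <- sample(10:30, 1L)
      s <- rand_seqs(1L, L)
      start <- (L - 3L) %/% 2L + 1L
      if (compatible) {
        substr(s, start, start + 2L) <- sample(c(comp, comp), 1L)
        return(s)
      }
      if (!(substr(s, start, start + 2L) %in% comp)) return(s)
    }
  }
  make_pairs <- function(epi_set, npos, nneg) {
    lab <- rep(c(1L, 0L), c(npos, nneg))
    epi <- sample(epi_set, npos + nneg, replace = TRUE)
    compatible <- xor(lab == 1L, runif(npos + nneg) < rule$noise)
    cdr3b <- vapply(seq_along(epi), function(i) {
      make_tcr(epi[i], compatible[i])
    }, character(1))
    a <- epi_allele[epi]
    data.frame(cdr3b = cdr3b, epitope = epi, pseudo = pseudos[a],
               allele = alleles[a], label = lab, compatible = compatible,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(train = make_pairs(train_epi, n_pos, n_neg),
       test = make_pairs(test_epi, n_test_pos, n_test_neg),
       rule = rule,
       epitopes = list(train = train_epi, test = test_epi))
}

#' Generate a toy TCR-epitope complex with planted contacts
#'
#' Epitope residues scatter within 2 Angstroms of the origin; TCR residues
#' in `contact_set` are placed within 5 Angstroms of the epitope centroid,
#' all others at 15-25 Angstroms.
#'
#' @param n_tcr_res Number of TCR residues.
#' @param contact_set Indices of contact residues.
#' @param seed Integer seed.
#' @param n_epitope_res Number of epitope residues.
#' @return List with `geometry` (a `residue_geometry`) and `contacts`.
#' @export
gen_toy_complex <- function(n_tcr_res, contact_set, seed = 1L,
                            n_epitope_res = 9L) {
  stopifnot(all(contact_set >= 1), all(contact_set <= n_tcr_res))
  set.seed(seed)
  unit <- function(n) {
    v <- matrix(rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  epitope <- unit(n_epitope_res) * runif(n_epitope_res, 0, 2)
  radius <- ifelse(seq_len(n_tcr_res) %in% contact_set,
                   runif(n_tcr_res, 3.0, 4.5), runif(n_tcr_res, 15, 25))
  tcr <- unit(n_tcr_res) * radius
  list(geometry = residue_geometry(tcr, epitope),
       contacts = sort(unique(as.integer(contact_set))))
}
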