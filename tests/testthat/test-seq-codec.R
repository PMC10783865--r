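test_that("vocabulary covers 20 amino acids plus specials, deterministically", {
  v <- build_vocab()
  expect_length(v$tokens, 24L)
  expect_setequal(intersect(v$tokens, AA_ALPHABET), AA_ALPHABET)
  expect_equal(sort(unname(v$id)), 0:23)
  expect_equal(length(unique(c(start_id(v), pad_id(v), mask_id(v)))), 3L)
  v2 <- build_vocab()
  expect_identical(vocab_id(v, "A"), vocab_id(v2, "A"))
  expect_identical(v$tokens, v2$tokens)
  expect_error(vocab_id(v, "B"), "unknown symbol")
})

test_that("TCR tokenization follows the start/residues/padding layout", {
  tok <- tokenize_tcr("CASSLGQAYEQYF")  # 13-mer
  expect_equal(tok$true_len, 14L)
  expect_equal(sum(tok$ids == pad_id(build_vocab())), 18L)
  expect_equal(tok$ids[1], start_id(build_vocab()))
  expect_equal(tok$segments, c(rep(0L, 14), rep(2L, 18)))
  expect_identical(tok, tokenize_tcr("CASSLGQAYEQYF"))
  expect_error(tokenize_tcr("CASSLGQAY"), "\\[10, 30\\]")    # 9-mer
  expect_error(tokenize_tcr(paste(rep("A", 31), collapse = "")),
               "\\[10, 30\\]")
  expect_error(tokenize_tcr("CASSLGQAYBQYF"), "non-canonical")
})

test_that("pMHC tokenization separates segments and pads correctly", {
  pseudo <- random_pseudo()
  tok <- tokenize_pmhc(pseudo, "SIINFEKLY")  # 34 + 9
  expect_equal(tok$true_len, 44L)
  expect_equal(as.vector(table(tok$segments)), c(35L, 9L, 8L))
  expect_true(all(tok$segments[tok$true_len + seq_len(8)] == 2L))
  expect_error(tokenize_pmhc(pseudo, paste(rep("A", 16), collapse = "")),
               "\\[8, 15\\]")
  expect_error(tokenize_pmhc(substr(pseudo, 1, 33), "SIINFEKLY"),
               "34 residues")
})

test_that("detokenization round-trips TCR and pMHC inputs exactly", {
  for (s in c("CASSLGQAYEQYF", random_cdr3b(3, 17, seed = 4))) {
    expect_equal(unname(detokenize(tokenize_tcr(s))), s)
  }
  pseudo <- random_pseudo()
  out <- detokenize(tokenize_pmhc(pseudo, "GILGFVFTL"))
  expect_equal(unname(out["pseudo"]), pseudo)
  expect_equal(unname(out["epitope"]), "GILGFVFTL")
})

test_that("MLM masking respects rate, targets and reproducibility", {
  tok <- tokenize_tcr("CASSLGQAYEQYF")
  set.seed(1)
  zero <- apply_mlm_mask(tok, rate = 0)
  expect_length(zero$mask_positions, 0L)
  expect_identical(zero$input_ids, tok$ids)

  set.seed(7)
  a <- apply_mlm_mask(tok, rate = 0.5)
  set.seed(7)
  b <- apply_mlm_mask(tok, rate = 0.5)
  expect_identical(a, b)
  # targets defined exactly at masked positions, never at start or pads
  expect_setequal(which(a$target_ids >= 0), a$mask_positions)
  expect_true(all(a$mask_positions > 1 & a$mask_positions <= tok$true_len))
})

test_that("masked counts are Binomial(L, rate)", {
  tok <- tokenize_tcr(random_cdr3b(1, 20, seed = 2))
  set.seed(3)
  counts <- replicate(4000, length(apply_mlm_mask(tok, 0.15)$mask_positions))
  expect_equal(mean(counts), 20 * 0.15, tolerance = 0.05)
  pv <- suppressWarnings(stats::chisq.test(
    table(factor(counts, levels = 0:20)),
    p = stats::dbinom(0:20, 20, 0.15)))$p.value
  expect_gt(pv, 0.01)
})

test_that("affinity transform is the clamped log-50000 scale", {
  expect_equal(ba_to_unit(50000), 0)
  expect_equal(ba_to_unit(1), 1)
  expect_equal(ba_to_unit(500), 1 - log(500) / log(50000), tolerance = 1e-12)
  expect_equal(round(ba_to_unit(500), 4), 0.4256)
  expect_error(ba_to_unit(0), "positive")
  # strictly decreasing on the unclamped range, constant at the ends
  x <- sort(exp(seq(log(1), log(50000), length.out = 50)))
  expect_true(all(diff(ba_to_unit(x)) < 0))
  expect_equal(ba_to_unit(c(50001, 1e7)), c(0, 0))
  expect_equal(ba_to_unit(c(0.5, 0.9)), c(1, 1))
})

test_that("tabular readers validate schemas and normalize case", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cdr3b,epitope,pseudo,label",
               paste0("cassLGQAYEQYF,SIINFEKLY,", random_pseudo(), ",1"),
               paste0("CASRTGESNQPQH,SIINFEKLY,", random_pseudo(), ",0"),
               paste0("CASSIRSSYEQYF,GILGFVFTL,", random_pseudo(), ",1")),
             tmp)
  df <- read_table(tmp, "pairs")
  expect_equal(nrow(df), 3L)
  expect_equal(df$cdr3b[1], "CASSLGQAYEQYF")  # upper-cased

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("allele,pseudo,epitope,assay,label",
               paste0("A1,", random_pseudo(), ",SIINFEKLY,BA,0.5"),
               paste0("A1,", random_pseudo(), ",SIINFEKLY,XX,0.5")), bad)
  expect_error(read_table(bad, "pmhc"), "line 3.*assay")

  noc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence", "CASSLGQAYEQYF"), noc)
  expect_error(read_table(noc, "tcr_corpus"), "missing column")
})

test_that("allele names resolve through a pseudo map", {
  pm <- data.frame(allele = c("A1", "B7"),
                   pseudo = c(random_pseudo(1), random_pseudo(2)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cdr3b,epitope,allele,label",
               "CASSLGQAYEQYF,SIINFEKLY,A1,1"), tmp)
  df <- read_table(tmp, "pairs", pseudo_map = pm)
  expect_equal(df$pseudo, pm$pseudo[1])
  pm2 <- data.frame(allele = "C3", pseudo = random_pseudo(3))
  expect_error(read_table(tmp, "pairs", pseudo_map = pm2), "not in pseudo_map")
})
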