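test_that("identical tools are fully concordant in both directions", {
  a <- standardize_calls(rbind(seg(1, 0, 1000, "loss"),
                               seg(2, 500, 2500, "gain")))
  b <- a
  b$tool_id <- "t2"
  cc <- pairwise_concordance(rbind(a, b))
  expect_true(all(cc$median_pct_concordant_seq_per_cnv == 100))
  expect_true(all(cc$pct_verified_cnvs == 100))
  expect_true(all(cc$pct_verified_cum_seq == 100))
})

test_that("concordance is asymmetric between coarse and fine callers", {
  a <- standardize_calls(seg(1, 0, 1000, "loss", tool_id = "A"))
  b <- standardize_calls(seg(1, 0, 500, "loss", tool_id = "B"))
  cc <- pairwise_concordance(rbind(a, b))
  ab <- cc[cc$predictor == "A" & cc$verifier == "B", ]
  ba <- cc[cc$predictor == "B" & cc$verifier == "A", ]
  expect_equal(ab$median_pct_concordant_seq_per_cnv, 50)
  expect_equal(ab$pct_verified_cnvs, 0)     # 0.5 does not reach >0.9
  expect_equal(ab$pct_verified_cum_seq, 50)
  expect_equal(ba$median_pct_concordant_seq_per_cnv, 100)
  expect_equal(ba$pct_verified_cnvs, 100)
  # class mismatch scores zero
  g <- b
  g$cn_class <- "gain"
  cc2 <- pairwise_concordance(rbind(a, g))
  expect_equal(cc2$pct_verified_cum_seq[cc2$predictor == "A" &
                                        cc2$verifier == "B"], 0)
})

test_that("restricting concordance to validated CNVs filters both sides", {
  ped <- data.frame(family_id = "F1", offspring_id = "s1",
                    father_id = "f1", mother_id = "m1",
                    population = "CEU", stringsAsFactors = FALSE)
  off_a <- rbind(seg(1, 0, 1000, "loss", tool_id = "A"),
                 seg(2, 0, 1000, "loss", tool_id = "A"))
  off_b <- rbind(seg(1, 0, 1000, "loss", tool_id = "B"),
                 seg(2, 0, 1000, "loss", tool_id = "B"))
  par_a <- seg(1, 0, 1000, "loss", "f1", tool_id = "A")
  par_b <- seg(1, 0, 1000, "loss", "f1", tool_id = "B")
  calls <- standardize_calls(rbind(off_a, off_b, par_a, par_b))
  rec <- validate_trios(calls, ped)
  off <- calls[calls$sample_id == "s1", ]
  cc <- pairwise_concordance(off, validated = rec)
  # only the chrom-1 CNV is validated, and the tools agree on it
  expect_true(all(cc$pct_verified_cnvs == 100))
})

test_that("consensus depth stacking matches the per-base oracle", {
  # worked example: three tools, k = 3 leaves only the common core
  calls <- standardize_calls(rbind(
    seg(1, 100, 200, "loss", tool_id = "t1"),
    seg(1, 150, 250, "loss", tool_id = "t2"),
    seg(1, 180, 300, "loss", tool_id = "t3")))
  cons <- consensus_calls(calls, k = 3)
  expect_equal(cons$start, 180)
  expect_equal(cons$end, 200)

  # k = 1 is the union, k > tools is empty with a warning
  u <- consensus_calls(calls, k = 1)
  expect_equal(u$start, 100)
  expect_equal(u$end, 300)
  expect_warning(e <- consensus_calls(calls, k = 4), "exceeds")
  expect_equal(nrow(e), 0)

  set.seed(17)
  for (rep in 1:40) {
    d <- standardize_calls(random_calls(
      sample(4:14, 1), max_pos = 150,
      tools = paste0("t", 1:4)))
    for (k in 1:4) {
      got <- suppressWarnings(consensus_calls(d, k))
      exp <- depth_oracle(d, k)
      if (is.null(exp)) {
        expect_equal(nrow(got), 0)
      } else {
        got <- got[order(got$cn_class, got$chrom, got$start), ]
        expect_equal(got$start, exp$start)
        expect_equal(got$end, exp$end)
        expect_equal(got$cn_class, exp$cn_class)
      }
    }
  }
})

test_that("consensus sets are nested in k and conserve stacked bases", {
  set.seed(19)
  calls <- standardize_calls(random_calls(60, max_pos = 3000,
                                          tools = paste0("t", 1:6)))
  cum_bases <- 0
  prev <- NULL
  prev_df <- NULL
  for (k in 1:6) {
    cons <- suppressWarnings(consensus_calls(calls, k))
    bases_k <- sum(cons$end - cons$start)
    if (!is.null(prev)) expect_lte(bases_k, prev)
    # nesting base-wise: every k-consensus base is covered by the
    # (k-1)-consensus
    if (!is.null(prev_df) && nrow(cons)) {
      q <- cons
      q$sample_id <- "s1"
      q$tool_id <- "x"
      s <- prev_df
      if (nrow(s)) {
        s$sample_id <- "s1"
        s$tool_id <- "x"
        covered <- sum(vapply(seq_len(nrow(q)), function(i)
          coverage_fraction(q[i, setdiff(names(q), "tool_id")],
                            s) * (q$end[i] - q$start[i]), numeric(1)))
        expect_equal(covered, bases_k)
      }
    }
    prev <- bases_k
    prev_df <- cons
    cum_bases <- cum_bases + bases_k
  }
  # sum over k of bases(depth >= k) equals total called bases (per-tool
  # merged), i.e. stacking conserves base pairs
  expect_equal(cum_bases, sum(calls$end - calls$start))
})

test_that("reference verification counts class-aware covered calls", {
  calls <- standardize_calls(rbind(
    seg(1, 0, 1000, "loss"), seg(2, 0, 1000, "loss"),
    seg(3, 0, 1000, "gain"), seg(4, 0, 1000, "loss")))
  ref <- data.frame(chrom = c(1, 2, 3), start = 0, end = 1000,
                    cn_class = c("loss", "loss", "gain"),
                    stringsAsFactors = FALSE)
  v <- verify_against_reference(calls, ref)
  expect_equal(v$summary$pct_verified, 75)

  # 1 bp breakpoint shift fails a threshold of 1 under >= comparison
  shifted <- data.frame(chrom = 1, start = 1, end = 1001,
                        cn_class = "loss", stringsAsFactors = FALSE)
  one <- standardize_calls(seg(1, 0, 1000, "loss"))
  v2 <- verify_against_reference(one, shifted, threshold = 1,
                                 comparison = ">=")
  expect_false(v2$records$verified)

  # class-blind matching for unannotated references
  ref_blind <- ref[, c("chrom", "start", "end")]
  expect_error(verify_against_reference(calls, ref_blind),
               "class_aware")
  v3 <- verify_against_reference(calls, ref_blind, class_aware = FALSE)
  expect_equal(v3$summary$pct_verified, 75)

  expect_warning(v4 <- verify_against_reference(calls, ref[0, ]),
                 "empty reference")
  expect_equal(v4$summary$pct_verified, 0)
})
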