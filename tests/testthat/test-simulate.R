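test_that("panels respect the genome, class mix and frequency model", {
  panel <- simulate_panel(400, ddr = 4, seed = 1)
  expect_true(all(panel$chrom %in% 1:22))
  expect_true(all(panel$end > panel$start))
  expect_true(all(panel$end <= sim_genome()[as.character(panel$chrom)]))
  # same-class loci never overlap
  expect_true(all(cnvtrio:::.covered_width(panel, panel) ==
                    panel$end - panel$start))
  # deletion fraction targets ddr/(1+ddr) = 0.8
  p_del <- mean(panel$cn_class == "loss")
  expect_lt(abs(p_del - 0.8), 3 * sqrt(0.8 * 0.2 / 400))
  # zero divergence gives identical population frequencies
  p0 <- simulate_panel(50, divergence = 0, seed = 2)
  expect_equal(p0$freq_CEU, p0$freq_YRI)
  # determinism
  expect_identical(simulate_panel(50, seed = 3), simulate_panel(50, seed = 3))
})

test_that("Mendelian transmission drives offspring carrier status", {
  # forced transmission: homozygous-carrier parents, rate 1
  panel <- simulate_panel(60, freq = 1, seed = 4)
  tr <- simulate_trios(panel, n_trios = 4, de_novo_rate = 0, seed = 5)
  off <- tr$truth[tr$truth$origin == "inherited", ]
  for (o in tr$pedigree$offspring_id) {
    expect_setequal(off$locus_id[off$sample_id == o], panel$locus_id)
  }
  # freq 0: nobody carries anything
  panel0 <- simulate_panel(60, freq = 0, seed = 6)
  tr0 <- simulate_trios(panel0, n_trios = 4, de_novo_rate = 0, seed = 7)
  expect_equal(nrow(tr0$truth), 0)

  # heterozygous carrier transmits to about half the offspring: with
  # allele frequency f the offspring carrier probability is 1 - (1-f)^2
  f <- 0.3
  panelf <- simulate_panel(250, freq = f, seed = 8)
  trf <- simulate_trios(panelf, n_trios = 8, de_novo_rate = 0, seed = 9)
  inh <- trf$truth[trf$truth$origin == "inherited", ]
  p_carry <- nrow(inh) / (250 * 8)
  p_exp <- 1 - (1 - f)^2
  expect_lt(abs(p_carry - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / (250 * 8)))

  # every inherited CNV is present in a flagged carrier parent
  tr2 <- simulate_trios(simulate_panel(80, seed = 10), n_trios = 6,
                        de_novo_rate = 0, seed = 11)
  inh2 <- tr2$truth[tr2$truth$origin == "inherited", ]
  for (i in seq_len(nrow(inh2))) {
    fam <- tr2$pedigree[tr2$pedigree$offspring_id == inh2$sample_id[i], ]
    par_ids <- switch(inh2$parent[i],
                      father = fam$father_id,
                      mother = fam$mother_id,
                      both = c(fam$father_id, fam$mother_id))
    carried <- tr2$truth$locus_id[tr2$truth$sample_id %in% par_ids]
    expect_true(inh2$locus_id[i] %in% carried)
  }
})

test_that("de novo events are appended at the configured rate", {
  panel <- simulate_panel(250, seed = 12)
  tr <- simulate_trios(panel, n_trios = 20, de_novo_rate = 0.05, seed = 13)
  off <- tr$truth[tr$truth$origin != "germline", ]
  frac <- mean(off$origin == "de_novo")
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(off)))
  # de novo segments never touch panel loci
  dn <- off[off$origin == "de_novo", ]
  expect_true(all(cnvtrio:::.covered_width(dn, panel,
                                           class_aware = FALSE) == 0))
  expect_error(simulate_trios(panel, de_novo_rate = 0.6), "de_novo_rate")
})

test_that("the noiseless caller reproduces the truth exactly", {
  panel <- simulate_panel(80, seed = 14)
  tr <- simulate_trios(panel, n_trios = 5, de_novo_rate = 0, seed = 15)
  calls <- simulate_calls(tr$truth, perfect_profile(), seed = 16)
  st <- standardize_calls(calls)
  truth_st <- standardize_calls(
    data.frame(tr$truth[, c("sample_id", "chrom", "start", "end",
                            "cn_class")],
               tool_id = "perfect", stringsAsFactors = FALSE))
  expect_equal(st[, c("sample_id", "chrom", "start", "end", "cn_class")],
               truth_st[, c("sample_id", "chrom", "start", "end",
                            "cn_class")])

  # sensitivity 0 and no false positives: silence
  mute <- tool_profile("mute", "hmm", sensitivity = 0, fp_rate_per_mb = 0,
                       jitter_sd = 0)
  expect_equal(nrow(simulate_calls(tr$truth, mute, seed = 17)), 0)
})

test_that("false positives follow the Poisson rate", {
  # sensitivity 0 leaves pure false positives over a synthetic truth
  truth <- data.frame(sample_id = sprintf("s%02d", 1:30), chrom = 1,
                      start = 0, end = 1000, cn_class = "loss",
                      stringsAsFactors = FALSE)
  lambda_mb <- 0.01
  prof <- tool_profile("fp", "hmm", sensitivity = 0,
                       fp_rate_per_mb = lambda_mb, jitter_sd = 0)
  calls <- simulate_calls(truth, prof, seed = 20)
  lambda <- lambda_mb * sum(sim_genome()) / 1e6
  n_fp <- nrow(calls) / 30
  expect_lt(abs(n_fp - lambda), 3 * sqrt(lambda / 30))
})

test_that("breakpoint jitter and fragmentation keep segments well-formed", {
  panel <- simulate_panel(100, seed = 21)
  tr <- simulate_trios(panel, n_trios = 4, de_novo_rate = 0, seed = 22)
  noisy <- tool_profile("noisy", "segmentation", sensitivity = 1,
                        fp_rate_per_mb = 0.05, jitter_sd = 3000,
                        fragmentation_prob = 0.6, fragment_gap = 1500)
  calls <- simulate_calls(tr$truth, noisy, seed = 23)
  expect_true(all(calls$start < calls$end))
  expect_true(all(calls$start >= 0))
  expect_true(all(calls$end <= sim_genome()[as.character(calls$chrom)]))
  # fragmentation produces more calls than true CNVs
  expect_gt(nrow(calls), nrow(tr$truth))
})

test_that("simulated studies are reproducible under a fixed seed", {
  a <- simulate_study(n_trios = 4, n_loci = 30, seed = 24,
                      profiles = default_profiles()[c(1, 4)])
  b <- simulate_study(n_trios = 4, n_loci = 30, seed = 24,
                      profiles = default_profiles()[c(1, 4)])
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
})

test_that("validation degrades as parental sensitivity drops", {
  panel <- simulate_panel(150, seed = 25)
  tr <- simulate_trios(panel, n_trios = 10, de_novo_rate = 0, seed = 26)
  rates <- sapply(c(1, 0.7, 0.4), function(s) {
    prof <- tool_profile("t", "hmm", sensitivity = s, fp_rate_per_mb = 0,
                         jitter_sd = 0)
    calls <- standardize_calls(simulate_calls(tr$truth, prof, seed = 27))
    mean(validate_trios(calls, tr$pedigree)$validated)
  })
  expect_true(all(diff(rates) < 0))
})
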