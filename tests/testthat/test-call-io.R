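test_that("genotypes collapse to classes with range checking", {
  expect_equal(collapse_genotype_to_class(c(0, 1)), c("loss", "loss"))
  expect_equal(collapse_genotype_to_class(2), "normal")
  expect_equal(collapse_genotype_to_class(3:6), rep("gain", 4))
  expect_error(collapse_genotype_to_class(7), "0..6")
  expect_error(collapse_genotype_to_class(-1), "0..6")
  expect_error(collapse_genotype_to_class(1.5), "0..6")
})

test_that("segment files round-trip and filter non-autosomal rows", {
  calls <- standardize_calls(rbind(
    seg(1, 100, 5000, "loss", n_markers = 5L),
    seg(2, 200, 900, "gain", n_markers = 3L),
    seg(22, 0, 400, "loss", n_markers = 2L)))
  f <- tempfile(fileext = ".tsv")
  write_call_file(calls, f)
  back <- read_call_file(f)
  expect_equal(back[, c("sample_id", "tool_id", "chrom", "start", "end",
                        "cn_class", "n_markers")],
               calls[, c("sample_id", "tool_id", "chrom", "start", "end",
                         "cn_class", "n_markers")])
  # a second round trip is byte-identical
  f2 <- tempfile(fileext = ".tsv")
  write_call_file(standardize_calls(back), f2)
  expect_identical(readLines(f), readLines(f2))

  # chrX row dropped with a message under autosome filtering
  lines <- readLines(f)
  writeLines(c(lines, "s1\tt1\tX\t10\t20\tloss\tNA"), f)
  expect_message(dropped <- read_call_file(f), "non-autosomal")
  expect_equal(nrow(dropped), nrow(calls))
})

test_that("genotype-coded files are collapsed on read and bad codes error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttool_id\tchrom\tstart\tend\tcn",
               "s1\tt1\t1\t100\t200\t1",
               "s1\tt1\t1\t300\t400\t4"), f)
  calls <- read_call_file(f)
  expect_equal(calls$cn_class, c("loss", "gain"))
  expect_equal(calls$cn_genotype, c(1L, 4L))

  writeLines(c("sample_id\ttool_id\tchrom\tstart\tend\tcn",
               "s1\tt1\t1\t100\t200\tdel"), f)
  expect_error(read_call_file(f), "unknown CN code 'del'")

  writeLines(c("sample_id\ttool_id\tchrom\tstart\tend\tcn",
               "s1\tt1\t1\t100\t200\tloss",
               "s1\tt1\t1\t500\t400\tloss"), f)
  expect_error(read_call_file(f), "line 3")
})

test_that("marker runs convert to segments and re-expand to the input", {
  mm <- data.frame(marker_id = paste0("m", 1:8),
                   chrom = c(1, 1, 1, 1, 1, 2, 2, 2),
                   position = c(100, 200, 300, 450, 600, 50, 80, 120),
                   stringsAsFactors = FALSE)
  # single run of three markers
  st <- data.frame(marker_id = c("m1", "m2", "m3"), state = rep("loss", 3),
                   stringsAsFactors = FALSE)
  out <- markers_to_segments(st, mm)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$end, 301)
  expect_equal(out$n_markers, 3L)

  # interrupted run -> two 1-marker segments
  st2 <- data.frame(marker_id = c("m1", "m2", "m3"),
                    state = c("loss", "normal", "loss"),
                    stringsAsFactors = FALSE)
  out2 <- markers_to_segments(st2, mm)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$n_markers, c(1L, 1L))

  # same state crossing a chromosome boundary is split
  st3 <- data.frame(marker_id = c("m4", "m5", "m6", "m7"),
                    state = rep("gain", 4), stringsAsFactors = FALSE)
  out3 <- markers_to_segments(st3, mm)
  expect_equal(out3$chrom, c(1, 2))
  expect_equal(out3$n_markers, c(2L, 2L))

  expect_error(markers_to_segments(
    data.frame(marker_id = "nope", state = "loss"), mm), "unknown marker")

  # property: re-expanding the segments against the map reproduces the
  # marker states (brute-force oracle over every marker)
  set.seed(42)
  for (rep in 1:20) {
    states <- sample(c("loss", "normal", "gain"), 8, replace = TRUE)
    stx <- data.frame(marker_id = mm$marker_id, state = states,
                      stringsAsFactors = FALSE)
    sg <- markers_to_segments(stx, mm)
    reexp <- vapply(seq_len(nrow(mm)), function(i) {
      hit <- sg$chrom == mm$chrom[i] & sg$start <= mm$position[i] &
        sg$end > mm$position[i]
      if (any(hit)) sg$cn_class[hit] else "normal"
    }, character(1))
    expect_equal(reexp, states)
  }
})

test_that("marker-dialect files are segmented per sample and tool", {
  mm <- data.frame(marker_id = paste0("m", 1:4), chrom = 1,
                   position = c(10, 20, 30, 40), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttool_id\tmarker_id\tcn",
               "s1\tt1\tm1\t1", "s1\tt1\tm2\t1",
               "s1\tt1\tm3\t2", "s1\tt1\tm4\t3",
               "s2\tt1\tm1\t2", "s2\tt1\tm2\t0"), f)
  calls <- read_call_file(f, dialect = "marker", marker_map = mm)
  expect_equal(nrow(calls), 3)
  s1 <- calls[calls$sample_id == "s1", ]
  expect_equal(s1$cn_class, c("loss", "gain"))
  expect_equal(s1$start, c(10, 40))
  expect_equal(s1$end, c(21, 41))
  expect_equal(calls$cn_class[calls$sample_id == "s2"], "loss")

  # a sample whose markers are all copy-neutral contributes no segments
  writeLines(c("sample_id\ttool_id\tmarker_id\tcn",
               "s1\tt1\tm1\t2", "s1\tt1\tm2\t2",
               "s2\tt1\tm1\t1"), f)
  calls2 <- read_call_file(f, dialect = "marker", marker_map = mm)
  expect_equal(calls2$sample_id, "s2")
})

test_that("standardization merges same-class unions and is idempotent", {
  raw <- rbind(seg(1, 100, 200, "loss"), seg(1, 150, 250, "loss"),
               seg(1, 150, 250, "gain"), seg(1, 400, 500, "normal"),
               seg(1, 250, 300, "loss"),     # book-ended with the union
               seg(1, 1000, 1500, "loss"))   # < 1 kb outlier retained
  st <- standardize_calls(raw)
  loss <- st[st$cn_class == "loss", ]
  expect_equal(loss$start, c(100, 1000))
  expect_equal(loss$end, c(300, 1500))
  expect_equal(st[st$cn_class == "gain", ]$start, 150)
  expect_false(any(st$cn_class == "normal"))
  # sub-kb calls survive
  expect_true(any(st$end - st$start < 1000))
  expect_identical(standardize_calls(st), st)

  # per-base union oracle: covered bases per class are preserved
  set.seed(7)
  for (rep in 1:20) {
    r <- random_calls(15, max_pos = 400)
    s <- standardize_calls(r)
    for (cl in c("loss", "gain")) for (ch in 1:3) {
      base_cov <- function(d) sum(vapply(0:400, function(b)
        any(d$chrom == ch & d$cn_class == cl & d$start <= b & d$end > b),
        logical(1)))
      expect_identical(base_cov(r), base_cov(s))
    }
    # total covered bp never increases and no same-class overlaps remain
    expect_lte(sum(s$end - s$start), sum(r$end - r$start))
    key <- paste(s$sample_id, s$tool_id, s$chrom, s$cn_class)
    for (k in unique(key)) {
      d <- s[key == k, ]
      if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }
})

test_that("standardization aggregates marker counts and genotypes", {
  raw <- rbind(seg(1, 100, 200, "loss", cn_genotype = 1L, n_markers = 4L),
               seg(1, 180, 300, "loss", cn_genotype = 1L, n_markers = 6L),
               seg(2, 100, 200, "loss", cn_genotype = 0L, n_markers = 2L),
               seg(2, 150, 300, "loss", cn_genotype = 1L, n_markers = 2L))
  st <- standardize_calls(raw)
  expect_equal(st$n_markers, c(10L, 4L))
  expect_equal(st$cn_genotype, c(1L, NA_integer_))
})

test_that("pedigrees round-trip through PED files with trio checks", {
  ped <- data.frame(family_id = c("F1", "F2"),
                    offspring_id = c("c1", "c2"),
                    father_id = c("f1", "f2"), mother_id = c("m1", "m2"),
                    population = c("CEU", "YRI"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".ped")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(back[, names(ped)], ped)

  bad <- ped
  bad$father_id[2] <- "c2"
  expect_error(write_pedigree(bad, f), "non-distinct")
})

test_that("BED export is six plain columns", {
  calls <- standardize_calls(seg(5, 1000, 2500, "gain", n_markers = 7L))
  f <- tempfile(fileext = ".bed")
  write_bed(calls, f)
  expect_equal(readLines(f), "chr5\t1000\t2500\tgain\t7\t.")
})
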