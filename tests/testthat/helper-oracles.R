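# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's sweep-based interval code:
# they enumerate integer base positions one by one, so they are only usable
# on small coordinates, but their correctness is self-evident.

seg <- function(chrom, start, end, cn_class, sample_id = "s1",
                tool_id = "t1", cn_genotype = NA_integer_,
                n_markers = NA_integer_) {
  data.frame(sample_id = sample_id, tool_id = tool_id, chrom = chrom,
             start = start, end = end, cn_class = cn_class,
             cn_genotype = cn_genotype, n_markers = n_markers,
             stringsAsFactors = FALSE)
}

# per-base coverage of `target` (single row) by the union of `others`
coverage_oracle <- function(target, others, same_class = TRUE) {
  if (!nrow(others)) return(0)
  bases <- seq(target$start, target$end - 1)
  keep <- others$chrom == target$chrom
  if (same_class) keep <- keep & others$cn_class == target$cn_class
  o <- others[keep, , drop = FALSE]
  covered <- vapply(bases, function(b) any(o$start <= b & o$end > b),
                    logical(1))
  mean(covered)
}

# per-base depth >= k regions, counting each tool once per base
depth_oracle <- function(calls, k, max_pos = 200) {
  res <- NULL
  combos <- unique(calls[, c("sample_id", "cn_class", "chrom")])
  for (i in seq_len(nrow(combos))) {
    d <- merge(calls, combos[i, ])
    rng <- 0:max_pos
    depth <- vapply(rng, function(b)
      length(unique(d$tool_id[d$start <= b & d$end > b])), integer(1))
    ok <- depth >= k
    if (!any(ok)) next
    r <- rle(ok)
    iend <- cumsum(r$lengths)
    istart <- iend - r$lengths + 1
    for (j in which(r$values)) {
      res <- rbind(res, data.frame(
        sample_id = combos$sample_id[i], chrom = combos$chrom[i],
        start = rng[istart[j]], end = rng[iend[j]] + 1,
        cn_class = combos$cn_class[i], stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) return(res)
  res <- res[order(res$sample_id, res$cn_class, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# random small call table on coordinates [0, max_pos)
random_calls <- function(n, max_pos = 1000, samples = "s1", tools = "t1",
                         classes = c("loss", "gain")) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  data.frame(sample_id = sample(samples, n, replace = TRUE),
             tool_id = sample(tools, n, replace = TRUE),
             chrom = sample(1:3, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_pos %/% 5, n, replace = TRUE),
             cn_class = sample(classes, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exhaustive signed-rank two-sided p-value by enumerating all 2^n sign
# assignments of the absolute differences (valid without ties/zeros)
signed_rank_enum <- function(a, b) {
  d <- a - b
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  list(statistic = v_obs, p_value = min(1, 2 * min(p_low, p_high)))
}

# tiny two-population trio study with a perfect caller for pipeline tests
perfect_profile <- function(tool_id = "perfect",
                            class = c("hmm", "segmentation")) {
  tool_profile(tool_id, match.arg(class), sensitivity = 1,
               fp_rate_per_mb = 0, jitter_sd = 0, fragmentation_prob = 0,
               class_confusion_prob = 0)
}
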