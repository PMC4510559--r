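# Internal segment model and interval arithmetic.
#
# Segments are rows of a plain data.frame with 0-based half-open coordinates
# (BED-compatible): chrom (integer 1..22), start, end, cn_class in
# {"loss","normal","gain"}, plus sample_id / tool_id provenance and optional
# cn_genotype (0..6) and n_markers.
#
# Coverage-by-union is the primitive every benchmark measure is built on
# (trio validation, concordance, reference verification), and it runs inside
# the permutation loops, so it is implemented as a single vectorized sweep:
# grouping keys (chrom, class, sample/tool) are encoded as offsets on one
# numeric axis, subject intervals are merged by a cummax run scan, and
# per-query covered widths come from binary searches (findInterval) against
# the merged set.  Doubles hold the encoded coordinates exactly (all values
# stay far below 2^53).

CN_CLASSES <- c("loss", "normal", "gain")

# hg19 autosome lengths (bp), chromosomes 1..22
HG19_AUTOSOMES <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
   59128983,  63025520,  48129895,  51304566
)
names(HG19_AUTOSOMES) <- as.character(1:22)

# offset between encoded key blocks; must exceed any base-pair coordinate
.KEY_OFFSET <- 2^34

.call_columns <- c("sample_id", "tool_id", "chrom", "start", "end", "cn_class")

.check_calls <- function(calls, what = "calls") {
  if (!is.data.frame(calls)) {
    stop(what, " must be a data.frame of CNV segments", call. = FALSE)
  }
  missing_cols <- setdiff(.call_columns, names(calls))
  if (length(missing_cols)) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(calls$cn_class %in% CN_CLASSES))
  if (length(bad)) {
    stop("unknown CN class '", calls$cn_class[bad[1]], "' in ", what,
         call. = FALSE)
  }
  bad <- which(!(calls$start < calls$end))
  if (length(bad)) {
    stop("segment with start >= end in ", what, " (row ", bad[1], ")",
         call. = FALSE)
  }
  invisible(calls)
}

.empty_calls <- function() {
  data.frame(sample_id = character(), tool_id = character(),
             chrom = integer(), start = numeric(), end = numeric(),
             cn_class = character(), cn_genotype = integer(),
             n_markers = integer(), stringsAsFactors = FALSE)
}

# Merge key-encoded intervals (sg, eg already sorted by sg) into maximal
# runs; overlapping or book-ended intervals join one run.  Returns merged
# starts/ends and the run id of every input interval.
.merge_encoded <- function(sg, eg) {
  n <- length(sg)
  cm <- cummax(c(-Inf, eg[-n]))
  new_run <- sg > cm
  new_run[1] <- TRUE
  run_id <- cumsum(new_run)
  run_last <- c(which(new_run)[-1] - 1L, n)
  list(ms = sg[new_run], me = cummax(eg)[run_last], run_id = run_id,
       first = which(new_run))
}

# For each query row, number of its bases covered by the union of subject
# rows sharing chromosome (and CN class when class_aware), and optionally an
# extra grouping key (e.g. sample or tool) on either side.
.covered_width <- function(query, subject, class_aware = TRUE,
                           query_extra = NULL, subject_extra = NULL) {
  nq <- nrow(query)
  out <- numeric(nq)
  if (nq == 0L || nrow(subject) == 0L) {
    return(out)
  }
  qk <- paste(query$chrom,
              if (class_aware) query$cn_class else "",
              if (is.null(query_extra)) "" else query_extra,
              sep = "\r")
  sk <- paste(subject$chrom,
              if (class_aware) subject$cn_class else "",
              if (is.null(subject_extra)) "" else subject_extra,
              sep = "\r")
  keys <- unique(c(qk, sk))
  qi <- match(qk, keys)
  si <- match(sk, keys)
  stopifnot(max(query$end, subject$end) < .KEY_OFFSET)

  sg <- si * .KEY_OFFSET + subject$start
  eg <- si * .KEY_OFFSET + subject$end
  ord <- order(sg)
  m <- .merge_encoded(sg[ord], eg[ord])

  qs <- qi * .KEY_OFFSET + query$start
  qe <- qi * .KEY_OFFSET + query$end
  i1 <- findInterval(qs, m$me) + 1L               # first merged end > qs
  i2 <- findInterval(qe, m$ms, left.open = TRUE)  # last merged start < qe
  hit <- i1 <= i2
  if (any(hit)) {
    cumw <- cumsum(m$me - m$ms)
    full <- cumw[i2[hit]] - c(0, cumw)[i1[hit]]
    out[hit] <- full -
      pmax(0, qs[hit] - m$ms[i1[hit]]) -
      pmax(0, m$me[i2[hit]] - qe[hit])
  }
  out
}

# Base-pair stacking depth: given group-assigned intervals, returns the
# maximal runs where at least k intervals overlap, per group, via a sorted
# +1/-1 boundary-event sweep on the key-encoded axis.
.depth_runs <- function(group, start, end, k) {
  empty <- data.frame(group = integer(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  if (!length(start)) return(empty)
  p <- c(group * .KEY_OFFSET + start, group * .KEY_OFFSET + end)
  delta <- rep(c(1, -1), each = length(start))
  o <- order(p)
  p <- p[o]
  depth <- cumsum(delta[o])
  n <- length(p)
  last_at_pos <- c(p[-1] != p[-n], TRUE)
  pos_u <- p[last_at_pos]
  depth_u <- depth[last_at_pos]   # depth on [pos_u[i], pos_u[i+1])
  ok <- depth_u >= k              # final depth is 0, so ok ends FALSE
  if (!any(ok)) return(empty)
  r <- rle(ok)
  iend <- cumsum(r$lengths)
  istart <- iend - r$lengths + 1L
  s <- pos_u[istart[r$values]]
  e <- pos_u[iend[r$values] + 1L]
  data.frame(group = as.integer(s %/% .KEY_OFFSET),
             start = s %% .KEY_OFFSET, end = e %% .KEY_OFFSET,
             stringsAsFactors = FALSE)
}

.meets <- function(coverage, threshold, comparison = c(">", ">=")) {
  comparison <- match.arg(comparison)
  if (comparison == ">") coverage > threshold else coverage >= threshold
}
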