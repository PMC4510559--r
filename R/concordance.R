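# Inter-tool concordance, multi-tool consensus regions and verification
# against an external reference variant set.

#' Asymmetric pairwise concordance between tools
#'
#' For every ordered (predictor, verifier) tool pair, measures how much of
#' the predictor's called sequence the verifier assigns the same CN class,
#' per shared sample.  Three measures are reported, each as the median over
#' samples:
#' \enumerate{
#'   \item \code{median_pct_concordant_seq_per_cnv}: per-CNV concordant
#'     fraction (verifier same-class union coverage of each predictor CNV),
#'     median per sample, then median over samples;
#'   \item \code{pct_verified_cnvs}: percentage of predictor CNVs whose
#'     concordant fraction passes the threshold;
#'   \item \code{pct_verified_cum_seq}: percentage of the predictor's
#'     cumulated CNV sequence covered by verifier same-class calls.
#' }
#' The measure is deliberately asymmetric (a fragmenting tool may be fully
#' covered by a coarse tool but not vice versa).  Optionally restricted to
#' family-validated CNVs by passing validation records.
#'
#' @param calls standardized segment data.frame with at least two tools.
#' @param threshold coverage fraction a CNV must exceed to count as
#'   verified (default 0.9, strict \code{>}).
#' @param comparison \code{">"} (default) or \code{">="}.
#' @param validated optional validation records
#'   (\code{\link{validate_trios}}); when given, only calls matching a
#'   validated record enter the comparison (predictor and verifier side).
#' @return data.frame with one row per ordered tool pair.
#' @export
pairwise_concordance <- function(calls, threshold = 0.9, comparison = ">",
                                 validated = NULL) {
  .check_calls(calls)
  if (!is.null(validated)) {
    calls <- .restrict_to_validated(calls, validated)
  }
  tools <- sort(unique(calls$tool_id))
  if (length(tools) < 2L) {
    stop("pairwise concordance needs at least 2 tools", call. = FALSE)
  }
  rows <- list()
  for (pred in tools) {
    pc <- calls[calls$tool_id == pred, , drop = FALSE]
    for (verif in tools) {
      vc <- calls[calls$tool_id == verif, , drop = FALSE]
      shared <- intersect(unique(pc$sample_id), unique(vc$sample_id))
      if (!length(shared)) {
        stop("tools ", pred, " and ", verif, " share no samples",
             call. = FALSE)
      }
      p <- pc[pc$sample_id %in% shared, , drop = FALSE]
      v <- vc[vc$sample_id %in% shared, , drop = FALSE]
      len <- p$end - p$start
      frac <- .covered_width(p, v, query_extra = p$sample_id,
                             subject_extra = v$sample_id) / len
      per_sample <- split(seq_len(nrow(p)), p$sample_id)
      m_cnv <- vapply(per_sample, function(i) stats::median(frac[i]),
                      numeric(1))
      m_ver <- vapply(per_sample, function(i)
        mean(.meets(frac[i], threshold, comparison)), numeric(1))
      m_seq <- vapply(per_sample, function(i)
        sum(frac[i] * len[i]) / sum(len[i]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = pred, verifier = verif,
        median_pct_concordant_seq_per_cnv = 100 * stats::median(m_cnv),
        pct_verified_cnvs = 100 * stats::median(m_ver),
        pct_verified_cum_seq = 100 * stats::median(m_seq),
        n_samples = length(shared), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.restrict_to_validated <- function(calls, records) {
  ok <- records[records$validated, , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$tool_id, d$chrom, d$start, d$end,
                           d$cn_class, sep = "\r")
  calls[key(calls) %in% key(ok), , drop = FALSE]
}

#' Multi-tool consensus call set
#'
#' Regions called with the same CN class by at least \code{k} tools, defined
#' by base-pair stacking depth: per sample and class, each tool contributes
#' its merged call track, the per-base depth is computed, and maximal runs
#' with depth >= k are emitted as consensus segments.  \code{k = 1}
#' degenerates to the union of all tools; consensus sets are nested in
#' \code{k}.
#'
#' @param calls standardized segment data.frame.
#' @param k minimum number of agreeing tools (default 3).
#' @return segment data.frame (\code{sample_id, chrom, start, end,
#'   cn_class}) with attribute \code{k}; empty with a warning when \code{k}
#'   exceeds the number of tools present.
#' @export
consensus_calls <- function(calls, k = 3) {
  .check_calls(calls)
  n_tools <- length(unique(calls$tool_id))
  empty <- data.frame(sample_id = character(), chrom = integer(),
                      start = numeric(), end = numeric(),
                      cn_class = character(), stringsAsFactors = FALSE)
  if (k > n_tools) {
    warning("k = ", k, " exceeds the ", n_tools,
            " tool(s) present; consensus is empty")
    return(structure(empty, k = k))
  }
  # one merged track per tool, so a tool counts once per base
  tkey <- paste(calls$sample_id, calls$cn_class, calls$chrom, calls$tool_id,
                sep = "\r")
  ti <- match(tkey, unique(tkey))
  sg <- ti * .KEY_OFFSET + calls$start
  eg <- ti * .KEY_OFFSET + calls$end
  ord <- order(sg)
  m <- .merge_encoded(sg[ord], eg[ord])
  first <- ord[m$first]
  track <- data.frame(sample_id = calls$sample_id[first],
                      cn_class = calls$cn_class[first],
                      chrom = calls$chrom[first],
                      start = m$ms %% .KEY_OFFSET,
                      end = m$me %% .KEY_OFFSET, stringsAsFactors = FALSE)
  gkey <- paste(track$sample_id, track$cn_class, track$chrom, sep = "\r")
  gi <- match(gkey, unique(gkey))
  runs <- .depth_runs(gi, track$start, track$end, k)
  if (!nrow(runs)) {
    out <- empty
  } else {
    gfirst <- match(unique(gkey), gkey)
    out <- data.frame(sample_id = track$sample_id[gfirst][runs$group],
                      chrom = track$chrom[gfirst][runs$group],
                      start = runs$start, end = runs$end,
                      cn_class = track$cn_class[gfirst][runs$group],
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k)
}

#' Verify calls against an external reference variant set
#'
#' Each call is verified when the union of reference segments (of the same
#' CN class when \code{class_aware}, of any class otherwise, e.g. for
#' references without gain/loss annotation) covers more than the threshold
#' fraction of it.
#'
#' @param calls standardized segment data.frame.
#' @param reference segment data.frame with \code{chrom, start, end} and,
#'   when \code{class_aware}, \code{cn_class}.
#' @param threshold required coverage fraction (default 0.9).
#' @param class_aware match CN classes (default TRUE).
#' @param comparison \code{">"} (default) or \code{">="}.
#' @return list with \code{records} (per-call coverage and verified flag)
#'   and \code{summary} (per sample and tool, \code{pct_verified}).
#' @export
verify_against_reference <- function(calls, reference, threshold = 0.9,
                                     class_aware = TRUE, comparison = ">") {
  .check_calls(calls)
  if (class_aware && !"cn_class" %in% names(reference)) {
    stop("reference lacks cn_class; use class_aware = FALSE", call. = FALSE)
  }
  if (!nrow(reference)) {
    warning("empty reference: no call can be verified")
  }
  len <- calls$end - calls$start
  frac <- .covered_width(calls, reference, class_aware = class_aware) / len
  records <- data.frame(calls, coverage_reference = frac,
                        verified = .meets(frac, threshold, comparison),
                        stringsAsFactors = FALSE)
  key <- paste(records$sample_id, records$tool_id, sep = "\r")
  summary <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(sample_id = d$sample_id[1], tool_id = d$tool_id[1],
               n_cnvs = nrow(d), n_verified = sum(d$verified),
               pct_verified = 100 * mean(d$verified),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
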