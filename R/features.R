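# Per-sample descriptive features of predicted CNVs: counts, lengths,
# cumulative length, marker density and the deletions-to-duplications ratio.

#' Per-sample CNV features
#'
#' Computes, for every (sample, tool) pair present in a standardized call
#' table, the descriptive statistics used to characterize a caller: number
#' of CNVs (and of deletions/duplications), median and cumulative segment
#' length, median markers per CNV, median inter-marker distance, and the
#' deletions-to-duplications ratio (DDR).
#'
#' The inter-marker distance of one CNV is its mean marker gap,
#' \code{length / (n_markers - 1)}; CNVs with fewer than two markers are
#' excluded from the distance median.  Marker counts come from the call
#' records, or are recomputed from \code{marker_map} when provided.  DDR is
#' \code{NA} when a sample has no duplications (rather than infinity).
#' All lengths are reported in base pairs.
#'
#' @param calls standardized segment data.frame
#'   (\code{\link{standardize_calls}}).
#' @param marker_map optional marker map; when given, \code{n_markers} is
#'   recomputed as the number of mapped markers inside each segment.
#' @return data.frame with one row per (sample, tool): \code{n_cnvs,
#'   n_deletions, n_duplications, median_length, cum_length, median_markers,
#'   median_intermarker_dist, ddr}.
#' @export
cnv_features <- function(calls, marker_map = NULL) {
  .check_calls(calls)
  if (!is.null(marker_map)) {
    calls$n_markers <- .count_markers(calls, marker_map)
  }
  if (!"n_markers" %in% names(calls)) calls$n_markers <- NA_integer_

  key <- paste(calls$sample_id, calls$tool_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(calls)), key), function(i) {
    d <- calls[i, ]
    len <- d$end - d$start
    n_del <- sum(d$cn_class == "loss")
    n_dup <- sum(d$cn_class == "gain")
    gap <- ifelse(!is.na(d$n_markers) & d$n_markers >= 2,
                  len / (d$n_markers - 1), NA_real_)
    data.frame(sample_id = d$sample_id[1], tool_id = d$tool_id[1],
               n_cnvs = nrow(d), n_deletions = n_del, n_duplications = n_dup,
               median_length = stats::median(len),
               cum_length = sum(len),
               median_markers = if (all(is.na(d$n_markers))) NA_real_
                 else stats::median(d$n_markers, na.rm = TRUE),
               median_intermarker_dist = if (all(is.na(gap))) NA_real_
                 else stats::median(gap, na.rm = TRUE),
               ddr = if (n_dup > 0) n_del / n_dup else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.count_markers <- function(calls, marker_map) {
  mm <- data.frame(chrom = marker_map$chrom, start = marker_map$position,
                   end = marker_map$position + 1,
                   cn_class = "x", stringsAsFactors = FALSE)
  q <- calls
  q$cn_class <- "x"
  as.integer(.covered_width(q, mm, class_aware = TRUE))
}

#' Summarize features over samples
#'
#' Median and inter-quartile range of each per-sample feature, per group
#' (typically per tool, optionally split further by population).  Quantiles
#' use linear interpolation between order statistics (R type 7) throughout
#' the package.
#'
#' @param features per-sample feature rows (\code{\link{cnv_features}} or any
#'   data.frame of per-sample statistics with grouping columns).
#' @param by character vector of grouping column names (default
#'   \code{"tool_id"}).
#' @return data.frame with, per group and per numeric feature, columns
#'   \code{<feature>_median}, \code{<feature>_q25}, \code{<feature>_q75}.
#' @export
summarize_features <- function(features, by = "tool_id") {
  missing_by <- setdiff(by, names(features))
  if (length(missing_by)) {
    stop("grouping column(s) not found: ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                             logical(1))], by)
  key <- do.call(paste, c(features[by], sep = "\r"))
  groups <- split(seq_len(nrow(features)), key)
  rows <- lapply(groups, function(i) {
    g <- features[i, , drop = FALSE]
    out <- g[1, by, drop = FALSE]
    out$n_samples <- length(unique(g$sample_id))
    for (cc in num_cols) {
      v <- g[[cc]]
      v <- v[!is.na(v)]
      if (!length(v)) {
        q <- c(NA_real_, NA_real_, NA_real_)
      } else {
        q <- stats::quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
      }
      out[[paste0(cc, "_median")]] <- q[1]
      out[[paste0(cc, "_q25")]] <- q[2]
      out[[paste0(cc, "_q75")]] <- q[3]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median absolute deviation per group
#'
#' Dispersion of a per-tool statistic within algorithm classes (e.g. HMM vs
#' segmentation): the median absolute deviation from the group median, with
#' a configurable consistency scaling (default 1.4826, the factor that makes
#' the MAD a consistent sigma estimate under normality; use 1 for the raw
#' MAD).
#'
#' @param values numeric vector, one entry per tool.
#' @param groups grouping labels aligned with \code{values}.
#' @param constant scaling constant passed to \code{\link[stats]{mad}}.
#' @return named numeric vector of MADs, one per group.
#' @export
group_mad <- function(values, groups, constant = 1.4826) {
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("each group needs at least 2 values (got ",
         min(tab), ")", call. = FALSE)
  }
  vapply(split(values, groups), stats::mad, numeric(1), constant = constant)
}
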