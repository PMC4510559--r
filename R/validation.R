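# Family-based in-silico validation: an offspring CNV is validated when a
# union of same-class parental segments covers more than a threshold
# fraction of it in at least one parent.

#' Coverage fraction of one segment by a set of segments
#'
#' Fraction of the target's bases covered by the union of segments in
#' \code{others} on the same chromosome and (when \code{same_class}) of the
#' same CN class.  Continuity is not required: fragmented covering segments
#' count through their union.
#'
#' @param target a one-row segment data.frame or a list/row with
#'   \code{chrom, start, end, cn_class}.
#' @param others segment data.frame.
#' @param same_class restrict covering segments to the target's CN class
#'   (default TRUE).
#' @return a fraction in [0, 1].
#' @examples
#' target <- data.frame(chrom = 1, start = 100, end = 200, cn_class = "loss")
#' others <- data.frame(chrom = 1, start = c(90, 150), end = c(150, 195),
#'                      cn_class = "loss")
#' coverage_fraction(target, others)  # 0.95
#' @export
coverage_fraction <- function(target, others, same_class = TRUE) {
  target <- as.data.frame(target, stringsAsFactors = FALSE)
  if (nrow(target) != 1L) {
    stop("target must be a single segment", call. = FALSE)
  }
  w <- .covered_width(target, others, class_aware = same_class)
  as.numeric(w / (target$end - target$start))
}

#' Validate offspring CNVs against parental call sets
#'
#' For every CNV called in a trio offspring, computes the fraction of its
#' bases covered by the union of same-class segments called in the father
#' and in the mother (each parent evaluated separately, never pooled), and
#' flags it as validated when at least one parent's coverage passes the
#' threshold.
#'
#' In \code{same_tool} mode parental calls come from the tool that made the
#' offspring call and the comparison is strict (coverage \emph{greater than}
#' the threshold).  In \code{extended} mode a parental call set from any
#' tool may validate (each (parent, tool) union evaluated separately, the
#' best taken) and the comparison is \code{>=}; this compensates
#' false-negative parental predictions by the offspring's own tool.  Both
#' comparisons can be overridden via \code{comparison}.
#'
#' @param calls standardized segment data.frame covering offspring and
#'   parents.
#' @param pedigree trio data.frame (\code{offspring_id, father_id,
#'   mother_id, population}).
#' @param threshold required coverage fraction (default 0.9).
#' @param mode \code{"same_tool"} (default) or \code{"extended"}.
#' @param comparison \code{">"} or \code{">="}; default \code{">"} for
#'   same-tool, \code{">="} for extended.
#' @return data.frame of per-CNV validation records: offspring segment
#'   fields, \code{length}, \code{coverage_father}, \code{coverage_mother},
#'   \code{coverage_best}, \code{validated}, \code{threshold}, \code{mode},
#'   \code{population}.
#' @export
validate_trios <- function(calls, pedigree, threshold = 0.9,
                           mode = c("same_tool", "extended"),
                           comparison = NULL) {
  mode <- match.arg(mode)
  if (is.null(comparison)) comparison <- if (mode == "same_tool") ">" else ">="
  .check_calls(calls)
  .check_pedigree(pedigree)

  off <- calls[calls$sample_id %in% pedigree$offspring_id, , drop = FALSE]
  father_of <- stats::setNames(pedigree$father_id, pedigree$offspring_id)
  mother_of <- stats::setNames(pedigree$mother_id, pedigree$offspring_id)
  pop_of <- stats::setNames(pedigree$population, pedigree$offspring_id)
  parents <- unique(c(pedigree$father_id, pedigree$mother_id))
  par_calls <- calls[calls$sample_id %in% parents, , drop = FALSE]

  len <- off$end - off$start
  if (mode == "same_tool") {
    cov_f <- .covered_width(
      off, par_calls,
      query_extra = paste(father_of[off$sample_id], off$tool_id),
      subject_extra = paste(par_calls$sample_id, par_calls$tool_id)) / len
    cov_m <- .covered_width(
      off, par_calls,
      query_extra = paste(mother_of[off$sample_id], off$tool_id),
      subject_extra = paste(par_calls$sample_id, par_calls$tool_id)) / len
  } else {
    cov_f <- cov_m <- rep(0, nrow(off))
    for (t in unique(par_calls$tool_id)) {
      pt <- par_calls[par_calls$tool_id == t, , drop = FALSE]
      cov_f <- pmax(cov_f, .covered_width(
        off, pt, query_extra = father_of[off$sample_id],
        subject_extra = pt$sample_id) / len)
      cov_m <- pmax(cov_m, .covered_width(
        off, pt, query_extra = mother_of[off$sample_id],
        subject_extra = pt$sample_id) / len)
    }
  }

  out <- data.frame(sample_id = off$sample_id, tool_id = off$tool_id,
                    chrom = off$chrom, start = off$start, end = off$end,
                    cn_class = off$cn_class, length = len,
                    coverage_father = cov_f, coverage_mother = cov_m,
                    coverage_best = pmax(cov_f, cov_m),
                    stringsAsFactors = FALSE)
  out$validated <- .meets(out$coverage_best, threshold, comparison)
  out$threshold <- threshold
  out$mode <- mode
  out$population <- as.character(pop_of[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Summarize validation records per sample
#'
#' Per (sample, tool): percentage of validated CNVs overall and split into
#' deletions and duplications, the DDR restricted to validated CNVs, and the
#' validated cumulative sequence (validated base pairs as a percentage of
#' all CNV base pairs of that sample).
#'
#' @param records validation records (\code{\link{validate_trios}}).
#' @return data.frame with one row per (sample, tool).
#' @export
summarize_validation <- function(records) {
  if (!nrow(records)) {
    stop("no validation records to summarize", call. = FALSE)
  }
  key <- paste(records$sample_id, records$tool_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(records)), key), function(i) {
    d <- records[i, ]
    del <- d$cn_class == "loss"
    dup <- d$cn_class == "gain"
    v <- d$validated
    data.frame(
      sample_id = d$sample_id[1], tool_id = d$tool_id[1],
      population = if ("population" %in% names(d)) d$population[1]
        else NA_character_,
      n_cnvs = nrow(d), n_validated = sum(v),
      pct_validated = 100 * mean(v),
      pct_validated_deletions = if (any(del)) 100 * mean(v[del]) else NA_real_,
      pct_validated_duplications = if (any(dup)) 100 * mean(v[dup])
        else NA_real_,
      ddr_validated = if (sum(v & dup) > 0) sum(v & del) / sum(v & dup)
        else NA_real_,
      pct_validated_sequence = 100 * sum(d$length[v]) / sum(d$length),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation rate stratified by CNV size
#'
#' Bins validation records by segment length and reports per-bin counts and
#' validated fraction.  CNVs outside the given edges fall into open-ended
#' extreme bins.
#'
#' @param records validation records.
#' @param bin_edges strictly increasing numeric vector of inner bin edges
#'   (bp).
#' @return data.frame with columns \code{bin}, \code{n}, \code{n_validated},
#'   \code{pct_validated} (NA for empty bins).
#' @export
validation_by_size <- function(records, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  edges <- c(-Inf, bin_edges, Inf)
  bin <- cut(records$length, breaks = edges, right = FALSE)
  rows <- lapply(levels(bin), function(b) {
    i <- which(bin == b)
    data.frame(bin = b, n = length(i),
               n_validated = sum(records$validated[i]),
               pct_validated = if (length(i))
                 100 * mean(records$validated[i]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
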