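# Permutation null for family-based validation: randomly reassign parent
# pairs to offspring and re-run the validation to estimate how often a CNV
# would appear "validated" by chance alone.

#' Randomly reassign parents to offspring
#'
#' Produces a permuted pedigree in which every offspring receives the parent
#' pair of another trio.  With \code{exclude_self} (default) the permutation
#' is a derangement: no offspring keeps its true parents, so true
#' inheritance cannot leak into the null.  With
#' \code{scope = "within_population"} parent pairs are only exchanged among
#' trios of the same population label.  \code{keep_pairs = FALSE} permutes
#' fathers and mothers independently instead of moving couples as units.
#'
#' @param pedigree trio data.frame.
#' @param scope \code{"pooled"} (default) or \code{"within_population"}.
#' @param keep_pairs reassign father-mother couples as units (default TRUE).
#' @param exclude_self forbid reassignment of the true parents (default
#'   TRUE).
#' @return a pedigree data.frame with permuted \code{father_id} /
#'   \code{mother_id}.
#' @export
permute_parents <- function(pedigree,
                            scope = c("pooled", "within_population"),
                            keep_pairs = TRUE, exclude_self = TRUE) {
  scope <- match.arg(scope)
  .check_pedigree(pedigree)
  out <- pedigree
  blocks <- if (scope == "pooled") {
    list(seq_len(nrow(pedigree)))
  } else {
    split(seq_len(nrow(pedigree)), pedigree$population)
  }
  for (idx in blocks) {
    if (length(idx) < 2L) {
      stop("permutation scope with fewer than 2 trios", call. = FALSE)
    }
    if (keep_pairs) {
      p <- .rand_perm(length(idx), derange = exclude_self)
      out$father_id[idx] <- pedigree$father_id[idx][p]
      out$mother_id[idx] <- pedigree$mother_id[idx][p]
    } else {
      pf <- .rand_perm(length(idx), derange = exclude_self)
      pm <- .rand_perm(length(idx), derange = exclude_self)
      out$father_id[idx] <- pedigree$father_id[idx][pf]
      out$mother_id[idx] <- pedigree$mother_id[idx][pm]
    }
  }
  out
}

# uniform random permutation of 1..n, optionally without fixed points
.rand_perm <- function(n, derange = TRUE) {
  repeat {
    p <- sample.int(n)
    if (!derange || !any(p == seq_len(n))) return(p)
  }
}

#' Pseudo-validation rate under permuted pedigrees
#'
#' Estimates the chance component of family-based validation: parents are
#' randomly reassigned to offspring (\code{\link{permute_parents}}), the
#' validation is re-run, and the per-sample validated percentage is
#' summarized per tool.  Replicated draws (default 10) give a median and
#' IQR over replicates of the per-sample median validated percentage.
#'
#' When a seed is supplied, replicate \code{i} uses \code{seed + i - 1} so
#' the replicate stream is reproducible and extensible.
#'
#' @param calls standardized segment data.frame.
#' @param pedigree trio data.frame.
#' @param n_replicates number of permutation replicates (default 10).
#' @param scope,keep_pairs,exclude_self passed to
#'   \code{\link{permute_parents}}.
#' @param threshold,mode,comparison passed to \code{\link{validate_trios}}.
#' @param seed optional integer seed.
#' @return a list of class \code{"pseudo_validation"}:
#'   \describe{
#'     \item{summary}{per tool: median and IQR over replicates of the
#'       per-sample median validated \%, plus the pooled validated fraction
#'       over all replicate evaluations.}
#'     \item{replicates}{per (replicate, tool): per-sample median \% and
#'       pooled counts.}
#'     \item{per_sample}{per (replicate, sample, tool) validated counts.}
#'   }
#' @export
pseudo_validation <- function(calls, pedigree, n_replicates = 10,
                              scope = c("pooled", "within_population"),
                              keep_pairs = TRUE, exclude_self = TRUE,
                              threshold = 0.9, mode = "same_tool",
                              comparison = NULL, seed = NULL) {
  scope <- match.arg(scope)
  per_sample <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (!is.null(seed)) set.seed(seed + r - 1L)
    ped_r <- permute_parents(pedigree, scope = scope,
                             keep_pairs = keep_pairs,
                             exclude_self = exclude_self)
    rec <- validate_trios(calls, ped_r, threshold = threshold, mode = mode,
                          comparison = comparison)
    s <- summarize_validation(rec)
    s$replicate <- r
    per_sample[[r]] <- s
  }
  per_sample <- do.call(rbind, per_sample)

  rep_key <- paste(per_sample$replicate, per_sample$tool_id, sep = "\r")
  replicates <- do.call(rbind, lapply(split(per_sample, rep_key), function(d) {
    data.frame(replicate = d$replicate[1], tool_id = d$tool_id[1],
               median_pct_validated = stats::median(d$pct_validated),
               n_cnvs = sum(d$n_cnvs), n_validated = sum(d$n_validated),
               stringsAsFactors = FALSE)
  }))
  rownames(replicates) <- NULL

  summary <- do.call(rbind, lapply(split(replicates, replicates$tool_id),
                                   function(d) {
    q <- stats::quantile(d$median_pct_validated, c(0.5, 0.25, 0.75),
                         type = 7, names = FALSE)
    data.frame(tool_id = d$tool_id[1], scope = scope,
               pct_pseudo_validated = q[1], q25 = q[2], q75 = q[3],
               pooled_fraction = sum(d$n_validated) / sum(d$n_cnvs),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  structure(list(summary = summary, replicates = replicates,
                 per_sample = per_sample),
            class = "pseudo_validation")
}

#' @export
print.pseudo_validation <- function(x, ...) {
  cat("Pseudo-validation under permuted pedigrees (",
      x$summary$n_replicates[1], " replicates, scope: ",
      x$summary$scope[1], ")\n\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
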