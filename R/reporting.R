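# Group comparisons (HMM vs segmentation, CEU vs YRI), benchmark
# orchestration and report export.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-sample values (e.g. the
#' per-sample median of an HMM-group statistic vs the segmentation group).
#' Delegates to \code{\link[stats]{wilcox.test}}: exact when the sample is
#' small and free of ties/zeros, normal approximation with continuity
#' correction otherwise.  When every pairwise difference is zero the test
#' is undefined and \code{NA} is returned with a note.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with \code{n}, \code{median_a}, \code{median_b},
#'   \code{statistic} (V, rank sum of positive differences), \code{p_value}
#'   and \code{method}.
#' @export
paired_rank_test <- function(a, b) {
  if (length(a) != length(b)) {
    stop("a and b must be paired vectors of equal length", call. = FALSE)
  }
  d <- a - b
  if (all(d == 0)) {
    return(list(n = length(a), median_a = stats::median(a),
                median_b = stats::median(b), statistic = NA_real_,
                p_value = NA_real_,
                method = "undefined: all differences are zero"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(n = length(a), median_a = stats::median(a),
       median_b = stats::median(b),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Permutation test on the between-class MAD difference
#'
#' Tests whether the dispersion (median absolute deviation) of a per-tool
#' statistic differs between two tool classes by permuting the class
#' labels.  The statistic is \code{|MAD(class A) - MAD(class B)|}.  When
#' the number of distinct label assignments is small (at most
#' \code{max_exact}; 6 tools split 3/3 give only 20) the null distribution
#' is enumerated exhaustively and the p-value is the exact fraction of
#' assignments with a statistic at least as large as observed.  Otherwise
#' \code{n_perm} random shuffles are drawn and the add-one-corrected
#' p-value \code{(#{perm >= obs} + 1) / (n_perm + 1)} is reported.
#'
#' @param values per-tool statistic.
#' @param labels two-level class labels aligned with \code{values}.
#' @param n_perm number of random permutations when sampling (default
#'   10000).
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) exhaustive
#'   enumeration; default \code{NULL} enumerates when feasible.
#' @param max_exact enumeration feasibility cap (default 10000
#'   assignments).
#' @param constant MAD scaling constant (default 1.4826).
#' @param seed optional seed for the sampling fallback.
#' @return list with \code{observed} (the MAD difference), \code{p_value},
#'   \code{method} and \code{n_assignments} or \code{n_perm}.
#' @export
label_permutation_test <- function(values, labels, n_perm = 10000,
                                   exact = NULL, max_exact = 10000,
                                   constant = 1.4826, seed = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop("labels must have exactly two levels", call. = FALSE)
  }
  n <- length(values)
  n_a <- sum(labels == lev[1])
  stat <- function(lab_a_idx) {
    abs(stats::mad(values[lab_a_idx], constant = constant) -
        stats::mad(values[-lab_a_idx], constant = constant))
  }
  obs <- stat(which(labels == lev[1]))
  if (obs == 0) {
    return(list(observed = 0, p_value = 1, method = "degenerate",
                n_assignments = NA_integer_))
  }
  n_distinct <- choose(n, n_a)
  do_exact <- if (is.null(exact)) n_distinct <= max_exact else exact
  eps <- sqrt(.Machine$double.eps)
  if (do_exact) {
    combos <- utils::combn(n, n_a)
    perm_stats <- apply(combos, 2, stat)
    p <- mean(perm_stats >= obs - eps)
    list(observed = obs, p_value = p, method = "exact enumeration",
         n_assignments = ncol(combos))
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm_stats <- replicate(n_perm, stat(sample.int(n, n_a)))
    p <- (sum(perm_stats >= obs - eps) + 1) / (n_perm + 1)
    list(observed = obs, p_value = p, method = "random permutations",
         n_perm = n_perm)
  }
}

#' Compare tool classes on a per-sample statistic
#'
#' For each sample, takes the median of a feature over the tools of each
#' class (e.g. HMM vs segmentation), then compares the two per-sample
#' vectors with the paired signed-rank test.
#'
#' @param features per-sample feature rows (\code{\link{cnv_features}} or
#'   \code{\link{summarize_validation}} output).
#' @param column name of the numeric column to compare.
#' @param tool_classes named character vector mapping tool_id to class
#'   label (two levels).
#' @return list with \code{per_sample} (sample, value per class) and
#'   \code{test} (\code{\link{paired_rank_test}} result); class medians in
#'   \code{medians}.
#' @export
compare_tool_classes <- function(features, column, tool_classes) {
  if (!column %in% names(features)) {
    stop("column '", column, "' not found", call. = FALSE)
  }
  cls <- tool_classes[features$tool_id]
  if (anyNA(cls)) {
    stop("tool(s) without a class label: ",
         paste(unique(features$tool_id[is.na(cls)]), collapse = ", "),
         call. = FALSE)
  }
  lev <- unique(tool_classes)
  if (length(lev) != 2L) {
    stop("tool_classes must define exactly two classes", call. = FALSE)
  }
  per_sample <- do.call(rbind, lapply(split(seq_len(nrow(features)),
                                            features$sample_id),
                                      function(i) {
    v <- features[[column]][i]
    g <- cls[i]
    data.frame(sample_id = features$sample_id[i[1]],
               a = stats::median(v[g == lev[1]], na.rm = TRUE),
               b = stats::median(v[g == lev[2]], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  names(per_sample)[2:3] <- lev
  keep <- stats::complete.cases(per_sample)
  test <- paired_rank_test(per_sample[[lev[1]]][keep],
                           per_sample[[lev[2]]][keep])
  list(column = column, per_sample = per_sample,
       medians = stats::setNames(c(test$median_a, test$median_b), lev),
       test = test)
}

#' Run the full trio benchmark
#'
#' Orchestrates the complete analysis on a standardized call table and a
#' trio pedigree: per-sample features, same-tool and extended family
#' validation, the permuted-pedigree pseudo-validation null (pooled and
#' within population), pairwise concordance, the multi-tool consensus set,
#' optional external-reference verification, and (when tool classes are
#' supplied) the HMM-vs-segmentation group comparisons.
#'
#' @param calls segment data.frame (standardized internally).
#' @param pedigree trio data.frame.
#' @param marker_map optional marker map for marker-density features.
#' @param tool_classes optional named vector tool_id -> class label.
#' @param threshold validation coverage threshold (default 0.9).
#' @param pseudo_replicates permutation replicates (default 10).
#' @param k_consensus consensus depth (default 3).
#' @param reference optional external reference segment data.frame.
#' @param seed optional integer seed (drives the permutation null).
#' @return object of class \code{"cnv_benchmark"}.
#' @export
cnv_benchmark <- function(calls, pedigree, marker_map = NULL,
                          tool_classes = NULL, threshold = 0.9,
                          pseudo_replicates = 10, k_consensus = 3,
                          reference = NULL, seed = NULL) {
  .check_pedigree(pedigree)
  calls <- standardize_calls(calls)
  offspring <- calls[calls$sample_id %in% pedigree$offspring_id, ,
                     drop = FALSE]

  features <- cnv_features(offspring, marker_map = marker_map)
  pop_of <- stats::setNames(pedigree$population, pedigree$offspring_id)
  features$population <- as.character(pop_of[features$sample_id])

  records_same <- validate_trios(calls, pedigree, threshold = threshold,
                                 mode = "same_tool")
  records_ext <- validate_trios(calls, pedigree, threshold = threshold,
                                mode = "extended")
  validation <- summarize_validation(records_same)
  validation_ext <- summarize_validation(records_ext)
  validated_features <- cnv_features(
    .restrict_to_validated(offspring, records_same),
    marker_map = marker_map)

  pseudo_pooled <- pseudo_validation(
    calls, pedigree, n_replicates = pseudo_replicates, scope = "pooled",
    threshold = threshold, seed = seed)
  pseudo_within <- if (all(table(pedigree$population) >= 2)) {
    pseudo_validation(
      calls, pedigree, n_replicates = pseudo_replicates,
      scope = "within_population", threshold = threshold,
      seed = if (is.null(seed)) NULL else seed + pseudo_replicates)
  } else {
    message("within-population permutation skipped: a population has ",
            "fewer than 2 trios")
    NULL
  }

  n_tools <- length(unique(calls$tool_id))
  concordance <- if (n_tools >= 2) {
    pairwise_concordance(offspring, threshold = threshold,
                         validated = records_same)
  } else {
    NULL
  }
  consensus <- consensus_calls(offspring, k = min(k_consensus, n_tools))
  ref_verification <- if (!is.null(reference)) {
    verify_against_reference(offspring, reference,
                             threshold = threshold,
                             class_aware = "cn_class" %in% names(reference))
  } else {
    NULL
  }

  group_tests <- NULL
  if (!is.null(tool_classes)) {
    group_tests <- list(
      n_cnvs = compare_tool_classes(features, "n_cnvs", tool_classes),
      pct_validated = compare_tool_classes(validation, "pct_validated",
                                           tool_classes))
  }

  structure(list(
    calls = calls, pedigree = pedigree, threshold = threshold,
    features = features,
    feature_summary = summarize_features(features),
    validation_records = records_same,
    validation = validation,
    validation_summary = summarize_features(
      validation[!vapply(validation, is.logical, logical(1))]),
    validation_extended = validation_ext,
    validated_features = validated_features,
    pseudo_validation = list(pooled = pseudo_pooled,
                             within_population = pseudo_within),
    concordance = concordance,
    consensus = consensus,
    reference_verification = ref_verification,
    group_tests = group_tests), class = "cnv_benchmark")
}

#' @export
print.cnv_benchmark <- function(x, ...) {
  n_tools <- length(unique(x$calls$tool_id))
  cat("Family-based CNV benchmark\n")
  cat("  trios: ", nrow(x$pedigree), ", tools: ", n_tools,
      ", offspring CNV calls: ", nrow(x$validation_records), "\n", sep = "")
  cat("  validation threshold: >", x$threshold * 100, "% same-class",
      " parental coverage\n\n", sep = "")
  v <- summarize_features(x$validation)
  cat("Median per-sample validated CNVs [%] per tool:\n")
  print(data.frame(tool_id = v$tool_id,
                   pct_validated = round(v$pct_validated_median, 1),
                   q25 = round(v$pct_validated_q25, 1),
                   q75 = round(v$pct_validated_q75, 1)),
        row.names = FALSE)
  cat("\nPseudo-validation (chance) [%], pooled pedigree permutation:\n")
  p <- x$pseudo_validation$pooled$summary
  print(data.frame(tool_id = p$tool_id,
                   pct_pseudo = round(p$pct_pseudo_validated, 1)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.cnv_benchmark <- function(object, ...) {
  list(features = object$feature_summary,
       validation = summarize_features(object$validation),
       pseudo_validation = lapply(object$pseudo_validation,
                                  function(p) p$summary),
       concordance = object$concordance,
       group_tests = lapply(object$group_tests, function(g)
         c(g$medians, p_value = g$test$p_value)))
}

#' Run the benchmark from a config and write report tables
#'
#' Config-driven entry point.  \code{config} is a named list (or the path
#' of a YAML file with the same structure) with either file inputs
#' (\code{calls}, \code{pedigree}, optional \code{marker_map}: paths read
#' via the package readers) or a \code{simulate} block (arguments to
#' \code{\link{simulate_study}}), plus optional \code{threshold},
#' \code{pseudo_replicates}, \code{k_consensus}, \code{seed},
#' \code{tool_classes}.  Writes tab-separated report tables
#' (\code{table1_features.tsv}, \code{table2_validation.tsv},
#' \code{table3_validated_features.tsv},
#' \code{table4_pseudovalidation.tsv}, \code{s6_concordance_counts.tsv},
#' \code{s7_concordance_sequence.tsv}, \code{consensus.bed}) and a
#' \code{manifest.tsv} into \code{out_dir}.
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if missing); \code{NULL} skips
#'   file output.
#' @return the \code{\link{cnv_benchmark}} object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  has_files <- !is.null(config$calls) && !is.null(config$pedigree)
  has_sim <- !is.null(config$simulate)
  if (!has_files && !has_sim) {
    stop("config must provide either 'calls' + 'pedigree' paths or a ",
         "'simulate' block", call. = FALSE)
  }
  if (has_files) {
    calls <- read_call_file(config$calls)
    pedigree <- read_pedigree(config$pedigree)
    marker_map <- if (!is.null(config$marker_map)) {
      read_marker_map(config$marker_map)
    } else NULL
    tool_classes <- unlist(config$tool_classes) %||% NULL
  } else {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    study <- do.call(simulate_study, sim_args)
    calls <- study$calls
    pedigree <- study$pedigree
    marker_map <- NULL
    tool_classes <- vapply(study$profiles, `[[`, character(1),
                           "algorithm_class")
    names(tool_classes) <- vapply(study$profiles, `[[`, character(1),
                                  "tool_id")
  }

  bench <- cnv_benchmark(
    calls, pedigree, marker_map = marker_map, tool_classes = tool_classes,
    threshold = config$threshold %||% 0.9,
    pseudo_replicates = config$pseudo_replicates %||% 10,
    k_consensus = config$k_consensus %||% 3,
    seed = config$seed %||% NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(d, f) {
      utils::write.table(d, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }
    files <- c(
      w(bench$feature_summary, "table1_features.tsv"),
      w(summarize_features(bench$validation), "table2_validation.tsv"),
      w(summarize_features(bench$validated_features),
        "table3_validated_features.tsv"),
      w(rbind(bench$pseudo_validation$pooled$summary,
              bench$pseudo_validation$within_population$summary),
        "table4_pseudovalidation.tsv"))
    if (!is.null(bench$concordance)) {
      files <- c(files,
        w(bench$concordance[, c("predictor", "verifier",
                                "pct_verified_cnvs")],
          "s6_concordance_counts.tsv"),
        w(bench$concordance[, c("predictor", "verifier",
                                "median_pct_concordant_seq_per_cnv",
                                "pct_verified_cum_seq")],
          "s7_concordance_sequence.tsv"))
    }
    if (nrow(bench$consensus)) {
      cons2 <- bench$consensus
      cons2$tool_id <- "consensus"
      cons2$n_markers <- NA_integer_
      write_bed(cons2, file.path(out_dir, "consensus.bed"))
      files <- c(files, "consensus.bed")
    }
    manifest <- data.frame(file = files, stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bench)
}
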