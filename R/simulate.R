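# Trio/caller simulator: CNV locus panels with population structure,
# Mendelian transmission with a small de novo component, and tool-class
# error profiles (HMM-like vs segmentation-like), so the whole benchmark is
# testable end to end without array data.

#' Autosome length model
#'
#' The 22 hg19 autosome lengths in bp, optionally scaled down for
#' desk-scale simulations.
#'
#' @param scale multiplicative factor on all lengths (default 1).
#' @return named numeric vector, names \code{"1"}..\code{"22"}.
#' @export
sim_genome <- function(scale = 1) {
  round(HG19_AUTOSOMES * scale)
}

#' Simulate a CNV locus panel
#'
#' Places \code{n_loci} non-overlapping (within class) CNV loci on the
#' autosomes, with log-normal lengths, a deletion/duplication mix targeting
#' a given DDR, and per-population allele frequencies.
#'
#' Frequencies: a base allele frequency is drawn uniformly from
#' \code{freq_range} (or fixed at \code{freq}); population-specific
#' frequencies perturb the base on the logit scale with sd
#' \code{divergence} (0 gives identical frequencies in all populations).
#'
#' @param n_loci number of loci.
#' @param populations population labels (default \code{c("CEU","YRI")}).
#' @param ddr target deletions-to-duplications ratio: each locus is a loss
#'   with probability \code{ddr/(1+ddr)} (default 4, within the 2.8--5.5
#'   range typical of SNP-array call sets).
#' @param freq optional fixed allele frequency for all loci and populations
#'   (overrides \code{freq_range}/\code{divergence}).
#' @param freq_range range of the base allele frequency (default
#'   \code{c(0.01, 0.2)}).
#' @param divergence logit-scale sd of the population perturbation
#'   (default 0.5).
#' @param genome named autosome length vector (\code{\link{sim_genome}}).
#' @param length_meanlog,length_sdlog log-normal length parameters
#'   (default meanlog \code{log(1e4)}, sdlog 1: median 10 kb).
#' @param seed optional integer seed.
#' @return data.frame of loci: \code{locus_id, chrom, start, end, cn_class}
#'   and one \code{freq_<population>} column per population; attribute
#'   \code{populations}.
#' @export
simulate_panel <- function(n_loci, populations = c("CEU", "YRI"), ddr = 4,
                           freq = NULL, freq_range = c(0.01, 0.2),
                           divergence = 0.5, genome = sim_genome(),
                           length_meanlog = log(1e4), length_sdlog = 1,
                           seed = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.integer(names(genome))
  cls <- ifelse(stats::runif(n_loci) < ddr / (1 + ddr), "loss", "gain")
  len <- pmax(100, round(stats::rlnorm(n_loci, length_meanlog,
                                       length_sdlog)))
  if (any(len >= max(genome))) {
    stop("simulated locus longer than the largest chromosome; ",
         "reduce length_sdlog or enlarge the genome", call. = FALSE)
  }
  chrom <- start <- numeric(n_loci)
  placed <- data.frame(chrom = integer(), start = numeric(),
                       end = numeric(), cn_class = character(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_loci)) {
    ok <- FALSE
    for (attempt in 1:1000) {
      ch <- sample(chroms, 1, prob = genome)
      if (genome[as.character(ch)] <= len[i]) next
      s <- floor(stats::runif(1, 0, genome[as.character(ch)] - len[i]))
      cand <- data.frame(chrom = ch, start = s, end = s + len[i],
                         cn_class = cls[i], stringsAsFactors = FALSE)
      if (.covered_width(cand, placed, class_aware = TRUE) == 0) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place locus ", i,
           " without same-class overlap; genome too small", call. = FALSE)
    }
    placed <- rbind(placed, cand)
    chrom[i] <- ch
    start[i] <- s
  }
  out <- data.frame(locus_id = sprintf("L%04d", seq_len(n_loci)),
                    chrom = as.integer(chrom), start = start,
                    end = start + len, cn_class = cls,
                    stringsAsFactors = FALSE)
  base <- if (is.null(freq)) {
    stats::runif(n_loci, freq_range[1], freq_range[2])
  } else {
    rep(freq, n_loci)
  }
  for (p in populations) {
    out[[paste0("freq_", p)]] <- if (is.null(freq) && divergence > 0) {
      stats::plogis(stats::qlogis(base) + stats::rnorm(n_loci, 0,
                                                       divergence))
    } else {
      base
    }
  }
  structure(out, populations = populations)
}

#' Simulate trio genotypes with Mendelian transmission
#'
#' Draws parental carrier copies (0/1/2 variant chromosomes) per locus from
#' the population allele frequency, transmits one chromosome per parent to
#' the offspring (each variant copy transmitted with probability 1/2), and
#' appends de novo offspring events at new genomic positions so that the
#' expected de novo fraction of offspring CNVs equals \code{de_novo_rate}.
#' De novo segments never overlap panel loci and therefore cannot be
#' validated by parental truth.
#'
#' @param panel locus panel (\code{\link{simulate_panel}}).
#' @param n_trios number of trios (default 30).
#' @param populations per-trio population labels; defaults to cycling
#'   through the panel's populations (half CEU / half YRI for the default
#'   panel).
#' @param de_novo_rate expected fraction of offspring CNVs that are de novo
#'   (default 0.01, the "up to 99\% inherited" regime; must be < 0.5).
#' @param genome autosome lengths used for de novo placement.
#' @param seed optional integer seed.
#' @return list with \code{truth} (per-sample true segments:
#'   \code{sample_id, chrom, start, end, cn_class, origin, parent,
#'   locus_id}), \code{pedigree}, and the \code{panel}.
#' @export
simulate_trios <- function(panel, n_trios = 30, populations = NULL,
                           de_novo_rate = 0.01, genome = sim_genome(),
                           seed = NULL) {
  if (de_novo_rate < 0 || de_novo_rate >= 0.5) {
    stop("de_novo_rate must be in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pops <- attr(panel, "populations")
  if (is.null(populations)) {
    populations <- rep(pops, length.out = n_trios)
  }
  stopifnot(length(populations) == n_trios)

  n_loci <- nrow(panel)
  truth <- list()
  ped <- list()
  for (t in seq_len(n_trios)) {
    fam <- sprintf("F%03d", t)
    ids <- paste0(fam, c("_off", "_fat", "_mot"))
    pop <- populations[t]
    f <- panel[[paste0("freq_", pop)]]
    fat <- stats::rbinom(n_loci, 2, f)
    mot <- stats::rbinom(n_loci, 2, f)
    tf <- stats::rbinom(n_loci, 1, fat / 2)
    tm <- stats::rbinom(n_loci, 1, mot / 2)

    seg <- function(idx, sample_id, origin, parent) {
      if (!length(idx)) return(NULL)
      data.frame(sample_id = sample_id, chrom = panel$chrom[idx],
                 start = panel$start[idx], end = panel$end[idx],
                 cn_class = panel$cn_class[idx], origin = origin,
                 parent = parent, locus_id = panel$locus_id[idx],
                 stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- seg(which(fat > 0), ids[2], "germline",
                                       NA_character_)
    truth[[length(truth) + 1L]] <- seg(which(mot > 0), ids[3], "germline",
                                       NA_character_)
    inh <- which(tf + tm > 0)
    if (length(inh)) {
      s <- seg(inh, ids[1], "inherited", NA_character_)
      s$parent <- ifelse(tf[inh] > 0 & tm[inh] > 0, "both",
                         ifelse(tf[inh] > 0, "father", "mother"))
      truth[[length(truth) + 1L]] <- s
    }
    # de novo events at fresh positions, never on panel loci
    n_dn <- if (de_novo_rate > 0 && length(inh)) {
      stats::rbinom(1, length(inh), de_novo_rate / (1 - de_novo_rate))
    } else 0L
    if (n_dn > 0) {
      dn <- .place_segments(n_dn, genome, avoid = panel,
                            meanlog = log(1e4), sdlog = 1)
      dn$sample_id <- ids[1]
      dn$cn_class <- ifelse(stats::runif(n_dn) < 0.8, "loss", "gain")
      dn$origin <- "de_novo"
      dn$parent <- NA_character_
      dn$locus_id <- NA_character_
      truth[[length(truth) + 1L]] <-
        dn[, c("sample_id", "chrom", "start", "end", "cn_class", "origin",
               "parent", "locus_id")]
    }
    ped[[t]] <- data.frame(family_id = fam, offspring_id = ids[1],
                           father_id = ids[2], mother_id = ids[3],
                           population = pop, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(), chrom = integer(),
                        start = numeric(), end = numeric(),
                        cn_class = character(), origin = character(),
                        parent = character(), locus_id = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(truth = truth, pedigree = do.call(rbind, ped), panel = panel)
}

# draw n random segments avoiding overlap with `avoid` (any class)
.place_segments <- function(n, genome, avoid, meanlog, sdlog) {
  chroms <- as.integer(names(genome))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      len <- max(100, round(stats::rlnorm(1, meanlog, sdlog)))
      ch <- sample(chroms, 1, prob = genome)
      if (genome[as.character(ch)] <= len) next
      s <- floor(stats::runif(1, 0, genome[as.character(ch)] - len))
      cand <- data.frame(chrom = ch, start = s, end = s + len,
                         cn_class = "x", stringsAsFactors = FALSE)
      if (.covered_width(cand, avoid, class_aware = FALSE) == 0) break
    }
    out[[i]] <- cand
  }
  do.call(rbind, out)
}

#' Tool error profile for the call simulator
#'
#' Bundles the error model of one simulated caller.  Two qualitative
#' archetypes are provided: \code{"hmm"} (fewer, cleaner calls: high
#' sensitivity, low false-positive rate, no fragmentation) and
#' \code{"segmentation"} (more, fragmented calls: higher false-positive
#' rate, nonzero fragmentation probability).  Defaults reproduce the
#' direction, not the magnitude, of the differences observed between real
#' HMM and segmentation callers.
#'
#' @param tool_id tool name.
#' @param class \code{"hmm"} or \code{"segmentation"}.
#' @param sensitivity per-CNV detection probability.
#' @param fp_rate_per_mb Poisson rate of false-positive calls per Mb.
#' @param jitter_sd sd (bp) of Gaussian breakpoint jitter.
#' @param fragmentation_prob probability a detected call is split in two.
#' @param fragment_gap gap (bp) inserted between fragments.
#' @param class_confusion_prob probability of flipping loss/gain.
#' @param emits_genotypes whether the tool reports integer CN genotypes.
#' @return list of class \code{"tool_profile"}.
#' @export
tool_profile <- function(tool_id, class = c("hmm", "segmentation"),
                         sensitivity = NULL, fp_rate_per_mb = NULL,
                         jitter_sd = NULL, fragmentation_prob = NULL,
                         fragment_gap = NULL, class_confusion_prob = NULL,
                         emits_genotypes = NULL) {
  class <- match.arg(class)
  def <- if (class == "hmm") {
    list(sensitivity = 0.85, fp_rate_per_mb = 0.005, jitter_sd = 500,
         fragmentation_prob = 0, fragment_gap = 0,
         class_confusion_prob = 0.01, emits_genotypes = TRUE)
  } else {
    list(sensitivity = 0.80, fp_rate_per_mb = 0.02, jitter_sd = 1000,
         fragmentation_prob = 0.3, fragment_gap = 2000,
         class_confusion_prob = 0.02, emits_genotypes = FALSE)
  }
  p <- list(tool_id = tool_id, algorithm_class = class,
            sensitivity = sensitivity %||% def$sensitivity,
            fp_rate_per_mb = fp_rate_per_mb %||% def$fp_rate_per_mb,
            jitter_sd = jitter_sd %||% def$jitter_sd,
            fragmentation_prob = fragmentation_prob %||%
              def$fragmentation_prob,
            fragment_gap = fragment_gap %||% def$fragment_gap,
            class_confusion_prob = class_confusion_prob %||%
              def$class_confusion_prob,
            emits_genotypes = emits_genotypes %||% def$emits_genotypes)
  probs <- unlist(p[c("sensitivity", "fragmentation_prob",
                      "class_confusion_prob")])
  if (any(probs < 0 | probs > 1) || p$jitter_sd < 0 ||
      p$fp_rate_per_mb < 0) {
    stop("invalid tool profile parameters", call. = FALSE)
  }
  structure(p, class = "tool_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default six-tool profile set
#'
#' Three HMM-like and three segmentation-like profiles with mild
#' within-class parameter variation, mirroring a typical six-caller
#' benchmark panel.
#'
#' @return named list of \code{\link{tool_profile}} objects.
#' @export
default_profiles <- function() {
  list(
    hmmA = tool_profile("hmmA", "hmm", sensitivity = 0.88),
    hmmB = tool_profile("hmmB", "hmm", sensitivity = 0.85),
    hmmC = tool_profile("hmmC", "hmm", sensitivity = 0.82,
                        fp_rate_per_mb = 0.008),
    segA = tool_profile("segA", "segmentation", fp_rate_per_mb = 0.015),
    segB = tool_profile("segB", "segmentation", fp_rate_per_mb = 0.02),
    segC = tool_profile("segC", "segmentation", fp_rate_per_mb = 0.025,
                        fragmentation_prob = 0.4)
  )
}

#' Simulate noisy caller output from a truth set
#'
#' Applies one tool profile to every sample in a truth set: each true CNV
#' is detected with probability \code{sensitivity}; detected calls get
#' Gaussian breakpoint jitter (clamped so start < end and within the
#' chromosome), are fragmented into two sub-segments with probability
#' \code{fragmentation_prob}, and have their class flipped with probability
#' \code{class_confusion_prob}; false positives are added as a Poisson
#' process along the genome with classes drawn from a DDR prior.
#'
#' @param truth truth segment data.frame (\code{\link{simulate_trios}}).
#' @param profile a \code{\link{tool_profile}}.
#' @param genome autosome lengths.
#' @param marker_map optional marker map; when given, \code{n_markers} is
#'   filled with the marker count inside each call.
#' @param fp_ddr DDR prior for false-positive classes (default 4).
#' @param seed optional integer seed.
#' @return raw (unstandardized) call data.frame.
#' @export
simulate_calls <- function(truth, profile, genome = sim_genome(),
                           marker_map = NULL, fp_ddr = 4, seed = NULL) {
  stopifnot(inherits(profile, "tool_profile"))
  if (!is.null(seed)) set.seed(seed)
  samples <- unique(truth$sample_id)
  total_mb <- sum(genome) / 1e6
  out <- list()
  for (sm in samples) {
    tr <- truth[truth$sample_id == sm, , drop = FALSE]
    det <- tr[stats::runif(nrow(tr)) < profile$sensitivity, , drop = FALSE]
    segs <- NULL
    if (nrow(det)) {
      s <- det$start
      e <- det$end
      if (profile$jitter_sd > 0) {
        s2 <- s + round(stats::rnorm(length(s), 0, profile$jitter_sd))
        e2 <- e + round(stats::rnorm(length(e), 0, profile$jitter_sd))
        chrlen <- genome[as.character(det$chrom)]
        s2 <- pmax(0, s2)
        e2 <- pmin(chrlen, e2)
        ok <- s2 < e2
        s <- ifelse(ok, s2, s)   # degenerate jitter: keep true breakpoints
        e <- ifelse(ok, e2, e)
      }
      cls <- det$cn_class
      flip <- stats::runif(length(cls)) < profile$class_confusion_prob
      cls[flip] <- ifelse(cls[flip] == "loss", "gain", "loss")
      segs <- data.frame(chrom = det$chrom, start = s, end = e,
                         cn_class = cls, stringsAsFactors = FALSE)
      if (profile$fragmentation_prob > 0) {
        frag <- stats::runif(nrow(segs)) < profile$fragmentation_prob &
          (segs$end - segs$start) > profile$fragment_gap + 2
        if (any(frag)) {
          f <- segs[frag, , drop = FALSE]
          g <- pmin(profile$fragment_gap, f$end - f$start - 2)
          cut1 <- f$start + floor((f$end - f$start - g) / 2)
          left <- transform(f, end = cut1)
          right <- transform(f, start = cut1 + g)
          segs <- rbind(segs[!frag, , drop = FALSE], left, right)
        }
      }
    }
    n_fp <- stats::rpois(1, profile$fp_rate_per_mb * total_mb)
    if (n_fp > 0) {
      fp <- .place_segments(n_fp, genome,
                            avoid = data.frame(chrom = integer(),
                                               start = numeric(),
                                               end = numeric()),
                            meanlog = log(1e4), sdlog = 1)
      fp$cn_class <- ifelse(stats::runif(n_fp) < fp_ddr / (1 + fp_ddr),
                            "loss", "gain")
      segs <- rbind(segs, fp[, c("chrom", "start", "end", "cn_class")])
    }
    if (is.null(segs) || !nrow(segs)) next
    segs$sample_id <- sm
    segs$tool_id <- profile$tool_id
    out[[sm]] <- segs
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) return(.empty_calls())
  calls$cn_genotype <- if (profile$emits_genotypes) {
    ifelse(calls$cn_class == "loss",
           ifelse(stats::runif(nrow(calls)) < 0.9, 1L, 0L),
           ifelse(stats::runif(nrow(calls)) < 0.8, 3L, 4L))
  } else {
    NA_integer_
  }
  calls$n_markers <- if (!is.null(marker_map)) {
    .count_markers(calls, marker_map)
  } else {
    NA_integer_
  }
  calls <- calls[, c("sample_id", "tool_id", "chrom", "start", "end",
                     "cn_class", "cn_genotype", "n_markers")]
  rownames(calls) <- NULL
  calls
}

#' Simulate a marker map
#'
#' Markers on a regular grid per chromosome (spacing in bp), emulating the
#' array's marker density at whatever scale the genome model uses.
#'
#' @param genome autosome lengths.
#' @param spacing inter-marker spacing in bp (default 700, close to the
#'   684 bp median of a 1.8M-marker array).
#' @return marker map data.frame (\code{marker_id, chrom, position}).
#' @export
simulate_marker_map <- function(genome = sim_genome(1e-3), spacing = 700) {
  pieces <- lapply(names(genome), function(ch) {
    pos <- seq(0, genome[[ch]] - 1, by = spacing)
    data.frame(marker_id = sprintf("m%s_%06d", ch, seq_along(pos)),
               chrom = as.integer(ch), position = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate a complete multi-tool trio study
#'
#' Convenience wrapper: panel + trios + one call set per tool profile,
#' standardized and bound into a single call table.
#'
#' @param n_trios,n_loci study size (defaults 30 trios, 200 loci).
#' @param profiles list of \code{\link{tool_profile}}s (default
#'   \code{\link{default_profiles}()}).
#' @param de_novo_rate passed to \code{\link{simulate_trios}}.
#' @param genome autosome lengths.
#' @param seed optional integer seed; sub-stages use derived seeds.
#' @param ... further arguments to \code{\link{simulate_panel}}.
#' @return list with \code{calls} (standardized, all tools),
#'   \code{pedigree}, \code{truth}, \code{panel}, \code{profiles}.
#' @export
simulate_study <- function(n_trios = 30, n_loci = 200,
                           profiles = default_profiles(),
                           de_novo_rate = 0.01, genome = sim_genome(),
                           seed = NULL, ...) {
  panel <- simulate_panel(n_loci, genome = genome, seed = seed, ...)
  trios <- simulate_trios(panel, n_trios = n_trios,
                          de_novo_rate = de_novo_rate, genome = genome,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  calls <- list()
  for (i in seq_along(profiles)) {
    calls[[i]] <- simulate_calls(
      trios$truth, profiles[[i]], genome = genome,
      seed = if (is.null(seed)) NULL else seed + 1L + i)
  }
  calls <- standardize_calls(do.call(rbind, calls))
  list(calls = calls, pedigree = trios$pedigree, truth = trios$truth,
       panel = panel, profiles = profiles)
}
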