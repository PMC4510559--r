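#' Collapse copy-number genotypes to copy-number classes
#'
#' HMM-based callers report integer copy-number genotypes (0--6 copies in a
#' diploid genome); segmentation callers report only the direction of change.
#' For tool comparison both are reduced to the three-state class: 0 or 1
#' copies is a \code{"loss"}, 2 copies is \code{"normal"}, 3 or more copies
#' is a \code{"gain"}.
#'
#' @param cn_genotype integer vector of copy numbers, each in 0..6.
#' @return character vector of classes (\code{"loss"}, \code{"normal"},
#'   \code{"gain"}).
#' @examples
#' collapse_genotype_to_class(c(0, 1, 2, 3, 6))
#' @export
collapse_genotype_to_class <- function(cn_genotype) {
  g <- suppressWarnings(as.numeric(cn_genotype))
  bad <- which(is.na(g) | g != round(g) | g < 0 | g > 6)
  if (length(bad)) {
    stop("invalid CN genotype '", cn_genotype[bad[1]],
         "': must be an integer in 0..6", call. = FALSE)
  }
  c("loss", "loss", "normal", "gain", "gain", "gain", "gain")[g + 1]
}

#' Read a CNV call file
#'
#' Reads a tab-separated call file into the common segment model.  The
#' segment dialect expects a header
#' \code{sample_id tool_id chrom start end cn} (optional \code{n_markers});
#' \code{cn} holds either class labels (\code{loss}/\code{normal}/\code{gain})
#' or integer CN genotypes 0--6, which are collapsed to classes via
#' \code{\link{collapse_genotype_to_class}}.  The marker dialect expects
#' \code{sample_id tool_id marker_id cn} and requires a marker map; marker
#' runs are converted to segments with \code{\link{markers_to_segments}}.
#'
#' Coordinates are 0-based half-open (BED convention).  Non-autosomal rows
#' (chrom outside 1..22) are dropped with a message, since the benchmark is
#' confined to autosomes.
#'
#' @param path file path.
#' @param dialect \code{"segment"} (default) or \code{"marker"}.
#' @param marker_map marker map data.frame (see \code{\link{read_marker_map}});
#'   required for the marker dialect.
#' @return data.frame of segments with columns \code{sample_id, tool_id,
#'   chrom, start, end, cn_class, cn_genotype, n_markers}.
#' @seealso \code{\link{standardize_calls}}, \code{\link{write_call_file}}
#' @export
read_call_file <- function(path, dialect = c("segment", "marker"),
                           marker_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  if (dialect == "marker") {
    need <- c("sample_id", "tool_id", "marker_id", "cn")
    if (!all(need %in% names(raw))) {
      stop("marker dialect requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(marker_map)) {
      stop("marker dialect requires a marker_map", call. = FALSE)
    }
    pieces <- lapply(split(raw, paste(raw$sample_id, raw$tool_id, sep = "\r")),
                     function(d) {
      seg <- markers_to_segments(
        data.frame(marker_id = d$marker_id, state = d$cn,
                   stringsAsFactors = FALSE),
        marker_map)
      if (!nrow(seg)) return(.empty_calls())
      seg$sample_id <- d$sample_id[1]
      seg$tool_id <- d$tool_id[1]
      seg
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    return(out[, c("sample_id", "tool_id", "chrom", "start", "end",
                   "cn_class", "cn_genotype", "n_markers")])
  }

  need <- c("sample_id", "tool_id", "chrom", "start", "end", "cn")
  if (!all(need %in% names(raw))) {
    stop("segment dialect requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("malformed segment at line ", bad[1] + 1L, " of ", path,
         " (need numeric start < end)", call. = FALSE)
  }

  cn <- raw$cn
  if (all(cn %in% CN_CLASSES)) {
    cn_class <- cn
    cn_genotype <- rep(NA_integer_, length(cn))
  } else if (all(grepl("^[0-9]+$", cn))) {
    cn_genotype <- as.integer(cn)
    cn_class <- collapse_genotype_to_class(cn_genotype)
  } else {
    bad_code <- setdiff(unique(cn), c(CN_CLASSES, as.character(0:6)))
    stop("unknown CN code '", bad_code[1], "' in ", path, call. = FALSE)
  }

  chrom <- suppressWarnings(as.integer(sub("^chr", "", raw$chrom)))
  autosomal <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (any(!autosomal)) {
    message("dropped ", sum(!autosomal),
            " non-autosomal row(s) from ", basename(path))
  }
  n_markers <- if ("n_markers" %in% names(raw)) {
    suppressWarnings(as.integer(raw$n_markers))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  out <- data.frame(sample_id = raw$sample_id, tool_id = raw$tool_id,
                    chrom = chrom, start = start, end = end,
                    cn_class = cn_class, cn_genotype = cn_genotype,
                    n_markers = n_markers, stringsAsFactors = FALSE)
  out <- out[autosomal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a CNV call file
#'
#' Writes segments as tab-separated text in the canonical layout read back by
#' \code{\link{read_call_file}}.
#'
#' @param calls segment data.frame.
#' @param path output path.
#' @param cn either \code{"class"} (default) or \code{"genotype"} for the
#'   \code{cn} column content.
#' @return the path, invisibly.
#' @export
write_call_file <- function(calls, path, cn = c("class", "genotype")) {
  cn <- match.arg(cn)
  .check_calls(calls)
  out <- data.frame(sample_id = calls$sample_id, tool_id = calls$tool_id,
                    chrom = calls$chrom,
                    start = format(calls$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    cn = if (cn == "class") calls$cn_class
                         else calls$cn_genotype,
                    n_markers = if ("n_markers" %in% names(calls))
                      calls$n_markers else NA_integer_,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export calls as BED6
#'
#' BED6 export of a call table: name is the CN class, score the marker count
#' (0 when unknown).  Chromosomes are written with a \code{chr} prefix.
#'
#' @inheritParams write_call_file
#' @return the path, invisibly.
#' @export
write_bed <- function(calls, path) {
  .check_calls(calls)
  score <- if ("n_markers" %in% names(calls)) calls$n_markers else NA
  score[is.na(score)] <- 0
  out <- data.frame(chrom = paste0("chr", calls$chrom),
                    start = format(calls$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    name = calls$cn_class, score = score, strand = ".",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a marker map
#'
#' Tab-separated file with header \code{marker_id chrom position} mapping
#' array markers to autosomal base-pair positions.  Positions are sorted
#' within chromosome; marker ids must be unique.
#'
#' @param path file path.
#' @return data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{position}, sorted by (chrom, position).
#' @export
read_marker_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "position")
  if (!all(need %in% names(m))) {
    stop("marker map requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$marker_id)) {
    stop("duplicated marker id in ", path, call. = FALSE)
  }
  m$chrom <- as.integer(sub("^chr", "", m$chrom))
  m$position <- as.numeric(m$position)
  m <- m[order(m$chrom, m$position), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Read a PED-style pedigree into trios
#'
#' Whitespace-separated PED layout
#' \code{family individual father mother sex population}: rows with both
#' parental ids present (not \code{"0"}) define trio offspring.  The sixth
#' column (the PED phenotype slot) carries the population label.
#'
#' @param path file path.
#' @return data.frame of trios: \code{family_id, offspring_id, father_id,
#'   mother_id, population}.
#' @export
read_pedigree <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(p) < 6) {
    stop("pedigree requires 6 columns: family individual father mother ",
         "sex population", call. = FALSE)
  }
  names(p)[1:6] <- c("family_id", "individual", "father", "mother",
                     "sex", "population")
  off <- p$father != "0" & p$mother != "0"
  ped <- data.frame(family_id = p$family_id[off],
                    offspring_id = p$individual[off],
                    father_id = p$father[off],
                    mother_id = p$mother[off],
                    population = as.character(p$population[off]),
                    stringsAsFactors = FALSE)
  .check_pedigree(ped)
  ped
}

#' Write a trio pedigree in PED layout
#'
#' @param pedigree trio data.frame as returned by \code{\link{read_pedigree}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  .check_pedigree(pedigree)
  rows <- lapply(seq_len(nrow(pedigree)), function(i) {
    tr <- pedigree[i, ]
    rbind(
      data.frame(family_id = tr$family_id, individual = tr$father_id,
                 father = "0", mother = "0", sex = 1,
                 population = tr$population, stringsAsFactors = FALSE),
      data.frame(family_id = tr$family_id, individual = tr$mother_id,
                 father = "0", mother = "0", sex = 2,
                 population = tr$population, stringsAsFactors = FALSE),
      data.frame(family_id = tr$family_id, individual = tr$offspring_id,
                 father = tr$father_id, mother = tr$mother_id, sex = 0,
                 population = tr$population, stringsAsFactors = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.check_pedigree <- function(pedigree) {
  need <- c("offspring_id", "father_id", "mother_id", "population")
  if (!is.data.frame(pedigree) || !all(need %in% names(pedigree))) {
    stop("pedigree must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pedigree$offspring_id)) {
    stop("an individual appears more than once as offspring", call. = FALSE)
  }
  same <- pedigree$offspring_id == pedigree$father_id |
    pedigree$offspring_id == pedigree$mother_id |
    pedigree$father_id == pedigree$mother_id
  if (any(same)) {
    stop("trio with non-distinct ids: offspring ",
         pedigree$offspring_id[which(same)[1]], call. = FALSE)
  }
  invisible(pedigree)
}

#' Convert marker-level caller output to segments
#'
#' Some callers emit one CN state per marker rather than segments.  Maximal
#' runs of consecutive markers (in map order, per chromosome) sharing one
#' non-normal state become a single segment spanning the first marker
#' position to the last marker position + 1, with \code{n_markers} set to the
#' run length.  Runs never cross a chromosome boundary or an intervening
#' marker of a different state.
#'
#' @param marker_states data.frame with columns \code{marker_id} and
#'   \code{state} (class labels or integer CN genotypes 0--6).
#' @param marker_map marker map data.frame (\code{\link{read_marker_map}}).
#' @return segment data.frame (no provenance columns; the caller attaches
#'   \code{sample_id}/\code{tool_id}).
#' @export
markers_to_segments <- function(marker_states, marker_map) {
  if (!all(c("marker_id", "state") %in% names(marker_states))) {
    stop("marker_states requires columns marker_id, state", call. = FALSE)
  }
  idx <- match(marker_states$marker_id, marker_map$marker_id)
  if (anyNA(idx)) {
    stop("unknown marker id '",
         marker_states$marker_id[which(is.na(idx))[1]], "'", call. = FALSE)
  }
  st <- marker_states$state
  if (all(st %in% CN_CLASSES)) {
    cls <- st
    gt <- rep(NA_integer_, length(st))
  } else {
    gt <- suppressWarnings(as.integer(st))
    cls <- collapse_genotype_to_class(st)
  }
  d <- data.frame(chrom = marker_map$chrom[idx],
                  position = marker_map$position[idx],
                  cn_class = cls, cn_genotype = gt,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$position), , drop = FALSE]

  # run boundaries: state change or chromosome change
  n <- nrow(d)
  if (n == 0L) return(.empty_calls()[, -(1:2)])
  new_run <- c(TRUE, d$cn_class[-1] != d$cn_class[-n] |
                 d$chrom[-1] != d$chrom[-n])
  run_id <- cumsum(new_run)
  keep <- d$cn_class != "normal"
  segs <- lapply(split(which(keep), run_id[keep]), function(i) {
    data.frame(chrom = d$chrom[i[1]],
               start = d$position[i[1]],
               end = d$position[i[length(i)]] + 1,
               cn_class = d$cn_class[i[1]],
               cn_genotype = if (length(unique(d$cn_genotype[i])) == 1L)
                 d$cn_genotype[i[1]] else NA_integer_,
               n_markers = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(chrom = integer(), start = numeric(), end = numeric(),
                      cn_class = character(), cn_genotype = integer(),
                      n_markers = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Standardize a call table
#'
#' Brings heterogeneous caller output onto the common footing used by every
#' downstream comparison: normal-class segments are dropped (a CNV is a gain
#' or a loss), non-autosomal rows are removed, and overlapping or book-ended
#' same-class segments from the same (sample, tool) are merged into their
#' union.  Segments shorter than 1 kb are retained.  The operation is
#' idempotent and never increases the covered base pairs of a class.
#'
#' @param calls segment data.frame.
#' @return standardized segment data.frame sorted by (sample, tool, chrom,
#'   start); \code{n_markers} of merged segments is the sum over the merged
#'   parts (NA if any part is unknown), \code{cn_genotype} is kept only when
#'   constant across the merged parts.
#' @export
standardize_calls <- function(calls) {
  if (!nrow(calls)) return(.empty_calls())
  if (!"cn_class" %in% names(calls) && "cn_genotype" %in% names(calls)) {
    calls$cn_class <- collapse_genotype_to_class(calls$cn_genotype)
  }
  .check_calls(calls)
  if (!"cn_genotype" %in% names(calls)) calls$cn_genotype <- NA_integer_
  if (!"n_markers" %in% names(calls)) calls$n_markers <- NA_integer_

  calls$chrom <- as.integer(calls$chrom)
  keep <- !is.na(calls$chrom) & calls$chrom >= 1L & calls$chrom <= 22L &
    calls$cn_class != "normal"
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(calls)) return(.empty_calls())

  key <- paste(calls$sample_id, calls$tool_id, calls$chrom, calls$cn_class,
               sep = "\r")
  ki <- match(key, unique(key))
  sg <- ki * .KEY_OFFSET + calls$start
  eg <- ki * .KEY_OFFSET + calls$end
  ord <- order(sg, eg)
  m <- .merge_encoded(sg[ord], eg[ord])
  first <- ord[m$first]          # original row starting each merged run

  nm <- calls$n_markers[ord]
  nm_merged <- as.integer(rowsum(as.numeric(nm), m$run_id)[, 1])
  gt <- calls$cn_genotype[ord]
  gt_first <- gt[m$first][m$run_id]
  gt_varies <- rowsum(as.numeric(gt != gt_first), m$run_id)[, 1]
  gt_merged <- ifelse(!is.na(gt_varies) & gt_varies == 0,
                      gt[m$first], NA_integer_)

  out <- data.frame(sample_id = calls$sample_id[first],
                    tool_id = calls$tool_id[first],
                    chrom = calls$chrom[first],
                    start = m$ms %% .KEY_OFFSET,
                    end = m$me %% .KEY_OFFSET,
                    cn_class = calls$cn_class[first],
                    cn_genotype = as.integer(gt_merged),
                    n_markers = nm_merged,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$tool_id, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
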