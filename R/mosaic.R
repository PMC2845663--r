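#' Per-marker identity profile of a genotype pair
#'
#' Classifies every marker of a pair of genotypes as \code{identical}
#' (equal called homozygous dosages), \code{divergent} (opposite
#' homozygotes), \code{het_involved} (either genotype heterozygous) or
#' \code{missing} (either call missing). The classification is symmetric
#' in the pair.
#'
#' @param g1,g2 dosage vectors on the same marker map.
#' @param map the \code{\link{marker_map}}.
#' @return data.frame of class \code{pairwise_profile}: marker_id, chrom,
#'   pos, status.
#' @export
pairwise_profile <- function(g1, g2, map) {
  if (length(g1) != nrow(map) || length(g2) != nrow(map)) {
    stop("genotype length does not match the marker map")
  }
  status <- rep("missing", nrow(map))
  called <- !is.na(g1) & !is.na(g2)
  het <- called & (g1 == 1L | g2 == 1L)
  status[het] <- "het_involved"
  hom <- called & !het
  status[hom & g1 == g2] <- "identical"
  status[hom & g1 != g2] <- "divergent"
  out <- data.frame(
    marker_id = map$marker_id, chrom = map$chrom, pos = map$pos,
    status = status, stringsAsFactors = FALSE
  )
  class(out) <- c("pairwise_profile", "data.frame")
  out
}

# iterative minimum-run smoothing of an informative state sequence:
# repeatedly flip the shortest run below min_run (ties: leftmost) to the
# state of its longer flanking run (ties: left flank)
smooth_runs <- function(states, min_run) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) return(states)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(states)
    k <- short[which.min(r$lengths[short])]
    left_len <- if (k > 1L) r$lengths[k - 1L] else -1L
    right_len <- if (k < length(r$lengths)) r$lengths[k + 1L] else -1L
    new_state <- if (left_len >= right_len) r$values[k - 1L] else r$values[k + 1L]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    states[starts[k]:ends[k]] <- new_state
  }
}

#' Segment a pairwise profile into identity/divergence mosaic blocks
#'
#' Markers with \code{identical} or \code{divergent} status are the
#' informative markers; heterozygous-involved and missing markers are
#' neutral and never break a run. Informative runs shorter than
#' \code{min_run} are merged into the flanking state (longer flank wins,
#' left flank on ties). Blocks tile each chromosome: each block runs from
#' just after the previous block's last informative marker to its own last
#' informative marker, and the last block extends to the chromosome end.
#'
#' @param profile a \code{\link{pairwise_profile}}.
#' @param min_run minimum informative markers per block (default 5);
#'   \code{min_run = 1} reproduces the raw state sequence losslessly.
#' @return data.frame of class \code{mosaic_blocks}: chrom, start_idx,
#'   end_idx (0-based inclusive indices in genome-wide marker order),
#'   start_bp, end_bp, state, n_markers (informative markers), flagged
#'   (TRUE for chromosomes with fewer than min_run informative markers).
#' @export
segment_blocks <- function(profile, min_run = 5) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    rows <- which(profile$chrom == ch)
    st <- profile$status[rows]
    inf_local <- which(st %in% c("identical", "divergent"))
    states <- ifelse(st[inf_local] == "identical", "identity", "divergence")
    if (length(inf_local) < min_run) {
      maj <- if (!length(states)) NA_character_
      else names(sort(table(states), decreasing = TRUE))[1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_idx = rows[1] - 1L, end_idx = rows[length(rows)] - 1L,
        start_bp = profile$pos[rows[1]], end_bp = profile$pos[rows[length(rows)]],
        state = maj, n_markers = length(inf_local), flagged = TRUE,
        stringsAsFactors = FALSE
      )
      next
    }
    states <- smooth_runs(states, min_run)
    r <- rle(states)
    ends_inf <- cumsum(r$lengths)
    starts_inf <- ends_inf - r$lengths + 1L
    prev_end_local <- 0L
    for (k in seq_along(r$lengths)) {
      start_local <- prev_end_local + 1L
      end_local <- if (k == length(r$lengths)) length(rows)
      else inf_local[ends_inf[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_idx = rows[start_local] - 1L, end_idx = rows[end_local] - 1L,
        start_bp = profile$pos[rows[start_local]], end_bp = profile$pos[rows[end_local]],
        state = r$values[k], n_markers = r$lengths[k], flagged = FALSE,
        stringsAsFactors = FALSE
      )
      prev_end_local <- end_local
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mosaic_blocks", "data.frame")
  res
}

#' Detect stretches of linked heterozygous markers in one genotype
#'
#' Scans each chromosome for maximal runs of dosage-1 calls, allowing up
#' to \code{max_interrupt} called non-heterozygous markers inside a run;
#' missing calls are neutral. Runs begin and end on heterozygous markers
#' and must contain at least \code{min_run} of them.
#'
#' @param calls dosage vector of one sample.
#' @param map the \code{\link{marker_map}}.
#' @param min_run minimum heterozygous markers per stretch (default 3).
#' @param max_interrupt tolerated called homozygous markers inside a
#'   stretch (default 1).
#' @return data.frame of class \code{het_stretches}: chrom, start_idx,
#'   end_idx (0-based, genome-wide order), start_bp, end_bp, n_het.
#'   Attribute \code{het_fraction} is the genome-wide fraction of called
#'   markers that are heterozygous.
#' @export
detect_het_stretches <- function(calls, map, min_run = 3, max_interrupt = 1) {
  stopifnot(length(calls) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    called <- rows[!is.na(calls[rows])]
    if (!length(called)) next
    runs <- list()
    start <- last_het <- NA_integer_
    n_het <- 0L; pend <- 0L
    close_run <- function() {
      if (!is.na(start) && n_het >= min_run) {
        runs[[length(runs) + 1L]] <<- c(start, last_het, n_het)
      }
    }
    for (i in called) {
      if (calls[i] == 1L) {
        if (is.na(start)) { start <- i; n_het <- 0L }
        last_het <- i; n_het <- n_het + 1L; pend <- 0L
      } else if (!is.na(start)) {
        pend <- pend + 1L
        if (pend > max_interrupt) {
          close_run()
          start <- last_het <- NA_integer_; n_het <- 0L; pend <- 0L
        }
      }
    }
    close_run()
    for (r in runs) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_idx = r[1] - 1L, end_idx = r[2] - 1L,
        start_bp = map$pos[r[1]], end_bp = map$pos[r[2]], n_het = r[3]
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = integer(0), start_idx = integer(0), end_idx = integer(0),
    start_bp = integer(0), end_bp = integer(0), n_het = integer(0)
  )
  rownames(res) <- NULL
  attr(res, "het_fraction") <- mean(calls == 1L, na.rm = TRUE)
  class(res) <- c("het_stretches", "data.frame")
  res
}

#' Assign putative parents to a candidate first-generation outcross
#'
#' Searches all pairs of fully homozygous candidate MLGs for the pair
#' maximising the fraction of their differentiating markers (opposite
#' homozygotes, both called) at which the child is heterozygous; ties go
#' to the pair with more differentiating markers, then to lexicographic
#' MLG ids. The verdict is \code{first_generation} when that fraction
#' reaches \code{threshold} and the child is homozygous-and-matching at
#' the markers where the two parents agree; \code{none} when the child is
#' itself compatible with a candidate MLG (a self-descendant) or no pair
#' differs anywhere; otherwise \code{later_generation_or_recombinant}.
#' Missing child calls are neutral and drop out of the fraction.
#'
#' @param child dosage vector of the individual to classify.
#' @param candidates matrix of candidate parent MLG call vectors (rows,
#'   with rownames as MLG ids), or an \code{mlg_table} from
#'   \code{\link{identify_mlgs}} (its fully homozygous MLGs are used).
#' @param threshold minimum heterozygous fraction for a first-generation
#'   call (default 1.0, i.e. heterozygous at every differentiating marker).
#' @return list of class \code{f1_call}: parents (two MLG ids or NULL),
#'   n_differentiating, fraction_het, verdict.
#' @export
assign_f1_parents <- function(child, candidates, threshold = 1.0) {
  if (inherits(candidates, "mlg_table")) {
    hom <- rowSums(candidates$mlg_calls == 1L, na.rm = TRUE) == 0L
    candidates <- candidates$mlg_calls[hom, , drop = FALSE]
  }
  candidates <- as.matrix(candidates)
  if (is.null(rownames(candidates))) {
    rownames(candidates) <- paste0("cand", seq_len(nrow(candidates)))
  }
  hom_ok <- rowSums(candidates == 1L, na.rm = TRUE) == 0L
  candidates <- candidates[hom_ok, , drop = FALSE]
  if (nrow(candidates) < 2L) stop("need at least 2 homozygous candidate MLGs")

  compatible_with <- vapply(seq_len(nrow(candidates)), function(i) {
    both <- !is.na(child) & !is.na(candidates[i, ])
    !any(child[both] != candidates[i, both])
  }, logical(1))

  ids <- rownames(candidates)
  best <- NULL
  for (i in seq_len(nrow(candidates) - 1L)) {
    for (j in seq(i + 1L, nrow(candidates))) {
      p1 <- candidates[i, ]; p2 <- candidates[j, ]
      diff <- which(!is.na(p1) & !is.na(p2) & p1 != p2)
      child_called <- diff[!is.na(child[diff])]
      if (!length(child_called)) next
      frac <- mean(child[child_called] == 1L)
      cand <- list(i = i, j = j, k = length(child_called), frac = frac)
      if (is.null(best) ||
        frac > best$frac ||
        (frac == best$frac && cand$k > best$k) ||
        (frac == best$frac && cand$k == best$k &&
          paste(sort(ids[c(i, j)]), collapse = "|") <
            paste(sort(ids[c(best$i, best$j)]), collapse = "|"))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(parents = NULL, n_differentiating = 0L,
      fraction_het = NA_real_, verdict = "none"), class = "f1_call"))
  }
  if (any(compatible_with)) {
    return(structure(list(parents = sort(ids[c(best$i, best$j)]),
      n_differentiating = best$k, fraction_het = best$frac,
      verdict = "none"), class = "f1_call"))
  }
  p1 <- candidates[best$i, ]; p2 <- candidates[best$j, ]
  agree <- which(!is.na(p1) & !is.na(p2) & p1 == p2 & !is.na(child))
  matches_elsewhere <- all(child[agree] == p1[agree])
  verdict <- if (best$frac >= threshold && matches_elsewhere) {
    "first_generation"
  } else "later_generation_or_recombinant"
  structure(list(
    parents = sort(ids[c(best$i, best$j)]),
    n_differentiating = best$k, fraction_het = best$frac, verdict = verdict
  ), class = "f1_call")
}

# founder-origin painting of one genotype at the differentiating markers
# of a founder pair; returns labels "A"/"B"/"U" (unexplained) /NA (missing)
paint_against <- function(g, pA, pB, diff_idx) {
  lab <- rep(NA_character_, length(diff_idx))
  gd <- g[diff_idx]
  lab[!is.na(gd) & gd == pA[diff_idx]] <- "A"
  lab[!is.na(gd) & gd == pB[diff_idx]] <- "B"
  lab[!is.na(gd) & gd != pA[diff_idx] & gd != pB[diff_idx]] <- "U"
  lab
}

# minimum number of A/B switches along each chromosome, ignoring U/NA
count_breakpoints <- function(lab, chrom) {
  total <- 0L
  for (ch in unique(chrom)) {
    s <- lab[chrom == ch]
    s <- s[!is.na(s) & s != "U"]
    if (length(s) > 1L) total <- total + sum(s[-1] != s[-length(s)])
  }
  total
}

#' Reconstruct a natural recombinant-inbred stand from two founders
#'
#' Given the distinct fully homozygous MLGs of a stand, searches all pairs
#' of them as candidate ancestral founders. For each pair, every MLG is
#' painted by founder origin at the pair's differentiating markers;
#' markers matching neither founder are unexplained. Breakpoints are
#' counted as founder-origin switches along the marker order per
#' chromosome (the minimum possible, since origin is determined at every
#' explained marker). The best pair maximises the number of
#' differentiating markers (a recombinant of the true founders always
#' differs from each of them at fewer markers than they differ from each
#' other), then minimises total unexplained markers, then total
#' breakpoints, then lexicographic founder ids.
#'
#' @param mlg_calls matrix of the stand's distinct MLG call vectors (rows,
#'   rownames = MLG ids), or an \code{mlg_table}. Candidate founders are
#'   the fully homozygous MLGs (at least 3 distinct ones are required);
#'   every supplied MLG is painted, so residually heterozygous genotypes
#'   accumulate unexplained markers where they match neither founder.
#' @param map the \code{\link{marker_map}}.
#' @return list of class \code{ril_reconstruction}: founders (ids),
#'   diff_idx (0-based marker indices where founders differ), painting
#'   (MLG x differentiating-marker label matrix), breakpoints and
#'   unexplained per MLG.
#' @export
reconstruct_ril <- function(mlg_calls, map) {
  if (inherits(mlg_calls, "mlg_table")) mlg_calls <- mlg_calls$mlg_calls
  mlg_calls <- as.matrix(mlg_calls)
  if (is.null(rownames(mlg_calls))) {
    rownames(mlg_calls) <- paste0("mlg", seq_len(nrow(mlg_calls)))
  }
  all_ids <- rownames(mlg_calls)
  hom <- rowSums(mlg_calls == 1L, na.rm = TRUE) == 0L
  H <- mlg_calls[hom, , drop = FALSE]
  distinct <- !duplicated(apply(H, 1, paste, collapse = ","))
  H <- H[distinct, , drop = FALSE]
  if (nrow(H) < 3L) stop("need at least 3 distinct fully homozygous MLGs")
  ids <- rownames(H)
  best <- NULL
  for (i in seq_len(nrow(H) - 1L)) {
    for (j in seq(i + 1L, nrow(H))) {
      pA <- H[i, ]; pB <- H[j, ]
      diff_idx <- which(!is.na(pA) & !is.na(pB) & pA != pB)
      if (!length(diff_idx)) next
      paint <- matrix(NA_character_, nrow(mlg_calls), length(diff_idx),
        dimnames = list(all_ids, map$marker_id[diff_idx]))
      for (r in seq_len(nrow(mlg_calls))) {
        paint[r, ] <- paint_against(mlg_calls[r, ], pA, pB, diff_idx)
      }
      unexpl <- rowSums(paint == "U", na.rm = TRUE)
      bp <- vapply(seq_len(nrow(mlg_calls)), function(r) {
        count_breakpoints(paint[r, ], map$chrom[diff_idx])
      }, integer(1))
      cand <- list(i = i, j = j, diff_idx = diff_idx, paint = paint,
        unexpl = unexpl, bp = bp,
        score = c(-length(diff_idx), sum(unexpl), sum(bp)))
      better <- is.null(best)
      if (!better) {
        for (k in 1:3) {
          if (cand$score[k] < best$score[k]) { better <- TRUE; break }
          if (cand$score[k] > best$score[k]) break
        }
        if (!better && all(cand$score == best$score) &&
          paste(sort(ids[c(i, j)]), collapse = "|") <
            paste(sort(ids[c(best$i, best$j)]), collapse = "|")) {
          better <- TRUE
        }
      }
      if (better) best <- cand
    }
  }
  if (is.null(best)) stop("no candidate founder pair differs at any marker")
  structure(list(
    founders = ids[c(best$i, best$j)],
    diff_idx = best$diff_idx - 1L,
    painting = best$paint,
    breakpoints = stats::setNames(best$bp, all_ids),
    unexplained = stats::setNames(best$unexpl, all_ids)
  ), class = "ril_reconstruction")
}

#' Export mosaic blocks as BED intervals
#'
#' Writes 0-based half-open bp intervals (chrom, start, end, state) for
#' genome-browser viewing.
#'
#' @param blocks a \code{\link{segment_blocks}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(
    chrom = paste0("chr", blocks$chrom),
    start = blocks$start_bp - 1L,
    end = blocks$end_bp,
    name = blocks$state
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
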