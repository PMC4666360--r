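# Candidate non-reference Alu loci from discordant read pairs: one mate
# anchored uniquely on the reference, the other matching an Alu consensus
# (or a reference Alu copy); clustering of forward/reverse anchors plus
# soft-clip evidence, a read-depth cap, and exclusion of calls near
# annotated reference Alus.

#' Find Alu-supporting discordant read pairs
#'
#' Returns pairs where exactly one read maps with
#' `MAPQ >= anchor_mapq_min` and its mate either locally aligns to an Alu
#' consensus with at least `min_match` matched bases at `min_identity`
#' identity (either orientation), or maps inside a reference-catalog Alu
#' interval.  Properly paired concordant reads are excluded.
#'
#' @param alignments coordinate-sorted `"alignments"` table
#' @param alu_library named character vector of Alu consensus sequences
#' @param reference_catalog optional `repeat_catalog` of reference Alus
#' @param anchor_mapq_min minimum anchor mapping quality (default 20)
#' @param min_match,min_identity mate-vs-consensus local alignment
#'   thresholds (defaults 30 bp, 0.90)
#' @return data.frame of anchored pairs
#' @export
find_discordant_pairs <- function(alignments, alu_library,
                                  reference_catalog = NULL,
                                  anchor_mapq_min = 20L, min_match = 30L,
                                  min_identity = 0.90) {
  stopifnot(length(alu_library) > 0)
  check_sorted(alignments)
  a <- alignments
  key <- paste0(a$qname, "/", a$mate)
  mkey <- paste0(a$qname, "/", 3L - a$mate)
  midx <- match(mkey, key)
  ok_anchor <- a$mapped & a$mapq >= anchor_mapq_min & !a$proper
  mate_is_anchor <- a$mapped[midx] & a$mapq[midx] >= anchor_mapq_min
  cand <- which(ok_anchor & !is.na(midx) & !mate_is_anchor)
  if (length(cand) == 0L) return(empty_anchored_pairs())
  mate <- a[midx[cand], , drop = FALSE]
  # (b) mate maps inside a reference Alu interval
  ev_catalog <- rep(FALSE, length(cand))
  if (!is.null(reference_catalog) && nrow(reference_catalog)) {
    mp <- !is.na(mate$pos)
    ev_catalog[mp] <- in_mask(mate$chrom[mp], mate$pos[mp],
                              reference_catalog)
  }
  # (a) mate aligns locally to an Alu consensus
  hit <- alu_hits(mate$seq, alu_library, min_match, min_identity)
  keep <- ev_catalog | hit$pass
  if (!any(keep)) return(empty_anchored_pairs())
  anc <- a[cand[keep], , drop = FALSE]
  mt <- mate[keep, , drop = FALSE]
  anchor_end <- anc$pos + cigar_ref_span(anc$cigar)
  data.frame(qname = anc$qname, chrom = anc$chrom, anchor_pos = anc$pos,
             anchor_end = anchor_end, anchor_strand = anc$strand,
             mapq = anc$mapq, mate_seq = mt$seq,
             alu_target = hit$target[keep], alu_match = hit$match[keep],
             alu_identity = hit$identity[keep],
             evidence = ifelse(hit$pass[keep], "library", "catalog"),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_anchored_pairs <- function() {
  data.frame(qname = character(), chrom = character(),
             anchor_pos = integer(), anchor_end = integer(),
             anchor_strand = character(), mapq = integer(),
             mate_seq = character(), alu_target = character(),
             alu_match = integer(), alu_identity = numeric(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' @keywords internal
check_sorted <- function(alignments) {
  m <- alignments[alignments$mapped, , drop = FALSE]
  for (cn in unique(m$chrom)) {
    p <- m$pos[m$chrom == cn]
    if (is.unsorted(p))
      stop("alignments are not coordinate-sorted; sort by (chrom, pos) ",
           "before discovery")
  }
  invisible(TRUE)
}

# best local alignment of each sequence (both orientations) against the
# consensus library; delegates to Biostrings
#' @keywords internal
alu_hits <- function(seqs, alu_library, min_match = 30L,
                     min_identity = 0.90) {
  n <- length(seqs)
  best_match <- integer(n); best_id <- numeric(n)
  best_target <- rep(NA_character_, n)
  best_start <- integer(n); best_end <- integer(n)
  best_sub_start <- integer(n); best_sub_end <- integer(n)
  best_strand <- rep("+", n)
  if (n == 0L)
    return(list(pass = logical(0), target = character(0),
                match = integer(0), identity = numeric(0),
                start = integer(0), end = integer(0), strand = character(0),
                sub_start = integer(0), sub_end = integer(0)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (ori in c("+", "-")) {
    qs <- if (ori == "+") seqs else revcomp(seqs)
    pat <- Biostrings::DNAStringSet(qs)
    for (target in names(alu_library)) {
      aln <- Biostrings::pairwiseAlignment(
        pat, alu_library[[target]], type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      nm <- Biostrings::nmatch(aln)
      len <- nm + Biostrings::nmismatch(aln)
      id <- ifelse(len > 0, nm / len, 0)
      better <- nm > best_match
      if (any(better)) {
        best_match[better] <- nm[better]
        best_id[better] <- id[better]
        best_target[better] <- target
        rng <- IRanges_of(aln)
        srng <- subject_range_of(aln)
        if (ori == "+") {
          best_start[better] <- rng$start[better] - 1L
          best_end[better] <- rng$end[better]
        } else {
          L <- nchar(seqs)
          best_start[better] <- L[better] - rng$end[better]
          best_end[better] <- L[better] - rng$start[better] + 1L
        }
        best_sub_start[better] <- srng$start[better]
        best_sub_end[better] <- srng$end[better]
        best_strand[better] <- ori
      }
    }
  }
  list(pass = best_match >= min_match & best_id >= min_identity,
       target = best_target, match = best_match, identity = best_id,
       start = best_start, end = best_end, strand = best_strand,
       sub_start = best_sub_start, sub_end = best_sub_end)
}

#' @keywords internal
IRanges_of <- function(aln) {
  r <- Biostrings::pattern(aln)
  list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
}

#' @keywords internal
subject_range_of <- function(aln) {
  r <- Biostrings::subject(aln)
  list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
}

# reference span consumed by a CIGAR (M/D/N/=/X); fast path for the
# ubiquitous "<n>M" and "<n>M<n>S"/"<n>S<n>M" forms
#' @keywords internal
cigar_ref_span <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  clip <- is.na(out) & grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cigar)
  if (any(clip))
    out[clip] <- as.integer(sub("^.*?([0-9]+)M.*$", "\\1", cigar[clip]))
  rest <- which(is.na(out))
  if (length(rest)) out[rest] <- vapply(cigar[rest], function(cg) {
    if (cg == "*") return(0L)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Extract qualifying soft-clipped reads
#'
#' Terminal soft clips of at least `min_clip` bases whose mean clipped base
#' quality is at least `min_qual`.  The clip position is the reference
#' coordinate of the junction: the alignment end for right clips, the
#' alignment start for left clips.
#'
#' @param alignments an `"alignments"` table
#' @param min_clip minimum clip length (default 20)
#' @param min_qual minimum mean clipped-base quality (default 20)
#' @return data.frame with `qname`, `chrom`, `clip_pos`, `side`, `len`,
#'   `mean_qual`
#' @export
extract_soft_clips <- function(alignments, min_clip = 20L, min_qual = 20) {
  a <- alignments[alignments$mapped & grepl("S", alignments$cigar,
                                            fixed = TRUE), , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(qname = character(), chrom = character(),
                      clip_pos = integer(), side = character(),
                      len = integer(), mean_qual = numeric(),
                      stringsAsFactors = FALSE))
  left <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                         ifelse(grepl("^[0-9]+S", a$cigar), a$cigar, "0S")))
  right <- as.integer(sub("^.*?([0-9]+)S$", "\\1",
                          ifelse(grepl("[0-9]+S$", a$cigar), a$cigar, "0S")))
  span <- cigar_ref_span(a$cigar)
  rl <- nchar(a$seq)
  mean_q <- function(qual, from, to) {
    vapply(seq_along(qual), function(i) {
      if (to[i] < from[i]) return(0)
      mean(as.integer(charToRaw(substr(qual[i], from[i], to[i]))) - 33L)
    }, numeric(1))
  }
  rows <- list()
  wl <- which(left >= min_clip)
  if (length(wl)) {
    mq <- mean_q(a$qual[wl], rep(1L, length(wl)), left[wl])
    keep <- mq >= min_qual
    rows$left <- data.frame(qname = a$qname[wl][keep],
                            chrom = a$chrom[wl][keep],
                            clip_pos = a$pos[wl][keep], side = "left",
                            len = left[wl][keep], mean_qual = mq[keep],
                            stringsAsFactors = FALSE)
  }
  wr <- which(right >= min_clip)
  if (length(wr)) {
    mq <- mean_q(a$qual[wr], rl[wr] - right[wr] + 1L, rl[wr])
    keep <- mq >= min_qual
    rows$right <- data.frame(qname = a$qname[wr][keep],
                             chrom = a$chrom[wr][keep],
                             clip_pos = (a$pos + span)[wr][keep],
                             side = "right", len = right[wr][keep],
                             mean_qual = mq[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster anchored pairs into candidate insertion sites
#'
#' Forward anchors within one fragment length upstream and reverse anchors
#' downstream of a putative site are paired into a two-sided cluster.  The
#' predicted position is the dominant soft-clip position when available,
#' otherwise the midpoint between the rightmost forward-anchor end and the
#' leftmost reverse-anchor start (ties toward the smaller coordinate).
#' Sites with local read depth above `max_depth` are suppressed, as are
#' sites with fewer than `min_reads` supporting pairs.
#'
#' Support levels: 8 = both clusters plus a junction soft clip on each
#' side; 7 = both clusters plus a clip on one side; 6 = both clusters, no
#' clip; 5 and below = single-sided evidence (only emitted when
#' `emit_single_sided`).
#'
#' @param pairs output of [find_discordant_pairs()]
#' @param soft_clips output of [extract_soft_clips()]
#' @param fragment_mean,fragment_sd fragment length distribution
#' @param min_reads minimum supporting pairs per call (default 2)
#' @param max_depth local read-depth cap (default 1000)
#' @param alignments optional `"alignments"` table used to measure local
#'   depth; depth is 0 when omitted
#' @param emit_single_sided emit support level <= 5 calls (default FALSE)
#' @return data.frame of class `"candidate_sites"`, with a `manifest`
#'   attribute mapping site id to supporting read names
#' @export
cluster_candidates <- function(pairs, soft_clips = NULL,
                               fragment_mean = 350, fragment_sd = 35,
                               min_reads = 2L, max_depth = 1000L,
                               alignments = NULL,
                               emit_single_sided = FALSE) {
  stopifnot(min_reads >= 1)
  span <- fragment_mean + 3 * fragment_sd
  sites <- list(); manifest <- list()
  for (cn in unique(pairs$chrom)) {
    p <- pairs[pairs$chrom == cn, , drop = FALSE]
    fw <- p[p$anchor_strand == "+", , drop = FALSE]
    rv <- p[p$anchor_strand == "-", , drop = FALSE]
    cl_f <- cluster_1d(fw$anchor_end, span)
    cl_r <- cluster_1d(rv$anchor_pos, span)
    used_r <- logical(length(cl_r))
    sc <- if (!is.null(soft_clips))
      soft_clips[soft_clips$chrom == cn, , drop = FALSE] else NULL
    emit <- function(fi, ri) {
      nF <- if (is.null(fi)) 0L else length(cl_f[[fi]])
      nR <- if (is.null(ri)) 0L else length(cl_r[[ri]])
      f_end <- if (nF) max(fw$anchor_end[cl_f[[fi]]]) else NA_integer_
      r_start <- if (nR) min(rv$anchor_pos[cl_r[[ri]]]) else NA_integer_
      pos0 <- if (nF && nR) (f_end + r_start) %/% 2L
              else if (nF) f_end else r_start
      clip_right <- clip_left <- 0L; clip_pos <- NA_integer_
      if (!is.null(sc) && nrow(sc)) {
        lo <- if (nF) f_end - 50L else pos0 - span
        hi <- if (nR) r_start + 50L else pos0 + span
        near <- sc[sc$clip_pos >= lo & sc$clip_pos <= hi, , drop = FALSE]
        if (nrow(near)) {
          tab <- sort(table(near$clip_pos), decreasing = TRUE)
          best <- as.integer(names(tab))[tab == max(tab)]
          clip_pos <- min(best)
          atbp <- near[abs(near$clip_pos - clip_pos) <= 5L, , drop = FALSE]
          clip_right <- sum(atbp$side == "right")
          clip_left <- sum(atbp$side == "left")
        }
      }
      pos <- if (!is.na(clip_pos)) clip_pos else pos0
      level <- if (nF > 0L && nR > 0L) {
        if (clip_right > 0L && clip_left > 0L) 8L
        else if (clip_right + clip_left > 0L) 7L else 6L
      } else 5L
      qn <- c(if (nF) fw$qname[cl_f[[fi]]], if (nR) rv$qname[cl_r[[ri]]])
      list(row = data.frame(chrom = cn, pos = pos, n_forward = nF,
                            n_reverse = nR, n_pairs = nF + nR,
                            clip_left = clip_left, clip_right = clip_right,
                            support_level = level, depth = 0L,
                            stringsAsFactors = FALSE),
           qnames = unique(qn))
    }
    r_starts <- vapply(cl_r, function(i) min(rv$anchor_pos[i]), numeric(1))
    for (fi in seq_along(cl_f)) {
      f_end <- max(fw$anchor_end[cl_f[[fi]]])
      cand <- which(!used_r & r_starts >= f_end - 50 &
                    r_starts <= f_end + span)
      if (length(cand)) {
        ri <- cand[which.min(r_starts[cand])]
        used_r[ri] <- TRUE
        res <- emit(fi, ri)
      } else res <- emit(fi, NULL)
      sites[[length(sites) + 1L]] <- res$row
      manifest[[length(manifest) + 1L]] <- res$qnames
    }
    for (ri in which(!used_r)) {
      res <- emit(NULL, ri)
      sites[[length(sites) + 1L]] <- res$row
      manifest[[length(manifest) + 1L]] <- res$qnames
    }
  }
  if (length(sites) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      n_forward = integer(), n_reverse = integer(),
                      n_pairs = integer(), clip_left = integer(),
                      clip_right = integer(), support_level = integer(),
                      depth = integer(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_sites", "data.frame")
    attr(out, "manifest") <- list()
    return(out)
  }
  out <- do.call(rbind, sites)
  keep <- out$n_pairs >= min_reads
  if (!emit_single_sided) keep <- keep & out$support_level >= 6L
  out <- out[keep, , drop = FALSE]
  manifest <- manifest[keep]
  if (!is.null(alignments) && nrow(out)) {
    out$depth <- local_depth(alignments, out$chrom, out$pos)
    deep <- out$depth <= max_depth
    out <- out[deep, , drop = FALSE]
    manifest <- manifest[deep]
  }
  rownames(out) <- NULL
  out$site_id <- if (nrow(out)) sprintf("site_%03d", seq_len(nrow(out)))
                 else character(0)
  names(manifest) <- out$site_id
  class(out) <- c("candidate_sites", "data.frame")
  attr(out, "manifest") <- manifest
  out
}

# single-linkage clustering of sorted positions with a maximum gap
#' @keywords internal
cluster_1d <- function(pos, gap) {
  if (length(pos) == 0L) return(list())
  o <- order(pos)
  p <- pos[o]
  breaks <- c(0L, which(diff(p) > gap), length(p))
  lapply(seq_len(length(breaks) - 1L), function(i) {
    o[(breaks[i] + 1L):breaks[i + 1L]]
  })
}

# mapped reads overlapping pos (count, a proxy for per-base depth)
#' @keywords internal
local_depth <- function(alignments, chrom, pos) {
  a <- alignments[alignments$mapped, , drop = FALSE]
  ends <- a$pos + cigar_ref_span(a$cigar)
  out <- integer(length(pos))
  for (cn in unique(chrom)) {
    sel <- a$chrom == cn
    ss <- sort(a$pos[sel]); ee <- sort(ends[sel])
    i <- which(chrom == cn)
    out[i] <- findInterval(pos[i], ss) - findInterval(pos[i], ee)
  }
  out
}

#' Remove candidate sites near annotated reference Alus
#'
#' Drops sites whose predicted position falls within `pad` of any interval
#' in `catalog` whose label matches `family_filter`.  Pass an
#' already-padded [exclusion_mask()] output with `pad = 0`.  Idempotent.
#'
#' @param sites `"candidate_sites"` table
#' @param catalog repeat catalog (or padded mask)
#' @param pad extra padding in bp (default 500)
#' @param family_filter label prefix (default `"Alu"`)
#' @return filtered `"candidate_sites"` (manifest attribute subset
#'   accordingly); the number removed is reported via `message()`
#' @export
filter_near_reference <- function(sites, catalog, pad = 500L,
                                  family_filter = "Alu") {
  mask <- exclusion_mask(catalog, family_filter, pad)
  drop <- in_mask(sites$chrom, sites$pos, mask)
  if (any(drop))
    message(sum(drop), " candidate site(s) removed near reference ",
            family_filter)
  man <- attr(sites, "manifest")
  out <- sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "manifest") <- man[out$site_id]
  class(out) <- c("candidate_sites", "data.frame")
  out
}
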