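# Per-site local assembly: collect insertion-supporting reads, build
# contigs with a greedy overlap-layout-consensus assembler (ungapped
# suffix-prefix overlaps, both orientations, quality-weighted consensus),
# scaffold read-pair-linked contigs with 300-N spacers, and apply the
# Alu-match / flanking-sequence filters.

#' Collect reads for a candidate site
#'
#' Union of (a) the discovery manifest pairs for the site and (b) pairs
#' with a qualifying soft-clipped read whose junction falls within a
#' `window` bp window centred on the predicted breakpoint.  Both mates of
#' every selected pair are returned.
#'
#' @param site one row of a `"candidate_sites"` table
#' @param alignments an `"alignments"` table
#' @param manifest character vector of supporting read names for the site
#'   (from the `manifest` attribute of [cluster_candidates()])
#' @param window total window width in bp (default 200)
#' @param min_clip,min_qual soft-clip filters (defaults 20 bp, Q20)
#' @param clips optional precomputed [extract_soft_clips()] table
#' @return data.frame of reads: `id` (`qname/mate`), `qname`, `seq`, `qual`
#' @export
collect_reads <- function(site, alignments, manifest = character(),
                          window = 200L, min_clip = 20L, min_qual = 20,
                          clips = NULL) {
  if (is.null(clips))
    clips <- extract_soft_clips(alignments, min_clip, min_qual)
  half <- window %/% 2L
  near <- clips$chrom == site$chrom &
    clips$clip_pos >= site$pos - half & clips$clip_pos <= site$pos + half
  qn <- unique(c(manifest, clips$qname[near]))
  a <- alignments[alignments$qname %in% qn, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(id = character(), qname = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  a <- a[order(a$qname, a$mate), , drop = FALSE]
  data.frame(id = paste0(a$qname, "/", a$mate), qname = a$qname,
             seq = a$seq, qual = a$qual, stringsAsFactors = FALSE)
}

#' Greedy overlap-layout-consensus assembly
#'
#' Computes all pairwise ungapped suffix-prefix overlaps of at least
#' `min_overlap` bp at `min_identity` identity (both orientations), then
#' iteratively merges the highest-scoring overlap (score = matched bp;
#' ties broken toward the longer resulting contig, then the
#' lexicographically smaller read id).  Consensus bases are chosen by
#' quality-weighted majority.  Contigs with fewer than
#' `min_reads_per_contig` member reads are discarded.
#'
#' @param reads data.frame from [collect_reads()]
#' @param min_overlap minimum overlap length (default 16)
#' @param min_identity minimum overlap identity (default 0.90)
#' @param min_reads_per_contig minimum members per emitted contig
#'   (default 2)
#' @return list of contigs, each a list with `seq`, `depth`, `members`
#'   (data.frame of `id`, `offset`, `strand`)
#' @export
assemble <- function(reads, min_overlap = 16L, min_identity = 0.90,
                     min_reads_per_contig = 2L) {
  stopifnot(nrow(reads) > 0L)
  reads <- reads[!duplicated(reads$id), , drop = FALSE]
  tigs <- lapply(seq_len(nrow(reads)), function(i) {
    q <- as.integer(charToRaw(reads$qual[i])) - 33L
    list(seq = reads$seq[i], weight = q, depth = rep(1L, nchar(reads$seq[i])),
         members = data.frame(id = reads$id[i], offset = 0L, strand = "+",
                              len = nchar(reads$seq[i]),
                              stringsAsFactors = FALSE))
  })
  n0 <- length(tigs)
  seqs <- vapply(tigs, `[[`, character(1), "seq")
  rcs <- revcomp(seqs)
  # overlap tables over ordered pairs (j placed after i)
  SC <- matrix(-1L, n0, n0); LEN <- matrix(0L, n0, n0)
  RC <- matrix(0L, n0, n0)
  ov <- function(i, j) {
    best <- c(0L, -1L, 0L)
    r <- .best_overlap_cpp(seqs[i], seqs[j], min_overlap, min_identity)
    if (r[1] > 0L && r[2] > best[2]) best <- c(r, 0L)
    r <- .best_overlap_cpp(seqs[i], rcs[j], min_overlap, min_identity)
    if (r[1] > 0L && r[2] > best[2]) best <- c(r, 1L)
    best
  }
  set_ov <- function(i, j) {
    r <- ov(i, j)
    SC[i, j] <<- r[2]; LEN[i, j] <<- r[1]; RC[i, j] <<- r[3]
  }
  for (i in seq_len(n0)) for (j in seq_len(n0)) if (i != j) set_ov(i, j)
  alive <- rep(TRUE, n0)
  first_id <- vapply(tigs, function(t) t$members$id[1], character(1))
  repeat {
    if (sum(alive) < 2L) break
    m <- max(SC)
    if (m <= 0L) break
    cand <- which(SC == m, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      newlen <- nchar(seqs[cand[, 1]]) + nchar(seqs[cand[, 2]]) -
        LEN[cand]
      cand <- cand[newlen == max(newlen), , drop = FALSE]
      if (nrow(cand) > 1L) {
        key <- pmin(first_id[cand[, 1]], first_id[cand[, 2]])
        cand <- cand[order(key), , drop = FALSE]
      }
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    L <- LEN[i, j]
    tj <- tigs[[j]]
    if (RC[i, j]) tj <- flip_contig(tj)
    tigs[[i]] <- merge_contigs(tigs[[i]], tj, L)
    seqs[i] <- tigs[[i]]$seq; rcs[i] <- revcomp(seqs[i])
    first_id[i] <- min(first_id[i], first_id[j])
    alive[j] <- FALSE
    SC[j, ] <- -1L; SC[, j] <- -1L
    for (k in which(alive)) if (k != i) { set_ov(i, k); set_ov(k, i) }
  }
  out <- tigs[alive]
  out <- Filter(function(t) nrow(t$members) >= min_reads_per_contig, out)
  lapply(out, function(t) t[c("seq", "depth", "members")])
}

#' @keywords internal
flip_contig <- function(t) {
  L <- nchar(t$seq)
  t$seq <- revcomp(t$seq)
  t$weight <- rev(t$weight)
  t$depth <- rev(t$depth)
  t$members$offset <- L - t$members$offset - t$members$len
  t$members$strand <- ifelse(t$members$strand == "+", "-", "+")
  t
}

# append contig b after a with an ungapped overlap of length L;
# quality-weighted majority in the overlap
#' @keywords internal
merge_contigs <- function(a, b, L) {
  la <- nchar(a$seq); lb <- nchar(b$seq)
  va <- chars(a$seq); vb <- chars(b$seq)
  ia <- (la - L + 1L):la; ib <- seq_len(L)
  wa <- a$weight[ia]; wb <- b$weight[ib]
  keep_a <- va[ia] == vb[ib] | wa >= wb
  merged_mid <- ifelse(keep_a, va[ia], vb[ib])
  w_mid <- ifelse(va[ia] == vb[ib], wa + wb, pmax(wa, wb))
  d_mid <- a$depth[ia] + b$depth[ib]
  seq <- paste(c(va[seq_len(la - L)], merged_mid, vb[(L + 1L):lb][seq_len(max(0L, lb - L))]),
               collapse = "")
  weight <- c(a$weight[seq_len(la - L)], w_mid,
              b$weight[(L + 1L):lb][seq_len(max(0L, lb - L))])
  depth <- c(a$depth[seq_len(la - L)], d_mid,
             b$depth[(L + 1L):lb][seq_len(max(0L, lb - L))])
  mb <- b$members
  mb$offset <- mb$offset + (la - L)
  list(seq = seq, weight = weight, depth = depth,
       members = rbind(a$members, mb))
}

#' Scaffold read-pair-linked contigs
#'
#' Contigs whose member reads include opposite mates of at least one pair
#' are joined in mate order with exactly 300 `N` characters at each
#' unresolved join.  Contradictory link orientations leave the contigs
#' unjoined with a warning.  Unlinked contigs are emitted as single-contig
#' scaffolds.
#'
#' @param contigs list of contigs from [assemble()]
#' @param spacer number of `N`s per join (default 300)
#' @return list of scaffolds, each a list with `seq`, `contigs` (indices),
#'   `links` (pair count per join)
#' @export
scaffold_contigs <- function(contigs, spacer = 300L) {
  n <- length(contigs)
  if (n == 0L) return(list())
  mem <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- contigs[[i]]$members
    data.frame(contig = i, qname = sub("/[12]$", "", m$id),
               mate = as.integer(sub("^.*/", "", m$id)),
               offset = m$offset, strand = m$strand,
               stringsAsFactors = FALSE)
  }))
  links <- merge(mem[mem$mate == 1L, ], mem[mem$mate == 2L, ],
                 by = "qname", suffixes = c("_1", "_2"))
  links <- links[links$contig_1 != links$contig_2, , drop = FALSE]
  joined <- rep(FALSE, n)
  scaffolds <- list()
  if (nrow(links)) {
    key <- paste(pmin(links$contig_1, links$contig_2),
                 pmax(links$contig_1, links$contig_2))
    for (k in unique(key)) {
      lk <- links[key == k, , drop = FALSE]
      i <- pmin(lk$contig_1[1], lk$contig_2[1])
      j <- pmax(lk$contig_1[1], lk$contig_2[1])
      if (joined[i] || joined[j]) next
      # expected orientation: the two mates of an FR pair point at each
      # other, so within a correctly joined scaffold they land on opposite
      # strands
      consistent <- lk$strand_1 != lk$strand_2
      if (!all(consistent) && any(consistent)) {
        warning("contradictory link orientations between contigs ", i,
                " and ", j, "; left unjoined")
        next
      }
      # order: the contig carrying the forward mate comes first
      first_is_i <- ifelse(lk$strand_1 == "+", lk$contig_1 == i,
                           lk$contig_2 == i)
      a <- if (mean(first_is_i) >= 0.5) i else j
      b <- if (a == i) j else i
      scaffolds[[length(scaffolds) + 1L]] <- list(
        seq = paste0(contigs[[a]]$seq, strrep("N", spacer),
                     contigs[[b]]$seq),
        contigs = c(a, b), links = nrow(lk))
      joined[i] <- joined[j] <- TRUE
    }
  }
  for (i in which(!joined)) {
    scaffolds[[length(scaffolds) + 1L]] <- list(seq = contigs[[i]]$seq,
                                                contigs = i, links = 0L)
  }
  scaffolds
}

#' Apply the assembly filters to a scaffold
#'
#' Requires an Alu-library match of at least `min_match` bases at
#' `min_identity` identity and at least `min_flank` bp of contiguous
#' non-gap (non-N) sequence on at least one side of the match.
#'
#' @param scaffold a scaffold (list with `seq`) or a bare sequence string
#' @param alu_library consensus library
#' @param min_match,min_identity,min_flank filter thresholds (30 bp, 0.90,
#'   30 bp)
#' @return list: `pass`, `target`, `matched_bp`, `identity`,
#'   `elem_start`/`elem_end` (0-based half-open scaffold interval),
#'   `elem_strand`, `flank5`, `flank3` (contiguous non-N run lengths
#'   outside the match), `gap_within_100bp`
#' @export
filter_assembly <- function(scaffold, alu_library, min_match = 30L,
                            min_identity = 0.90, min_flank = 30L) {
  seq <- if (is.list(scaffold)) scaffold$seq else scaffold
  hit <- alu_hits(seq, alu_library, min_match, min_identity)
  res <- list(pass = FALSE, target = hit$target, matched_bp = hit$match,
              identity = hit$identity, elem_start = hit$start,
              elem_end = hit$end, elem_strand = hit$strand,
              sub_start = hit$sub_start, sub_end = hit$sub_end,
              flank5 = 0L, flank3 = 0L, gap_within_100bp = FALSE,
              seq = seq)
  if (is.na(hit$target) || hit$match < min_match ||
      hit$identity < min_identity)
    return(res)
  v <- chars(seq)
  left <- v[seq_len(hit$start)]
  right <- if (hit$end < length(v)) v[(hit$end + 1L):length(v)] else character()
  run_len <- function(x) { # contiguous non-N run adjacent to the match
    if (length(x) == 0L) return(0L)
    nn <- x != "N"
    r <- rle(nn)
    if (!r$values[length(r$values)]) 0L else r$lengths[length(r$lengths)]
  }
  res$flank5 <- run_len(left)
  res$flank3 <- run_len(rev(right))  # run adjacent to the match on the right
  res$gap_within_100bp <-
    (res$flank5 < 100L && length(left) > res$flank5) ||
    (res$flank3 < 100L && length(right) > res$flank3)
  res$pass <- max(res$flank5, res$flank3) >= min_flank
  res
}
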