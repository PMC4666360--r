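# Breakpoint resolution by scored three-way alignment.  The assembled
# left and right flanks of an insertion are each globally aligned to the
# same reference window; the two pairwise alignments are merged on
# reference coordinates into a three-way alignment whose columns are
# labelled '*' (all three agree), '1' (left flank matches reference),
# '2' (right flank matches reference) or 'N' (no match).  Cumulative
# +1/-1/-3 score tracks, scanned from each end, locate the two
# breakpoints; the region where both flanks align to the reference is the
# overlap (candidate TSD span), and a gap between them is a target-site
# deletion.

#' Scored global or fit pairwise alignment
#'
#' Affine-gap alignment (match +5, mismatch -4, gap open 16, gap extend 4
#' by default; a gap of length L costs `gap_open + L * gap_extend`).
#' `mode = "global"` aligns both sequences end to end; `mode = "fit"`
#' aligns the query end to end with free leading/trailing reference bases,
#' used to place a flank inside a reference window.  Traceback is
#' deterministic (diagonal preferred over a reference gap over a query
#' gap).  `N` mismatches everything.
#'
#' @param query,reference nucleotide strings
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#' @param mode `"global"` or `"fit"`
#' @return list of class `"pairwise_alignment"`: `score`, `pattern`
#'   (gapped query), `subject` (gapped reference), `ref_start`/`ref_end`
#'   (0-based half-open aligned reference span), `reference` (the full
#'   reference string)
#' @export
global_align <- function(query, reference, match = 5L, mismatch = -4L,
                         gap_open = 16L, gap_extend = 4L,
                         mode = c("global", "fit")) {
  mode <- match.arg(mode)
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  r <- .aln_pair_cpp(query, reference, as.integer(match),
                     as.integer(mismatch), as.integer(gap_open),
                     as.integer(gap_extend), mode == "fit")
  structure(list(score = r$score, pattern = r$pattern, subject = r$subject,
                 ref_start = r$ref_start, ref_end = r$ref_end,
                 reference = reference),
            class = "pairwise_alignment")
}

#' Merge two flank-vs-reference alignments into a three-way alignment
#'
#' Both alignments must be against the identical reference string.  The
#' merge is synchronized on reference coordinates: wherever one alignment
#' gaps the reference (an insertion in that flank), a corresponding gap
#' column is inserted for the other flank; every reference base appears in
#' exactly one column.
#'
#' @param left_aln,right_aln `"pairwise_alignment"` objects over the same
#'   reference
#' @return list of class `"threeway_alignment"`: parallel vectors `ref`,
#'   `left`, `right` (characters, `"-"` for gap or absent), `ref_pos`
#'   (0-based reference position, `NA` for insertion columns) and `label`
#'   in `{*, 1, 2, N}`
#' @export
merge_threeway <- function(left_aln, right_aln) {
  if (!identical(left_aln$reference, right_aln$reference))
    stop("alignments are not against the same reference sequence")
  ref <- left_aln$reference
  cols_l <- alignment_columns(left_aln)
  cols_r <- alignment_columns(right_aln)
  # the merge spans the union of the two aligned reference spans; window
  # margins covered by neither flank carry no evidence and are excluded
  span_lo <- min(left_aln$ref_start, right_aln$ref_start)
  span_hi <- max(left_aln$ref_end, right_aln$ref_end)
  m <- nchar(ref)
  # per reference position: insertion columns (ref gap) attached before the
  # position, then the reference column itself
  ref_c <- chars(ref)
  out_ref <- character(); out_l <- character(); out_r <- character()
  out_pos <- integer()
  li <- cols_l$ins; ri <- cols_r$ins
  for (p in span_lo:span_hi) {
    if (!is.null(li[[as.character(p)]])) {
      ins <- li[[as.character(p)]]
      out_ref <- c(out_ref, rep("-", length(ins)))
      out_l <- c(out_l, ins)
      out_r <- c(out_r, rep("-", length(ins)))
      out_pos <- c(out_pos, rep(NA_integer_, length(ins)))
    }
    if (!is.null(ri[[as.character(p)]])) {
      ins <- ri[[as.character(p)]]
      out_ref <- c(out_ref, rep("-", length(ins)))
      out_l <- c(out_l, rep("-", length(ins)))
      out_r <- c(out_r, ins)
      out_pos <- c(out_pos, rep(NA_integer_, length(ins)))
    }
    if (p < span_hi && p < m) {
      out_ref <- c(out_ref, ref_c[p + 1L])
      out_l <- c(out_l, cols_l$base[p + 1L])
      out_r <- c(out_r, cols_r$base[p + 1L])
      out_pos <- c(out_pos, p)
    }
  }
  lab <- ifelse(out_ref != "-" & out_l == out_ref & out_r == out_ref, "*",
         ifelse(out_ref != "-" & out_l == out_ref, "1",
         ifelse(out_ref != "-" & out_r == out_ref, "2", "N")))
  structure(list(ref = out_ref, left = out_l, right = out_r,
                 ref_pos = out_pos, label = lab),
            class = "threeway_alignment")
}

# per-reference-position flank base ('-' when gapped/uncovered) and
# insertions keyed by the reference position they precede
#' @keywords internal
alignment_columns <- function(aln) {
  m <- nchar(aln$reference)
  base <- rep("-", m)
  ins <- list()
  qs <- chars(aln$pattern); rs <- chars(aln$subject)
  rp <- aln$ref_start  # 0-based position of next reference base
  pend <- character()
  for (k in seq_along(qs)) {
    if (rs[k] == "-") {
      pend <- c(pend, qs[k])
    } else {
      if (length(pend)) {
        ins[[as.character(rp)]] <- c(ins[[as.character(rp)]], pend)
        pend <- character()
      }
      base[rp + 1L] <- qs[k]
      rp <- rp + 1L
    }
  }
  if (length(pend)) ins[[as.character(rp)]] <- c(ins[[as.character(rp)]],
                                                 pend)
  list(base = base, ins = ins)
}

#' Score a three-way alignment and call breakpoints
#'
#' The left track scans left to right, scoring +1 for `1`/`*`, -1 for `N`
#' and -3 for `2`; the right track scans right to left with the roles of
#' `1` and `2` swapped.  The left breakpoint is the reference coordinate
#' at the left track's maximum (rightmost on ties), the right breakpoint
#' the right track's maximum (leftmost on ties).  When
#' `left_bp >= right_bp` the interval `[right_bp, left_bp]` is the overlap
#' region (candidate TSD span); otherwise `right_bp - left_bp - 1` is a
#' target-site deletion.
#'
#' @param threeway a `"threeway_alignment"`
#' @return list with `left_track`, `right_track` (cumulative score
#'   vectors), `left_bp`, `right_bp` (0-based reference coordinates),
#'   `overlap_len`, `target_deletion`, `overlap_cols` (column indices of
#'   the overlap region)
#' @export
score_breakpoints <- function(threeway) {
  lab <- threeway$label
  n <- length(lab)
  stopifnot(n > 0)
  inc_l <- ifelse(lab %in% c("1", "*"), 1L, ifelse(lab == "N", -1L, -3L))
  inc_r <- ifelse(lab %in% c("2", "*"), 1L, ifelse(lab == "N", -1L, -3L))
  left_track <- cumsum(inc_l)
  right_track <- rev(cumsum(rev(inc_r)))
  lmax <- max(left_track)
  lcol <- max(which(left_track == lmax))         # rightmost maximum
  rmax <- max(right_track)
  rcol <- min(which(right_track == rmax))        # leftmost maximum
  # report breakpoints respective to the reference
  lbp <- ref_coord_at(threeway, lcol, "before")
  rbp <- ref_coord_at(threeway, rcol, "after")
  if (!is.na(lbp) && !is.na(rbp) && lbp >= rbp) {
    overlap <- lbp - rbp + 1L
    tdel <- 0L
    ocols <- which(!is.na(threeway$ref_pos) & threeway$ref_pos >= rbp &
                   threeway$ref_pos <= lbp)
  } else {
    overlap <- 0L
    tdel <- if (!is.na(lbp) && !is.na(rbp)) rbp - lbp - 1L else NA_integer_
    ocols <- integer()
  }
  list(left_track = left_track, right_track = right_track,
       left_bp = lbp, right_bp = rbp, overlap_len = overlap,
       target_deletion = tdel, overlap_cols = ocols)
}

#' @keywords internal
ref_coord_at <- function(threeway, col, side) {
  rp <- threeway$ref_pos
  if (side == "before") {
    cand <- rp[seq_len(col)]
    cand <- cand[!is.na(cand)]
    if (length(cand)) cand[length(cand)] else NA_integer_
  } else {
    cand <- rp[col:length(rp)]
    cand <- cand[!is.na(cand)]
    if (length(cand)) cand[1] else NA_integer_
  }
}

#' Refine a candidate TSD within the overlap region
#'
#' Within the overlap, the run of columns where both flanks exactly match
#' the reference, grown from the element-proximal end of the overlap (the
#' element 3' side) until the first mismatching column, becomes the
#' refined TSD.  An overlap with internal mismatches therefore yields a
#' TSD shorter than the overlap.
#'
#' @param call result of [score_breakpoints()]
#' @param threeway the `"threeway_alignment"` it was computed from
#' @return `call` with `tsd` (string, possibly `""`) and `tsd_len` added
#' @export
refine_tsd <- function(call, threeway) {
  cols <- call$overlap_cols
  if (length(cols) == 0L) {
    call$tsd <- ""; call$tsd_len <- 0L
    return(call)
  }
  star <- threeway$label[cols] == "*"
  runs <- rle(star)
  if (!any(runs$values)) {
    call$tsd <- ""; call$tsd_len <- 0L
    return(call)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]  # maximal run; ties -> first
  # (element-proximal, i.e. 5'-most in reference coordinates) run
  sel <- cols[starts[best]:ends[best]]
  call$tsd <- paste(threeway$ref[sel], collapse = "")
  call$tsd_len <- length(sel)
  call
}

#' Resolve breakpoints for an assembled site
#'
#' Orients the scaffold against the reference, locates the Alu match
#' (extended through the adjacent poly-A run, which is assigned to the
#' element rather than the flank), extracts the contiguous non-gap flanks,
#' fit-aligns them to the reference window around the predicted site,
#' merges, scores and refines.  A site is genotypable when both
#' breakpoints are flanked by at least `min_genotype_flank` bp of non-gap
#' assembled sequence.
#'
#' @param scaffold scaffold (list with `seq`) or sequence string that
#'   passed [filter_assembly()]
#' @param genome reference genome
#' @param site one row of a `"candidate_sites"` table
#' @param alu_library consensus library
#' @param flank window half-width for the reference extraction
#'   (default 600, matching the genotyping allele span)
#' @param min_genotype_flank non-gap flank needed on both sides for
#'   genotyping (default 100)
#' @return list of class `"breakpoint_call"`; `NULL` when the scaffold has
#'   no qualifying Alu match
#' @export
call_site <- function(scaffold, genome, site, alu_library, flank = 600L,
                      min_genotype_flank = 100L) {
  seq <- if (is.list(scaffold)) scaffold$seq else scaffold
  win_start <- max(0L, site$pos - flank)
  win_end <- min(nchar(unclass(genome)[[site$chrom]]), site$pos + flank)
  window <- extract_sequence(genome, site$chrom, win_start, win_end)
  # orientation vs reference: better local score of scaffold (either
  # orientation) against the window wins
  ori <- scaffold_orientation(seq, window)
  if (ori == "-") seq <- revcomp(seq)
  filt <- filter_assembly(seq, alu_library)
  if (is.na(filt$target) || !filt$pass) return(NULL)
  # canonical element 5' boundary: the local alignment may absorb flank
  # bases across isolated mismatches; re-anchor so that only the
  # contiguous run of consensus-matching bases adjacent to the element is
  # absorbed (the same convention the truth normalization uses)
  filt <- refine_elem5(seq, filt, alu_library[[filt$target]])
  span <- element_span_with_polyA(seq, filt)
  es <- span[1]; ee <- span[2]
  v <- chars(seq)
  left_all <- substr(seq, 1L, es)
  right_all <- if (ee < nchar(seq)) substr(seq, ee + 1L, nchar(seq)) else ""
  left_flank <- last_nonN_run(left_all)
  right_flank <- first_nonN_run(right_all)
  res <- list(chrom = site$chrom, site_id = site$site_id %||% NA_character_,
              target = filt$target, elem_start = es, elem_end = ee,
              elem_strand = filt$elem_strand,
              element_seq = substr(seq, es + 1L, ee),
              scaffold_seq = seq,
              flank5 = nchar(left_flank), flank3 = nchar(right_flank),
              gap_within_100bp = filt$gap_within_100bp,
              both_flanks_ok = nchar(left_flank) > 0 &&
                nchar(right_flank) > 0)
  if (!res$both_flanks_ok) {
    res$genotypable <- FALSE
    class(res) <- "breakpoint_call"
    return(res)
  }
  left_aln <- global_align(left_flank, window, mode = "fit")
  right_aln <- global_align(right_flank, window, mode = "fit")
  tw <- merge_threeway(left_aln, right_aln)
  call <- score_breakpoints(tw)
  call <- refine_tsd(call, tw)
  res$left_bp_raw <- call$left_bp + win_start
  res$right_bp_raw <- call$right_bp + win_start
  # canonical representation: the poly-A(/T) run adjacent to one junction
  # makes the TSD/poly-A split ambiguous whenever the reference continues
  # the homopolymer; normalize to the maximal-TSD (minimal-deletion)
  # representation, exactly as indel calls are left-aligned before
  # comparison
  tail_run <- polyA_run_length(seq, filt, span)
  norm <- normalize_breakpoints(window, call$left_bp, call$right_bp,
                                filt$elem_strand, tail_run)
  res$left_bp <- norm$left_bp + win_start
  res$right_bp <- norm$right_bp + win_start
  res$overlap_len <- norm$overlap_len
  res$target_deletion <- norm$target_deletion
  slid <- norm$slid
  res$tsd <- if (norm$overlap_len > 0L) {
    raw_run <- call$tsd_len
    # extend the refined exact-match run through the normalized columns
    substr(window, norm$right_bp + 1L, norm$right_bp + min(
      norm$overlap_len, raw_run + slid))
  } else ""
  res$tsd_len <- nchar(res$tsd)
  res$threeway <- tw
  # scaffold coordinates of the novel inserted segment: between the left
  # flank base aligned at the left breakpoint and the right flank base
  # aligned at the right breakpoint
  lq <- query_pos_at_ref(left_aln, call$left_bp, "last_at_or_before")
  rq <- query_pos_at_ref(right_aln, call$right_bp, "first_at_or_after")
  left_off <- es - nchar(left_flank)          # 0-based scaffold offset
  right_off <- ee + (regexpr(right_flank, right_all, fixed = TRUE) - 1L)
  if (!is.na(lq) && !is.na(rq)) {
    ins_from <- left_off + lq            # 0-based, exclusive of flank base
    ins_to <- right_off + rq - 1L        # 0-based, exclusive
    res$inserted_seq <- if (ins_to > ins_from)
      substr(seq, ins_from + 1L, ins_to) else ""
  } else res$inserted_seq <- res$element_seq
  res$genotypable <- res$flank5 >= min_genotype_flank &&
    res$flank3 >= min_genotype_flank
  class(res) <- "breakpoint_call"
  res
}

#' @keywords internal
scaffold_orientation <- function(seq, window) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  sc <- function(s) Biostrings::score(Biostrings::pairwiseAlignment(
    s, window, type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2))
  if (sc(seq) >= sc(revcomp(seq))) "+" else "-"
}

# Re-anchor the element 5' boundary with the contiguous-match convention:
# from the first clean 10-column match run, walk 5' (in element
# orientation) while scaffold and consensus bases continue to match
# contiguously.  Assumes the boundary region is locally ungapped.
#' @keywords internal
refine_elem5 <- function(seq, filt, consensus) {
  v <- chars(seq)
  cv <- chars(consensus)
  if (filt$elem_strand == "+") {
    base_at <- function(i) {                # i = 0 is the match start
      s <- filt$elem_start + 1L + i
      if (s < 1L || s > length(v)) NA_character_ else v[s]
    }
  } else {
    base_at <- function(i) {
      s <- filt$elem_end - i
      if (s < 1L || s > length(v)) NA_character_
      else chartr("ACGT", "TGCA", v[s])
    }
  }
  cons_at <- function(i) {
    c <- filt$sub_start + i
    if (c < 1L || c > length(cv)) NA_character_ else cv[c]
  }
  m <- function(i) {
    a <- base_at(i); b <- cons_at(i)
    !is.na(a) && !is.na(b) && a == b && a != "N"
  }
  i0 <- NA_integer_
  for (i in 0:60) {
    if (all(vapply(i:(i + 9L), m, logical(1)))) { i0 <- i; break }
  }
  if (is.na(i0)) return(filt)
  b <- i0
  while (m(b - 1L)) b <- b - 1L
  if (filt$elem_strand == "+") filt$elem_start <- filt$elem_start + b
  else filt$elem_end <- filt$elem_end - b
  filt$sub_start <- filt$sub_start + b
  filt
}

# length of the homopolymer tail attributed to the element (the A-run at a
# plus-strand element's 3' end, the T-run at a minus-strand element's 5'
# end) -- the budget available for TSD normalization
#' @keywords internal
polyA_run_length <- function(seq, filt, span) {
  v <- chars(seq)
  if (filt$elem_strand == "+") {
    n <- 0L; k <- span[2]
    while (k >= 1L && v[k] == "A") { n <- n + 1L; k <- k - 1L }
  } else {
    n <- 0L; k <- span[1] + 1L
    while (k <= length(v) && v[k] == "T") { n <- n + 1L; k <- k + 1L }
  }
  n
}

# maximal-TSD (minimal-deletion) canonical representation: slide the
# poly-A-adjacent breakpoint through the reference homopolymer, consuming
# the tail budget
#' @keywords internal
normalize_breakpoints <- function(window, left_bp, right_bp, elem_strand,
                                  budget) {
  slid <- 0L
  wc <- chars(window)
  if (!is.na(left_bp) && !is.na(right_bp)) {
    if (elem_strand == "+") {
      while (budget > 0L && right_bp >= 1L && wc[right_bp] == "A") {
        right_bp <- right_bp - 1L; budget <- budget - 1L; slid <- slid + 1L
      }
    } else {
      while (budget > 0L && left_bp + 2L <= length(wc) &&
             wc[left_bp + 2L] == "T") {
        left_bp <- left_bp + 1L; budget <- budget - 1L; slid <- slid + 1L
      }
    }
  }
  if (!is.na(left_bp) && !is.na(right_bp) && left_bp >= right_bp) {
    list(left_bp = left_bp, right_bp = right_bp,
         overlap_len = left_bp - right_bp + 1L, target_deletion = 0L,
         slid = slid)
  } else {
    list(left_bp = left_bp, right_bp = right_bp, overlap_len = 0L,
         target_deletion = if (!is.na(left_bp) && !is.na(right_bp))
           right_bp - left_bp - 1L else NA_integer_,
         slid = slid)
  }
}

# extend the element interval through the adjacent homopolymer tail:
# the A-run 3' of a plus-strand element, the T-run 5' of a minus-strand one
#' @keywords internal
element_span_with_polyA <- function(seq, filt) {
  v <- chars(seq)
  es <- filt$elem_start; ee <- filt$elem_end
  if (filt$elem_strand == "+") {
    while (ee < length(v) && v[ee + 1L] == "A") ee <- ee + 1L
  } else {
    while (es > 0L && v[es] == "T") es <- es - 1L
  }
  c(es, ee)
}

#' @keywords internal
last_nonN_run <- function(s) {
  if (nchar(s) == 0L) return("")
  sub(".*N", "", s)
}

#' @keywords internal
first_nonN_run <- function(s) {
  if (nchar(s) == 0L) return("")
  sub("N.*", "", s)
}

# 1-based query position aligned at (or adjacent to) a reference position
#' @keywords internal
query_pos_at_ref <- function(aln, ref_pos, side) {
  qs <- chars(aln$pattern); rs <- chars(aln$subject)
  rp <- aln$ref_start
  qp <- 0L
  best <- NA_integer_
  for (k in seq_along(qs)) {
    if (qs[k] != "-") qp <- qp + 1L
    if (rs[k] != "-") {
      if (side == "last_at_or_before") {
        if (rp <= ref_pos && qp > 0L) best <- qp
        if (rp >= ref_pos) break
      } else {
        if (rp >= ref_pos && qp > 0L && qs[k] != "-") { best <- qp; break }
      }
      rp <- rp + 1L
    }
  }
  best
}

#' @export
print.breakpoint_call <- function(x, ...) {
  cat("breakpoint call:", x$chrom,
      if (!is.null(x$left_bp)) paste0("left_bp=", x$left_bp,
                                      " right_bp=", x$right_bp), "\n")
  cat("  element:", x$target, "strand", x$elem_strand,
      sprintf("[%d,%d)", x$elem_start, x$elem_end), "\n")
  if (!is.null(x$tsd_len))
    cat("  overlap:", x$overlap_len, "bp; TSD:", x$tsd_len,
        "bp; target deletion:", x$target_deletion, "bp\n")
  cat("  genotypable:", x$genotypable, "\n")
  invisible(x)
}

#' Render a three-way alignment in the 1/2/* column notation
#'
#' @param threeway a `"threeway_alignment"`
#' @param width wrap width (default 60)
#' @return character vector of text lines, invisibly printed
#' @export
render_threeway <- function(threeway, width = 60L) {
  n <- length(threeway$ref)
  out <- character()
  for (s in seq(1L, n, by = width)) {
    e <- min(n, s + width - 1L)
    out <- c(out,
             paste0("ref   ", paste(threeway$ref[s:e], collapse = "")),
             paste0("left  ", paste(threeway$left[s:e], collapse = "")),
             paste0("right ", paste(threeway$right[s:e], collapse = "")),
             paste0("label ", paste(threeway$label[s:e], collapse = "")),
             "")
  }
  out
}
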