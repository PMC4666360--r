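# Subfamily assignment against a consensus profile alignment, 5'
# truncation measurement, microhomology at the truncation point, and
# cohort summary tables.

#' Trim the poly-A tail from an element sequence
#'
#' The tail is the maximal 3'-terminal run of at least `min_len` bases
#' that is at least `min_frac` adenine.
#'
#' @param seq element sequence (element-forward orientation)
#' @param min_len,min_frac tail definition (defaults 5 bp, 80 percent A)
#' @return sequence with the tail removed
#' @export
trim_polyA <- function(seq, min_len = 5L, min_frac = 0.8) {
  v <- rev(chars(seq))
  isA <- cumsum(v == "A")
  k <- seq_along(v)
  # the tail must itself begin with an A (v is reversed: its k-th element
  # is the candidate tail's first base)
  ok <- which(k >= min_len & isA / k >= min_frac & v == "A")
  if (length(ok) == 0L) return(seq)
  substr(seq, 1L, nchar(seq) - max(ok))
}

#' Build a consensus profile library
#'
#' Center-star progressive alignment: the consensus with the highest total
#' pairwise identity to the others is the center; every other consensus is
#' globally aligned to it and gaps are merged on center coordinates.
#' De-gapping any profile row reproduces the input consensus.
#'
#' @param consensus named character vector (subfamily -> consensus), or a
#'   FASTA path
#' @return list of class `"consensus_library"`: `sequences` (ungapped),
#'   `profile` (named gapped rows, equal length), `center` (name),
#'   `center_map` (profile column of each center base)
#' @export
build_profile <- function(consensus) {
  if (is.character(consensus) && length(consensus) == 1L &&
      file.exists(consensus))
    consensus <- unclass(read_fasta(consensus))
  stopifnot(length(consensus) >= 2L)
  nm <- names(consensus)
  n <- length(consensus)
  idsum <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- global_align(consensus[[i]], consensus[[j]])
    idsum[i] <- idsum[i] + a$score
  }
  center <- nm[which.max(idsum)]
  cs <- consensus[[center]]
  m <- nchar(cs)
  # per input: bases over center positions plus insertions keyed by the
  # center position they precede
  parts <- lapply(nm, function(x) {
    if (x == center)
      return(list(base = chars(cs), ins = list()))
    alignment_columns(global_align(consensus[[x]], cs))
  })
  names(parts) <- nm
  ins_len <- integer(m + 1L)
  for (p in parts) for (k in names(p$ins)) {
    i <- as.integer(k) + 1L
    ins_len[i] <- max(ins_len[i], length(p$ins[[k]]))
  }
  rows <- vapply(parts, function(p) {
    out <- character()
    for (pos in 0:m) {
      L <- ins_len[pos + 1L]
      if (L > 0L) {
        ins <- p$ins[[as.character(pos)]] %||% character()
        out <- c(out, ins, rep("-", L - length(ins)))
      }
      if (pos < m) out <- c(out, p$base[pos + 1L])
    }
    paste(out, collapse = "")
  }, character(1))
  center_map <- integer(m)
  ins_start <- integer(m + 1L)
  col <- 0L
  for (pos in 0:m) {
    ins_start[pos + 1L] <- col + 1L
    col <- col + ins_len[pos + 1L]
    if (pos < m) {
      col <- col + 1L
      center_map[pos + 1L] <- col
    }
  }
  structure(list(sequences = consensus, profile = rows, center = center,
                 center_map = center_map, ins_len = ins_len,
                 ins_start = ins_start),
            class = "consensus_library")
}

# orient an element (forward vs reverse complement) against the library
# center and trim the poly-A tail
#' @keywords internal
orient_element <- function(element, library) {
  cs <- library$sequences[[library$center]]
  fw <- global_align(element, cs)$score
  rv <- global_align(revcomp(element), cs)$score
  if (rv > fw) revcomp(element) else element
}

#' Assign an element to an Alu subfamily
#'
#' The element (poly-A trimmed, orientation resolved against the library)
#' is aligned to the profile via the center sequence; per subfamily the
#' divergence is the proportion of differing positions over the columns
#' within the element's aligned span where either sequence has a base.
#' The minimum mismatch count wins; exact count ties are deemed
#' unclassified.
#'
#' @param element element sequence
#' @param library a `"consensus_library"`
#' @return list of class `"subfamily_call"`: `subfamily` (or
#'   `"unclassified"`), `divergence`, `runner_up`, `tie`, `divergences`
#' @export
assign_subfamily <- function(element, library) {
  stopifnot(nchar(element) > 0)
  el <- trim_polyA(orient_element(element, library))
  cs <- library$sequences[[library$center]]
  aln <- global_align(el, cs, mode = "fit")
  cols <- alignment_columns(aln)
  ncol_p <- nchar(library$profile[[1]])
  erow <- rep("-", ncol_p)
  covered <- which(cols$base != "-")
  if (length(covered) == 0L)
    return(structure(list(subfamily = "unclassified", divergence = NA_real_,
                          runner_up = NA_real_, tie = FALSE,
                          divergences = NULL),
                     class = "subfamily_call"))
  erow[library$center_map[covered]] <- cols$base[covered]
  # element bases inserted relative to the center are placed into the
  # profile's insertion columns at the same center position (left-aligned,
  # matching the profile construction); overflow bases are dropped
  for (k in names(cols$ins)) {
    p <- as.integer(k)
    v <- cols$ins[[k]]
    nfit <- min(length(v), library$ins_len[p + 1L])
    if (nfit > 0L)
      erow[library$ins_start[p + 1L] + seq_len(nfit) - 1L] <- v[seq_len(nfit)]
  }
  span <- range(library$center_map[covered])
  idx <- span[1]:span[2]
  ev <- erow[idx]
  mm <- vapply(library$profile, function(r) {
    rv <- chars(r)[idx]
    has <- ev != "-" | rv != "-"
    sum(has & ev != rv)
  }, numeric(1))
  den <- vapply(library$profile, function(r) {
    rv <- chars(r)[idx]
    sum(ev != "-" | rv != "-")
  }, numeric(1))
  div <- mm / pmax(den, 1)
  o <- order(mm, names(mm))
  tie <- length(mm) > 1L && mm[o[1]] == mm[o[2]]
  structure(list(
    subfamily = if (tie) "unclassified" else names(mm)[o[1]],
    divergence = unname(div[o[1]]),
    runner_up = if (length(mm) > 1L) unname(div[o[2]]) else NA_real_,
    tie = tie, divergences = div), class = "subfamily_call")
}

#' Measure 5' truncation against a subfamily consensus
#'
#' Offset is the 1-based position of the first consensus base covered by
#' the (poly-A trimmed) element; bins follow the truncation classes
#' full-length (1-5), short (7-45), long (55-171), other.
#'
#' @param element element sequence (element-forward)
#' @param subfamily_consensus consensus sequence
#' @return list: `offset`, `end` (last covered consensus position),
#'   `bin`
#' @export
measure_truncation <- function(element, subfamily_consensus) {
  el <- trim_polyA(element)
  aln <- global_align(el, subfamily_consensus, mode = "fit")
  offset <- aln$ref_start + 1L
  bin <- truncation_bin(offset)
  list(offset = offset, end = aln$ref_end, bin = bin)
}

#' @keywords internal
truncation_bin <- function(offset) {
  ifelse(offset >= 1 & offset <= 5, "full_length",
  ifelse(offset >= 7 & offset <= 45, "short_trunc",
  ifelse(offset >= 55 & offset <= 171, "long_trunc", "other")))
}

#' Microhomology at the 5' truncation break
#'
#' Counts contiguous positions, walking 5' from the element junction in
#' element orientation, where the genomic target base equals the consensus
#' base immediately 5' of the element's first aligned base.  Also reports
#' the 6 bp nic-site window at the insertion point and whether it matches
#' the canonical L1 ORF2p pattern `TTTT/AA` (on the insertion strand).
#'
#' @param call a `"breakpoint_call"` (provides junction coordinates and
#'   element strand)
#' @param offset truncation offset from [measure_truncation()]
#' @param consensus subfamily consensus sequence
#' @param genome reference genome
#' @return list: `shared` (contiguous shared base count), `hexamer`,
#'   `canonical`
#' @export
detect_microhomology <- function(call, offset, consensus, genome) {
  refseq <- unclass(genome)[[call$chrom]]
  if (call$elem_strand == "+") {
    # element 5' break at the left junction; genomic flank read leftward
    gpos <- call$left_bp + 1L   # 1-based index of last flank base
    step <- -1L
  } else {
    gpos <- call$right_bp + 1L  # 1-based index of first downstream base
    step <- +1L
  }
  shared <- 0L
  cpos <- offset - 1L           # consensus base immediately 5' of break
  while (cpos >= 1L && gpos >= 1L && gpos <= nchar(refseq)) {
    g <- substr(refseq, gpos, gpos)
    if (call$elem_strand == "-") g <- revcomp(g)
    if (g != substr(consensus, cpos, cpos)) break
    shared <- shared + 1L
    cpos <- cpos - 1L
    gpos <- gpos + step
  }
  site <- call$left_bp + 1L
  hex <- if (call$elem_strand == "+") {
    if (site - 4L >= 1L) substr(refseq, site - 3L, site + 2L) else ""
  } else {
    s <- call$right_bp + 1L
    if (s + 3L <= nchar(refseq) && s - 2L >= 1L)
      revcomp(substr(refseq, s - 2L, s + 3L)) else ""
  }
  list(shared = shared, hexamer = hex,
       canonical = identical(hex, "TTTTAA"))
}

#' Summarize a classified cohort
#'
#' @param calls data.frame with columns `subfamily` (label or
#'   `"unclassified"`) and optionally `trunc_bin` and `microhomology`
#' @return list of class `"cohort_summary"`: `subfamily_table` (count,
#'   pct_total over all elements, pct_assigned over labelled elements),
#'   `truncation_table` (per subfamily and bin), `microhomology_table`
#' @export
summarize_cohort <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  total <- nrow(calls)
  tab <- table(calls$subfamily)
  assigned <- sum(tab[names(tab) != "unclassified"])
  sub_tab <- data.frame(
    subfamily = names(tab), count = as.integer(tab),
    pct_total = round_half_up(100 * as.integer(tab) / total, 1),
    pct_assigned = ifelse(names(tab) == "unclassified", NA_real_,
                          round_half_up(100 * as.integer(tab) / assigned,
                                        1)),
    stringsAsFactors = FALSE)
  sub_tab <- sub_tab[order(-sub_tab$count), ]
  rownames(sub_tab) <- NULL
  trunc_tab <- NULL
  if ("trunc_bin" %in% names(calls)) {
    rows <- list()
    for (sf in unique(calls$subfamily)) {
      d <- calls[calls$subfamily == sf, , drop = FALSE]
      bt <- table(factor(d$trunc_bin,
                         levels = c("full_length", "short_trunc",
                                    "long_trunc", "other")))
      rows[[sf]] <- data.frame(
        subfamily = sf, bin = names(bt), count = as.integer(bt),
        pct = round_half_up(100 * as.integer(bt) / nrow(d), 2),
        stringsAsFactors = FALSE)
    }
    trunc_tab <- do.call(rbind, rows)
    rownames(trunc_tab) <- NULL
  }
  micro_tab <- NULL
  if ("microhomology" %in% names(calls)) {
    mh <- calls$microhomology[!is.na(calls$microhomology)]
    if (length(mh)) {
      cls <- cut(mh, c(-1, 0, 1, Inf), labels = c("0", "1", ">=2"))
      mt <- table(cls)
      micro_tab <- data.frame(shared = names(mt), count = as.integer(mt),
                              pct = round_half_up(100 * as.integer(mt) /
                                                  length(mh), 1),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(subfamily_table = sub_tab, truncation_table = trunc_tab,
                 microhomology_table = micro_tab, n = total,
                 n_assigned = assigned),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort of", x$n, "elements (", x$n_assigned, "assigned )\n")
  print(head(x$subfamily_table, 15))
  invisible(x)
}
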