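# Paired-end read simulation from implant haplotypes, with exact coordinate
# projection of every read back onto the unmodified reference.  Projection
# stands in for a short-read mapper: reads fully inside reference-derived
# segments map with MAPQ 60, reads crossing an insertion junction are
# soft-clipped at the junction, and reads inside inserted sequence are
# reported unmapped (their mapped mates are the discovery anchors).

#' Simulate paired-end reads from a haplotype and project them to the
#' reference
#'
#' Fragment count per chromosome is Poisson with mean
#' `coverage * length / (2 * read_len)`; fragment lengths are normal
#' `(frag_mean, frag_sd)`; sequencing errors are iid substitutions at
#' `error_rate`.  Deterministic under `seed`.
#'
#' @param hap result of [implant_insertions()] (or a plain genome, treated
#'   as having no insertions)
#' @param coverage target haploid coverage
#' @param read_len read length in bp (default 101, 2x101 bp libraries)
#' @param frag_mean,frag_sd fragment length distribution (defaults 350/35)
#' @param error_rate per-base substitution error rate
#' @param min_anchor minimum reference-aligned bases for a junction read to
#'   be reported mapped (soft-clipped) rather than unmapped
#' @param base_quality constant Phred base quality assigned to simulated
#'   bases (default 40)
#' @param seed RNG seed
#' @return data.frame of read alignments (one row per read; both mates
#'   present) of class `"alignments"`
#' @export
simulate_paired_reads <- function(hap, coverage, read_len = 101L,
                                  frag_mean = 350, frag_sd = 35,
                                  error_rate = 0, min_anchor = 20L,
                                  base_quality = 40L, seed = NULL) {
  stopifnot(frag_mean > read_len, coverage > 0)
  if (is(hap, "genome")) {
    seqs <- unclass(hap)
    blocks <- lapply(seqs, function(s) data.frame(
      hap_start = 0L, hap_end = nchar(s), ref_start = 0L,
      inserted = FALSE, implant = NA_integer_))
  } else {
    seqs <- unclass(hap$haplotype)
    blocks <- hap$blocks
  }
  local_seed(seed, {
    rows <- lapply(names(seqs), function(cn) {
      L <- nchar(seqs[[cn]])
      np <- rpois(1L, coverage * L / (2 * read_len))
      if (np == 0L) return(NULL)
      flen <- pmin(L, pmax(read_len, round(rnorm(np, frag_mean, frag_sd))))
      fs <- floor(runif(np) * (L - flen + 1))
      s1 <- fs; e1 <- fs + read_len
      s2 <- fs + flen - read_len; e2 <- fs + flen
      seq1 <- substring(seqs[[cn]], s1 + 1L, e1)
      seq2 <- substring(seqs[[cn]], s2 + 1L, e2)
      if (error_rate > 0) {
        seq1 <- add_errors(seq1, error_rate)
        seq2 <- add_errors(seq2, error_rate)
      }
      qname <- sprintf("%s_p%07d", cn, seq_len(np))
      b <- blocks[[cn]]
      p1 <- project_read(s1, e1, b, min_anchor, read_len)
      p2 <- project_read(s2, e2, b, min_anchor, read_len)
      qual <- strrep(rawToChar(as.raw(33L + base_quality)), read_len)
      mk <- function(p, seqv, mate, strand, hs) data.frame(
        qname = qname, mate = mate, chrom = cn, pos = p$pos, mapq = p$mapq,
        cigar = p$cigar, strand = strand, mapped = p$mapped,
        seq = seqv, qual = qual, hap_pos = hs, stringsAsFactors = FALSE)
      r1 <- mk(p1, seq1, 1L, "+", s1)
      r2 <- mk(p2, seq2, 2L, "-", s2)
      r1$mate_mapped <- r2$mapped; r2$mate_mapped <- r1$mapped
      r1$mpos <- r2$pos; r2$mpos <- r1$pos
      span <- ifelse(r1$mapped & r2$mapped,
                     abs(pmax(r2$pos + read_len, r1$pos + read_len) -
                         pmin(r1$pos, r2$pos)), NA_real_)
      proper <- !is.na(span) & span <= frag_mean + 4 * frag_sd
      r1$proper <- proper; r2$proper <- proper
      rbind(r1, r2)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no reads simulated")
    out <- out[order(out$chrom, ifelse(is.na(out$pos), .Machine$integer.max,
                                       out$pos)), ]
    rownames(out) <- NULL
    class(out) <- c("alignments", "data.frame")
    out
  })
}

# classify reads against the haplotype->reference block map
#' @keywords internal
project_read <- function(s, e, b, min_anchor, read_len) {
  i1 <- findInterval(s, b$hap_start)
  i2 <- findInterval(e - 1L, b$hap_start)
  n <- length(s)
  pos <- rep(NA_integer_, n); cigar <- rep("*", n)
  mapped <- rep(FALSE, n); mapq <- rep(0L, n)
  same <- i1 == i2
  w <- same & !b$inserted[i1]
  pos[w] <- b$ref_start[i1[w]] + (s[w] - b$hap_start[i1[w]])
  cigar[w] <- paste0(read_len, "M"); mapped[w] <- TRUE; mapq[w] <- 60L
  cross <- i2 == i1 + 1L
  # read starts in reference, runs into inserted sequence: clip on the right
  w <- cross & !b$inserted[i1] & b$inserted[pmin(i2, nrow(b))]
  m <- b$hap_end[i1[w]] - s[w]
  ok <- m >= min_anchor
  idx <- which(w)[ok]
  pos[idx] <- b$ref_start[i1[idx]] + (s[idx] - b$hap_start[i1[idx]])
  cigar[idx] <- paste0(m[ok], "M", read_len - m[ok], "S")
  mapped[idx] <- TRUE; mapq[idx] <- 60L
  # read starts in inserted sequence, ends in reference: clip on the left
  w <- cross & b$inserted[i1] & !b$inserted[pmin(i2, nrow(b))]
  m <- e[w] - b$hap_start[i2[w]]
  ok <- m >= min_anchor
  idx <- which(w)[ok]
  pos[idx] <- b$ref_start[i2[idx]]
  cigar[idx] <- paste0(read_len - m[ok], "S", m[ok], "M")
  mapped[idx] <- TRUE; mapq[idx] <- 60L
  list(pos = pos, cigar = cigar, mapped = mapped, mapq = mapq)
}

#' @keywords internal
add_errors <- function(seqs, rate) {
  rl <- nchar(seqs[1])
  nerr <- rbinom(length(seqs), rl, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    v <- chars(seqs[i])
    pos <- sample.int(rl, nerr[i])
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Write simulated pairs as a pair of FASTQ files
#'
#' Mate 2 is written in sequencing orientation (reverse complement of the
#' stored reference-forward sequence).
#'
#' @param alignments an `"alignments"` table
#' @param path1,path2 output FASTQ paths for mates 1 and 2
#' @return invisibly, `c(path1, path2)`
#' @export
write_fastq <- function(alignments, path1, path2) {
  for (m in 1:2) {
    a <- alignments[alignments$mate == m, , drop = FALSE]
    a <- a[order(a$qname), , drop = FALSE]
    sq <- if (m == 1L) a$seq else revcomp(a$seq)
    ql <- a$qual
    lines <- as.vector(rbind(paste0("@", a$qname, "/", m), sq, "+", ql))
    writeLines(lines, if (m == 1L) path1 else path2)
  }
  invisible(c(path1, path2))
}

#' Write an alignment table as SAM
#'
#' @param alignments an `"alignments"` table
#' @param genome genome providing `@SQ` headers
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, genome, path) {
  seqs <- unclass(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  a <- alignments
  flag <- 1L +
    ifelse(a$proper & a$mapped & a$mate_mapped, 2L, 0L) +
    ifelse(a$mapped, 0L, 4L) + ifelse(a$mate_mapped, 0L, 8L) +
    ifelse(a$strand == "-", 16L, 0L) +
    ifelse(a$mate == 1L, 64L + 32L, 128L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  a$qname, flag,
                  ifelse(a$mapped, a$chrom, "*"),
                  ifelse(a$mapped, a$pos + 1L, 0L),
                  a$mapq, a$cigar,
                  ifelse(a$mate_mapped, "=", "*"),
                  ifelse(a$mate_mapped, a$mpos + 1L, 0L),
                  a$seq, a$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Minimal reader for the columns the pipeline consumes; mate pairing is
#' reconstructed from flags.
#'
#' @param path SAM path
#' @return an `"alignments"` table
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[`, character(1), 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  a <- data.frame(
    qname = vapply(f, `[`, character(1), 1L),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = vapply(f, `[`, character(1), 3L),
    pos = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
    mapq = as.integer(vapply(f, `[`, character(1), 5L)),
    cigar = vapply(f, `[`, character(1), 6L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapped = mapped,
    seq = vapply(f, `[`, character(1), 10L),
    qual = vapply(f, `[`, character(1), 11L),
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    mpos = as.integer(vapply(f, `[`, character(1), 8L)) - 1L,
    proper = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  a$pos[!a$mapped] <- NA_integer_
  a$chrom[a$chrom == "*"] <- NA_character_
  # unmapped mates inherit their mate's chromosome for windowed retrieval
  idx <- which(!a$mapped & a$mate_mapped)
  if (length(idx)) {
    key <- paste0(a$qname, "/", 3L - a$mate)
    lut <- setNames(a$chrom, paste0(a$qname, "/", a$mate))
    a$chrom[idx] <- lut[key[idx]]
  }
  class(a) <- c("alignments", "data.frame")
  a
}
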