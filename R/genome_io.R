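# Coordinate conventions: all internal coordinates are 0-based, half-open
# [start, end).  Conversion to/from 1-based formats (RepeatMasker .out, SAM,
# VCF) happens only at the format boundary.

#' Read a FASTA file into a genome object
#'
#' A genome is an ordered named character vector of uppercase nucleotide
#' sequences over `{A,C,G,T,N}`.
#'
#' @param path path to a (multi-record) FASTA file
#' @return named character vector of class `"genome"`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters (outside ACGTN) in FASTA record '",
         names(seqs)[bad][1], "'")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in ", path)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  structure(seqs, class = "genome")
}

#' Write a genome to FASTA (wrapped at 60 columns)
#'
#' @param genome genome object (named character vector)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Construct a repeat catalog of genomic intervals
#'
#' @param chrom,start,end,strand,label parallel vectors; coordinates are
#'   0-based half-open, strand is `"+"` or `"-"`.
#' @param genome optional genome to validate coordinates against
#' @return data.frame of class `"repeat_catalog"`
#' @export
repeat_catalog <- function(chrom = character(), start = integer(),
                           end = integer(), strand = "+", label = "",
                           genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   label = rep_len(as.character(label), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_catalog(df, genome)
}

#' @keywords internal
validate_catalog <- function(df, genome = NULL) {
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("invalid interval: need 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (!is.null(genome)) {
      len <- nchar(unclass(genome))[df$chrom]
      if (anyNA(len)) stop("interval on unknown chromosome: ",
                           df$chrom[is.na(len)][1])
      if (any(df$end > len)) stop("interval beyond chromosome end")
    }
  }
  class(df) <- c("repeat_catalog", "data.frame")
  df
}

#' Read repeat annotations (RepeatMasker .out or BED)
#'
#' RepeatMasker `.out` rows carry 1-based inclusive coordinates and use `C`
#' for the minus strand; both are converted on input.  BED intervals pass
#' through unchanged.
#'
#' @param path annotation file
#' @param dialect `"bed"` or `"repeatmasker_out"`
#' @param genome optional genome for coordinate validation
#' @return a `repeat_catalog`
#' @export
read_repeat_annotations <- function(path,
                                    dialect = c("bed", "repeatmasker_out"),
                                    genome = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "repeatmasker_out") lines <- tail(lines, -3L)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(repeat_catalog(genome = genome))
  if (dialect == "bed") {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 3L)) stop("malformed BED line: ", lines[nf < 3L][1])
    df <- data.frame(
      chrom = vapply(f, `[`, character(1), 1L),
      start = as.integer(vapply(f, `[`, character(1), 2L)),
      end = as.integer(vapply(f, `[`, character(1), 3L)),
      strand = ifelse(nf >= 6L, vapply(f, `[`, character(1), 6L), "+"),
      label = ifelse(nf >= 4L, vapply(f, `[`, character(1), 4L), ""),
      stringsAsFactors = FALSE)
    df$strand[is.na(df$strand) | !df$strand %in% c("+", "-")] <- "+"
  } else {
    f <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(f) < 11L))
      stop("malformed RepeatMasker row: ", lines[lengths(f) < 11L][1])
    df <- data.frame(
      chrom = vapply(f, `[`, character(1), 5L),
      start = as.integer(vapply(f, `[`, character(1), 6L)) - 1L,
      end = as.integer(vapply(f, `[`, character(1), 7L)),
      strand = ifelse(vapply(f, `[`, character(1), 9L) == "C", "-", "+"),
      label = vapply(f, `[`, character(1), 10L),
      stringsAsFactors = FALSE)
  }
  validate_catalog(df, genome)
}

#' Build a padded exclusion mask from a repeat catalog
#'
#' Selects intervals whose label starts with `family_filter`
#' (case-insensitive, so `"Alu"` matches `AluYa5`), expands each by `pad`
#' on both sides, clips to chromosome bounds when a genome is supplied, and
#' merges overlapping or touching intervals.  The result is sorted and
#' pairwise disjoint.
#'
#' @param catalog a `repeat_catalog`
#' @param family_filter case-insensitive label prefix (default `"Alu"`)
#' @param pad non-negative padding in bp (default 500, the locus exclusion
#'   distance used at discovery time)
#' @param genome optional genome used to clip to chromosome bounds
#' @return a merged `repeat_catalog`
#' @export
exclusion_mask <- function(catalog, family_filter = "Alu", pad = 500L,
                           genome = NULL) {
  stopifnot(pad >= 0)
  keep <- startsWith(tolower(catalog$label), tolower(family_filter))
  df <- catalog[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(repeat_catalog())
  df$start <- pmax(0L, df$start - as.integer(pad))
  df$end <- df$end + as.integer(pad)
  if (!is.null(genome)) {
    len <- nchar(unclass(genome))[df$chrom]
    df$end <- pmin(df$end, as.integer(len))
  }
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    ms <- s[1]; me <- e[1]; rs <- integer(); re <- integer()
    if (nrow(d) > 1L) for (i in 2:nrow(d)) {
      if (s[i] <= me) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    rs <- c(rs, ms); re <- c(re, me)
    data.frame(chrom = d$chrom[1], start = rs, end = re, strand = "+",
               label = family_filter, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_catalog(out)
}

#' Extract a (stranded) sequence from a genome
#'
#' @param genome genome object
#' @param chrom chromosome name
#' @param start,end 0-based half-open coordinates
#' @param strand `"+"` or `"-"`; minus returns the reverse complement
#' @return nucleotide string
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  seqs <- unclass(genome)
  if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
  L <- nchar(seqs[[chrom]])
  if (start < 0 || end > L || start >= end)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", L, ")")
  s <- substr(seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

# TRUE for each position falling inside any mask interval on its chromosome
#' @keywords internal
in_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  out <- logical(length(pos))
  for (cn in unique(chrom)) {
    m <- mask[mask$chrom == cn, , drop = FALSE]
    idx <- which(chrom == cn)
    if (nrow(m) == 0L || length(idx) == 0L) next
    m <- m[order(m$start), , drop = FALSE]
    k <- findInterval(pos[idx], m$start)
    hit <- k >= 1L & pos[idx] < m$end[pmax(k, 1L)]
    out[idx] <- hit
  }
  out
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "sequence(s),",
      format(sum(nchar(unclass(x))), big.mark = ","), "bp total\n")
  invisible(x)
}
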