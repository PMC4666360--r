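# Synthetic genomes and implanted Alu insertions with retrotransposition
# hallmarks: target site duplication (or target-site deletion), poly-A tail,
# optional 5' truncation, either strand.

#' Load the bundled synthetic Alu consensus library
#'
#' Subfamily names follow the field's naming but the sequences are synthetic
#' stand-ins (the RepBase consensus library is licensed); see
#' `inst/extdata/alu_consensus_synthetic.fa`.
#'
#' @return named character vector: subfamily -> consensus sequence
#' @export
synthetic_alu_library <- function() {
  path <- system.file("extdata", "alu_consensus_synthetic.fa",
                      package = "aluvar", mustWork = TRUE)
  unclass(read_fasta(path))
}

#' Generate a random toy genome with annotated reference Alu copies
#'
#' Uniform random sequence with `n_ref_alu` (possibly diverged) copies of
#' library consensuses planted at uniform positions, annotated in the
#' returned catalog -- the substrate for masking and discovery filters.
#'
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param library consensus library (default the bundled synthetic one)
#' @param n_ref_alu number of reference Alu copies to plant
#' @param divergence per-base substitution rate applied to planted copies
#' @param seed RNG seed
#' @return list with `genome` and `catalog`
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 1e6L),
                            library = synthetic_alu_library(),
                            n_ref_alu = 20L, divergence = 0.05,
                            seed = NULL) {
  local_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- names(chrom_lengths)
    cat_rows <- list()
    if (n_ref_alu > 0L) {
      wt <- chrom_lengths / sum(chrom_lengths)
      for (i in seq_len(n_ref_alu)) {
        cn <- sample(names(seqs), 1L, prob = wt)
        fam <- sample(names(library), 1L)
        el <- mutate_sequence(library[[fam]], divergence)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") el <- revcomp(el)
        L <- nchar(seqs[[cn]])
        pos <- sample.int(L - nchar(el), 1L) - 1L
        substr(seqs[[cn]], pos + 1L, pos + nchar(el)) <- el
        cat_rows[[i]] <- data.frame(chrom = cn, start = pos,
                                    end = pos + nchar(el), strand = strand,
                                    label = fam, stringsAsFactors = FALSE)
      }
    }
    catalog <- if (length(cat_rows)) validate_catalog(do.call(rbind, cat_rows))
               else repeat_catalog()
    list(genome = structure(seqs, class = "genome"), catalog = catalog)
  })
}

# iid substitutions at `rate`, never to the original base
#' @keywords internal
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  v <- chars(seq)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

#' Draw implant specifications for a synthetic cohort
#'
#' Sites come from the nic-site rejection sampler; hallmark parameters
#' follow the stated world: TSD length uniform 5-25 bp (the TPRT stagger
#' range), poly-A tails uniform 10-30 bp, and 5' truncation offsets from a
#' three-component mixture (85% offset 1-5, 10% in 7-45, 5% in 55-171,
#' relative to the consensus start).
#'
#' @param sites data.frame from [sample_insertion_sites()]
#' @param library consensus library
#' @param subfamilies subfamily names to draw from (default: all in library)
#' @param subfamily_prob optional sampling weights
#' @param tsd_range inclusive TSD length range (default `c(5, 25)`)
#' @param polyA_range inclusive poly-A length range (default `c(10, 30)`)
#' @param trunc_mix mixture weights for the full-length / short / long
#'   truncation classes (default `c(0.85, 0.10, 0.05)`)
#' @param deletion_prob probability an implant carries a target-site
#'   deletion (1-6 bp) instead of a TSD (default 0)
#' @param rate per-base substitution rate applied to each element copy
#' @param seed RNG seed
#' @return data.frame of implant specs
#' @export
draw_implant_specs <- function(sites, library,
                               subfamilies = names(library),
                               subfamily_prob = NULL,
                               tsd_range = c(5L, 25L),
                               polyA_range = c(10L, 30L),
                               trunc_mix = c(0.85, 0.10, 0.05),
                               deletion_prob = 0, rate = 0, seed = NULL) {
  local_seed(seed, {
    n <- nrow(sites)
    fam <- sample(subfamilies, n, replace = TRUE, prob = subfamily_prob)
    cls <- sample.int(3L, n, replace = TRUE, prob = trunc_mix)
    trunc <- integer(n)
    trunc[cls == 1L] <- sample(0:4, sum(cls == 1L), replace = TRUE)
    trunc[cls == 2L] <- sample(6:44, sum(cls == 2L), replace = TRUE)
    trunc[cls == 3L] <- sample(54:170, sum(cls == 3L), replace = TRUE)
    del <- rbinom(n, 1L, deletion_prob) == 1L
    tsd <- ifelse(del, 0L,
                  sample(tsd_range[1]:tsd_range[2], n, replace = TRUE))
    tdel <- ifelse(del, sample(1:6, n, replace = TRUE), 0L)
    data.frame(chrom = sites$chrom, site = sites$pos, strand = sites$strand,
               subfamily = fam, truncation_offset = trunc,
               tsd_length = as.integer(tsd), target_deletion = as.integer(tdel),
               polyA_length = sample(polyA_range[1]:polyA_range[2], n,
                                     replace = TRUE),
               rate = rate, stringsAsFactors = FALSE)
  })
}

#' Implant Alu insertions into a genome
#'
#' At each spec site the inserted sequence is
#' `element[truncation_offset + 1 ..] + poly-A`, reverse-complemented as a
#' unit for minus-strand specs, followed by a duplicate of the `tsd_length`
#' reference bases immediately 5' of the site (or, for target-site
#' deletions, with `target_deletion` reference bases removed after the
#' insertion point).  Returns the modified haplotype genome, a truth table
#' in unmodified-reference coordinates, and a haplotype<->reference block
#' map used by the read simulator.
#'
#' @param genome reference genome
#' @param specs data.frame of implant specs (see [draw_implant_specs()])
#' @param library consensus library
#' @param seed RNG seed (used only when `rate > 0`)
#' @return list with `haplotype` (genome), `truth` (data.frame), and
#'   `blocks` (per-chromosome block map)
#' @export
implant_insertions <- function(genome, specs, library, seed = NULL) {
  stopifnot(all(specs$subfamily %in% names(library)))
  stopifnot(all(specs$tsd_length >= 0), all(specs$target_deletion >= 0),
            all(specs$polyA_length >= 0))
  if (any(specs$tsd_length > 0 & specs$target_deletion > 0))
    stop("tsd_length and target_deletion are mutually exclusive")
  local_seed(seed, {
    seqs <- unclass(genome)
    out_seqs <- seqs
    blocks <- list()
    truth_rows <- list()
    for (cn in names(seqs)) {
      sp <- specs[specs$chrom == cn, , drop = FALSE]
      sp <- sp[order(sp$site), , drop = FALSE]
      if (nrow(sp) > 1L) {
        lo <- sp$site - sp$tsd_length - 1L
        hi <- sp$site + sp$target_deletion + 1L
        if (any(lo[-1L] < hi[-nrow(sp)]))
          stop("overlapping implant specs on ", cn)
      }
      refseq <- seqs[[cn]]
      pieces <- character(); bl <- list()
      ref_cursor <- 0L; hap_cursor <- 0L
      for (i in seq_len(nrow(sp))) {
        s <- sp[i, ]
        el <- library[[s$subfamily]]
        if (s$truncation_offset >= nchar(el))
          stop("truncation_offset >= element length")
        el <- substr(el, s$truncation_offset + 1L, nchar(el))
        el <- mutate_sequence(el, s$rate)
        ins <- paste0(el, strrep("A", s$polyA_length))
        if (s$strand == "-") ins <- revcomp(ins)
        dup <- if (s$tsd_length > 0)
          substr(refseq, s$site - s$tsd_length + 1L, s$site) else ""
        block_seq <- paste0(ins, dup)
        up <- substr(refseq, ref_cursor + 1L, s$site)
        pieces <- c(pieces, up, block_seq)
        bl[[length(bl) + 1L]] <- data.frame(
          hap_start = hap_cursor, hap_end = hap_cursor + nchar(up),
          ref_start = ref_cursor, inserted = FALSE, implant = NA_integer_)
        hap_cursor <- hap_cursor + nchar(up)
        bl[[length(bl) + 1L]] <- data.frame(
          hap_start = hap_cursor, hap_end = hap_cursor + nchar(block_seq),
          ref_start = NA_integer_, inserted = TRUE, implant = i)
        ctx <- if (s$truncation_offset > 0L)
          rev(chars(substr(library[[s$subfamily]], 1L,
                           s$truncation_offset))) else character()
        nrm <- normalize_truth(refseq, s$site, s$tsd_length,
                               s$target_deletion, s$polyA_length, s$strand,
                               elem5_context = ctx)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          chrom = cn, site = s$site, strand = s$strand,
          subfamily = s$subfamily, truncation_offset = s$truncation_offset,
          tsd_length = s$tsd_length, target_deletion = s$target_deletion,
          tsd_norm = nrm$tsd, target_deletion_norm = nrm$tdel,
          polyA_length = s$polyA_length, hap_pos = hap_cursor,
          ins_len = nchar(block_seq), ins_seq = ins,
          stringsAsFactors = FALSE)
        hap_cursor <- hap_cursor + nchar(block_seq)
        ref_cursor <- s$site + s$target_deletion
      }
      rest <- substr(refseq, ref_cursor + 1L, nchar(refseq))
      pieces <- c(pieces, rest)
      bl[[length(bl) + 1L]] <- data.frame(
        hap_start = hap_cursor, hap_end = hap_cursor + nchar(rest),
        ref_start = ref_cursor, inserted = FALSE, implant = NA_integer_)
      out_seqs[[cn]] <- paste(pieces, collapse = "")
      blocks[[cn]] <- do.call(rbind, bl)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
             else data.frame()
    rownames(truth) <- NULL
    list(haplotype = structure(out_seqs, class = "genome"),
         truth = truth, blocks = blocks)
  })
}

#' Canonical (maximal-TSD) representation of an implant
#'
#' The split between the element poly-A(/T) tail and an adjacent TSD copy
#' or retained reference homopolymer is not identifiable from the product
#' haplotype: `(tsd, polyA)` and `(tsd + 1, polyA - 1)` produce the same
#' sequence whenever the reference continues the homopolymer.  Truth
#' tables and breakpoint calls are therefore both normalized to the
#' maximal-TSD (minimal-deletion) representation before comparison, the
#' same convention as left-aligning indels.
#'
#' A second ambiguity arises at the element 5' junction of truncated
#' elements: genomic bases matching the consensus immediately 5' of the
#' truncation point (microhomology) can equally be read as element or
#' flank; the canonical form absorbs them into the element (which is what
#' a local aligner does).  Supply `elem5_context` -- the consensus bases
#' preceding the element start, innermost first -- to apply it.
#'
#' @param refseq reference chromosome sequence
#' @param site 0-based insertion point
#' @param tsd,target_deletion,polyA drawn hallmark lengths
#' @param strand insertion strand
#' @param elem5_context character vector of consensus bases 5' of the
#'   element start, innermost first (empty for full-length elements)
#' @return list with normalized `tsd` and `tdel`
#' @export
normalize_truth <- function(refseq, site, tsd, target_deletion, polyA,
                            strand, elem5_context = character()) {
  # microhomology absorption at the element 5' junction
  j <- 0L
  n <- length(elem5_context)
  if (n > 0L) {
    if (strand == "+") {
      while (j < n && site - j >= 1L) {
        g <- substr(refseq, site - j, site - j)
        if (g != elem5_context[j + 1L]) break
        j <- j + 1L
      }
      site <- site - j
    } else {
      # element-5'-adjacent genomic bases: the TSD copy after the element
      # (or the retained downstream sequence), read in element orientation
      p0 <- if (target_deletion > 0L) site + target_deletion
            else site - tsd
      while (j < n && p0 + j < nchar(refseq)) {
        g <- revcomp(substr(refseq, p0 + j + 1L, p0 + j + 1L))
        if (g != elem5_context[j + 1L]) break
        j <- j + 1L
      }
    }
    if (target_deletion > 0L) target_deletion <- target_deletion + j
    else if (j > tsd) { target_deletion <- j - tsd; tsd <- 0L }
    else tsd <- tsd - j
  }
  budget <- polyA
  if (strand == "+") {
    p <- if (target_deletion > 0L) site + target_deletion else site - tsd
    while (budget > 0L && p >= 1L && substr(refseq, p, p) == "A") {
      p <- p - 1L; budget <- budget - 1L
    }
    if (p >= site) list(tsd = 0L, tdel = p - site)
    else list(tsd = site - p, tdel = 0L)
  } else {
    q <- site  # TSD end (exclusive) or deletion start
    dend <- site + target_deletion
    while (budget > 0L && q < nchar(refseq) &&
           substr(refseq, q + 1L, q + 1L) == "T") {
      q <- q + 1L; budget <- budget - 1L
    }
    if (q <= dend && target_deletion > 0L) list(tsd = 0L, tdel = dend - q)
    else list(tsd = tsd + (q - dend), tdel = 0L)
  }
}

#' Write an implant truth table as TSV
#' @param truth truth table from [implant_insertions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth[, setdiff(names(truth), "ins_seq")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
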