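# In silico genotyping: reconstruct the reference and insertion alleles
# per site, remap read pairs to both, convert the alignment-score gap to a
# Phred-scaled confidence, compute dosage likelihoods treating that
# quality as an error probability, estimate the population allele
# frequency by ploidy-aware EM under Hardy-Weinberg equilibrium, and call
# posterior genotypes.

#' Build the reference and insertion alleles for a genotypable site
#'
#' The reference allele spans `flank` bp upstream and downstream of the
#' inferred TSD span; the insertion allele replaces the appropriate
#' portion with the assembled inserted sequence, duplicating the TSD or
#' removing target-site-deleted bases.
#'
#' @param call a genotypable `"breakpoint_call"`
#' @param genome reference genome
#' @param flank flank length (default 600)
#' @return list of class `"allele_pair"`: `ref_allele`, `alt_allele`,
#'   `region` (0-based half-open reference interval of the ref allele),
#'   `chrom`
#' @export
build_alleles <- function(call, genome, flank = 600L) {
  refseq <- unclass(genome)[[call$chrom]]
  L <- nchar(refseq)
  up_end <- call$left_bp + 1L           # exclusive end of upstream segment
  a <- min(call$right_bp, up_end)
  b <- max(call$right_bp, up_end)
  start <- a - flank; end <- b + flank
  if (start < 0L || end > L) {
    warning("allele flank truncated at chromosome boundary")
    start <- max(0L, start); end <- min(L, end)
  }
  ref_allele <- substr(refseq, start + 1L, end)
  alt_allele <- paste0(substr(refseq, start + 1L, up_end),
                       call$inserted_seq,
                       substr(refseq, call$right_bp + 1L, end))
  structure(list(ref_allele = ref_allele, alt_allele = alt_allele,
                 region = c(start, end), chrom = call$chrom),
            class = "allele_pair")
}

#' Extract site-proximal read pairs and remap them to both alleles
#'
#' Pairs with at least one read originally mapped within the reference
#' allele region at `MAPQ >= mapq_min` are locally aligned (each mate,
#' both orientations) to the reference and insertion alleles.  The pair
#' score per allele is the sum of its mates' best scores; the winning
#' allele gets a Phred-like confidence `q = min(60, 2 * score gap)`.
#' Equal scores give a tie with `q = 0`.
#'
#' @param alignments an `"alignments"` table (one sample)
#' @param allele_pair an `"allele_pair"`
#' @param mapq_min original-mapping quality threshold (default 20)
#' @return data.frame: `qname`, `best` in `{ref, alt, tie}`, `q`
#' @export
extract_and_remap <- function(alignments, allele_pair, mapq_min = 20L) {
  a <- alignments
  inreg <- a$mapped & a$chrom == allele_pair$chrom &
    a$mapq >= mapq_min & a$pos >= allele_pair$region[1] &
    a$pos < allele_pair$region[2]
  qn <- unique(a$qname[inreg])
  if (length(qn) == 0L)
    return(data.frame(qname = character(), best = character(),
                      q = numeric(), stringsAsFactors = FALSE))
  reads <- a[a$qname %in% qn, , drop = FALSE]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3)
  score_vs <- function(seqs, target) {
    s1 <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs), target, type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 3))
    s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(revcomp(seqs)), target, type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 3))
    pmax(s1, s2)
  }
  sr <- score_vs(reads$seq, allele_pair$ref_allele)
  sa <- score_vs(reads$seq, allele_pair$alt_allele)
  pr <- tapply(sr, reads$qname, sum)
  pa <- tapply(sa, reads$qname, sum)
  gap <- pa - pr[names(pa)]
  best <- ifelse(gap > 0, "alt", ifelse(gap < 0, "ref", "tie"))
  q <- pmin(60, 2 * abs(gap))
  data.frame(qname = names(pa), best = unname(best), q = unname(q),
             stringsAsFactors = FALSE)
}

#' Genotype likelihoods from pair mappings
#'
#' Treating each pair's confidence as an error probability
#' `e = 10^(-q/10)`: the probability of the pair under its winning allele
#' is `1 - e` and under the other allele `e`; under dosage `d` of the
#' insertion allele at ploidy `p` it is the mixture
#' `(d/p) P(pair|alt) + (1 - d/p) P(pair|ref)`.  Tie pairs (`q = 0`)
#' contribute identically to every dosage and are dropped.
#'
#' @param mappings data.frame from [extract_and_remap()]
#' @param ploidy 1 or 2
#' @return list of class `"genotype_likelihoods"`: `loglik` (natural log,
#'   one per dosage `0..ploidy`), `ploidy`, `n_pairs` (informative pairs)
#' @export
compute_gl <- function(mappings, ploidy = 2L) {
  stopifnot(ploidy %in% c(1L, 2L))
  m <- mappings[mappings$best != "tie" & mappings$q > 0, , drop = FALSE]
  d <- 0:ploidy
  ll <- numeric(length(d))
  if (nrow(m)) {
    e <- 10^(-m$q / 10)
    p_alt <- ifelse(m$best == "alt", 1 - e, e)
    p_ref <- ifelse(m$best == "alt", e, 1 - e)
    for (i in seq_along(d)) {
      w <- d[i] / ploidy
      ll[i] <- sum(log(w * p_alt + (1 - w) * p_ref))
    }
  }
  structure(list(loglik = ll, ploidy = ploidy, n_pairs = nrow(m)),
            class = "genotype_likelihoods")
}

#' @keywords internal
hwe_prior <- function(f, ploidy) {
  if (ploidy == 1L) c(1 - f, f)
  else c((1 - f)^2, 2 * f * (1 - f), f^2)
}

#' EM estimate of the insertion allele frequency
#'
#' Ploidy-aware EM under Hardy-Weinberg equilibrium: E-step computes each
#' sample's posterior dosage under HWE priors at the current `f`; M-step
#' sets `f` to the expected dosage fraction.  The marginal log-likelihood
#' is non-decreasing.
#'
#' @param gls list of `"genotype_likelihoods"` (one per sample)
#' @param f0 initial frequency (default 0.5)
#' @param tol convergence tolerance on `|delta f|` (default 1e-6)
#' @param max_iter iteration cap (default 100)
#' @return list of class `"af_estimate"`: `f`, `iterations`, `converged`,
#'   `loglik_trace`
#' @export
em_allele_frequency <- function(gls, f0 = 0.5, tol = 1e-6,
                                max_iter = 100L) {
  stopifnot(length(gls) >= 1L)
  f <- f0
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    num <- 0; den <- 0; ll <- 0
    for (g in gls) {
      pri <- hwe_prior(f, g$ploidy)
      w <- pri * exp(g$loglik - max(g$loglik))
      ll <- ll + log(sum(w)) + max(g$loglik)
      post <- w / sum(w)
      num <- num + sum(post * (0:g$ploidy))
      den <- den + g$ploidy
    }
    trace <- c(trace, ll)
    f_new <- num / den
    if (abs(f_new - f) < tol) {
      f <- f_new; converged <- TRUE
      break
    }
    f <- f_new
  }
  structure(list(f = f, iterations = it, converged = converged,
                 loglik_trace = trace), class = "af_estimate")
}

#' Posterior genotype calls
#'
#' Combines HWE priors at allele frequency `f` with the genotype
#' likelihoods; the called dosage is the posterior argmax (ties toward
#' the lower dosage).
#'
#' @param gls list of `"genotype_likelihoods"` (one per sample; names are
#'   sample ids)
#' @param f allele frequency in `[0, 1]`
#' @return data.frame: `sample`, `ploidy`, `dosage`, posterior per dosage
#'   (`post0`, `post1`, `post2`; `post2` `NA` for haploids), `n_pairs`
#' @export
call_genotypes <- function(gls, f) {
  stopifnot(f >= 0, f <= 1)
  rows <- lapply(seq_along(gls), function(i) {
    g <- gls[[i]]
    pri <- hwe_prior(f, g$ploidy)
    w <- pri * exp(g$loglik - max(g$loglik))
    post <- w / sum(w)
    d <- which.max(post) - 1L     # first maximum = lower dosage on ties
    data.frame(sample = names(gls)[i] %||% as.character(i),
               ploidy = g$ploidy, dosage = d,
               post0 = post[1], post1 = post[2],
               post2 = if (g$ploidy == 2L) post[3] else NA_real_,
               n_pairs = g$n_pairs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype concordance
#'
#' Fraction of matched (site, sample) keys with identical calls.
#'
#' @param calls,truth data.frames with columns `key` and `dosage`
#' @return list: `concordance` (fraction), `matching`, `total`,
#'   `percent` (printed convention: rounded to the nearest integer)
#' @export
concordance <- function(calls, truth) {
  i <- match(calls$key, truth$key)
  if (anyNA(i)) stop("call/truth keys do not match")
  if (nrow(calls) == 0L) stop("no calls to compare")
  ok <- calls$dosage == truth$dosage[i]
  list(concordance = mean(ok), matching = sum(ok), total = length(ok),
       percent = round_half_up(100 * mean(ok), 0))
}

#' Write genotyped sites as VCF 4.2
#'
#' One record per site with symbolic ALT `<INS:ME:ALU>`; INFO carries
#' SVLEN, TSD, SUBFAMILY and the EM allele frequency, FORMAT is
#' GT:GL:DP (GL in log10).
#'
#' @param sites list of per-site lists: `call` (breakpoint_call), `af`
#'   (af_estimate), `genotypes` (from [call_genotypes()]),
#'   `gls` (list of genotype_likelihoods), `subfamily`
#' @param genome reference genome
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(sites, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=INS:ME:ALU,Description=\"Alu mobile element insertion\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion length\">",
           "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
           "##INFO=<ID=SUBFAMILY,Number=1,Type=String,Description=\"Alu subfamily\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"EM allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Informative pairs\">",
           sprintf("##contig=<ID=%s,length=%d>", names(unclass(genome)),
                   nchar(unclass(genome))))
  samples <- unique(unlist(lapply(sites, function(s) s$genotypes$sample)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  body <- vapply(sites, function(s) {
    cl <- s$call
    pos1 <- cl$left_bp + 1L            # 1-based position of last ref base
    refbase <- substr(unclass(genome)[[cl$chrom]], pos1, pos1)
    gt <- vapply(samples, function(sm) {
      r <- s$genotypes[s$genotypes$sample == sm, , drop = FALSE]
      if (nrow(r) == 0L) return("./.")
      g <- s$gls[[sm]]
      gl10 <- paste(sprintf("%.2f", g$loglik / log(10)), collapse = ",")
      gts <- if (r$ploidy == 2L) c("0/0", "0/1", "1/1") else c("0", "1")
      paste(gts[r$dosage + 1L], gl10, r$n_pairs, sep = ":")
    }, character(1))
    info <- sprintf("SVLEN=%d;TSD=%s;SUBFAMILY=%s;AF=%.4f",
                    nchar(cl$inserted_seq),
                    if (nzchar(cl$tsd)) cl$tsd else ".",
                    s$subfamily %||% cl$target, s$af$f)
    paste(c(cl$chrom, pos1, s$id %||% ".", refbase, "<INS:ME:ALU>", ".",
            "PASS", info, "GT:GL:DP", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
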