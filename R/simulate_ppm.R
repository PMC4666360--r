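# L1 endonuclease nic-site model: a position probability matrix over a 5-bp
# motif, and rejection sampling of insertion sites proportional to the
# PPM-implied site probability.

#' Build a position probability matrix from nic-site sequences
#'
#' `probs[b, j] = (count of b at column j + pseudocount) / (n + 4 * pseudocount)`.
#' The pseudocount is applied per base per column so that unobserved bases
#' retain non-zero sampling probability.
#'
#' @param nic_sites character vector of equal-length `{A,C,G,T}` strings
#' @param pseudocount non-negative pseudocount (default 1)
#' @return matrix of class `"ppm"` with rows `A,C,G,T`, one column per motif
#'   position; every column sums to 1.
#' @export
build_ppm <- function(nic_sites, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  if (length(nic_sites) == 0L && pseudocount == 0)
    stop("empty site list with pseudocount 0")
  w <- unique(nchar(nic_sites))
  if (length(w) > 1L) stop("nic sites must all have the same length")
  w <- if (length(w)) w else stop("cannot infer motif width from empty input")
  if (any(grepl("[^ACGT]", nic_sites)))
    stop("nic sites must be over {A,C,G,T}")
  m <- do.call(rbind, strsplit(nic_sites, "", fixed = TRUE))
  n <- length(nic_sites)
  probs <- vapply(seq_len(w), function(j) {
    cnt <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  probs <- matrix(probs, nrow = 4, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
  structure(probs, class = "ppm", n_sites = n, pseudocount = pseudocount)
}

#' Probability of a nic-site window under a PPM
#'
#' The product over motif columns of the column probability of the observed
#' base.  On the minus strand the window is reverse-complemented before
#' scoring.  Any `N` in the window gives probability 0.
#'
#' @param ppm a `"ppm"` matrix
#' @param window nucleotide string of length `ncol(ppm)`
#' @param strand `"+"` or `"-"`
#' @return probability in `[0, 1]`
#' @export
site_probability <- function(ppm, window, strand = "+") {
  if (nchar(window) != ncol(ppm))
    stop("window length ", nchar(window), " != PPM width ", ncol(ppm))
  if (strand == "-") window <- revcomp(window)
  b <- match(chars(window), rownames(ppm))
  if (anyNA(b)) return(0)
  prod(ppm[cbind(b, seq_along(b))])
}

# vectorized window scoring used by the sampler
#' @keywords internal
site_probability_batch <- function(ppm, windows, strands) {
  neg <- strands == "-"
  windows[neg] <- revcomp(windows[neg])
  m <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  p <- rep(1, length(windows))
  for (j in seq_len(ncol(ppm))) {
    pj <- unname(ppm[, j][m[, j]])
    pj[is.na(pj)] <- 0
    p <- p * pj
  }
  p
}

#' Rejection-sample insertion sites matching the nic-site model
#'
#' Draws a uniform genomic position and strand, scores the 5'-anchored
#' motif-width window at that position with the PPM (reverse-complemented on
#' the minus strand), samples a uniform deviate `p` and accepts the site iff
#' `p < P`.  Positions inside `mask` intervals are rejected before scoring.
#' Repeats until `n` sites are accepted.
#'
#' @param genome genome object
#' @param ppm a `"ppm"` matrix
#' @param n number of sites to accept
#' @param mask optional `repeat_catalog` exclusion mask (already padded)
#' @param seed optional RNG seed
#' @param attempt_cap maximum attempts per requested site before erroring
#'   (guards against an everywhere-zero acceptance probability)
#' @return data.frame with columns `chrom`, `pos` (0-based window start),
#'   `strand`, `prob`
#' @export
sample_insertion_sites <- function(genome, ppm, n, mask = NULL, seed = NULL,
                                   attempt_cap = 1e7) {
  stopifnot(n >= 1)
  seqs <- unclass(genome)
  w <- ncol(ppm)
  lens <- nchar(seqs)
  if (any(lens < w)) stop("genome sequence shorter than motif width")
  local_seed(seed, {
    wt <- (lens - w + 1) / sum(lens - w + 1)
    acc_chrom <- character(); acc_pos <- integer()
    acc_strand <- character(); acc_prob <- numeric()
    attempts <- 0
    batch <- max(1000L, min(50000L, n * 20L))
    while (length(acc_pos) < n) {
      if (attempts > attempt_cap * n)
        stop("rejection sampler exceeded attempt cap (",
             format(attempt_cap, scientific = TRUE), " per site); ",
             "acceptance probability may be zero everywhere")
      ci <- sample(names(seqs), batch, replace = TRUE, prob = wt)
      pos <- floor(runif(batch) * (lens[ci] - w + 1))
      strand <- ifelse(runif(batch) < 0.5, "+", "-")
      attempts <- attempts + batch
      keep <- !in_mask(ci, pos, mask)
      if (!any(keep)) next
      ci <- ci[keep]; pos <- pos[keep]; strand <- strand[keep]
      win <- substr(seqs[ci], pos + 1L, pos + w)
      P <- site_probability_batch(ppm, win, strand)
      acc <- runif(length(P)) < P
      if (any(acc)) {
        acc_chrom <- c(acc_chrom, ci[acc])
        acc_pos <- c(acc_pos, as.integer(pos[acc]))
        acc_strand <- c(acc_strand, strand[acc])
        acc_prob <- c(acc_prob, P[acc])
      }
    }
    idx <- seq_len(n)
    data.frame(chrom = acc_chrom[idx], pos = acc_pos[idx],
               strand = acc_strand[idx], prob = acc_prob[idx],
               stringsAsFactors = FALSE)
  })
}

#' Default synthetic L1-EN nic-site list
#'
#' The published 99 experimentally determined 5-bp nic sites are not
#' redistributable; the package ships a clearly synthetic stand-in list of
#' 99 sites drawn once from a TT|AAA-biased model (see
#' `inst/extdata/nic_sites_synthetic.txt`).
#'
#' @return character vector of 99 5-bp sites
#' @export
default_nic_sites <- function() {
  path <- system.file("extdata", "nic_sites_synthetic.txt",
                      package = "aluvar", mustWork = TRUE)
  readLines(path)
}

#' @export
print.ppm <- function(x, ...) {
  cat("position probability matrix:", ncol(x), "columns, built from",
      attr(x, "n_sites"), "sites (pseudocount", attr(x, "pseudocount"),
      ")\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}
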