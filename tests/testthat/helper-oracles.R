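# Independent oracles and small fixture builders shared across tests.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

tiny_genome <- function(seqs) structure(seqs, class = "genome")

# Brute-force affine-gap global alignment score (Gotoh recurrences written
# independently in R; no traceback).  Gap of length L costs open + L * ext.
oracle_global_score <- function(q, r, match = 5, mismatch = -4,
                                open = 16, ext = 4) {
  qn <- strsplit(q, "")[[1]]; rn <- strsplit(r, "")[[1]]
  n <- length(qn); m <- length(rn)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in reference
  Y <- matrix(NEG, n + 1, m + 1)  # gap in query
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  s <- function(a, b) if (a == "N" || b == "N" || a != b) mismatch else match
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      s(qn[i - 1], rn[j - 1])
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                   Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive per-column argmax oracle for the breakpoint score tracks.
oracle_breakpoints <- function(labels) {
  n <- length(labels)
  inc_l <- ifelse(labels %in% c("1", "*"), 1,
                  ifelse(labels == "N", -1, -3))
  inc_r <- ifelse(labels %in% c("2", "*"), 1,
                  ifelse(labels == "N", -1, -3))
  left <- vapply(seq_len(n), function(k) sum(inc_l[1:k]), numeric(1))
  right <- vapply(seq_len(n), function(k) sum(inc_r[k:n]), numeric(1))
  list(left_col = max(which(left == max(left))),
       right_col = min(which(right == max(right))),
       left = left, right = right)
}

# a synthetic threeway_alignment with given labels over a reference of
# matching length (bases chosen consistently with each label)
fake_threeway <- function(labels) {
  n <- length(labels)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  left <- right <- character(n)
  for (i in seq_len(n)) {
    if (labels[i] == "*") { left[i] <- ref[i]; right[i] <- ref[i] }
    else if (labels[i] == "1") { left[i] <- ref[i]; right[i] <- other(ref[i]) }
    else if (labels[i] == "2") { right[i] <- ref[i]; left[i] <- other(ref[i]) }
    else { left[i] <- other(ref[i]); right[i] <- other(ref[i]) }
  }
  structure(list(ref = ref, left = left, right = right,
                 ref_pos = seq_len(n) - 1L, label = labels),
            class = "threeway_alignment")
}

# grid-search maximizer of the EM marginal likelihood
oracle_grid_af <- function(gls, step = 0.001) {
  fs <- seq(0, 1, by = step)
  ll <- vapply(fs, function(f) {
    sum(vapply(gls, function(g) {
      pri <- if (g$ploidy == 1) c(1 - f, f) else
        c((1 - f)^2, 2 * f * (1 - f), f^2)
      mx <- max(g$loglik)
      log(sum(pri * exp(g$loglik - mx))) + mx
    }, numeric(1)))
  }, numeric(1))
  fs[which.max(ll)]
}

# genotype likelihoods object from dosage counts of q-scored pairs
gl_from_pairs <- function(n_ref, n_alt, q = 30, ploidy = 2L) {
  n <- n_ref + n_alt
  m <- data.frame(qname = sprintf("p%03d", seq_len(n)),
                  best = c(rep("ref", n_ref), rep("alt", n_alt)),
                  q = rep_len(q, n), stringsAsFactors = FALSE)
  compute_gl(m, ploidy = ploidy)
}

# a small simulated world shared by discovery/assembly/breakpoint tests
cached_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      cfg <- pipeline_config(seed = 5)
      w <<- simulate_world(cfg, genome_length = 200000L, n_implants = 5L,
                           n_ref_alu = 6L)
    }
    w
  }
})

cached_run <- local({
  r <- NULL
  function() {
    if (is.null(r)) {
      w <- cached_world()
      r <<- discover_and_assemble(w$alignments, w$genome, w$catalog,
                                  w$library, pipeline_config(seed = 5))
    }
    r
  }
})
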