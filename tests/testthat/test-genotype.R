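test_that("allele construction honours TSD duplication and deletions", {
  w <- cached_world()
  run <- cached_run()
  cl <- Filter(function(x) isTRUE(x$genotypable), run$calls)[[1]]
  ap <- build_alleles(cl, w$genome)
  # shared flanks and the length identity
  expect_identical(substr(ap$alt_allele, 1, 600),
                   substr(ap$ref_allele, 1, 600))
  expect_identical(substr(ap$alt_allele, nchar(ap$alt_allele) - 599,
                          nchar(ap$alt_allele)),
                   substr(ap$ref_allele, nchar(ap$ref_allele) - 599,
                          nchar(ap$ref_allele)))
  expect_equal(nchar(ap$alt_allele),
               nchar(ap$ref_allele) + nchar(cl$inserted_seq) +
                 cl$overlap_len - cl$target_deletion)
  # a TSD site carries the duplicated segment twice around the insertion
  if (cl$tsd_len > 0) {
    expect_equal(length(gregexpr(cl$tsd, ap$alt_allele,
                                 fixed = TRUE)[[1]]) >=
                 length(gregexpr(cl$tsd, ap$ref_allele,
                                 fixed = TRUE)[[1]]) + 1, TRUE)
  }
})

test_that("remapping separates junction pairs from reference pairs", {
  w <- cached_world()
  run <- cached_run()
  cl <- Filter(function(x) isTRUE(x$genotypable), run$calls)[[1]]
  ap <- build_alleles(cl, w$genome)
  mp <- extract_and_remap(w$alignments, ap)
  expect_gt(nrow(mp), 0)
  # the carrier is haploid for the insertion: alt evidence dominates
  expect_gt(sum(mp$best == "alt"), 0)
  expect_equal(sum(mp$best == "ref" & mp$q > 10), 0)
  expect_true(all(mp$q[mp$best == "tie"] == 0))
})

test_that("genotype likelihoods match closed-form arithmetic", {
  # one alt pair at q=30: likelihood proportional to (0.001, 0.5, 0.999)
  gl <- gl_from_pairs(0, 1, q = 30)
  expect_equal(exp(gl$loglik), c(0.001, 0.5005, 0.999), tolerance = 1e-3)
  # zero informative pairs: flat
  expect_true(all(compute_gl(data.frame(qname = "a", best = "tie",
                                        q = 0))$loglik == 0))
  # balanced evidence puts the diploid maximum at d = 1
  gl2 <- gl_from_pairs(5, 5, q = 30)
  expect_equal(which.max(gl2$loglik) - 1L, 1L)
  # permutation invariance and doubling
  m <- data.frame(qname = letters[1:6],
                  best = c("alt", "ref", "alt", "alt", "ref", "alt"),
                  q = c(30, 20, 10, 60, 30, 25))
  a <- compute_gl(m); b <- compute_gl(m[sample(6), ])
  expect_equal(a$loglik, b$loglik)
  dbl <- compute_gl(rbind(m, transform(m, qname = paste0(qname, "2"))))
  expect_equal(dbl$loglik, 2 * a$loglik)
})

test_that("EM frequency estimation: symmetry, boundary, oracle", {
  certain <- function(d, ploidy = 2L) {
    ll <- rep(-200, ploidy + 1); ll[d + 1] <- 0
    structure(list(loglik = ll, ploidy = ploidy, n_pairs = 10L),
              class = "genotype_likelihoods")
  }
  est <- em_allele_frequency(list(certain(0), certain(2)))
  expect_equal(est$f, 0.5, tolerance = 1e-4)
  est2 <- em_allele_frequency(list(certain(2), certain(2), certain(2)))
  expect_gt(est2$f, 0.999)
  expect_true(all(diff(est$loglik_trace) > -1e-9))
  # grid-search oracle agreement on random noisy panels
  set.seed(79)
  for (trial in 1:20) {
    gls <- lapply(1:12, function(i) {
      nref <- sample(0:6, 1); nalt <- sample(0:6, 1)
      pl <- sample(c(1L, 2L), 1)
      gl_from_pairs(nref, nalt, q = sample(c(10, 20, 30), 1), ploidy = pl)
    })
    est <- em_allele_frequency(gls)
    expect_lt(abs(est$f - oracle_grid_af(gls)), 0.002)
    expect_true(all(diff(est$loglik_trace) > -1e-9))
  }
})

test_that("EM recovers the true frequency on simulated panels", {
  set.seed(83)
  for (f_true in c(0.1, 0.3, 0.5)) {
    for (rep in 1:3) {
      # informative pairs proportional to dosage: 5 alt-supporting pairs
      # per alt haplotype and 5 ref-supporting per ref haplotype
      gls <- lapply(1:30, function(i) {
        d <- rbinom(1, 2, f_true)
        gl_from_pairs(5 * (2 - d), 5 * d, q = 30)
      })
      est <- em_allele_frequency(gls)
      se <- sqrt(f_true * (1 - f_true) / 60)
      expect_lt(abs(est$f - f_true), 3 * se + 0.02)
    }
  }
})

test_that("posterior genotype calls follow prior-times-likelihood", {
  flat <- structure(list(loglik = c(0, 0, 0), ploidy = 2L, n_pairs = 0L),
                    class = "genotype_likelihoods")
  gt <- call_genotypes(list(s1 = flat), f = 0.1)
  expect_equal(gt$dosage, 0L)     # prior (0.81, 0.18, 0.01) dominates
  expect_equal(gt$post0, 0.81)
  # L proportional to (0.001, 0.5, 0.999) under HWE(0.5) priors
  # (0.25, 0.5, 0.25): posteriors (0.0005, 0.5005, 0.4990) -> d = 1
  strong <- structure(list(loglik = log(c(0.001, 0.5, 0.999)), ploidy = 2L,
                           n_pairs = 1L), class = "genotype_likelihoods")
  gt2 <- call_genotypes(list(s1 = strong), f = 0.5)
  expect_equal(gt2$dosage, 1L)
  expect_gt(gt2$post1, gt2$post2)
  # stronger evidence overrides the heterozygote prior weight
  vstrong <- structure(list(loglik = log(c(1e-6, 0.3, 0.999)), ploidy = 2L,
                            n_pairs = 2L), class = "genotype_likelihoods")
  expect_equal(call_genotypes(list(s1 = vstrong), f = 0.5)$dosage, 2L)
  # haploid samples never get heterozygous calls
  set.seed(89)
  for (i in 1:20) {
    g <- gl_from_pairs(sample(0:5, 1), sample(0:5, 1), q = 30, ploidy = 1L)
    gt3 <- call_genotypes(list(m = g), f = runif(1))
    expect_true(gt3$dosage %in% c(0L, 1L))
    expect_true(is.na(gt3$post2))
  }
})

test_that("concordance arithmetic and key contract", {
  calls <- data.frame(key = sprintf("s%03d", 1:110),
                      dosage = c(rep(1, 109), 2))
  truth <- data.frame(key = sprintf("s%03d", 1:110), dosage = rep(1, 110))
  cc <- concordance(calls, truth)
  expect_equal(cc$matching, 109L)
  expect_equal(cc$percent, 99)
  expect_identical(concordance(truth, truth)$concordance, 1)
  expect_error(concordance(data.frame(key = "x", dosage = 1), truth),
               "keys")
})

test_that("VCF output is well-formed", {
  w <- cached_world()
  run <- cached_run()
  cl <- Filter(function(x) isTRUE(x$genotypable), run$calls)[[1]]
  ap <- build_alleles(cl, w$genome)
  mp <- extract_and_remap(w$alignments, ap)
  gl <- compute_gl(mp, ploidy = 1L)
  gls <- list(sample1 = gl)
  af <- em_allele_frequency(gls)
  sites <- list(list(call = cl, af = af, gls = gls, id = "site1",
                     genotypes = call_genotypes(gls, af$f),
                     subfamily = cl$target))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sites, w$genome, p)
  lines <- readLines(p)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  f <- strsplit(body, "\t")[[1]]
  expect_identical(f[5], "<INS:ME:ALU>")
  expect_match(f[8], "SVLEN=")
  expect_match(f[10], "^1:")
})
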