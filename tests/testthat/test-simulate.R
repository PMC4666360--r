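test_that("build_ppm matches hand-computed probabilities", {
  p <- build_ppm(c("A", "C", "G", "T"), 0)
  expect_true(all(abs(p - 0.25) < 1e-12))
  p2 <- build_ppm(c("A", "A"), 1)
  expect_equal(unname(p2["A", 1]), 3 / 6)
  expect_equal(unname(p2["C", 1]), 1 / 6)
  # 99 five-base sites with pseudocount 1: columns sum to 1, unobserved
  # bases get 1/103
  set.seed(3)
  sites <- replicate(99, paste(sample(c("A", "C", "G"), 5, TRUE),
                               collapse = ""))
  p3 <- build_ppm(sites, 1)
  expect_equal(ncol(p3), 5L)
  expect_true(all(abs(colSums(p3) - 1) < 1e-9))
  expect_true(all(p3["T", ] == 1 / 103))
  expect_error(build_ppm(c("AA", "A")), "same length")
  expect_error(build_ppm(character(), 0), "empty")
})

test_that("adding an observation strictly increases that base's probability", {
  set.seed(7)
  sites <- replicate(20, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                               collapse = ""))
  p <- build_ppm(sites, 1)
  p2 <- build_ppm(c(sites, "AAAA"), 1)
  expect_true(all(p2["A", ] > p["A", ]))
})

test_that("site_probability multiplies columns and handles strand and N", {
  p <- build_ppm(c("AA", "AC"), 0)
  expect_equal(site_probability(p, "AC", "+"), 0.5)
  expect_equal(site_probability(p, "AN", "+"), 0)
  expect_error(site_probability(p, "ACG", "+"), "width")
  # minus strand scores the reverse complement
  expect_equal(site_probability(p, "GT", "-"),
               site_probability(p, "AC", "+"))
  u <- build_ppm(c("AAAAA", "CCCCC", "GGGGG", "TTTTT"), 0)
  expect_equal(site_probability(u, "ACGTA", "+"), 0.25^5)
})

test_that("rejection sampler respects the mask and the attempt cap", {
  set.seed(11)
  g <- tiny_genome(c(chr1 = rand_seq(20000)))
  ppm <- build_ppm(default_nic_sites(), 1)
  mask <- repeat_catalog("chr1", 5000L, 15000L, "+", "Alu")
  s <- sample_insertion_sites(g, ppm, 300, mask = mask, seed = 2)
  expect_equal(nrow(s), 300L)
  expect_false(any(s$pos >= 5000 & s$pos < 15000))
  # strand ratio within a generous binomial band
  expect_gt(mean(s$strand == "+"), 0.35)
  expect_lt(mean(s$strand == "+"), 0.65)
  # full-genome mask cannot terminate
  full <- repeat_catalog("chr1", 0L, 20000L, "+", "Alu")
  expect_error(sample_insertion_sites(g, ppm, 1, mask = full, seed = 1,
                                      attempt_cap = 1e4),
               "attempt cap")
  # determinism under a fixed seed
  s2 <- sample_insertion_sites(g, ppm, 50, seed = 9)
  s3 <- sample_insertion_sites(g, ppm, 50, seed = 9)
  expect_identical(s2, s3)
})

test_that("a unique certain 5-mer attracts every accepted site", {
  g <- tiny_genome(c(chr1 = paste0(strrep("C", 100), "TTAAA",
                                   strrep("G", 100))))
  ppm <- build_ppm("TTAAA", 0)  # probability 1 at the motif, 0 elsewhere
  s <- sample_insertion_sites(g, ppm, 20, seed = 3)
  # acceptance only at the motif (either strand scores 0 elsewhere)
  expect_true(all(s$pos == 100 & s$strand == "+"))
})

test_that("implant construction matches hand-built haplotypes", {
  g <- tiny_genome(c(chr1 = "AAAACCCCGGGG"))
  lib <- c(X = "TTTT")
  sp <- data.frame(chrom = "chr1", site = 8L, strand = "+", subfamily = "X",
                   truncation_offset = 0L, tsd_length = 4L,
                   target_deletion = 0L, polyA_length = 0L, rate = 0)
  imp <- implant_insertions(g, sp, lib)
  expect_identical(unclass(imp$haplotype)[["chr1"]], "AAAACCCCTTTTCCCCGGGG")
  # blunt insertion: length adds exactly the element length
  sp$tsd_length <- 0L
  expect_equal(nchar(unclass(implant_insertions(g, sp, lib)$haplotype)[[1]]),
               12L + 4L)
  # target deletion removes bases at the target
  sp$target_deletion <- 3L
  expect_equal(nchar(unclass(implant_insertions(g, sp, lib)$haplotype)[[1]]),
               12L - 3L + 4L)
  # minus strand inserts the reverse complement as a unit
  sp2 <- data.frame(chrom = "chr1", site = 8L, strand = "-", subfamily = "X",
                    truncation_offset = 1L, tsd_length = 2L,
                    target_deletion = 0L, polyA_length = 3L, rate = 0)
  imp2 <- implant_insertions(g, sp2, c(X = "TGCA"))
  # insert = revcomp(GCA + AAA) = TTTTGC, then the 2-base duplicate "CC"
  expect_identical(unclass(imp2$haplotype)[["chr1"]],
                   "AAAACCCCTTTTGCCCGGGG")
  expect_error(implant_insertions(g, rbind(sp, sp), lib), "overlapping")
})

test_that("TSD round-trip identity holds across a simulated cohort", {
  set.seed(13)
  g <- tiny_genome(c(chr1 = rand_seq(60000)))
  lib <- synthetic_alu_library()
  ppm <- build_ppm(default_nic_sites(), 1)
  sites <- sample_insertion_sites(g, ppm, 12, seed = 4)
  sites <- sites[order(sites$pos), ]
  sites <- sites[c(TRUE, diff(sites$pos) > 1500), ]
  specs <- draw_implant_specs(sites, lib, seed = 5)
  imp <- implant_insertions(g, specs, lib)
  hap <- unclass(imp$haplotype)[["chr1"]]
  for (k in seq_len(nrow(imp$truth))) {
    t <- imp$truth[k, ]
    if (t$tsd_length == 0) next
    dup <- extract_sequence(g, "chr1", t$site - t$tsd_length, t$site)
    inserted_block <- substr(hap, t$hap_pos + 1L, t$hap_pos + t$ins_len)
    expect_identical(substr(inserted_block,
                            t$ins_len - t$tsd_length + 1L, t$ins_len), dup)
  }
})

test_that("read simulator honours coverage, errors, and determinism", {
  set.seed(17)
  g <- tiny_genome(c(chr1 = rand_seq(10000)))
  a <- simulate_paired_reads(g, coverage = 30, read_len = 100,
                             frag_mean = 300, frag_sd = 20, seed = 21)
  np <- nrow(a) / 2
  lambda <- 30 * 10000 / 200
  expect_lt(abs(np - lambda), 5 * sqrt(lambda))
  # error-free reads are perfect substrings of the haplotype
  idx <- sample(nrow(a), 50)
  expect_true(all(vapply(idx, function(i)
    grepl(a$seq[i], unclass(g)[["chr1"]], fixed = TRUE), logical(1))))
  # same seed, byte-identical FASTQ
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_fastq(simulate_paired_reads(g, 5, seed = 7), f1, f2)
  write_fastq(simulate_paired_reads(g, 5, seed = 7), g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  # nonzero error rate perturbs about the expected number of bases
  ae <- simulate_paired_reads(g, coverage = 10, error_rate = 0.01,
                              seed = 3)
  mm <- mean(!vapply(seq_len(200), function(i)
    grepl(ae$seq[i], unclass(g)[["chr1"]], fixed = TRUE), logical(1)))
  expect_gt(mm, 0.3)  # P(read has >=1 error) ~ 1 - 0.99^101 ~ 0.64
})

test_that("SAM round trip preserves the alignment table essentials", {
  w <- cached_world()
  a <- w$alignments[1:400, ]
  p <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, w$genome, p)
  b <- read_sam(p)
  expect_equal(nrow(b), nrow(a))
  i <- match(paste0(a$qname, "/", a$mate), paste0(b$qname, "/", b$mate))
  expect_false(anyNA(i))
  expect_equal(b$pos[i], a$pos)
  expect_identical(b$cigar[i], a$cigar)
  expect_identical(b$seq[i], a$seq)
  expect_identical(b$mapped[i], a$mapped)
})
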