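test_that("global aligner reproduces hand alignments", {
  s <- rand_seq(20)
  a <- global_align(s, s)
  expect_equal(a$score, 100)
  expect_identical(a$pattern, a$subject)
  # single deletion costs open + extend
  b <- global_align("ACGT", "ACT")
  expect_identical(b$pattern, "ACGT")
  expect_identical(b$subject, "AC-T")
  expect_equal(b$score, 3 * 5 - 20)
  # fit mode places the query freely inside the reference
  f <- global_align("TTTT", "AAAATTTTCCCC", mode = "fit")
  expect_equal(f$score, 20)
  expect_equal(c(f$ref_start, f$ref_end), c(4, 8))
})

test_that("global aligner matches the brute-force DP oracle", {
  set.seed(47)
  for (i in 1:50) {
    q <- rand_seq(sample(5:30, 1))
    r <- rand_seq(sample(5:30, 1))
    expect_equal(global_align(q, r)$score, oracle_global_score(q, r),
                 info = paste(q, r))
  }
})

test_that("three-way merge labels columns per the 1/2/*/N scheme", {
  ref <- rand_seq(40)
  la <- global_align(ref, ref, mode = "fit")
  ra <- global_align(ref, ref, mode = "fit")
  tw <- merge_threeway(la, ra)
  expect_true(all(tw$label == "*"))
  expect_equal(length(tw$label), 40L)
  expect_error(merge_threeway(la, global_align(ref, rand_seq(40),
                                               mode = "fit")),
               "same reference")
  # disjoint half coverage gives a '1' run then a '2' run
  set.seed(49)
  ref2 <- rand_seq(60)
  la2 <- global_align(substr(ref2, 1, 30), ref2, mode = "fit")
  ra2 <- global_align(substr(ref2, 31, 60), ref2, mode = "fit")
  tw2 <- merge_threeway(la2, ra2)
  expect_identical(paste(tw2$label, collapse = ""),
                   paste0(strrep("1", 30), strrep("2", 30)))
  # a 5 bp TSD fixture: central 5 columns are '*'
  la3 <- global_align(substr(ref2, 1, 35), ref2, mode = "fit")
  ra3 <- global_align(substr(ref2, 31, 60), ref2, mode = "fit")
  tw3 <- merge_threeway(la3, ra3)
  expect_identical(paste(tw3$label[31:35], collapse = ""), "*****")
  # label conservation: exactly one label per column
  expect_equal(sum(tw3$label %in% c("*", "1", "2", "N")), length(tw3$label))
})

test_that("breakpoint scoring matches the exhaustive argmax oracle", {
  set.seed(53)
  for (i in 1:200) {
    labs <- sample(c("*", "1", "2", "N"), sample(10:80, 1), replace = TRUE,
                   prob = c(.2, .35, .35, .1))
    tw <- fake_threeway(labs)
    got <- score_breakpoints(tw)
    want <- oracle_breakpoints(labs)
    expect_equal(got$left_track, want$left)
    expect_equal(got$right_track, want$right)
    expect_equal(got$left_bp, want$left_col - 1L)
    expect_equal(got$right_bp, want$right_col - 1L)
  }
})

test_that("overlap geometry and TSD refinement follow the breakpoints", {
  # blunt: '1'-run then '2'-run, no overlap, no deletion
  tw <- fake_threeway(c(rep("1", 20), rep("2", 20)))
  sb <- score_breakpoints(tw)
  expect_equal(sb$overlap_len, 0L)
  expect_equal(sb$target_deletion, 0L)
  expect_identical(refine_tsd(sb, tw)$tsd, "")
  # 14 bp TSD: overlap 14 and a 14-base refined TSD
  tw2 <- fake_threeway(c(rep("1", 20), rep("*", 14), rep("2", 20)))
  sb2 <- score_breakpoints(tw2)
  expect_equal(sb2$overlap_len, 14L)
  r2 <- refine_tsd(sb2, tw2)
  expect_equal(r2$tsd_len, 14L)
  expect_identical(r2$tsd, paste(tw2$ref[21:34], collapse = ""))
  # overlap larger than the identical run: TSD shorter than overlap
  labs3 <- c(rep("1", 10), rep("*", 20), "N", rep("*", 25), rep("2", 10))
  tw3 <- fake_threeway(labs3)
  sb3 <- score_breakpoints(tw3)
  expect_equal(sb3$overlap_len, 46L)
  expect_equal(refine_tsd(sb3, tw3)$tsd_len, 25L)
  # deletion: right breakpoint beyond the left one
  tw4 <- fake_threeway(c(rep("1", 20), rep("N", 3), rep("2", 20)))
  sb4 <- score_breakpoints(tw4)
  expect_equal(sb4$target_deletion, 3L)
  expect_equal(sb4$overlap_len, 0L)
})

mk_scaffold <- function(genome, site, lib, fam = "AluYa5", tsd = 14L,
                        tdel = 0L, polyA = 20L, strand = "+",
                        flank = 150L, trunc = 0L) {
  sp <- data.frame(chrom = "chr1", site = site, strand = strand,
                   subfamily = fam, truncation_offset = trunc,
                   tsd_length = tsd, target_deletion = tdel,
                   polyA_length = polyA, rate = 0)
  imp <- implant_insertions(genome, sp, lib)
  hap <- unclass(imp$haplotype)[["chr1"]]
  t <- imp$truth
  list(seq = substr(hap, t$hap_pos - flank + 1L,
                    t$hap_pos + t$ins_len + flank),
       truth = t)
}

test_that("call_site recovers TSDs and target deletions on fixtures", {
  set.seed(59)
  g <- tiny_genome(c(chr1 = rand_seq(6000)))
  lib <- synthetic_alu_library()
  site <- data.frame(chrom = "chr1", pos = 3000L, site_id = "s1")
  # 14 bp TSD
  fx <- mk_scaffold(g, 3000L, lib, tsd = 14L)
  cl <- call_site(fx$seq, g, site, lib)
  expect_s3_class(cl, "breakpoint_call")
  expect_equal(cl$overlap_len, fx$truth$tsd_norm)
  expect_equal(cl$tsd_len, fx$truth$tsd_norm)
  expect_equal(cl$target_deletion, 0L)
  expect_true(cl$genotypable)
  expect_equal(cl$left_bp, 2999L)
  # 3 bp target-site deletion
  fx2 <- mk_scaffold(g, 3000L, lib, tsd = 0L, tdel = 3L)
  cl2 <- call_site(fx2$seq, g, site, lib)
  expect_equal(cl2$target_deletion, fx2$truth$target_deletion_norm)
  expect_equal(cl2$overlap_len, fx2$truth$tsd_norm)
  # a spacer near the element forfeits genotypability
  gappy <- paste0(substr(fx$seq, 1, 30), strrep("N", 300),
                  substr(fx$seq, 101, nchar(fx$seq)))
  cl3 <- call_site(gappy, g, site, lib)
  expect_false(is.null(cl3))
  expect_false(cl3$genotypable)
})

test_that("strand symmetry: minus-strand implants give mirrored calls", {
  set.seed(61)
  g <- tiny_genome(c(chr1 = rand_seq(6000)))
  lib <- synthetic_alu_library()
  site <- data.frame(chrom = "chr1", pos = 3000L, site_id = "s1")
  for (tsd in c(8L, 17L)) {
    fx <- mk_scaffold(g, 3000L, lib, tsd = tsd, strand = "-")
    cl <- call_site(fx$seq, g, site, lib)
    expect_equal(cl$elem_strand, "-")
    expect_equal(cl$tsd_len, fx$truth$tsd_norm)
    # the same scaffold reverse-complemented gives the identical call
    cl2 <- call_site(revcomp(fx$seq), g, site, lib)
    expect_equal(cl2$tsd_len, cl$tsd_len)
    expect_equal(cl2$left_bp, cl$left_bp)
    expect_equal(cl2$right_bp, cl$right_bp)
  }
})

test_that("breakpoint cohort: classification and TSD lengths recovered", {
  # error-free scaffolds across TSD 0-25, deletions 0-6, mixed strands
  set.seed(67)
  g <- tiny_genome(c(chr1 = rand_seq(60000)))
  lib <- synthetic_alu_library()
  n_ok_class <- 0L; n_ok_tsd <- 0L; n <- 60L
  for (i in seq_len(n)) {
    pos <- 1000L + (i - 1L) * 950L
    del <- sample(c(0L, 0L, 0L, 1:6), 1)
    tsd <- if (del > 0L) 0L else sample(0:25, 1)
    fam <- sample(names(lib), 1)
    trunc <- sample(c(0L, 0L, 10L, 60L), 1)
    fx <- mk_scaffold(g, pos, lib, fam = fam, tsd = tsd, tdel = del,
                      strand = sample(c("+", "-"), 1), trunc = trunc)
    site <- data.frame(chrom = "chr1", pos = pos, site_id = "s")
    cl <- call_site(fx$seq, g, site, lib)
    if (is.null(cl) || !isTRUE(cl$genotypable)) next
    want_class <- if (fx$truth$tsd_norm > 0) "overlap"
                  else if (fx$truth$target_deletion_norm > 0) "deletion"
                  else "blunt"
    got_class <- if (cl$overlap_len > 0) "overlap"
                 else if (cl$target_deletion > 0) "deletion" else "blunt"
    if (identical(want_class, got_class)) n_ok_class <- n_ok_class + 1L
    if (cl$tsd_len == fx$truth$tsd_norm) n_ok_tsd <- n_ok_tsd + 1L
  }
  expect_equal(n_ok_class, n)
  expect_gte(n_ok_tsd / n, 0.95)
})
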