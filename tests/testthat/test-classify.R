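test_that("profile construction round-trips its inputs", {
  lib <- synthetic_alu_library()
  prof <- build_profile(lib)
  expect_setequal(names(prof$profile), names(lib))
  L <- unique(nchar(prof$profile))
  expect_length(L, 1L)
  expect_gte(L, max(nchar(lib)))
  for (nm in names(lib))
    expect_identical(gsub("-", "", prof$profile[[nm]]), lib[[nm]])
  # an insertion-bearing consensus yields a gap block in the others
  expect_true(grepl("-", prof$profile[["AluY"]]) ||
              !grepl("-", prof$profile[["AluYb8"]]))
  # two identical sequences: gapless two-row profile
  p2 <- build_profile(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(unname(p2$profile), c("ACGTACGT", "ACGTACGT"))
})

test_that("subfamily assignment: identity, hand-counted divergence, ties", {
  lib <- synthetic_alu_library()
  prof <- build_profile(lib)
  sf <- assign_subfamily(lib[["AluYb8"]], prof)
  expect_identical(sf$subfamily, "AluYb8")
  expect_equal(sf$divergence, 0)
  # three substitutions give divergence 3 / aligned columns
  el <- lib[["AluYa5"]]
  v <- chars(el <- lib[["AluYa5"]])
  v <- strsplit(el, "")[[1]]
  v[c(50, 120, 200)] <- vapply(v[c(50, 120, 200)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  sf2 <- assign_subfamily(paste(v, collapse = ""), prof)
  expect_identical(sf2$subfamily, "AluYa5")
  expect_equal(sf2$divergence, 3 / nchar(el))
  # an element equidistant from two consensuses is unclassified
  a <- strrep("ACGT", 20)
  b <- a; substr(b, 1, 2) <- "TG"   # 2 diffs from a
  mid <- a; substr(mid, 1, 1) <- "T"  # 1 diff from each
  pm <- build_profile(c(one = a, two = b))
  sfm <- assign_subfamily(mid, pm)
  expect_true(sfm$tie)
  expect_identical(sfm$subfamily, "unclassified")
})

test_that("classification is strand-invariant and recovers the generator", {
  lib <- synthetic_alu_library()
  prof <- build_profile(lib)
  set.seed(71)
  n_ok <- 0L; n <- 60L
  for (i in seq_len(n)) {
    fam <- sample(names(lib), 1)
    el <- aluvar:::mutate_sequence(lib[[fam]], 0.03)
    el <- paste0(el, strrep("A", sample(10:30, 1)))
    if (i %% 2 == 0) el <- revcomp(el)
    sf <- assign_subfamily(el, prof)
    if (identical(sf$subfamily, fam)) n_ok <- n_ok + 1L
    if (i <= 5) {
      sf2 <- assign_subfamily(revcomp(el), prof)
      expect_identical(sf2$subfamily, sf$subfamily)
      expect_equal(sf2$divergence, sf$divergence)
    }
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("poly-A trimming finds the mostly-A 3' tail", {
  expect_identical(trim_polyA("ACGTACGTAAAAAAAAAA"), "ACGTACGT")
  expect_identical(trim_polyA("ACGTACGTAAAAGAAAAA"), "ACGTACGT")
  expect_identical(trim_polyA("ACGTACGT"), "ACGTACGT")  # no tail
  expect_identical(trim_polyA("ACGTAAA"), "ACGTAAA")    # below min length
})

test_that("truncation offsets and bins follow the consensus alignment", {
  lib <- synthetic_alu_library()
  cons <- lib[["AluYa5"]]
  full <- measure_truncation(paste0(cons, strrep("A", 20)), cons)
  expect_equal(full$offset, 1L)
  expect_identical(full$bin, "full_length")
  t40 <- measure_truncation(substr(cons, 41, nchar(cons)), cons)
  expect_equal(t40$offset, 41L)
  expect_identical(t40$bin, "short_trunc")
  t100 <- measure_truncation(substr(cons, 101, nchar(cons)), cons)
  expect_equal(t100$offset, 101L)
  expect_identical(t100$bin, "long_trunc")
  expect_identical(aluvar:::truncation_bin(6L), "other")
  expect_identical(aluvar:::truncation_bin(200L), "other")
})

test_that("microhomology counts shared bases at the 5' break", {
  lib <- c(X = paste0("GGCCGG", rand_seq(100), "TCCTG"))
  set.seed(73)
  # engineer a + strand genome whose flank shares exactly 2 bases with the
  # consensus immediately 5' of a truncation at offset 7
  cons <- lib[["X"]]
  flank <- paste0(rand_seq(50), "ZZ")  # placeholder tail
  shared <- substr(cons, 5, 6)         # bases 5' of offset 7
  flank <- paste0(rand_seq(48), "T", shared)  # break the run after 2
  stopifnot(substr(cons, 4, 4) != "T")
  call <- list(chrom = "chr1", left_bp = 50L, right_bp = 40L,
               elem_strand = "+")
  g <- tiny_genome(c(chr1 = paste0(substr(flank, 1, 51), rand_seq(100))))
  mh <- detect_microhomology(call, offset = 7L, cons, g)
  expect_equal(mh$shared, 2L)
  # no shared base
  g2 <- tiny_genome(c(chr1 = paste0(strrep("C", 51), rand_seq(60))))
  stopifnot(substr(cons, 6, 6) != "C")
  mh2 <- detect_microhomology(call, offset = 7L, cons, g2)
  expect_equal(mh2$shared, 0L)
  # canonical nic hexamer TTTT/AA at the insertion point
  g3 <- tiny_genome(c(chr1 = paste0(strrep("G", 47), "TTTTAA",
                                    rand_seq(60))))
  call3 <- list(chrom = "chr1", left_bp = 50L, right_bp = 44L,
                elem_strand = "+")
  mh3 <- detect_microhomology(call3, offset = 7L, cons, g3)
  expect_identical(mh3$hexamer, "TTTTAA")
  expect_true(mh3$canonical)
})

test_that("cohort summary reproduces fraction arithmetic", {
  calls <- data.frame(
    subfamily = c(rep("AluYa5", 6), rep("AluYb8", 3), "unclassified"),
    trunc_bin = c(rep("full_length", 5), "short_trunc",
                  rep("full_length", 2), "long_trunc", NA),
    microhomology = c(0, 1, 2, NA, NA, 1, 0, 0, 3, NA))
  s <- summarize_cohort(calls)
  ya5 <- s$subfamily_table[s$subfamily_table$subfamily == "AluYa5", ]
  expect_equal(ya5$count, 6L)
  expect_equal(ya5$pct_total, 60)
  expect_equal(ya5$pct_assigned, round(100 * 6 / 9, 1))
  tt <- s$truncation_table
  expect_equal(tt$pct[tt$subfamily == "AluYa5" & tt$bin == "full_length"],
               round(100 * 5 / 6, 2))
  # truncation-bin percentages sum to 100 within each subfamily
  for (sf in c("AluYa5", "AluYb8"))
    expect_equal(sum(tt$pct[tt$subfamily == sf]), 100, tolerance = 0.05)
  mh <- s$microhomology_table
  expect_equal(mh$count[mh$shared == "0"], 3L)
  expect_equal(mh$count[mh$shared == ">=2"], 2L)
  # single element cohort: 100% in its own bin
  s1 <- summarize_cohort(data.frame(subfamily = "AluY",
                                    trunc_bin = "full_length"))
  expect_equal(s1$subfamily_table$pct_total, 100)
})
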