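mk_reads <- function(seqs, ids = sprintf("r%02d/1", seq_along(seqs))) {
  data.frame(id = ids, qname = sub("/[12]$", "", ids), seq = seqs,
             qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

test_that("two overlapping error-free reads merge into the exact template", {
  set.seed(31)
  tpl <- rand_seq(160)
  r1 <- substr(tpl, 1, 100); r2 <- substr(tpl, 61, 160)
  tigs <- assemble(mk_reads(c(r1, r2)))
  expect_length(tigs, 1L)
  expect_identical(tigs[[1]]$seq, tpl)
  expect_equal(nrow(tigs[[1]]$members), 2L)
  # opposite-strand read pair still assembles after orientation resolution
  tigs2 <- assemble(mk_reads(c(r1, revcomp(r2))))
  expect_length(tigs2, 1L)
  expect_true(tigs2[[1]]$seq == tpl || tigs2[[1]]$seq == revcomp(tpl))
  # a 10 bp overlap is below the floor: both reads stay singletons
  # (periodic, rc-dissimilar bodies preclude chance overlaps)
  j <- rand_seq(10)
  ra <- paste0(strrep("AACC", 23), j)
  rb <- paste0(j, strrep("TTTG", 15))
  expect_length(assemble(mk_reads(c(ra, rb), c("a/1", "b/1"))), 0L)
})

test_that("greedy assembler reconstructs the spanned template substring", {
  # oracle: for error-free reads tiling one template, the single contig
  # must equal the exact substring between the leftmost and rightmost read
  set.seed(37)
  for (trial in 1:25) {
    tpl <- rand_seq(sample(250:420, 1))
    n <- sample(3:8, 1)
    starts <- sort(sample(0:(nchar(tpl) - 120), n))
    # force chaining overlaps >= 30 bp
    starts <- cumsum(c(sample(0:40, 1), sample(10:60, n - 1, TRUE)))
    starts <- starts[starts + 120 <= nchar(tpl)]
    if (length(starts) < 2) next
    seqs <- substring(tpl, starts + 1, starts + 120)
    tigs <- assemble(mk_reads(seqs))
    expect_length(tigs, 1L)
    expect_identical(tigs[[1]]$seq,
                     substr(tpl, min(starts) + 1, max(starts) + 120))
    # member conservation
    expect_equal(nrow(tigs[[1]]$members), length(seqs))
    expect_gte(nchar(tigs[[1]]$seq), 120)
  }
})

test_that("collect_reads unions manifest pairs with qualifying clip pairs", {
  w <- cached_world()
  run <- cached_run()
  sites <- run$sites
  man <- attr(sites, "manifest")
  site <- sites[1, , drop = FALSE]
  reads <- collect_reads(site, w$alignments, man[[site$site_id]])
  expect_gt(nrow(reads), length(man[[site$site_id]]))
  # both mates of each selected pair are present
  tab <- table(reads$qname)
  expect_true(all(tab == 2L))
})

test_that("scaffolding joins linked contigs with a 300-N spacer", {
  set.seed(41)
  tpl <- rand_seq(700)
  mk <- function(s, id, strand = "+") {
    m <- data.frame(id = id, offset = 0L, strand = strand, len = nchar(s),
                    stringsAsFactors = FALSE)
    list(seq = s, depth = rep(1L, nchar(s)), weight = rep(30L, nchar(s)),
         members = m)
  }
  # pair p1 bridges the contigs: mate 1 forward in A, mate 2 reverse in B
  a <- mk(substr(tpl, 1, 200), c("p1/1", "q1/1"))
  b <- mk(substr(tpl, 501, 700), c("p1/2", "q2/1"))
  b$members$strand <- c("-", "+")
  sc <- scaffold_contigs(list(a, b))
  expect_length(sc, 1L)
  expect_identical(sc[[1]]$seq,
                   paste0(a$seq, strrep("N", 300), b$seq))
  expect_equal(sc[[1]]$links, 1L)
  # no links: scaffolds are the contigs
  sc2 <- scaffold_contigs(list(mk(a$seq, "x/1"), mk(b$seq, "y/1")))
  expect_length(sc2, 2L)
  # contradictory orientations leave contigs unjoined
  a2 <- mk(a$seq, c("p1/1", "p2/1"))
  b2 <- mk(b$seq, c("p1/2", "p2/2"))
  b2$members$strand <- c("-", "+")  # p2 implies same-strand join
  expect_warning(sc3 <- scaffold_contigs(list(a2, b2)), "contradictory")
  expect_length(sc3, 2L)
})

test_that("assembly filter enforces the Alu-match and flank rules", {
  lib <- synthetic_alu_library()
  set.seed(43)
  el <- lib[["AluYa5"]]
  ok <- paste0(rand_seq(50), el, rand_seq(40))
  f <- filter_assembly(ok, lib)
  expect_true(f$pass)
  expect_identical(f$target, "AluYa5")
  expect_gte(f$matched_bp, 30)
  expect_equal(f$flank5, 50L)
  expect_equal(f$flank3, 40L)
  # a bare element has no flank
  expect_false(filter_assembly(el, lib)$pass)
  # a 25 bp fragment fails the match rule
  frag <- paste0(rand_seq(60), substr(el, 1, 25), rand_seq(60))
  expect_false(filter_assembly(frag, lib)$pass)
  # gap within 100 bp of the match boundary is flagged
  gapped <- paste0(rand_seq(200), strrep("N", 300), rand_seq(50), el,
                   rand_seq(200))
  fg <- filter_assembly(gapped, lib)
  expect_true(fg$pass)
  expect_true(fg$gap_within_100bp)
})

test_that("implant round trip: a passing scaffold contains the element", {
  w <- cached_world()
  run <- cached_run()
  hits <- 0L
  for (k in seq_len(nrow(w$truth))) {
    t <- w$truth[k, ]
    for (id in names(run$calls)) {
      x <- run$calls[[id]]
      sseq <- x$scaffold_seq
      if (grepl(t$ins_seq, sseq, fixed = TRUE) ||
          grepl(revcomp(t$ins_seq), sseq, fixed = TRUE)) {
        hits <- hits + 1L
        break
      }
    }
  }
  expect_equal(hits, nrow(w$truth))
})
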