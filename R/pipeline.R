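# Pipeline orchestration: a single config object whose defaults are the
# published operating point, and a composite runner covering
# simulate -> discover -> assemble -> breakpoint -> classify -> genotype
# -> evaluate.

#' Default pipeline configuration
#'
#' Every stage block defaults to the published operating point: assembly
#' read-collection window 200 bp, reference-Alu exclusion pad 500 bp,
#' minimum 2 supporting pairs, read-depth cap 1000, soft-clip filter
#' 20 bp / Q20, Alu match filter 30 bp / 90 percent identity, 30 bp
#' assembly flank, 100 bp genotypable-flank rule, 600 bp allele flank,
#' MAPQ 20, 300-N scaffold spacer, 100 bp intersection window.
#'
#' @param seed global seed (all stage randomness derives from it)
#' @return nested list of class `"pipeline_config"`
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(read_len = 101L, frag_mean = 350, frag_sd = 35,
                    coverage = 30, error_rate = 0,
                    tsd_range = c(5L, 25L), polyA_range = c(10L, 30L),
                    trunc_mix = c(0.85, 0.10, 0.05), pseudocount = 1),
    discover = list(min_reads = 2L, max_depth = 1000L, pad = 500L,
                    anchor_mapq_min = 20L, min_match = 30L,
                    min_identity = 0.90),
    assemble = list(window = 200L, min_clip = 20L, min_clip_qual = 20,
                    min_overlap = 16L, min_identity = 0.90,
                    min_reads_per_contig = 2L, spacer = 300L,
                    min_match = 30L, min_flank = 30L),
    breakpoint = list(flank = 600L, min_genotype_flank = 100L,
                      match = 5L, mismatch = -4L, gap_open = 16L,
                      gap_extend = 4L),
    genotype = list(flank = 600L, mapq_min = 20L, tol = 1e-6,
                    max_iter = 100L),
    evaluate = list(window = 100L)),
    class = "pipeline_config")
}

#' Run the discovery-to-breakpoint pipeline on one aligned sample
#'
#' Convenience composite used by tests and the full runner: discordant
#' pair discovery, candidate clustering, reference-Alu filtering, per-site
#' read collection, greedy OLC assembly, scaffolding, assembly filtering
#' and breakpoint calling.
#'
#' @param alignments coordinate-sorted `"alignments"` table
#' @param genome reference genome
#' @param catalog reference repeat catalog
#' @param library Alu consensus library
#' @param config a `"pipeline_config"`
#' @return list: `sites` (candidate table), `calls` (list of
#'   `"breakpoint_call"`, named by site id)
#' @export
discover_and_assemble <- function(alignments, genome, catalog, library,
                                  config = pipeline_config()) {
  dc <- config$discover; ac <- config$assemble; bc <- config$breakpoint
  pairs <- find_discordant_pairs(alignments, library, catalog,
                                 anchor_mapq_min = dc$anchor_mapq_min,
                                 min_match = dc$min_match,
                                 min_identity = dc$min_identity)
  clips <- extract_soft_clips(alignments, ac$min_clip, ac$min_clip_qual)
  sites <- cluster_candidates(pairs, clips,
                              fragment_mean = config$simulate$frag_mean,
                              fragment_sd = config$simulate$frag_sd,
                              min_reads = dc$min_reads,
                              max_depth = dc$max_depth,
                              alignments = alignments)
  sites <- filter_near_reference(sites, catalog, pad = dc$pad)
  manifest <- attr(sites, "manifest")
  calls <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    reads <- collect_reads(site, alignments, manifest[[site$site_id]],
                           window = ac$window, min_clip = ac$min_clip,
                           min_qual = ac$min_clip_qual, clips = clips)
    if (nrow(reads) == 0L) next
    contigs <- assemble(reads, min_overlap = ac$min_overlap,
                        min_identity = ac$min_identity,
                        min_reads_per_contig = ac$min_reads_per_contig)
    if (length(contigs) == 0L) next
    scaffolds <- scaffold_contigs(contigs, spacer = ac$spacer)
    best <- NULL
    for (sc in scaffolds) {
      filt <- filter_assembly(sc, library, min_match = ac$min_match,
                              min_identity = ac$min_identity,
                              min_flank = ac$min_flank)
      if (!filt$pass) next
      cl <- call_site(sc, genome, site, library, flank = bc$flank,
                      min_genotype_flank = bc$min_genotype_flank)
      if (is.null(cl)) next
      if (is.null(best) || isTRUE(cl$genotypable) &&
          !isTRUE(best$genotypable)) best <- cl
    }
    if (!is.null(best)) calls[[site$site_id]] <- best
  }
  list(sites = sites, calls = calls)
}

#' Run pipeline stages end to end
#'
#' Runs the requested stages in dependency order on a synthetic world
#' generated from the config seed, writing TSV/FASTA/VCF artifacts with a
#' provenance header into `outdir`.  Reruns with the same config produce
#' identical outputs.
#'
#' @param config a `"pipeline_config"`
#' @param stages ordered subset of
#'   `c("simulate", "discover", "assemble", "breakpoint", "classify",
#'   "genotype", "evaluate")` (default: all)
#' @param outdir output directory (created if needed)
#' @param world optional pre-built world (list with `genome`, `catalog`,
#'   `library`, `truth`, `alignments`); when absent the simulate stage
#'   must be included
#' @param genome_length,n_implants,n_ref_alu synthetic world size
#' @return list of stage artifacts (invisibly writes files)
#' @export
run_pipeline <- function(config = pipeline_config(), stages = NULL,
                         outdir = tempfile("aluvar_run_"),
                         world = NULL, genome_length = 200000L,
                         n_implants = 8L, n_ref_alu = 10L) {
  all_stages <- c("simulate", "discover", "assemble", "breakpoint",
                  "classify", "genotype", "evaluate")
  stages <- stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("# aluvar %s | seed %d | config %s",
                  as.character(utils::packageVersion("aluvar")),
                  config$seed,
                  substr(config_hash(config), 1, 12))
  write_artifact <- function(df, name) {
    p <- file.path(outdir, name)
    con <- file(p, "w")
    writeLines(prov, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    p
  }
  out <- list(outdir = outdir)
  if ("simulate" %in% stages && is.null(world)) {
    world <- simulate_world(config, genome_length, n_implants, n_ref_alu)
    write_fasta(world$genome, file.path(outdir, "reference.fa"))
    write_artifact(world$truth[, setdiff(names(world$truth), "ins_seq")],
                   "truth.tsv")
    write_fastq(world$alignments, file.path(outdir, "reads_1.fastq"),
                file.path(outdir, "reads_2.fastq"))
    write_sam(world$alignments, world$genome,
              file.path(outdir, "reads.sam"))
  }
  if (is.null(world))
    stop("no input world: run the 'simulate' stage first or supply one")
  out$world <- world
  need_calls <- any(c("discover", "assemble", "breakpoint", "classify",
                      "genotype", "evaluate") %in% stages)
  if (need_calls) {
    da <- discover_and_assemble(world$alignments, world$genome,
                                world$catalog, world$library, config)
    out$sites <- da$sites
    out$calls <- da$calls
    write_artifact(as.data.frame(da$sites), "candidates.tsv")
    if (length(da$calls)) {
      bp <- do.call(rbind, lapply(names(da$calls), function(id) {
        x <- da$calls[[id]]
        data.frame(site_id = id, chrom = x$chrom,
                   left_bp = x$left_bp %||% NA, right_bp = x$right_bp %||% NA,
                   overlap_len = x$overlap_len %||% NA,
                   tsd = x$tsd %||% "", target_del = x$target_deletion %||% NA,
                   strand = x$elem_strand, target = x$target,
                   genotypable = x$genotypable, stringsAsFactors = FALSE)
      }))
      write_artifact(bp, "breakpoints.tsv")
    }
  }
  if ("classify" %in% stages && length(out$calls)) {
    lib_prof <- build_profile(world$library)
    cls <- do.call(rbind, lapply(names(out$calls), function(id) {
      x <- out$calls[[id]]
      sf <- assign_subfamily(x$element_seq, lib_prof)
      tr <- if (sf$subfamily != "unclassified")
        measure_truncation(orient_element(x$element_seq, lib_prof),
                           world$library[[sf$subfamily]])
      else list(offset = NA_integer_, bin = NA_character_)
      data.frame(site_id = id, subfamily = sf$subfamily,
                 divergence = sf$divergence, trunc_offset = tr$offset,
                 trunc_bin = tr$bin, stringsAsFactors = FALSE)
    }))
    out$classification <- cls
    write_artifact(cls, "classification.tsv")
  }
  if ("genotype" %in% stages && length(out$calls)) {
    gcalls <- Filter(function(x) isTRUE(x$genotypable), out$calls)
    vsites <- list()
    for (id in names(gcalls)) {
      cl <- gcalls[[id]]
      ap <- build_alleles(cl, world$genome, flank = config$genotype$flank)
      mp <- extract_and_remap(world$alignments, ap,
                              mapq_min = config$genotype$mapq_min)
      gl <- compute_gl(mp, ploidy = world$ploidy %||% 1L)
      gls <- setNames(list(gl), world$sample %||% "sample1")
      af <- em_allele_frequency(gls, tol = config$genotype$tol,
                                max_iter = config$genotype$max_iter)
      vsites[[id]] <- list(call = cl, af = af,
                           genotypes = call_genotypes(gls, af$f),
                           gls = gls, id = id)
    }
    out$genotyped <- vsites
    if (length(vsites))
      write_vcf(vsites, world$genome, file.path(outdir, "calls.vcf"))
  }
  if ("evaluate" %in% stages && !is.null(out$calls)) {
    pred <- data.frame(
      chrom = vapply(out$calls, `[[`, character(1), "chrom"),
      pos = vapply(out$calls, function(x) x$left_bp %||% NA_integer_,
                   numeric(1)))
    truth <- data.frame(chrom = world$truth$chrom, pos = world$truth$site)
    out$performance <- performance_metrics(pred, truth,
                                           window = config$evaluate$window)
    write_artifact(as.data.frame(out$performance), "performance.tsv")
  }
  invisible(out)
}

#' Generate a complete synthetic world from a config
#'
#' A random genome with annotated reference Alus, nic-site-model sampled
#' implant positions outside the padded mask, implanted insertions, and
#' simulated error-free-or-noisy paired reads from a single (haploid)
#' carrier sample -- mirroring the effectively haploid samples used as
#' truth resources when benchmarking insertion discovery.
#'
#' @param config a `"pipeline_config"`
#' @param genome_length,n_implants,n_ref_alu world size
#' @return list: `genome`, `catalog`, `library`, `specs`, `truth`,
#'   `alignments`, `sample`, `ploidy`
#' @export
simulate_world <- function(config = pipeline_config(),
                           genome_length = 200000L, n_implants = 8L,
                           n_ref_alu = 10L) {
  seed <- config$seed
  library <- synthetic_alu_library()
  gen <- simulate_genome(c(chr1 = as.integer(genome_length)),
                         library = library, n_ref_alu = n_ref_alu,
                         seed = seed)
  ppm <- build_ppm(default_nic_sites(), config$simulate$pseudocount)
  mask <- exclusion_mask(gen$catalog, "Alu", config$discover$pad,
                         gen$genome)
  sites <- sample_insertion_sites(gen$genome, ppm, n_implants, mask,
                                  seed = seed + 1L)
  # keep implant sites well separated so local assemblies are independent
  sites <- sites[order(sites$chrom, sites$pos), ]
  keep <- c(TRUE, diff(sites$pos) > 2000)
  sites <- sites[keep, , drop = FALSE]
  specs <- draw_implant_specs(sites, library,
                              tsd_range = config$simulate$tsd_range,
                              polyA_range = config$simulate$polyA_range,
                              trunc_mix = config$simulate$trunc_mix,
                              seed = seed + 2L)
  imp <- implant_insertions(gen$genome, specs, library, seed = seed + 3L)
  aln <- simulate_paired_reads(imp, coverage = config$simulate$coverage,
                               read_len = config$simulate$read_len,
                               frag_mean = config$simulate$frag_mean,
                               frag_sd = config$simulate$frag_sd,
                               error_rate = config$simulate$error_rate,
                               seed = seed + 4L)
  list(genome = gen$genome, catalog = gen$catalog, library = library,
       specs = specs, truth = imp$truth, blocks = imp$blocks,
       alignments = aln, sample = "sample1", ploidy = 1L)
}

#' @keywords internal
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  # small stable rolling hash (no external digest dependency)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
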