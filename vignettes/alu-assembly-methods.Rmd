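---
title: "Methods: assembly-first detection and genotyping of non-reference Alu insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly-first detection and genotyping of non-reference Alu insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluvar)
```

# Scope and model

`aluvar` detects polymorphic Alu mobile-element insertions that are
present in a sequenced sample but absent from the reference genome. The
pipeline is assembly-first: rather than reporting read-signature calls,
it requires that the full insertion — element, poly-A tail, both
junctions and flanking sequence — be locally reconstructed before a
site is accepted. This trades sensitivity (insertions landing inside
existing repeats are largely unrecoverable with ~100 bp reads) for a
call set precise enough to support breakpoint-level annotation and
allele-specific genotyping.

The generative model the pipeline assumes, and that the simulator
implements, is target-primed reverse transcription (TPRT): the L1
endonuclease makes staggered single-stranded nicks ~5–25 bp apart at a
degenerate T-rich motif; the element is copied in, leaving a target
site duplication (TSD) of the inter-nick bases and a 3' poly-A tail.
A minority of events instead delete a few target bases ("target-site
deletion") or insert bluntly, and a minority of elements are 5'
truncated by premature termination of reverse transcription.

# Stages and the parameters that matter

All defaults live in one place, `pipeline_config()`, and are asserted
by a parameter-audit test.

* **Discovery.** Anchored discordant pairs: one mate mapped with
  MAPQ ≥ 20 (`anchor_mapq_min`), the other matching an Alu consensus
  by local alignment with ≥ 30 matched bases at ≥ 90% identity
  (`min_match`, `min_identity`) or mapping into an annotated reference
  Alu. Forward- and reverse-anchor clusters within one fragment length
  are paired; calls need ≥ 2 supporting pairs (`min_reads`), local
  read depth ≤ 1000 (`max_depth`), and must lie further than 500 bp
  (`pad`) from any annotated reference Alu. Support levels 6–8 encode
  two-sided cluster evidence with soft-clips on neither, one, or both
  sides; single-sided evidence (≤ 5) is not emitted by default.
* **Assembly.** Reads from a 200 bp window (`window`) around the
  predicted breakpoint — manifest pairs plus pairs with a soft clip of
  ≥ 20 bp at mean clipped quality ≥ 20 — are assembled by greedy
  overlap-layout-consensus: ungapped suffix–prefix overlaps of
  ≥ 16 bp (`min_overlap`) at ≥ 90% identity, both orientations,
  highest matched-base count merged first, quality-weighted majority
  consensus. Read-pair-linked contigs are scaffolded with exactly
  300 `N`s per join. A scaffold passes if it carries an Alu match of
  ≥ 30 bp at ≥ 90% identity with ≥ 30 bp of contiguous non-gap flank.
* **Breakpoints.** The scaffold is oriented against the reference;
  the element interval is extended through the adjacent poly-A (or
  poly-T) run — the tail belongs to the element, not the flank — and
  the flanks are fit-aligned (query global, reference ends free) to
  the ± 600 bp reference window under match +5, mismatch −4, gap open
  16, gap extend 4 (a gap of length L costs 16 + 4L). The merged
  three-way alignment is scored with the +1/−1/−3 scheme from each
  end; track maxima give the breakpoints, their overlap the candidate
  TSD (refined to the exact-match run grown from the element-proximal
  end), and a gap between them a target-site deletion. A site is
  genotypable when both junctions have ≥ 100 bp of non-gap assembled
  flank.
* **Classification.** A center-star profile alignment of the
  consensus library; each element (poly-A trimmed, orientation
  resolved) is aligned to the profile via the center sequence and
  scored per subfamily as mismatches over jointly covered columns.
  The minimum mismatch count wins; exact ties are unclassified.
  Truncation offset is the first consensus position covered
  (full-length 1–5, short 7–45, long 55–171, other). Microhomology is
  the contiguous run of genomic bases 5' of the junction equal to the
  consensus bases 5' of the truncation point; it is only meaningful
  for truncated elements.
* **Genotyping.** Reference allele = 600 bp either side of the TSD
  span; insertion allele replaces the appropriate segment with the
  assembled insertion, duplicating the TSD or deleting target bases.
  Pairs with an original mapping in the region at MAPQ ≥ 20 are
  realigned to both alleles; the pair score gap maps to
  q = min(60, 2·gap), ties get q = 0 and drop out. Dosage
  likelihoods treat q as an error probability; EM under
  Hardy–Weinberg equilibrium (initial f = 0.5, tolerance 1e−6)
  estimates the allele frequency; posteriors combine HWE(f) priors
  with the likelihoods, argmax called, ties to the lower dosage.
  Haploid samples (e.g. male X) use the two-genotype prior and can
  never be heterozygous.

# The synthetic world

The simulator is first-class code, not a fixture. It emulates:

* a uniform-random genome with planted, annotated "reference Alu"
  copies (the substrate for the exclusion mask);
* insertion sites rejection-sampled from a 5-bp nic-site PPM
  (per-base pseudocount 1, minus-strand windows scored on the reverse
  complement, masked positions rejected before scoring, attempt cap
  1e7 per site);
* implants with TSD length uniform 5–25 bp (the TPRT stagger range),
  poly-A tails uniform 10–30 bp (typical young-Alu tails; kept below
  read length so junction reads bridge the homopolymer), truncation
  offsets from an 85/10/5 mixture over the full-length/short/long
  classes, optional 1–6 bp target-site deletions, either strand, and
  an optional per-copy substitution rate;
* paired-end reads (2 × 101 bp, fragment 350 ± 35 bp, Poisson
  coverage, iid substitution errors) whose alignments against the
  reference are produced by exact coordinate projection: anchored
  reads at MAPQ 60, junction reads soft-clipped at the insertion
  point, element-interior reads unmapped with a mapped mate.

What it deliberately does not model: indel sequencing errors, base
quality profiles and GC bias, chimeric fragments, mapping ambiguity in
repeats (every anchor is a unique mapper by construction), and somatic
mosaicism. A green end-to-end test therefore establishes that the
algorithmic chain is correct under clean mappings, not that a real
aligner's errors are survivable; conversely the discovery filters
(depth cap, reference-Alu exclusion, MAPQ floor) are exercised exactly
as specified.

The bundled nic-site list and consensus library are synthetic
stand-ins (the published 99 experimentally determined nic sites and
the licensed RepBase consensuses are not redistributable); both are
plainly labelled and any user-supplied FASTA/site list can be used
instead. The package does not claim to reproduce the exact published
PPM.

# Canonical representation of junction calls

Two boundary ambiguities are inherent to the data, not to any
algorithm:

1. **TSD vs poly-A.** If the duplicated target sequence begins with
   adenines (plus strand; thymines mirror on minus), those bases can
   equally be read as tail or as TSD — `(tsd, polyA)` and
   `(tsd + 1, polyA − 1)` produce byte-identical haplotypes whenever
   the reference continues the homopolymer.
2. **Element 5' microhomology.** Genomic bases 5' of the junction that
   match the consensus immediately 5' of a truncated element's start
   can be read as flank or as element; this is the same signature that
   motivates the premature-TPRT microhomology analysis.

Exactly as indel calls are left-aligned before comparison, both the
simulator's truth tables and the breakpoint caller normalize to one
canonical form: the element absorbs the contiguous consensus-matching
run at its 5' junction, and the TSD is maximal through the reference
homopolymer at the poly-A junction (deletions minimal). The drawn
values are retained alongside the normalized ones. Without this
convention, "exact TSD length" has an information-theoretic ceiling
around 75% on random sequence, which no caller can beat.

# Numerical and tie-breaking conventions

* Alignment traceback prefers diagonal over a reference gap over a
  query gap; fit alignments take the smallest reference end offset on
  score ties. `N` mismatches everything, including `N`.
* Left-track maxima are resolved to the rightmost column, right-track
  to the leftmost — jointly maximizing the reported overlap.
* The three-way merge spans the union of the two flank alignments'
  reference spans; window margins covered by neither flank carry no
  evidence and are excluded from the score tracks.
* Assembly merge ties: longer resulting contig, then lexicographically
  smaller earliest read id. Consensus ties: higher summed quality,
  then the first-listed base.
* Genotype posterior ties call the lower dosage. EM stops at
  |Δf| < 1e−6 or 100 iterations (flagged unconverged).
* Percentages in summary tables are rounded half-up to the printed
  precision; raw fractions are always retained.

# Design choices where the design was open

* **Support-level ladder.** The upstream caller's filter-tag semantics
  are not published; levels 6/7/8 are defined here as two-sided
  read-pair support with 0/1/2-sided junction soft-clips, reproducing
  the "two-sided support" gate without claiming equivalence.
* **Assembler.** The external assembler's exact parameter semantics
  (its published flag string is internally inconsistent) are not
  reproduced; the contract is defined by minimum overlap 16, identity
  0.90 and ≥ 2 reads per contig, with downstream filters unchanged.
  Overlaps are ungapped, which matches a substitution-only error
  model; indel-noisy data would need a banded-gapped overlap step.
* **Manual curation loop.** The published semi-automated re-extraction
  is replaced by deterministic conventions (union-span merge, boundary
  re-anchoring) — no per-site human input.
* **%Assigned denominator.** The published cohort table's assigned-set
  denominator is internally inconsistent (the subfamily counts sum to
  neither printed total); `summarize_cohort()` uses the count of
  elements carrying a subfamily label and documents the discrepancy.
* **EM everywhere.** LD-aware genotype refinement (used upstream for
  autosomes) is out of scope; the EM path is applied to all
  chromosomes with ploidy from a sample sheet.
* **Remapper.** Read remapping for genotyping uses an internal local
  aligner with q = min(60, 2·score-gap); the interface accepts any
  per-pair (best allele, q) table, so a real mapper's MAPQ can be
  substituted.

# Known limitations

* Insertions within or near existing Alu copies are excluded by
  design (the 500 bp mask); sensitivity in repeat-dense regions is
  correspondingly low, as the benchmark arithmetic in the acceptance
  suite makes explicit.
* The greedy assembler has no special handling for long homopolymer
  joins; a poly-A tail approaching read length can fragment the
  assembly (flagged via the gap-within-100-bp rule rather than
  repaired).
* The center-star profile left-aligns insertions from different
  consensuses at the same center position without aligning them to
  each other; divergence estimates for elements with long private
  insertions relative to the center are slightly conservative.
* Scaffolding handles pairwise links; longer contig chains are
  emitted unjoined rather than ordered.
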