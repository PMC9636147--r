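---
title: "Detecting and dating founder mitochondrial lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating founder mitochondrial lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfounder)
```

## The problem

Populations that have gone through strong bottlenecks and founder events —
the canonical human example being diaspora populations such as the Roma —
carry a mitochondrial gene pool dominated by a handful of maternal lineages
that expanded from few founding mothers. Detecting those lineages in a
panel of whole mitogenomes, dating their expansion, and contrasting the
carrier population with a host population is a standard analysis in
mitochondrial population genetics, but it is usually assembled by hand from
half a dozen tools (an external haplogroup classifier, BLAST searches, the
Network program, spreadsheet clock arithmetic, and an AMOVA package).
`mtfounder` implements the whole chain as one testable pipeline operating
on a single currency: the **variant profile**, an individual's mitogenome
expressed as its set of differences from the revised Cambridge Reference
Sequence (rCRS, 16,569 bp) in standard mtDNA nomenclature (`A2833G`,
`8281d`, `315.1C`, `@` for back mutations).

## Pipeline model

The stages, each usable on its own:

1. **Anchoring** (`read_fasta_panel`, `call_variants`): sequences of
   exactly 16,569 columns are compared position-wise; other lengths are
   globally aligned first. IUPAC ambiguity codes become *missing data*,
   excluded from every downstream count — the conservative choice, since
   counting an ambiguous site as a variant fabricates signal, while
   excluding it only loses a little power. Indels are recorded but all
   downstream statistics (classification, founder definitions, distances,
   clocks) use substitutions only, consistent with standard mtDNA clock
   practice. The molecule is treated as linear anchored at position 1; the
   control region therefore spans the origin.

2. **Haplogroup classification** (`classify_haplogroup`): each profile is
   scored against every node of a phylotree-style tree by the Kulczynski
   measure, `(|F∩E|/|E| + |F∩E|/|F|) / 2`, where `E` is the node's
   cumulative expected variant set and `F` the profile's observed set, both
   after removing hotspot positions and sites missing in the profile. Ties
   break to the deepest node, then lexicographically. An empty ratio
   denominator counts as 1, so the empty profile scores 1 on the reference
   lineage itself. The packaged tree is a ~58-node *synthetic mini-tree*
   covering the H, J, T, U, K, M backbones: clade-defining variants follow
   published forms where those are well known (e.g. the U3b1c signature
   `A2833G T7759C T8895C C11119T T12783C T15262C`, or `C16261T` for H7a1),
   and backbone assignments are synthetic. Real analyses should supply a
   full phylotree export in the same three-column TSV format.

3. **Founder scan** (`detect_founder_lineages`): a founder lineage is a
   group of **more than `min_carriers`** (default 4) same-haplogroup
   sequences that share **at least one** non-hotspot substitution *beyond
   the haplogroup's own cumulative profile*, reach a relative frequency of
   at least `min_freq` (default 4/144 ≈ 0.0278, i.e. four carriers in a
   144-sample panel), and whose full shared signature is absent from the
   reference panel. The "shared mutation" clause is deliberately read as
   *private to the haplogroup* rather than *any* shared variant: shared
   haplogroup-defining variants are trivially shared by construction and
   would make every haplogroup a founder lineage. Nested candidate carrier
   sets collapse to the maximal set; overlapping non-nested sets resolve
   deterministically to the larger one, so each sample belongs to at most
   one lineage and population fractions partition cleanly. Lineages whose
   signature occurs in the reference panel are reported with
   `exclusivity = "violated"` instead of being silently dropped, and the
   nearest outside match (sample and shared-variant overlap) is always
   reported so a user can replicate the manual judgment that a BLAST hit
   list would support. `scan_reference_population` applies the same logic
   to the host population, either whole-panel or per region with the
   relaxed `> 2` carrier threshold appropriate for region-sized groups.

4. **Dating** (`rho_sigma`, `rho_to_years`): the age of a clade is
   estimated with the ρ statistic — the mean number of substitution
   differences between the clade members and their root haplotype, taken
   as the strict consensus of the clade unless supplied explicitly. The
   standard error uses the genealogy-weighted estimator: `sqrt(ρ/n)` for a
   star genealogy, or `Σ l_b (n_b/n)²` over branches when a tree is
   supplied. When only profiles are given the star form is used and
   labeled as such. Conversion to years uses
   `age = ρ / (μ·L)` with `μ = 2.355e-8` substitutions/site/year and `L`
   the callable sites (16,569 minus the hotspot list by default). The
   optional purifying-selection correction models the familiar
   time-dependence of the mitochondrial clock: a fraction `f` of new
   mutations (mostly mildly deleterious non-synonymous changes) is
   tolerated at first but purged over a timescale `τ`, so
   `ρ(t) = μL((1−f)t + fτ(1−e^{−t/τ}))`, inverted numerically (the curve
   is strictly monotone). The shipped calibration is **synthetic**: `f` is
   chosen so the long-term rate `(1−f)μ` equals the canonical
   purifying-corrected whole-genome rate 1.665e-8, and `τ = 12,000` years
   is of the order of published saturation scales. Users reproducing a
   specific published correction should replace
   `inst/extdata/selection_curve_synthetic.tsv` with their own
   calibration. σ converts through the local slope of the same curve.
   Reported ages are rounded to 0.1 kya, the field's usual precision.

5. **Networks** (`build_mj_network`, `extract_parsimony_tree`): the
   median-joining construction over the binary encoding of segregating
   sites — the ε-relaxed minimum spanning network, iteratively augmented
   with majority-consensus median vectors of partly-linked triples
   (minimal connection cost first), pruning median vectors of degree ≤ 2,
   until convergence. ε defaults to 0 and hotspot sites are down-weighted
   to 0. Tree renderings are deterministic: a minimum spanning tree of the
   network with canonical tie-breaks, rooted at a supplied haplotype
   (inserted if unobserved), dangling median chains pruned, and branches
   labeled with variant strings; losing a derived allele along the
   root-to-tip direction renders as a `@` back mutation. On small
   instances the extracted tree provably reaches the exhaustive
   Steiner-search parsimony length (tested).

6. **Population statistics** (`diversity_summary`, `amova`,
   `pairwise_phist`, `composition_chi2`): unbiased haplotype diversity
   `H = n/(n−1)(1−Σp²)`, nucleotide diversity as mean pairwise
   substitution differences per callable site, and the Excoffier
   sums-of-squares AMOVA on squared substitution distances, one-level or
   nested (populations × regions), with Φ statistics and label-permutation
   p-values `(#{Φ* ≥ Φ} + 1)/(B + 1)`. Negative variance components are
   reported as-is (they are legitimate method-of-moments estimates and the
   natural reading of a slightly negative among-group percentage);
   a panel with zero total molecular variance reports Φ = 0 by convention.
   The distance is the plain count of differing substitution sites —
   the simplest model consistent with haplotype-level mtDNA data.

7. **Deleterious load** (`annotate_coding`, `lineage_load_comparison`):
   coding substitutions are translated with the vertebrate mitochondrial
   code (light-strand genes on the reverse complement; overlapping genes
   yield one consequence per frame; trailing incomplete stop codons are
   left untranslated), scored against a user-supplied pathogenicity table
   keyed by (position, ref AA, alt AA), and founder vs non-founder score
   distributions are compared with a two-sided Mann–Whitney U test — exact
   for tie-free groups of ≤ 8, normal approximation with tie correction
   otherwise. Pooling defaults to per-variant (each distinct variant
   counted once per group); per-individual pooling and a
   defining-variants-only scope are available because published analyses
   are often ambiguous on this point, and the two pooling choices can
   disagree. Per-ancestry-class breakdowns carry a Benjamini–Hochberg
   adjusted column alongside raw p-values.

## The synthetic-panel generator

`simulate_panel` is first-class, tested code, not a fixture: it emits a
two-population panel together with a manifest that exactly describes every
planted variant, so each pipeline stage can be validated against known
truth. Founder clades are star genealogies — founder haplotype =
haplogroup cumulative profile + signature drawn from unused non-hotspot
positions; each carrier adds `Poisson(μ·L·age)` private substitutions —
because the ρ/σ closed forms are exact for stars, making parameter-recovery
tests sharp. The host population draws backbone haplogroups plus Poisson
private variants; admixed study samples copy host haplotypes (shared
haplotypes across populations); hotspot noise and missing data are applied
per sample. Planted coding non-synonymous variants receive pathogenicity
scores from Beta(2,8) when they belong to a founder signature and Beta(5,4)
otherwise, emulating the empirical contrast between old, selection-filtered
founder variation and younger private variation.

The `"roma-like"` preset encodes the study design this package was built
around: 144 study mitogenomes against a 1,066-sequence host panel, nine
founder lineages — two on South Asian (M) backbones carrying 20 samples
jointly, seven on West-Eurasian backbones carrying 74 (the largest, a
U3b1 clade of 44) — so the expected founder fraction is 94/144 ≈ 65.3%,
with clade ages between 0.4 and 2.5 ky. Carrier counts per lineage were
fixed once from the published per-lineage frequencies, under the
constraint that every planted lineage clears the `> 4` carrier threshold.

What the generator does *not* emulate: recombination (absent in mtDNA),
heteroplasmy, sequencing error beyond uniform missingness, rate
heterogeneity among non-hotspot sites, transition/transversion bias (off
by default), and realistic coalescent tree shapes inside clades (a
structured-genealogy σ path exists but stars are the default). Passing
tests therefore demonstrate algorithmic correctness under the stated
model, not robustness to every artefact of real sequence data.

## Numerical and design choices

- **Packaged reference**: the shipped reference sequence is a synthetic
  stand-in with exact rCRS dimensions and the published rCRS gene
  coordinates (`synthetic_rcrs.fasta`); every computation is
  coordinate-based, so supplying the true rCRS FASTA changes nothing
  structurally. Protein genes whose length is not a multiple of 3 end in
  post-transcriptionally completed stop codons; the trailing incomplete
  codon is not translated.
- **Problem sizes in tests**: Monte-Carlo checks use 100–200 replicates of
  20–40-sample panels and permutation tests use 49–999 permutations;
  these sizes give stable two-standard-error bounds for the quantities
  checked while keeping the whole suite comfortably re-runnable.
- **Determinism**: every stochastic routine takes an explicit seed;
  identical seeds give byte-identical simulated panels and stage outputs.
  Classification, scanning and network construction are deterministic with
  documented tie-breaks (score → depth → name; carrier-set size → label;
  canonical node order).
- **Degenerate inputs**: `H` is flagged undefined for n < 2; AMOVA warns
  on size-1 groups; χ² drops zero-margin rows/columns with a warning and
  warns on expected counts < 5; singleton clades date with `n = 1` flagged
  low-confidence; networks refuse > 200 segregating sites unless forced
  (median generation is combinatorial).
- **Open reading of the founder definition**: the frequency threshold and
  the carrier-count threshold are independent knobs (`min_freq`,
  `min_carriers`) because published definitions combine them ambiguously;
  the defaults apply both jointly.

## Limitations

The classifier returns only the best node, not ranked alternatives; the
exclusivity check is exact-signature matching within a *local* reference
panel rather than a global database search, so "exclusive" means
"exclusive within the supplied panel"; phylogeographic origin assignment
remains expert judgment on the reported nearest matches and network
figures; and the selection-correction calibration shipped here is a
documented synthetic stand-in, not a published curve.
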