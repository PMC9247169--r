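---
title: "Dissecting mito-nuclear phylogenetic discordance with phylodiscord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mito-nuclear phylogenetic discordance with phylodiscord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep branches of a phylogeny are often resolved differently by
different genomic compartments. In bivalve mollusks, mitochondrial
markers — and nuclear OXPHOS subunits that physically interact with
them — group Heterodonta with Pteriomorphia, while other nuclear
markers group Heterodonta with Palaeoheterodonta. Two candidate trees
that differ by a single nearest-neighbor interchange (NNI) at one
focal branch summarize the conflict. `phylodiscord` quantifies, site
by site and marker by marker, which data support which resolution, and
tests whether that support co-varies with subunit contact and with
strand-specific nucleotide composition. Because the real study's
inputs (35 transcriptomes, NCBI mitogenome surveys) are not
reproducible at desk scale, the package ships a synthetic-data module
that plants a known truth with the same statistical structure, so the
whole chain of inference can be validated.

## The likelihood model

Sites evolve under a reversible Markov substitution model
Q = S·diag(π), rescaled so that −Σᵢ πᵢ Qᵢᵢ = 1: branch lengths are
expected substitutions per site. Amino-acid models are Poisson
(uniform exchangeabilities), WAG or LG (published empirical matrices,
taken from phangorn's distribution of them); the nucleotide model is
GTR-like with free exchangeabilities. Frequencies can be the matrix
defaults, user-supplied, or counted from the data.

Rate heterogeneity across sites uses the discrete-gamma approximation
with `n_categories` (default 4) equal-probability categories
represented by their **means** — the dominant convention in ML
phylogenetics (the alternative, category medians, does not integrate
to 1). The gamma shape α defaults to 0.8 in the simulator, a
mid-range value for conserved protein-coding markers; small α means
strong heterogeneity.

Per-site log-likelihoods come from Felsenstein pruning. Partial
likelihood vectors are rescaled per node by the per-site maximum, with
the log of the scaler accumulated separately, so alignments of any
length cannot underflow; the test suite checks agreement with the
unscaled brute-force enumeration of all internal-state assignments to
1e-8 on trees small enough to enumerate. Gaps and ambiguity codes
(IUPAC for nucleotides; B/Z/J/X for amino acids) contribute a partial
vector of ones over their compatible states. Reversibility makes the
likelihood invariant to root placement (checked to 1e-8), so unrooted
trees are scored by rooting arbitrarily.

## Branch-length optimization

Scoring a constrained topology fairly requires fitting its branch
lengths. `optimize_branch_lengths()` uses coordinate ascent: sweeping
the tree in pre-order, each branch is optimized by a bounded Brent
search (default interval [1e-8, 10]) while all others are held fixed.
The pre-order sweep keeps every quantity current at the moment each
branch is optimized — below-partials are untouched by ancestral
updates, above-partials are rebuilt on the way down — so every
accepted move maximizes the exact current likelihood and the total
log-likelihood is monotone non-decreasing. Through the model
eigensystem the per-branch objective collapses to one matrix–vector
product per gamma category, so the search is cheap. Sweeps stop when
a pass improves the total by less than `tol` (default 1e-6 nats) or
after `max_passes` (default 50; a `converged` attribute reports which
happened). Two-taxon data recover the analytic Poisson-distance MLE
to 1e-4; 2000-site simulations recover an 8-taxon tree's branch
lengths with mean absolute relative error under 15%.

## Sitewise contrast, ΔCLS, and the SH test

With both topologies scored, ΔSLSᵢ = ℓᵢ(mt) − ℓᵢ(nuc); positive
favors the mt-topology. Sites with ΔSLS strictly above 0.5 (or below
−0.5) count as strong — the threshold is a parameter, and the
boundary value itself is weak, following the strict inequalities of
the source convention. Summing ΔSLS over a marker group gives ΔCLS;
dividing by the group's site count gives the average ΔCLS, which is
comparable across groups of different size. Marker-level ΔCLS values
sum exactly to the matrix-level value.

The Shimodaira–Hasegawa test is implemented by RELL: site
log-likelihood vectors are resampled with replacement (no
re-optimization), each tree's resampled totals are centered at their
own mean, and a tree's one-sided p-value is the fraction of resamples
in which its centered gap to the resampled best tree reaches its
observed gap. The best tree has p = 1 by construction, and the test
is invariant to adding a constant to every site.

## Concordance factors

For an internal branch, the four surrounding subtrees define
quartets: one leaf drawn from each (uniform with replacement,
seeded). A site is decisive for a quartet when all four states are
unambiguous and form exactly a 2+2 pattern; it supports whichever of
the three resolutions pairs the equal states. sCF for a resolution is
the mean over quartets of the percentage of decisive sites supporting
it, so the three resolutions sum to 100 wherever defined; branches
with no decisive site in any quartet are reported missing, not zero.
Sites with three or four distinct states, gaps, or ambiguity are
indecisive — the parsimony-informative 2+2 definition keeps sampled
values equal to the exhaustive all-quartet computation (checked to 1
percentage point at 10,000 quartets). Quartet draws restart from the
user seed for every branch and marker, which makes results invariant
to input order and gives identical markers identical values. The
default of 100 quartets per branch matches common tool practice; the
1/3 plurality threshold is attached to per-marker reports as
metadata.

gCF counts, for each reference branch, the gene trees containing at
least one taxon from each of the four subtrees (decisive) and, among
those, the trees whose induced bipartition reproduces the reference
grouping (concordant). Unresolved gene trees are decisive but never
concordant — a conservative convention, flagged in the output so
users can recompute excluding polytomies.

## Composition statistics

All statistics ignore case, gaps, and ambiguous bases in both
numerator and denominator. AT skew = (A−T)/(A+T) and GC skew =
(G−C)/(G+C) measure strand asymmetry (each negates under reverse
complement); GT content = (G+T)/(A+C+G+T) maps to its complement. A
codon is GT-rich when its first **and** second positions are each G
or T — the conjunctive reading, which keeps the statistic distinct
from plain positional GT content; the disjunctive reading is
available via `positions = "either"` since the verbal definition
admits both. Four-fold degenerate families are derived from the
genetic-code table (standard table 1 or invertebrate mitochondrial
table 5, the default for mitochondrial genes): first-two-base
prefixes whose four third-position variants encode one residue; the
third-position GT content of those codons approximates neutral
mutational pressure. Unassigned regions are the complement of the
union of annotated features (strand ignored, coordinates 1-based
inclusive); their GT content is scored on the plus strand, the
convention assumed when the source strand is unstated.

## Group tests

Kruskal–Wallis uses the tie-corrected H with the χ² approximation on
k−1 degrees of freedom regardless of group size (the common practice
at these sample sizes; no exact small-sample tables). Dunn's z uses
mean-rank differences with tie-corrected variance and two-sided
normal p-values, Bonferroni-adjusted over all pairs; singleton groups
compute but are flagged low-power. The contact comparison uses the
pooled-variance Student t by default — the test named by the source
convention — with Welch available because unequal group variances are
plausible for sCF values.

## The synthetic-data generator

`make_topology_pair()` builds two trees on the same leaves differing
only in the focal branch's resolution (unrooted RF distance exactly
2). Branch lengths are exponential with mean 0.1 substitutions/site;
the focal branch defaults to 0.05, short enough that discrimination
is statistically nontrivial. `simulate_alignment()` draws root states
from π, a gamma category per site, and evolves states down each
branch; the clade shift is nonstationary — branches inside the
shifted clade (including its stem) use a model whose equilibrium mass
on G+T (nucleotides) or on the residues of GT-rich codon families
(F, L, V, C, W, G; amino acids) is raised by `shift_delta`, mirroring
a mutational/deamination mechanism rather than post-editing the data.
The shift moves exactly `shift_delta` of mass: targets scale to
m + δ, the rest to 1 − m − δ.

Coding sequences are drawn as independent codon triplets from
position-specific nucleotide frequencies with stop codons rejected —
composition, not selection, is the target, so no full codon model is
used. Mock mitogenomes interleave each taxon's simulated CDS with
unassigned spacers drawn from the taxon's (possibly shifted)
background frequencies.

Defaults emulate the study conditions: four clades of three taxa;
the thirteen mitochondrial OXPHOS markers plus two nuclear CII
markers at realistic protein lengths, grouped into the six complex
groups (CV, CIV, CIII, CII, CI-ms, CI-ps — the CI split separating
the nadh genes that change strand in Palaeoheterodonta from those
that do not); `shift_delta = 0.1` for Palaeoheterodonta (the source
reports the pattern only as boxplots, so the effect size is a
package choice, fixed once); all partitions simulated on `tree_a`.
For the contact analysis, `default_nuox_partitions()` mirrors the
nuclear OXPHOS panel on which that comparison was originally made —
24 contact markers versus 31 non-contact (the group sizes behind
"d.f. = 23, 30") — with the focal branch scaled 2× for contact and
0.25× for non-contact markers: a deliberately clear plant, since the
point of the fixture is that the detection chain finds a signal known
to be there. The 15-marker mitochondrial panel is too small for a
reliably significant two-sample comparison at modest effect sizes,
which is itself informative about the method's sample-size
requirements.

What the generator does **not** emulate: alignment error and masking,
paralogy, compositional heterogeneity within clades, selection on
codons, missing data patterns of real transcriptomes, and
heteroplasmy. Passing tests therefore show the statistics and their
power under the planted mechanism, not robustness to those real-data
complications.

## Numerical and design choices

- Internal coordinates are 0-based half-open only transiently; all
  user-facing tables and file formats are 1-based inclusive.
- Missing values are explicit `NA` sentinels in TSV output.
- The per-site likelihood scaling contract: identical to unscaled
  arithmetic wherever both are representable (tested).
- A site with zero likelihood (conflicting fixed states across a
  zero-length path) reports −Inf with a warning, never an error.
- Brent searches use an x-tolerance of 1e-6 within [1e-8, 10]; after
  each search the lower bound and the incumbent are also compared, so
  degenerate optima at the boundary are found exactly.
- Validation problem sizes: the likelihood oracle enumerates ≤5-leaf
  trees (10 sites, 2 gamma categories); power analyses use 20
  replicates of 50 partitions × 200 amino-acid sites on 8 taxa, with
  branch-length fitting at `max_passes = 3, tol = 0.01` from the
  generating/NNI-mapped starting lengths — at this size additional
  passes change total log-likelihoods by well under the contrast
  magnitudes; the type-I error check uses 2000 null Kruskal–Wallis
  datasets of 3 × 15 observations.

## Known limitations

- No topology search: trees are inputs (the constrained-topology
  analog is branch-length fitting only). No bootstrap, Bayesian, or
  mixture/codon models.
- The SH implementation resamples sites independently; partitioned
  block-resampling is not offered.
- sCF is undefined (missing) for branches/markers with no decisive
  site, which real, highly gapped markers can produce often.
- Gene trees are inputs; the package never infers them.
- Exact reproduction of the source study's numbers is out of scope by
  construction — they depend on unavailable transcriptome data; the
  package validates the method chain on planted truth instead.
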