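# phylodiscord

Tools for dissecting mito-nuclear phylogenetic discordance: when
mitochondrial and nuclear markers support two different resolutions of
the same deep branch — as in bivalves, where mitochondrial (and,
strikingly, nuclear OXPHOS) markers recover Amarsipobranchia
(Heterodonta + Pteriomorphia) while other nuclear markers recover
Heteroconchia (Heterodonta + Palaeoheterodonta) — the interesting
questions are *which sites and which markers* carry each signal, and
whether the discordant signal tracks a biological covariate such as
physical contact between subunits or strand-specific nucleotide
composition.

`phylodiscord` implements that dissection as a reusable, tested
pipeline, exercised end to end on synthetic data with known truth:

- **Sitewise topology contrast.** A fixed-topology likelihood engine
  (reversible amino-acid and nucleotide models, discrete-gamma rate
  heterogeneity, Felsenstein pruning, branch-length optimization on a
  constrained topology) produces per-site log-likelihoods under two
  candidate trees. The per-site difference ΔSLS = ℓ(mt) − ℓ(nuc)
  favors the mt-topology when positive; sites with |ΔSLS| > 0.5 are
  classified as strong; sums within a marker group give the groupwise
  score ΔCLS and its per-site average.
- **Tree comparison.** Shimodaira–Hasegawa test via RELL resampling of
  the sitewise log-likelihoods (centered, one-sided).
- **Concordance factors.** Site concordance (sCF) by seeded quartet
  sampling around any internal branch — a site is decisive when the
  four sampled leaves show an unambiguous 2+2 pattern — and gene
  concordance (gCF) by bipartition matching over gene trees; the three
  resolutions of a branch close to 100%.
- **Strand composition.** AT skew (A−T)/(A+T), GC skew (G−C)/(G+C),
  GT content, the frequency of GT-rich codons (G/T at both first and
  second codon positions), GT content at third positions of four-fold
  degenerate codons (families derived from genetic-code tables 1 and
  5), and GT content of the unassigned regions of annotated genomes.
- **Group tests.** Kruskal–Wallis with tie correction, Dunn's post-hoc
  test with Bonferroni correction, pooled/Welch two-sample t — used to
  compare composition across clades and sCF between markers in contact
  with mitochondrial subunits versus not.
- **Synthetic data.** A seeded generator that builds a pair of
  topologies differing by one NNI at a focal branch, simulates
  partitioned alignments with planted per-marker signal, applies a
  clade-specific GT compositional shift (nonstationary model swap on
  the shifted clade's branches), and writes a complete on-disk fixture
  (FASTA, Newick, partition file, group maps, mock annotated
  mitogenomes, JSON manifest).

## Worked example

```r
library(phylodiscord)

# a planted fixture: 4 clades, 15 OXPHOS-like markers simulated on
# tree_a, Palaeoheterodonta carrying a +0.1 GT shift
cfg <- sim_config(seed = 7)
fx  <- make_study_fixture(cfg, "fixture")

# score both topologies and contrast them per complex
res <- run_pipeline(pipeline_config("fixture", "reports", seed = 7))
res$by_complex[, c("group", "delta_cls", "avg_delta_cls", "scf_mt", "scf_nuc")]
```

```
  group delta_cls avg_delta_cls   scf_mt  scf_nuc
1    CV 16.901168   0.061458791 69.10705 13.64108
2   CIV 23.356320   0.023473689 56.82544 22.83297
3  CIII  5.719386   0.015457800 59.65891 22.59138
4 CI-ms 16.826657   0.021033322 59.04088 22.97765
5 CI-ps  5.782669   0.004739893 47.78632 21.10763
6   CII  2.594367   0.002982031 47.22572 19.04760
```

Every complex has a positive ΔCLS and a focal-branch sCF above the
1/3 plurality line under the generating topology — the fixture was
simulated wholly on `tree_a`, and the contrast recovers that. The SH
test in `res$sh` rejects the alternative resolution (ΔlnL = 71.2,
p = 0), the contact/non-contact comparison in `res$contact` finds the
markers simulated with stronger focal signal significantly more
concordant (mean sCF 60.6 vs 39.7, p = 0.018), and
`res$composition_tests` flags Palaeoheterodonta as significantly
GT-richer than every other clade (Dunn/Bonferroni adjusted
p < 1e-14).

A thin command-line wrapper over the same functions is installed at
`inst/cli/phylodiscord.R` (subcommands `simulate`, `score`,
`contrast`, `concord`, `compose`, `test`, `all`).

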