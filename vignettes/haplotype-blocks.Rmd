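---
title: "Haplotype-block construction and genomic prediction with hapblockr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block construction and genomic prediction with hapblockr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dense SNP panels in breeding populations are highly redundant: physically
close markers are co-inherited in blocks separated by (historical)
recombination events. Grouping markers into haplotype blocks and treating the
distinct allele strings within a block as the alleles of one multi-allelic
locus can (i) remove redundancy, (ii) tag causal variants that no single
biallelic SNP tags, and (iii) absorb local epistasis between tightly linked
loci into additive haplotype effects. Whether any of this improves genomic
prediction depends on the trait, the population and — critically — on how the
blocks are built. `hapblockr` implements the standard block-construction
rules, the haplotype coding, the kernels and the prediction models needed to
study exactly that question, plus a population simulator so that every claim
in the test suite is reproducible from code alone.

## Block construction rules

All builders partition each chromosome into non-overlapping blocks that
jointly cover every marker; markers that no rule groups become size-1 blocks
("unblocked SNPs"). Marker coordinates are 1-based bp (as in VCF); block
ranges are half-open marker-index intervals, which avoids any off-by-one
ambiguity downstream.

* **LD threshold** (`blocks_ld_threshold`): blocks are seeded at the adjacent
  pair with the highest r² meeting the threshold and extended at both borders
  while the candidate marker and the *current border marker* stay above the
  threshold. A tolerance of 1 (the default) lets one failing marker be
  absorbed when the next marker passes against the same border marker;
  tolerated markers at a chromosome end with no subsequent passing marker are
  not absorbed. Seed ties break to the lowest marker index. The canonical
  parameter grid is 0.01–1.00 in steps of 0.01 (`ld_threshold_grid()`).
* **Fixed marker windows** (`blocks_fixed_markers`): consecutive windows of
  `m` markers from the start of each chromosome; the grid
  `window_size_grid("markers", ...)` is `ceiling(2^x)` for x = 1, 1.5, 2, …,
  truncated after the first value that reaches the chromosome extent so the
  whole-chromosome block remains representable.
* **Fixed bp windows** (`blocks_fixed_bp`): bins `[1, w], (w, 2w], …`
  anchored at position 1; the bp grid uses x = 10, 10.5, 11, …
* **D′ confidence intervals** (`blocks_gabriel`): a pair is in "strong LD"
  when the 95% upper confidence bound on D′ exceeds 0.98 and the lower bound
  exceeds 0.70. Blocks grow left-to-right while the (first marker, candidate)
  pair stays strong. We follow the simplified outermost-pair growth rule, not
  the original human-map rule that requires 95% of informative interior pairs
  to be strong — the latter is a different algorithm with additional
  parameters that the sources this package follows do not use.
* **Four-gamete rule** (`blocks_four_gamete`): a candidate joins a block only
  if no pair (block member, candidate) shows all four two-locus gametes at
  ≥ 1% frequency; otherwise a border is created.
* **Solid spine of LD** (`blocks_solid_spine`): from each anchor the farthest
  marker with pairwise D′ > 0.8 closes a block; intermediate markers need not
  be in LD. Scanning resumes after a found block (greedy, non-overlapping) —
  overlap resolution is unspecified in the method's description, and the
  greedy choice keeps the partition property without further parameters.

Subgroup-specific block systems (merge/split algorithms) are out of scope;
`import_partition()` accepts externally computed intervals instead.

### D′ confidence bounds

The original Gabriel-style implementation derives D′ bounds from a
likelihood grid. We use a nonparametric percentile bootstrap over
individuals (both gametes of a phased diploid resample together,
`n_boot = 200`, seeded per marker pair so results do not depend on
evaluation order). The bootstrap is assumption-free, testable against its
own stored replicates, and a documented swap point: any classifier of
"strong LD" can be plugged into the growth rule. Replicates in which a locus
collapses to monomorphic are redrawn up to 10 times, then dropped with a
warning; monomorphic-pair LD is an error everywhere else rather than a
silent zero, because silent zeros would corrupt threshold-based extension.

## Haplotype coding

Within each block, the distinct gamete strings are the haplotype alleles; a
homozygous line contributes one gamete, a phased hybrid two. Blocks with two
haplotypes are coded like biallelic SNPs (one column, minor-haplotype
dosage); blocks with k > 2 haplotypes contribute one column per haplotype.
The columns of a k > 2 block are linearly redundant (they sum to 2 per
sample) — we keep all k deliberately: the genomic relationship matrix is
centered, so the redundancy is harmless, and the per-haplotype coding is
reproduced literally. Columns are centered by twice the haplotype frequency
and the VanRaden denominator `2 Σ p(1−p)` accumulates over all emitted
columns. With an all-singleton partition this reduces bit-for-bit to the
standard centered SNP design — the coding-equivalence tests rely on it.

Rare haplotypes are *not* excluded by default (the analyses this package
mirrors kept them); `build_design(..., min_hap_freq = )` exists because
exclusion is the obvious dimensionality lever.

## Kernels and models

* `grm_vanraden`: G = ZZ′ / (2 Σ p(1−p)). On fully inbred panels
  `mean(diag(G)) ≈ 2`; variance components on G therefore map to phenotypic
  variance through the kernel's mean diagonal, which is how `fit_gblup`
  reports `heritability`.
* `epistatic_grm`: the additive×additive kernel is the Hadamard square of G.
* `gaussian_kernels`: K = exp(−h·d²/mean(d²)) with the mean off-diagonal
  squared Euclidean distance as the normalizer, so the printed bandwidths
  {0.1, 0.5, 2.5} are scale-free.
* `fit_gblup` / `fit_egblup`: REML. Single-kernel fits use the spectral
  shortcut (one symmetric eigendecomposition, 1-D search over the log
  variance ratio); multi-kernel fits optimize the profiled likelihood over
  log variance ratios with a Cholesky factorization per evaluation. Both
  profile out the residual variance, making the fits exactly
  scale-equivariant; variance ratios are bounded in `exp(±23)`, i.e.
  components are clamped inside the optimizer, never truncated post hoc. A
  diagonal jitter of `1e-8 · mean(diag)` is added before any factorization.
* `fit_bayesian_lasso`: Gibbs sampler for the Park–Casella scale-mixture
  representation (inner loop in C++). λ² carries a Gamma(1.1, rate) hyperprior
  whose mode sits at the heuristic `2(1−R2)·MSx/R2` with R2 = 0.5; the
  residual variance has a scaled-inv-χ²(5, ·) prior from `var(y)`.
* `fit_rkhs`: kernel averaging — one random effect per Gaussian kernel,
  sampled in each kernel's eigenbasis; the variance components weight the
  kernels. The literature's summation index for this model is garbled in
  places; it is read as l = 1..L over all supplied kernels.

Chain defaults are 6000 iterations, 1000 burn-in, thinning 5 — longer than
the defaults of the reference implementations, which the source analyses ran
as-is; we prefer chain quality over speed and record the settings in every
fit object.

## Cross-validation

`random_cv` is repeated random subsampling (100 independent 80/20 splits by
default), *not* k-fold; validation size is `round(n·0.2)` with exact ties
rounded up. Per-run seeds derive deterministically from the master seed, so
any run can be replayed in isolation. Failed runs are excluded from the mean
and counted, never scored zero (zero-filling would bias method comparisons).
`family_cv` leaves each family of ≥ 3 samples out once. Accuracy is the
plain Pearson correlation between observed and predicted values; per-run
accuracies are averaged arithmetically (no Fisher z), matching how such
results are usually reported.

## The simulator and what a green test establishes

`simulate_population` is a forward-in-time founder-recombination simulator,
not a coalescent: founders are homozygous lines with independent allele
frequencies ~ U(0.1, 0.9); descendants are mosaics produced by meioses with
Poisson(1.5) crossovers at uniform positions per chromosome per meiosis,
then fixed as doubled haploids. This produces the block-like, distance-
decaying LD and the controllable family structure (NAM half-sib DH families,
in-silico testcross hybrids) that the package's methods presume. Defaults —
10 founders, 3 generations, 1.5 crossovers per chromosome, 50 Mbp
chromosomes — are a deliberately generic crop-panel world: small enough to
test in seconds, structured enough that LD-based blocks are non-trivial.

`simulate_phenotypes` draws additive QTL effects on standardized dosages
plus local epistatic pairs (centered dosage products within a 5 Mbp window)
scaled to a 4:1 additive:epistatic variance ratio; the residual is
orthogonalized against the genetic values and rescaled so the realized
sample heritability equals the target *exactly*.

What the simulator does not emulate: array ascertainment bias, genotyping
and imputation error, mutation, selection, recombination hotspots, and
allopolyploid marker ambiguity. A green directional test (e.g. "whole-
chromosome blocks hurt accuracy, 2–4-marker windows match SNPs") therefore
establishes that the implementation reproduces the expected behavior in a
clean, structured population — not that the effect sizes transfer to any
particular crop dataset.

## Numerical and design choices, in one place

* Marker filtering (MAF ≥ 0.05 inclusive, ≤ 10% missing) runs before
  imputation, following the order in which the steps are conventionally
  described; the naive seeded frequency-sampling imputer is a stand-in for
  haplotype-aware imputation, which is out of scope.
* Minor-allele orientation is fixed at read time from the full sample.
* Heterozygous unphased input is rejected wherever haplotypes are needed;
  the intended material is DH/inbred lines and phased in-silico hybrids.
* Relationship correlations exclude the diagonal: off-diagonal entries are
  the relationship coefficients proper.
* Whether MAF should be computed before or after imputation, and whether
  relationship correlations should include diagonals, are unspecified in the
  sources; the choices above are fixed and tested.
* Pipeline configs are JSON rather than YAML (no YAML parser in the
  supported dependency set); structure is unchanged.

## Known limitations

* Bootstrap D′ bounds are wider than likelihood-grid bounds at small n, so
  `blocks_gabriel` is conservative on tiny panels.
* The Bayesian samplers predict new samples from posterior means (plug-in),
  not by joint sampling with masked phenotypes; the difference is negligible
  for point accuracy but matters for predictive intervals, which the package
  does not provide.
* EM-based haplotype-frequency estimation for unphased heterozygotes,
  pedigree kernels, dominance, BayesB/Cπ-type models and machine-learning
  predictors are deliberately out of scope.
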