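---
title: "Methods: genomic diversity analysis of ddRAD SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic diversity analysis of ddRAD SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radpop implements the statistical pipeline used to characterise genomic
diversity in crop germplasm collections genotyped with reduced-representation
(ddRAD) SNPs — the setting is a panel of a few hundred tomato accessions
(landraces, heirlooms, cultivars, breeding lines) typed at tens of thousands
of biallelic SNPs, with particular interest in the Mediterranean long
shelf-life 'da serbo' landrace group. This vignette explains each model and
procedure, the parameters that matter, and the choices made where the design
was genuinely open.

## The genotype container and coordinate conventions

All analyses run on an accessions x loci dosage matrix counting ALT alleles
(0/1/2, `NA` for missing). Dosage is deliberately ALT-oriented rather than
minor-allele-oriented: I/O is then deterministic and independent of allele
frequencies, and the minor-allele orientation is applied once, panel-wide, in
the diversity statistics. VCF positions are 1-based; BED gene intervals are
0-based half-open. The conversion lives in a single internal predicate
(`start < pos <= end`), because a silent off-by-one at this boundary is the
classic failure mode of region queries; both boundary directions are pinned
by tests. Multi-allelic and indel records are excluded at read time, not
split: every downstream statistic (PIC, gene diversity, r², the contrast
screen) is defined for biallelic SNPs. Phased and unphased genotype
separators are treated identically since phase is unused.

## Staged variant filtering

Quality control mirrors the standard reduced-representation workflow:
a locus-presence filter (locus kept when genotyped in at least `r` = 0.75 of
accessions, the `populations -r` criterion), then a minor-allele-frequency
floor (MAF >= 0.05), then a missingness ceiling (<= 20%), each stage applied
to the survivors of the previous one. Call rate and missing fraction are
complementary, but both knobs are exposed because reports conventionally
list them separately. The MAF threshold is implemented as inclusive (>=),
matching common tooling defaults; the boundary is tested explicitly. The
composed pipeline is idempotent, and its survivor sets are checked against a
brute-force per-locus oracle on random matrices.

Per-chromosome SNP density reports mean inter-SNP spacing as
`(max pos - min pos) / (count - 1)` — the standard span-based definition —
and is undefined for chromosomes with fewer than two loci.

## Diversity statistics

For ALT frequency `p` (computed over non-missing calls) and `q = 1 - p`:

* Gene diversity (Nei expected heterozygosity): `2pq`, range [0, 0.5].
* PIC (Botstein): `1 - (p² + q²) - 2p²q²`, range [0, 0.375].

These two ranges differ, although descriptions of biallelic marker
statistics sometimes attach the 0–0.5 range to both; the observed maximum
PIC of 0.375 in real SNP panels confirms the Botstein form, and both
statistics are implemented with their correct analytic ranges. Observed
heterozygosity is the heterozygote fraction per locus; per-sample
heterozygosity is the percent of heterozygous calls per accession. Because
ambiguity between observed and expected heterozygosity is common in survey
papers, both are always reported.

Group-wise MAF (`group_maf()`) fixes the minor allele from the full panel
and reports that allele's frequency within the group. A per-group
re-orientation would make a cross-group contrast incoherent (the two values
could refer to different alleles), so a group value may legitimately exceed
0.5.

## The admixture model

Genotypes follow `g_ij ~ Binomial(2, π_ij)` with `π_ij = Σ_k q_ik f_kj`:
`Q` holds per-accession ancestry proportions over `K` clusters, `F` the
cluster allele frequencies. Estimation is by block EM on allele-copy
responsibilities; the log-likelihood is computed at the start of every
iteration, so the trace is provably non-decreasing and tested as such. EM is
used instead of quasi-Newton block relaxation because the two share
stationary points and monotonicity is straightforward to verify; convergence
is `|Δℓ| < tol` (default 1e-4) with `max_iter` 2000. Cluster frequencies are
clamped to [1e-6, 1-1e-6].

Random initialisations started near the symmetric configuration (all
clusters equal) can linger on that saddle long enough to trip the
convergence test, so the first restart uses a spectral warm start: k-means
on the leading principal components of the mean-imputed dosage matrix seeds
`F` with distinct frequency profiles. Remaining restarts are random, and the
best final likelihood wins. Labels are ordered by total membership for
reporting; comparisons across restarts, folds or against simulated truth use
explicit alignment (exhaustive permutation search for K <= 7, greedy
correlation matching above).

The number of clusters is chosen by ten-fold cross-validation in the
entry-masking sense: non-missing genotype *entries* are partitioned into
folds, each fold is hidden in turn, and the held-out entries are scored by
mean binomial deviance `-[g log π + (2-g) log(1-π)]/2`. Masking entries
rather than whole samples matches the cross-validation semantics
popularised by the ADMIXTURE software. Accessions whose top membership is below 0.5 (or
tied) are reported as admixed. Between-cluster F_ST is the Hudson-type ratio
of averages computed from the fitted `F`; no finite-sample correction is
applied there because the frequencies are parameters, not samples (the
empirical estimator `hudson_fst()`, used on observed genotypes, does apply
the correction). A loci-bootstrap for membership standard errors is provided
but off by default: it refits the model per replicate and is rarely needed
outside final reporting.

## Distances, clustering and ordination

The dissimilarity index between two accessions is the proportion of
unmatching alleles over co-non-missing loci, `mean(|g_a - g_b|/2)` — equal
to one minus the allele-sharing proportion, so the "allele-sharing distance"
used for dendrograms and the "dissimilarity index" used for redundancy
detection are the same quantity under two names. Identical accessions score
exactly 0 and are labelled redundant; `redundancy_scan()` lists all pairs
below a threshold (default 0.005, chosen to bracket observed near-duplicate
values of ~0.002 while staying an order of magnitude below typical
within-group distances). Pairs with no shared locus are an error unless
explicitly allowed.

Hierarchical clustering uses Ward.D2 on this distance; trees export to
Newick. Principal-coordinates MDS double-centres the squared distances and
keeps the leading positive eigenvalues; negative eigenvalues (the distance
is not exactly Euclidean) are reported, never used, and each axis is
sign-fixed by making its largest-magnitude loading positive so embeddings
are reproducible.

The non-parametric cluster-number analysis runs Lloyd k-means (k-means++
seeding, best of `restarts`) on the top MDS coordinates — a distance-based
strategy in the AWclust tradition, which makes an information criterion
well-defined on coordinates. Model selection uses the spherical-Gaussian
hard-assignment BIC (the X-means criterion): with pooled variance
`σ̂² = WSS/(d(n-k))`,

```
loglik = Σ_c n_c log(n_c/n) - (n d/2) log(2π σ̂²) - d(n-k)/2
BIC    = -2 loglik + (k - 1 + k d + 1) log n
```

A simpler `n d log(WSS/(nd)) + k d log n` score was considered and rejected:
splitting a single Gaussian cluster reduces WSS by a roughly constant
factor, so that score keeps decreasing with k and can never select a finite
optimum on well-separated data — the multinomial assignment term in the
X-means form is what makes the criterion consistent (verified numerically on
two 10σ-separated blobs, where the implemented criterion selects k = 2).

## Linkage disequilibrium

r² is the squared Pearson correlation of dosages over co-non-missing
samples — composite LD, which needs no phasing and coincides with haplotype
r² in highly homozygous (selfing) material; it is undefined for loci
monomorphic on the shared subset and invariant to REF/ALT orientation.
Decay curves score all intra-chromosomal pairs up to `max_dist_bp` (default
300 kb), binned by distance (default 100 bp bins to 10 kb, 1 kb beyond; any
break vector can be supplied — sparse panels want wider bins). The
half-decay distance is this package's operationalisation of "rapid decay":
the smallest bin midpoint where the 3-bin smoothed curve falls to midway
between its peak and the far-field level (mean of the last decile of bins).
LD pruning slides a window (50 SNPs, step 5) and, while any in-window pair
exceeds `r2_max` = 0.2, removes the lower-MAF member (ties: higher index);
the procedure is deterministic and idempotent.

## The private-allele contrast screen

To find loci distinguishing a focus group (default the 'da serbo'
landraces), MAF is computed separately in the group and its complement under
panel-global orientation. A hit requires group MAF strictly above 0.4 and
complement MAF strictly below 0.2; hits with complement MAF below 0.1 form
the `most_contrasting` tier (tiers are nested by construction). The strict
inequalities follow the thresholds as conventionally printed and the
boundary is tested. The screen is a descriptive threshold rule — no
multiple-testing correction — but an optional Fisher-exact p-value column on
allele counts can be attached as clearly-extra output. Loci with undefined
group frequency are excluded; a `min_group_calls` floor (default 1, i.e.
only non-missing calls are required) is exposed because per-group call-rate
requirements vary between studies. Hits can be annotated genic/intergenic
against gene intervals, reporting all overlapping interval names.

## Mini-core selection

The mini-core objective is the mean entry-to-nearest-entry (E-NE) distance
of the selected subset on the allele-sharing dissimilarity — the canonical
spread criterion of core-collection samplers (mean entry-to-entry is
available behind a flag). Core size defaults to `round(0.2 n)`, the
conventional 20% sampling intensity (58 from a panel of 288). Optimisation
is steepest-ascent single-swap local search with random restarts: strictly
improving swaps guarantee termination, determinism comes from the seed, and
on instances small enough to enumerate (n <= 12) the search attains the
exhaustive optimum in >= 95% of random instances, which serves as the
optimality safety-net in tests. Representation reports cross-tabulate the
core against biological status and ancestry cluster and flag any cluster
left empty.

## The synthetic panel generator

Every stage above is validated against panels with known truth from
`simulate_panel()`. The generative model:

* **Subpopulation frequencies.** Ancestral frequencies are Uniform(0.05,
  0.95) — a spectrum whose common alleles survive the 0.05 MAF floor — and
  each of `K` populations diverges under the Balding–Nichols Beta model with
  parameter `F_k` (`E[f] = p`, `Var[f] = F p(1-p)`), so pairwise population
  F_ST is `F` by construction and recovery can be tested quantitatively.
* **Linkage.** Each population has `n_founders` (default 10) founder
  haplotypes; a sample haplotype copies a founder and switches founders
  across a gap of `d` bp with probability `1 - exp(-ρ d)`. Founder sharing
  decays with distance, so r² decays with distance with half-decay on the
  order of a few kb at the default `ρ` = 2e-4 (calibrated empirically: at
  this rate the measured half-decay is ~2–3 kb, inside the "decays within a
  few kb" regime reported for tomato collections; the true decay scale of
  any particular crop is not otherwise calibrated).
* **Inbreeding.** The second allele copies the first per locus with
  probability `selfing` (default 0.90). Without this knob a founder-mosaic
  model yields ~25–30% heterozygosity; tomato landraces are predominantly
  selfing with per-sample heterozygosity around 2–5%, and the default
  reproduces that band. Setting `selfing = 0` with a large founder pool and
  a high switch rate gives Hardy–Weinberg sampling, used by the tests that
  need binomial allele-frequency noise (e.g. F_ST recovery).
* **Admixture.** A fraction of samples (default 3%, matching roughly 9 of
  288 admixed accessions) draws its membership row from Dirichlet(α) with
  α = 0.1.
* **Composition.** Biological statuses are apportioned by largest remainder
  from the observed panel composition (77 'da serbo', 75 fresh-consumption
  landraces, 46 heirlooms, 76 cultivars, 14 breeding lines out of 288).
* **Planted truth.** `n_private` loci (default 20 at L = 2000 — sparse, but
  enough plantings to estimate recall) are resampled so the ALT allele is
  the global minor allele with frequency ~0.55 in the 'da serbo' group and
  ~0.02 elsewhere, comfortably inside the > 0.4 / < 0.1 contrast contract at
  group sizes >= 30 while leaving the screen's thresholds doing real work.
  Near-duplicate pairs copy an accession (within its status group, so the
  composition is preserved) and perturb each call with probability 1e-3.
  Missingness is MCAR (default 5%), applied last.

All draws flow from one seed; the same configuration is byte-reproducible.
What the generator does *not* emulate: coalescent genealogies and
recombination-graph realism, selection or demographic history, non-random
missingness, genotyping error structure beyond the duplicate perturbation,
and linkage between the planted contrast loci and their background. Passing
tests therefore demonstrate correctness of the statistical machinery under
a controlled, well-specified model — not robustness to every artefact of
real ddRAD data.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each property has enough
signal without waste: admixture recovery at n = 90, L = 1000, K = 3
(membership mean absolute error <= 0.05 after label alignment);
cross-validated K selection at n = 120, L = 1500 with true K = 6 over
K ∈ 1..8 (a looser EM tolerance of 1e-2 is used inside CV, where held-out
deviance — not the final likelihood digit — is the quantity of interest);
F_ST recovery at n = 100 per population, L = 5000; LD background at n = 100
(expected unlinked r² ≈ 1/n); core-selection optimality on 100 instances
with n <= 12. Degenerate inputs are defined, not accidental: all-missing
columns are errors where a frequency is required; empty filter survivor sets
return valid empty objects; k-means empty-cluster collapses restart and a
persistently unrealisable k is reported as such; MDS warns and truncates
when fewer positive eigenvalues exist than requested dimensions; ties are
broken deterministically everywhere (argmax ties classify as admixed; equal
MAF in pruning drops the higher index).

## Known limitations

The EM optimiser, like all admixture estimators, converges to local optima;
the spectral warm start plus restarts is a mitigation, not a guarantee. The
composite-r² estimator equals haplotype r² only in predominantly homozygous
material; in an outcrossing panel the two diverge. The half-decay statistic
depends on the binning and far-field window on sparse panels — use wider
bins when pair counts per bin are small. Swap local search for the core is
quadratic per step and intended for panels of hundreds, not tens of
thousands, of accessions. The contrast screen is descriptive: with small
groups, frequency-sampling noise produces false hits at rates the simulator
quantifies, and any inferential use should go through the optional exact
test or an explicit resampling design.
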