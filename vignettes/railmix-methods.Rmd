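---
title: "railmix: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{railmix: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(railmix)
```

railmix classifies cryptic introgression between two hybridizing species —
developed around the king rail / clapper rail system — from a small panel of
diagnostic nuclear SNPs plus a short mitochondrial fragment. This vignette
is the package's own account of the science: the models, the assumptions
they carry, every threshold that matters, and the places where the design
was genuinely open.

## 1. The likelihood shared by hybrid index and supervised Q

Genotypes are coded as counts of the king-associated allele, `g ∈ {0, 1, 2}`
with `NA` for unscored loci. Each of an individual's `2 × n_scored` allele
copies is modelled as an independent draw from a two-component mixture: with
probability `h` the copy descends from the king gene pool (where the
king-associated allele has frequency `p_K` at that locus), otherwise from
the clapper pool (frequency `p_C`). The log-likelihood

```
l(h) = Σ_loci [ g · log(h·p_K + (1−h)·p_C) + (2−g) · log(h·(1−p_K) + (1−h)·(1−p_C)) ]
```

is a sum of logs of affine functions of `h`, hence concave with a unique
maximiser on `[0, 1]`. `hybrid_index()` and `supervised_q()` optimise this
same function (they agree to 1e-6 by construction, which the tests assert),
differing only in presentation: one reports `h`, the other a two-cluster
membership vector.

**Numerical choices.** On a fixed-difference panel (`p_K = 1`, `p_C = 0`
everywhere) the MLE has the exact closed form "king-allele fraction among
scored copies", and the implementation returns that closed form so boundary
values are exact (`h = 1` for a pure king cohort, not `1 − ε`). Otherwise
Brent search (`stats::optimize`, tolerance 1e-9) is polished by an explicit
endpoint comparison, because the optimum of a concave function may sit on
the boundary where Brent never evaluates. Zero-scored individuals yield
`NA` with `n_scored = 0` rather than an error. A 2-log-likelihood-unit
profile support interval is reported for context; classification uses point
estimates only, as in the original survey protocol.

## 2. Interspecific heterozygosity and hybrid classes

Interspecific heterozygosity is the fraction of scored loci with `g = 1`.
With fixed parental differences an F1 is heterozygous everywhere, an
expected half of loci stay heterozygous after one backcross, and so on — so
the pair `(h, het)` dates the hybridization event. Classification applies
the published thresholds in order:

1. `h ∈ [0.25, 0.75]` and `het > 0.3` → `F1F2`;
2. `h ∈ [0.05, 0.25)` → `BACKCROSS_CLAPPER`; `h ∈ (0.75, 0.95]` →
   `BACKCROSS_KING` (mirror image — the original rules are stated only for
   the clapper side because no king-side admixture was observed);
3. `h < 0.05` → `PURE_CLAPPER`; `h > 0.95` → `PURE_KING`;
4. everything else → `UNASSIGNED`.

**Tie-breaks and the undefined cell.** The published intervals overlap at
`h = 0.25`; we give that boundary to the F1/F2 window when `het > 0.3`
(conservative about recent hybrids) and otherwise let it fall through to
`UNASSIGNED`. Intermediate `h` with low heterozygosity — the genotype of a
long-stabilised hybrid swarm — is genuinely not covered by any published
rule, and forcing it into a class would hide exactly the individuals a
manager should look at; it stays `UNASSIGNED` and is surfaced in reports.
Every point of the unit square maps to exactly one class (property-tested).

In the cyto-nuclear table, nuclear status collapses to
`pure_clapper` / `mixed` / `pure_king`. `UNASSIGNED` individuals are counted
as `mixed`: their intermediate hybrid index implies ancestry from both
species even though no generation class applies. This is our extension —
the three-level scheme has no cell for them.

## 3. Unsupervised admixture: ML EM instead of Bayesian MCMC

The reference analysis used Bayesian clustering (STRUCTURE, admixture model
with correlated allele frequencies, 5 runs × K). railmix replaces it with
maximum-likelihood admixture à la ADMIXTURE: `g_il ~ Binomial(2, Σ_k q_ik
f_kl)` with independent cluster frequencies, fitted by block EM. The
substitution is deliberate: deterministic, seconds on a laptop, and at 13
strongly diagnostic loci with K = 2 the point estimates support the same
0.98 / 0.50 thresholding. Five random restarts (mirroring the five runs per
K of the field protocol) guard against local optima; K is compared by mean
log-likelihood across starts, with the choice of K left to the user.

**What the substitution changes.** A Bayesian posterior mean is shrunk
toward the corners by the prior and the correlated-frequency model; a plain
MLE is not. Under the package's own generator (panel differentials
truncated-normal with mean 0.96, SD 0.08, floor 0.7), a pure individual
carrying one or two king alleles at the panel's weaker loci
(`p_C ≈ 0.1–0.15`) receives an interior membership: the *optimum* of the
likelihood — verified against the fully-separated labelling, which scores
~20 log-units worse — places pure cohorts a mean ≈ 0.02 off the corners.
Consequences documented (and tested as the true behaviour rather than
papered over):

* not every pure-site individual reaches `Q ≥ 0.98`, so surveys simulated
  with the default panel flag some genuinely pure sites `ADMIXED` — a
  conservative failure mode for reference building;
* the parameter-recovery bound (mean `|q̂ − truth| < 0.02` on 30 + 30 pure
  individuals) is tested on the fixed-difference panel, where it is a
  property of the estimator rather than of the panel's weak-locus tail.

**Numerical choices.** Frequencies and memberships are clamped to
`[1e-9, 1 − 1e-9]` to keep the likelihood finite at data configurations
that push parameters to the boundary; the monotone-ascent invariant is
asserted in tests with slack 1e-8 to absorb the clamp. Convergence is a
log-likelihood gain below `tol = 1e-6` (cap 2000 iterations; non-convergence
is flagged, not thrown). Label switching is resolved by matching estimated
cluster frequencies to supplied reference frequencies — never by membership
magnitude, which would be circular. `K = 1` is handled in closed form.

**Site purity.** A site is pure only if *every* individual has `Q ≥ 0.98`
toward the same species (closed at 0.98; the admixed interval
`[0.50, 0.98)` is half-open so the two rules partition `[0.5, 1]`). A site
whose individuals are all "pure" but for different species cannot serve as
a single-species reference and is classed `ADMIXED`; the original survey
never met this case, so the rule is ours.

## 4. Genotype calling and QC

GT-seq style ratio calling: cells with fewer than `min_depth = 10` total
reads are not scored (published cutoff); otherwise the allele-1 read
fraction `f` calls homozygous at `f ≥ 0.9` or `f ≤ 0.1`, heterozygous in
`[0.35, 0.65]`, and is left unscored (ambiguous) in between. The ratio
cutoffs are *conventions of the cited GT-seq pipeline*, not published
values, and are exposed as arguments. Ambiguity maps to missing, mirroring
"not scored", rather than raising an error. Calling is monotone under depth
scaling (property-tested).

Sample QC applies both published filters, the weaker one first so it cannot
be masked: drop samples scored at fewer than 4 loci, then samples missing
at more than 30% of loci. With 13 loci the 30% rule is strictly stronger,
so order is immaterial here, but both knobs are exposed. The filter is
idempotent.

## 5. Mitochondrial species identification

Diagnostic sites are the alignment columns where the two voucher sets are
reciprocally fixed for different nucleotides (`N`, gaps and IUPAC
ambiguities carry no information). A sample is called to species when it
matches at least `min_match = 6` of the 8 sites — the published floor, which
is panel-specific (it was set by the minimum number of diagnostic alleles
among voucher specimens) and therefore configurable. Sites with `N`/gap in
the sample count toward neither species; if both species could reach the
floor the function stops, since that indicates `min_match ≤ |sites|/2`.

Sequences are assumed co-registered to the voucher frame: the fragment is
protein-coding, so real data have no indels after standard alignment, and
bundling an aligner is out of scope. `register_offset()` handles the
off-by-k case by ungapped sliding-window identity.

## 6. The synthetic-data generator: the stated world

The generator reproduces the statistical structure the analysis assumes,
with defaults fixed once from the study system:

| Parameter | Default | Why |
|---|---|---|
| panel size | 13 loci | size of the published diagnostic panel |
| differential distribution | Normal(0.96, 0.08) truncated to [0.7, 1] | published panel statistics (mean, SD, floor) |
| parental frequency placement | symmetric about 0.5 | only the differential is published; symmetry adds no further assumption |
| pure-parent genotypes | Hardy–Weinberg at panel frequencies | standard reference-population model |
| crosses | per-locus Mendelian gametes from explicitly simulated parents | makes Mendelian conservation true by construction, testable via `keep_parents` |
| backcross recursion | hybrid × pure only, depth 2 | matches the class vocabulary (F1, F2, BC1, BC2) |
| sex of cross parents | Bernoulli(0.5), recorded | maternal mtDNA inheritance drives cyto-nuclear discordance |
| read depth | NB(mean 2400, size 1.5) | the study reports ≈31,869 reads/sample over 13 loci ≈ 2,450× per locus; size 1.5 gives the strong overdispersion typical of amplicon pools |
| allele error rate | 0.005 | typical amplicon miscall/index-hop rate; must stay ≪ the 0.1 hom cutoff |
| mtDNA fragment | 620 bp, 8 diagnostic sites | published fragment |
| mtDNA background divergence (demo) | 0.002 | rare within-species polymorphism; never hits diagnostic sites unless `diagnostic_site_noise > 0` |

What the generator does **not** emulate: linkage between loci (the
diagnostic-panel analysis assumes independence anyway), selection against
hybrids, spatial/clinal structure, coalescent depth (shared ancestral
polymorphism enters only through the `< 1` differentials), within-species
mtDNA phylogeography, and laboratory artefacts other than symmetric
per-read allele error. A green test therefore establishes that the
*analysis* behaves as specified on data obeying its own assumptions — not
that those assumptions hold in any particular marsh.

One worked consequence of the stated world: a first-generation backcross on
a fixed panel is heterozygous at `X ~ Binomial(13, 1/2)` loci, with
`h = X/26` and `het = 2h`. So `P(classified BACKCROSS) = P(2 ≤ X ≤ 6) ≈
0.50`, with most of the remainder falling in the F1/F2 window
(`X ≥ 7 ⇒ h ≥ 0.269, het ≥ 0.538`). BC1 recovery around 50% is thus the
*correct* behaviour of the published thresholds at 13 loci, which is why the
tests assert the exact binomial expectation and report a confusion matrix
instead of demanding near-perfect recovery.

## 7. Pipeline and reproducibility

`run_pipeline()` executes nine stages (load, call, QC, mtDNA, ancestry,
site purity, reference selection, hybrid index, classification/summaries).
Reference parental frequencies are re-estimated from pooled all-pure sites
(mirroring reference-file construction in the original analysis) and fall
back to the input panel, with a warning, for a species lacking a pure site.
Every stochastic stage derives its stream from the single config seed via a
fixed linear-congruential child-seed map; the manifest records stages,
parameters and output checksums but no timestamps or absolute paths, so
identical configurations produce byte-identical output trees (asserted in
the acceptance suite). Diagnostic-site positions are 1-based throughout, as
is idiomatic in R.

## 8. Known limitations

* The hybrid-index model treats loci and allele copies as independent;
  uncertainty from the small panel is reported (support intervals) but not
  propagated into classes.
* ML memberships are not posterior probabilities; the 0.98 purity cutoff is
  stricter in effect than under Bayesian shrinkage (see §3).
* The EM likelihood is multimodal in principle; five restarts are a
  heuristic, with the grid-search bound tested only at toy sizes.
* `derive_diagnostic_sites()` requires pre-aligned, equal-length input; it
  will not rescue indel-containing or reverse-complemented sequences.
* The simulator's pedigree classes stop at second-generation backcrosses;
  deeper introgression appears only through the `UNASSIGNED`/pure tail.
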