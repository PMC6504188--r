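---
title: "Fine-mapping HLA association signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping HLA association signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafinemap)
```

## The problem

The major histocompatibility complex (6p21.3) carries the strongest
genetic signals of most autoimmune diseases, systemic lupus erythematosus
(SLE) included, but extreme allelic diversity and long-range linkage
disequilibrium make it hard to say *which* classical allele or amino-acid
residue drives a signal. The established strategy is to impute, from SNP
genotypes, the dosages of classical HLA alleles and of the amino-acid
residues they encode (SNP2HLA-style output), and then dissect the region
with multi-allelic association tests and nested conditional analysis.

`hlafinemap` implements that workflow end to end: the dosage data model,
marker-level logistic association, multi-allelic omnibus likelihood-ratio
tests, the stepwise conditional framework, cross-cohort combination,
liability-scale heritability, risk-residue burden and genetic risk scores,
EM haplotype estimation with Lewontin LD, autoantibody sub-phenotype
contrasts, and a contact-potential model of which binding-groove
side-chains prefer immunogenic peptides. Because individual-level HLA
genotypes are access-restricted, the package also contains a first-class
synthetic-cohort generator; every stage is exercised and verified on data
with known ground truth.

## Data model

A *marker* is one imputed biallelic indicator: a SNP, a 2- or 4-digit
classical allele, or an amino-acid residue presence marker
(`AA_<gene>_<position>_<bp>_<residue>`, with `x` for absence/indel
groupings). Dosages live in $[0,2]$ and are used as-is in regression —
no rounding — matching how imputed dosages are analyzed in practice;
best-guess hard calls appear only where the method requires discrete
genotypes (burden counts, haplotype phasing). Genomic coordinates are
1-based hg19 positions carried through from the marker names, never
recomputed.

Markers are filtered on imputation quality with a *strict* threshold
(r² > 0.7; r² > 0.8 for quantitative-outcome analyses) and on carrier
frequency (default 0.005). The frequency floor is this package's guard —
residues rarer than that produce quasi-separated logistic fits and
uninterpretable omnibus degrees of freedom.

## The omnibus test and the conditional scan

At an amino-acid position with $n$ observed residues, association is a
likelihood-ratio test between

$$A_0: \operatorname{logit} P(y_i = 1) = \theta + \beta_0 S_i +
\textstyle\sum_{j=1}^{3}\beta_j P_{ij}$$

and $A_1$, which adds the dosages $V_{ik}$ of every residue at the
position except the most frequent one (the reference, recomputed in the
analyzed sample). The statistic $D = -2\ln(L_{A_0}/L_{A_1})$ is referred
to $\chi^2$ with degrees of freedom equal to the number of linearly
independent residue columns actually added. Residues within a position
are near-collinear with each other and with allele blocks, so the package
rank-reduces by pivoted QR on the residualized columns and lowers the
degrees of freedom accordingly; a position fully explained by the
conditioning set yields $D = 0$, zero degrees of freedom, and $p = 1$.
Fits use iteratively reweighted least squares (at most 100 iterations,
relative log-likelihood tolerance $10^{-9}$); markers with fewer than ten
carriers in either outcome group are dropped from that model with a
machine-readable reason.

The conditional scan iterates: omnibus-test every candidate position
given the current conditioning set; if the best position clears the
omnibus threshold ($5\times10^{-5}$; marker-level reporting uses
$5\times10^{-8}$), record it and add its residues as covariates
(stage A); re-scan within the same gene, so a second independent position
of that gene can enter before the gene's full 4-digit allele block is
added (stage B); then continue at the gene level. This reproduces the
published sequencing in which a second DRB1 position enters after the
primary one and before allele conditioning. Ties at a step are broken by
smaller p, then gene name, then position — the ordering when two genes
tie is not specified by the source analysis, so the package fixes a
deterministic rule. Individuals with missing covariates are dropped
listwise per model.

Sub-phenotype (autoantibody) analysis runs the same machinery on three
contrasts — antibody-positive versus antibody-negative cases,
positive cases versus controls, negative cases versus controls — and
refuses strata under 50 individuals (a guard; the source analysis is
silent on small strata). A linear-model variant with identical
conditioning semantics serves continuous outcomes such as expression.

## Cross-cohort combination

Directional marker results combine by sample-size weighted z-scores
($z_i$ the signed probit of $p_i/2$, weights $\sqrt{n_{\mathrm{eff},i}}$
with $n_\mathrm{eff} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$);
combined odds ratios use inverse-variance weighting of log odds ratios
(the standard-error approach). Omnibus p-values, having no direction,
combine by textbook Fisher's method ($-2\sum\ln p_i \sim \chi^2_{2k}$).
Cohorts are disjoint samples, which is the independence assumption
Fisher's method needs. All three combiners are the identity for a single
cohort.

## Liability-scale heritability

For a risk residue with risk-allele frequency $p$, odds ratio
$\mathrm{OR}$ and disease prevalence $K$: genotype frequencies are
Hardy–Weinberg; genotype penetrances follow multiplicative odds anchored
so the population risk equals $K$; each genotype's mean liability shift
is recovered by inverting the normal threshold model; and $V_g$ is the
variance of the genotype liability means on the unit-variance liability
scale. The implementation is verified against an independent oracle that
re-derives the threshold and the shifts by numerical integration of the
normal density. The total over independent residues drops any residue
flagged as a proxy of another included one — two tightly linked
positions tag one signal and must not be counted twice. $K$ is a
required parameter (default 0.001): the published total depends on a
prevalence that is not stated alongside it, so exact reproduction of
that percentage is out of scope by design.

## Burden and genetic risk scores

Best-guess genotypes are rounded dosages, masked when the implied
genotype certainty ($1 - $ distance to the nearest integer) falls below
0.8; "uncertain" is undefined in the source description, so the cutoff is
explicit and tunable. Individuals missing any call are excluded. The
package reports per-count-bin odds ratios against the zero-count
reference (top bin pooled as printed), a least-squares line of OR on
count, additive versus all-pairwise-interaction logistic models compared
by AIC, and weighted (count × log OR) versus unweighted genetic risk
scores compared by ROC AUC with a paired bootstrap (2,000 resamples,
via pROC). The GRS is computed per individual (a per-haplotype variant
of the published description is ambiguous; per-individual is the
implemented default).

## Haplotypes and linkage disequilibrium

Haplotype frequencies come from a hand-written EM over phase ambiguity:
individuals sharing a multi-locus genotype pattern share their
configuration set, the log-likelihood is checked to be non-decreasing at
every iteration, convergence is a relative change under $10^{-8}$ (cap
1,000 iterations), and five seeded restarts keep the best likelihood.
The state space is capped at $10^6$ phase configurations with an
explicit error. Haplotype association regresses case/control status on
EM posterior expected haplotype dosages (with a best-guess option;
posterior dosages are the stabler default), with the usual covariates,
skipping haplotypes under 0.5% frequency. Pairwise LD uses Lewontin's
normalization: $D' = D / D_\mathrm{max}$ with the bound depending on the
sign of $D$, and $r^2 = D^2 / (f_A(1-f_A)f_B(1-f_B))$.

## The immunogenic-peptide preference model

The epitope model asks: which amino acids, placed in an MHC
binding-groove position, favor presentation of immunogenic peptides? For
groove residue $g$,

$$\mathrm{score}(g) = \sum_{a \in \mathrm{non\text{-}imm}} V(g,a) -
\sum_{a \in \mathrm{imm}} V(g,a),$$

where $V$ is a symmetric 20×20 pairwise contact potential (lower = more
favorable) and the immunogenic / non-immunogenic peptide residue lists
are disease-specific: RA uses the experimentally derived lists
(Trp/Phe/Ile/Glu vs Ser/Met/Gln/Lys); for SLE, whose autoantigens are
predominantly positively charged, Glu is replaced by Arg and Lys is
dropped (Trp/Phe/Ile/Arg vs Ser/Met/Gln). The sign convention is chosen
so that *higher scores mean stronger preference for immunogenic
peptides, i.e. predicted risk*. A `score_min` variant contrasts minima
instead of sums and is the documented tie-break; residual ties break
alphabetically. Classification takes the top `n_risk` and bottom
`n_protective` of the ranking; the published "broad" profile is 9/2/9,
and the stricter groupings used for observed-residue tallies are carried
as explicit residue sets because they are not derivable from rank
cutoffs alone.

The packaged potential is a **synthetic stand-in**, not the published
supplementary matrix (which is unavailable as machine-readable text). It
was constructed once, from a physically motivated base (hydrophobic
attraction plus electrostatics) refined by penalized least squares, so
that its preference rankings reproduce the published SLE and RA group
orderings exactly; the construction script ships with the repository and
the CSV header records the provenance. Conclusions that depend on
individual potential cells, rather than on the published orderings,
should not be drawn from it.

Autoantigen profiling computes net charge by Henderson–Hasselbalch over
the ionizable groups (D, E, C, Y, H, K, R and termini) with the EMBOSS
pKa set, the isoelectric point by root-finding on the monotone charge–pH
curve (tolerance $10^{-3}$ pH units), and per-residue charge. The
original calculations used a commercial tool with an unpublished pKa
set, so exact pI agreement is not claimed. Poly-citrullination is
modeled as R→Q substitution (citrulline's closest natural analogue);
the operation is idempotent by construction.

## The synthetic-cohort generator

The generator inverts the analysis model. Chromosomes carry one 4-digit
allele per gene, drawn from marginal frequency tables or from explicit
multi-gene joint haplotype tables (inter-gene LD is specified by joint
frequencies, not a recombination model — adequate for a fixed 4-Mb
region). Residues follow deterministically from an allele→protein map,
so residue dosage equals the sum of its carrying alleles' dosages
exactly, and each chromosome carries exactly one residue per position.
Case status is Bernoulli under the logistic model above, with the
intercept solved numerically to hit the requested case fraction. Sex is
population-balanced with a strong sex effect on the log-odds
(default $\log 9$), which makes cases roughly 90% female — the SLE
demography — and exercises the sex covariate. PCs are standard normal
with per-cohort offsets, exercising the PC covariates. Antibody
sub-phenotypes are drawn among cases only from logistic models on
configured markers.

Imputation noise acts on the dosage scale: shrinkage toward the mean
plus Gaussian noise, clipped to $[0,2]$. Clipping alone would push the
realized accuracy above the nominal value, so the noise scale is
calibrated per marker by bisection until the realized squared
correlation with the truth matches the target; the *realized* value is
what gets recorded as the marker's imputation r². A single RNG stream
keyed by the seed drives every draw in a documented order, so identical
seeds give bit-identical cohorts.

The bundled "toy-asia" conditions ship six cohorts (KR, HC1, MC
discovery; HC2, JP1, JP2 replication) at one tenth of the published
sample sizes, a DRB1 allele→residue map whose 14 binding-groove
positions are transcribed from published allele tables (the Class I /
DP / DQ maps are invented toy maps carrying the independently associated
positions), a DRB1\*15:01–DQB1\*06:02 joint haplotype block at
r² = 0.92, planted effects at the six independent positions with the
published most-risk odds ratios (DRB1-13 1.43, DRB1-37 1.20, A-70 1.16,
DPB1-35 1.29, DQB1-37 1.25, B-9 2.43), and nRNP/Ro sub-phenotype
effects (DRB1-11 Asp 1.82 / Ser 0.62; DPB1-35 Leu 1.3). Real
inter-cohort frequency differences are not published, so the bundled
frequency tables are illustrative.

What the generator does *not* emulate: genuine imputation-posterior
dosage distributions (noise is Gaussian-on-dosage, not genotype-posterior
shaped), reference-panel mismatch between cohorts, fine-scale
recombination within genes, population stratification beyond PC offsets,
and allele-frequency estimation error. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the stated generative model, not that any particular biological
conclusion transfers to restricted real cohorts.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent route:
the omnibus LRT against `stats::glm` two-model refits; type-I error and
p-value uniformity on 500 null replicates of a five-residue position
(n = 400); planted-signal recovery of DRB1-13 (OR 1.4) plus B-9 (OR 1.3)
at 5,000/5,000 over 100 simulated cohorts (joint recovery and
no-false-position rates); So–Sham $V_g$ against numerical integration to
three significant figures; EM haplotype frequencies against a
coarse-to-fine brute-force likelihood grid (final step $10^{-5}$) on
two-locus fixtures; Lewontin statistics against closed forms; burden
linearity (R² ≥ 0.85) and additive-AIC preference on 50 additive
simulations at n = 10,000; and the preference-score orderings against
the published groupings. Estimator-recovery checks at fixed tolerances
average over a few replicates so the tolerance sits at two to three
standard errors of the estimate — a single draw at these sample sizes
would make the stated bands coin-flips. These problem sizes were chosen
to make the full verification suite run in minutes on one core while
keeping every bound statistically meaningful.

## Known limitations

* Fisher-combined values printed in the source's headline table do not
  reproduce under textbook Fisher's method under any degrees-of-freedom
  convention we tried; the package implements the textbook method and
  does not chase those cells.
* The contact potential is synthetic (see above); analyses that need the
  true published matrix should load their own CSV via
  `load_contact_potential(path)`.
* No mixed models or kinship correction; no genome-wide scan outside the
  HLA region; no recombination-aware phasing; no peptide–MHC binding
  prediction — the epitope model is deliberately position-agnostic and
  additive.
* Heritability totals depend on the assumed prevalence; report $K$
  alongside any percentage.
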