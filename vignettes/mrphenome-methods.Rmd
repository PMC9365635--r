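---
title: "Methods: phenome-wide Mendelian randomization screening with mrphenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide Mendelian randomization screening with mrphenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrphenome)
```

## The problem

Observational associations between a risk factor and a disease such as
atrial fibrillation are confounded and can run in either direction.
Mendelian randomization (MR) uses genetic variants as instrumental
variables: because alleles are assigned at conception, a variant that
raises an exposure can probe the exposure's causal effect on an outcome,
provided the variant affects the outcome only through that exposure. In
the two-sample setting, only GWAS summary statistics are needed — per-SNP
effect estimates $\hat\beta_{Xj}, \hat\beta_{Yj}$ with standard errors
from separate exposure and outcome samples.

`mrphenome` implements the full machinery for running such analyses at
phenome scale and in both directions: thousands of candidate exposures
against one outcome, and one disease-liability instrument against
thousands of candidate consequences, with a dedicated cis-pQTL +
colocalization arm for circulating proteins and a multivariable follow-up
for correlated risk factors. Because real phenome-wide inputs are
consortium GWAS downloads, the package also ships a synthetic
summary-statistics generator with known ground truth, so that every stage
— harmonization, clumping, estimation, verdicts, colocalization — is
testable at desk scale.

## Data model and harmonization

Summary statistics are plain data frames (variant id, chromosome, 1-based
position, effect/other allele, effect-allele frequency, beta, SE, p, and
sample sizes), read from tab-delimited files with a configurable column
map. Row-level invariants (positive SE, p in (0,1], frequency in (0,1),
distinct alleles, consistent case/control counts) are enforced at read
time; invalid rows are dropped and counted, and duplicated variant ids
resolve to the smallest p.

Harmonization aligns each shared SNP's outcome association to the
exposure's effect allele: swapped labels flip the outcome beta and
complement its frequency. Palindromic SNPs (A/T, C/G) cannot be resolved
by allele labels; following ecosystem practice we drop those with
minor-allele frequency above 0.42 and align the rest by frequency. SNPs
with missing frequency are kept for estimation but excluded from
palindrome resolution. Harmonization is idempotent, and every downstream
estimator is invariant to relabeling effect/other alleles — both
properties are enforced by tests.

Binary traits analysed by linear regression on a 0/1 phenotype (the UK
Biobank rapid-GWAS convention) are rescaled to approximate log odds by
multiplying beta and SE by $1/(\mu(1-\mu))$, $\mu$ the case fraction. The
factor is symmetric in $\mu \leftrightarrow 1-\mu$, and a table-level
guard makes the scaling idempotent.

## Instruments

Clumping is greedy: among SNPs with $p \le 5\times10^{-8}$, repeatedly
take the smallest-p unassigned SNP as an index and absorb all SNPs within
10 Mb on the same chromosome with LD $r^2 \ge 0.001$ to it. Ties at equal
p break by chromosome, position, then id, so output is independent of row
order. A SNP pair absent from the LD reference is treated conservatively
as $r^2 = 1$ within 1 Mb and unlinked beyond — missing LD information
should not admit unverifiable near-duplicates. The implementation is
checked against an independent brute-force oracle on random AR(1)
chromosomes.

Instruments absent from the outcome GWAS may be rescued by the
highest-$r^2$ proxy above $r^2 > 0.8$ (ties: smaller p); the sign of r
orients the proxy's alleles. If no proxy exists the SNP is dropped and
counted. Proxy search is used by the forward/reverse screens, not the cis
protein arm.

Per-SNP variance explained uses $r^2 = t^2/(t^2 + n - 2)$, $t =
\beta/\mathrm{se}$. Steiger filtering keeps SNPs with $r^2_X > r^2_Y$
(strict), with a two-sample z-test on Fisher-transformed correlations for
a per-SNP p-value. For binary traits the $r^2$ is computed on the
observed analysis scale; no liability-scale correction is applied.
Instrument strength is summarised by $F_j = (\beta_j/\mathrm{se}_j)^2$
and its mean; genome-wide-significant SNPs have $F \ge 29.7$ by
construction.

Protein exposures are instrumented in cis only: SNPs within 100 kb of the
coding gene, $p \le 5\times10^{-8}$, explaining more variance in the
protein than in the outcome, then clumped within the window. Selection is
anchored on the gene body; colocalization (below) is anchored on the
leading cis-pQTL — the two anchors reflect how the two analyses are
defined.

## The estimator suite

Five univariable methods plus a Steiger-filtered IVW:

- **Wald ratio** (single SNP): $\hat\theta = \beta_Y/\beta_X$, first-order
  SE $|\mathrm{se}_Y/\beta_X|$.
- **IVW**: WLS of $\beta_Y$ on $\beta_X$ through the origin, weights
  $1/\mathrm{se}_Y^2$; the primary estimator.
- **MR-Egger**: the same regression with an intercept after orienting all
  $\beta_X \ge 0$; the intercept estimates average directional
  pleiotropy.
- **Weighted median**: interpolated median of ratio estimates under
  inverse-variance weights; consistent when valid instruments carry
  $\ge 50\%$ of the weight.
- **Simple / weighted mode**: argmax of a normal-kernel density of the
  ratio estimates, bandwidth $0.9\,\min(\mathrm{sd},
  \mathrm{mad})\,J^{-1/5}$ on a 512-point grid; argmax ties resolve to
  the smallest grid value.

Numerical conventions, chosen once and documented because the method
names alone do not pin them down: heterogeneity is handled by
multiplicative random-effects inflation floored at 1 (variance scaled by
$\max(1, Q/\mathrm{df})$ — no under-dispersion), p-values are two-sided
normal throughout (not t), and median/mode SEs come from a parametric
bootstrap (default 1000 draws) under a mandatory explicit seed. Results
from t-based or additive-random-effects dialects will differ slightly;
that is expected and explainable.

## The three-stage verdict and Bonferroni control

A screened pair is called robust only if it clears all of:

1. at least 4 instrument SNPs (the minimum to run all five methods) and
   primary IVW $p <$ the Bonferroni threshold $0.05/n_\text{tests}$
   rounded to one significant figure (5048 exposures $\to 10^{-5}$;
   10 308 outcomes $\to 5\times10^{-6}$);
2. weighted-median estimate directionally concordant with IVW and median
   $p < 0.05$;
3. Steiger-filtered IVW directionally concordant and its
   $p < 0.05/n_{12}$, where $n_{12}$ counts pairs passing stages 1–2.

Stage 3's divisor is data-dependent, so the screens evaluate stages 1–2
for every pair first and stage 3 in a second pass. All thresholds are
strict inequalities. For display only, pairs failing the verdict are
plotted at $p = 1$; stored results are never altered. The screens only
run the bootstrap-heavy median/mode estimators for pairs that clear the
stage-1 IVW test — verdicts are identical, since stages 2–3 are only
defined for stage-1 passers, and the saving makes null-calibration
studies tractable.

Proteins pass through a simpler gate: cis Wald/IVW $p$ below the same
exposure-screen threshold, followed by colocalization at the leading
cis-pQTL $\pm 100$ kb. A protein can pass MR through LD confounding
alone, which is exactly what the colocalization posterior is there to
catch.

## Colocalization

Per-SNP approximate Bayes factors use Wakefield's form: with $V =
\mathrm{se}^2$, $W$ the prior effect variance, $z = \beta/\mathrm{se}$,
$\log\mathrm{ABF} = \tfrac12[\log(V/(V+W)) + z^2 W/(V+W)]$. Hypothesis
sums (H0: no association; H1/H2: one trait only; H3: distinct causal
variants; H4: shared variant) are accumulated in log space with
log-sum-exp, so $|z|$ up to 50 is safe. Priors default to $p_1 = p_2 =
10^{-4}$, $p_{12} = 10^{-5}$; prior effect SD 0.15 for quantitative
traits and 0.2 for case-control traits on the log-odds scale. The module
reports raw posteriors; evidence labels (e.g. "strong" at PP4 $\ge$ 0.8)
belong to the report layer and are configurable. The single-causal-variant
assumption is inherited from the method; multi-signal loci are out of
scope.

## Multivariable MR

Direct effects come from no-intercept WLS of $\beta_Y$ on the $J \times
K$ matrix of exposure betas, weights $1/\mathrm{se}_Y^2$, with the same
multiplicative inflation (df $J - K$); $K = 1$ reduces exactly to IVW.
Cross-exposure sampling covariance is set to zero — summary data carry no
overlap information — and this is noted in outputs. Conditional
instrument strength for exposure $k$ regresses its betas on the other
exposures' betas (weights $1/\mathrm{se}_{Xk}^2$) and forms $F_k =
Q_k/(J - K + 1)$ from the weighted residual sum of squares; the cited
method's df convention has dialects, so ours is documented and tested for
its structural properties (equality to the mean univariable F at
$K = 1$; strict depression under shared instruments; approximate equality
under orthogonal instruments), not against external supplementary values.
The staged builder fits within-category models, pools survivors
($p < 0.05$, strict) with listed singleton factors, and refits, emitting
the full audit trail.

## The synthetic world

The generator encodes the structural assumptions the estimators rely on,
with defaults fixed once:

- per-SNP SEs $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, MAF
  $\sim U(0.05, 0.5)$;
- instrument effects $\gamma \sim N(0, 0.03^2)$, resampled to pass
  $p < 5\times10^{-8}$ at the exposure sample size when strong
  instruments are requested (keeping per-SNP F near realistic
  GWAS-significant values);
- $\hat\beta_X \sim N(\gamma, \mathrm{se}_X^2)$, $\hat\beta_Y \sim
  N(\theta\gamma + \alpha, \mathrm{se}_Y^2)$; default design 50 SNPs,
  $\theta = 0.3$, $n_X = 50\,000$, $n_Y = 100\,000$;
- pleiotropy modes: none; balanced ($\alpha \sim N(0, 0.01^2)$);
  directional ($\alpha = 0.05$ on a chosen fraction of SNPs, signed to
  the exposure-raising allele — under Egger's orientation an unsigned
  constant would average to zero, which is a property of the orientation
  step, not of pleiotropy); reverse (the variant acts on the outcome
  first);
- colocalization regions: AR(1) LD $r_{ij} = \rho^{|i-j|}$, z-vectors
  $\sim N(R\lambda, R)$ with the non-centrality at the causal index;
- the phenome: a mixture of quantitative, binary (linear-scale, case
  fraction 0.1) and protein traits against one case-control outcome
  sized like a large AF GWAS (60 620 cases, 970 216 controls); causal
  traits draw $|\theta| \sim N(0.3, 0.05^2)$ with random sign; proteins
  use a proteomics-scale $n = 3301$ with a strong cis-pQTL
  ($\beta = 0.8$ SD), sharing its causal variant with the outcome when
  truly causal. One global seed fans out to per-trait streams, so adding
  a trait does not perturb the others.

What the generator does **not** emulate: realistic minor-allele-frequency
spectra and LD beyond AR(1), sample overlap between the two GWAS,
population stratification, winner's curse in instrument selection, and
liability-scale subtleties of binary traits. A green test therefore
establishes that the algorithms are implemented correctly and calibrated
under their own assumptions — not that those assumptions hold in any
particular real dataset.

## Degenerate inputs and tie-breaks

Single-SNP instruments fall back to the Wald ratio (flagged); Egger
refuses collinear designs; all-equal ratio estimates give a zero
bandwidth and return the common value; argmax ties take the smallest grid
value; clumping ties take chromosome/position/id order; proxy ties take
the smaller p. Screens record machine-readable reasons for every
non-estimable or failed entry rather than omitting rows.

## Known limitations

No MR-PRESSO/contamination-mixture/CAUSE estimators; no liability-scale
(coarsening-adjusted) re-interpretation of binary-outcome estimates; no
SuSiE-style multi-signal colocalization; no remote GWAS retrieval, VCF
parsing or genome-build liftover; LD enters only through the matrix
interface. These reflect deliberate scope, not oversights.
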