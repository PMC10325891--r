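---
title: "ratioscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ratioscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioscreen)
```

`ratioscreen` implements the computational stages of a FACS-based CRISPRi
screen for near-cognate start-codon usage: a generative simulator of the
dual-fluorescence reporter population and the tail-sort-and-sequence screen,
the sgRNA/gene enrichment statistics with an empirical hit threshold,
internally controlled flow-cytometry quantification, dual-sgRNA interaction
analysis, and perturbation-profile clustering with gene-set summaries. This
vignette records the models, the tunable parameters, and the design choices
made where the underlying experimental analysis left the method open.

## The reporter noise model

The reporter is bicistronic: GFP initiated at a near-cognate start codon
(CUG by default) and mCherry driven by an IRES as an internal expression
control. Per cell, fluorescence is modelled as

$$
\mathrm{GFP} = A + \mu_G\, E\, I_G, \qquad
\mathrm{mCherry} = \mu_M\, E\, I_M,
$$

where $A$ is a constant GFP autofluorescence background, $\mu_G$ is the
mean reporter signal ($\mu_G = \mu_{AUG} \cdot \varepsilon_{codon}$, with
$\varepsilon$ the relative initiation efficiency of the start codon), and
$E$, $I_G$, $I_M$ are mean-one lognormal factors: one *extrinsic* factor
shared by both channels (cell state, size, integration site, transcript
abundance) and one *intrinsic* factor per channel. The shared factor cancels
in the GFP/mCherry ratio, which is what makes the ratiometric readout much
tighter than either channel alone.

With log-scale variances $s^2$ (extrinsic) and $\sigma_G^2, \sigma_M^2$
(intrinsic), the model gives closed-form population statistics:

* per-channel CV: $\mathrm{CV} = \sqrt{e^{v}-1}$ with
  $v_G = s^2 + \sigma_G^2$, $v_M = s^2 + \sigma_M^2$;
* ratio log-variance: $\sigma_G^2 + \sigma_M^2$ (the extrinsic term cancels);
* linear-scale Pearson correlation:
  $\rho = (e^{s^2}-1)/\sqrt{(e^{v_G}-1)(e^{v_M}-1)}$.

`calibrate_noise()` inverts these three equations for the three noise SDs
given a target GFP CV, ratio CV and correlation, solving the correlation
equation by root finding on the feasible interval of $s^2$.

### Feasibility and the default calibration

The three targets are not independent. With both CVs fixed, the attainable
correlation is bounded: it is maximal when all GFP noise is extrinsic
($\sigma_G = 0$) and minimal when the entire ratio variance sits in the GFP
channel ($\sigma_M = 0$). For a GFP CV of 76% and a ratio CV of 22% the
attainable band is approximately $[0.935, 0.940]$ for a pure signal, rising
to about $[0.953, 0.956]$ once the constant autofluorescence background is
accounted for (the background dilutes the *measured* GFP CV by
$\mu_G/(A+\mu_G)$, so the underlying signal must be noisier than the
measured 76%). A correlation of 0.96 at these CVs is therefore outside the
model family; no choice of the three SDs reaches it. `calibrate_noise()`
reports such targets as infeasible, naming the constraint that would be
violated, which is the honest behaviour for a three-parameter model asked
for a fourth independent property.

`default_calibration()` targets the measured statistics GFP CV 76%, ratio CV
22% and correlation 0.96. It matches both CVs exactly (using closed-form
lognormal moments that include the background term) and, because 0.96 is
infeasible, returns the maximum-correlation boundary solution
($\sigma_G = 0$, achieved $r \approx 0.956$), recording both targets and
achieved values as attributes. A correlation model that loaded the shared
factor asymmetrically onto the two channels could reconcile all three
targets, but would require mCherry to be noisier than GFP, for which there
is no support in the measured statistics; the symmetric model is retained.

Other default constants: CUG and GUG initiate at $1/920$ of AUG efficiency;
total mean CUG GFP is $13\times$ the autofluorescence background (so
$A = \mu_G/12$); mean mCherry is arbitrary at 5000 units since every
downstream statistic is either ratiometric or internally controlled.

## The screen simulator

`simulate_screen()` produces read-count tables with the structure the
scoring stage assumes:

1. each replicate is an independent cohort of cells (the conservative
   approximation to splitting one infected pool); an `infected_fraction`
   (default 0.9, the post-selection BFP+ fraction) of cells receives an
   sgRNA, uniformly across the library by default with an optional
   lognormal abundance skew;
2. sgRNA effects act multiplicatively on the near-cognate GFP initiation
   term and/or on mCherry, in a `penetrance` fraction of assigned cells;
   growth/dropout effects are deliberately excluded (a single-timepoint
   sort does not observe them);
3. events pass a viability gate, a singlet gate, and a BFP gate; BFP+
   events are ranked by GFP/mCherry and the top and bottom `tail_fraction`
   (default 15%, giving exactly `floor(N * 0.15)` events per tail) are
   sorted, with an optional uniform retention factor modelling finite sort
   efficiency (default off);
4. each tail sample is sequenced by drawing `reads_per_sample` reads
   multinomially from the tail's sgRNA composition.

Cell numbers and read depth default to a coverage multiple (cells and reads
per library sgRNA, default 100), which keeps the simulator honest about the
two sampling layers a real screen has: cells into tails, then reads onto
sgRNAs.

Randomness discipline: a single top-level seed; every stage and replicate
derives a child stream via a stable string hash (`derive_seed()`), so runs
are bit-reproducible end to end and replicates are independent.

The simulated event mixture can include debris (low, diffuse scatter) and
doublets (summed fluorescence, depressed FSC-H/FSC-A ratio). The defaults
are a clean population; contaminant fractions are switched on explicitly
where gating behaviour is under study. The tail-gate boundary separation
(the percent difference between the upper and lower ratio boundaries) is
reported as a population diagnostic but not enforced, since it is an
emergent property of the noise model rather than a design parameter.

## Screen scoring

`score_screen()` follows the sorted-screen convention:

* **sgRNA enrichment** — per replicate,
  $\log_2$ of the pseudocounted high-tail frequency over the low-tail
  frequency. Counts are normalised to sample frequencies before the ratio
  because sequencing depth differs between samples; at equal depth this
  reduces to the plain count ratio. The default pseudocount of 1 read
  protects zero counts and is configurable.
* **gene score** — the signed mean of the gene's top three sgRNAs ranked by
  `|enrichment|` (ranking by magnitude keeps bidirectional phenotypes
  honest; a `rank_by = "signed"` switch is provided since the original
  convention is not documented). Genes with fewer than three scored sgRNAs
  are unscorable and excluded from hit calling.
* **gene p-value** — a two-sided Mann–Whitney test of the gene's
  per-replicate sgRNA enrichments against the non-targeting sgRNA
  enrichments of the same replicate. The tie-corrected normal approximation
  (no continuity correction) is used for large null sets; exact enumeration
  is used below a configurable size threshold. Per-replicate p-values are
  combined with Fisher's method ($-2\sum\ln p$ on $\chi^2_{2k}$), and
  replicate enrichments are averaged.
* **hit threshold** — non-targeting sgRNAs are shuffled into disjoint
  *quasi-genes* of five and scored exactly like real genes; a group's own
  sgRNAs are excluded from its Mann–Whitney null so quasi-genes and real
  genes are scored identically. The threshold is the maximum
  `|score * -log10(p)|` over quasi-genes, and a gene is a hit only if it
  strictly exceeds it, so no quasi-gene is ever called.

### What the empirical threshold does and does not control

The quasi-gene threshold is an empirical max-null rule. Under a fully null
screen its false-positive behaviour is set by exchangeability: with $G$
null genes and $Q$ quasi-genes the probability that no gene exceeds the
quasi maximum is $Q/(G+Q)$, and the expected number of false calls is
roughly $G/(Q+1)$. At 500 genes and 379 quasi-genes (the library geometry
with 1895 non-targeting controls) about half of null screens therefore
contain at least one false hit — roughly one expected false call per
screen, which is negligible against hundreds of true hits in a
genome-scale screen but means the rule is *not* a zero-false-positive
guarantee, and the test suite documents this property rather than
asserting it away.

## Flow-cytometry quantification

Gating is viability → singlet → BFP, in that fixed order. The interactive
gates of a bench analysis are replaced by reproducible automatic rules, all
overridable by explicit values: a density-quantile viability gate (kernel
density of log-scatter, retaining the densest fraction; an explicit FSC/SSC
polygon is also supported), a central-band or explicit-interval singlet
gate on FSC-H/FSC-A, and a BFP threshold placed at the density valley
between the two largest modes of log-BFP (with an error, rather than a
guess, on unimodal input).

The reporter phenotype is internally controlled within a well:
$\Delta GFP$ and $\Delta mCherry$ are the differences in channel means
between infected (BFP+) and uninfected cells, and the primary score
transforms $d = \Delta GFP - \Delta mCherry$. A raw $\log_2 d$ is undefined
for the depleting phenotypes the assay must report, so the score is the
signed pseudo-log $\mathrm{sign}(d)\log_2(1+|d|/u)$ with a configurable
unit $u$: odd, strictly monotone, exactly invertible, equal to
$\log_2(d/u)$ for $d \gg u$, and zero iff $d = 0$. The raw difference is
always reported alongside. With $u$ anchored at the mean reporter signal,
a pure GFP fold-change $f$ scores $\log_2 f$, which is what makes
independent effects additive on the score scale. Means, not medians, are
used for the channel summaries, matching the upstream convention.

## Dual-sgRNA interactions

The no-interaction expectation for a double knockdown is the sum of the two
single-knockdown scores. "Conforms to additivity" is operationalised as a
z-test: the deviation $d = \bar e_{AB} - \bar e_A - \bar e_B$ against the
pooled standard error of the three independent well means, additive when
$|z| \le 2$ by default. Non-additive pairs are labelled *buffering* when
the observed double effect is weaker in magnitude than expected
($|e_{AB}| < |e_A + e_B|$, the epistatic-max pattern) and *synergistic*
otherwise; the split is a reporting convention, not a mechanistic claim.
Pairs without well replication are reported `untested` rather than guessed.

## Profile clustering

The perturbation-response matrix (perturbations × genes, normalised
z-scores) is embedded by rank-20 truncated SVD; the reconstruction serves
as light imputation and the scaled left singular vectors as row
coordinates. Response genes are filtered by two strict rules over the
comparison set: maximum $|z| > 1$ and median $|z| > 0.1$ (read per response
gene, across the perturbations in the comparison). Perturbations and
response genes are then k-means clustered independently (defaults 5 and 3
clusters, 25 seeded restarts keeping the best inertia, inputs canonically
sorted by identifier so results are order-invariant). The "permissive"
clustering — whose original algorithm is unnamed — is concretised as
average-linkage agglomerative clustering on correlation distance over the
embedded rows, cut at a configurable threshold, allowing singletons. The
choice of truncated SVD for the embedding is likewise this package's
concretisation, recorded rather than asserted as the original method.

## Gene-set summaries

Per-gene log2 fold-changes are pseudocounted ratios of normalised
abundances. A set response is summarised as $k/n$: evaluable members (in
the table and above an expression floor in at least one condition, default
1 on the counts-per-million scale since gene lengths, and hence TPM, are
not available) with fold-change strictly above the threshold (default
2-fold). Over-representation uses the one-sided hypergeometric upper tail —
the test family is a package decision, as the upstream analysis does not
name one. Gene-set membership is always an input (GMT), never bundled,
since annotation versions shift denominators.

## Problem sizes and what the tests show

The test suite exercises the full study geometry where it matters: null
calibration and recovery use 500 genes × 5 sgRNAs plus 1895 non-targeting
controls at 100× coverage in 2 replicates; population statistics use 1e5
cells; smaller fixtures (tens of genes, thousands of cells) cover the
remaining contracts. Planted 4-fold-effect genes (25/500) are recovered
with sensitivity ≥ 0.8 at zero quasi-gene calls.

The simulator reproduces the population statistics the analysis assumes —
lognormal channels, a shared extrinsic factor, constant background — but
not features of real cytometry it deliberately omits: spectral spillover,
instrument transforms (arcsinh/logicle), autofluorescence variability,
growth-based sgRNA depletion during outgrowth, sort-purity structure beyond
uniform retention, and clustered lentiviral integration effects. Passing
tests therefore validate the statistical machinery under the stated
generative model, not the biology of any particular screen.

## Known limitations

* The three printed population targets (GFP CV 76%, ratio CV 22%,
  r = 0.96) are jointly outside the symmetric shared-factor lognormal
  family; the default calibration reaches r ≈ 0.956 at exact CVs. This is
  a property of the model class, documented above, not a numerical issue.
* The empirical max-quasi-gene threshold admits on the order of
  $G/(Q+1)$ false calls per screen, as derived above.
* Exact Mann–Whitney enumeration is only used for small problems; at
  $n_1 = 5$ the normal approximation has a median relative error of a few
  percent against exact enumeration, with occasional lattice-driven
  excursions above 10% in the tails.
* FCS binary parsing is out of scope; events enter as CSV exports.
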