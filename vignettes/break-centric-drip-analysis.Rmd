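---
title: "Break-centric DRIP-seq analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Break-centric DRIP-seq analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driploop)
library(dplyr)
```

## The scientific problem

DNA double-strand breaks (DSBs) rapidly accumulate DNA:RNA hybrids (R-loops)
around the cut, and these break-induced hybrids are required for an efficient
damage response. DRIP-seq (DNA:RNA-hybrid immunoprecipitation with the S9.6
antibody, followed by sequencing) measures hybrid levels genome-wide. In a
cell system where a restriction enzyme can be induced to cut at a known set
of loci, DRIP-seq before and after cut induction — with and without siRNA
knockdown of a candidate hybrid-forming factor — lets one ask, site by site,
whether break-induced hybrid formation depends on that factor.

`driploop` implements that analysis as a tested pipeline:

1. **Fragment coverage**: paired-end alignments collapsed to fragments
   (BEDPE → fragment spans), per-base depth by a sweep line, normalization to
   fragments-per-million.
2. **Break-centric quantification**: mean normalized signal in a window of
   half-width $W$ around each cut; per-arm damaged/undamaged log2 fold change
   $\mathrm{log_2FC} = \log_2\!\frac{m_{+} + \varepsilon}{m_{-} + \varepsilon}$;
   the deviation from the identity line
   $\Delta = \mathrm{log_2FC}_{kd} - \mathrm{log_2FC}_{ctrl}$; classification
   of each site as knockdown-**dependent** ($\Delta < -\tau$), **increased**
   ($\Delta > +\tau$) or **independent** (otherwise); DSB-centred metagenes;
   rank-sum group contrasts; and the Pearson correlation between a site's
   pre-existing hybrid level and its induced fold change, per siRNA arm.
3. **Statistics**: one-sided Mann–Whitney with exact small-sample enumeration,
   Pearson correlation test, paired t — all implemented in the package and
   cross-checked against independent oracles in the test suite.
4. **qPCR assays**: DRIP-qPCR percent input with damaged/undamaged fold
   change, and the restriction-protection ssDNA resection assay.
5. **Proteomic meta-analysis**: cross-study hit frequencies, thresholded
   candidate sets, 2–3 set Venn decompositions, annotation queries, and SQ/TQ
   motif scanning.
6. **Synthetic data**: a generator for every input, with planted ground truth,
   so each step can be validated end to end at desk scale.

## The synthetic experiment and what it emulates

The generator's defaults describe the study design the analysis targets:
99 frequently cut restriction loci, four sequencing conditions
(control/knockdown siRNA × ±4 h cut induction), two biological replicates,
RNase-H-pretreated controls, and a planted composition of 40
knockdown-dependent, 51 independent and 8 increased sites — with dependence
coupled to *low* pre-existing hybrid levels.

Per site $i$, the expected fragment count in the window is

$$\mu_i = b + p_i + [\text{+OHT}] \cdot I_i \cdot m(\text{siRNA}, c_i),$$

where $b$ is the background rate per window, $p_i$ the pre-existing hybrid
level (log-normal across sites), $I_i$ the break-induced magnitude, and the
knockdown multiplier $m$ is 1 on the control arm and, under knockdown, 0 for
dependent sites, 1 for independent sites and 2.5 for increased sites. Counts
are negative-binomial with $\mathrm{Var} = \mu + \phi\mu^2$ — replicate
overdispersion on top of counting noise; $\phi \to 0$ recovers Poisson.
Fragment midpoints are uniform in the window; lengths are truncated normal
(mean 300, sd 100, floor 50 bp), a generic model of a sonication smear.

Three generator choices deserve explanation:

* **Induction is proportional to the basal level.**
  $I_i = f \cdot (b + p_i) \cdot u_i$ with fold $f = 4$ and a log-normal
  per-site jitter $u_i$ (sdlog 0.3). The control-arm fold change is then
  (to first order) independent of the pre-existing level, which is exactly
  the observed biology this pipeline must reproduce: in the presence of the
  helicase, break-induced hybrid formation does *not* track a locus's innate
  hybrid propensity; the correlation only appears on the knockdown arm,
  where dependent (hybrid-poor) loci fail to induce. An additive,
  basal-independent increment would bake a spurious control-arm correlation
  into the simulation. The realized additive magnitude is stored per site in
  `induction_magnitude`.
* **Auto library sizing.** By default each library contains the realized site
  fragments plus background scattered at the same areal density
  ($b$ per $2W$ bp) over the window-free genome, so coverage density is
  uniform genome-wide and an RNase-H library with residual 0 is
  indistinguishable from background *by construction* — the property the
  nuclease-sensitivity control tests. Signal-rich (+OHT) libraries come out
  deeper, as a real immunoprecipitation would. A fixed `library_size` is
  also supported (background becomes the top-up and the total is exact).
* **Depth and noise scale.** Defaults ($b = 80$, median $p \approx 150$
  fragments per window, $\phi = 0.002$, two replicates) give a per-site
  $\Delta$ standard error well below the $\tau = 0.5$ classification
  threshold, so the planted classes are recoverable at the ≥95% level the
  package promises, while a full four-condition, two-replicate experiment
  simulates in a couple of seconds. Per-site induced folds vary ~2.5–6.5×,
  a plausible biological spread.

**What the generator does not emulate:** sequence-dependent hybrid formation
(sites are coordinates, not recognition motifs), GC/skew effects, chromatin
context, mappability, PCR duplicates, or replicate-level batch effects.
Passing tests therefore demonstrate that the *analysis* recovers planted
structure under a realistic count model — not that any particular biological
dataset has these properties.

## Analysis parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `window_bp` ($W$) | 2000 | bp | Half-width of the quantification window. Break-induced hybrids concentrate within a few kb of the cut; configurable. |
| `eps` ($\varepsilon$) | 0.1 | normalized signal | Pseudocount in both numerator and denominator. Typical window signals are in the hundreds, so classification is insensitive to $\varepsilon$ over a wide range; it exists to keep fold changes finite at empty windows. `eps = 0` raises an explicit error on zero denominators. |
| `tau` ($\tau$) | 0.5 | log2 units | Deviation-from-identity threshold. Ties at exactly $\pm\tau$ are classed independent (strict inequalities; conservative). |
| metagene `span`, `bin_width` | 5000, 100 | bp | Bins tile $[-\text{span}, +\text{span})$ exactly; off-contig bins are dropped per site and contributing counts recorded. |
| `dilution` (qPCR) | none | fraction | The input-dilution factor has no default: it must be known from the experiment. |

Replicates are combined as the **mean of per-replicate log2 fold changes**
(not the fold change of pooled counts): this matches how replicate metagenes
are averaged and is robust to depth imbalance between replicates.

The high/low transcription contrast splits sites at the **median**
transcription level. No multiple-testing correction is applied across group
contrasts — each is reported with its own per-test p-value, as is standard
for this kind of site-level analysis; callers comparing many contrasts
should adjust accordingly.

## Statistical engines

* **Rank-sum** (`wilcoxon_one_sided()`): Mann–Whitney $U$ with midranks for
  ties. For combined $n \le 12$ and tie-free data the p-value is computed by
  full enumeration of all $\binom{n}{n_x}$ assignments; otherwise a normal
  approximation with tie correction and continuity correction is used. The
  test suite verifies the two agree within 0.02 for group sizes ≥ 3 — at
  groups of 2 the normal tail is off by up to ~0.045, a known small-sample
  limitation, and the exact path is what the package actually uses there.
* **Pearson** (`pearson_test()`): $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df,
  two-sided. Degenerate (zero-variance) inputs raise an error rather than
  returning NaN.
* **Paired t** (`paired_t()`): two-sided by default (one-sided available).
  `a == b` exactly returns $t = 0, p = 1$; a constant non-zero difference has
  no within-pair variance and raises an error (reported as NA by
  `drip_fold_change()` on noise-free plates).

Both calibration properties (type-I error of the Pearson and paired-t tests
within [0.04, 0.06] at $\alpha = 0.05$ over 10,000 null simulations) are
asserted in the test suite.

One caveat surfaced during design: the pre-existing level is the *measured*
undamaged signal, which is also the denominator of the fold change, so shared
measurement noise induces a small spurious negative correlation (a classic
ratio-versus-denominator artifact). At the default sequencing depth this
artifact is negligible; at much shallower depth it would bias the control-arm
correlation downward. Users quantifying very shallow data should be aware of
it — it is a property of the estimator, not of the simulation.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout (BED convention); fragments,
  not read mates, are the unit of coverage.
* Coverage tracks are run-length encoded, canonical (sorted, merged equal
  adjacent runs, zero runs implicit), and written to bedGraph with
  full-precision decimals, so `read_bedgraph(write_bedgraph(x))` is an exact
  identity.
* Per-million scaling uses the constant $10^6/L$; any constant cancels in
  fold changes.
* Windows are clipped at contig edges and averaged over the width actually
  used; a window entirely out of bounds is an error.
* BEDPE rows with mates on different contigs cannot define a fragment: they
  are skipped with a warning and counted, not silently dropped.
* Resection dCt below −0.5 (digestion apparently increasing template) is
  flagged as assay-inconsistent but still reported.
* The ssDNA formula $100/(2^{\Delta Ct - 1} + 0.5)$ is the established
  quantification for restriction-protection resection assays in this cell
  system; amplification efficiency is fixed at 2 by default and configurable.

## Problem sizes used by the test suite

The suite validates the pipeline at the study's own scale: the default
99-site, two-replicate experiment (≈0.3–0.6 M fragments across the four
conditions) for single runs, 50-seed Monte-Carlo for the correlation-switch
and group-contrast properties, 10,000-replicate nulls for test calibration,
and 100–200 random instances for the exact coverage and set-algebra oracles.
Unit tests use a 6-site miniature of the same design.

## Known limitations

* Identifier harmonization across proteomic studies is the caller's
  responsibility; identifiers are opaque uppercased strings.
* The metagene averages per-site log2 fold changes; pooling coverage before
  forming the ratio is a different estimator and is not offered.
* The transcription-activity covariate is taken as supplied; the package does
  not derive it from expression data.
* No peak calling or hybrid-domain detection outside the declared windows.
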