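---
title: "Methods: metabolic-rate-aware NOGF scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic-rate-aware NOGF scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petoscan)
```

## The statistical problem

Across species, the number of genes a genome devotes to a functional
category (NOGF) can be correlated with body mass $M$ to test whether
large-bodied species are genomically better defended against cancer.
The confounder is Kleiber's law. With whole-organism metabolic rate
$B \propto M^{3/4}$, the mass-specific rate $B_c = B/M \propto M^{-1/4}$
is almost a deterministic decreasing function of $M$: on log scales the
two are correlated at $|r| \approx 0.95$ in mammalian data. Any category
whose gene count tracks cellular metabolism therefore inherits a negative
correlation with body mass that has nothing to do with body size per se.

petoscan treats each category $j$ with count vector $G_j$ and computes,
on $\log_{10} M$ and $\log_{10} B_c$ (counts untransformed):

* the simple Pearson correlation $r_M$ with its two-sided $t$ test on
  $n-2$ df;
* the first-order partial correlation
  $r_p = (r_{GM} - r_{GB_c} r_{B_cM}) / \sqrt{(1-r_{GB_c}^2)(1-r_{B_cM}^2)}$,
  tested on $n-3$ df (one conditioning variable — the standard first-order
  partial $t$ test; equivalently the Pearson correlation of the OLS
  residuals of $G$ on $\log B_c$ and of $\log M$ on $\log B_c$);
* the standardized partial regression coefficient of $\log M$ in
  $G \sim \log M + \log B_c$, i.e. the OLS coefficient rescaled by
  $\mathrm{sd}(\log M)/\mathrm{sd}(G)$, as a multivariate companion to
  $r_p$ (its sign always agrees with $r_p$);
* $R^2$ before and after correction as $r_M^2$ and $r_p^2$.

Dataset-level diagnostics aggregate the per-category results: the mean of
$r$ with a normal-approximation 95% CI
($\bar r \pm 1.96\,s/\sqrt{k}$; a bootstrap percentile CI is available
via `ci_method = "bootstrap"` since the sampling distribution of a mean
of dependent correlations has no clean closed form), the fraction of
categories with $p$ strictly below $\alpha$ (default 0.05), and the
correlation of correlations: the Pearson correlation across categories
between the $r_M$ and $r_{B_c}$ vectors. If NOGF–$M$ associations are
created by the $B_c$–$M$ coupling, each category satisfies
$r_M \approx r_{B_cM}\, r_{B_c}$ and the meta-correlation collapses
toward $-1$; genuinely mass-driven signal pulls it away from the line.

No multiple-testing correction is applied by default — the scan is
reported at raw $p < \alpha$, with Benjamini–Hochberg columns available
via `p_adjust = "BH"` — because the object of interest is the *shift* in
the significant fraction under correction, not any single category.

## Enrichment

Second-level (upper) functional categories are tested for
over-representation of significant third-level categories with Fisher's
exact test on the inside/outside × significant/non-significant table.
The default is the one-sided (greater) test, since enrichment asks only
about over-representation; the two-sided variant (the `fisher.test`
convention: summing all margin-fixed tables no more probable than the
observed one) is available. Categories with undefined $p$-values (zero
count variance) are treated as non-significant so the margins always sum
to the full category set. The odds ratio reported is the sample OR with a
Haldane 0.5 correction when a cell is empty; significance is summarized
as $-\log_{10} p$.

## Phylogenetically independent contrasts

Cross-species correlations over-count phylogenetically clustered trait
shifts. The contrast transform is implemented directly by Felsenstein's
pruning recursion: at an internal node with child values $x_1, x_2$ and
augmented branch lengths $v_1, v_2$, the standardized contrast is
$(x_1 - x_2)/\sqrt{v_1+v_2}$, the node value is the precision-weighted
mean, and the parent branch is augmented by $v_1 v_2/(v_1+v_2)$. Three
conventions make the output deterministic and reproducible:

* **sign** — contrast signs are arbitrary in theory, so the child taken
  first is the one whose subtree holds the lexicographically smallest tip
  label; magnitudes are invariant to input rotation (and agree with
  `ape::pic`, which is used as an independent cross-check in the tests,
  never as the implementation);
* **degenerate branches** — zero-length branches are accepted on input;
  only when a contrast denominator is exactly zero is an epsilon
  (default $10^{-8}$) substituted, with a warning;
* **polytomies** — rejected rather than silently zero-resolved;
  `resolve_polytomies()` is the explicit opt-in.

Associations between contrast sets are computed through the origin
($r = \sum c_x c_y / \sqrt{\sum c_x^2 \sum c_y^2}$, $t$ test on $k-1$ df
for $k$ contrasts), because contrasts have expectation zero; the partial
correlation on contrasts applies the same first-order formula to the
three through-origin correlations with df reduced to $k-2$. Species
present in the count matrix but absent from the tree (or vice versa) are
dropped with a warning and an auditable list — the analogue of omitting a
species whose trait data exist but whose phylogenetic position does not.
Branch-length units are taken as given; contrast results are only as good
as the input tree's calibration.

## The synthetic generator

The generator exists so that every downstream stage can be tested with
known ground truth. It emulates, per `synthetic_config()`:

* $\log_{10} M \sim \mathrm{Uniform}(0, 8)$ — body masses from 1 g to
  $10^8$ g, the span from shrew-sized to whale-sized mammals (an optional
  Brownian-motion mode evolves $\log_{10} M$ along a Yule tree instead,
  for contrast-specific tests);
* $\log_{10} B = \log_{10} 0.02 + \alpha \log_{10} M + \varepsilon$,
  $\alpha = 3/4$, $\varepsilon \sim N(0, \sigma_B^2)$; the intercept
  (0.02 W for a 1 g organism) is a scale constant with no effect on any
  correlation;
* $B_c = B/M$, so the $B_c$ exponent is exactly $\alpha - 1 = -1/4$;
* $\sigma_B$ **calibration**: the defining choice. The synthetic confound
  should be as strong as the real one, so the default solves
  $|\mathrm{corr}(\log B_c, \log M)| = \rho$ for the noise:
  $\sigma_B = |\alpha - 1|\,\mathrm{sd}(\log_{10} M)\sqrt{1/\rho^2 - 1}$
  with $\rho = 0.95$, the observed magnitude of the mammalian $B_c$–$M$
  correlation. Over the default 8-decade mass range this gives
  $\sigma_B \approx 0.19$ log10 units;
* counts: category $j$ carries a class label and effect
  $\beta_j$ ($\beta_j \sim N(0, 0.5^2)$ for non-null classes by default;
  `effect_mode = "fixed"` draws $\pm$`effect_size_sd` for
  fixed-magnitude power studies) and
  $G_{ij} \sim \mathrm{Poisson}(\exp(a_0 + \beta_j z_i))$ with
  $a_0 = \log 50$ and $z_i$ the z-scored $\log_{10} B_c$ (class
  `bc_driven`), z-scored $\log_{10} M$ (`m_driven`), or $\beta_j = 0$
  (`null`). Poisson keeps counts integer with realistic mild
  heteroscedasticity and no extra dispersion parameter. The linear
  predictor is clamped to $|a_0 + \beta z| \le 30$ to guard overflow;
* the default class mix (0.7 `bc_driven`, 0 `m_driven`, 0.3 `null`)
  encodes the scenario the scan is designed to expose — a dataset whose
  apparent body-mass signal is entirely metabolic-rate-driven;
* categories are grouped into synthetic upper categories of at most 20,
  each holding a single class, so enrichment has a known concentrated
  signal;
* trees: a pure-birth (Yule) process — exponential waiting times with
  rate equal to the number of extant lineages, uniform choice of the
  splitting lineage — giving rooted binary trees with $n-1$ internal
  nodes.

Everything derives from one integer seed, at every granularity, so any
output is bit-reproducible from its manifest.

One property of this design matters when interpreting tests: the Poisson
log link is convex, so the *linear* correlation between a raw count and
$z$ peaks near $|\beta| \approx 0.5$ and falls again for larger effects
($\mathrm{corr}(Z, e^{bZ}) = b/\sqrt{e^{b^2}-1}$ for normal $Z$).
Power statements are therefore made at $|\beta| = 0.5$, where a
`bc_driven` category correlates with $\log B_c$ at $|r| \gtrsim 0.9$ for
$n = 200$ species.

What the generator does **not** emulate: realistic per-category count
scales or category sizes (all categories share $a_0$), gene overlap
between categories (which in real annotation data induces
multi-collinearity and blocks a joint multivariate model), correlated
effects among related categories, and any direct model of cancer
incidence. Passing tests demonstrate that the statistical machinery
recovers the generating mechanism under these idealized conditions, not
that real NOGF data satisfy them.

## Data-model conventions

* Units: body mass in grams, metabolic rate in watts, mass-specific rate
  in W/g; consistency $B_c = B/M$ is enforced to $10^{-9}$ relative.
* One representative species per genus, chosen by genome completion year.
  "Earliest" is the default reading (the longest-annotated, most mature
  genome) with "latest" available; ties break lexicographically by
  species id. A genus with several members and missing years is an
  error, not a silent choice.
* KEGG BRITE `.keg` flat files: only the `A/B/C/D` line prefixes are
  structural; HTML markup is stripped; `C` lines are third-level
  categories; `D` lines are genes, deduplicated within a category on the
  first whitespace token (a gene listed twice is one gene); a `D` line
  with no open `C` category is a format error. Genes appearing in several
  categories are counted once per category, independently.
* NOGF matrices are stored on disk categories-as-rows (the orientation of
  supplementary tables), species-as-rows in memory; a transpose flag
  covers both conventions.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on synthetic data at
the study scale the methods target: 33 species for the headline
calibrations (averaged over 100–200 replicate datasets), 342 categories
for scan-level summaries, 5000 categories for null-calibration checks,
and 50 replicates for the mechanism-recovery power study at
$|\beta| = 0.5$. Correlations are clamped to $[-1, 1]$ before $t$
transforms; $1 - r^2$ is floored at machine epsilon; exact-fit slopes
report a zero standard error without warnings. A category with zero count
variance yields a flagged row with `NA` statistics rather than being
dropped, and every species exclusion is recorded on the fitted object.

## Known limitations

* The partial correlation removes only the *linear* effect of
  $\log B_c$; strongly nonlinear metabolic dependence leaks into $r_p$
  (visible in the synthetic data as mild excess significance of
  `bc_driven` categories after correction at $n = 33$).
* Within one dataset, all categories share the same species-level noise
  draw, so per-dataset means of $r_p$ fluctuate around zero far more than
  independent sampling would suggest; dataset-level conclusions should be
  replicated across datasets (the tests average over seeds for exactly
  this reason).
* Contrast-based scans assume Brownian evolution and correct branch
  lengths; no phylogenetic GLS or Ornstein–Uhlenbeck alternatives are
  provided.
* The whole-matrix multivariate model (all categories as joint
  predictors) is deliberately out of scope: with overlapping gene sets it
  is singular.
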