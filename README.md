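# petoscan

Comparative-genomic scans of gene-family counts against body mass, with
explicit correction for the allometric scaling of metabolic rate.

## The problem

Peto's paradox is the observation that cancer incidence does not rise with
body size, even though a large animal carries vastly more cells than a
small one. One candidate explanation is *gene abundance*: larger species
may carry more copies of cancer-suppressing genes and fewer
cancer-promoting ones. The natural test is to correlate, across species,
the number of genes in each functional category (NOGF, the per-species
count of genes annotated to a category such as a KEGG pathway) with body
mass *M*.

That test has a trap. Whole-organism metabolic rate scales as
*B* ∝ *M*^3/4 (Kleiber's law), so the mass-specific rate
*B*<sub>c</sub> = *B*/*M* ∝ *M*^−1/4 is tightly *negatively* coupled to
body mass (across mammals, r ≈ −0.95 on log scales). Any gene category
whose size tracks cellular metabolic rate will therefore show a spurious
negative correlation with body mass. petoscan implements the scan
together with the diagnostics and corrections that separate genuine
body-mass effects from metabolic-rate artefacts:

- **simple scan** — Pearson r of NOGF with log₁₀ M per category;
- **B_c-corrected scan** — first-order partial correlation
  r_p = (r_GM − r_GBc·r_BcM) / √((1 − r_GBc²)(1 − r_BcM²)) and the
  standardized partial regression coefficient of M in
  NOGF ~ log₁₀M + log₁₀B_c;
- **correlation of correlations** — across categories, the correlation of
  the NOGF–M correlation vector with the NOGF–B_c correlation vector; a
  value near −1 is the signature of a metabolic-rate-driven scan;
- **enrichment** — Fisher's exact test for over-representation of
  significant categories inside each second-level functional category;
- **phylogenetically independent contrasts** — Felsenstein's pruning
  recursion implemented from scratch, with correlations of contrasts
  computed through the origin, to confirm results are not artefacts of
  shared ancestry;
- **allometric fitting** — log–log OLS estimate of the scaling exponent
  with its standard error;
- **synthetic data** — a fully seeded generator (log-uniform masses,
  Kleiber-law rates with calibrated lognormal noise, Poisson counts driven
  by log B_c, log M, or nothing) with ground-truth labels, so the whole
  pipeline is testable end to end;
- **KEGG BRITE** — a `.keg` flat-file counter that turns per-species
  hierarchy files into an NOGF matrix.

## Worked example

```r
library(petoscan)

cfg     <- synthetic_config(n_species = 33, n_categories = 342, seed = 7)
species <- generate_species(cfg)

fit_power_law(species$body_mass_g, species$mass_specific_rate_Wg)
#> Allometric power-law fit (log10-log10 OLS)
#>   exponent : -0.2528 +/- 0.0108 (SE)
#>   intercept: 10^-1.6771
#>   Pearson r = -0.973, p = 2.57e-21, n = 33

gen  <- generate_function_matrix(species, cfg)
scan <- nogf_scan(gen$counts, species, hierarchy = gen$hierarchy)
summary(scan)
#> NOGF scan summary (ols): 33 species, 342 categories (0 flagged)
#>   mean r   (NOGF-M)            : +0.015 (95% CI -0.058 .. +0.088)
#>   mean r_p (B_c-corrected)     : +0.029 (95% CI +0.010 .. +0.047)
#>   significant at p < 0.05        : 228/342 (66.7%) uncorrected, 6/342 (1.8%) corrected
#>   corr(r_M, r_Bc) across categories: -0.999 (p = 0)
```

The generated dataset has 70% of categories driven by mass-specific
metabolic rate and none by body mass itself, and the summary shows exactly
the diagnostic pattern that situation produces: two-thirds of categories
"correlate" with body mass, almost none survive the B_c correction, and
the correlation-of-correlations sits at −1. The same scan on contrasts
confirms it is not a phylogenetic artefact:

```r
tree <- generate_tree(33, seed = 9)
nogf_scan(gen$counts, species, hierarchy = gen$hierarchy,
          method = "pic", tree = tree)
#> NOGF scan (pic), 33 species, 342 categories (0 flagged undefined)
#>   significant NOGF-M (p < 0.05):  246/342 (71.9%) uncorrected, 47/342 (13.7%) B_c-corrected
```

`enrich(scan, field = "p_M")` then shows the significant categories
concentrated in the upper categories that house the metabolic-rate-driven
classes, `top_table(scan)` lists the strongest corrected associations,
and `run_full_analysis(out_dir)` writes the full TSV report bundle (scan
results, meta summary, enrichment tables, allometric fits, ground-truth
confusion table, manifest) in one call.

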