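# crowdemog

Demographic model comparison and introgression statistics for
four-population secondary-contact systems, built around the European
crow hybrid zone.

## The problem

Western European carrion crows (EURw) share their all-black plumage
with the Iberian refugial population (SPA) but are genomically almost
indistinguishable from grey-coated hooded crows (EURns), except for a
single highly differentiated plumage locus on chr18.  Two histories can
generate this pattern, and telling them apart is the package's purpose:

* **Genome-wide swamping (GWS)** — topology `((SPA,EURw),(EURns,IRQ))`:
  EURw is of Iberian ancestry, and massive post-contact gene flow from
  EURns homogenised the whole genome except the selection-protected
  colour locus (a *barrier locus*).
* **Locus-specific introgression (LSI)** — topology
  `((IRQ,(EURw,EURns)),SPA)`: EURw and EURns are true sisters and only
  the black plumage allele introgressed from Iberia.

The package is for population geneticists who want to run — or study at
desk scale — the full inference chain that discriminates the two on
putatively neutral variation.

## What it implements

* A structured-coalescent simulator (Rcpp) for independent
  non-recombining loci under isolation-with-migration models with
  population splits, epoch-bounded asymmetric migration and exponential
  growth, with infinite-sites and finite-sites (HKY, ts/tv = 2)
  mutation layers.  Validated analytically (`E[T2] = 2N`,
  `E[pi] = 4 N mu`) and distributionally against msprime.
* Folded joint-SFS composite likelihood: per pair of populations the
  folded spectrum counts minor-allele configurations `(i, j)`; the
  expected spectrum under a model is Monte-Carlo-estimated from
  expected branch lengths; the composite log-likelihood is
  `sum_c O_c log10 p_c` summed over the six population pairs, and
  models are compared by `AIC = 2k - 2 ln(10) log10(L)`.
* ECM-style fitting (cyclic golden-section conditional maximisation
  with common random numbers), single-parameter profile likelihoods,
  parametric bootstrap with `2 theta_hat - mean(theta*)` bias
  correction.
* Topology weighting: per-block NJ gene trees (model-corrected
  distances, outgroup rooting), exact or sampled one-leaf-per-taxon
  subtree classification, `k^2`-cell ternary binning of 3-topology
  weights, and observed-vs-simulated L1 comparison.
* Windowed statistics: pi, d_XY, Hudson F_ST (ratio of sums),
  `d_a = d_XY - (pi_x + pi_y)/2` and its time conversion
  `T = d_a / (2 mu) * g`, Tajima's D, Patterson's D, f4-ratio,
  Malinsky's f_dM in 50-SNP windows, four-gamete violation fractions,
  and exact Hardy-Weinberg filtering with a barrier-contig exemption.
* A synthetic-data generator producing VCF + population map + haploid
  outgroup table + truth record, with a chr18-like migration-resistant
  barrier region, under either scenario at the published point
  estimates (times 504/131/34.5/20.0 kya, the six migration rates, and
  growth in the expanding populations).

## Worked example

```r
library(crowdemog)

gws <- build_gws_model()   # fastsimcoal point estimates + default sizes
ds <- generate_dataset("gws",
  layout = list(n_contigs = 8, loci_per_contig = 25, locus_length = 1000,
                barrier_contig = 8, barrier_loci = 15),
  seed = 1)
ds
#> <synthetic_dataset> scenario gws: 2149 SNPs, 50 samples, 8 contigs
#>   (barrier on contig8)

ws <- window_stats(ds$geno, window_size = 25000)
fst <- subset(ws, stat == "fst" & pop_a == "EURw" & pop_b == "EURns")
mean(fst$value[fst$contig == "contig8"], na.rm = TRUE)   # barrier
#> 0.205
mean(fst$value[fst$contig != "contig8"], na.rm = TRUE)   # background
#> 0.0207

fd <- fdm_windows(ds$geno, "SPA", "EURw", "EURns", window_snps = 50)
mean(fd$fdm, na.rm = TRUE)
#> 0.198
```

The barrier region keeps an order of magnitude more EURw–EURns
differentiation than the swamped background (0.205 vs 0.021), and the
genome-wide f_dM of 0.198 reflects the EURw–EURns gene flow that the
swamping scenario posits.

The full comparison chain — generate, window statistics, folded joint
SFS of all six pairs, fit both scenarios, AIC, topology-weighting
comparison — runs in one call:

```r
report <- run_comparison(list(seed = 3,
                              fit = list(n_sim_loci = 300),
                              twisst = list(n_trees = 400)))
report$aic_table
#>   scenario log10_lik k      AIC converged delta_AIC
#> 1      gws -39780.90 5 183207.8      TRUE    0.0000
#> 2      lsi -39865.49 5 183597.4      TRUE  389.5524
report$winner
#> "gws"
```

Both scenarios are fitted with five role-equivalent free parameters to
data generated under genome-wide swamping; the generating scenario wins
by about 390 AIC units on this ~0.5-Mb dataset.

See `vignettes/model-comparison.Rmd` for the model descriptions, the
conventions (forward-time migration rates, years-to-generations
conversion, folding and binning rules), the design choices and the
known limitations.

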