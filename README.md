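# mitochron

Dating maternal-lineage founder events from whole mitochondrial genomes.

Mitogenome phylogeography reads population history off a single
non-recombining locus: clades of related sequences (haplogroups) are
placed on a rooted, mutation-annotated tree, and the mutations carried by
a clade's sampled descendants are converted into a coalescence age with a
molecular clock. `mitochron` implements that whole chain for researchers
who date migrations and expansions from mtDNA:

* **Variant profiles & haplogroups** — per-sample substitution profiles
  from an aligned FASTA against an rCRS-frame reference, and deterministic
  motif-based haplogroup calls against a PhyloTree-style motif database.
* **Tree building** — reduced-median network construction over binary
  characters, with reticulations resolved by a mutation-frequency rule
  (recurrence goes to hypervariable sites) into a rooted mutation tree.
* **Chronology** — the rho statistic with its Saillard standard error,

  &nbsp;&nbsp;ρ = Σₑ nₑ·lₑ / n,  σ² = Σₑ (nₑ/n)²·lₑ,

  converted to years under a **synonymous clock** (1 synonymous
  substitution / 7884 yr) or a **whole-molecule clock** (1 substitution /
  3624 yr, purifying-selection-corrected rate constants); plus a Poisson
  maximum-likelihood clock model over node ages and a likelihood-ratio
  test for clock violation (clock vs saturated branch model, chi-square
  with #edges − #internal-nodes df).
* **Phylogeography** — regional clade ages by two repartitioning
  approaches (all regional samples vs origin-aware basal lineages), clade
  origin inference (basal-branch geography, rho diversity, centre of
  gravity), founder arrival-window classification, and per-population
  lineage-origin frequency tables.
* **Sex bias** — harmonised mtDNA / Y-chromosome / autosomal ancestry
  fractions per population and the paternal-minus-maternal contrasts.
* **Synthetic data** — a coalescent simulator (constant size, growth,
  star expansions, and two-phase founder/re-expansion scenarios) with
  known node ages, so every stage above is validated against ground
  truth with no downloads.

## Worked example: the secondary founder effect

A clade founded 55 ka whose root type survives and re-expands 40 ka
(80% of today's samples descend from the re-expansion) looks much younger
to rho than it is — and origin-aware regional repartitioning recovers the
deep age:

```r
library(mitochron)

ref   <- synthetic_reference()
truth <- simulate_genealogy(40, dem_two_region_founder(), seed = 7)
truth <- drop_mutations(truth, mu = 1 / (3624 * 16569), seed = 8,
                        reference = ref)

tips  <- which(truth$nodes$type == "sample")
profs <- tibble::tibble(
  sample_id = truth$nodes$label[tips],
  region    = truth$nodes$region[tips],
  mutations = lapply(tips, function(v) cumulative_profile(truth, v))
)
tree <- network_to_tree(reduced_median(profs), profiles = profs)
ck   <- clock_whole_molecule()

age_estimate(tree, clock = ck)
#>   node  method clock            rho sigma age_years ci_low ci_high n_tips
#> 1 root  rho    whole_molecule  13.0  1.03    46931. 39596.  54265.     40

glance(ml_clock_ages(tree, ck))
#>     lnL converged clock          years_per_substitution n_edges root_age_years
#> 1 -120. TRUE      whole_molecule                   3624      93         51739.

tidy(lrt_clock(tree, ck))
#>   statistic    df p_value
#> 1      46.8    39   0.183

regional_age_all_samples(tree, region = "west", clock = ck)$age_years
#> [1] 53001
regional_age_by_origin(tree, region = "west", clock = ck)$age_years
#> [1] 56776

true_tmrca(truth)
#> [1] 55000.03
```

The true clade age is 55 ka. The tip-averaged rho age (46.9 ka) is pulled
toward the 40 ka re-expansion; the ML age (51.7 ka), anchored by the deep
branches, is bitten less; and the origin-aware regional age (56.8 ka vs
53.0 ka for the naive regional estimate) restores the founding-era signal
by excluding immigrant members of the young foreign-origin clade. The LRT
finds no clock violation in these clock-simulated data (p = 0.18).

Window classification and the sex-bias summary work off tabular inputs:

```r
assign_window(21000)            # -> LGM
assign_window(3000)             # -> bronze_age

a <- readr::read_tsv(system.file("extdata", "synthetic_ancestry.tsv",
                                 package = "mitochron"))
sex_bias_summary(harmonize_ancestry(a))
```

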