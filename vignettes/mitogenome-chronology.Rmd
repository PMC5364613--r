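---
title: "Dating maternal founder events from mitogenomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating maternal founder events from mitogenomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochron)
```

## What the package does

Whole mitochondrial genomes accumulate substitutions at a roughly constant
rate, so the mutations carried by the sampled descendants of a clade
measure the clade's coalescence age. `mitochron` implements the full chain
of inference used in mitogenome phylogeography: variant profiles from
aligned sequences, motif-based haplogroup calls, a mutation-annotated
rooted tree built by reduced-median network construction, clade ages under
two molecular clocks by both the rho statistic and a Poisson
maximum-likelihood clock model, a likelihood-ratio test for clock
violation, regional repartitioning of clade ages, founder time-window
classification, and a cross-marker (mtDNA / Y / autosomal) sex-bias
summary. A coalescent simulator with known node ages provides ground truth
for every stage, so the whole pipeline is testable without any external
data.

## The rho statistic and its standard error

For a clade root with $n$ sampled descendant leaves, the rho statistic is
the mean number of counted mutations from the root to each leaf:

$$\rho \;=\; \frac{1}{n}\sum_{\text{leaves } i} m_i
      \;=\; \frac{1}{n}\sum_{\text{edges } e} n_e\, l_e ,$$

where $n_e$ is the number of sample leaves descending through edge $e$ and
$l_e$ its counted mutations. Both forms are implemented (`rho(method =
"edge")` / `method = "path"`) and property-tested for equality. Treating
the per-edge counts as independent Poisson draws gives the estimator's
standard error

$$\sigma^2 \;=\; \sum_e \left(\frac{n_e}{n}\right)^2 l_e ,$$

which on a star phylogeny reduces to $\sigma^2 = \rho/n$. Ages are
$\hat T = c(\rho\, y)$ with symmetric 95% intervals
$c((\rho \pm 1.96\,\sigma)\, y)$ truncated at zero, where $y$ is the
clock's years-per-substitution and $c(\cdot)$ a monotone correction hook.

## Clocks

Two standard clocks are provided:

* **synonymous clock** — one *synonymous* substitution per **7884 years**;
  only codon changes that leave every overlapping reading frame's amino
  acid unchanged (vertebrate mitochondrial code, light-strand genes
  complemented) are counted;
* **whole-molecule clock** — one substitution per **3624 years**, counting
  every substitution outside the exclusion lists.

Both published rate constants are already corrected for purifying
selection, which is why the correction hook defaults to the identity; a
user can plug in any monotone curve with $c(0)=0$. Indels never enter
clock counts, and a configurable hotspot list (defaults: 16182, 16183,
16194, 16519 and the length-variant neighbourhoods around 309 and 573) is
excluded — standard practice for substitution clocks on mitogenomes, and
configurable because published analyses rarely state their exact exclusion
sets.

## The Poisson maximum-likelihood clock

The ML model treats each edge's counted mutations as
$k_e \sim \text{Poisson}\!\big((a_{p(e)} - a_{c(e)})/y\big)$ with sample
leaves fixed at age 0 and the order constraint
$a_\text{parent} \ge a_\text{child}$. This is a deliberately reduced
single-rate model: it keeps the statistical contrast that matters (shared
node ages versus free branch lengths) at desk scale, rather than refitting
a general substitution model with rate heterogeneity.

Numerically, the constrained problem is solved on the log-increment
parametrisation $a_v = \max_{c \in \text{children}(v)} a_c + e^{z_v}$,
which makes the constraints implicit, with quasi-Newton (BFGS) ascent
initialised at the rho ages and a final cyclic coordinate polish.
Single-coordinate updates alone were tried first and rejected: with hard
order constraints they jam at the boundary several log-likelihood units
below the optimum, which materially distorts the likelihood-ratio test.
Profile-likelihood intervals (`ml_age_ci`) re-optimise all other ages with
the target age pinned and bisect on the $\chi^2_1$ cutoff.

The clock-violation LRT compares the fitted clock model against the
saturated model ($\lambda_e = k_e$); the statistic
$2(\ell_\text{free} - \ell_\text{clock})$ is referred to chi-square with
$\#\text{edges} - \#\text{internal nodes}$ degrees of freedom. A known
limitation, visible in the calibration experiment: with sparse counts
(around one mutation per edge, typical of dense mitogenome trees) the
deviance is markedly *conservative*, because many fitted ages sit on
constraint boundaries. The package's calibration experiment therefore
simulates at about 5 counted substitutions per clock interval — the
moderate-count regime the chi-square reference assumes — and the test's
conservatism at sparser counts should be kept in mind when a
non-significant result is interpreted.

## Reduced-median networks and tree resolution

Tree building works on binary characters (multi-allelic positions are
split per derived allele). The network stage iteratively adds the
majority-rule (Steiner) median of haplotype triplets until closure, then
applies a reduction pass controlled by the conventional parameter
$r = 2$: where a cycle offers two parallel resolutions, the inferred
median supported by the lighter site weight is removed when the competing
weight is at least $r$ times larger. Inferred medians not needed to
connect observed haplotypes are pruned. Network links are minimal geodesic
connections — unit Hamming distance wherever an intermediate haplotype
exists, a single multi-mutation link where none does (the two-haplotype
network is one link carrying all their differences).

Reticulations are resolved into a tree by a minimum-weight spanning tree
over the links, with edge weight equal to the summed site weights. Site
weights are scaled 1–99, inversely proportional to a packaged relative
mutation-frequency spectrum (`default_site_frequencies()`, a stylised
spectrum with the well-known control-region and coding hotspots elevated).
Minimising total inverse-frequency weight places recurrence on
high-frequency sites and keeps rare mutations unique, which is exactly the
frequency rule used in manual curation. Residual ties break
deterministically by site label and node key. Samples attach to their
haplotype nodes as zero-length leaves, so ancestral haplotypes that are
themselves sampled sit at internal nodes and correctly depress rho.

**Identifiability.** A split witnessed by no mutation cannot be
reconstructed from sequence data, whatever the method. Recovery
experiments therefore compare the built tree against the true genealogy
*after contracting zero-mutation internal edges*
(`collapse_zero_edges()`), and the infinite-sites recovery experiment uses
an elevated rate so that most internal edges are witnessed. The
finite-sites default, by contrast, deliberately allows recurrent hits so
that homoplasy stress-tests the network stage.

## Haplogroup calling

The motif database is a rooted tree of labels; each node's defining
mutations are given in PhyloTree-style notation, with a trailing `!`
marking a back mutation that restores the reference-state expectation.
A profile is scored against every node's *cumulative* expectation as
`matched − 0.5 × expected-but-absent`; private mutations do not penalise.
Ties prefer the deeper node, then the lexicographically first label. This
reproduces the behaviour that matters for downstream dating —
deterministic, nesting-consistent calls — without re-implementing any
particular tool's proprietary rank score. The packaged
`synthetic_motifs.tsv` is a stylised miniature, not a real nomenclature
build.

## Regional ages, origins and founder windows

Two repartitioning approaches are implemented for a haplogroup and a
region:

1. **All samples** (`regional_age_all_samples`) — keep every leaf of the
   region and recompute $\rho/\sigma$ from the haplogroup root.
2. **By origin** (`regional_age_by_origin`) — keep only subclades whose
   inferred origin is the target region, and within them only the
   region's basal lineages, recursively excluding leaves nested inside a
   major subclade assigned to a different region. Minor subclades (below
   `min_samples = 5`) fall back to the modal region of their leaves.

Approach 2 is what neutralises the secondary-founder artefact: immigrant
members of a young clade of foreign origin no longer dilute the deep
local age.

Clade origin (`infer_origin`) scores each region by three min-max
normalised components with equal default weights: the number of basal
branches containing the region, the region's internal rho diversity, and
proximity to the clade's leaf-weighted centre of gravity. The centre of
gravity needs coordinates; by default regions sit at unit spacing on a
line in label order, and real analyses should supply a `centroids` table.
The published criteria name these three signals without weights or a
geometry, so the score here is one documented operationalisation, and the
full per-region evidence table is returned for audit.

Arrival windows default to contiguous intervals in ka — bronze age
[0, 4), neolithic [4, 9), postglacial [9, 13), late glacial [13, 17),
LGM [17, 24), pre-LGM [24, ∞) — bracketing the conventional narrative
horizons; exact cutoffs are configuration, and a call whose 95% CI spans
a boundary is flagged `boundary_ambiguous`.

## Sex-bias summaries

Per population and origin class, the summary contrasts the paternal and
maternal ancestry fractions: $\Delta = f_Y - f_{mt}$, the ratio
$f_Y / f_{mt}$ (reported only when $f_{mt} > 0$), and the gap between the
autosomal fraction and the uniparental midpoint. Because each system's
fractions sum to one, the deltas sum to zero within a population — an
exact identity used as a test. The `marked_bias` flag at $|\Delta| >
0.25$ is a reporting convention of this package, recorded in the output
attributes, not an inferential statistic. Autosomal fractions are
consumed from an external clustering run's mean components; the package
does not refit genome-wide cluster models.

## The synthetic-data generator

`simulate_genealogy()` draws Kingman coalescent genealogies with
piecewise-constant $N(t)$ (generation time 25 years, configurable);
`drop_mutations()` adds per-edge Poisson mutation counts at
$\mu L \times \text{duration}$ with uniform site choice (finite sites by
default, an infinite-sites switch for clean oracle tests);
`emit_dataset()` writes the aligned FASTA, metadata TSV and truth JSON
that the I/O stage consumes. All randomness flows from explicit seeds,
with separate seeds for genealogy and mutation draws.

Four scenario families are provided. `dem_constant` and `dem_growth` are
standard. `dem_star(T)` is the idealised instantaneous expansion used for
recovery calibration. The two-phase founder scenarios
(`dem_founder_reexpansion`, `dem_two_region_founder`) encode a clade that
originates at `T1` and is re-expanded at `T2` by a single surviving
lineage carrying a near-root haplotype: the burst tips stay distinct
until `T2` and close star-like there, the deep remnant lineages stay
distinct until `T1`, and the root-to-burst path carries exactly
`founder_mutations` (default one) defining mutations rather than a
Poisson draw. That conditioning is the point of the scenario: a
re-expanded near-root type attaches the young burst almost at the clade
root, so rho — which averages over tips — is pulled toward `T2`, while
the ML model, anchored by the deep branches, is pulled less. The
two-region variant samples a configurable fraction (`p_back = 0.3`) of
burst tips in the origin region, which is what contaminates the naive
regional age and what approach 2 removes.

**Rates.** The default mutation rate is the whole-molecule anchor
$2.514\times10^{-8}$ per site per year. Note that
$\mu L \times 3624 \approx 1.5$: the published clock interval is a
selection-corrected calibration, not the raw expected count per 3624
years. Recovery and calibration experiments therefore simulate at the
rate of the clock under test (one counted substitution per
`years_per_substitution`), so that they probe the estimators rather than
build a fixed 1.5× scale offset into every comparison.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: site-rate heterogeneity beyond the
hotspot list, purifying selection and its time-dependence, sequencing and
alignment error, partial (HVS-only) records, and real sampling structure.
The validation demonstrates that the estimators are correct under their
own model assumptions and that the founder-effect mechanism behaves as
described; it does not certify rate constants against external
calibration.

## Validation experiments and problem sizes

The `experiment_*` functions regenerate everything from seeds: star
recovery (200 replicates of a 50-tip, 50 ka expansion; mean age and 95%
CI coverage), founder bias (200 replicates, 50 tips, `T1 = 55` ka,
`T2 = 40` ka, 80% burst; rho vs ML shortfall and the approach-1 vs
approach-2 contrast), LRT calibration (500 null replicates, 20 tips) and
power (200 replicates with one lineage at 5× rate), and topology recovery
(100 infinite-sites replicates, 8–30 tips). `scripts/acceptance.R` runs
all of them and writes the resulting numbers as JSON; the test suite
asserts the same properties at the same sizes.

## Worked example

```{r example, eval = FALSE}
ref <- synthetic_reference()
truth <- simulate_genealogy(40, dem_two_region_founder(), seed = 7)
truth <- drop_mutations(truth, mu = 1 / (3624 * 16569), seed = 8,
                        reference = ref)

profs <- tibble::tibble(
  sample_id = truth$nodes$label[truth$nodes$type == "sample"],
  region = truth$nodes$region[truth$nodes$type == "sample"],
  mutations = lapply(which(truth$nodes$type == "sample"),
                     function(v) cumulative_profile(truth, v))
)
tree <- network_to_tree(reduced_median(profs), profiles = profs)

ck <- clock_whole_molecule()
age_estimate(tree, clock = ck)                       # rho age of the clade
glance(ml_clock_ages(tree, ck))                      # ML age and lnL
tidy(lrt_clock(tree, ck))                            # clock-violation LRT
regional_age_all_samples(tree, region = "west", clock = ck)
regional_age_by_origin(tree, region = "west", clock = ck)
```

## Known limitations

* The reduced-median implementation is a documented variant; the exact
  behaviour of the historical desktop tool is not published to
  reproducible precision.
* The ML clock is single-rate Poisson on counted mutations; it does not
  model substitution-type exchangeabilities, rate heterogeneity across
  sites, or partition structure.
* The LRT is conservative at sparse per-edge counts (see above).
* Median closure is exponential in the number of incompatible characters;
  a safety cap (`max_medians`) guards pathological inputs.
* Haplogroup calls depend entirely on the supplied motif database; the
  packaged database is a synthetic miniature for examples and tests.
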