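---
title: "Linkage mapping and synteny analysis in an F1 outbred whitefish cross: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping and synteny analysis in an F1 outbred cross: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whitemap)
```

# The problem

A single wild-caught F1 family — two outbred parents and 156 offspring
genotyped at biallelic RAD-seq SNPs — is enough to build a genetic linkage
map. Because the parents are outbred, each marker falls into one of three
informative configurations (a *pseudo-testcross* design):

* **MAT_INF** — mother Aa, father homozygous: offspring segregate 1:1 and
  reveal which maternal haplotype they received; only the mother's meioses
  are observable.
* **PAT_INF** — the mirror image, informative for the father.
* **BOTH_INF** — both parents Aa (an intercross marker): offspring segregate
  1:2:1, and only the *homozygous* offspring reveal allele origin — a
  heterozygous offspring may have received either allele from either parent.

Because the two sexes recombine at different rates (heterochiasmy), the same
marker order carries distinct female and male centimorgan coordinates; their
ratio summarises the sex difference. After map construction, each linkage
group is matched to a chromosome of a related reference genome (Atlantic
Salmon) by majority mapping of its markers, and the genome-wide distribution
of confident mappings is interpreted through the lens of the salmonid
whole-genome duplication: chromosome arms that rediploidized in the common
ancestor (AORe) retain 1:1 cross-species orthology and attract confident
mappings, while lineage-specific (LORe) arms do not.

`whitemap` implements this whole chain — simulation, filtering, two-point
linkage, grouping, ordering, sex-specific maps, summary statistics, synteny —
with a tidyverse-style API (tibbles in, tibbles out; `tidy()`/`glance()`
methods; `autoplot()` figures).

# The synthetic cross generator

Nothing downstream is testable against truth without a generator, so the
generator is a first-class module. `sim_config()` fixes the study conditions;
its defaults emulate the whitefish design:

| parameter | default | meaning |
|---|---|---|
| `n_offspring` | 156 | family size |
| `n_groups` | 40 | linkage groups (chromosomes) |
| `markers_per_group` | 135 | ~5395/40 SNPs |
| `mean_spacing_cM` | 0.42 | mean male-map gap between RAD loci (exponential) |
| `female_expansion` | 1.09 | female = male distance × factor |
| `seg_mix` | 1/3 each | MAT_INF : PAT_INF : BOTH_INF |
| `error_rate` | 0.01 | symmetric genotype replacement |
| `missing_rate` | 0.05 | per-call missingness |
| `rad_multi_snp` | .55/.25/.12/.08 | RAD loci with 1/2/3/4+ SNPs |

Design choices, and what they imply:

* **Crossovers are interference-free** (Haldane): between adjacent markers at
  sex distance $d$ cM the haplotype origin switches with probability
  $r = \tfrac12(1-e^{-2d/100})$, independently across intervals. This makes
  the simulator and the estimator mutually consistent — passing recovery
  tests therefore validates the estimation machinery, *not* the adequacy of
  the no-interference assumption for real meioses.
* **Heterochiasmy is a uniform expansion factor**: the study reports
  genome-wide ratios (1.09 total, 1.25 per-group), not interval-level sex
  differences, so a single factor is the faithful minimal model.
* **Multi-SNP RAD loci are fully linked clusters** (0 cM spacing), giving
  the SNP-thinning filter realistic input.
* **Genotyping error is symmetric replacement** among the two other
  genotypes; this is the simplest model that exposes the well-known
  map-inflation effect of genotyping error (asserted in the test suite:
  estimated length grows strictly with the error rate).
* Parental linkage phases are drawn uniformly at random per marker, as in
  real data — phase is *never* an input to estimation.

What the generator does **not** emulate: read-level noise and coverage
(allele-depth), crossover interference, segregation distortion with a
biological cause, and population structure. Tests passing on this generator
say nothing about those.

# Filtering

The informative-marker funnel mirrors the published pipeline and logs every
removal (`filter_log()`): segregation typing and removal of uninformative
markers (any marker with a missing parent call is uninformative by
definition); RAD loci with more than three SNPs removed outright and loci
with two or three SNPs thinned to one random SNP; markers with offspring
missingness strictly above 20% removed (exactly 20% is kept — "over 20%");
and a segregation-distortion chi-square at tolerance 0.001.

Two open points were decided here:

* **Three-SNP RAD loci.** The published rule states ">3 removed" and
  "2 → pick one" but is silent on exactly 3; we thin them to one random SNP,
  consistent with the one-SNP-per-locus intent.
* **The 1:2:1 test for intercross markers.** Both variants are implemented.
  The default tests only the homozygote classes against 1:1, for two
  reasons: heterozygous offspring of a BOTH_INF marker carry no phase
  information, so the informative-offspring ratio is the quantity the
  mapping stage actually consumes; and empirically the three-class Pearson
  test with df = 2 is anti-conservative in the far tail (measured type-I
  rate ≈ 0.0018 at nominal 0.001 over 55 000 simulated undistorted markers,
  versus ≈ 0.0009 for the homozygote variant, with 156 offspring). The
  calibration experiment in `tests/testthat/test-acceptance.R` asserts that
  the removal rate's binomial confidence interval covers the nominal
  tolerance.

Hard genotype calls are used throughout; the original pipeline's conversion
to genotype likelihoods is deliberately out of scope and documented as a
simplification.

# Two-point estimation

For a marker pair and a parent, every offspring whose transmissions are
determined at both markers contributes one meiosis. With phase unknown,
recombinants are counted under one phase and folded, $k = \min(k, n-k)$ —
the likelihood-maximising phase — giving $\hat r = k/n$ and

$$\mathrm{LOD} = k\log_{10}(2\hat r) + (n-k)\log_{10}(2(1-\hat r)),$$

which is $n\log_{10}2$ at $\hat r = 0$ and exactly 0 at $\hat r = 1/2$. In
the joint context the two parents' folded counts are pooled.

**Why intercross × intercross pairs need more care.** For a BOTH × BOTH
pair, the offspring with determined transmissions are the doubly homozygous
ones — and whether an offspring is doubly homozygous *depends on the
recombination events themselves*. With equal parental phases the subset is
depleted of recombinants; with opposite phases it is *enriched* for them
(we measured folded counting estimates near 0.39 at a true $r\approx0.1$,
from as few as 13 conditioned meioses out of 150). Direct counting is
therefore both starved and biased for these pairs. They are instead fitted
by EM over the full two-locus transmission likelihood of the 3 × 3 offspring
genotype table, maximised over the four parental phase pairings
(convergence at $|\Delta r| < 10^{-6}$, at most 100 iterations), vectorised
across all pairs. The single-pair path (`pair_estimate()`) is verified in
the test suite against a brute-force oracle that numerically maximises the
enumerated likelihood. For pseudo-testcross × intercross pairs one can show
the heterozygous offspring carry exactly zero two-point information (the EM
fixed point equals the counting estimate), so counting is used there.

A caveat worth knowing: even the full likelihood extracts little information
from an *opposite-phase* BOTH × BOTH pair (the 9-cell table is nearly
independent of $r$ for one parent), so such pairs legitimately produce weak
LODs and poorly determined sex-specific estimates. Two downstream choices
respond to this.

# Grouping, ordering, positions

**Grouping** is single-linkage transitive closure over pairs with
LOD ≥ `lod_limit` (threshold inclusive), with components below `min_markers`
dissolved into an unassigned pool — never force-merged. Raising the limit
can only refine the partition (a tested invariant).

**Ordering** minimises the sum of adjacent recombination fractions (SARF):
each of three seeded runs builds a path from the farthest pair by greedy
insertion, then polishes with alternating 2-opt reversals and single-marker
relocations until no move improves; the best run wins (ties to the lowest
run index) and orientation is canonicalised. Marker pairs with *no* shared
informative meiosis (MAT × PAT pairs) have no estimate; their entries are
imputed as shortest-path Haldane distances through estimated pairs before
ordering. (A flat 0.5 penalty — the obvious alternative — makes the
criterion prefer sorting markers by segregation type over the true order;
we measured a SARF of 2.0 for that artefactual order versus 11.2 for the
truth under the penalty scheme.) On groups of ≤ 8 markers the heuristic is
required, in the acceptance suite, to match the exhaustive-minimum SARF in
200/200 noisy random instances.

**Positions.** For a sex-specific map the walk runs along the order over the
markers informative for that parent; markers not informative for the sex
inherit the running position (they cannot recombine in that parent's map,
so a group of purely paternal markers has a 0 cM female map). Each
interval's distance is the Haldane (optionally Kosambi) transform — but
taken as the *shortest supported-path distance* (edges are pairs with
LOD ≥ 3) rather than the raw adjacent estimate, because an adjacent
opposite-phase intercross pair can leave $\hat r$ drifting to 0.5 and the
mapped interval diverging. Intervals with no path contribute 0 cM; a
configurable 50 cM cap remains as a guard.

**The sex-averaged map** is the per-marker mean of the two completed sex
maps. The alternative sometimes suggested — pooling recombinant/total counts
per adjacent interval — is also implemented (`averaged_method = "pooled"`)
but is *not* the default: across a junction between a maternal-only and a
paternal-only marker the pooled count is structurally zero, so with mixture
proportions $p_m, p_p$ a fraction $\approx 2p_mp_p$ of intervals contribute
nothing and group length is deterministically deflated (≈ 22% under the
default mixture) — far outside the 10% recovery tolerance the package holds
itself to.

# Choosing the grouping threshold for the validation experiment

The published threshold is lodLimit = 16, tuned to a study with ~7800
markers (≈ 3 × 10⁷ candidate pairs) and a 0.43 cM map. The package keeps 16
as the default everywhere (`build_map()`, `pipeline_config()`).

The standing validation experiment (`recovery_experiment()`) simulates a
deliberately smaller design — 5 groups × 60 markers at 2 cM mean exponential
spacing, 156 offspring, no genotyping error, female expansion 1.5 — so the
threshold question must be re-asked at that scale. Two facts decide it:

* *False linkage*: with ≈ 4.5 × 10⁴ candidate pairs, Bonferroni control at
  the 5% level needs only LOD ≈ 5.2; any threshold in the 6–10 band keeps
  expected false links below 10⁻⁴.
* *True linkage*: exponential spacing puts roughly one ≥ 8 cM gap in every
  60-marker group, and the best two-point LOD spanning such a gap with 156
  offspring is ~15–20 — so at a threshold of 16 legitimate chains break.
  We measured mean ARI ≈ 0.87 at LOD 16 under these conditions, versus
  ARI = 1 in 10/10 replicates at LOD 8. One test documents exactly this
  fragmentation behaviour.

`recovery_experiment()` therefore defaults to `lod_limit = 8` —
conservative by three orders of magnitude against false linkage at this
design size — and reports: ARI = 1 in 10/10 seeds; mean absolute relative
error of sex-averaged group lengths ≈ 8% (tolerance 10%); pooled
female:male ratio ≈ 1.46 against a simulated 1.5 (tolerance ±0.15).

Problem sizes were chosen so the full validation (10 replicates of
300 markers × 156 offspring, plus a 55 000-marker calibration run and a
20 000-marker synteny run) completes in a few minutes on one CPU; they are
stated here as the package's validation design.

# Map statistics

`map_summary()` reports per group: SNP count, length (last position) per
map, cM-per-marker, female:male ratio (undefined, and excluded from the
per-group mean, when either sex length is 0); globally: totals, per-group
means, the total-length F:M ratio, and the per-group-mean F:M ratio. Two
conventions were fixed after checking them against the published table:

* The printed per-group "SNPs/cM" columns actually equal length/SNPs
  (e.g. 75.96/253 = 0.30), i.e. cM per marker; the packaged fixture renames
  them accordingly.
* The global marker spacing is the *unweighted mean* of per-group
  cM-per-marker (reproducing the printed 0.46); the alternative
  Σlength/ΣSNPs (= 0.43) is exposed as `overall_cM_per_marker`.

The published 40-row table ships as a checksum-verified fixture
(`load_table1()`), and `map_summary()` on it reproduces every printed total
and average; the acceptance suite asserts each one.

# Synteny

Mapping records (marker, chromosome, bp, MAPQ — the SAM RNAME/POS/MAPQ of a
primary alignment; the alignment itself is out of scope) are filtered at
MAPQ > 30, *strictly*, and restricted to mapped markers. Each linkage group's
homolog is the chromosome with most hits; ties break to the lower chromosome
number but are always flagged `ambiguous` (the real data never faced a tie,
and a silent choice would hide one). Groups are ranked by homolog chromosome
and median concordant hit position and renamed `W01…`.

The rediploidization contrast distributes the retained hit total over
chromosome arms in proportion to arm length, after excluding the six
`mixed`-class arms — exclusion happens *before* the denominator is computed,
which makes conservation exact: expected counts sum to the hits on included
arms (a tested invariant on every run). Per-arm ratio = expected/observed,
`NA` (and excluded) when observed = 0, mirroring the published handling of
the zero-hit arm. The AORe vs LORe ratio sets are compared with a two-sided
Wilcoxon rank-sum test via `stats::wilcox.test` — exact when tie-free and
small, normal approximation with tie and continuity corrections otherwise —
and the implementation is cross-checked in the tests against a from-scratch
enumeration over all group assignments for every tie-free input with
$n_1+n_2 \le 12$. The reported `W` counts AORe-over-LORe pairs, so the
published complete-separation outcome corresponds to `W = 0`; a synthetic
run with LORe arms receiving hits at 20% of their length-proportional rate
reproduces exactly that.

The packaged arm table is **synthetic**: it honours the published class
structure (30 AORe arms, the 14 published LORe block arms, the 6 named mixed
arms) with plausible—not measured—lengths, and is named
`salmon_arms_synthetic.csv` to say so. Users with the real annotation supply
their own CSV.

# Numerical and degenerate-input conventions

* Genotypes are ALT-allele dosages 0/1/2 with NA missing; genotypes
  impossible under the parental pair (i.e. genotyping errors) become NA
  transmissions and, in the EM, structural-zero cells are dropped.
* EM: $r$ is clamped to $[10^{-9}, 0.5]$; phase families are compared by
  log-likelihood; LODs are floored at 0.
* Orders with equal criterion values resolve by run index; orientation by
  lexicographic endpoint comparison.
* A group whose estimate graph is disconnected raises an error naming the
  group; a marker pair with zero shared meioses is skipped (`pair_estimate`
  returns a zero-row tibble).
* Degenerate maps (all lengths 0) report `NA` ratios rather than erroring;
  an empty map errors.
* Every stochastic function takes a seed; `run_pipeline()` derives all stage
  seeds from one master seed and writes byte-identical outputs on re-runs.

# Known limitations

* Two-point distances, not multipoint: with inter-marker spacing below the
  estimator's noise floor (≈ 0.5 cM at n = 156) local order errors and
  noise folding inflate map length — the dense default simulation shows
  this, and it is why absolute cM comparisons against the published maps
  (built with a multipoint likelihood) are out of reach; only
  table-derived statistics are asserted.
* Hard calls only; no genotype likelihoods, no error correction during
  ordering, no crossover interference, no sex-chromosome detection.
* The synthetic arm table supports method validation, not biological
  inference about real salmon arms.
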