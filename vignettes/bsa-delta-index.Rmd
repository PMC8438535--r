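---
title: "Mapping a dominant restorer locus by bulked-segregant delta-index scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant restorer locus by bulked-segregant delta-index scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The problem

Cytoplasmic male sterility (CMS) in crops such as oilseed rape is a
maternally inherited failure of pollen development; a nuclear
*restorer-of-fertility* (*Rf*) gene can suppress it. When a restorer line is
crossed to a CMS line and the F1 is selfed, a single dominant restorer
allele segregates 3 fertile : 1 sterile in the F2. Locating that locus is a
classic mapping problem, and bulked-segregant analysis by sequencing
(BSA-seq, also called QTL-seq) is the standard shortcut: pool DNA from the
phenotypic extremes of the F2, sequence each pool, and look for the genomic
region where the two pools' allele frequencies diverge.

`bsascan` implements that analysis end to end — the per-site index
statistic, its quality filter, the sliding-window scan and the
candidate-interval call — together with the accompanying genetic
statistics (segregation chi-square, recombinant-count map distances) and a
simulator of the whole experiment, so every stage can be exercised and
validated without any sequencing data.

## The statistic

At a biallelic site, a pool's **SNP/InDel index** is the proportion of its
reads carrying the allele that differs from the reference genome:

$$\mathrm{index} = \frac{n_\mathrm{alt}}{n_\mathrm{ref} + n_\mathrm{alt}}.$$

The index is undefined (`NA`) at zero depth; undefined values propagate as
missing and are never treated as 0. The **delta index** is the sterile-pool
index minus the fertile-pool index,
$\Delta = \mathrm{index}_S - \mathrm{index}_F \in [-1, 1]$.

Under a dominant single-gene model with the CMS parent as reference, the
causal site behaves as follows. Sterile F2 plants are homozygous for the
CMS-parent allele, so the sterile-pool index is 0 (up to sequencing
error). Fertile F2 plants are 1/3 homozygous and 2/3 heterozygous for the
restorer allele, so the fertile pool's restorer-allele frequency is
$\tfrac{1}{3}\cdot 1 + \tfrac{2}{3}\cdot\tfrac{1}{2} = \tfrac{2}{3}$, and
$|\Delta| \to 2/3$ at the causal locus while unlinked sites have
$E[\Delta] = 0$. A detection line at $|\Delta| = 0.5$ separates the two
regimes; it is the conventional guide for a locus fully linked in one bulk.

Three processing steps surround the statistic:

* **Quality filter.** Sites with an index below 0.3 *in both pools* are
  discarded (`filter_low_index()`, strict `<`, so a site exactly at 0.3 is
  retained). The both-pools rule matters: at a causal-region site one pool
  sits near 0 and the other near 1, and a per-pool filter would delete the
  signal itself. A stricter per-pool mode is available behind
  `policy = "either"`. Sites with an undefined index in either pool are
  always discarded.
* **Sliding windows.** Per-site indices are noisy at realistic depths, so
  the scan averages them in 1-Mb windows advanced in 100-kb steps
  (`window_scan()`). Windows are anchored at position 1 and only full
  windows are used, except that a chromosome shorter than one window gets a
  single whole-chromosome window; this anchoring is deterministic and
  oracle-checkable. Because every window averages one shared site set, the
  window's mean delta equals the difference of its mean indices exactly —
  the suite asserts this to 12 decimals rather than assuming it.
* **Interval calling.** Runs of consecutive windows (starts one step apart)
  with $|\bar\Delta| \ge 0.5$ are merged into candidate intervals
  (`call_intervals()`), recording the peak $|\bar\Delta|$ and the run
  length. Calls are made on $|\bar\Delta|$, so swapping the pools changes
  only signs, never calls. Since windows are ten steps wide, two runs
  separated by a single sub-threshold window can still overlap physically;
  overlapping qualifying regions are always merged into one interval. A
  `min_windows` run-length requirement and a `max_gap` tolerance exist as
  flags but default to 1 and 0 — no run-length rule is part of the method
  itself.

## Genetic statistics

`segregation_chi_square()` tests observed fertile/sterile counts against
3:1 with Yates' continuity correction by default — the convention for
1-df segregation tests; the corrected deviation $|O - E| - 0.5$ is floored
at 0 so a perfect fit scores exactly 0. The p-value comes from the
$\chi^2_1$ survival function and is reported as computed.

```{r segtest}
segregation_chi_square(1606, 555)
```

Fine mapping counts recombinant plants: a sterile F2 plant carrying any
restorer-parent allele at a linked marker evidences a marker–locus
crossover (`classify_recombinant()`). Each plant contributes two scored
gametes and at fine-mapping distances at most one crossover per gamete is
assumed, so `genetic_distance()` converts $r$ recombinant plants among $N$
plants to $c = r/(2N)$ and $100\,c$ cM. A gamete-level entry point
(`gamete_distance()`) accommodates double recombinants, which the
plant-level count cannot represent. At independence the plant-level
fraction tends to $3/8$ rather than $1/2$ (a plant is "recombinant" if
*either* gamete carries a restorer-parent allele); the estimator is meant
for tightly linked markers, and `estimate_distance_from_simulation()` warns
when the marker is unlinked.

```{r dist}
genetic_distance(4, 3899)
```

## What the simulator emulates

`simulate_bsa_experiment()` generates the data structure the scan assumes:

* **Meiosis.** Each F2 plant is the union of two independent gametes; each
  gamete is a recombinant mosaic of the two parental haplotypes. Crossover
  counts per chromosome are Poisson with mean equal to the genetic length
  in Morgans and positions are uniform on the genetic map — the Haldane
  no-interference model, chosen because it is the standard and makes every
  recombination fraction analytically checkable. Physical and genetic
  scales are tied by a single `cm_per_mb` scalar (default 2 cM/Mb, a
  typical plant average; the experiment being emulated reports none).
* **Phenotype and bulks.** Fertility is determined by the dominant rule
  (genotype ≥ 1 at the causal site), and `make_bulks()` draws disjoint
  random subsets of the required sizes (defaults 37 fertile / 38 sterile)
  from the phenotype classes.
* **Pooled reads.** At each site the pool's allele frequency is computed
  from the bulked genotypes; depth is Poisson (`mean_depth`, optionally per
  pool, default 60 at desk scale) and the ALT read count binomial with a
  symmetric per-read flip probability (`error_rate`, default 0.005). "ALT"
  is the allele differing from the designated reference parent: by default
  the CMS parent plays the reference everywhere, with `"restorer"` and
  per-site `"random"` alternatives to exercise the index definition under
  mosaic references.
* **Sites.** Default 500 sites per chromosome placed uniformly at random,
  classed SNP or InDel in roughly a 1:2 ratio as seen in resequencing of
  diverged Brassica parents; `site_positions` fixes sites explicitly when a
  test needs exact map distances.

The default study conditions are a desk-scale genome of four 20-Mb
chromosomes with the causal locus at 10 Mb of the first, `n_f2 = 300`
(which keeps the sterile class far above the 38-plant bulk), bulks of
37/38, depth 60 and error 0.005. Full-scan validation uses 50 replicates
of this configuration; causal-site checks use 200 replicates at depth 100;
distribution-level properties (bulk allele frequency, recombination
recovery) use up to 10,000 small single-site replicates. These sizes make
the whole suite run in well under a minute while leaving the binomial
sampling bands narrow enough to be informative.

The simulator intentionally does **not** emulate read-level artefacts:
there is no FASTQ simulation, alignment, mapping bias, variant-calling
error, depth overdispersion beyond Poisson, or segmental duplication.
Passing tests therefore validate the statistical machinery of the scan —
index arithmetic, filtering, windowing, interval logic, and their sampling
behaviour under the stated model — not robustness to upstream artefacts in
real resequencing data, whose variant calling is out of scope here.

## Numerical and design choices

* One top-level seed drives a single generator stream, so runs are
  bit-reproducible; every output file header records the seed and an MD5
  hash of the full parameter set.
* The filter threshold comparison is strict (`< 0.3` discarded), matching
  the stated rule; ties at the threshold are retained.
* Degenerate inputs: zero-depth sites give `NA` indices and are discarded
  by the filter; empty windows carry `NA` means and are excluded from
  interval calling; a chromosome with no qualifying windows yields no
  interval, and the report says so explicitly.
* Coordinates are 1-based inclusive internally (VCF convention);
  conversion to 0-based half-open happens only when writing BED.
* Multiallelic VCF records and records missing the AD field in either pool
  are dropped with a reported count — pool-level allele depths at biallelic
  sites are the unit of analysis.
* No confidence envelope is computed for the delta index under the null:
  the method uses the fixed 0.5 guide line. LOESS-style smoothing variants
  are likewise out of scope.

## A worked desk-scale run

```{r run, eval = FALSE}
cfg <- run_config(seed = 11)
res <- run_pipeline(cfg, out_prefix = "demo/run")
res$intervals
format_interval_report(res$intervals)
```

On the default conditions this calls a single interval on the causal
chromosome spanning the true locus, with a peak $|\bar\Delta|$ near the
theoretical 2/3 — smoothed slightly below it by linked flanking sites
inside the 1-Mb window. The run also writes the simulated VCF, a truth
sidecar with the per-bulk allele frequencies, the windows table, the BED
and text interval reports, the segregation test of the simulated
population, and a JSON manifest of parameters and stage-by-stage counts.

## Known limitations

* The plant-level distance estimator assumes no double recombinants within
  a plant; use the gamete-level entry when that assumption fails.
* Window anchoring at position 1 with full windows only is one of several
  defensible conventions; trailing bases shorter than one window on long
  chromosomes are covered by overlapping windows but never form a window
  of their own.
* The simulator's Poisson-depth model understates the depth dispersion of
  real pooled libraries; detection margins on real data will be somewhat
  wider than the simulation bands suggest.
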