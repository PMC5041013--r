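---
title: "Scoring genomic UV photoreactivity from bipyrimidine signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genomic UV photoreactivity from bipyrimidine signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipyrimidine)
```

## The model

UV light damages DNA almost exclusively at adjacent pyrimidines on the same
strand. The four ordered bipyrimidine doublets (5'→3': TT, TC, CT, CC) can
each form cyclobutane pyrimidine dimers and 6-4 photoproducts, but with very
different efficiencies; UV-B photoproduct-yield experiments rank them
TC > TT > CT > CC with intrinsic photoreactivities 1.73, 1.19, 0.61 and
0.39. A genome's *theoretical photoreactivity* is the weighted sum of its
bipyrimidine incidences:

$$P_g = 1.73\,TC_i + 1.19\,TT_i + 0.61\,CT_i + 0.39\,CC_i$$

where each incidence $XY_i$ is the overlapping count of doublet $XY$ divided
by the genome size **in bases** (not in windows; for megabase genomes the
difference is below $10^{-6}$ but the contract is fixed). Because the four
incidences sum to less than one, $0 \le P_g < 1.73$.

The scientific question this quantifies: salt-lake archaea are G+C-rich
(their sampled genomes average 63.1% G+C versus roughly 44–49% for other
prokaryote groups) and unusually UV-resistant. Limiting T limits TT dimers,
but it *increases* C-containing doublets, so whether the composition is
photoprotective overall depends on the full weighted signature — hence
$P_g$ rather than a thymine count.

Under an infinitely long i.i.d. strand-symmetric composition with G+C
fraction $g$ (so $p_T = p_A = (1-g)/2$, $p_C = p_G = g/2$), the expectation
has the closed form implemented by `expected_pg_iid()`:

$$E[P_g] = 1.19\,t^2 + (1.73 + 0.61)\,t c + 0.39\,c^2, \qquad
  t = \tfrac{1-g}{2},\; c = \tfrac{g}{2},$$

which is strictly decreasing in $g$ (derivative $-(0.04 + 1.52g)/4$). This
is the idealized form of the negative $P_g$–G+C relationship seen across
real genomes, and it anchors the simulation tests.

## Counting conventions

`count_dinucleotides()` slides a width-2, step-1 window along the given
strand only, 5'→3'. Design choices a user should know:

* **Single strand by default.** The score takes *directional* incidences
  (TC ≠ CT), and the reference analyses count the deposited strand only. A
  `both_strands` option exists on the scoring layer (it counts the reverse
  complement as extra records), but it is off by default and all bundled
  analyses use the default.
* **Ambiguity masking.** A window containing any non-ACGT character counts
  toward no doublet. Ambiguous bases still count toward genome size
  (assembly "size" includes Ns), while G+C% is computed over unambiguous
  bases only, the usual convention. Recomputed G+C values may therefore
  differ from database values by up to ~0.1% depending on the database's
  denominator.
* **Linear sequences.** No window wraps from the last base to the first,
  although many prokaryote chromosomes are circular; the effect is at most
  one count per record.
* **Record boundaries.** `aggregate_genome()` sums counts across the
  records of a multi-record file (chromosome plus plasmids) and never
  counts a window spanning two records — a junction is not biological
  adjacency. One FASTA file is always treated as one genome.
* **Input normalization.** `read_fasta()` upper-cases residues and maps U
  to T (RNA-alphabet input must not silently lose all T counts); gap
  characters are rejected rather than stripped, because stripping would
  silently change coordinates of aligned input. Gzip is detected from magic
  bytes, not extensions.

The counting engine itself is ~20 lines of vectorized integer coding; its
correctness is established in the tests against two independent oracles (a
naive position-by-position scan and `Biostrings::dinucleotideFrequency`).

## A worked example

```{r example}
row <- score_genome(c(genome = "TTCC"))
row[, c("genome_label", "tc_i", "tt_i", "ct_i", "cc_i", "gc_percent", "pg")]
```

`TTCC` has three windows — TT, TC, CC — over four bases, so three
incidences equal 0.25 and $P_g = (1.73 + 1.19 + 0.39)/4 = 0.8275$.

The in-package dataset `halophilic_archaea` carries the 29-species
halophilic-archaea sample (G+C, genome size, gene count); its G+C column
reproduces the reported group summary:

```{r halo}
summarize_group(halophilic_archaea$gc_percent, "halophilic_archaea")
```

The reported half-width for this group is 1.28; from the published 2-dp
G+C values the recomputation gives 1.2748, a one-unit-in-the-last-digit
discrepancy attributable to the original use of unrounded database values.

## The synthetic-genome generator

Real analyses of this kind score hundreds of multi-megabase assemblies
downloaded from NCBI. The simulator stands in for that corpus so every
stage runs self-contained:

* `simulate_genome()` draws i.i.d. bases (optionally first-order Markov, to
  produce dinucleotide structure an i.i.d. model cannot express, and to
  break the strand-symmetry assumption in tests).
* `simulate_group()` emulates one taxonomic sample group: per-genome G+C
  drawn from a normal truncated to [20, 80] (preventing degenerate
  compositions in the tails), lengths uniform on a range, everything
  reproducible from one seed. Seeds are split per genome, so enlarging a
  group never changes the genomes already generated.
* `reference_group_specs()` encodes the five study groups (non-halophilic
  archaea n=68, bacteria n=101, cyanobacteria n=32, enterobacteriaceae
  n=42, halophilic archaea n=29) at their reported mean G+C. Only
  mean ± 1.96 SE is reported per group, so the per-group SD is back-derived
  as $\mathrm{halfwidth}/1.96 \times \sqrt{n}$.
* `sample_representatives()` implements the bias-reduction step of keeping
  one randomly chosen strain per species (or genus) from a candidate table.

Default genome lengths for the bundled specs are $10^5$–$2\times10^5$
bases rather than the real 2–6 Mb. Incidences are length-normalized, and at
$10^5$ bases their Monte-Carlo noise (SD $\approx 10^{-3}$ on $P_g$) is an
order of magnitude below the intergroup differences being tested, so the
group-level conclusions are insensitive to this choice while runs stay in
the seconds range. What the simulator deliberately does **not** emulate:
codon structure, GC skew, repeats, and phylogenetic correlation between
genomes. Passing tests on synthetic data therefore demonstrate that the
*pipeline* recovers the relationships present in its input model — e.g.
the negative $P_g$ ~ G+C slope — not that real genomes follow an i.i.d.
model; on real genomes $R^2$ is substantially below the synthetic value
(the published figure is 0.714 over 272 genomes) precisely because real
dinucleotide signatures deviate from composition-only expectations.

## The statistical stage

`summarize_group()` reports mean, median (midpoint convention for even n)
and the 1.96·SE half-width with the unbiased (n−1) SD — the error-bar
convention used throughout. `welch_t_test()` is the unequal-variance test
with Satterthwaite degrees of freedom (p = 1 by convention when both groups
are constant and equal). `anova_tukey()` runs fixed-effects one-way ANOVA
with all-pairs Tukey HSD contrasts on the pooled error term. Note the
"post-hoc Tukey contrasts" of the original analysis were max-t tests from a
multivariate-t family (multcomp); Tukey HSD agrees closely for near-balanced
designs but not exactly. The anchor for equivalence is exact: with two
groups the Tukey-adjusted p equals the pooled-variance t-test p, which the
tests assert to $10^{-6}$. `regress_pg_gc()` is OLS of $P_g$ on G+C percent
together with the Pearson correlation test; for simple linear regression
$R^2 = r^2$, enforced internally to $10^{-10}$. All p-values are carried at
full precision; threshold styles like "p < 10⁻⁴" are presentation only.

Calibration is tested by simulation: the Welch type-I error over 2000 null
replicates must land in [0.03, 0.07] at α = 0.05, and a five-group power
simulation at the reported group means/SEs must separate the halophilic
group from every other group at adjusted p < 10⁻⁴ in ≥ 95% of 100 seeds.

## Numerical and degenerate-input choices

* Probability vectors must sum to 1 within $10^{-9}$; G+C targets outside
  (20, 80)% are rejected for group simulation.
* An all-ambiguous genome has undefined G+C and raises an error, as do
  empty records, empty groups, constant-G+C regression input and
  zero-variance correlation input.
* The truncated-normal draw uses simple rejection sampling (the truncation
  region always covers the mean for valid specs, so acceptance is high).
* Group medians with even n use the midpoint of the central order
  statistics.
* TSV outputs print floats at 6 significant digits, '.' decimal, no locale
  formatting; JSON carries scalars at full precision.
* Every pipeline run directory receives a `config.json` with the resolved
  parameters, seed and package version, and contains no timestamps, so
  reruns with the same seed are byte-identical (the manifest stores paths
  relative to itself for the same reason).

## Problem sizes used by the bundled checks

The test-suite and acceptance computations use 200 genomes of $10^5$ bases
for the closed-form/simulation agreement at 63% G+C, a 100-genome sweep
with G+C uniform on [30, 70]% for the regression direction ($R^2 > 0.9$ on
synthetic data), 2000 replicates for Welch calibration and 100 seeds for
the Tukey power check — sizes at which Monte-Carlo error is comfortably
inside the asserted tolerances while a full run stays under a minute.

## Known limitations

* $P_g$ is composition-based: it ignores flanking-sequence effects on
  photoproduct formation, the wavelength dependence of the CPD/6-4PP ratio,
  and repair capacity — it is a propensity score, not a lesion predictor.
* Group comparisons treat genomes as independent; related taxa share
  composition by descent, so a phylogenetically corrected contrast would be
  more conservative.
* The intrinsic photoreactivity coefficients are fixed constants taken from
  UV-B experiments; the package deliberately provides no mechanism to refit
  them.
* Scoring the real *Haloquadratum walsbyi* assembly (the canonical low-G+C
  outlier, reported $P_g$ = 0.260 at 47.9% G+C) requires downloading the
  RefSeq genome; the package ships only the machinery, not the assembly.
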