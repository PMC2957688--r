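---
title: "Quantitative homozygosity mapping: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative homozygosity mapping: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhmap)
```

## The problem

A patient with a rare autosomal recessive disease born to consanguineous
parents usually carries the two disease alleles identical by descent: both
copies come from one ancestral haplotype, transmitted down both sides of
the consanguinity loop. The chromosomal neighbourhood of the locus is then
*autozygous* — homozygous over a contiguous segment (an AS). If the
patient's coefficient of consanguinity is $F$ and the disease-allele
population frequency is $p$, the disease locus is autozygous with
probability

$$P_{AS} = \frac{F}{(1-F)\,p + F},$$

which approaches 1 for inbred patients and rare alleles. Homozygosity
mapping therefore localizes recessive genes by finding genomic regions
autozygous in every affected individual. On dense SNP arrays the
observable proxy of an AS is a *run of homozygous SNPs* (RHS): a stretch
of consecutive calls containing no heterozygote whose genetic length
exceeds a cutoff $c$.

`qhmap` implements that strategy end to end: choose $c$ from closed-form
error-rate curves, remove likely-mistyped heterozygous calls, detect
RHSs, check the reported inbreeding history by Monte Carlo, intersect
RHSs across patients, rank the overlaps with a case-control statistic,
and attach localization probabilities to the result.

## Segment-length model and the cutoff

A subject is $m$ meioses from the common-ancestor couple on the paternal
side of the loop and $n$ on the maternal side ($m = n = 3$ for
first-cousin parents). Under Haldane's interference-free model,
crossovers in each meiosis form a Poisson process of rate $1/100$ per cM,
so an AS is interrupted at total rate $\lambda = (m+n)/100$ and its
genetic length is approximately $\mathrm{Exp}(\lambda)$ — mean
$100/(m+n)$ cM, 16.7 cM for first cousins. The approximation assumes
segments much shorter than the chromosome; the simulator (below) makes no
such assumption.

Three error rates govern the cutoff choice:

* **false negatives** — ASs shorter than $c$, weighted by length:
  $R_{fn} = 1 - e^{-\lambda c}(1 + \lambda c)$ (`false_negative_rate()`);
* **type A false positives** — heterozygote-free gaps longer than $c$
  that contain no AS, with heterozygous SNPs modeled as a Poisson process
  of rate $\lambda_{het} = N_{het}/L_{autosome}$:
  $R_{A} = (1 + \lambda_{het} c)\,e^{-\lambda_{het} c}$
  (`type_a_false_positive_rate()`);
* **type B false positives** — the overhang of an RHS beyond the AS it
  contains, on average half an inter-heterozygote spacing at each end,
  giving $R_{B} = N_{RHS}/N_{het}$ (`type_b_false_positive_rate()`).
  Every RHS is assumed to contain an AS, so $R_B$ deliberately
  overestimates — preferable to an underestimate when choosing $c$.

`cutoff_table()` evaluates all curves on a grid (default 0–3 cM in steps
of 0.01). The package default is $c = 0.6$ cM, at which the
false-negative rate for a first-cousin offspring is about $6\times
10^{-4}$; the default prioritizes a low false-positive rate, which keeps
the downstream overlap analysis small. It is a convention, not a
re-derived optimum, and every entry point accepts another value.

## Genotyping-error correction

A single mistyped heterozygote splits a long RHS in two. Since
inter-heterozygote gaps are approximately $\mathrm{Exp}(\lambda_{het})$,
the distance $d = x + y$ from the previous to the next heterozygous SNP
around a genuine heterozygote is Erlang-2, with survival probability
$(1 + \lambda_{het} d)\,e^{-\lambda_{het} d}$. `correct_calls()` scores
every heterozygous call this way (chromosome ends serve as flanking
points for the outermost calls) and sets calls with $P < 0.01$ to
no-call — removal, not flipping, because the true homozygous allele is
not knowable from the calls alone.

Two design points deserve emphasis:

* **Distances are measured once, in the observed data, and all
  qualifying calls are removed simultaneously.** Re-measuring distances
  among survivors and iterating is tempting (clustered mistypes can
  shield one another) but diverges: a removed call's flanking distance
  accrues wholesale to its neighbour, whose new distance is strictly
  larger and therefore also below threshold, and the cascade consumes
  every heterozygote on the chromosome. Under observed-data distances a
  re-scan changes nothing, so the single pass is its own fixed point.
  The shielding configuration that survives this choice requires three
  mistypes within a normal inter-heterozygote spacing, which at an array
  error rate of 0.003 is vanishingly rare.
* **The threshold equals the expected false-removal fraction.** Because
  the score is the exact survival function of the null spacing
  distribution, about 1% of genuine heterozygotes are removed at the
  0.01 default. These sit next to genuinely long gaps, so the damage is
  a slight outward extension of RHS bounds, already accounted for by the
  type B term.

`inject_errors()` corrupts `floor(N_{called} × rate)` calls (uniformly
chosen, each flipped to one of the other two genotypes at random) so the
correction can be validated against known truth; at the array scale of
701,753 called SNPs and rate 0.003 that is 2,105 altered calls. On 100
synthetic first-cousin genomes corrupted at that rate, the
corrupt–correct–detect pipeline in the acceptance suite restores more
than 99% of the total true-AS length, and effectively all of the length
of ASs longer than 2 cM.

## RHS detection and the consanguinity estimate

`detect_rhs()` takes maximal heterozygote-free stretches with at least
`min_snps` homozygous SNPs (default 1) and keeps those whose genetic
length strictly exceeds $c$. Genetic bounds extend to the flanking
heterozygous SNPs (or the chromosome map ends) — matching the type B
accounting of end overhangs — while physical bounds are the outermost
homozygous SNPs, reported as 0-based half-open BED intervals. No-calls
neither break nor extend runs and are excluded from all counts.

The coefficient of consanguinity is estimated as
$\hat F = \text{total RHS length} / L_{autosome}$ (`estimate_f()`);
for first-cousin offspring it should be near $1/16$. The longest RHS
indexes the recency of inbreeding and feeds the history check.

## Monte Carlo validation of the inbreeding history

`longest_as_distribution()` simulates descents through the loop until
`n_events` (default 100,000) events with at least one AS have occurred.
The loop is modeled with a common-ancestor *couple* — four founder
haplotypes — which is what makes the locus-wise autozygosity probability
$4 \cdot (1/2)^{m+n}$, i.e. $1/16$ at $m=n=3$; a single shared ancestor
would halve it. Each transmitted homolog is a founder-origin mosaic
built from independent two-state crossover-phase processes (one per
meiosis on the path), and ASs are the intervals where the paternal and
maternal homologs carry the same founder haplotype. This composition
reproduces the $\mathrm{Exp}((m+n)/100)$ law for interior segments
exactly, while naturally handling finite chromosome ends. The kernel is
compiled (Rcpp) and uses R's RNG, so runs are reproducible from
`set.seed()`; 100,000 events over the full autosome set take seconds.

Chromosome genetic lengths default to a bundled sex-averaged table of
the 22 autosomes (3,548 cM total, deCODE-style reference values); any
reference map can be supplied instead (`reference_map()`,
`interpolate_cm()` — piecewise linear, exact at anchors, linearly
extended and floored at 0 beyond the outermost anchors).

`history_consistency()` compares an observed longest RHS to the central
$1-2\alpha$ range of the simulated distribution (default
$\alpha = 0.025$, the central 95% range; the 2.5% quantile for
first cousins is about 20.9 cM). The 95% range is interpreted as
central, so both "too short" and "too long" verdicts are possible;
$\alpha$ is exposed for users preferring a one-sided 5% rule.

## Overlap and case-control prioritization

`intersect_regions()` intersects the per-patient RHS sets in genetic
coordinates. Some genomic regions are prone to false or uninteresting
sharing (SNP spacing, haplotype blocks, population substructure), so
overlaps are ranked by a case-control statistic: at each SNP,
`sharing_counts()` counts covering RHSs among $n_1$ patients and $n_2$
controls, and `u_statistic()` computes the two-proportion z statistic
with +0.5 continuity corrections and a one-sided upper-tail normal P
value. The variance uses the standard $(1/n_1 + 1/n_2)$; an
`n1_only_variance` flag reproduces the $(1/n_1 + 1/n_1)$ form found in
some implementations. No multiple-testing correction is applied —
the $-\log_{10} P$ values rank regions rather than test a global null.
`rank_overlaps()` annotates each overlap with its maximum
$-\log_{10} P$, breaking ties by genetic length, then position.

Localization probabilities compose as
$P_{\text{GeneIsInRHS}} = (1 - R_{fn}) \cdot P_{AS}$ per patient
(with $\hat F$ from the data) and
$P_{\text{GeneIsInOverlap}} = \prod_{\text{patients}}
P_{\text{GeneIsInRHS}}$. The disease-allele frequency $p$ is
disease-specific and always supplied by the user.

## The synthetic-data generator

`synth_config()` describes a compact genome whose defaults were chosen
once to mirror the statistical regime of a high-density array at desk
scale: 4 chromosomes of 100 cM with 5,000 markers each (0.02 cM mean
spacing — dense enough that $\lambda_{het} \approx 18$ per cM keeps
type A false positives negligible at the default cutoff, as on a real
array), major-allele frequencies Uniform(0.5, 0.95) (mean heterozygosity
0.365), a first-cousin pedigree, genotyping error rate 0.003 (the
array's maximum claimed error rate) and a 1% no-call rate. Physical
positions use a 1 cM = 1 Mb toy scale. Array scale (hundreds of
thousands of SNPs over the full 22 autosomes) is a configuration, not
the default.

Founders are in linkage equilibrium: no LD, haplotype blocks or
population substructure are modeled. Consequently synthetic outbred
controls carry almost no RHSs, and synthetic false-positive rates
undershoot real data — passing tests demonstrate the machinery and its
calibration, not the field behaviour of real control panels. One visible
consequence: in the planted-locus benchmark (`make_benchmark()`, which
rejection-samples cases until autozygous at the locus and pairs them
with outbred controls), all-case overlaps saturate the sharing statistic
($x_1 = n_1$, $x_2 = 0$), and when conditioning produces an adjacent
coincidental all-case overlap the length tie-break occasionally ranks it
first; with real controls the statistic discriminates.

## Numerical and interface conventions

* Physical coordinates: 1-based in call tables, 0-based half-open in BED
  output; genetic coordinates always cM from pter, half-open for
  coverage tests.
* Only autosomes 1–22 are processed; other rows are dropped with a
  logged count.
* Correction and detection are deterministic; all stochastic components
  (simulator, generator, error injection) take explicit seeds and are
  bit-reproducible under them.
* Problem sizes in the validation suite — 100 restoration replicates,
  100 planted-locus benchmarks, 20,000 simulation events for quantile
  checks, 800 pooled segments for the distributional test — were chosen
  as the smallest sizes at which Monte Carlo error is comfortably below
  the effect sizes being checked.
* Degenerate inputs: tracks without heterozygotes pass through
  correction unchanged; empty tracks yield empty segment sets; ties in
  the ranking are broken deterministically.

## Known limitations

* No LD simulation — see above; type B inflation from haplotype blocks
  is acknowledged but un-modeled.
* The Erlang-2 spacing score treats chromosome ends as heterozygous
  flanks, slightly conservative for the outermost calls.
* Interference-free crossovers only; no sex-specific maps; no X
  chromosome.
* `m = n = 1` (both parents the ancestor couple's children of the same
  couple... i.e. the degenerate incest loop) is supported mechanically,
  but pedigree interpretation is the user's responsibility; the couple
  model requires at least one side with $m \ge 2$ for autozygosity to
  arise.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
cfg <- synth_config()
bench <- make_benchmark(cfg, n_cases = 5, n_controls = 20)
res <- run_pipeline(bench$cases, bench$controls, p_allele = 0.001,
                    chrom_lengths_cm = cfg$chrom_lengths_cm,
                    check_history = TRUE, history_events = 2000)
res$summary
head(res$ranked_overlaps)
bench$planted
```

The summary reports, per case, the RHS count, total and longest RHS
length, $\hat F$, the history verdict and $P_{\text{GeneIsInRHS}}$; the
top-ranked overlap should contain the planted locus.
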