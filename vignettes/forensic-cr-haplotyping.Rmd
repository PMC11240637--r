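---
title: "Forensic mtDNA control-region haplotyping: models, estimators and design"
author: "crhaplo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic mtDNA control-region haplotyping: models, estimators and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crhaplo)
```

## The problem

When poached game or processed animal material must be linked to a suspect
or a source population, nuclear profiling is often impossible: the material
is degraded, minute, or mixed. Mitochondrial DNA survives such conditions
far better, and its non-coding control region (D-loop) concentrates most of
the intraspecific variation. A control-region **haplotype** — the
combination of bases an animal carries at the region's variable sites — is
matrilineally inherited as a unit, so a database of haplotype frequencies
in the relevant population turns a sequence match into a quantifiable piece
of evidence.

`crhaplo` implements this workflow for amplicon-style control-region
surveys, with the Hungarian fallow deer (*Dama dama*) population as its
motivating case: a species with strong founder effects in its introduced
herds, hence very few mitotypes per country, hence high match
probabilities — exactly the regime in which careless reporting overstates
evidence.

## Sequence model and haplotype collapsing

Coordinates are 1-based inclusive mitogenome positions throughout (the
GenBank convention), and primer names encode the 5' base position, so the
amplicon spanned by F15,386/R16,330 is the inclusive interval
[15386, 16330]: L = 945 bp.

Placement of a sample on the reference window is colinear and gap-free: a
sliding-offset search minimising mismatches over the sample's unambiguous
bases. This is deliberate. In the surveyed populations every polymorphic
position is a substitution; an alignment that can open gaps would silently
reinterpret a damaged read. A sequence that needs an internal gap is
therefore a hard, named error — forensic traceability is preferred to
permissiveness. A placement whose best mismatch fraction exceeds 10%
(configurable) is rejected as unmappable rather than force-fitted.

IUPAC ambiguity codes and `N` are missing data: they contribute no
segregating-site evidence, no match discrepancies, and they block haplotype
*assignment* (though not *constraint*) when they fall on a variable site.
A sample covering every registered variable site unambiguously maps to
exactly one registered haplotype, or — with `allow_new = TRUE` — registers
the next sequential name (`Hun7`, `Hun8`, ...). Discovery order for
simultaneous novelties is sorted sample-id order, making the partition
independent of input order. Partial sequences instead receive a
**consistency set**: every registered haplotype agreeing with them at each
covered position. A set, not a name, because a degraded fragment that
"matches Hun2" may equally match Hun1 if the discriminating site is
missing — reporting the set keeps the downstream match probability honest
(the summed frequency of the set is an upper bound).

## Estimators

With haplotype counts $c_i$, $n = \sum_i c_i$, frequencies $p_i = c_i/n$:

* **Random match probability** $\mathrm{RMP} = \sum_i p_i^2$ — the
  probability that two randomly drawn, unrelated individuals share a
  haplotype; the forensic weight of a control-region match.
* **Haplotype diversity** $H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$
  (unbiased form; the plain form omits the factor).
* **Nucleotide diversity**
  $\pi = \frac{n}{n-1}\cdot\frac{\sum_{i<j} 2 p_i p_j d_{ij}}{L}$ per site,
  where $d_{ij}$ is the number of sites at which haplotypes $i$ and $j$
  differ and $L$ the evaluated alignment length.

The unbiased corrections are the default because they are what standard
polymorphism software reports and what regional survey tables are built
from: with NW's $n = 34$ and $\sum p_i^2 = 0.585$, only the corrected form
reproduces the tabulated $H_d = 0.428$. The default $L = 450$ bp likewise
follows from the combined analysis that this package's fixtures model: all
variable sites fall inside the 450-bp control-region section surveyed
earlier, and the tabulated NW $\pi = 0.00095$ decomposes as
$0.42781/L \Rightarrow L = 450$. Both are plain arguments for other
datasets.

Two aggregation conventions exist for a country-wide RMP and they are *not*
equivalent: the unweighted mean of regional RMPs (0.547 for the fallow deer
table) and the pooled $\sum p_i^2$ of the summed counts (0.438). The
headline follows the mean-of-regions convention, matching how such surveys
report the figure; the pooled variant is always computed alongside
(`attr(stats_table(...), "rmp_overall_pooled")`) because pooled counts are
what reproduce the overall $H_d$ — the asymmetry is a property of the
reported tables, and the package surfaces it instead of hiding it. Display
rounding is half-up to 3 decimals (5 for $\pi$), with full precision
retained everywhere internally; rounding never feeds computation.

`check_hd_rmp()` audits a printed (n, Hd, RMP) row for internal
consistency, allowing each printed entry half a unit of rounding error
(the RMP's half-unit propagated through $n/(n-1)$). On the fallow deer
table it flags the SW row (printed Hd 0.611 implies $\sum p_i^2 \approx
0.405$, but RMP prints 0.617); the package reproduces each printed number
from its own printed inputs and does not guess which entry is wrong. The NM
row is a milder case: its printed RMP (0.484) implies Hd 0.5285, which
rounds to 0.528 against a printed 0.529 — one unit in the last digit, within
the audit band.

## Differentiation

* **Fst** is the Hudson–Slatkin–Maddison sequence estimator
  $F_{st} = 1 - H_w/H_b$: $H_w$ is the unweighted mean of the two
  within-population mean pairwise difference counts (over distinct
  individual pairs), $H_b$ the mean difference count over all
  between-population pairs; $H_b = 0$ is defined as 0. The choice is an
  assumption, documented as such: survey papers in this area name only the
  software they used, and this is that software's conventional
  sequence-data estimator. A finite-sample property worth knowing: for
  identical or near-identical polymorphic compositions the estimator is
  slightly *negative* (distinct-pair $H_w$ exceeds $H_b$), which is why
  published matrices show entries like −0.022 for undifferentiated pairs.
  Negative values are reported as computed, never clamped — they read as
  "effectively zero".
* **Gst** is Nei's frequency-based analogue $(H_t - H_s)/H_t$. The
  corrected form (default) uses the Nei–Chesser small-sample estimators in
  their haploid form — $\tilde H_s = \frac{\tilde n}{\tilde n - 1} H_s$,
  $\tilde H_t = H_t + \tilde H_s/(\tilde n s)$ with $\tilde n$ the harmonic
  mean sample size and $s$ the number of populations — honouring the
  requirement that the statistic "consider the population sizes". Both
  forms are available.
* **Significance** is by permutation: individual labels are shuffled across
  the pooled pair and the statistic recomputed; the add-one estimator
  $p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$ avoids reporting $p = 0$.
  Default 10,000 permutations; seeded and reproducible. No multiple-testing
  adjustment is applied across the 15 pairs by default, matching standard
  reporting practice for such matrices; the annotation layer instead flags
  pairs at the conventional $F_{st} \ge 0.15$ threshold for a significant
  genetic difference between subpopulations.

Reproducing the *specific published* Fst/Gst matrix numerically is out of
scope by design: those values depend on the true per-region compositions
and the true inter-haplotype difference matrix, which published summary
tables under-determine. The package's correctness claim for this module is
instead equivalence with an exhaustive-pair enumeration oracle on small
instances, exactness at the boundary cases, and invariance properties —
all property-tested.

## Forensic match evaluation

`compare_sequences()` implements the conservative convention for mtDNA
casework: **two or more** nucleotide discrepancies between evidence and
reference are required for an exclusion; exactly one is inconclusive
(a possible heteroplasmy or sequencing artefact); zero is a match.
Discrepancies are counted only over jointly covered, unambiguous
positions, the compared-position count is always reported so that a
zero-overlap comparison cannot masquerade as a match (it is a distinct
error), and the verdict is symmetric in its arguments.

A match's weight is the matched haplotype's frequency — per region and
overall, since the package cannot know which population the evidence donor
belongs to; the caller chooses. Because under-sampling *over*estimates rare
haplotype frequencies, the plain sample frequency is already a
conservative-leaning headline; the add-one estimator $(x+1)/(n+1)$ and an
optional one-sided 95% Clopper–Pearson upper bound are reported alongside
for unseen or rare haplotypes.

## The synthetic-data generator

No per-sample genotypes are published for the motivating survey — only
summary statistics, global haplotype counts and presence constraints. The
generator therefore reconstructs compositions rather than simulating
evolution:

* `derive_counts_from_stats(n, k, rmp)` exhaustively enumerates the integer
  compositions of $n$ into $k$ positive parts and returns those whose
  $\sum p_i^2$ matches the target within tolerance — with the residual
  reported, never hidden. For the regional table rows this inversion is
  unique at tolerance $5\times10^{-4}$: NW {24,10}, NM {23,18,1},
  NE {23,17,1}, SM {25,5,1}, SE {4,2,1}.
* The SW row, being internally inconsistent, cannot satisfy both its
  printed entries; the fixture fixes SW to {19,13,5}, the composition
  reproducing its printed $H_d = 0.611$.
* Three fixture variants exist because the published per-region
  compositions and the published global counts are jointly infeasible at
  printed precision (the forced southern compositions carry 14
  non-Hun1/Hun2 animals against 16 globally): `"regional"` realises each
  region's statistics individually; `"global_192"` realises the global
  counts {66,108,1,1,9,7} exactly while keeping region sizes;
  `"new_collection_138"` is the newly collected subset (138 animals, four
  haplotypes). Tests target each variant separately.
* Haplotype-to-count assignment within a region follows the documented
  presence constraints (Hun3 a NE singleton, Hun4 a NM singleton,
  Hun5/Hun6 southern only); the six variable sites sit inside the 450-bp
  sub-window, and the inter-haplotype difference matrix (Hun2 one step off
  the reference haplotype Hun1, etc.) is a documented constant of the
  fixture chosen to reproduce the per-region segregating-site counts
  (NW 1, NM 2, NE 2, SW 3, SM 2, SE 4; 6 overall). It is **not** a claim
  about the real sequences, whose states were never published.

Sampling is exact — counts, not multinomial draws — so every statistics
test is non-stochastic; the seed affects only the synthetic reference
bases and the order in which haplotypes are dealt to sample ids. This is a
deliberate trade: parameter-recovery tests can demand *zero* error, at the
price that the fixtures exercise no sampling noise. What passing tests
show is therefore that the estimators and the pipeline are correct on data
of exactly the published structure; they say nothing about robustness to
alignment error, heteroplasmy, contamination or sequencing noise, none of
which the generator emulates. `fragment_samples()` adds the one degradation
mode the forensic use case demands — partial contiguous coverage — which
exercises the consistency-set machinery.

## Numerical and degenerate-input choices

* Ties in placement go to the smallest offset; a fully ambiguous sequence
  places at offset 0 with zero compared positions reported.
* $H_d$ and $\pi$ are undefined (NA) for single-individual regions; RMP is
  still reported (trivially 1 for one individual).
* $H_b = 0$ defines Fst as 0; $H_t = 0$ defines Gst as 0 with a warning.
* Permutation p-values use the add-one estimator, so the attainable minimum
  is $1/(1+n_{perm})$.
* Display rounding is half-up (survey-table convention), not banker's.

## Problem sizes

The shipped fixtures are the survey's own sizes (192 / 138 samples, 945-bp
window, six haplotypes); the full test suite, including the
exhaustive-oracle property tests (populations of total size ≤ 12, 3
haplotypes) and pipeline runs with reduced permutation counts, completes in
well under a minute. The pipeline default of 10,000 permutations is meant
for real runs; tests and examples use 99–499 because permutation p-values
enter them only through determinism and calibration checks.

## Worked example

```{r example, eval = FALSE}
fx <- fallow_deer_fixture("regional", seed = 1)
pos <- map_sequences(fx$sequences, fx$reference)
asn <- assign_haplotypes(pos, fx$registry, fx$reference)
st <- stats_table(pos, asn$assignments, fx$metadata, asn$registry, L = 450)
st
attr(st, "rmp_overall_pooled")

tab <- haplotype_frequencies(asn$assignments, fx$metadata)
dm <- differentiation_matrix(tab, registry_diff_matrix(asn$registry),
                             n_perm = 999, seed = 1)
dm
```

## Known limitations

* No chromatogram or quality-score handling; input is called bases.
* No indel support, by contract; datasets with control-region indels need a
  different placement model.
* No likelihood-ratio framework: match weight is frequency-based RMP, which
  is the reporting convention for mtDNA (a lineage marker, not an
  individual identifier).
* The generator reconstructs composition, not evolution: no coalescent
  structure, no mutation model, no within-region geography.
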