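---
title: "Context-dependent mutation rates from mutation accumulation data"
author: "contextmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent mutation rates from mutation accumulation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextmut)
```

## The model

Spontaneous mutation rates are not uniform along a chromosome: the
identity of the bases immediately 5' and 3' of a site can change its
substitution rate by orders of magnitude, and bacterial chromosomes
additionally show systematic asymmetry between the two replichores (the
arcs replicated by the two forks that leave the replication origin).
`contextmut` estimates these context-dependent rates from mutation
accumulation (MA) experiments, in which `N` bottlenecked lineages evolve
for `G` generations each so that essentially all non-lethal mutations
fix regardless of fitness effect.

For each trinucleotide context the chromosome-wide rate is

    u_bs(t) = M(t) / ( GWTC(t) * G * N )

where `M(t)` is the number of observed mutations whose center base sits
in context `t = (5' base, ref, 3' base)` and `GWTC(t)` is the
genome-wide occurrence count of `t` — the number of mutable sites in
that context. Replichore-specific rates use the replichore-wide counts
(RWTC) of the same contexts. The canonical store is the 192-class
resolution (4 upstream x 4 reference x 3 alternate x 4 downstream); the
64-triplet view is an aggregation over the three alternate bases, and
the "conditional" rate renormalises each triplet's mutation count to the
genome-wide content of its center nucleotide instead of the full
triplet.

## Replication landmarks and strand orientation

The origin (ORI) and terminus (TER) are either supplied by the user —
an ORI of `0` is accepted and normalised to position 1 — or detected
from cumulative GC skew. Each counted site contributes `+1` for G, `-1`
for C and `0` otherwise; under the G-rich-leading-strand convention the
running sum attains its minimum at the origin and its maximum at the
terminus. Detection can restrict the counted sites to third codon
positions of complete CDS features (minus-strand CDS contribute the
complement base), which suppresses the protein-coding signal that
contaminates all-site skew in gene-dense genomes.

Two numerical details matter here:

* **Detrending.** On a circular genome the raw cumulative sum depends
  on where the deposited sequence starts; when the ORI→TER arc wraps
  across the sequence end and the total G−C balance is near zero, the
  start phase can out-compete the true extremum. `detect_ori_ter`
  therefore subtracts the linear first-to-last trend before locating
  the extrema on circular genomes, making the result equivariant under
  rotation of the sequence.
* **Ties** at equal extrema are broken toward the smallest coordinate,
  so detection is deterministic.

The convention assigning ORI to the minimum is a configuration switch
(`invert`) because the sign convention varies across the literature;
genomes with inverted skew polarity simply flip it.

The **right replichore** is the half-open arc from the ORI toward
increasing coordinates up to, but excluding, the TER (wrapping on
circular genomes); the left replichore is the complement. The ORI
belongs to the right arc and the TER to the left, so every position has
exactly one replichore. Reading the reference strand 5'→3', the left
replichore is then the leading-strand template and the right replichore
the lagging-strand template; under the default
`lagging_template_revcomp` convention the triplet, reference and
alternate base of right-replichore variants are replaced by their
reverse complements so both replichores are read in their synthesis
orientation, and the right-replichore rate denominators are taken from
the complement-strand context counts for consistency. The
`as_reference` convention disables the transformation.

## Context counting

Context tables are built by a sliding window of width `k` (3 by
default; 4 and 5 are available for the extended neighbourhood of a
variant, whose two bases on each side are always recorded). Windows are
keyed by the coordinate of their center base (odd `k`) or the base left
of center (even `k`), and a window belongs to a replichore exactly when
its key coordinate does — rates are per mutable site, so the mutable
base decides membership. Circular genomes wrap windows across the
junction, so a chromosome of length `L` contributes exactly `L`
windows and the two replichore tables sum to the chromosome table key
by key; linear genomes contribute `L - k + 1`. Windows containing `N`
are counted separately as skipped, never silently dropped, and variants
whose immediate context contains `N` (or which sit at the ends of a
linear genome) are excluded with a logged reason.

## Input handling

Variants are accepted as standard VCF 4.x (only single-nucleotide
substitution records are retained; multi-allelic ALT fields are split
into one candidate per allele) or as a minimal base-call CSV with
columns `position,ref,alt`, the header detected by a non-numeric first
field. Every candidate is checked against the reference genome;
records whose ref/alt are not single `A/C/G/T` bases, whose ref equals
alt, whose position is out of range, or whose ref mismatches the genome
go to an exclusion log with a reason rather than aborting the run — MA
datasets frequently carry strain/reference offsets, and the retained
plus excluded records always account for every candidate. GenBank
annotation is parsed from the flat file's FEATURES table with
`join()`/`complement()` locations resolved and partial (`<`/`>`, or
length not divisible by 3) CDS flagged and excluded from codon-resolved
analyses.

## Tunable parameters

* `generations` (`G`, generations elapsed per lineage) and `lineages`
  (`N`): the MA design parameters; both scale the denominator of every
  rate. Non-MA data can use a molecular-clock estimate for `G`.
  One uniform `G` per run is assumed.
* `scaling_mode`: display scaling only — `default_1e-8` divides rates
  by 1e-8 (a rate of 3e-8 displays as 3.0), `mean_scaled` divides by
  the mean of non-missing rates, `custom` by a user factor. Unscaled
  rates are always retained in the CSVs, and cross-organism
  correlations are computed on unscaled rates, so scaling can never
  change rank order or correlation structure.
* `n_bins` (25/50/75): spatial bins anchored at the ORI. Bin index is
  `floor(offset * n_bins / L) + 1` on the 0-based ORI-relative offset,
  so bin 1 starts exactly at the origin and a terminus at `L/2` of 25
  bins falls in bin 13; boundaries tile `[0, L)` with widths differing
  by at most one base.
* `convention`: strand orientation as above.

## Missing versus zero

A context class with a positive denominator and no observed mutations
has a true zero rate; a class whose triplet never occurs in the region
has a missing rate (`NA`), because nothing could have been observed.
Observed mutations with a zero denominator indicate a convention
mismatch between counts and variants and are flagged inconsistent with
a warning rather than silently absorbed. Cross-organism Pearson
correlations drop entries missing in either vector (pairwise-complete)
and report a missing coefficient below three complete pairs or for
constant vectors.

## The synthetic study generator

Every analysis step is testable without downloads because the fixture
module generates all three inputs with exact bookkeeping:

* **Genomes** are i.i.d. at a requested GC content. A planted-skew mode
  enriches the ORI→TER arc for G over C (and the complementary arc for
  C over G) and anchors the four boundary bases (`…C|G…` at the origin,
  `…G|C…` at the terminus) so the planted switch points are exact
  profile extrema. At maximal skew strength each arc is pure-G or
  pure-C among its strong bases, which suppresses G+C-mixed triplets —
  so skewed genomes are used for origin-detection checks and i.i.d.
  genomes (with a manual ORI/TER, the same route as a user-supplied
  origin) for rate recovery.
* **Annotations** are non-overlapping CDS with lengths divisible by 3
  on random strands, written as a GenBank flat file that the parser
  round-trips; planted codon tallies are recorded independently.
* **Mutations** are drawn per `(context, alt)` pair as
  `Poisson(occurrences * G * N * u_true)` (or deterministically in
  exact mode), placed uniformly without replacement among matching
  sites, and emitted as both VCF and base-call files. The exact planted
  counts are stored, so recovery can be asserted exactly, not just in
  expectation. Default test magnitudes (`u_true` around 1e-6 per site
  per generation, `G = 5077`, `N = 50`) mirror a mismatch-repair
  deficient MA design, keeping planted counts informative on
  kilobase-scale fixtures.

Randomness uses one named substream per generator stage (a
deterministic seed derived from the user seed and the stage name), so
adding a stage never perturbs earlier draws and any output is
reproducible from the seed alone.

What passing tests on these fixtures do **not** show: real genomes have
gene-dense, codon-biased, repeat-laden sequence whose skew is noisier
than the planted two-arc structure; real MA variant calls carry
alignment and calling artefacts that the generator does not emulate
(only their bookkeeping consequences — exclusions — are modelled); and
hotspot clustering beyond the context rate map, indels, and selection
are out of the generator's scope.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run on genomes of 1–10 kb
with 20–50 replicate seeds per property; these sizes already make every
structural check exact (conservation, keyspace, recovery of planted
counts) while keeping the whole suite in the tens of seconds. The
pipeline itself is linear in genome length and has been exercised at
megabase scale; per-position window extraction is the dominant cost.

## Known limitations

* Single chromosome per run; plasmids/chromids need separate runs.
* No confidence intervals on rates — point estimates only, matching
  the MA-analysis tradition the package follows.
* The skew detector models a single origin; multi-replicon archaeal or
  eukaryotic chromosomes need a manually supplied ORI/TER.
* The GenBank parser targets the common flat-file subset (simple,
  `complement`, `join`, partial markers); remote or cross-accession
  locations are ignored.

## A minimal run

```{r example, eval = FALSE}
st <- generate_study(tempfile("fx"), length = 10000, gc_fraction = 0.44,
                     n_cds = 12,
                     u_true = list(ACG = c(T = 2e-6),
                                   TCT = c(A = 1e-6, G = 5e-7)),
                     G = 5077, N = 50, seed = 1)
cfg <- soa_config(st$fasta, st$genbank, st$vcf, dialect = "vcf",
                  generations = 5077, lineages = 50, scaling = "0",
                  ori = 1, ter = 5001, out = tempfile("out"),
                  run_id = "demo")
run <- run_soa(cfg)
subset(run$rates$genome, M > 0)
```
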