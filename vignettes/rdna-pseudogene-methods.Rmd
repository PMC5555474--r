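---
title: "Methods: mining, classifying and profiling RIP-derived rDNA pseudogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, classifying and profiling RIP-derived rDNA pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnarip)
```

# The model

A fungal genome carries its 45S rDNA unit
(18S–ITS1–5.8S–ITS2–28S–IGS) in many near-identical tandem copies.
Repeat-induced point mutation (RIP) recognizes such duplications during
sexual reproduction and converts C to T on one strand and, equivalently,
G to A on the other, with a strong dinucleotide-context bias: a C is most
vulnerable when followed by A (and the mirrored G when preceded by T).
A copy that escapes the homogenizing machinery of concerted evolution and
accumulates these transitions becomes a pseudogene with three diagnostic
signatures:

1. **Lowered GC.** Every RIP hit converts a G:C pair into A:T, so GC
   content falls roughly in proportion to the per-site RIP rate. Within
   one genome, subunit GC values split into two non-overlapping bands —
   a functional band (around 46–53%) and a pseudogenic band below it.
2. **A one-sided substitution spectrum.** Against the most-intact
   (highest-GC) copy, nearly all differences are C→T and G→A; every
   other substitution class stays at error-like frequency (below 0.1%).
3. **Phylogenetic misbehavior.** Because all pseudogenized copies lose
   C/G at the same eligible sites, they share derived states and cluster
   together: neighbor-joining trees of a subunit separate copies by gene
   type rather than species, with the functional/pseudogene split
   carried by a long internal edge.

The package operationalizes each signature and validates the whole chain
on a simulator whose truth table records every planted mutation.

# The analysis chain and its assumptions

## Mining (`iterative_search`, `annotate_subunits`, `excise_introns`)

Repeats are found by query expansion: the reference unit seeds a search,
every recovered repeat becomes a query for the next round, and rounds
repeat until no new interval is added (`max_rounds` 10 guards
non-termination). This mirrors iterated homology searching and is what
lets heavily decayed copies — below the identity floor relative to the
functional seed — be reached through intermediate copies.

The engine is self-contained: exact `k = 12`-mer seeds sampled every
`stride = 8` bp of the query, seed clusters (gap > 2 kb splits clusters)
padded by 15% of the query length, then Smith–Waterman–Gotoh alignment
(match +1, mismatch −1, gap open −5, extend −1) of query versus candidate
region. A hit needs identity ≥ `min_identity` (default 0.70) over a span
≥ `min_hit_length` (default 200 bp). The floor of 0.70 deliberately sits
well below the ~80% identity at which RIP stops recognizing duplicates,
so copies decayed by ~20% are still caught directly, with query expansion
covering anything deeper. Hits within 100 bp on one contig and strand are
merged, because a decayed repeat can fragment into several local hits.
Identity is computed over all alignment columns (gaps count in the
denominator, ambiguity codes are excluded entirely).

Subunit boundaries come from local alignment of each reference subunit
against the strand-normalized hit. A subunit is *present* at coverage
≥ 0.9 for the coding subunits and ≥ 0.5 for spacers, whose edges erode
faster; a repeat is *complete* when all six subunits are present with
full coding coverage. Insertions relative to the reference that span at
least `min_insert = 50` alignment columns are excised as introns — 50 bp
separates genuine spliceosomal-intron-scale insertions from ordinary
alignment gaps, which rarely exceed a few bases here. Shorter runs are
left untouched.

Coordinates are 1-based inclusive throughout, the native convention of
R and its genomic-interval packages, and emitted TSVs use the same
convention with strand in {+,−}.

## Classification (`split_gc_groups`, `mutation_spectrum`, `call_pseudogene`)

GC groups are split at the largest gap in the sorted per-subunit GC
values; a gap below `min_gap` (2 percentage points) means no bimodality
and everything stays functional-side. The rule assumes the bands are
densely populated relative to the gap between them — true for genomes
with many paralogs, and the no-bimodality guard covers the rest.

The reference for spectra is the single highest-GC sequence (ties broken
by smallest identifier, for determinism). Spectra count the 12 directed
substitution classes per alignment column; columns with a gap on either
side are indel columns and excluded from the `aligned_sites`
denominator. All rates in the package — G→A, C→T, "other", and the RIP
rate — share that denominator, which is what makes
`rip_rate == gA_rate + cT_rate` an exact identity rather than an
approximation.

A low-GC copy is called a **pseudogene** when it shows at least one RIP
transition and its non-RIP substitutions are *consistent with noise*:
a one-sided binomial test at `alpha = 0.01` against the noise rate
`max_other_rate = 0.001`. The hard cutoff `other_rate <= 0.001`
(recoverable with `alpha = 1`) is deliberately not the default: when the
true background sits at the threshold itself, roughly half of genuine
pseudogenes would land above it by sampling noise alone and be demoted.
The binomial formulation keeps the intended semantics — "other mutation
types occur at error-like frequency" — while being robust to that
boundary effect. Low-GC copies failing the test are *undetermined*, for
review, never silently called.

Primer-candidate windows (`find_discriminating_sites`) are 20-column
stretches where all pseudogenes agree, differ from every functional copy
in ≥ 2 positions, and (by default) place one difference in the three
3'-terminal positions, since primer specificity is dominated by the 3'
end. Windows at GC < 0.25 carry a low-complexity warning: RIP pushes
pseudogene-specific primers toward extreme AT content, which is exactly
the regime where amplification tends to fail.

## RIP profiling (`classify_rip_context`, `compute_rip_profile`, `windowed_rip`)

Context is always read from the consensus, never from the mutated query:
the neighbor of a RIPped site is often RIPped itself, and reading the
query would systematically misclassify CpA sites whose A used to be a G.
Across indels the nearest non-gap consensus column provides the
neighbor; a site at the sequence edge is `unclassified`.

Two summary ratios are reported. `dominance` is the raw count ratio of
the CpA class to the other three classes combined (denominator guarded
at 1 and flagged when empty). `preference` divides each side by its
opportunity — eligible consensus sites per class — and is the statistic
that actually tests "CpA/TpG sites are mutated more frequently": with a
3:1 rate bias but three other contexts sharing the denominator, raw
counts sit near 1 even when the per-site bias is strong. Windowed tracks
tile the alignment (the final window is truncated, not dropped, so
tiling sums reproduce the global counts) and tally invariant and gap
columns separately, matching the categories of RIPCAL-style mutation
maps.

## Structure impact (`map_mutations_to_structure`)

The pairing table (two-column TSV or nested dot-bracket; pseudoknots
rejected) assigns each mutation to a paired or unpaired reference
position. A paired-site mutation is *disrupting* when the post-mutation
pair leaves {AU, UA, GC, CG, GU, UG} — GU wobble counts as valid, the
standard convention for rRNA helices, with a strict Watson–Crick mode
available. Both partners are applied before judging, so compensatory
double mutations are not flagged, and each broken pair is reported once
even when both partners mutated.

## Phylogeny (`dist_rdna`, `nj_tree`, `bootstrap_support`, `clade_purity`)

p-distance is differences over comparable sites; K2P corrects
transitions (P) and transversions (Q) separately:
d = −½·ln(1−2P−Q) − ¼·ln(1−2Q). Pairs whose log arguments are
non-positive are saturated, flagged, and refuse to enter NJ (the error
names the offending pairs rather than guessing). Deletion handling is
`pairwise` (drop columns gapped in the pair) or `complete` (drop columns
gapped anywhere); the pipeline picks complete deletion when every
sequence is full length and pairwise otherwise, mirroring how mixed
partial/complete data sets are normally treated — and the choice remains
an explicit flag because either convention is defensible for mixed sets.

NJ is the canonical Saitou–Nei agglomeration. Two determinism rules make
trees reproducible to the byte: Q-criterion ties are broken by the
lexicographically smallest pair of representative identifiers (an
internal node is represented by its smallest leaf), and negative branch
lengths are clamped to zero with the deficit moved to the sister branch
so path lengths are preserved. Bootstrap resamples alignment columns
with replacement; support is the percentage of replicate trees
containing each original bipartition, replicates with saturated
distances are dropped and counted (warning above 5%). Supports are
reported as integers 0–100 and never used to collapse edges — hiding
weak support is a display decision, not a topology decision.

`clade_purity` scans every edge for the exact functional/pseudogene
bipartition and otherwise reports the minimum number of misplaced leaves
over all edges, so "almost separated" trees are quantified rather than
just failed.

# The simulator: what it emulates, and what it does not

`generate_reference_unit` builds a 7,660 bp unit (18S 1,800; ITS1 200;
5.8S 160; ITS2 200; 28S 3,300; IGS 2,000) with coding GC 0.48 and spacer
GC 0.50 — inside the observed functional band. The G+C count per subunit
is fixed by construction, so realized GC is always within one percentage
point of target and the functional band is guaranteed.

`apply_rip` applies one pass against the entering sequence: every
eligible C (with a 3' neighbor) and G (with a 5' neighbor) is mutated
independently with its context rate. Default rates
{CpA 0.60, CpC 0.25, CpG 0.25, CpT 0.35} encode the strong CpA/TpG
preference of fungal RIP and were chosen so that a pseudogenized copy
loses ~15–25% of aligned sites to transitions — the band reported for
heavily RIPped rDNA — and drops from GC 0.48 to roughly 0.30. Background
noise (default 0.001 per site, emulating error-like non-RIP variation)
draws uniformly from the alternative bases that do not produce C→T or
G→A, keeping the two signal classes clean. Because real data do not say
whether RIP acted in one or several sexual cycles, `rounds` is exposed
as a knob; the default of one round keeps every logged context exactly
recoverable from the unmutated template, which is what makes the
context-honesty and log-replay tests exact rather than statistical.

`build_synthetic_assembly` plants `n_paralogs = 10` copies
(`pseudogene_fraction = 0.8`, at least one always functional,
`complete_fraction = 0.7`; partial copies keep a random 35–75% of the
unit from a random end), each in its own contig between 500 bp random
flanks, on a random strand. Functional copies are byte-identical to the
template, matching the observation that functional copies within a
genome are identical; intron-like insertions (off by default) go only
into RIPped copies for the same reason.

Deliberately **not** modeled: unequal crossing-over/gene-conversion
dynamics (concerted evolution appears only through its end state —
identical functional copies), chromosomal arrangement of the tandem
array, read-level assembly artifacts (contigs are clean), and
multi-species genealogies. Passing the end-to-end tests therefore shows
the analysis is correct *given* repeats embedded in contigs with RIP-like
decay; it cannot certify behavior on collapsed repeats or chimeric
assemblies, where copy number itself is unreliable.

# Numerical choices and degenerate inputs

* Alignment scoring is integer throughout; tie-breaking prefers
  diagonal > gap-in-query > gap-in-reference, making gapped outputs
  unique and reproducible.
* `rip_rate` vs `gA_rate + cT_rate` agreement is tested at 1e−9 but
  holds to machine precision by construction.
* Zero-rate RIP is the identity; an all-gap or empty comparable set
  yields flagged `NA` distances, never silent zeros; a distance matrix
  with undefined entries stops NJ with the pairs named.
* `dominance` on a fixture with no non-CpA mutations reports count/1
  with an explicit flag instead of dividing by zero.
* Bootstrap with identical sequences yields a star-like topology whose
  resolved edges trivially reach 100; the purity scan still works
  because it never assumes binary resolution.
* All randomness flows through a single integer seed per entry point
  (`with_seed` isolates the RNG state, so library calls never perturb a
  caller's stream). Fixed seed means byte-identical FASTA, TSV, YAML and
  Newick outputs across reruns.

# Problem sizes used by the test suite

Unit and property tests run on a scaled-down unit (1,220 bp: 18S 300,
ITS1 60, 5.8S 100, ITS2 60, 28S 500, IGS 200) — large enough for stable
GC bands and context statistics, small enough that the full suite,
including two complete pipeline runs and a byte-reproducibility check,
finishes in a few minutes. The end-to-end scientific checks use the
full-size unit: a 10-copy default genome, a 50-copy parameter-recovery
experiment at context rates {CpA 0.3, others 0.1} (estimates agree
within three binomial standard errors; CpA preference ≈ 3 and highly
significant; call sensitivity and specificity 1.0), and a 5 + 5
functional/pseudogene bootstrap experiment whose separating bipartition
reaches support ≥ 95 at 100 replicates.

# Known limitations

* The aligner is exact dynamic programming without banding; fine at
  rDNA-unit scale (seconds for 7.6 kb × 10 kb), not meant for
  chromosome-scale pairwise alignment.
* The anchor multiple alignment (`anchor_msa`) is reference-anchored:
  exact for substitution-dominated divergence (the RIP regime), but it
  does not align inserted segments against each other.
* GC-gap splitting assumes the two bands are each denser than the gap
  between them; datasets with two or three paralogs rely on the
  `min_gap` guard and on the spectrum-based call, not the split alone.
* Structure impact judges isolated base pairs; it does not re-fold the
  molecule or score thermodynamic stability, so "disrupting" is a
  per-pair statement, not a prediction of misfolding.
* The simulator's truth table defines correctness for the pipeline's
  scores; on real assemblies, collapsed repeats mean reported copy
  numbers are lower bounds, and the functional copy may itself be absent
  from the assembly.
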