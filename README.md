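# rdnarip

Discovery and RIP profiling of ribosomal DNA pseudogenes in fungal genome
assemblies.

## The problem

The 45S rDNA tandem repeat (18S–ITS1–5.8S–ITS2–28S–IGS) is the workhorse of
fungal molecular systematics and is usually assumed to evolve in concert:
all copies in a genome stay essentially identical. In many filamentous
ascomycetes this assumption fails, because **repeat-induced point mutation
(RIP)** — a genome-defense process acting on duplicated sequences during
sexual reproduction — converts some rDNA copies into pseudogenes by
hammering them with C→T and G→A transitions (G:C→A:T on the two strands),
preferentially at CpA/TpG dinucleotides. The resulting paralogs have
sharply lowered GC content, a substitution spectrum dominated by the two
transition classes, disrupted rRNA secondary structure, and they contaminate
ITS/18S/28S phylogenies, where they cluster by gene type (functional vs
pseudogenic) rather than by species.

`rdnarip` implements the full desk analysis for this phenomenon, for anyone
who wants to screen an assembly for rDNA paralogs and decide which copies
to trust:

* **Mining** — iterative query-expansion homology search (exact k-mer
  seeding + local affine-gap alignment, Smith–Waterman–Gotoh in C++):
  copies too decayed to be found from the functional seed are reached
  through intermediate copies, rounds repeating until no new repeat
  appears. Subunit boundaries are annotated by local alignment against a
  reference unit and intron-like insertions in 18S/28S are excised.
* **Classification** — per-subunit GC content; split into the high-GC
  (functional) and low-GC band at the largest gap; substitution spectra of
  every copy against the highest-GC reference; pseudogene calls requiring
  low GC, G→A/C→T dominance, and non-RIP substitutions consistent with
  noise (≤0.1%, one-sided binomial test).
* **RIP profiling** — every transition classified by its consensus
  dinucleotide context (CpA↔TpA | TpG↔TpA, CpC↔TpC | GpG↔GpA,
  CpG↔TpG | CpG↔CpA, CpT↔TpT | ApG↔ApA), per-copy RIP rate
  (= G→A rate + C→T rate over aligned sites), CpA dominance and
  opportunity-normalized CpA preference, and RIPCAL-style windowed
  mutation tracks.
* **Structure impact** — mutations mapped onto an rRNA base-pairing table
  (two-column TSV or dot-bracket); a mutation at a paired site is
  *disrupting* when the post-mutation pair is outside {AU, UA, GC, CG,
  GU, UG}.
* **Phylogeny** — p-distance and Kimura two-parameter distances
  (`d = -½·ln(1−2P−Q) − ¼·ln(1−2Q)`, pairwise or complete deletion),
  canonical Saitou–Nei neighbor-joining with deterministic tie-breaking,
  column-resampling bootstrap, and a clade-purity statistic testing
  whether some edge of the tree exactly separates functional from
  pseudogenic copies.
* **Simulation** — a seeded synthetic-genome generator (unit template →
  context-biased RIP → fragmented contigs with flanks and random strand)
  with a mutation-level truth table, so the whole pipeline is validated
  end-to-end with no external data.

## A worked example

```r
library(rdnarip)

report <- run_pipeline(pipeline_config(mode = "synthetic", seed = 42,
                                       outdir = "run42"))
print(report)
```

```
rDNA pseudogene pipeline report
 subunit n_paralogs n_pseudogene_calls avg_p_distance avg_gA_rate avg_cT_rate
     18S          9                  8         0.1989     0.09348     0.08298
    5.8S          9                  8         0.2034     0.08712     0.09653
     28S          7                  6         0.1969     0.08543     0.08927
 avg_rip_rate separating
       0.1765       TRUE
       0.1837       TRUE
       0.1747       TRUE
truth: sensitivity 1.000, specificity 1.000 (TP 8 FP 0 TN 1 FN 0)
```

Reading this: the simulated genome carried 10 rDNA repeats (8 RIPped, 3 of
them truncated); mining recovered all of them; 9 copies carried a usable
18S. Within each subunit the low-GC copies show G→A and C→T rates around
9% each, i.e. an overall RIP rate of 17–18% of aligned sites — the level at
which heavily RIPped rDNA repeats are typically observed — while average
p-distances near 0.2 confirm the striking intragenomic divergence RIP
leaves behind. `separating = TRUE` means the NJ tree of each subunit has an
edge that exactly splits functional copies from pseudogenes, and the
truth-table line confirms every pseudogene call was correct. Per-stage
TSVs, Newick trees with bootstrap supports, and a RIPCAL-style windowed
mutation track are written under `run42/`.

Individual stages are plain functions (`iterative_search()`,
`classify_paralogs()`, `compute_rip_profile()`, `windowed_rip()`,
`map_mutations_to_structure()`, `nj_tree()`, `bootstrap_support()`,
`clade_purity()`, …) and a thin CLI lives in `inst/scripts/rdnarip`.

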