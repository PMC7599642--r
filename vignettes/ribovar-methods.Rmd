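---
title: "Methods: analysing intragenomic 18S rDNA variation with ribovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing intragenomic 18S rDNA variation with ribovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribovar)
```

## The analysis problem

Ribosomal RNA genes occur in hundreds of near-identical copies per
genome. Concerted evolution normally keeps them homogeneous, but in
long-term cell cultures the balance between mutation and homogenisation
shifts, and individual cloned copies of the 18S gene start to differ.
`ribovar` analyses sets of 20–50 cloned full-length copies (about
1809 nt each) per cell line: it asks *how many* changes each copy
carries, *what kind* they are, *where* on the gene they cluster, *how*
the copies are related genealogically, and *whether* the changes alter
local rRNA secondary structure. A cytogenetic module summarises the
accompanying chromosome-number and nucleoli-count instability.

## Coordinates, alignment and substitution calling

All internal coordinates are 1-based inclusive, the convention
biologists use to report gene positions; BED-style 0-based half-open
input is converted at the I/O boundary. Clones are aligned to the
reference with an end-to-end global alignment (match +1, mismatch −1,
linear gap −2, no terminal-gap forgiveness): clones are full-length
amplicons diverging by well under 1%, so this simple scoring is
adequate and keeps alignments deterministic; a clone whose length
deviates from the reference by more than 10% is rejected as not being
a full-length copy. Aligned clones are projected onto ungapped
reference coordinates (clone insertions are dropped), which places all
clones of a line on one shared coordinate system.

A substitution is called at every column where both sequences carry an
unambiguous `A/C/G/T` and the bases differ. Columns with gaps or
ambiguity codes are skipped entirely, because only unambiguous
substitution *directions* (reference → clone) enter the classification:

* **transition** — both bases purines or both pyrimidines
  (A↔G, C↔T); everything else is a transversion;
* **methylation-associated (Met)** — exactly C→T and G→A, the
  deamination footprint of 5-methylcytosine. No reverse-strand
  symmetrisation is applied: the class is sequence-context bookkeeping,
  not a claim about actual methylation state;
* **amination-associated (Am)** — exactly T→A, T→C and T→G
  (a reference T replaced by any base).

Met and Am are disjoint by construction (Met requires a C or G
reference base, Am requires T). Indels are deliberately not treated as
events; the analysis concerns point substitutions.

The per-line summary keeps all statistics unrounded; rounding (half-up,
percentages to 1–2 decimals, per-gene means to 2) happens only when
printing. With zero transversions the *ts*/*tv* ratio is reported as
`Inf` and should be excluded from comparisons.

## Nucleotide diversity and site classes

Diversity π is the average over all unordered sequence pairs of the
proportion of differing sites among sites validly compared for that
pair (pairwise deletion). On gap-free alignments this equals the
column-wise average pairwise-difference proportion, which the test
suite checks to 1e-12. Sliding windows are 100 sites advanced by 25 —
the field's standard profile resolution for a gene of this size — with
windows anchored at their start column; a trailing window that would
run past the alignment is discarded rather than shrunk (a determinism
choice: every reported window then has identical support). For a
1809-site alignment that yields 69 windows, the last starting at 1701;
the final 8 sites are not covered by any window.

A variable site with at least two bases each present in at least two
sequences is parsimony-informative (the standard two-bases-twice
rule); any other variable site is a singleton. Columns with fewer than
two valid bases are treated as invariant.

Hotspot tables assign each substitution to *every* annotated region
containing it (overlaps allowed) and report, per region, the call count
(optionally restricted to the Met or Am class) plus the peak window π
over windows intersecting the region. Region coordinates must be
user-supplied: the positions of ES3b-c and hairpins h6–h33 on a
particular 18S gene come from structure-informed annotation, which the
package cannot derive from sequence alone. `default_regions()` provides
a synthetic, diagrammatically plausible layout used by the simulator
and the examples — it is a stand-in, not an annotation of any real
gene.

## Ribotypes and networks

Sequences identical over mutually valid columns collapse into one
ribotype (greedy, first-seen order — deterministic and linear in the
common case of few ambiguities). Distances between ribotypes are
Hamming counts over valid columns.

The minimum spanning tree uses Kruskal's algorithm with a fixed
tie-break (weight, then the lexicographically smaller node-id pair),
so identical inputs always give identical trees.

The median-joining construction works on the variable columns only
(invariant columns carry no signal). Each round computes the
ε-relaxed minimum spanning network — an edge (u, v) is feasible when
its distance is at most the minimax path distance between u and v
plus ε — and considers the majority-consensus vector of every node
triple with at least two feasible links. A candidate median is adopted
(best improvement first, lexicographic sequence order breaking ties)
only if adding it strictly reduces the total minimum-spanning length;
the loop repeats until no candidate improves, then medians whose
removal leaves the spanning length unchanged are pruned. The final
graph keeps all feasible edges, so it contains a minimum spanning tree
of the observed plus median nodes and is always connected. Where all
three states of a triple differ in a column, the first node's state is
kept — one deterministic representative of the quasi-median set rather
than a branching enumeration. ε defaults to 0 (parsimony-strict), the
usual choice when no recombination is expected within an rDNA array.
With every observed sequence one step from a common ancestor the
output is exactly a star with one hub and no medians, the topology
diagnostic of a recent expansion.

## Secondary structure of short segments

Full thermodynamic folding is out of scope; structures here come from
a deterministic nested dynamic programme in two modes. `maxpair`
maximises Watson–Crick + GU pair count (the classical base-pair
maximisation recursion); `stacking` — the default — adds one point for
each stacked neighbour pair, which penalises isolated pairs and makes
helices contiguous, capturing the helix-versus-loop trade-offs that
comparisons between allele structures rest on. The minimum hairpin
loop is 3 nt (the steric minimum); segments are limited to 300 nt and
folded independently per annotated region. Traceback is deterministic:
whenever pairing the left end attains the optimum it pairs with its
smallest admissible partner, and stacked continuations win ties — so
alleles with identical segment sequences always receive identical
structures.

The loop census attributes every unpaired base to exactly one feature:
hairpin loops (no nested helix), bulges (one nested helix, unpaired on
one side only), interior loops (unpaired both sides), multibranch
loops (≥2 nested helices) or the exterior. Two structures have the
same *shape* when their feature multisets agree (helix count and the
size multisets of each loop type, interior loops compared
orientation-insensitively); base-pair distance is the symmetric
difference of the pair sets. Intersegment complementarity (the ES3–ES6
contact) is scored by sliding one site against the reverse of the
other over all offsets and counting pairable positions, with GU wobble
allowed by default.

## Cytogenetic summaries

Chromosome counts are summarised by range, mean ± SE and a decade
histogram (bins 1–10, 11–20, …); a user-supplied interval (e.g. the
hyper-diploid 48–80 class) yields the modal-class share. Nucleoli are
split into macro (≥2 µm) and micro (<2 µm) counts per nucleus with
means ± SE (SE = sample SD/√n; a single observation reports SE 0 with
a warning). The correlation between per-line mean nucleoli and mean
chromosomes uses the product-moment formula with a t-distribution
p-value; because "mean number of nucleoli" is ambiguous between
macro-only and macro + micro totals, both conventions are exposed and
both should be checked. With only three lines the p-value is
descriptive, not a serious inferential quantity.

## The synthetic generator

The generator exists so every stage of the pipeline can be exercised
and validated without external sequence data. Per clone it draws a
Poisson(λ) number of substitution events; each event samples a
(position, alternative base) jointly with weight
hotspot(pos) × κ^[transition] × m^[C→T or G→A], where κ is the
transition bias and m the methylation-context multiplier. Two draws
hitting one site keep the last, and the returned ground truth lists
the *resolved* events, so substitution calling recovers the truth list
exactly — the end-to-end consistency the tests rely on. The `two_level`
genealogy draws ~√n sub-founders carrying half of λ and derives each
clone from a random sub-founder plus its own half, producing the
compound (major + secondary star) network topology; `star` derives
every clone independently. A `duplicate_fraction` of clones are exact
copies, modelling shared ribotypes.

Preset conditions per line were fixed once from the published per-line
summaries: clone numbers 20/46/46; λ = 2.05, 5.20 and 3.30 (the
printed mean substitutions per gene copy); κ = 25, 4 and 9 (from the
printed transition/transversion counts); and m solved per line from
the generator's expected Met share, κm/(κ(1 + m) + 4) = printed Met%,
giving 0.33, 0.96 and 0.75. Hotspot placements follow the reported
per-line peaks (ES3 for the young stem line; h7/h8/h17 for the old
stem line; h33 for the ovary line) on the synthetic region layout. The
generator emulates mostly-singleton variation, transition bias,
methylation-context rates, hotspots and genealogy shape; it does *not*
emulate indels, gene conversion/recombination between rDNA copies,
PCR/sequencing error structure, or the strand asymmetry of individual
directed types (a single κ cannot make T→C dominate C→T as in the
young line) — so passing tests demonstrate correct recovery of the
planted statistical structure, not realism of every feature of real
clone sets.

## Numerical and design notes

* Alignment is delegated to a standard Needleman–Wunsch implementation
  with the scoring above; tests verify score optimality against an
  exhaustive DP oracle on 20-nt pairs.
* π, site classes, distances and Hamming matrices are exact integer /
  rational computations; the only tolerance in the suite is 1e-12 for
  the column-wise π identity.
* All stochastic functions take explicit seeds; a `NULL` seed means
  "use the caller's RNG stream", which is how `simulate_line()` drives
  reference, parameters and clones from one seed.
* Degenerate inputs fail loudly: empty FASTA, duplicate ids, start >
  end regions, <2 sequences for diversity, zero-variance correlation
  input, crossing pairs in a structure.
* Problem sizes in the test suite were chosen to keep exhaustive
  oracles exact and fast: folding is checked against full enumeration
  for sequences ≤14 nt, MSTs against Prüfer enumeration for ≤6 nodes,
  parameter recovery on 46-clone sets at λ = 5.2 over three fixed
  seeds (recovery asserted within 3 standard errors, √(λ/n)).

## Known limitations

* The stacking score is a structural surrogate, not free energy;
  structures should be read comparatively (same/different shape,
  feature counts), never as kcal/mol predictions.
* Median-joining adds one quasi-median per triple rather than the full
  quasi-median set; on highly reticulate data the network can be
  sparser than a full Bandelt construction, though it always contains
  an MST.
* Ribotype collapsing with ambiguity codes is greedy and
  order-dependent in the rare case where an ambiguous sequence matches
  several ribotypes; first-seen order is the documented tie-break.
* The p-distance `mean_K` equals `mean_D × sites` only on gap-free
  alignments; with gaps the per-pair denominators differ.
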