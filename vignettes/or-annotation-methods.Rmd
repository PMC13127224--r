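---
title: "Annotating olfactory receptor repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating olfactory receptor repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscan)
```

## The problem

Fish olfactory receptor (OR) genes are intronless, rhodopsin-like GPCRs
that occur in large, tandemly duplicated chromosomal clusters and decay
readily into pseudogenes. Annotating a repertoire from a genome assembly
therefore involves a chain of small, well-defined steps: find OR-like
loci by translated homology, reconstruct each single-exon gene model,
decide whether it is functional, partial, or a pseudogene, and then
characterize the repertoire — clusters and their orientation, conserved
motifs, transmembrane topology, glycosylation sequons, and phylogenetic
group membership. `orscan` implements this chain end to end and ships a
simulator that plants genes with known truth, so every stage can be
validated quantitatively without touching external databases.

## Translated homology search

Each chromosome is translated in all six frames (stops as `*`, codons
containing `N` as `X`, so ambiguity never fabricates a stop). The scan is
a TBLASTN-style heuristic: exact 4-mer amino-acid seeds against the query
set are grouped per (query, frame, diagonal), and each seeded diagonal is
scored by its best ungapped BLOSUM62 segment (a maximum-subarray pass
along the diagonal restricted to the query's projection). Because an
ungapped segment is itself a feasible local alignment, the reported score
can never exceed the exact Smith–Waterman optimum for the same pair; on
substitution-only planted genes the two coincide, which the tests check
against an exhaustive dynamic-programming oracle.

Significance uses the Karlin–Altschul expectation
$E = K\,m\,n\,e^{-\lambda S}$ with the standard gapped BLOSUM62 (11/1)
constants $\lambda = 0.267$, $K = 0.041$ as configurable defaults, a
query length $m$ in residues and a search space $n$ equal to the
translated genome length summed over both strands. Hits above the cutoff
(default $E \le 10^{-10}$) are discarded. A single BLOSUM62 mismatch
costs at worst $-4$, so a lone premature stop does not split the
ungapped segment: the flanking signal bridges it, and the lesion remains
inside the aligned span where defect detection can see it.

HSPs on one chromosome and strand within 5 kb of each other are chained
into candidate loci (single linkage; the gap only needs to bridge
frameshift-split HSPs of a single-exon gene), and each locus takes its
representative query by lowest E-value, then longest aligned span, then
lexicographic id.

## Gene models and the three-way classification

The locus envelope is extended by 1.5 kb per side — enough to span a full
~310-codon OR open reading frame beyond any HSP — and the in-frame
segment (between consecutive stop codons in the frame of the best HSP)
that overlaps the alignment becomes the gene. The CDS starts at the ATG
nearest the aligned region; anchoring at the nearest rather than the
farthest upstream ATG recovers planted coordinates exactly, because
random flanking sequence occasionally offers a spurious in-frame ATG
further upstream.

Defects are collected as evidence:

* `premature_stop` — the ORF's terminating stop falls strictly inside the
  aligned span, short of the projected query end;
* `frameshift` — chained HSPs of one query advance along the query while
  switching reading frame on the same strand;
* `missing_start` / `missing_stop` — no ATG precedes the aligned region
  within its in-frame segment, or no stop terminates it inside the
  extended region;
* `too_short` — at most 250 residues with nothing else to blame.

Only HSPs with at least 50% identity contribute defect evidence. OR
helices resemble one another enough that a query seeds weak off-diagonal
self-hits (20–25% identity), and without the filter those mimic frame
switches and stretch the aligned span past the true stop, producing
false pseudogene calls on intact genes.

Classification is a deterministic function of the defect set: a
premature stop or frameshift makes a **pseudogene**; otherwise a missing
start/stop or a short peptide makes a **partial** gene; otherwise the
model is **functional**, which consequently requires an intact ORF
longer than 250 residues (strict inequality: 250 exactly is partial).
When disruptive and boundary defects co-occur, the disruptive one wins —
a broken reading frame is the stronger evidence about coding status.
The three statuses partition every model set by construction.

Each surviving model must also score better against the OR query set
than against a decoy (non-OR) set under exact local alignment — a
self-contained stand-in for the conventional reciprocal check against an
external protein database, which a reproducible package cannot assume.
Overlapping same-strand models are deduplicated keeping the higher
verification score, then the longer peptide.

## Topology and sequons

Transmembrane annotation uses Kyte–Doolittle hydropathy averaged over a
19-residue window (truncated at the ends): maximal runs above 1.6 become
segments, segments closer than 3 residues merge, and segments shorter
than 15 residues are dropped. Seven segments is the canonical GPCR
architecture; counts in [6, 8] set `topology_ok`. The annotation is
deliberately non-filtering by default — it *rechecks* candidates rather
than rejecting them — with an optional strict mode (`require_7tm`) that
drops genes outside the range. This windowed-hydropathy predictor is a
transparent, dependency-free method; it does not model helix orientation
the way an HMM-based topology predictor would, and its counts should be
read as architecture summaries, not membrane-protein structure calls.

N-glycosylation sites are canonical sequons: N-X-S/T with X ≠ P,
overlapping occurrences all reported, verified in tests against an
independent position-by-position oracle.

## Clusters, orientation, and summary tables

A cluster is a maximal single-linkage chain of genes on one chromosome
whose consecutive nearest-edge gaps are strictly below 1 Mb (an exactly
1,000,000-bp gap does not join; edge-to-edge distance is the conservative
reading of "within 1 Mb of each other", and transitive chaining is the
documented resolution of whether the rule chains). Clustering is
shuffle-invariant and is tested against a brute-force transitive-closure
oracle. A cluster with at least two members all on one strand is flagged
as a candidate tandem array — shared transcriptional orientation being
the classic signature of tandem duplication.

Repertoire summaries count functional / partial / pseudogene at species
and chromosome level with percentages rounded half-up to two decimals,
the convention of published repertoire tables. Category counts sum to
totals at every granularity by construction; no relation between
chromosome size and OR count is assumed — size is a reporting field only.

## ZOOPS-EM motif discovery

Conserved motifs are found with a zero-or-one-occurrence-per-sequence
(ZOOPS) finite mixture over a 0-order background of empirical residue
frequencies. The expected complete-data update is standard EM on site
posteriors with a Dirichlet-style pseudocount (0.01) on the position
weight matrix; iteration stops when the observed log-likelihood improves
by less than `tol` (default 1e-6) or at `max_iter`. Starting points are
chosen from the data, MEME-fashion: the most frequently repeated words
of the requested width plus randomly drawn words (5 starts by default),
each run to convergence, best fit kept. Everything is deterministic
given the seed, and the log-likelihood trace is exposed so monotonicity
is testable.

Widths are scanned over the grid {8, 10, 12, 15, 20, 30, 50} (within the
conventional 5–50 range; exhaustive width scanning is possible but
quadratically slower and not the default). Candidate widths are compared
— and the returned motifs are ranked — by a length-penalized
log-likelihood ratio, $\mathrm{LLR} - \tfrac{1}{2}\,19\,w\,\log n$,
a BIC-style charge of 19 free parameters per column. Raw LLR grows
almost linearly in width, so unpenalized ranking would always favor the
widest window regardless of how sharp the signal is. After each motif is
accepted, its sites are masked with a neutral symbol that scores as
background (and cannot host later sites), and the next motif is sought;
five motifs are retained by default. Information content per column,
$\log_2 20 + \sum_a p_a \log_2 p_a$, is reported for logo rendering.

## Distance-based group classification

OR repertoires divide into type I (groups β, γ, δ, ε, ζ) and type II
(η, κ); θ and λ labels are accepted on references but reported as
non-OR. Rather than re-implementing approximate-maximum-likelihood tree
inference, the package computes pairwise global-alignment distances
(BLOSUM62, 11/1; distance = 1 − identity over aligned columns) and
applies neighbor joining — exact on additive matrices, property-tested
on random trees — with negative branch lengths clamped to zero and
newick export so users can substitute an externally built tree. This is
the package's one intentional methodological substitution relative to
alignment-plus-ML practice; bootstrap support is out of scope because no
multiple alignment exists to resample in the distance-only path.

The default classifier assigns each gene the group of its nearest
labelled reference (ties at full precision resolve to the
alphabetically first group); a tree mode instead takes the majority
group of the smallest clade containing the gene and at least one
reference, falling back to nearest-reference on ties. Expansion is
flagged per group when the focal count is at least twice the mean
reference-species count (the denominator floored at 1 so groups absent
from references stay finite).

## The simulator: what it emulates, and what it does not

`make_or_template()` builds a 310-residue peptide with the OR
architecture: seven 21-residue hydrophobic helices (Ile/Val edges, an
Ile/Leu/Val core — hydrophobic enough that every helix provably clears
the hydropathy threshold for a full 15-residue run even against the most
hydrophilic loop edge the generator can draw), hydrophilic loops whose
interior composition is group-specific (distinct residue pools keep
group templates ≥ 25% diverged, so classification tests are well-posed),
the conserved `MAYDRYVAIC` block after the third helix, an N-terminal
sequon, and a uniform-synonymous-codon back-translation with ATG start
and single stop. Codon bias is irrelevant to every protein-level test
and is not modelled.

`generate_genome()` embeds mutated copies of the templates in iid
background at a requested GC, laid out as oriented tandem clusters.
Defaults are the benchmark conditions used throughout the package: two
1-Mb chromosomes, three clusters of ten copies, within-cluster gaps of
5–50 kb, 5% amino-acid divergence per copy, and lesion rates matching a
large fish OR repertoire — about 6% of copies pseudogenized (one
premature stop or a 1-nt frameshift, uniformly chosen, placed in the
middle 60% of the CDS so lesions stay inside aligned spans) and about 3%
truncated (the first or last 35% of the CDS removed). Arrays on one
chromosome share orientation, so arrays that land within 1 Mb of each
other merge into a single consistent tandem cluster; truth cluster
labels are accordingly derived by applying the < 1 Mb rule to the
planted coordinates, which keeps cluster recovery well-defined. Output
is byte-identical under a fixed seed.

What the simulator does *not* emulate: repeats and isochores, multi-exon
decoy genes, codon bias, realistic intergenic composition, assembly
gaps, or sequencing error. Passing the planted-truth benchmarks
therefore demonstrates the pipeline's internal correctness — coordinate
arithmetic, defect logic, statistics — not its robustness to the full
messiness of real assemblies, where repeat-masking and curated query
sets do substantial work.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 is written 1-based
  inclusive and BED 0-based half-open.
* Codons containing N translate to `X`, and `X` never matches a stop —
  ambiguous sequence cannot create a defect.
* The E-value filter is applied to ungapped segment scores; equal raw
  scores tie-break deterministically (chromosome, coordinate, query id),
  so scan output order is reproducible.
* Empty HSP sets, empty gene tables, and singleton clusters all
  propagate as empty/size-one results rather than errors; an empty
  repertoire summary warns and reports zero percentages.
* Percentages round half away from zero at two decimals, matching the
  printed precision of published repertoire tables.
* EM ties and restarts are fully seeded; site calls require posterior
  ≥ 0.5, so a sequence with no credible site contributes nothing.

## Benchmark problem sizes

The shipped tests and the acceptance script run the benchmark layout
(2 × 1 Mb, 30 genes) end to end, a 200-gene lesion simulation for the
binomial check on planted pseudogene fractions, 200 random pairs against
the exhaustive alignment oracle, 100 random layouts against the cluster
closure oracle, and 50 random additive matrices (≤ 8 taxa) for
neighbor-joining exactness. These sizes were chosen to give stable
pass/fail behaviour at interactive runtimes; all scale linearly in the
obvious parameters if larger runs are wanted.

## Known limitations

* The scan's seeding requires an exact 4-mer match per diagonal; at
  amino-acid divergences far beyond the benchmark's 5–10% the heuristic
  will progressively miss diagonals that exhaustive Smith–Waterman would
  find.
* Frameshift detection relies on the scan emitting HSPs in two frames;
  a frameshift within a few residues of a CDS end leaves too little
  signal in the second frame and degrades to a premature-stop or
  boundary call.
* Alignment-guided "resurrection" of pseudogene peptides and multi-exon
  repair are deliberately out of scope.
* Karlin–Altschul statistics use fixed precomputed constants rather than
  composition-adjusted per-query estimation.
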