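---
title: "Methods: gene structure, intron phase and phylogeny in setstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene structure, intron phase and phylogeny in setstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setstruct)
```

## Scope and model of the data

`setstruct` implements the comparative analysis of a desk-scale gene
family — the motivating case is the plant Su(var)3-9 class of SET-domain
histone methyltransferase genes — in which the evolutionary signal of
interest is carried by *gene structure* (intron positions and phases)
rather than, or in addition to, sequence divergence. The pipeline takes
per-gene pairs of genomic DNA and mRNA (CDS) sequences, a protein
alignment of the conserved regions, and ordered domain annotations, and
produces: inferred exon/intron structures, intron positions projected
onto the codon alignment, shared-position (synapomorphy) sets, per-group
phase statistics, a rule-based domain-architecture classification, and a
bootstrapped neighbor-joining tree.

## Spliced alignment and canonicalization

`infer_structure()` decomposes the genomic sequence into an alternating
exon/intron chain that starts and ends with an exon and whose exons
concatenate to the mRNA. The mRNA is taken to be the CDS including the
stop codon; UTRs are out of scope, and inputs are assumed sense-strand.
All internal coordinates are 0-based half-open; reports print 1-based
positions.

Several decompositions can reproduce the same mRNA (the classic case is
a repeated base at an exon/intron junction). A deterministic
canonicalization selects exactly one, minimizing in order:

1. exonic substitutions (mismatches),
2. non-GT-AG introns,
3. the number of introns,
4. and finally preferring the leftmost intron placement (intron
   coordinates compared left to right).

The first two keys are a determinization of what a curator does when
inspecting splice consensus signals by eye; their order (mismatches
before splice-signal canonicality) matters only when `max_mismatches > 0`,
and was chosen so that the reported structure never trades a sequence
error for a nicer splice site without the user raising the budget. The
intron-count key prevents an intron from being split into two when a
single one suffices. The engine is a full dynamic program over
(mRNA position, genomic position) with dominating weights for the first
three keys and a greedy forward walk over suffix-optimal costs for the
leftmost rule; an `N` in either sequence matches anything. Inputs are
capped at 20 kb — every input in scope (curated gene pairs, simulated
families) is far below this, so no heuristic seeding layer is provided.

Tunable parameters: `max_mismatches` (default 0; substitutions between a
gene's CDS and its genomic copy are rare in curated pairs),
`min_intron` (default 4 nt, the smallest length that can carry both
splice dinucleotides), and `require_gt_ag` (default `FALSE`: non-GT-AG
introns are accepted with a warning, mirroring inspection rather than
rejection of non-canonical borders).

## Intron phase and position conventions

The phase of an intron is its CDS offset modulo 3 (`compute_phase()`):
phase 0 lies between codons, phase 1 after the first base of a codon,
phase 2 after the second.

`backtranslate_alignment()` expands a protein alignment row-by-row into
a codon alignment (residue → source codon, gap → `---`), verifying
per-row length consistency and codon-to-residue fidelity; a trailing
stop codon is trimmed. `project_introns()` then maps each intron to the
**1-based nucleotide alignment column of the last exonic base before the
intron**. This convention had to be fixed by us — published figures
rarely define their numbering — and is declared in every report
manifest. The aligned region may be a sub-interval of the CDS (e.g.
conserved domains only); the offset of the region within the CDS is
located by exact substring match, and introns falling outside it are
reported with `in_region = FALSE` rather than dropped.

Two intron positions are *identical* only when their alignment columns
are exactly equal; positions apart by even one base pair are never
merged (`shared_intron_positions()`). Near-identical positions within a
configurable window (default 6 nt) are surfaced by `sliding_report()`
as candidate intron sliding, for inspection only. Phase agreement at a
shared column is reported but not required: because gaps in the codon
alignment come in whole codons, equal columns force equal phases, so a
disagreement flags an upstream inconsistency rather than biology.

`assign_structural_groups()` partitions genes by single linkage, linking
two genes when they share at least `min_shared` identical positions
(default 2 — one shared intron is weak evidence, and the threshold can
be lowered to 1 to explore single-intron affinities). Genes without
in-region introns form the distinguished `"intronless"` class, the
candidate retrogene set.

## Phase statistics and rounding

`tabulate_phase_stats()` reproduces the conventional per-group summary:
intron counts by phase, totals, mean introns per gene, and phase
percentages, plus a grand-total row. Means are rounded half-up to one
decimal and percentages half-up to integers (base R rounds half to
even, which published tables do not use). Published tables of this kind
sometimes contain derived cells inconsistent with their own counts;
`flag_printed_discrepancies()` compares a printed table cell-by-cell
against the recomputation and reports every disagreement instead of
silently matching.

## Domain-architecture classification

`classify_architecture()` applies presence/absence rules in a fixed
order to the controlled vocabulary (AT_hook, SRA, ZnF_C2H2, WIYLD, AWS,
TPR_1, PreSET, SET, PostSET; `XXX` marks unannotated stretches and
carries no signal): SRA → type A (A1 with AT_hook, A2 with PostSET,
else A3); ZnF_C2H2 → B1; WIYLD → C1/C2 by PostSET; AWS without PreSET →
D1; otherwise type E (E3 with TPR_1, E1 with PostSET, else E2).
Eligibility mirrors the family definition: SET plus PreSET or AWS;
anything else is rejected, matching the upstream exclusion of proteins
lacking a PreSET domain. The rule order resolves overlaps (SRA outranks
ZnF_C2H2); multiple domain copies collapse to presence; a marker domain
C-terminal to SET still classifies but warns, since these architectures
are read as linear N→C patterns.

## Distances, neighbor joining and bootstrap

`p_distance_matrix()` computes the proportion of differing sites per
pair with pairwise deletion: columns holding a gap or an ambiguity
(`X`/`N`) in either row are excluded for that pair; ambiguity characters
are treated as gaps because a site that cannot be compared should not
count as identity or difference. A Poisson-corrected distance
`-ln(1 - p)` is available; likelihood-based models (JTT+Γ) are out of
scope since the shape parameter needed to reproduce them is not
recoverable.

`nj_tree()` is a from-scratch Saitou–Nei implementation. Ties in the Q
criterion are broken by the lexicographically smallest pair of cluster
labels (a cluster is labelled by its smallest leaf id), making the
output deterministic even on degenerate inputs. Negative branch lengths
are clamped to zero without redistribution — the simplest defensible
convention, and documented as such. On additive inputs the
implementation recovers the generating topology and path lengths to
numerical precision (this is asserted in the test suite against both
the generating trees and an exhaustive least-squares topology search).

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds distance + NJ per replicate, and maps the percentage of
replicates containing each bipartition onto the internal edges of the
full-data tree (not a majority-rule consensus, matching how such trees
are conventionally displayed). Replicates with a zero-overlap pair are
discarded and counted, with a warning above 1%. Support strengths are
categorized as weak (50–75), moderate (76–85) and strong (86–100);
below 50 is unsupported.

## The simulator: a stated world

`simulate_family()` evolves one ancestral gene along a declared guide
tree. The ancestral CDS is random codons without internal stops;
ancestral introns are GT..AG with uniform random interiors in a
configurable length range. Per branch, in order: point substitutions at
the branch length (expected substitutions/site) — exonic substitutions
never create a stop codon and the terminal stop and all splice
dinucleotides are immutable; intron losses (each intron independently,
probability `intron_loss`); intron gains (Poisson(`intron_gain`),
positions uniform over free CDS offsets, so gains never collide with
existing introns and no artificial sliding arises); retroposition
(probability `retroposition`): the lineage loses every intron at once,
the signature of a reverse-transcribed mRNA reinserted into the genome.
Deterministic scenarios pin events to named branches via
`forced_events`. Exons are indel-free, so the true protein alignment is
gapless and exact — conserved-domain regions of real families are
similarly low-indel, which is what makes the projection stage's ground
truth unambiguous.

What the simulator does **not** emulate: indels in exons (hence no
alignment uncertainty), rate heterogeneity across sites, codon-usage
bias, non-GT-AG introns, intron sliding, and domain-content evolution
(architectures are declared per clade, not evolved). A green
end-to-end test therefore establishes that the pipeline's logic is
correct on cleanly stated histories, not that it is robust to alignment
error — on real data the protein alignment is an input and its quality
is the user's responsibility.

`scenario_suvh()` is the bundled preset: a conserved intron-rich clade
of five genes (all six ancestral introns at identical positions and
phases), two independently retroposed intronless clades (3 + 2 genes),
and a divergent clade of four genes whose stem branch remodels the
structure (five losses, three gains, plus further gains inside the
clade), so it forms its own structural class — the three classes of
gene structure that comparative work on this family describes. Branch
lengths are at most 0.04 expected substitutions per site, within the
low-divergence regime in which exact structure recovery is the
documented expectation. The ancestral gene has seven exons
(120+93+150+96+120+63+60 = 702 nt of CDS) and introns of 60–120 nt,
typical of compact plant genes.

## Pipeline and reproducibility

`run_pipeline()` chains the stages, writes every table as TSV plus the
tree as Newick, and records a manifest (package version, seed,
parameters, the position convention, and all collected warnings —
non-GT-AG introns, discarded bootstrap replicates — so that "manual
inspection" steps are auditable). Stage outputs are pure functions of
inputs, parameters and seed; any stage failure aborts with the stage
named and leaves a `FAILED` marker beside the partial outputs. For
simulated inputs the bundle includes a truth-versus-inferred comparison
with exact-match flags per gene and a topology-recovery flag.

The package is a library, not a shell tool: the exported functions, the
`scripts/acceptance.R` entry point, and this vignette are the intended
interfaces.

## Worked example

```{r example, eval = FALSE}
sim <- scenario_suvh(seed = 101)
res <- run_pipeline(run_config(out_dir = tempfile("suvh_run"),
                               simulation = sim,
                               params = list(n_boot = 1000L), seed = 101))
glance(res)
res$shared
autoplot(res$incidence)
```

## Known limitations

* Spliced alignment models substitutions only; exonic indels between
  mRNA and genomic copies are not handled (out of scope by design).
* One mRNA per gene; multi-isoform reconciliation is not attempted.
* The leftmost-placement rule is a convention: where a junction is
  genuinely ambiguous, the reported coordinates are canonical, not
  necessarily historical.
* Bootstrap supports are mapped onto the full-data tree; splits absent
  from that tree are not reported even if frequent among replicates.
* `nj_tree()` is quadratic per join and intended for at most a few
  hundred taxa.
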