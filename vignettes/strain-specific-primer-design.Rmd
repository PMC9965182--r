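---
title: "Strain-specific primer design and attachment qPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-specific primer design and attachment qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainprimer)
```

This vignette is the package's own account of the methods it
implements: the genome-subtraction model behind unique-region
discovery, the thermodynamic and combinatorial model behind primer
design, the mismatch model behind in silico specificity, and the
standard-curve model behind attachment qPCR. It also records the
numerical choices made where the underlying procedures were open to
interpretation, and what the synthetic-data generators do and do not
emulate.

## The design problem

Two bacterial strains of one species can share 97–100% of their 16S
rRNA genes and still differ by mobile elements, islands and
strain-specific genes. A strain-specific assay exploits exactly those
differences: find stretches of the reference genome with no counterpart
in any close relative ("query") genome, design a primer pair inside one
such stretch, and confirm computationally that the pair amplifies one
product from the reference and nothing from the relatives.

## Unique-region discovery

### The matching engine

Whole-genome aligners solve a more general problem than subtraction
needs. The package's engine answers only "which reference positions lie
inside a convincing match to some query": exact `seed_k`-mer seeds
(default 15) shared between reference and query are grouped by diagonal
(reference offset minus query offset), consecutive seeds on one
diagonal within `chain_gap` (150 bp) are chained, and chains are
extended outward base by base under an X-drop rule (match +1, mismatch
−1, stop 10 below the running maximum). A segment counts as a match
when its ungapped identity is at least `min_match_identity` (85%) and
its length at least `min_anchor_len` (31 bp). The identity default
mirrors the 85% cutoff conventional in bacterial pan-genome
subtraction; the 31 bp anchor floor is what keeps chance 15-mer hits
(expected a handful per 100 kb × 100 kb comparison) from ever counting
as matches, because a spurious seed cannot extend 16 further matching
bases through random sequence.

Indels are handled implicitly: they shift the diagonal, so a diverged
region simply falls into several shorter ungapped segments, each judged
on its own identity. Repeated k-mers take their first query occurrence;
for the near-clonal comparisons this engine is meant for (congeners at
≥ 85% identity) this has no practical effect, but heavily repetitive
genomes are outside its design envelope.

Runs of ambiguous bases (N) in the reference are force-marked as
covered, so no primer is ever designed across an assembly gap.

### Two subtraction modes

*Endpoint mode* fragments the reference into 1000 bp pieces and calls a
fragment novel when fewer than `core_threshold` (2) genomes contain it
— i.e., with the default threshold, when no query matches it. "Matches
it" is quantified as the best overlapping segment's identity scaled by
the fraction of the fragment it covers, so a fragment half-covered at
99% identity scores ~49.5 and is still novel at the 85% cutoff. A
fragment that straddles the boundary of a planted novel segment is
therefore usually called novel too; merged novel regions shorter than
500 bp are dropped. These sizes (500/1000/85/2) are the conventional
configuration for novel-region finding in bacterial comparative
genomics and are the package defaults.

*qPCR mode* complements the per-base coverage mask, keeps uncovered
runs, tiles runs longer than 250 bp into non-overlapping 250 bp
windows (a sliding tile would only produce near-duplicate candidate
regions; non-overlap was chosen to avoid redundancy), and keeps
windows of 150–250 bp with 40–60% GC — short enough to host a
100–200 bp qPCR product, GC-balanced enough to prime reliably.

### Off-target confirmation

Each surviving region is scored against a user-supplied local
background collection, standing in for a nucleotide-database search:
per background record, the chained matches are summarized as weighted
mean identity × fraction of the region covered, and the region's score
is the maximum over records (0 = no hit, 100 = verbatim present).
"Most unique" is not a standardized quantity; identity × coverage was
chosen because it penalizes both a short perfect hit and a long sloppy
one, and the score is recorded in the output so users can apply their
own cutoff. With no background supplied, scores are 0 and screening
falls entirely to the in silico PCR stage against the query panel —
documented as the package's local-specificity semantics (no remote
database is ever queried; a retrieval step could be slotted in where
the background argument enters the pipeline).

## Primer design

### Melting temperature

Unified nearest-neighbor thermodynamics: ΔH and ΔS are summed over
dinucleotide stacks with terminal initiation terms, entropy is
salt-corrected by 0.368·N·ln[Na⁺] (N = number of stacks), and

Tm(°C) = 1000·ΔH / (ΔS_salt + R·ln(C_T/4)) − 273.15

at the defaults of 50 mM monovalent salt and 50 nM total oligo — the
regime most primer-design software assumes, and the regime under which
the published 57–63 °C constraint window makes sense. The
implementation is deterministic to well below 0.01 °C and agrees with
an independent nearest-neighbor implementation to 4 decimal places
(frozen in the test suite). Divalent corrections are deliberately out
of scope; they shift all candidates almost uniformly and would not
change rankings.

### Candidates, suitability and pairs

Candidate enumeration is exhaustive: every substring of the region, on
both strands, within the length bounds, GC bounds and Tm bounds, that
passes suitability screening. Suitability is the classic checklist:
homopolymer run ≤ 4, no 2–4 bp unit repeated more than 4 times,
self-complementarity any-score ≤ 8 and 3′-score ≤ 3 (match +1 /
mismatch −1 ungapped pairing scores), with the 3′ GC clamp reported but
not required. Thresholds are configurable; the defaults are the values
commonly used by online primer-checking tools.

Pairs combine a plus-strand candidate with a minus-strand candidate
lying 3′ of it, product size within bounds (100–200 bp in the qPCR
preset). The pair penalty is

penalty = 1.0·|Tm_f − Tm_r| + 0.5·pair_any + 1.0·pair_3p +
0.25·(|len_f − len_opt| + |len_r − len_opt|)

with weights chosen to dominate by Tm balance (the property qPCR is
most sensitive to), then 3′-end pairing (primer-dimer initiation), then
overall pairing and length deviation. No published penalty exists for
this assay; the weights live in the function signature and the ordering
they induce is exercised against planted fixtures in the tests. Ties
break by (forward offset, reverse offset) so runs are bit-reproducible.
The ranked list is capped at 500 pairs, reading the published "number
of primers to return" as a cap on ranked pairs rather than per-strand
candidates. Candidates are additionally capped at 200 per strand by
individual penalty before pairing; this bounds the quadratic pairing
step and, because the cap discards only high-penalty candidates, it
cannot change the top of the final ranking. The qPCR preset carries no
published Tm bounds, so the endpoint bounds (57–63 °C) apply there too
— logged in the constraint object and overridable.

## In silico PCR and specificity

A binding site is a primer footprint on either strand with IUPAC-aware
mismatch counts (total, and within the primer's 3′-terminal 3 bases as
hybridized — for a minus-strand site that window maps to the start of
the reverse-complemented footprint). The unintended-target rule is
applied literally as published: a site is non-functional only when
*both* clauses hold — at least 5 total mismatches *and* at least 2 in
the 3′ last-3 window. Independently, sites beyond
`max_mismatch_per_primer` (4) total mismatches are outside the scan
entirely, mirroring the mismatch ceiling of in silico PCR tools.
Amplicons are convergent site pairs (one site from each primer, either
role assignment) with non-overlapping footprints and products up to
4000 bp — a deliberate screening window an order of magnitude wider
than the design window, so near-miss off-target products are not
silently ignored. Reference amplicons are counted under a perfect-match
rule by default, so "exactly 1 reference amplicon" means one perfect
product.

Selection applies the published criteria lexicographically, in sentence
order: fewest non-target amplicons, then (after excluding pairs without
exactly one reference amplicon) lowest pair complementarity, then
design penalty, then coordinates. Whether the original criteria were
meant jointly or lexicographically is not stated; lexicographic order
matches the sentence and is reproducible.

RISA fingerprints reuse the same machinery: the sorted, deduplicated
product lengths of a 16S→spacer→23S primer pair are the predicted
electrophoretic pattern. The spacer-flanking primer sequences are
user-supplied inputs, not bundled constants.

## 16S processing

Sanger read pairs are merged by end-gap-free overlap alignment
(match +1, mismatch −1, gap −2, minimum score 10); agreements emit the
base, disagreements emit N — the package cannot consult chromatograms,
so it never silently picks a read. The consensus is cropped to a fixed
window anchored on the conserved U515 motif: 385 bases kept 5′ of the
anchor start and 216 bases 3′ of the anchor end, giving
385 + 19 + 216 = 620 processed bases — the only arithmetic consistent
with a 620 bp product, which pins down how "upstream/downstream" is
oriented. The anchor must occur exactly once; a reverse-strand-only
match auto-orients the sequence first.

Percent identity between marker sequences is global alignment
(match +1, mismatch −1, linear gap −2) with identity = matches /
alignment columns, gap columns included in the denominator. End gaps
are penalized: for near-full-length marker comparisons this is the
definition under which "identical up to k substitutions" gives exactly
(L−k)/L, and it is pinned by tests against a DP oracle. Query genomes
pass the marker filter when identity is strictly greater than 97% — a
candidate at exactly 97.0% is excluded. rRNA genes are located by
exemplar alignment (clusters of chained matches covering ≥ 80% of the
exemplar at ≥ 80% identity) rather than an HMM gene finder; the
thresholds are generous enough to recover congeneric 16S copies while
excluding chance matches, and remove any external-tool dependency.

## Attachment qPCR quantification

Copy number is mass-based: copies = m(ng)·6.022×10²³ /
(G(bp)·10⁹·660), with 660 Da per base pair of double-stranded DNA. A
standard curve is ordinary least squares Ct = a·log₁₀(copies) + b over
a tenfold ladder; amplification efficiency is E = 10^(−1/a) − 1
(reported as a percentage; 100% = perfect doubling, slope −3.3219).
The efficiency formula is the standard identity relating slope to
per-cycle gain; no other formula reproduces "100% at slope
−log₂10⁻¹". Reactions with Ct strictly above 30 are negative calls —
Ct = 30.0 itself is positive, per the strict reading of "Ct > 30" —
and a negative call on the bacterial side propagates to a "not
detected" ratio, while a negative call on the plant reference marker
is an error, because the normalization denominator is then undefined.
Technical replicates are averaged on the Ct scale before interpolation
by default (`average = "ct"`), with copy-scale averaging available;
the two differ only at noise levels where the assay is already
unreliable.

Group comparison is Kruskal–Wallis (base R) with Dunn's tie-corrected
z post hoc and Benjamini–Hochberg adjustment — the adjustment is a
choice, as "FDR" alone names a family; BH is its canonical member. The
compact letter display is built by insert-and-absorb so that two
groups share no letter exactly when their adjusted p falls below the
level, an equivalence asserted directly in the tests.

## Synthetic data: what it does and does not emulate

`make_strain_panel()` generates the study condition the tests run
under: a 100 kb random backbone at 50% GC, three queries mutated at 2%
substitutions and 0.2% indels (geometric lengths, mean 2), and a
200 bp unique segment with an exact GC count of 50% inserted into the
reference only. Queries derive from the backbone rather than being
independent genomes precisely so that "unique" has exact ground truth;
the truth interval is returned and asserted against. Substitutions are
uniform over alternatives — transition bias would not change any tested
logic. The 2% divergence corresponds to the within-species neighbors
the marker filter would retain; 100 kb keeps a full pipeline run at a
few seconds so twenty seeded panels fit comfortably in a test run (the
engine itself is linear in genome length and runs unchanged on real
multi-Mb genomes).

What the generator does **not** emulate: real gene-content differences
(unique regions here are random sequence, not mobile elements),
repeats and rRNA operon structure, GC skew and composition
heterogeneity, and assembly artifacts. Passing the planted-truth suite
therefore shows the subtraction/design/screening logic is correct, not
that any particular real genome yields a usable assay — on real data
the number of admissible unique regions, not the correctness of their
detection, is the binding constraint. Simulated qPCR
(Ct = Ct₁ − log₁₀(copies)/log₁₀(1+E) + ε) emulates curve geometry and
Gaussian Ct noise, not amplification inhibitors or plateau effects.

## Degenerate inputs and edge behavior

An empty query list gives an all-uncovered mask (and the endpoint/qPCR
entry points refuse to run, since subtraction against nothing is
meaningless); queries identical to the reference give a structured
"no design possible" outcome naming the failing stage rather than an
error, as do panels whose unique regions all fail the length/GC
filters. Primer scans return no sites when the primer exceeds the
contig; edge footprints hanging off a contig are never counted.
Coordinates are 0-based half-open everywhere internally and in BED
output; TSV reports convert to 1-based inclusive for human reading.

## Problem sizes used by the shipped checks

The test suite runs its end-to-end recovery on twenty 100 kb panels
(the generator defaults) and its oracle-equivalence checks on one
hundred random genome/primer cases up to 20 kb; monotonicity and
soundness properties run on 12–15 kb panels. These sizes are the
package's chosen simulation scale: large enough that seed statistics,
chaining and screening behave as they do at genome scale, small enough
to iterate on.

## Known limitations

- The matching engine is ungapped within segments; highly repetitive
  or rearranged genomes can over-fragment matches and inflate
  "unique" calls near repeat boundaries.
- Specificity is local: it extends exactly as far as the query panel
  and background collection supplied. It does not replace a search
  against a comprehensive nucleotide database.
- No secondary-structure folding (hairpin ΔG) and no degenerate-primer
  design; the suitability screen's ungapped self-complementarity is a
  proxy for dimer/hairpin propensity.
- The pair-complementarity metric of the original web screening tool is
  unpublished; the ungapped score used here is a documented stand-in.
- Multi-contig genomes are supported, but intervals never span contigs
  and no scaffolding inference is attempted.
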