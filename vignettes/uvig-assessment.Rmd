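---
title: "Assessing uncultivated virus genomes: completeness, quality tiers and vOTU clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing uncultivated virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvigkit)
```

## The problem

Uncultivated virus genomes (UViGs) are assembled from community
sequencing — viral or cellular metagenomes, metatranscriptomes, single
sorted virions, or proviruses detected inside microbial genomes — without
the virus ever being isolated. Because there is no isolate to fall back
on, everything we can say about such a genome must be read off the
sequence and its reporting metadata: how it was assembled and identified,
how complete it is likely to be, and which species-rank group it belongs
to. `uvigkit` implements the community reporting standard for these
genomes as a set of small, composable operations with a pipeline on top.

This vignette explains the models and conventions behind each component,
the tunable parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical edge cases.

## Metadata checklist

A UViG record is valid when its eight mandatory fields are present and
non-empty: the source of the genome, assembly software, virus
identification software, predicted genome type (Baltimore class) and
structure (segmented or not), detection type (free sequence vs provirus),
assembly quality tier, and number of contigs. Three design points:

- **Controlled vocabularies.** The standard names the fields but not
  always the full value lists; the vocabularies in `checklist_schema()`
  are the minimal sets directly traceable to the standard's text
  (e.g. the Baltimore-derived genome types, `segmented` /
  `nonsegmented` / `undetermined`), extensible via the `extra_vocab`
  argument rather than hard-coded guesses.
- **Software fields are free text.** The standard mandates *reporting*
  tools, versions, parameters and cutoffs, not a format; only
  non-emptiness is enforced.
- **New-taxon labels.** A record proposing a new taxon with a bare rank
  name ("genus") gets a warning, not a violation: uncultivated-genome
  taxa should be flagged "candidate"/"putative", but the record is not
  thereby invalid.

Validation is driven entirely by the schema (single source of truth), so
serialization (TSV, JSON, structured comment) and validation can never
disagree about what a field is.

## Completeness and quality tiers

Viruses mostly lack universal single-copy marker genes, so completeness
cannot be estimated the way it is for bacterial and archaeal
metagenome-assembled genomes. Two routes remain, used in order of
directness of evidence:

1. **Sequence-level evidence of completeness.** A direct terminal repeat
   (DTR) is the overlap signature a circular or circularly permuted
   genome leaves on its assembled contig; an inverted terminal repeat
   (ITR) characterizes some linear genomes; a resolved provirus
   integration site bounds a complete integrated genome. Any of these
   marks the genome *predicted complete*. The precedence
   DTR > ITR > integration site > reference length is our ordering (the
   standard lists the evidence types without one), ranking direct
   sequence evidence above annotation-derived evidence.
2. **Reference genome length.** Genome length is relatively homogeneous
   (about ±10%) within a virus (sub)family or genus, so given a
   taxonomic assignment the mean reference length of that taxon serves as
   the expected genome size and completeness is
   100 × observed / expected. The mean is the estimator consistent with
   the homogeneity framing via the coefficient of variation
   (CV = sd/mean); taxa with CV > 0.10 are flagged because the estimate
   is then unreliable. Segmented genomes need segment-level reference
   rows; without them a note is attached.

Tier assignment is a total function — every genome gets exactly one of:

- **genome fragment(s)**: completeness < 90% *or* no size estimate;
- **high-quality draft genome**: predicted complete or ≥ 90% of the
  expected genome; genomes read directly from a single long read
  (non-consensus) must additionally have mean phred > 20, i.e. > 99%
  average base-call accuracy;
- **finished**: a single contiguous sequence per replicon without gaps
  or ambiguities, complete, and extensively manually curated (gene
  functions and transcriptional units annotated). Any run of ten or
  more `N`s counts as a gap.

The 90% boundary is inclusive (≥ 90 is a draft), and raising
completeness with everything else fixed can never demote a genome — both
properties are tested by sweeping completeness in 0.1% steps.

**Circular contigs can lie.** Repeats sometimes circularize a partial
genome, so `circular_plausibility()` flags a DTR-bearing contig shorter
than half (default `plausibility_fraction = 0.5`) of its taxon's
expected length. The flag is advisory: predicted-complete status is
reported alongside the warning, and the tier is not changed
automatically, because the standard's remedy is manual validation, not
reclassification.

### Terminal repeat detection

Repeats are sought only anchored at the contig ends; the longest prefix
matching the terminal block (directly, or reverse complemented for ITRs)
within `max_mismatch` substitutions is reported, capped at half the
contig length. Matching is indel-free: DTRs arise from assembly overlap
and are near-exact, so a banded substitution-only comparison suffices
and keeps the scan exact and fast. Defaults `min_repeat_len = 20`,
`max_mismatch = 0`: the standard sets no minimum repeat length, and at
20 bp the per-position chance-match probability (4^-20) makes false
positives negligible at viral genome lengths — empirically < 1% over
1,000 random 1-kb sequences in the test suite. The minimum used should
be reported with any circularity call; it is recorded in the pipeline
manifest.

## ANI, AF and vOTU clustering

Species-rank virus groups — virus operational taxonomic units (vOTUs) —
are defined at **95% average nucleotide identity (ANI) over 85%
alignment fraction (AF)**, AF always relative to the shorter genome.

The engine is window-based (ANIb-style), authored in compiled code
rather than delegated to an external aligner, because the standard
prescribes thresholds, not an algorithm, and the alignment approach must
be reportable alongside the cutoffs:

1. The shorter genome is cut into non-overlapping windows of
   `window_bp` (default 500 bp). A trailing remainder shorter than
   100 bp is merged into the previous window, so identical genomes
   always reach AF = 100 regardless of divisibility; a genome shorter
   than one window is a single whole-sequence window.
2. Each window is mapped ungapped to its best location on either strand
   of the longer genome (assembly strand is arbitrary). The search is
   exact: seed k-mer hits only tighten a branch-and-bound over all
   offsets. `N` matches nothing, including itself.
3. Windows whose best hit reaches `min_window_identity` (default 70%)
   count as aligned. ANI is the length-weighted mean identity of
   aligned windows; AF is their summed length as a percent of the
   shorter genome. Non-overlapping query windows mean no aligned base
   is counted twice in AF — one convention among several possible, so it
   is stated here and recorded in output metadata.

Ungapped mapping is a deliberate simplification: within the species
radius (≥ 95% identity) indels are rare over 500-bp windows, and for the
substitution-only synthetic truth model the mapping is exact, which is
what lets the recovery tests demand agreement with the planted-mutation
oracle to 0.5 percentage points. Genomes with extensive indel
divergence will read slightly low; at the species cutoff this
conservatism is acceptable.

**The cutoff.** The default `wgani` mode follows the two-step rule:
pairs are gated on AF ≥ 85%, then whole-genome ANI — wgANI = ANI × AF,
an identity estimate over the shorter genome's full length — is compared
with the derived cutoff `wgani_cutoff()` = 95 × 85 / 100 = 80.75%. This
admits pairs such as 90% ANI on 100% AF. The alternative `plain` mode
(AF gate, then ANI ≥ 95% directly) is provided because the one-line
phrasing of the thresholds is also a defensible reading; every plain
pass is a wgani pass, never the reverse.

**Clustering** is greedy: genomes sorted by length (longest first, ties
by id), each joining the first existing cluster whose representative it
passes the cutoff with, else founding its own. Sorting plus the tie rule
make the result independent of input order, and representatives are
always the longest member — a proxy for the most complete genome, chosen
because the standard is silent on representative choice. Genomes under
10 kb trigger a warning: short fragments give unstable ANI/AF estimates
(see the fragmentation experiment below) and the usual practice is to
cluster contigs ≥ 10 kb.

## The synthetic generator

`simulate_genomes()` emulates exactly what the downstream operations
consume: random genomes at a stated GC content, planted terminal repeats
(the last `repeat_len` bases overwritten with a copy, direct or reverse
complemented, of the prefix), and planted vOTUs whose members derive
from a common ancestor by iid substitutions at a stated per-site rate,
transitions and transversions equiprobable. A single integer seed makes
every output byte-identical across runs. Defaults, chosen once as
realistic study conditions: genome lengths uniform in 10–50 kb (the
large majority of known virus genomes are well under 100 kb, and ≥ 10 kb
is the usual clustering substrate), GC 0.5, repeat length 40 bp,
within-vOTU divergence 2% (safely inside the 95% ANI species radius),
and unrelated random genomes between vOTUs.

What it does *not* emulate — and hence what passing tests do and do not
show: no indels or rearrangements (real within-species pairs have them;
the engine's ungapped windows would then undercall ANI slightly), no
repeat-driven misassembly, no chimeras, no compositional structure
(real genomes have skewed, autocorrelated composition that makes chance
window hits slightly more likely than in iid sequence), and mutation is
single-step so realized divergence equals the planted substitution count
(no back-mutation correction is needed by the oracle). Truth-recovery
results on this generator demonstrate correctness of the algorithms
under their stated model, not performance on real data.

`fragmentation_bias_experiment()` reproduces, at desk scale, the
observation that wgANI estimated from a partial genome can deviate
substantially from the complete-genome value: fragments of stated
lengths are cut uniformly from one member of each related pair
(complete-genome wgANI ≥ 70%, mirroring the pair-selection rule of the
original experiment) and compared with the other, complete member. The
deviation |wgANI_fragment − wgANI_complete| is pure sampling error of
local divergence, so its mean shrinks as fragments grow, and a
full-length fragment reproduces the complete value exactly. We report
the synthetic analogue of the deviation distribution without asserting
the magnitude observed on real reference pairs (up to ~50%), which
depends on the empirical pair set.

## Numerical choices and edge cases

- Problem sizes in the test suite — 20-kb genomes for ANI recovery at
  mutation rates 1/5/10% over 20 seeded replicates, 30 genomes in 10
  planted vOTUs for clustering recovery, 20 fragment replicates per
  length for the bias experiment — are the package's chosen desk-scale
  study conditions; all expected values are computed by independent
  oracles (exhaustive repeat enumeration, direct mismatch counts) rather
  than asserted from prior runs.
- Empty FASTA files parse to an empty set with a warning; duplicate ids
  are a hard error naming the id; IUPAC ambiguity codes collapse to `N`
  (with a warning) so the alphabet stays closed for the engine, which
  treats `N` as a mismatch everywhere.
- Completeness with no usable evidence is `NA`, never 0: "unknown" and
  "empty" are different statements, and `NA` routes the genome to the
  fragment tier via the no-size-estimate rule.
- `compute_ani_af()` orders each pair internally (shorter first, ties by
  lexicographic id) so the comparison is symmetric; equal-length
  identical calls return identical rows regardless of argument order.
- Window mapping ties (equal mismatch count at several offsets) resolve
  to the smallest offset on the forward strand — deterministic output
  for repetitive targets.
- Tier boundaries use `>=` comparisons, so exactly 90.0% completeness
  is a high-quality draft and exactly phred 20 is *not* sufficient
  (the rule is strictly greater than 20).

## Known limitations

- No contamination estimate: the standard deliberately omits one for
  UViGs (no tool or marker set exists), and so does this package.
- Genus/family-rank classification, marker-gene taxonomy, host
  prediction and functional annotation are out of scope; the checklist
  only records which tools were used.
- The ANI engine targets genome-scale comparisons at the species
  radius; it is not a general-purpose aligner, and AF from highly
  rearranged pairs reflects the window convention described above.
- Provirus boundary detection is not performed; an integration site is
  accepted as a metadata flag only.
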