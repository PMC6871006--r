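# uvigkit

Quality assessment, metadata validation and species-rank clustering for
**uncultivated virus genomes (UViGs)** — virus genomes assembled from
metagenomes, metatranscriptomes, proviruses in microbial genomes, or
single-virus sequencing, without isolating the virus in culture.

Most newly described viruses are now known only as UViGs, and community
reporting standards define how such genomes should be described: a
checklist of mandatory metadata, a three-tier assembly-quality scheme, and
a common species-rank clustering rule. `uvigkit` turns those standards
into working software:

- **Metadata validation** — a machine-readable checklist schema (eight
  mandatory fields with controlled vocabularies, open optional fields),
  record validation with per-field violations, and serialization to TSV,
  JSON or INSDC-style structured-comment blocks.
- **Terminal repeats** — detection of direct terminal repeats (DTR, the
  assembly signature of a circular genome) and inverted terminal repeats
  (ITR), the sequence-level evidence for calling a genome *predicted
  complete*, plus a plausibility check for suspiciously short circular
  contigs.
- **Completeness and quality tiers** — expected genome length from
  per-taxon reference statistics (mean and coefficient of variation
  CV = sd/mean, flagged when CV > 0.10), completeness as
  100 × observed/expected, and assignment to *genome fragment(s)*
  (< 90% or no size estimate), *high-quality draft genome* (≥ 90% or
  predicted complete; single-read genomes additionally need mean
  phred > 20, i.e. > 99% base-call accuracy) or *finished* (single
  gapless sequence, complete, extensively curated).
- **ANI/AF and vOTU clustering** — window-based average nucleotide
  identity (ANI) and alignment fraction (AF, relative to the shorter
  genome), with the species-rank cutoff of **95% ANI over 85% AF**. The
  default mode applies the AF ≥ 85% gate first and then compares
  whole-genome ANI, wgANI = ANI × AF, against the derived cutoff
  95 × 85 / 100 = **80.75%** (so 90% ANI on 100% AF passes). Greedy,
  order-independent clustering into virus operational taxonomic units
  (vOTUs) with longest-member representatives.
- **Synthetic benchmark** — a seeded generator of virus-like genomes with
  planted termini, planted vOTUs at known divergence, and random
  sub-fragments, plus a fragmentation-bias experiment quantifying how
  partial assemblies distort wgANI.

## Worked example

Simulate a small cohort — one planted vOTU of two genomes at 2%
divergence plus two unrelated genomes, one genome carrying a DTR — then
compare, cluster and classify:

```r
library(uvigkit)

sim <- simulate_genomes(sim_config(seed = 42, n_genomes = 2,
  length_range = c(15000, 25000), dtr_fraction = 0.25,
  votu_plan = list(c(2, 0.02))))

compute_ani_af(sim$genomes[1, ], sim$genomes[2, ])
#>     query_id  target_id      ani  af   wg_ani passes
#> 1 votu01_m01 votu01_m02 97.77621 100 97.77621   TRUE
```

The two vOTU members align end to end (AF 100%) at 97.8% identity —
close to the planted 2.1% realized divergence — and pass the species
cutoff (wgANI 97.8 ≥ 80.75). Clustering recovers the plant:

```r
cluster_votus(sim$genomes, min_length_warn = 0)
#> <votu_clustering: 4 genome(s) in 3 vOTU(s) at ANI 95% / AF 85% (wgani mode)>
```

The DTR-bearing genome is predicted complete and tiers as a
high-quality draft (it lacks the manual-curation flags required for
"finished"):

```r
uv <- group_contigs_to_uvigs(sim$genomes)
tt <- detect_termini(sim$genomes)
cmp <- estimate_completeness(uv[[1]], tt)
cmp
#> <completeness votu01_m01: method=dtr, observed=24,148 bp, predicted complete>
classify_quality(uv[[1]], cmp)
#> <quality_tier votu01_m01: high_quality_draft>
#>   - predicted complete (dtr evidence)
#>   - complete but lacking curation flags
```

`run_pipeline()` chains all of the above (validate → termini → quality →
cluster) into one per-UViG report plus a manifest of every threshold
used; `inst/scripts/uvigkit` exposes the same steps as a command-line
tool (`uvigkit run --fasta in.fna --metadata meta.tsv --out-dir out/`).

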