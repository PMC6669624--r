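---
title: "Comparative variant analysis of closely related viral isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative variant analysis of closely related viral isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Wild-collected isolates of large dsDNA viruses such as the *Cydia pomonella*
granulovirus (CpGV) are rarely clonal: a single field isolate is typically a
mixture of closely related genotypes. Characterising a new isolate therefore
involves two distinct comparisons:

* **between isolates** — single-nucleotide polymorphisms (SNPs) between the
  consensus genomes of the new isolate and a panel of fully sequenced
  relatives, scanned column by column on a whole-genome multiple alignment;
* **within the isolate** — single-nucleotide variants (SNVs) among the
  sequencing reads of the new isolate mapped against its own consensus,
  revealing the genotype mixture.

Cross-referencing the two lists is the informative step: an intra-isolate SNV
that sits exactly on a SNP column *unique* to the focal isolate, with the
variant base equal to the base all other isolates carry, is evidence that one
of the genotypes in the mixture resembles the wider panel rather than the
consensus. `isovar` implements both scans, the cross-reference, codon-level
effect annotation, ORF-table comparison, and a distance-based phylogeny, plus
a synthetic-cohort generator with a complete truth ledger so that every stage
can be validated without any external data.

# The SNP scan and its filter

`scan_snp_columns()` reports an alignment column if and only if **no isolate
has a gap in that column** and at least two distinct symbols occur.
"Undisrupted by indels" is read minimally: the column itself must be
gap-free, but flanking gaps do not disqualify it. A stricter exclusion zone
is available through `indel_window` (default 0 columns), which removes all
columns within the given radius of any gap-containing column.

Uniqueness attribution (`classify_uniqueness()`) treats every symbol as an
opaque token: an isolate is attributed when its symbol occurs in no other
isolate. Consequences of the opaque-token choice:

* IUPAC ambiguity symbols never match their constituent bases (`Y` is not
  `C`); a column like `(T, C, C, Y, C, C)` attributes both the `T` and the
  `Y` carrier. The bundled published CpGV tables count such footnoted columns
  among the focal isolate's unique SNPs, which forces exactly these
  semantics; expanded-set semantics would demote them.
* a column can be attributed to several isolates at once (each carrying a
  private symbol), or to none (two symbols, each shared by two or more
  isolates — still a SNP, class `"shared"`).

One column yields one record regardless of how many isolates it is
attributed to; attribution multiplicity is reported separately
(`n_attributed`), so summaries can count either way.

Pairwise identities are frequency-free consensus comparisons:
`100 * (1 - differing / shared)` over the columns where both isolates are
ungapped, reported to 2 decimal places. The read-level minimum-frequency
threshold deliberately plays no role here: with one consensus per isolate a
frequency has no column-level meaning.

# Coordinates

Every interface is 1-based inclusive: SNP tables, GFF3 CDS features, SAM
positions, pileups. `lift_coordinate()` moves positions between isolate
frames through the alignment; lifting into a gap returns `NA`, and the
round trip is the identity whenever neither direction hits a gap.

# ORF scanning, effects and comparison

`scan_orfs()` enumerates start-codon-to-stop frames on both strands under the
standard genetic code, keeps frames of at least `min_aa` amino acids
(default 50 — the conventional floor below which a frame is regarded as
absent), and resolves same-strand overlaps to the longest frame. Translation
length excludes the stop codon, so a complete ORF of `n` nt encodes
`n/3 - 1` aa.

`annotate_effect()` reports substitutions in the focal-to-other direction
("`I -> T`" means the focal genome encodes I where the compared sequence
encodes T), with classes synonymous / nonsynonymous / nonsense / stop_loss /
noncoding. A codon containing an ambiguity symbol is `"indeterminate"`,
never a substitution call. Reverse-strand codons are read on the reverse
complement; a property test asserts strand symmetry by comparing annotation
on a genome and on its reverse complement at mirrored coordinates.

`annotate_indel_effect()` applies the event and retranslates from the
unchanged start codon: in-frame events report the amino-acid delta,
stop-disrupting events the extension to the next in-frame stop, frameshifts
the new product length. Events overlapping the start codon, or not fully
inside the ORF, are flagged `"complex"` with no length claim.

`compare_orf_tables()` maps orthology purely by coordinate lift through the
whole-genome alignment (no homology search): a focal ORF matches a reference
ORF when their extents overlap by at least half of the shorter one. One
focal ORF that is the best match of several reference ORFs is a fusion;
several focal ORFs inside one reference extent are a split; no focal ORF of
at least `min_aa` aa is an absence; a reference extent lifting entirely into
gaps is `"unalignable"`. Truncations report
`percent lost = 100 * delta / reference aa`, rounded to one decimal.
Whether the stop codon belongs in the denominator is genuinely
underdetermined for the published percentages, so both conventions exist
behind `stop_in_denominator`; the default excludes the stop, which matches
the worked 159-aa-of-190 example at 83.7%.

# SNV calling

The caller is deliberately exactly the frequency-threshold rule, not a
genotype-likelihood model: every (position, alternate base) pair with
frequency at least `min_frequency` and coverage at least `min_coverage` is a
record, so tri-allelic sites yield two records. Choices worth stating:

* `min_frequency = 0.1`, **inclusive** at the boundary (10 alternate reads
  out of 100 is a call).
* frequency is alternate count over total coverage, where coverage counts
  aligned bases **plus deletions** (a deleted base still represents a
  spanning read).
* `min_coverage = 10` is a safety floor for synthetic edge cases; real
  deep-coverage data sits far above it. At low coverage a single sequencing
  error can reach the 0.1 floor (1 error in 10 reads), which is the expected
  behaviour of the rule, not a defect of the implementation — at the
  validated coverage of 2000 the binomial tail for a false call is below
  1e-12.
* strand is not tracked; no strand-bias filter is applied.
* insertion/deletion evidence at read level is handled by
  `indel_site_evidence()` (raw counts of spanning reads with and without the
  event), not emitted as SNV records.
* each aligned base counts once; overlapping mates of one fragment
  contribute two observations. This slightly correlates counts at a site
  (at most a factor of two in variance), which the validation tolerances
  account for.

# Cross-referencing SNVs with SNPs

Each SNV gets exactly one class: `no_overlap` (its position is not a SNP
column), `snp_overlap` (position match only), or `unique_snp_overlap`
(the column is attributed uniquely to the focal isolate **and** the
alternate base equals the base the non-focal isolates carry). "The base the
others carry" defaults to strict mode — all non-focal isolates must agree —
because the evidence reading is that a hidden genotype matches *the* panel
base; a majority mode is provided for columns where the panel itself is
split. The mixture report then brackets the focal isolate's genuinely unique
SNP count: every unique-overlap SNV may instead reflect a genotype carrying
the panel base, so the count ranges from `unique - n(unique_snp_overlap)` to
`unique`.

# The phylogeny

Distances are raw p-distances over pairwise gap-free columns — no
multiple-hit correction, since divergences in this regime are below 4% and
the published workflow names none. The tree is standard neighbor joining
(taxa sorted lexicographically first so ties break deterministically;
negative branch estimates clamped to zero) refined by a minimum-evolution
hill-climb: at each round all nearest-neighbor-interchange neighbors are
scored by total OLS branch length and the best strictly-improving move is
taken. The objective never increases; the refinement stops at a local
optimum or `max_rounds`.

Bootstrap resampling is implemented as multinomial reweighting of the
distinct column patterns (equivalent to resampling columns, far faster),
rebuilding the tree per replicate with the same NJ+ME procedure, and scoring
each internal bipartition of the reference tree. Internal edges of zero
length in a replicate are treated as unresolved, so an alignment of
identical sequences reports no supported bipartitions rather than a
spuriously certain star. Supports are invariant to isolate input order
because taxa are sorted internally.

`annotate_snp_counts()` writes the published-figure-style annotations: each
leaf gets its unique-SNP count; each internal node the number of
synapomorphic columns (all clade members share one symbol absent outside the
clade). On an unrooted tree each internal edge is scored on its stored child
side, which folds the two directions of the deepest split together; rooting
on an outgroup (`write_annotated_tree(..., outgroup =)`) gives proper clade
counts. Counting all columns partitioning a clade (rather than
synapomorphies) was considered and rejected as the default because it double
counts ancestral states; the synapomorphy definition is the one a reader of
per-clade annotations expects.

# The synthetic cohort generator

`cohort_spec()` fixes the study conditions everything is validated under:

| parameter | default | meaning |
|---|---|---|
| genomes | 6 × 120 kb | panel size and genome scale of the CpGV system |
| tree | balanced, rooted binary | `((i1,i2),((i3,i4),(i5,i6)))` |
| substitutions | 50 per branch | planted exactly; tens of unique SNPs per isolate |
| indels | 5 per branch, 1–30 bp | uniform positions and lengths |
| ORF density | 0.89 | coding fraction of the ancestor |
| mixture | g1 0.7 / g2 0.3 | read-level genotype mixture of the focal isolate |
| genotype 2 | reverts 11 unique + 20 shared substitutions, 35 private, lacks 1 insertion | 66 true SNV sites mirroring the published table structure |
| reads | paired 2 × 250 bp, fragments 500 ± 50 | MiSeq-like geometry |
| error | 0.0024 per base | uniform, quality-independent |
| coverage | 2000× | deep-coverage regime |

Design notes:

* **Per-branch counts are planted exactly**, not Poisson-sampled: branch
  lengths are read as event counts, which makes the ledger a sharp oracle.
  Substitution positions are uniform without replacement and avoid the
  branch's own indel intervals; indels resample on overlap (logged).
* **Alignment bookkeeping is by persistent site identifiers**: every
  ancestral position is a site, insertions mint fractional site ids between
  their neighbors, deletions remove sites. The union of surviving sites,
  ordered, *is* the true multiple alignment — no aligner runs anywhere. The
  ledger replay test reconstructs every leaf byte-exactly from the ancestor.
* **The mixture is realised at the read level** (each fragment draws a
  genotype), the way a mixed-genotype isolate actually presents in read
  data, rather than by pre-mixing sequences.
* **Quality strings are constant Q37** with errors injected independently of
  quality: the analysis consumes base identities only.

What the generator deliberately does **not** emulate: recombination,
structural rearrangement, alignment error (the truth alignment is exact,
whereas real aligner output is parameter-sensitive), quality-score
structure, coverage biases (GC, mappability), and mapping artefacts.
Passing the validation suite therefore demonstrates the correctness of the
bookkeeping and calling logic under the stated statistical model — it does
not certify behaviour on misaligned or bias-ridden real data, where the
alignment itself dominates the SNP totals.

# Problem sizes in the test suite

Most tests run on 3–5 kb cohorts at coverage 30–2000 so the whole suite
stays fast; the validation block additionally runs one full-scale cohort at
the study conditions above (120 kb, ~960,000 reads) and checks: exact
recovery of all planted SNP columns with their attributions, exact per-leaf
and per-clade branch counts, recall of planted SNVs at true frequency
≥ 0.15 with zero false calls, and site-by-site agreement of the overlap
classes with the generator's intent. Tree inference is validated by
generating-topology recovery on additive matrices up to 8 taxa, exhaustive
least-squares enumeration on 4 taxa, and a 100-matrix non-increase property
for the minimum-evolution objective.

# Known limitations

* The SNP scan consumes one consensus per isolate; within-isolate ambiguity
  enters only through IUPAC symbols already present in the consensus.
* Orthology by coordinate lift assumes the whole-genome alignment is
  broadly colinear; rearranged genomes would need a homology search, which
  is out of scope.
* The SNV caller has no error model beyond the frequency threshold; at
  coverages below ~100 the 0.1 threshold stops being conservative.
* p-distances are uncorrected; for divergences beyond ~10% a model-based
  correction would be preferable.
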