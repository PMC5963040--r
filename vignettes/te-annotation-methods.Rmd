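---
title: "De novo TE annotation with TEforge: models, rules and design choices"
author: "TEforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo TE annotation with TEforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Transposable elements (TEs) are mobile DNA sequences that can occupy large
fractions of eukaryotic genomes. Annotating them de novo in a newly
assembled genome is hard because no single detection principle covers all
element types: similarity search finds only what resembles a databank
entry, structural mining finds only elements with intact termini, and
repetitiveness-based methods find only families with enough copies.
TEforge implements a combination architecture: four complementary
detection approaches feed a shared curation, classification, family
building and annotation chain, and the whole chain is testable end to end
on synthetic genomes with planted elements.

The intended user is a genome-project bioinformatician who needs (i) a
repeat library for masking and downstream annotation, (ii) an inventory of
TE orders and superfamilies with genome proportions, and (iii) a shortlist
of potentially active autonomous families worth experimental follow-up.

# Pipeline model

The pipeline mirrors a three-step design:

1. **Detection** (four approaches):
   - *similarity*: seed-and-extend nucleotide search of a classified TE
     databank against the genome (`detectSimilarityNT`), and protein-domain
     search of consensus peptides (reverse transcriptase RT, integrase INT,
     endonuclease EN, transposase TASE) against six-frame translations
     (`detectSimilarityProt`);
   - *structural*: direct-repeat pairs with a target-site duplication (TSD)
     for LTR retrotransposons (`detectLTRPairs`), terminal inverted repeats
     with TSD for MITE-size elements (`detectTIRMite`), and poly-A tailed
     spans with TSD for SINEs (`detectSINE`);
   - *repetitiveness*: genome-wide repeated k-mers merged into instances,
     clustered, and collapsed to majority-vote consensi
     (`detectRepetitive`);
   - *read-based*: high-abundance k-mers from unassembled reads, greedily
     assembled by unique (k-1)-overlap (`detectFromReads`).
2. **Curation and classification**: similarity and read-based detections
   below 500 bp are removed; exact-containment redundancy is collapsed
   (CD-HIT-est semantics at 100% identity over 100% of the shorter
   sequence, both orientations); MITE/SINE detector output is routed
   directly to the non-autonomous bin; everything else passes an explicit
   Wicker rule cascade (below). Families are built per superfamily under
   the 80-80-80 rule with Markov clustering (inflation 1.5).
3. **Annotation**: three nested ("Russian doll") libraries — autonomous
   family representatives ⊆ total TEs (adding non-autonomous entries) ⊆
   repeated elements (adding uncategorized repetitiveness consensi) — are
   each annotated independently in two passes: a first pass keeps
   full-length-copy (FLC) entries (library coverage ≥ 0.95), a second pass
   annotates with the FLC subset and resolves overlaps by score. Genome
   proportions are unions of per-category intervals over total genome bp.

Annotating the three libraries independently avoids a competition effect:
if all entries competed in one run, a non-autonomous fragment could
displace the autonomous element that explains it, and the per-library
proportions would no longer be comparable. The report derives
non-autonomous % = total TE % − autonomous % and uncategorized-repeat % =
repeated % − total TE %, and `repeatContentSummary()` combines them with
externally computed simple-repeat and coding proportions.

# The classification cascade

The classifier replaces an opaque scoring engine with a priority cascade
that encodes the autonomy definitions explicitly. Rules fire in order; the
first match wins:

1. RT ∧ INT domains ∧ similarity to a known LTR element → autonomous LTR.
2. RT domain ∧ similarity to a known LINE element → autonomous LINE.
3. transposase (TASE) domain → autonomous TIR; TIR similarity *with a
   coding ORF (≥ 300 bp)* also qualifies. The weaker reading — TIR
   similarity alone — would label non-coding MITE relics autonomous, so the
   ORF condition is required; this is a deliberate reading of an "or" that
   is ambiguous in its source formulation.
4. direct terminal pair ∧ no domains → TRIM (≤ 4 kb) or LARD (> 4 kb).
5. inverted terminal pair ∧ no ORF ∧ ≤ 800 bp → MITE.
6. poly-A tail ∧ TSD evidence ∧ SINE-range length ∧ no domains → SINE.
7. similarity-only inheritance (≥ 80% identity, ≥ 50% subject coverage):
   the subject's order is inherited; autonomy is granted only when the
   order-appropriate domain is also present.
8. otherwise noCat / uncategorized.

Superfamily is assigned by score-weighted majority over similarity hits
restricted to the assigned order. A plain subject-count majority would
mis-assign when conserved domain regions (shared RT/INT blocks) cross
superfamilies, so hits are weighted by alignment score.

# One aligner, one scoring scheme

Every nucleotide comparison in the package — similarity detection,
evidence extraction, family graphs, annotation, coverage scoring — uses a
single seed-and-extend aligner: exact 12-mer seeds grouped on
near-constant diagonals, then affine-gap local extension under match +2,
mismatch −3, gap open 5, gap extend 2. `N` never matches anything,
including itself. Two numerical details matter:

- *Windowed extension*: the dynamic program runs over the seed-covered
  query region plus a 150 bp margin, not the full query, so a short domain
  match inside a long library entry does not trigger a full-length
  quadratic alignment.
- *Diagonal fast path*: when the dominant diagonal of a seed cluster spans
  ≥ 90% of the cluster's query extent, the best gap-free local alignment is
  computed exactly in linear time (maximum-scoring subarray on the
  diagonal). With the affine gap open of 5, a gap-free optimum is also the
  unrestricted optimum whenever the underlying copy has no indels; when
  the diagonal solution fails the identity or length thresholds the full
  dynamic program runs instead. Divergence in the synthetic data is
  substitution-only, so the fast path is exact there; on indel-rich real
  data the fallback engages.

Identity is BLAST-style: matching columns over all alignment columns, gap
columns counting against.

Global alignment with free end gaps (used only for family mean pairwise
identity) delegates to `Biostrings::pairwiseAlignment(type = "overlap")`
under the same substitution scores; terminal gap blocks are excluded from
the identity denominator, matching the "free end gaps" convention of
interactive alignment viewers.

# The synthetic-data generator

`teTemplateCatalog()` fixes the study conditions: ten families — Copia and
Gypsy (LTR; identical 200/300 bp LTRs, RT+INT), L1 (LINE; EN+RT, 16 bp
poly-A), hAT, Mariner, Harbinger, PiggyBac (TIR; 13–30 bp inverted
termini, TASE) and non-coding MITE (400 bp), SINE (250 bp, 12 bp tail),
TRIM (900 bp, 120 bp LTRs). Element lengths and terminal structures follow
the conventional ranges for each superfamily. Copies are planted into an
i.i.d. uniform ACGT background with a freshly sampled TSD per insertion
(TSDs are a property of the insertion event, not the family), per-copy
point mutations at the requested divergence, optional truncation to a
20–60% prefix, and a random strand. Everything is deterministic given the
seed, and any subset of the catalogue realizes identically because
per-family seeds derive from the family id.

Domain consensi are generated, fixed 64-mers carrying the canonical short
catalytic motifs of each domain class (LPQG/YMDD for RT, D..D..E-like
triads for INT and TASE, GDxN for EN); they stand in for profile-HMM
databanks at desk scale. Reverse translation uses one fixed codon per
amino acid, so a shared domain yields an identical nucleotide block in
every family that carries it — this is what lets similarity rules operate
across families, the way conserved domains do in real databanks. Each
transposase ORF additionally carries a 60-residue family-specific segment;
simulated peptides are drawn from that segment (not from the shared TASE
core) so that peptide evidence resolves families. Expressed-family
transcript intervals extend 2.5 kb past the element boundaries,
emulating transcriptional read-through; annotated copies that carry
modest detector flanks therefore still show full coverage, while silent
copies stay below 50%.

What the generator does **not** model: GC content and compositional
heterogeneity, indel divergence, nested insertions, sequencing error,
paired-end structure, segmental duplications, tandem/satellite repeats,
and real phylogenetic structure within families. Green tests on synthetic
genomes therefore demonstrate the machinery's correctness under its
stated contracts, not field performance on real assemblies — in
particular, real-data family fragmentation (as seen in highly diverged
hAT populations) and satellite-driven false positives are outside what
these tests can show.

# Benchmarking and evaluation

`coverageScore()` computes, per reference consensus, the fraction of the
*reference* length covered by the union of local alignments with a
detected sequence — detected-sequence coverage is deliberately not used,
since a long chimeric detection should not score higher than a clean one.
Families scoring below 0.40 count as undetected, 0.40–0.70 as partial,
≥ 0.70 as complete. `assessClassification()` scores order-level agreement
(MITE/TRIM/LARD counting as their own orders) with half-up integer
percentages; `approachContribution()` credits, for each detected family,
the approach that produced its best-covering sequence (ties: longer
sequence, then smaller id). Excluded reference entries are handled by an
exclusion-list argument rather than hard-coding.

# Parameters

All thresholds live in `teConfig()`; the load-bearing ones:

| parameter | default | meaning |
|---|---|---|
| `min_detected_len` | 500 bp | length filter on similarity/read-based detections; boundary kept |
| `partial_cov` / `complete_cov` | 0.40 / 0.70 | benchmark status thresholds on reference coverage |
| `flc_cov` | 0.95 | library coverage for full-length-copy selection (conventional FLC cutoff) |
| `family_identity` / `family_coverage` / `family_min_len` | 0.80 / 0.80 / 80 bp | the 80-80-80 family rule |
| `mcl_inflation` | 1.5 | Markov clustering inflation |
| `expressed_cov` | 0.90 | transcript coverage for the expressed flag |
| `trim_lard_boundary` | 4000 bp | TRIM vs LARD size boundary |
| `mite_max_len` | 800 bp | MITE detector / rule size cap |
| `ltr_min`–`ltr_max`, `ltr_elem_min`–`ltr_elem_max`, `ltr_identity`, `ltr_tsd` | 100–1000 bp, 1–15 kb, 0.85, 4–6 bp | LTR pair detector, mirroring the documented conventions of structural LTR miners |
| `tir_min`, `tir_tsd` | 10 bp, 2–10 bp | TIR/MITE detector |
| `sine_len_range`, `sine_min_tail`, `sine_tsd` | 80–600 bp, 8 bp, 7–10 bp | SINE detector; the TSD floor of 7 bp keeps the background false-positive rate of short exact TSD matches near zero |
| `repeat_k`, `repeat_min_copies` | 16, 3 | repetitiveness detector |
| `reads_k`, `abundance_factor` | 21, 5 | read-based detector |
| `domain_min_score` | 100 | BLOSUM62 score floor for a domain hit |
| `orf_min_len` | 300 bp | ORF floor for coding evidence |
| `terminal_arm_min`, `terminal_identity` | 20 bp, 0.80 | terminal repeat scan in evidence extraction |
| `chain_gap` | 500 bp | co-linear fragment chaining in annotation |

Degenerate inputs are handled conservatively: empty genomes/libraries
yield empty results (not errors); library entries absent from the genome
simply produce no intervals; ties everywhere break deterministically
(score, then length, then lexicographic id).

# Design choices where the design was open

- **Coordinates.** Internally everything is 1-based inclusive
  (GRanges/IRanges convention), so GFF3 emission is direct and BED emission
  converts on write. An earlier draft used 0-based half-open internally;
  the Bioconductor convention was chosen so that users can manipulate
  annotation output with stock GenomicRanges operations without conversion.
- **Redundancy semantics.** Only *exact* containment is removed at
  curation; near-duplicates are left to family clustering. A looser rule
  would silently merge diverged copies before classification sees them.
- **Library headers.** Entries are written with Wicker 3-letter codes plus
  a free-text suffix (`RLC_copia1`); MITE/TRIM/LARD, which have no Wicker
  code, use package codes (`DMM`, `RLT`, `RLD`) that parse back through
  `parseWickerCode()`.
- **Overlap resolution.** Higher alignment score wins; losers are trimmed
  to their non-overlapping remainder and kept only if ≥ 80 bp survives.
  This is an artifact rule (the source selection criteria were not
  available); it is deterministic and conservative.
- **Non-autonomous inheritance entries.** Classified non-autonomous
  entries of any order enter the total library (with the LARD restriction
  to the repetitiveness approach); this generalizes the explicit
  SINE/MITE/TRIM listing to the inheritance rule's output.
- **Manual curation steps** of the original design (family review, the
  selection of annotated copies) are replaced by deterministic filters, so
  reruns are reproducible.
- **Problem sizes.** The bundled study conditions use a 2 Mb two-contig
  background with 5–20 copies per family at 2% divergence and 10%
  fragmentation, with 4× simulated read coverage; module tests use a 150 kb
  five-family world at zero divergence. These sizes were chosen as the
  smallest at which every approach has a realistic substrate (the
  read-based k-mer histogram needs genuine coverage; repetitiveness needs
  ≥ 3 copies surviving fragmentation).

# Known limitations

- Helitron and Maverick structural detection is not implemented; Helitrons
  classify only via similarity inheritance. LINE-specific structural
  detection is likewise delegated to the domain + similarity routes.
- The MITE detector's inverted-seed anchoring needs two 10-mer seeds, so
  TIR arms shorter than 11 bp are not recoverable at the default seed size.
- The diagonal fast path trims gapped hits to their dominant diagonal when
  that diagonal alone already satisfies the thresholds; on indel-rich data
  coverage estimates can be slightly conservative.
- Family fragmentation under heavy divergence is expected behavior (the
  80-80-80 rule is strict); representatives of fragments still classify
  and annotate correctly, but family counts are not comparable across
  divergence regimes.
- Simple/tandem repeat annotation is out of scope; its genome proportion
  enters `repeatContentSummary()` as an externally computed input.
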