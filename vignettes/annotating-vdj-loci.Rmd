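---
title: "Directed annotation of IG/TR V, D and J genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed annotation of IG/TR V, D and J genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Immunoglobulin (IG) and T cell receptor (TR) loci contain clusters of
highly similar V, D and J gene segments.  A segment is only usable by the
recombination machinery if its flanking regulatory features are intact: a
recombination signal sequence (RSS) consisting of a conserved heptamer
(canonically `CACAGTG`) and nonamer (canonically `ACAAAAACC`) separated by
a 12 or 23 nt spacer; for V genes additionally a two-exon leader peptide
(L-PART1, L-PART2) with GT/AG splice dinucleotides; for J genes the
conserved [W/F]-G-X-G "J-motif" and a GT donor splice after the J-REGION.
Annotation therefore has two halves: *finding* gene segments, and *judging*
them — Functional, ORF (open reading frame with a defective regulatory
hallmark), or pseudogene (coding defect).

`vdjannot` implements directed annotation: genes are found by nucleotide
similarity to a germline reference set of known alleles, not de novo.  This
deliberately trades sensitivity to entirely novel genes for precision and
full feature-level reporting.

## The pipeline

1. **Similarity search.**  Reference alleles are searched against the
   assembly (one sense at a time).  V searches use word size 11 with gap
   open 5, gap extend 5, mismatch penalty −1 and e-value cutoff 10; D and J
   searches reduce the word size to 7, and D raises the cutoff to 100
   because D-REGIONs can be as short as 8 nt.  Either BLAST+ (`blastn`) or
   a built-in k-mer seed-and-extend aligner with the same word sizes and
   penalties can be used.  The internal backend ranks hits with a
   Karlin–Altschul-style e-value surrogate (λ = ln 3, K = 0.33, the
   ungapped solution for the +1/−1 scoring pair); only the ordering of
   these values matters downstream, and they are documented as approximate.
2. **Consolidation.**  Hits of one gene type whose assembly intervals
   overlap are grouped transitively; within a group the best hit wins by
   the ordered key (match fraction rounded to 2 decimals, e-value, aligned
   length, allele name).  The rounding keeps near-identical coverage from
   being separated by alignment noise; the name makes the result
   deterministic.  The winner is extended to full allele length using the
   hit's allele offsets, clamped at assembly edges with a truncation note.
3. **Feature localisation.**  Motifs are modelled as position weight
   matrices (PWMs).  The RSS is located by exhaustively maximising the
   *joint* log-likelihood of heptamer and nonamer over all placements with
   the spacer within its configured tolerance; the spacer contributes a
   placement constraint but no probability term, and the two motifs are
   weighted equally.  The V-REGION 3′ end is adjusted to meet the located
   heptamer (by default it may move up to 10 nt back or 40 nt forward).
   The leader search fixes L-PART2 as the 11 nt window ending at the
   V-REGION start (preceded by an AG acceptor) and enumerates L-PART1
   windows followed by a GT donor within 500 nt; placements whose spliced
   leader starts with ATG, is stop-free and is in frame with the V-REGION
   are preferred categorically, with joint PWM likelihood breaking ties.
   The J-motif is sought as an IUPAC pattern (default `TKGGGG`) at a
   configured offset from the J-REGION 3′ end, allowing only
   frame-preserving shifts (±3 nt).
4. **Classification.**  Functionality follows IMGT-style criteria.  For V:
   RSS motifs pass their PWM thresholds and match the canonical consensus
   when one is defined; leader parts pass their thresholds and splice to a
   stop-free sequence in frame with the V-REGION; the V-REGION is in frame
   with cysteines at IMGT positions 23 and 104 and has no stop codon at or
   before 104.  For D: all four RSS motifs must pass their thresholds for
   the candidate to be reported at all, and consensus agreement separates
   Functional from ORF (D genes are never pseudogenes — a D-REGION has no
   reading frame of its own before rearrangement).  For J: RSS thresholds
   and consensus, the J-motif at its expected position, and the GT donor.
   Stop codons strictly after position 104 (V) or upstream of the J-motif
   (J) do not block Functional — their nucleotides may be excised during
   junction formation — but are noted.  Failing V and J candidates are ORF
   when stop-free, otherwise pseudogenes.
5. **Overlap resolution.**  All Functional annotations are retained (mutual
   overlaps are noted, as they are rare in practice).  Non-functional
   annotations overlapping a Functional one are discarded.  Remaining
   non-functional annotations are resolved greedily by joint motif
   log-likelihood: one survives only if it overlaps nothing already
   retained.  Greedy resolution, rather than keeping one annotation per
   transitive overlap group, matters in practice: two genuine disjoint
   pseudogenes can be chained into one "group" by a low-scoring spurious
   candidate lying between them, and only the greedy rule keeps both.

Genes on the minus strand are found by rerunning the whole pipeline on the
reverse complement; hits are never mixed across senses.  Sense merging
happens on input coordinates before overlap resolution.

## PWMs, thresholds and numerical choices

A PWM is built from aligned training motifs with additive smoothing:
entry (i, b) = (count + pseudocount) / (n + 4·pseudocount).  The default
pseudocount 0.1 avoids −∞ scores for bases unseen in training with minimal
distortion.  Scores are natural-log likelihoods; an N base scores
log(1/4), so runs of N are uninformative rather than disqualifying, and
annotations whose feature windows contain N carry a note (draft assemblies
contain gaps).

The pass threshold of a PWM defaults to the *minimum log-likelihood of its
own training sequences* under the finished matrix.  This guarantees that no
motif the matrix was trained on is rejected by its own model; stricter
percentile-style thresholds can be set in the motif files.  Joint
likelihood of a motif pair is the plain sum of the two log-likelihoods.
Ties in placement go to the canonical spacer length, then the leftmost
position, making every search deterministic.

When several candidate framings exist for one locus position, Functional
framings win; otherwise the framing maximising the summed leader and RSS
log-likelihood is kept, with missing components contributing a large
negative sentinel (−10⁵) rather than −∞ so that comparisons stay finite.

IMGT position mapping globally aligns the candidate V sequence to its
closest allele (match +1, mismatch −1, gap open 5, gap extend 2) and
transfers the allele's IMGT gap pattern.  The frame is considered intact
when every indel run in the alignment has a length divisible by 3 — this is
robust to the aligner placing a codon-length gap off the codon boundary.  A
stop codon *at* position 104 counts as "before the second cysteine": it
destroys the cysteine itself.  When no gapped reference is available the
ungapped allele serves as a gap-free alignment and a note records the
lower-confidence mode.  Insertions relative to the reference cannot be
represented in a fixed IMGT frame and are noted.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `v_spacer`, `j_spacer` | 23 nt | RSS spacer for V 3′ and J 5′ RSS |
| `d5_spacer`, `d3_spacer` | 12 nt | RSS spacers flanking D |
| `spacer_tolerance` | 0 nt | allowed spacer deviation (configurable ±1) |
| `rss_search_window` | 40 nt | search beyond the matched gene end |
| `v_end_adjust_max` | 10 nt | max pull-back of the V-REGION 3′ end |
| `d_end_adjust_max`, `j_start_adjust_max` | 5 nt | boundary adjustment for D/J |
| `leader_search_window` | 500 nt | L-PART1 search range upstream of the V-REGION |
| `l_part2_length` | 11 nt | canonical L-PART2 length |
| `j_motif_pattern` | `TKGGGG` | nucleotide start of [W/F]-G-X-G |
| `j_motif_offset` | 34 nt | J-motif start upstream of the J-REGION 3′ end |
| `j_motif_tolerance` | 3 nt | frame-preserving shift allowance |

The window sizes are not dictated by any biological constant; they were
chosen once to cover canonical leader–intron spans and RSS geometry with
slack, and are all surfaced in `locus_config()`.  Non-canonical spacer or
L-PART2 lengths observed in some loci are handled as configuration, not
inference.

## What the simulator emulates — and what it does not

`generate_locus()` builds a miniature heavy-chain-style locus: a V cluster,
then D, then J, separated by i.i.d. uniform intergenic sequence.  Each V
implant gets an ATG-initiated stop-free leader with enforced GT/AG splice
sites, a V-REGION copied from a reference allele, and RSS motifs sampled
from the PWMs with the consensus enforced (rejection sampling, falling back
to the per-position argmax); D implants get RSS on both sides, J implants
an RSS, the J-motif at the configured offset and a trailing GT.  The truth
table records every feature interval in report coordinates.
`implant_defect()` engineers single minimal lesions — broken heptamer or
nonamer consensus, leader stop, leader frameshift, cysteine-104 loss, stop
codons before or after position 104, lost donor GT, shifted J-motif, lost
J splice — each at most 3 substituted nt (or a 1 nt deletion), together
with the classification the criteria dictate.

The synthetic reference alleles are random non-stop codons with cysteines
fixed at positions 23 and 104, and the shipped motif training sets are
synthetic (canonical RSS sequences plus one-mismatch variants, invented
leader exons).  Real loci differ in ways the simulator does not model:
reference alleles are mutually homologous (gene families), intergenic
sequence contains repeats and real pseudogene relics, leaders and introns
vary in length, and PWMs trained on curated alignments are broader.
Passing tests on synthetic loci therefore demonstrates the correctness of
the machinery — search, motif placement, coordinate bookkeeping,
classification logic, overlap resolution — not field performance on real
assemblies, which depends on the quality of the reference set and PWM
parameters supplied by the user.

Uniform random intergenic sequence does produce occasional chance
similarity hits (exactly as BLAST does at these cutoffs, e.g. a chance
13-mer in 100 kb passes a V-search e-value of 10); these surface as
low-likelihood ORF/pseudogene annotations and are the reason overlap
resolution is exercised even on clean simulated loci.

## Problem sizes used in validation

The packaged validation (tests and `scripts/acceptance.R`) uses: 50
simulated loci of ~100 kb with 10 V + 5 D + 5 J intact implants each for
recovery; two replicates of the full 15-pair (gene type, defect) matrix
(30 cases); 200 random paired-motif instances against an exhaustive
brute-force oracle; 500 random overlapping annotation sets for the
resolution laws; 20 loci for strand symmetry; and 10 loci annotated with a
reference set carrying 5% random divergence for cross-reference
robustness.  These sizes keep every property at a scale where the
independent oracles (brute-force enumeration, ground-truth tables) remain
exact.

## Known limitations

* Directed search cannot find genes absent from the reference set; de novo
  RSS scanning is out of scope.
* D genes shorter than the word size (7 nt) would be unfindable; 8 nt is
  the practical minimum.
* The e-value surrogate of the internal backend is approximate; use the
  BLAST+ backend when absolute e-values matter.
* Stop detection after a frameshift reads the IMGT columns, not the
  shifted frame, so a frameshifted V without in-column stops is reported
  ORF rather than pseudogene.
* Genes spanning an assembly edge are truncated with a note rather than
  reconstructed.
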