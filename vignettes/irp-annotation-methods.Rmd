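---
title: "Methods: rule-based annotation of insulin/IGF-related peptide precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based annotation of insulin/IGF-related peptide precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpannot)
```

## The problem

Insulin/IGF-related peptides (irps) are notoriously variable in primary
sequence, yet their precursors share a rigid structural scaffold: a signal
peptide, a B chain with two cysteines, a connecting C peptide, and a
C-terminal A chain carrying the `C-C-x(n)-C-x(m)-C` motif. Around that
scaffold the families diverge in ways that are individually diagnostic:
IGF-type precursors stay single-chain and carry long charged C-terminal
extensions (D and E domains); gonad stimulating substance (GSS) type
precursors are processed into two chains at dibasic convertase sites;
octinsulins carry two extra cysteines (a predicted fourth disulfide
bridge); dilp7 orthologs carry a conserved N-terminal extension of the B
chain (the F domain); multinsulins resemble dilp7 orthologs without the
conserved F domain and with a distinct extra-cysteine placement. Gene
architecture adds an independent axis: all irp genes share a phase-1
intron in the C domain, dilp7-type and multinsulin genes add a phase-2
intron, multinsulin genes a further phase-1 intron, and IGF genes a
phase-0 intron near the end of the CDS. This package turns those
qualitative contrasts into an explicit, configurable and fully tested rule
system.

## Pipeline

`annotate_precursor()` runs the stages in order; each stage consumes only
the outputs of earlier ones.

1. **Cysteine framework** (`find_core_framework`). The A-chain motif is
   sought scanning from the C terminus (the A chain is C-terminal in every
   family considered), then the two B-chain cysteines upstream. Spacing
   bounds generalize the classical vertebrate insulin spacings; an
   assignment earns one point per spacing at its modal value (3, 8 and 12
   residues) and the best-scoring assignment wins, ties going to the most
   C-terminal A motif and then to the most C-terminal B pair. The search
   is exhaustive over candidate cysteine sextets, so a brute-force
   enumeration oracle can check it exactly.
2. **Signal peptide** (`predict_signal_cleavage`). A transparent
   two-component heuristic: the (-3,-1) small-residue rule (one point per
   small residue at the canonical positions) plus the mean Kyte-Doolittle
   hydropathy of the h-region window (positions -13..-6) added when it
   reaches 1.5. Candidate positions 15..35 are scored, the maximum wins,
   ties to the smallest position. This is a deliberately simple,
   documented stand-in for neural-network signal-peptide predictors; a
   user-supplied position always overrides it, and a precursor without any
   positive-scoring position is an error the batch driver reports per
   record.
3. **Convertase sites** (`find_furin_sites`, `find_dibasic_sites`). The
   furin rule is two-tiered: `[KR]-X-[KR]-R` (strong) and `[KR]-X-X-R`
   (relaxed), because the canonical processing sites of the two human IGF
   precursors, KSAR and KSER, satisfy only the relaxed form. Dibasic KR
   sites (and optional RR/KK/RK and monobasic R, all off by default) are
   accepted unless a contextual exclusion fires: bulky residue
   {W,F,Y,I,L,V} or proline at P1', proline at P3/P4, or a core-framework
   cysteine within 3 residues of P1 (steric hindrance by the nearby
   disulfide). Verdicts carry the complete reason trail rather than a
   probability — these are predictions, and the report preserves why each
   site was accepted or rejected.
4. **Domain segmentation** (`segment_domains`). B is anchored at most
   `b_lead = 8` residues upstream of CB1 (or at the nearest accepted
   cleavage boundary); a pre-B region of at least `f_min = 15` residues
   becomes an F domain, anything shorter merges into B. C is the region
   between the accepted sites flanking it (two-chain mode requires both),
   otherwise simply CB2..CA1. A runs from CA1 through CA4; a post-CA4 stub
   shorter than `d_min = 6` residues merges into A (vertebrate insulin has
   a single residue there), a longer extension becomes D up to the first
   accepted furin site and E beyond it. The partition property — ordered,
   disjoint intervals covering the precursor — is asserted in the tests.
5. **Features and family call** (`extract_features`, `classify_family`).
   Feature extraction is threshold-free aggregation; all thresholds live
   in the ordered decision rules, most specific marks first (extra
   cysteines, F domain, charged tail, two-chain residual). Confidence is
   `high` only with at least two concordant marks; gene-structure
   agreement counts as a mark, breaks the GSS/multinsulin tie, and is
   required for a high structural multinsulin call. Extra-cysteine
   placement is matched by containment — the configured diagnostic pair
   must be present — and the residual GSS rule tolerates a single unpaired
   stray cysteine at demoted confidence. Both choices follow from the
   bridge parity rule: an odd cysteine cannot form a bridge, so it is
   flagged (`unpaired_warning`) rather than treated as family evidence,
   and a stray substitution artifact must not veto an otherwise coherent
   call.
6. **Gene structure** (`compute_intron_phases`, `gene_signature`). Intron
   phase is the coding offset modulo 3; an intron inside a codon maps to
   that codon's residue (`aa_pos = offset %/% 3`). "Near the end of the
   CDS" for the IGF phase-0 intron is operationalized as the last 25% of
   coding nucleotides (`genes.igf_tail_frac`). The optional early phase-1
   intron of some IGF genes is not part of the signature, since it is not
   consistently present.

## Tunable parameters

Every threshold is a key in `irp_config()` and overridable from a flat
`section.key = value` file. The ones that matter most:

| key | default | meaning |
|---|---|---|
| `framework.*` | 2..6 / 6..14 / 8..16 / 5..80 | residue-spacing bounds of the cysteine core (A-motif gaps, B-pair spacing, C-domain span) |
| `cleavage.bulky` | `WFYILV` | P1' residues that block dibasic cleavage |
| `cleavage.disulfide_window` | 3 | residues from a core cysteine to P1 that block cleavage |
| `domains.b_lead` | 8 | B-chain residues allowed upstream of CB1 |
| `domains.f_min` | 15 | minimal pre-B length called an F domain |
| `domains.d_min` | 6 | post-CA4 stub below this merges into A |
| `classify.tail_min` | 25 | minimal D+E length for an IGF call |
| `classify.charged_min` | 0.3 | minimal charged fraction of the tail |
| `classify.f_identity_min` | 0.4 | minimal F identity versus references |
| `synteny.max_gap` | 1e6 bp | maximal intra-cluster gap; separates tens-of-kb adjacency from Mb-scale separation |
| `tm.window` / `tm.threshold` | 19 / 1.6 | classical Kyte-Doolittle membrane scan |
| `align.gap_open` / `align.gap_extend` | 11 / 1 | affine gap costs under BLOSUM62 |
| `dist.cap` | 5.0 | ceiling of the Poisson distance as p approaches 1 |

The classification thresholds are calibrated on the synthetic generator:
the underlying biology is described qualitatively in the literature
(tails "rich in charged residues", a "long" N-terminal extension), so the
numeric cutoffs are package conventions, chosen once to separate the
family templates with wide margins and exposed for adjustment on real
data.

## The synthetic-data generator

`make_precursor()` instantiates one hand-built template per family:
a shared 15-residue signal peptide; 26-residue B cores with CB1/CB2 at
the modal 12-residue spacing (8 residues of B upstream of CB1);
21-residue A cores with the modal 3/8 A-motif spacings; family-specific
marks (25-residue F domain for dilp7, extra cysteine pairs for
octinsulin at B-start/post-CA4 and for multinsulin inside C, a 65-residue
charged D+E tail ending in the relaxed furin motif for IGF, clean planted
KR sites flanking C for the two-chain families). Every C domain also
embeds a decoy KR followed by tryptophan, which the bulky-P1' rule must
reject. The IGF/GSS cores derive from one base sequence and the
dilp7/multinsulin cores from another, so similarity trees must recover
those two neighborhoods. The default multinsulin template carries the
extra C-domain cysteine pair (the four-bridge variant): it is the variant
that is structurally classifiable without gene evidence.

Noise substitutes each mutation-eligible position with the given
probability by one of the 19 alternative residues. Cysteines, planted
cleavage motifs and their exclusion contexts are never mutated — noise
probes the robustness of thresholds, not the destruction of the defining
marks — and for a fixed seed the mutated position sets are nested across
rates, which makes recovery-versus-noise curves monotone by construction.
`make_gene_model()` reverse-translates the precursor (fixed codon table,
stop codon included) and splits the CDS so the family's diagnostic intron
phases hold; `make_synteny_layout()` produces the clustered
(octinsulin-IGF-IGF-dilp7 adjacency, 20-50 kb gaps, GSS 6 Mb away) and
scattered layouts; `make_receptor()` builds the two receptor presets (12
LDLa + 6 LRR + 7 TM, and 1 LDLa + 4 LRR + 7 TM).

What passing tests show — and what they do not. The generator emulates
the *structural grammar* of the families, not real sequence statistics:
composition is hand-picked, there are no insertions or deletions, no
compositional drift, no incomplete records, and noise spares the defining
marks. Green tests therefore demonstrate that the rules implement the
intended grammar and are robust to point substitutions around it; they do
not demonstrate recall on real proteomes, where signal peptides,
low-complexity tails and degenerate repeats will be harder. The
configuration surface exists precisely so those thresholds can be re-tuned
against curated real sequences.

## Trees

`family_tree()` aligns the concatenated B+A core domains by default: the
cysteine scaffold keeps cross-family alignments meaningful, while C, D and
E regions are conserved only between close relatives and would mostly add
noise (`tree.region = "mature"` switches to the full mature sequence).
Distances are Poisson-corrected mismatch fractions (columns with gaps or
X excluded; capped at `dist.cap`), and the tree is plain neighbor joining
with the Q criterion, Studier-Keppler updates, negative branch lengths
clamped to zero, and ties broken towards the lexicographically smallest
label pair so the output is a deterministic function of its input. These
are *similarity* trees: a deliberately simple, fully testable method for
illustrating resemblance, with no claim to phylogenetic inference —
which is why no support values are attached.

## Receptor annotation

Transmembrane segments come from a centered 19-residue Kyte-Doolittle
window at threshold 1.6, discarding runs under 8 positions and merging
runs separated by fewer than 3. LDLa repeats are non-overlapping shortest
matches of `C-x(2,7)-C-x(3,9)-C-x(4,10)-C-x(2,8)-C-x(5,14)-C` that are
followed within 12 residues by an 8-residue window containing at least 3
acidic residues (the calcium-binding cluster); LRR repeats match
`J-x-x-J-x-J-x-x-[NC]-x-J` with `J in {L,I,V,F}`, collapsing matches
closer than 20 residues. These regular-expression profiles are
coarse-grained stand-ins for profile-HMM models: adequate for
architecture calls (`GRL101_like` = 7 TM with six or more LDLa repeats
plus LRRs; `single_LDLa_LGR_like` = 7 TM with one or two LDLa repeats
plus LRRs), not for exact repeat boundaries on divergent sequences.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; serialized
  GFF3/TSV coordinates are 1-based inclusive. Round trips are identity and
  are tested as such.
* `X` is retained as the unknown residue and excluded from all scoring
  windows (hydropathy contribution 0, alignment/identity columns with X
  dropped); `*` is stripped on input with a warning.
* Extra cysteines are tagged by their position relative to the core
  (beyond CA4 counts as distal/D even when the segmentation merged a short
  stub into A), so the tag reflects topology rather than interval
  bookkeeping.
* An alignment with zero scorable columns, a distance matrix that is
  asymmetric, and a CDS not divisible by 3 are errors, not warnings; a
  framework-less precursor is a valid `unclassified` result, and in batch
  mode every failure is one report row, never an abort.
* Segmentation refuses (per-record error) when the predicted signal
  peptide would swallow CB1 — a symptom of a mispredicted cleavage on a
  degenerate sequence.

## Problem sizes used by the test suite

The suites run at sizes chosen to keep the full check fast while leaving
no rule unexercised: alignment scores are verified against exhaustive
alignment-path enumeration on all 4-letter sequence pairs of length up to
2 plus 200 random longer pairs (lengths 3-6); neighbor joining is checked
against 200 random additive 6-leaf trees and against an independent
implementation; intron phases against a literal codon walker on 1,000
random exon partitions; classifier recovery on 50 noise-free and 200
noisy (5% substitution) replicates per family; the similarity-tree
neighborhood claims on a 50-leaf batch. All stochastic suites run under
fixed seeds.

## Known limitations

* The signal-peptide heuristic is far weaker than trained predictors;
  on real data, supply `signal_override` from a dedicated tool when
  available.
* The fourth disulfide bridge is counted, not paired: the package flags
  the extra pair and the parity anomaly but never asserts physical
  connectivity.
* Repeat detection is pattern-based; divergent LDLa/LRR units that a
  profile HMM would still find can be missed.
* Family rules assume the precursor is complete from signal peptide to
  terminus; fragments will typically come back `unclassified` with the
  reason recorded.
* Copy-number expansion and exon-shuffling chimerism of multinsulin genes
  are out of scope as classification inputs.
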