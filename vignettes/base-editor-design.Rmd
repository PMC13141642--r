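---
title: "Designing base-editor disruptions: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing base-editor disruptions: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## The model

A base editor is a deaminase fused to a Cas9 nickase. The guide RNA pairs
with a 20-nt protospacer whose 3′ end must abut a PAM — NGG for wild-type
SpCas9-derived editors, NG for PAM-relaxed variants — and the deaminase
converts target bases lying in a window of protospacer positions on the
*displaced* (guide-matching) strand: C→T for CBEs, A→G for ABEs. Positions
are numbered 1 (PAM-distal) to 20 (PAM-proximal). Because the guide can sit
on either genomic strand, the plus-strand record of an edit is C→T or G→A
(CBE) and A→G or T→C (ABE).

`bescan` treats guide design as a deterministic annotation problem: every
protospacer/PAM occurrence is enumerated on both strands, every target base
in the window becomes a candidate single-base edit, and each edit is
classified by what it does to the gene model it falls in:

* **Premature stop.** The edited codon is recomputed on the coding strand
  from the spliced CDS. Exactly five single-base conversions turn a sense
  codon into a stop, all of them CBE chemistry: CAA→TAA, CAG→TAG, CGA→TGA
  (position-1 C→T) and TGG→TAG, TGG→TGA (G→A via an opposite-strand
  guide). The package asserts by exhaustive enumeration over all
  64 codons × 3 positions that ABE admits no stop-gain route, which is why
  ABE stop cells in summaries are structurally dashes, not zeros that
  happen to occur.
* **Start loss.** Any in-window edit of the initiator ATG: GTG or ACG by
  ABE, ATA by CBE. Near-cognate initiation at ACG/GTG is a documented
  caveat of this strategy; the package still counts these as start-loss
  candidates (they are what the chemistry can produce) and reports the next
  in-frame ATG as context.
* **Splice disruption.** Any in-window intronic edit, subclassified as
  donor (intron positions 1–2, the GT), acceptor (last two positions, the
  AG), branch-region adenines, or other intronic. Only structural
  classification is attempted — no splicing-strength model — because
  empirically even adenine-targeted intronic edits abolish splicing
  unreliably (reported success in roughly 6 of 20 intronic guides). The
  tiering encodes exactly that: donor/acceptor hits are tier 1, everything
  else tier 2.

The consequence of a splice candidate is predicted by simulating full
retention of the affected intron: the intron sequence is re-inserted into
the spliced CDS at its position, translation restarts from the original
ATG, and the first stop codon, the truncated protein length, and the
frameshift status (intron length ≢ 0 mod 3) are reported. Retention is the
outcome observed in practice by cDNA sequencing of edited clones; partial
mis-splicing (cryptic sites, exon skipping) is out of scope.

## Parameters that matter

* **Editing window** (`window`, protospacer positions, default 4–8). The
  single largest determinant of genome-wide counts. Published editors
  differ: APOBEC3A-based CBEs in particular edit more widely than the
  canonical positions 4–8 window. Every output records the window used;
  widening it can only add candidates (a property the tests assert).
* **PAM dialect** (`pam`). NG is implemented as a 2-nt functional PAM —
  any base then G immediately 3′ of the protospacer — since relaxed-PAM
  Cas9 variants impose no constraint at the third position. Under this
  definition every NGG site is an NG site, so NG counts are supersets of
  NGG counts ("NG" means "NG including NGG", not "NG-only").
* **5′-quarter fraction** (`quarter`, default 0.25). A premature stop
  counts toward targetability only if its codon index is at most
  ⌈quarter × total codons⌉. The rule is stated in the field in terms of
  the coding sequence without specifying units or rounding; we chose codon
  units and ceiling rounding, and made the fraction configurable.
* **Branch window** (`branch_window`, default 50 nt). Intronic adenines
  within this 3′-terminal span are labelled `branch_region`. Fungal branch
  points are rarely annotated; this is a deliberate heuristic, which is
  why such candidates are tier 2.

## Summary semantics

Genome summaries count *genes*, not candidates: a gene with twenty stop
candidates counts once. "Any disruption" is the per-gene union of start
and stop — not their sum — and the "Either" editor row is the per-gene
union over CBE and ABE; both unions are computed from per-gene flags, so
the inequalities max ≤ union ≤ sum hold by construction and are asserted
on every run. Splice disruption is excluded from the main table (its
reliability tier is different in kind) and reported separately.
Percentages are rounded half-up to one decimal, matching the printed
precision of published tables; relative NGG→NG increases are rounded
half-up to integers. Genes whose models are structurally incomplete
(CDS not a multiple of three, non-ATG start, internal stops, N residues,
introns shorter than 4 nt) are flagged, excluded from summaries, and
counted in the metadata. When a gene has several transcripts the one with
the longest total CDS is kept (ties: smallest mRNA ID) — genome-scale
tables count genes, and published counts do not state their isoform
collapsing, so one deterministic rule is applied and recorded.

Internally all coordinates are 0-based half-open; GFF3 input and VCF
output use their standard 1-based dialects. This conversion happens in
exactly one module, which removes off-by-one ambiguity everywhere else.

## What the synthetic generator emulates

`simulate_genome()` produces a single chromosome of compact,
intron-containing genes on both strands — ATG…stop CDS, GT…AG introns of
50–70 nt, AT-leaning intergenic sequence — resembling the gene density and
intron geometry of filamentous-fungus genomes. Genes receive *planted*
target sites with configurable probabilities: a CBE-editable CAG codon
phased against an NGG or NG-only PAM, an ABE or CBE start-codon site, and
an ABE-editable splice donor. Each plant's template jointly fixes the
codon frame, the protospacer, and the PAM, so the site is discoverable
under the default window by construction, and every plant is recorded in a
truth manifest with its expected classification and genomic coordinate.

What passing the planted-truth tests shows: the scanner finds every site
it provably should (zero false negatives against the manifest), and
everything else it reports survives an independent position-by-position
verification. What it does not show: anything about editing *efficiency*
on real chromatin, sequence-context preferences of deaminases (for example
the TC-context bias of APOBEC enzymes), or real codon usage and intron
statistics — the generator makes no attempt to model those, and no
efficiency model is included anywhere in the package.

The albA-like fixture is synthetic in the same sense: the true genomic
sequence of the reporter locus is not public in printed form, so the
fixture reconstructs the documented geometry — the validated opposite- and
coding-strand CBE protospacers placed so the affected codons are
tryptophan-55 (TGG→TAG/TGA) and arginine-292 (CGA→TGA), an ABE-editable
donor in intron 2, an NG-only start-codon site, and intron lengths mixing
in-frame and frameshifting retention cases — and self-checks all of it at
build time. It is labelled synthetic wherever it appears.

## Numerical and degenerate-input choices

* Rounding is half-up (not banker's) wherever a printed-scale number is
  produced.
* Protospacers or PAMs containing N are skipped silently; genes whose CDS
  contains N are flagged and excluded from codon-level strategies.
* Edits at the terminator codon are never stop candidates; an edit whose
  reference base disagrees with the genome is a hard error (this guards
  the strand/coordinate arithmetic, and the property tests lean on it).
* Overlapping guides are all reported; deduplication is the consumer's
  job. Multi-base (bystander) combinations are not counted as separate
  candidates: gene-level counting needs one deterministic rule per base.
* Deterministic ordering everywhere (chromosome, then start, then strand;
  candidates by gene, strategy, coordinate), so repeated runs are
  byte-identical.
* The generator uses its own small Park–Miller stream, so seeded output is
  reproducible regardless of the caller's R RNG state.

## Problem sizes used in validation

The test suite validates scanner correctness against a naive enumerator on
a random 10-kb sequence, recovers planted truth on seeded genomes of up to
100 genes (~90 kb, ~150 planted sites), and exercises every property
(strand symmetry, NG ⊇ NGG, window monotonicity, edit-retranslation) on
genomes of 6–15 genes — sizes chosen to keep the whole suite fast while
still covering both strands, all plant types, and both PAM dialects many
times over.

## Known limitations

* No on-/off-target scoring and no gRNA secondary-structure checks; site
  discovery is exhaustive, not ranked.
* No editing-efficiency or sequence-context model; candidates are
  possibilities, not predictions of success.
* Genome-scale targetability counts depend on the annotation build and on
  the window parameter; comparisons across runs are only meaningful with
  the metadata block that every summary carries.
* One transcript per gene; trans-splicing, fuzzy coordinates, and GTF
  input are unsupported.
* CBE splice disruption (GT→AT donors, AG→AA acceptors) is enumerated in
  the candidate table but, like all splice candidates, excluded from the
  start/stop union in the summary table.
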