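# bescan

Base-editor guide design for gene disruption in filamentous fungi.

Cytosine base editors (CBEs, C·G → T·A) and adenine base editors (ABEs,
A·T → G·C) inactivate genes without double-strand breaks, but only where a
protospacer-adjacent motif (PAM) places the target base inside the editor's
narrow editing window. `bescan` is for researchers designing such
disruption experiments in compact fungal genomes (for example *Aspergillus
niger*): it scans a genome FASTA + GFF3 annotation for 20-nt protospacers
under strict NGG or relaxed NG PAMs on both strands, enumerates every
deamination achievable inside the window (default protospacer positions
4–8), and classifies the results into the three disruption strategies:

1. **Premature stop codon** (CBE only). A single C→T on either strand can
   convert exactly five sense codons into stops — CAA→TAA, CAG→TAG,
   CGA→TGA by direct editing, and TGG→TAG or TGG→TGA through a guide on the
   opposite strand (G→A on the coding strand). No single A→G conversion can
   create a stop, so ABE contributes nothing to this strategy. A stop is
   counted as reliably inactivating only within the 5′ quarter of the
   coding sequence (codon index ≤ ⌈0.25 · codons⌉).
2. **Start-codon loss**. ATG→GTG or ATG→ACG (ABE), ATG→ATA (CBE via the
   opposite strand).
3. **Splice-signal disruption**. Intronic edits classified by subsite:
   the GT donor, the AG acceptor, putative branch-point adenines in the
   3′-terminal intron region, or other intronic positions. Consequences are
   predicted by simulating retention of the affected intron — re-inserting
   it into the mature transcript, translating, and reporting the premature
   termination codon and frameshift status.

Per-gene flags are aggregated into a genome-wide targetability table
(gene counts per editor × strategy × PAM, with "any disruption" the
per-gene union of start and stop, and percentages on the printed scale).
A seeded synthetic-genome simulator plants manifest-tracked target sites so
the whole pipeline can be validated against known ground truth, and an
albA-like fixture gene embeds experimentally validated protospacers.

## Worked example

Design CBE/NGG candidates on the bundled albA-like fixture (600 codons,
five exons):

```r
library(bescan)
fx <- alba_fixture()
cand <- design_candidates(fx$sequences, fx$models, editors = "CBE", pam = "NGG")
cand
#> candidate_set: 50 candidate(s) [pam=NGG window=4-8]
#>
#>       premature_stop splice_disruption
#>   CBE             20                30

subset(as.data.frame(cand), strategy == "premature_stop" & codon_index %in% c(55, 292),
       select = c(codon_index, ref_codon, alt_codon, within_quarter, gcoord, plus_ref, plus_alt))
#>    codon_index ref_codon alt_codon within_quarter gcoord plus_ref plus_alt
#> 2           55       TGG       TAG           TRUE    420        G        A
#> 3           55       TGG       TAG           TRUE    420        G        A
#> 4           55       TGG       TGA           TRUE    421        G        A
#> 12         292       CGA       TGA          FALSE   1194        C        T
```

The tryptophan codon at position 55 is edited through an opposite-strand
guide (plus-strand record G→A), giving the TAG nonsense change; the
arginine CGA at codon 292 is edited directly (C→T) to TGA. Codon 55 falls
inside the 5′ quarter of the 600-codon CDS (quarter boundary: codon 150),
codon 292 does not. Overlapping guides reaching the same base are all
reported — deduplicate on `gcoord` if you need unique edits.

The genome-wide summary for the same fixture:

```r
summarize_targetability(fx$sequences, fx$models)
#> Editor  start_NGG  start_NG  stop_NGG  stop_NG  any_NGG     any_NG
#> CBE     0          0         1         1        1 (100.0%)  1 (100.0%)
#> ABE     0          1         -         -        0 (0.0%)    1 (100.0%)
#> Either  0          1         1         1        1 (100.0%)  1 (100.0%)
```

The ABE row's start count moving 0 → 1 from NGG to NG shows the fixture's
NG-only start-codon site: relaxing the PAM is what makes the start codon
reachable at all. The dashes are chemistry, not missing data: ABE cannot
create stop codons.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "bescan.R", package = "bescan"))') \
    design --fasta genome.fa --gff genes.gff3 --editor cbe --pam ngg -o run1
```

writing `run1.guides.tsv`, `run1.candidates.tsv`, `run1.guides.bed`, and
`run1.edits.vcf` (deterministic; reruns are byte-identical).

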