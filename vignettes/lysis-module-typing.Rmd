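---
title: "Mining and typing phage lysis modules with LysisTyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and typing phage lysis modules with LysisTyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LysisTyper)
```

## The problem

At the end of the lytic cycle, a phage infecting a Gram-positive host such as
*Streptococcus* kills the cell with a small cluster of genes, the **lysis
module**: a **holin**, a small membrane protein with one to three
transmembrane helices that permeabilizes the cytoplasmic membrane, and an
**endolysin**, a peptidoglycan hydrolase usually built from an N-terminal
enzymatically active domain (EAD: amidase, endopeptidase, glucosaminidase,
lysozyme, CHAP) and a C-terminal cell-wall-binding domain (CBD: ZoocinA_TRD,
CW_7, SH3_5, LysM, PlyCB, ...). Comparative questions about these modules —
how the genes are arranged, which domain architectures exist and how common
they are, whether genes are overprinted on one another, how many
transmembrane segments a holin family carries — all reduce to operations on
annotated genomes plus domain-evidence tables. LysisTyper implements that
analysis as a reusable, fully offline pipeline.

## Pipeline overview

1. **Input** — annotated genomes (GenBank flat files or GFF3+FASTA) become
   `PhageGenome` objects; domain evidence arrives as a HMMER3
   domtblout-dialect table, transporter evidence as a tabular BLASTp-style
   TSV. Internally all coordinates are 1-based inclusive, the GenBank
   convention; translation uses genetic code 11.
2. **Role assignment** (`classifyRoles`) — product keywords, cross-checked
   against domain evidence and an optional supplemental table.
3. **Module delineation and organization typing** (`delineateModules`,
   `classifyOrganization`) — contiguity with bounded intercalation, matched
   against a five-organization catalogue.
4. **Endolysin architecture typing** (`parseDomtblout`, `resolveOverlaps`,
   `buildArchitecture`, `rankArchitectures`, `upsetTable`, `flagAndCooccur`).
5. **Overlap detection** (`detectOverlaps`) and **holin characterization**
   (`predictTmds`, `assignFamily`, `tandemConsistencyReport`).
6. `runPipeline()` orchestrates all stages and writes every table.

```{r quick-run}
out <- file.path(tempdir(), "demo")
res <- runPipeline(defaultPanelSpec(seed = 42), out)
res$summary$organization_histogram
round(res$summary$holin_first_fraction, 3)
```

## Role assignment

Keywords are matched case-insensitively on whole word tokens, so `lysin`
never fires inside `holin`. Precedence is (1) product keyword, (2) domain
evidence, (3) supplemental evidence; on a keyword/domain conflict the keyword
wins with a warning, because the product string is the curated signal the
annotation pipeline produced, while a single domain hit may be spurious. Set
`evidenceFirst = TRUE` to flip this. The lexicon is data, not code
(`defaultRoleLexicon()`, YAML-serializable): the exact product vocabulary of
any given annotation pipeline is unknowable in advance, so it must be
editable.

A supplemental-evidence table (protein, subject, E-value) stands in for
interactive homology searches. It serves two purposes: rescuing the role of
an unannotated protein, and adding domains the primary table missed —
an endolysin that shows no catalytic domain in the primary table can gain,
say, a PGRP plus pneumo_PspA pair, which records amidase activity
(`applySupplementalEvidence`). All evidence is filtered at the same strict
E-value cutoff (< 0.01).

## Module delineation and the organization catalogue

`delineateModules` walks CDS features in genomic order and chains successive
holin/endolysin genes when each junction spans at most `maxIntercalated`
non-lysis ORFs (default 2) and at most `maxGapNt` of intergenic distance
(default 1000 nt). A chain must contain at least one holin and one endolysin.
The defaults are chosen to reproduce both published boundary cases: a
two-gene intercalation (endonuclease + hypothetical protein between two
endolysins) is kept inside one module, while a holin and an endolysin
separated by 18 unrelated genes yield *no* module — the genome is reported
with a diagnostic carrying the intervening ORF count instead.

The catalogue (`defaultOrganizationCatalogue()`) encodes five organizations
over the transcription-direction role signature:

| label | pattern | order |
|---|---|---|
| A | `HE` | holin-first |
| B | `HHE` | holin-first |
| C | `H(N)E` | holin-first, endonuclease optionally intercalated |
| D | `EH` | endolysin-first |
| E | `EEH` | endolysin-first |

Matching drops `X` (other intercalated) symbols, requires `N` to be licensed
by the pattern, walks the catalogue in order and stops at the first match.
Two consequences are deliberate. First, a C module whose endonuclease is
absent is signature-identical to A and therefore classifies as A; the
synthetic generator plants C always with its endonuclease so planted and
recovered labels agree. Second, catalogue order resolves any tie
deterministically. The catalogue is configuration: per-label gene counts
beyond the constraints "at most two ORFs per role, A–C holin-first, D–E
endolysin-first" are a best reading, and users can ship their own table.

Module direction comes from the member strands (`forward`, `reverse`,
`mixed`); members are reversed into transcription order for reverse-strand
modules before matching, never re-coordinated.

## Endolysin architectures

Architecture identity is the **ordered** N→C domain-name sequence — the same
domain set in a different arrangement is a different type, and repeated
domains are kept as repeats. Hits are filtered at independent E-value < 0.01;
overlapping hits on one protein are resolved greedily (lower E-value wins,
ties by bit score, then domain name, so exact duplicates collapse). Labels
`A1…An` are assigned by decreasing panel frequency with lexicographic
tie-breaks; they are panel-relative by construction, so re-running on a
different panel renumbers.

The package ships a 25-type reference table
(`referenceArchitectures()`, `inst/extdata/architecture_reference_synthetic.tsv`).
It is a *synthetic reconstruction*: a set of 25 distinct layouts with counts
summing to 256 that satisfies every constraint stated for the published
census (most common type `Amidase_5 & NLPC_P60 & ZoocinA_TRD`, runner-up
`ZoocinA_TRD` alone, one type with CW_7 motifs between its catalytic domains,
exactly seven CBD-less and three EAD-less types, the twelve rarest types
unique, counts non-increasing). The true memberships of the less frequent
types are published only graphically, so this table is the generator's
planting list and a worked example, not a claim about the real census.

`flagAndCooccur` reports, for every EAD-less endolysin, the catalytically
active partners co-encoded in the same genome (the classical pattern: a
CBD-only ORF riding with a complete enzyme, or a PlyCB-style binding subunit
paired with a PlyCA-style catalytic subunit); an EAD-less endolysin without a
partner is flagged as an exception that needs supplemental evidence.

Endolysin gene lengths between 228 and 1386 bp are treated as a descriptive
sanity range, not a filter.

## Overlap (overprinting) detection

`detectOverlaps` reports every intersecting feature pair (default restricted
to endolysin–endolysin pairs). Because "starting N nt downstream" is
ambiguous, each record carries both readings: `start_offset_nt`, the
5′-to-5′ distance measured along the upstream gene's transcription direction,
and `junction_offset_nt`, the distance from the downstream gene's 5′ start to
the upstream gene's 3′ end. `frame_offset = start_offset_nt mod 3` for
same-strand pairs and `NA` otherwise. Abutting genes (no shared nucleotide)
are not overlaps.

## Holin characterization

The TMD caller is a transparent hydropathy method, not a neural predictor:
Kyte–Doolittle scale, centered moving average with window 19, threshold 1.6 —
the classical parameterization for membrane-spanning segments. Maximal
above-threshold runs are merged when separated by fewer than `minGap = 5`
residues, then expanded by the window half-width on each side. The expansion
is the one numerically load-bearing choice: a window mean crosses the
threshold only where most of the *window* is hydrophobic, so the run of
above-threshold centers is systematically shorter than the helix itself
(a 21-residue helix yields roughly 13 above-threshold centers at these
settings). The reported segment is therefore the expanded run, clipped at the
midpoint where two expansions would collide, and `minTmdLen = 15` applies to
the expanded segment. Users with external predictions can bypass the caller
entirely and build `HolinProfile` objects from their own segment table.

TCDB family assignment is a pure best-hit rule over a supplied transporter
hit table: lowest E-value under 0.01, ties by bit score then subject
accession; the family is the first three dot-fields of the subject accession
(TCDB's class.subclass.family convention). How the original analysis resolved
multi-family ties is not stated anywhere; best-hit is this package's
decision. `tandemConsistencyReport` then checks the two published
regularities — two holins in one genome always belong to different families,
and TMD counts are constant within a family — reporting violations rather
than dropping them, and lists genomes whose two holins both have a single
TMD.

## The synthetic generator

`generatePanel()` emulates the structures the analysis assumes: multi-ORF
genomes with one planted cassette each (organization drawn from the
catalogue), flanking decoy ORFs with structural/hypothetical products
(exercising keyword negatives), optional minus-strand cassettes, optional
product obfuscation (a planted gene labeled "hypothetical protein", rescued
through its domain hits), a domtblout-dialect hit table for the planted
architectures plus noise hits that all carry E-values ≥ 0.01 by construction,
a TCDB-style table for the planted families, and a planted overlapping
endolysin pair at a configurable start offset. Nucleotide sequence is
back-translated with uniform codon choice under every non-overlapped ORF; the
DNA itself is never analyzed, only coordinates and proteins.

`defaultPanelSpec()` fixes the study conditions: 34 genomes — organization
mix A=20, B=5, C=3, D=3, E=2 (33 modules; 28 holin-first = 85% when printed
to the nearest percent) plus one genome with the 18-gene separation; the
first two-endolysin genome carries its endolysins as an overlapping pair at
+39 nt; endolysin layouts cycle through the 25-type reference; holin families
cycle through the nine TCDB holin families plus "unclassified" (one TMD for
1.E.26, 1.E.65 and unclassified; two for 1.E.11, 1.E.18, 1.E.24; three for
1.E.10, 1.E.16, 1.E.19, 1.E.21). The per-organization counts are a package
choice made once: only the totals (five organizations, ≤ 2 ORFs per role,
85/15 ordering split over 33 modules) are documented, not the per-label
counts. The 60–160 aa holin length range and the 21-aa helix length are
likewise generator choices within biological norms, not published values.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: realistic codon usage or intergenic signals, sequence
homology to real phage proteins, annotation pipelines that disagree on gene
boundaries, partial or fragmented assemblies, domain databases with
conflicting or missing models, and E-value distributions of genuinely
marginal homologs. The generator's noise model (decoy hits strictly above the
cutoff) verifies the filter's logic, not its real-world sensitivity.

Determinism: every generator entry point takes a seed and uses a single RNG
stream scoped to the call; the same spec regenerates byte-identical panels,
and `runPipeline` output files are byte-identical across reruns.

## Problem sizes and runtime

The shipped defaults keep everything desk-scale: the 34-genome default panel
(~10 ORFs per genome, genomes of roughly 5–15 kb), a 256-endolysin
architecture census, and a 36-protein holin recovery panel. The full test
suite and the acceptance script each run in well under two minutes on one
CPU.

## Known limitations

- GenBank parsing covers single-record files with simple or complement CDS
  locations; join/order compound locations and multi-contig assemblies are
  out of scope, as is de novo gene calling.
- The organization catalogue collapses C-without-endonuclease into A; modules
  with three or more ORFs of one role are reported as `unclassified` rather
  than forced into the nearest label.
- Architecture labels are panel-relative; cross-panel comparisons should pin
  labels to a reference table.
- The hydropathy caller reports segment positions and counts only; topology
  (in/out orientation) is not modeled.
- Taxonomy-based panel selection externalizes the representative-choice
  judgment as an optional priority score; by default ties are broken
  lexicographically.
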