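---
title: "Methods: phenotype-driven variant prioritization with ACMG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven variant prioritization with ACMG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgrank)
```

## The model

`acmgrank` treats variant prioritization as the intersection of two
independent measurements.

**Gene–disease validity** is a weighted evidence count. Each discovery
source $s$ (known-gene query, ontology expansion, mouse, zebrafish,
paralogy, interaction neighborhood, tissue expression, user list)
contributes a per-gene multiplicity $m_{g,s}$ — how many times that source
supports gene $g$ (distinct databases for the known-gene query, distinct
annotating terms for ontology expansion, seeds within reach for the
interaction neighborhood, qualifying tissues for expression. The validity
score is

$$\mathrm{score}(g) = \sum_s w_s \, m_{g,s}, \qquad w_s \ge 0 .$$

This is deliberately the *minimal* formula consistent with scoring a gene
"by the number of times it appears, with user-assigned weights": it is
linear in both weights and multiplicities (tested as a property), so an
analyst reweighting a source rescales exactly that source's contribution
and nothing else. Status is categorical: **known** iff the known-gene
query returns the gene (regardless of weights — strong published evidence
should not be diluted by a weight choice), **candidate** iff
$\mathrm{score} \ge$ a threshold (default 1: any single piece of candidate
evidence), else **novel**.

**Variant pathogenicity** follows the ACMG/AMP evidence-code scheme: flag
criteria per variant, then combine flags into the five-tier call.
Thirteen criteria are computable from the pipeline's inputs:

| criterion | rule (defaults) |
|---|---|
| PVS1 | frameshift/stopgain/splicing variant in a gene with pLI $\ge$ 0.9 or haploinsufficient |
| PS1 / PM5 | same / different alternate residue at an established pathogenic protein change (star quality $\ge$ 1) |
| PS2 | de novo in a trio: child het or hom-alt, both parents hom-ref |
| PM1 | residue inside a mutational-hotspot domain |
| PM2 | population MAF absent or $<$ 1e-5 |
| PM4 | in-frame indel or stop-loss |
| PP5 / BP6 | exact genomic key classified pathogenic / benign by a reputable source; a conflicted key sets neither |
| BA1 / BS1 | MAF $\ge$ 0.05 / $\ge$ 0.01 (and $<$ 0.05) |
| BP3 | in-frame indel in a repeat-flagged, non-hotspot domain |
| BP7 | synonymous |

The remaining 15 criteria (segregation, functional assays, case–control
counts, in-silico consensus, ...) require evidence the input formats do
not carry; the evaluators leave them FALSE but the combiner accepts them
when supplied externally (`external_flags`), so a laboratory with, say, a
computational PP3 pipeline can feed it in.

**Combining.** Pathogenic requires PVS1 plus corroboration ($\ge$1
strong, $\ge$2 moderate, moderate+supporting, or $\ge$2 supporting), or
$\ge$2 strong, or 1 strong with enough moderate/supporting; likely
pathogenic the familiar weaker bands; benign is BA1 or $\ge$2 benign-strong;
likely benign one benign-strong plus one supporting-benign or two
supporting-benign. When evidence fires on both sides the call is
*uncertain* — conflict is surfaced, never averaged. The implementation
uses $\ge$-band counts for vectorization; the test suite proves it
pointwise identical to an independently coded exact-count transcription of
the rules over all $2^{13}$ implemented-criterion combinations plus
10,000 random combinations of all 28 flags.

**Causality.** The call and the gene status intersect into four review
bins — P/LP×known (1), P/LP×candidate (2), P/LP×novel (3),
VUS×known (4) — ranked by bin then validity score. Everything else
(benign calls, VUS in unvalidated genes) is retained in the outputs but
unranked: the bins define the review list, not the universe.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `pm2_maf_cutoff` | 1e-5 | allele fraction | stringent "rare/absent in controls"; deliberately tighter than common practice so borderline-frequency LOF variants fall to VUS rather than LP |
| `ba1_maf_cutoff` | 0.05 | allele fraction | guideline stand-alone benign threshold |
| `bs1_maf_cutoff` | 0.01 | allele fraction | strong benign band; BA1/BS1/PM2 are made mutually exclusive by banding so one variant cannot carry self-contradictory frequency evidence |
| `pli_cutoff` | 0.9 | probability | conventional LOF-intolerance threshold feeding PVS1 |
| `expression_cutoff` | 1.0 | TPM | "expressed at all" in the tissue |
| `ppi_levels` | 1 | graph edges | direct interactors; level-2 grows candidate lists quickly |
| `exphenosion_levels` | 1 | ontology edges | one superclass step; expansion is ancestors-only (never descendants) |
| `module_weights` | known-gene 3, others 1 | — | encodes strong-vs-limited evidence; fully overridable |
| `candidate_threshold` | 1 | score | a single piece of candidate evidence suffices |
| `ps2_from_denovo` | TRUE | — | see limitations |

## The synthetic world

`generate_store()` emulates the *shape* of the real evidence: a layered
phenotype ontology DAG (a term at layer $L$ only parents into layer
$L-1$, acyclic by construction), disease–gene assertions spread over four
sources (each planted known gene in $\ge$1 source, the first in all
four), animal-model candidates, symmetric paralogue pairs, an
Erdős–Rényi-plus-hubs interaction graph, exponential-tailed tissue
expression, and constraint scores with planted known genes drawn
LOF-intolerant (pLI 0.92–1), as expected for dominant disease genes.
Protein domains of known genes occupy fixed windows (hotspot 100–150,
repeat 200–260) so planted variants can be positioned inside or outside
them deterministically.

`generate_trio_vcf()` plants variants whose annotations trigger *exactly*
a requested criteria profile under the default configuration, and rejects
contradictory requests (PM2 with a common allele frequency, PVS1 in a
LOF-tolerant gene, PVS1 with a synonymous class). Background variants are
common (MAF 0.01–0.4, so they classify benign/likely-benign/VUS) and are
transmitted Mendelianly under Hardy–Weinberg parental genotypes — hence
planted de novo events are the *only* de novo events, and background
amino-acid positions (500–900) avoid all domain windows.

What the generator does **not** emulate — and therefore what a green test
does not establish: linkage disequilibrium and regional mutation-rate
structure; realistic gene symbol vocabularies and aliasing; multi-transcript
annotation ambiguity; sequencing artifacts (the de novo detector sees
clean genotypes, not read-level evidence); correlated evidence across
sources (real databases copy from each other); and any calibration of the
validity score against expert-curated scales. Recovery of a planted
variant at rank 1 shows the machinery composes correctly, not that the
thresholds are clinically tuned.

## Numerical and design choices

- **Coordinates** are 1-based VCF; matching is assembly-agnostic on
  (chrom, pos, ref, alt). Multi-allelic rows are split before analysis,
  with comma-separated INFO values subset per allele when their length
  matches the ALT count; phased and unphased genotype separators are
  treated identically.
- **Known-gene multiplicity counts sources, not records** (1–4): four
  databases asserting the same association is stronger evidence than one
  database asserting it four times.
- **The interaction neighborhood excludes its seeds**: known genes are
  already known; re-reporting them would double-count in the validity sum.
- **Ties** in (bin, score) break by genomic coordinate — the ordering must
  be total for reproducible output; equal-evidence variants genuinely tie
  scientifically and any stable order is acceptable.
- **Lasso boundary is inclusive** (points on the polygon edge are
  selected, tolerance 1e-9): an analyst drawing a box through a point
  expects to capture it, and inclusivity makes selection reproducible. A
  zero-area polygon degenerates to boundary-only selection with a warning.
- **PM1 is evaluated literally** as "residue inside a hotspot domain"
  without a missense gate; the guideline scopes PM1 to missense, so
  synonymous/LOF variants inside hotspots would over-flag. The synthetic
  generator avoids creating such variants; real-data users should treat
  PM1 on non-missense classes with caution.
- **PS2 equals trio de novo status** by default. The guideline requires
  confirmed parentage and a phenotype match; a PED file proves neither.
  The simplification is explicit and can be disabled
  (`ps2_from_denovo = FALSE`), leaving PS2 to `external_flags`.
- **PS1/PP5/BP6 demand star quality ≥ 1**, and a genomic key with both
  pathogenic and benign assertions sets neither flag — conflicting
  third-party classifications should not silently pick a side.
- **Empty evidence is never an error**: a gene without a constraint record
  fails PVS1 with a "no constraint data" note; an unknown tissue or
  disease warns and contributes nothing. Load-time validation, by
  contrast, is strict: cycles, dangling ontology parents, asymmetric
  paralogue relations, non-canonical interaction edges, out-of-range pLI
  and malformed known-variant records all abort with the table and row.

## Limitations

- SNV/indel annotations only; no CNV/SV criteria.
- Family analysis is limited to trios (the first complete trio found in
  the PED file per VCF).
- Gene matching is by case-sensitive symbol; no alias resolution.
- The validity score is not mapped onto qualitative curation scales
  (limited/moderate/strong/definitive) beyond the known/candidate/novel
  trichotomy.
- Calls are an algorithmic, non-statistical screen. They are a triage
  aid, not a clinical determination; rigid frequency and dosage cutoffs
  will disagree with an expert on nuanced cases.
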