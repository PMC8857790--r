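# acmgrank

Phenotype-driven prioritization of genomic variants for clinical review.

## The problem

Interpreting a sequenced genome means finding the one or few medically
relevant variants among hundreds of thousands. Two orthogonal questions
decide whether a variant is a plausible cause of a patient's phenotype:

1. **Gene–disease validity** — how strong is the evidence that variation in
   this *gene* causes this disease?
2. **Variant pathogenicity** — how damaging is this particular *variant* to
   the gene product, per the ACMG/AMP evidence criteria (PVS1, PS1–4,
   PM1–6, PP1–5, BA1, BS1–4, BP1–7) combined into the five-tier scale
   pathogenic / likely pathogenic / uncertain (VUS) / likely benign /
   benign?

`acmgrank` automates both axes against **local, plain-text evidence
tables** (no network access), then intersects them: a variant is a strong
causal candidate when it scores high on both. It is aimed at genome
analysts triaging annotated VCFs from singletons, parent–child trios, or
cohorts.

## The method

**Gene validity.** Per-source gene lists are produced by

- a known-gene query over four medical-genetics sources
  (OMIM/Orphanet/MedGen/ClinVar-style tables), counting how many distinct
  sources support each gene (1–4);
- phenotype-ontology superclass expansion (walk up `levels` HPO parent
  edges, collect genes annotated to any reached term);
- candidate generators: mouse/zebrafish orthologue phenotypes, paralogues
  of known genes, the interaction-graph neighborhood within `ppi_levels`
  edges of known genes, and tissue expression above a TPM cutoff.

Each gene's validity score is the weighted count

```
score(g) = Σ_source  weight(source) × multiplicity(g, source)
```

with known-gene evidence weighted strong by default (`king = 3`, every
candidate source `= 1`). A gene is **known** if the known-gene query
returns it, **candidate** if its score reaches the threshold, else
**novel**.

**Variant pathogenicity.** Thirteen ACMG criteria have evaluators backed
by the evidence tables — PVS1 (null variant in a LOF-intolerant gene:
pLI ≥ 0.9 or haploinsufficient), PM2/BS1/BA1 (population-frequency bands
with a stringent PM2 cutoff of MAF < 1e-5; absent = PM2), PS1/PM5
(known pathogenic protein changes), PP5/BP6 (known classified genomic
keys), PM1/BP3 (hotspot / repeat domains), PM4/BP7 (consequence class),
and PS2 (trio de novo: child carries the allele, both parents homozygous
reference). Flags combine into the five-tier call by the guideline rules;
conflicting pathogenic and benign evidence resolves to *uncertain*. Each
true flag carries a written justification.

**Causality.** Variants land in four review bins — (1) P/LP in a known
gene, (2) P/LP in a candidate gene, (3) P/LP in a novel gene, (4) VUS in a
known gene — and are ranked by bin, then validity score. A polygon
("lasso") filter selects variants in the validity-vs-pathogenicity plane.

A seeded synthetic generator builds complete evidence stores and annotated
trio VCF/PED fixtures with planted criteria profiles, so the entire
pipeline is testable offline.

## Worked example

```r
library(acmgrank)

# a synthetic world: evidence store with planted known genes per disease
gen        <- generate_store(seed = 42)
disease    <- names(gen$manifest$diseases)[1]      # "MONDO:0000001"
known_gene <- gen$manifest$diseases[[1]]$known[1]  # "GENE0180"

# a trio VCF with one planted pathogenic de novo frameshift
trio <- generate_trio_vcf(seed = 43, gen$store,
  planted = list(list(gene = known_gene, profile = c("PVS1", "PS2", "PM2"))),
  n_background = 200, dir = tempfile())

res <- run_pipeline(run_config(seed = 1), vcf = trio$vcf, store = gen$store,
                    ped = trio$ped, phenotypes = disease, tissues = "heart",
                    out_dir = tempfile())
head(res$ranked[, .(rank_, bin, gene, call, gene_status, validity_score)], 3)
```

prints (stage log, then the ranking):

```
gene_discovery: 6 source list(s), 130 distinct genes
validity_engine: 130 gene(s) scored
trio: 201 record(s) in, 1 P/LP, 1 de novo, 2 binned
   rank_   bin     gene       call gene_status validity_score
1:     1     1 GENE0180 pathogenic       known             13
2:     2     4 GENE0187  uncertain       known              4
3:    NA    NA GENE0180     benign       known             13
```

The planted variant is flagged PVS1 + PS2 + PM2 → *pathogenic*, sits in a
known gene (validity 13 = 4 known-gene sources × 3 + candidate evidence),
so it falls in bin 1 and ranks first. A common variant in another known
gene is a VUS-in-known-gene (bin 4, rank 2); the benign background is
retained but unranked. The output directory holds the three
classification VCFs (`*.denovo.vcf`, `*.plp.vcf`, `*.all.vcf`), the
validity-annotated VCF, the ranked TSV and the scatter TSV.

## Command line

```sh
LAUNCHER=$(Rscript -e 'cat(system.file("cli", "acmgrank.R", package = "acmgrank"))')
Rscript $LAUNCHER simulate --seed 4 --out-dir demo
Rscript $LAUNCHER run --vcf demo/trio.vcf --ped demo/trio.ped \
    --store demo/store --disease MONDO:0000001 --out-dir demo/results
```

Subcommands: `discover`, `validity`, `vip`, `causality`, `simulate`,
`run`; common flags `--config`, `--seed`, `--out-dir`, `--weights`,
`--pm2-cutoff`, `--ppi-levels`, `--threshold`, `--lasso`.

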