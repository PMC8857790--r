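#' @title Seeded synthetic evidence and trio fixtures
#' @description
#' Deterministic generators for (1) a complete evidence store with planted
#' known/candidate genes per disease and (2) an annotated trio VCF + PED with
#' variants planted to trigger chosen ACMG criteria profiles among a
#' common/benign-profiled background. Both return a ground-truth manifest so
#' tests can assert recovery without touching the implementation under test.
#' @name simulate
NULL

.supported_profile_criteria <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PM4",
                                 "BA1", "BS1", "BP7")

#' Generate a synthetic evidence store
#'
#' Builds a layered-DAG phenotype ontology (a term at layer L only parents
#' into layer L-1, guaranteeing acyclicity by construction), term-gene
#' annotations, disease-gene records across the four known-gene sources
#' (every planted known gene appears in at least one source, the first in
#' all four), animal-model orthologue candidates, symmetric paralogue pairs,
#' an interaction graph, tissue expression, gene constraint (planted known
#' genes are LOF-intolerant, as expected for dominant disease genes), known
#' classified variants and protein domains. Domains of known genes occupy
#' fixed windows (hotspot 100-150, repeat 200-260) so planted variants can
#' be positioned inside or outside them deterministically.
#'
#' @param seed integer RNG seed; same seed, same store.
#' @param n_genes,n_terms,n_diseases store sizes (all >= 1).
#' @param n_known_per_disease known genes planted per disease.
#' @param n_candidates_per_disease animal-model candidate genes per disease.
#' @param ppi_density probability of a background interaction edge.
#' @param tissues tissue names for the expression table.
#' @return list with elements `store` (an `evidence_store`) and `manifest`
#'   (ground truth: planted known/candidate genes per disease, sizes, seed).
#' @export
generate_store <- function(seed, n_genes = 200, n_terms = 40, n_diseases = 3,
                           n_known_per_disease = 4,
                           n_candidates_per_disease = 3,
                           ppi_density = 0.02,
                           tissues = c("heart", "brain", "liver")) {
  stopifnot(n_genes >= 1, n_terms >= 1, n_diseases >= 1,
            n_known_per_disease >= 1)
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))

    # layered ontology DAG
    n_layers <- min(4L, n_terms)
    layer_of <- sort(rep_len(seq_len(n_layers), n_terms))
    term_ids <- sprintf("HP:%07d", seq_len(n_terms))
    parent_ids <- character(n_terms)
    for (i in seq_len(n_terms)) {
      if (layer_of[i] > 1L) {
        pool <- term_ids[layer_of == layer_of[i] - 1L]
        k <- min(length(pool), sample(1:2, 1))
        parent_ids[i] <- paste(sample(pool, k), collapse = ";")
      }
    }
    ontology <- data.table(term_id = term_ids,
                           name = paste("phenotype", seq_len(n_terms)),
                           parent_ids = parent_ids)
    term_genes <- rbindlist(lapply(seq_len(n_terms), function(i) {
      data.table(term_id = term_ids[i],
                 gene = sample(genes, min(n_genes, sample(1:4, 1))))
    }))
    term_genes <- unique(term_genes)

    disease_ids <- sprintf("MONDO:%07d", seq_len(n_diseases))
    sources <- c("omim", "orphanet", "medgen", "clinvar")
    known <- list(); cand <- list()
    pool <- genes
    dg <- list(); ortho <- list()
    for (d in disease_ids) {
      kn <- sample(pool, min(length(pool), n_known_per_disease))
      pool <- setdiff(pool, kn)
      known[[d]] <- kn
      for (j in seq_along(kn)) {
        src <- if (j == 1L) sources else
          sample(sources, sample(seq_along(sources), 1))
        dg[[length(dg) + 1L]] <- data.table(disease_id = d, gene = kn[j],
                                            source = src)
      }
      cd <- sample(pool, min(length(pool), n_candidates_per_disease))
      pool <- setdiff(pool, cd)
      cand[[d]] <- cd
      if (length(cd)) {
        org <- sample(c("mouse", "zebrafish"), length(cd), replace = TRUE)
        ortho[[length(ortho) + 1L]] <- data.table(disease_id = d,
                                                  human_gene = cd,
                                                  organism = org)
      }
    }
    disease_genes <- unique(rbindlist(dg))
    orthologs <- if (length(ortho)) unique(rbindlist(ortho)) else
      .empty_table("orthologs")

    known_all <- unique(unlist(known))
    cand_all <- unique(unlist(cand))

    # symmetric paralogue pairs seeded from known genes
    par <- list()
    for (g in known_all) {
      partners <- sample(setdiff(genes, g), sample(1:2, 1))
      for (p in partners) {
        par[[length(par) + 1L]] <- data.table(gene = c(g, p),
                                              paralogue = c(p, g))
      }
    }
    paralogues <- unique(rbindlist(par))

    # interaction graph: background density + known-candidate edges
    edges <- list()
    n_bg_edges <- rbinom(1, n_genes * (n_genes - 1) / 2, ppi_density)
    if (n_bg_edges > 0) {
      a <- sample(genes, n_bg_edges, replace = TRUE)
      b <- sample(genes, n_bg_edges, replace = TRUE)
      keep <- a != b
      edges[[1]] <- data.table(gene_a = pmin(a[keep], b[keep]),
                               gene_b = pmax(a[keep], b[keep]))
    }
    for (g in known_all) {
      partners <- sample(setdiff(genes, g), sample(1:3, 1))
      edges[[length(edges) + 1L]] <- data.table(gene_a = pmin(g, partners),
                                                gene_b = pmax(g, partners))
    }
    interactions <- unique(rbindlist(edges))

    # expression: known genes strongly expressed in the first tissue
    expr <- list()
    for (t in tissues) {
      on <- runif(n_genes) < 0.7
      expr[[length(expr) + 1L]] <- data.table(
        gene = genes[on], tissue = t,
        level = round(stats::rexp(sum(on), rate = 1 / 5), 3))
    }
    expr[[length(expr) + 1L]] <- data.table(gene = known_all,
                                            tissue = tissues[1],
                                            level = round(runif(
                                              length(known_all), 20, 80), 3))
    expression <- unique(rbindlist(expr), by = c("gene", "tissue"))

    constraint <- data.table(
      gene = genes,
      pli = round(runif(n_genes, 0, 0.85), 3),
      haploinsufficient = FALSE
    )
    constraint[gene %in% known_all,
               `:=`(pli = round(runif(.N, 0.92, 1), 3),
                    haploinsufficient = runif(.N) < 0.5)]

    # known classified variants: pathogenic protein changes in known genes,
    # a few benign genomic records elsewhere (chrom 22, pos < 1000)
    kv <- list()
    aa_letters <- c("R", "G", "L", "P", "S", "T", "W", "C")
    for (g in known_all) {
      kv[[length(kv) + 1L]] <- data.table(
        gene = g, aa_ref = sample(aa_letters, 1),
        aa_pos = sample(20:90, 1), aa_alt = sample(aa_letters, 1),
        chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
        alt = NA_character_, significance = "pathogenic",
        star_quality = sample(1:3, 1))
    }
    benign_genes <- sample(genes, min(n_genes, 5))
    kv[[length(kv) + 1L]] <- data.table(
      gene = benign_genes, aa_ref = NA_character_, aa_pos = NA_integer_,
      aa_alt = NA_character_, chrom = "22",
      pos = sample(1:999, length(benign_genes)),
      ref = sample(c("A", "C", "G", "T"), length(benign_genes), TRUE),
      alt = sample(c("A", "C", "G", "T"), length(benign_genes), TRUE),
      significance = "benign", star_quality = 2L)
    known_variants <- rbindlist(kv)
    known_variants <- known_variants[is.na(ref) | ref != alt]

    # domains: fixed windows on known genes for deterministic placement
    domains <- rbindlist(list(
      data.table(gene = known_all, aa_start = 100L, aa_end = 150L,
                 hotspot = TRUE, repeat_region = FALSE),
      data.table(gene = known_all, aa_start = 200L, aa_end = 260L,
                 hotspot = FALSE, repeat_region = TRUE)
    ))

    store <- evidence_store(
      ontology = ontology, term_genes = term_genes,
      disease_genes = disease_genes, orthologs = orthologs,
      paralogues = paralogues, interactions = interactions,
      expression = expression, constraint = constraint,
      known_variants = known_variants, domains = domains
    )
    manifest <- list(
      seed = seed, n_genes = n_genes, n_terms = n_terms,
      n_diseases = n_diseases, tissues = tissues, genes = genes,
      diseases = setNames(lapply(disease_ids, function(d) {
        list(known = known[[d]], candidates = cand[[d]])
      }), disease_ids)
    )
    list(store = store, manifest = manifest)
  })
}

.profile_fields <- function(profile, gene_symbol, store, pop_af_override = NULL) {
  profile <- unique(toupper(profile))
  unknown <- setdiff(profile, .supported_profile_criteria)
  if (length(unknown)) {
    ar_stop(sprintf("unsupported criteria in planted profile: %s",
                    paste(unknown, collapse = ", ")), "generation_error")
  }
  fields <- list(func_class = "exonic", exonic_func = "nonsynonymous",
                 aa_change = NA_character_, pop_af = 5e-4, de_novo = FALSE)
  if ("PVS1" %in% profile) {
    cons <- store$constraint[gene == gene_symbol]
    lof_intolerant <- nrow(cons) &&
      ((!is.na(cons$pli[1]) && cons$pli[1] >= 0.9) ||
         isTRUE(cons$haploinsufficient[1]))
    if (!lof_intolerant) {
      ar_stop(sprintf(
        "contradictory profile: PVS1 requested but gene %s is not LOF-intolerant in the store",
        gene_symbol), "generation_error")
    }
    if (any(c("BP7", "PM4") %in% profile)) {
      ar_stop("contradictory profile: PVS1 with BP7/PM4 consequence class",
              "generation_error")
    }
    fields$exonic_func <- "frameshift"
  }
  if ("PM4" %in% profile) {
    if ("BP7" %in% profile) {
      ar_stop("contradictory profile: PM4 with BP7", "generation_error")
    }
    fields$exonic_func <- "stoploss"
  }
  if ("BP7" %in% profile) fields$exonic_func <- "synonymous"

  freq_flags <- intersect(profile, c("PM2", "BA1", "BS1"))
  if (length(freq_flags) > 1L) {
    ar_stop("contradictory profile: PM2/BA1/BS1 are mutually exclusive",
            "generation_error")
  }
  fields$pop_af <- if ("PM2" %in% profile) NA_real_ else
    if ("BA1" %in% profile) 0.06 else
      if ("BS1" %in% profile) 0.02 else 5e-4
  if (!is.null(pop_af_override)) {
    if ("PM2" %in% profile && !is.na(pop_af_override) &&
        pop_af_override >= 1e-5) {
      ar_stop(sprintf(
        "contradictory profile: PM2 requested with pop_af %g >= cutoff 1e-05",
        pop_af_override), "generation_error")
    }
    fields$pop_af <- pop_af_override
  }

  aa_pos <- NULL
  if ("PS1" %in% profile) {
    hit <- store$known_variants[gene == gene_symbol & significance == "pathogenic" &
                                  !is.na(aa_pos)]
    if (!nrow(hit)) {
      ar_stop(sprintf(
        "contradictory profile: PS1 requested but no pathogenic protein change known for %s",
        gene_symbol), "generation_error")
    }
    fields$aa_change <- sprintf("%s:NM_000001:exon2:c.%dG>A:p.%s%d%s",
                                gene_symbol, hit$aa_pos[1] * 3, hit$aa_ref[1],
                                hit$aa_pos[1], hit$aa_alt[1])
    aa_pos <- hit$aa_pos[1]
  }
  if ("PM1" %in% profile) {
    if ("PS1" %in% profile) {
      ar_stop("contradictory profile: PS1 and PM1 need different aa positions here",
              "generation_error")
    }
    dom <- store$domains[gene == gene_symbol & hotspot == TRUE]
    if (!nrow(dom)) {
      ar_stop(sprintf(
        "contradictory profile: PM1 requested but %s has no hotspot domain",
        gene_symbol), "generation_error")
    }
    aa_pos <- as.integer(floor((dom$aa_start[1] + dom$aa_end[1]) / 2))
    fields$aa_change <- sprintf("%s:NM_000001:exon3:c.%dG>A:p.R%dC",
                                gene_symbol, aa_pos * 3, aa_pos)
  }
  if (is.null(aa_pos) && fields$exonic_func %in%
      c("nonsynonymous", "frameshift", "stoploss")) {
    # place outside any stored domain of the gene
    dom <- store$domains[gene == gene_symbol]
    aa_pos <- 500L
    while (nrow(dom) && any(dom$aa_start <= aa_pos & aa_pos <= dom$aa_end)) {
      aa_pos <- aa_pos + 100L
    }
    fields$aa_change <- sprintf("%s:NM_000001:exon5:c.%dG>A:p.R%d%s",
                                gene_symbol, aa_pos * 3, aa_pos,
                                if (fields$exonic_func == "frameshift")
                                  "Gfs*3" else "G")
  }
  if (any(c("PS2") %in% profile)) fields$de_novo <- TRUE
  fields
}

.format_af <- function(af) {
  ifelse(is.na(af), NA_character_, formatC(af, format = "g", digits = 6))
}

.vcf_meta_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=Gene.refGene,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=Func.refGene,Number=1,Type=String,Description="Genomic region class">',
    '##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description="Exonic consequence">',
    '##INFO=<ID=AAChange.refGene,Number=1,Type=String,Description="Protein change">',
    '##INFO=<ID=gnomAD_genome_ALL,Number=1,Type=Float,Description="Population allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
}

#' Generate a synthetic annotated trio VCF + PED with planted variants
#'
#' Plants variants whose annotations trigger exactly the requested ACMG
#' criteria profile under the default configuration, among a background of
#' common, benign-profiled variants transmitted Mendelianly (so the planted
#' de novo variants are the only de novo events). Deterministic given
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param store an `evidence_store` (planted genes must exist in it).
#' @param planted list of specifications, each a list with elements `gene`,
#'   `profile` (character vector of criteria among PVS1, PS1, PS2, PM1, PM2,
#'   PM4, BA1, BS1, BP7), optional `de_novo` (default TRUE when PS2 is in
#'   the profile) and optional `pop_af`.
#' @param n_background number of background variants.
#' @param dir output directory; `trio.vcf`, `trio.ped` and
#'   `trio_manifest.json` are written there.
#' @param samples sample ids, child first, then father, then mother.
#' @return list with `vcf`, `ped`, `manifest_path` file paths and the
#'   `manifest` (planted variant keys, profiles, background count).
#' @export
generate_trio_vcf <- function(seed, store, planted = list(),
                              n_background = 500, dir = tempfile("trio"),
                              samples = c("CHILD", "FATHER", "MOTHER")) {
  stopifnot(length(samples) == 3)
  genes_in_store <- unique(store$constraint$gene)
  for (p in planted) {
    if (!p$gene %in% genes_in_store) {
      ar_stop(sprintf("planted gene %s not present in store", p$gene),
              "generation_error")
    }
  }
  with_seed(seed, {
    rows <- list()
    manifest_planted <- list()
    used_pos <- new.env()
    bases <- c("A", "C", "G", "T")

    for (i in seq_along(planted)) {
      p <- planted[[i]]
      fields <- .profile_fields(p$profile, p$gene, store,
                                pop_af_override = p$pop_af)
      de_novo <- p$de_novo %||% fields$de_novo
      chrom <- "1"
      pos <- 900000L + i * 10L
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      gts <- if (de_novo) c("0/1", "0/0", "0/0") else c("0/1", "0/1", "0/0")
      info <- c(
        paste0("Gene.refGene=", p$gene),
        paste0("Func.refGene=", fields$func_class),
        paste0("ExonicFunc.refGene=", fields$exonic_func),
        if (!is.na(fields$aa_change))
          paste0("AAChange.refGene=", fields$aa_change),
        if (!is.na(fields$pop_af))
          paste0("gnomAD_genome_ALL=", .format_af(fields$pop_af))
      )
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        info = paste(info, collapse = ";"), gts = list(gts))
      manifest_planted[[i]] <- list(
        gene = p$gene, chrom = chrom, pos = pos, ref = ref, alt = alt,
        key = paste(chrom, pos, ref, alt, sep = ":"),
        profile = sort(unique(toupper(p$profile))), de_novo = de_novo)
    }

    # background: common, Mendelianly transmitted, outside domain windows,
    # genomic keys disjoint from the known-variant table (chrom 22 pos<1000)
    if (n_background > 0) {
      bg_gene <- sample(genes_in_store, n_background, replace = TRUE)
      bg_chrom <- as.character(sample(2:21, n_background, replace = TRUE))
      bg_pos <- 10000L + sample.int(5000000L, n_background)
      bg_ref <- sample(bases, n_background, replace = TRUE)
      bg_alt <- vapply(bg_ref, function(r) sample(setdiff(bases, r), 1), "")
      syn <- runif(n_background) < 0.6
      bg_exf <- ifelse(syn, "synonymous", "nonsynonymous")
      bg_af <- round(runif(n_background, 0.01, 0.4), 5)
      bg_aa_pos <- sample(500:900, n_background, replace = TRUE)
      # Mendelian genotypes under HWE at the population frequency
      draw_gt <- function(af) {
        a1 <- runif(1) < af; a2 <- runif(1) < af
        sum(a1, a2)
      }
      for (j in seq_len(n_background)) {
        fa <- draw_gt(bg_af[j]); mo <- draw_gt(bg_af[j])
        child <- (if (fa == 2) 1 else if (fa == 1) sample(0:1, 1) else 0) +
          (if (mo == 2) 1 else if (mo == 1) sample(0:1, 1) else 0)
        gt_str <- c("0/0", "0/1", "1/1")
        info <- c(
          paste0("Gene.refGene=", bg_gene[j]),
          "Func.refGene=exonic",
          paste0("ExonicFunc.refGene=", bg_exf[j]),
          if (!syn[j]) paste0("AAChange.refGene=",
                              sprintf("%s:NM_000001:exon5:c.%dC>T:p.L%dF",
                                      bg_gene[j], bg_aa_pos[j] * 3,
                                      bg_aa_pos[j])),
          paste0("gnomAD_genome_ALL=", .format_af(bg_af[j]))
        )
        rows[[length(rows) + 1L]] <- data.table(
          chrom = bg_chrom[j], pos = bg_pos[j], ref = bg_ref[j],
          alt = bg_alt[j], info = paste(info, collapse = ";"),
          gts = list(gt_str[c(child, fa, mo) + 1L]))
      }
    }

    dt <- rbindlist(rows)
    dt <- unique(dt, by = c("chrom", "pos", "ref", "alt"))
    setorder(dt, chrom, pos, ref, alt)

    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf_path <- file.path(dir, "trio.vcf")
    ped_path <- file.path(dir, "trio.ped")
    man_path <- file.path(dir, "trio_manifest.json")
    body <- vapply(seq_len(nrow(dt)), function(i) {
      paste(c(dt$chrom[i], dt$pos[i], ".", dt$ref[i], dt$alt[i], ".", "PASS",
              dt$info[i], "GT", dt$gts[[i]]), collapse = "\t")
    }, "")
    hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t")
    writeLines(c(.vcf_meta_lines(), hdr, body), vcf_path)
    writeLines(c(
      paste("FAM1", samples[1], samples[2], samples[3], "1", "2"),
      paste("FAM1", samples[2], "0", "0", "1", "1"),
      paste("FAM1", samples[3], "0", "0", "2", "1")
    ), ped_path)
    manifest <- list(seed = seed, samples = samples,
                     planted = manifest_planted, n_background = n_background)
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
    list(vcf = vcf_path, ped = ped_path, manifest_path = man_path,
         manifest = manifest)
  })
}
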