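#' @title End-to-end prioritization pipeline
#' @description
#' Chains gene discovery -> validity scoring -> ACMG classification ->
#' causality binning/ranking over one or more VCFs, writing the three
#' per-sample classification VCFs, a validity-annotated VCF, a ranked TSV
#' and the scatter TSV. With several VCFs (a cohort) per-sample rankings are
#' pooled into one table under the same sort key, annotated with sample ids.
#' @name pipeline
NULL

#' Run gene discovery for a set of phenotype / disease identifiers
#'
#' Phenotype CURIEs (`HP:`) drive ontology expansion; disease CURIEs
#' (`MONDO:`) drive the known-gene query and the animal-model candidates.
#' Paralogue and interaction candidates are seeded from the known genes;
#' expression candidates come from the requested tissues. A user gene list
#' is carried as its own source.
#'
#' @param phenotypes character vector of HP:/MONDO: CURIEs.
#' @param tissues optional character vector of tissue names.
#' @param user_genes optional character vector of gene symbols.
#' @param store an `evidence_store`.
#' @param config a `run_config`.
#' @return named list of `gene_list` objects (one per active source).
#' @export
discover_genes <- function(phenotypes, tissues = NULL, user_genes = NULL,
                           store, config = run_config()) {
  hp <- phenotypes[is_curie(phenotypes, "HP")]
  mondo <- phenotypes[is_curie(phenotypes, "MONDO")]
  lists <- list()
  if (length(hp)) {
    lists$exphenosion <- expand_phenotype(hp, config$exphenosion_levels,
                                          store)$genes
  }
  if (length(mondo)) {
    lists$king <- suppressWarnings(king_query(mondo, store))
    for (org in c("mouse", "zebrafish")) {
      gl <- cross_species_candidates(mondo, org, store)
      if (length(gl$genes)) lists[[org]] <- gl
    }
    if (length(lists$king$genes)) {
      hom <- paralogue_candidates(lists$king$genes, store)
      if (length(hom$genes)) lists$homology <- hom
      ppi <- ppi_candidates(lists$king$genes, config$ppi_levels, store)
      if (length(ppi$genes)) lists$ppi <- ppi
    }
  }
  if (length(tissues)) {
    ex <- suppressWarnings(
      expression_candidates(tissues, config$expression_cutoff, store))
    if (length(ex$genes)) lists$expression <- ex
  }
  if (length(user_genes)) {
    lists$user <- gene_list("user",
                            setNames(rep(1L, length(unique(user_genes))),
                                     unique(user_genes)))
  }
  lists
}

#' Run the full prioritization pipeline
#'
#' Stages: gene discovery, validity scoring, ACMG classification (with trio
#' de novo detection when a PED file identifies a trio among the VCF
#' samples), causality binning and ranking. With no phenotype/disease input
#' the validity stage is skipped: all genes score 0 (novel) and only the
#' pathogenicity ranking applies. Deterministic given `config$seed`.
#'
#' @param config a `run_config`.
#' @param vcf path(s) to annotated VCF file(s); several paths form a cohort.
#' @param store an `evidence_store` (or a directory for [load_store()]).
#' @param ped optional PED file path for trio analysis.
#' @param phenotypes character vector of HP:/MONDO: CURIEs.
#' @param tissues,user_genes optional discovery inputs.
#' @param out_dir output directory (created).
#' @return list with `ranked` (pooled ranked table), `per_sample` (list of
#'   per-VCF results: records, assessments, ranked, files) and
#'   `validity` (the gene score table).
#' @export
run_pipeline <- function(config = run_config(), vcf, store, ped = NULL,
                         phenotypes = character(), tissues = NULL,
                         user_genes = NULL, out_dir = tempfile("run")) {
  if (is.character(store)) store <- load_store(store)
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ar_stop(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  lists <- stage("gene_discovery", {
    if (length(phenotypes) || length(tissues) || length(user_genes)) {
      discover_genes(phenotypes, tissues, user_genes, store, config)
    } else list()
  })
  message(sprintf("gene_discovery: %d source list(s), %d distinct genes",
                  length(lists),
                  length(unique(unlist(lapply(lists, `[[`, "genes"))))))

  validity <- stage("validity_engine", {
    if (length(lists)) {
      score_genes(build_matrix(lists, config$module_weights),
                  known_rule = config$known_gene_rule,
                  candidate_threshold = config$candidate_threshold)
    } else {
      data.table(gene = character(), score = numeric(), status = character())
    }
  })
  message(sprintf("validity_engine: %d gene(s) scored", nrow(validity)))

  ped_dt <- if (!is.null(ped)) stage("io_formats", read_ped(ped)) else NULL

  per_sample <- list()
  ranked_all <- list()
  labels <- make.unique(sub("\\.vcf$", "", basename(vcf)), sep = "_")
  for (vi in seq_along(vcf)) {
    vpath <- vcf[vi]
    label <- labels[vi]
    records <- stage("io_formats", read_vcf(vpath, config$info_key_map))
    records <- annotate_validity(records, validity)
    trio <- NULL
    if (!is.null(ped_dt)) {
      trios <- find_trios(ped_dt, attr(records, "samples"))
      if (length(trios)) trio <- trios[[1]]
    }
    vip <- stage("vip_engine", classify_vcf(
      records, store, config, trio = trio,
      out_stem = file.path(out_dir, label)))
    write_vcf(records, file.path(out_dir, paste0(label, ".validity.vcf")),
              annotations = list(
                VALIDITY_SCORE = records$validity_score,
                GENE_STATUS = records$gene_status),
              descriptions = c(
                VALIDITY_SCORE = "Weighted gene-disease validity score",
                GENE_STATUS = "known / candidate / novel"))
    ranked <- stage("causality_ranker", rank_variants(
      assign_bins(records, vip$assessments), sample_id = label))
    message(sprintf(
      "%s: %d record(s) in, %d P/LP, %d de novo, %d binned",
      label, nrow(records),
      sum(vip$assessments$call %in% c("pathogenic", "likely_pathogenic")),
      sum(vip$assessments$de_novo %in% TRUE), sum(!is.na(ranked$bin))))
    fwrite(ranked, file.path(out_dir, paste0(label, ".ranked.tsv")),
           sep = "\t")
    scatter_export(ranked,
                   tsv_path = file.path(out_dir, paste0(label, ".scatter.tsv")))
    per_sample[[label]] <- list(records = records,
                                assessments = vip$assessments,
                                ranked = ranked, files = vip$files)
    ranked_all[[label]] <- ranked
  }

  pooled <- rank_variants(rbindlist(ranked_all, use.names = TRUE))
  fwrite(pooled, file.path(out_dir, "cohort.ranked.tsv"), sep = "\t")
  list(ranked = pooled, per_sample = per_sample, validity = validity,
       out_dir = out_dir)
}
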