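#' @title Phenotype-driven gene discovery
#' @description
#' Produces per-source gene lists: ontology superclass expansion of
#' phenotype terms, the known-gene query over the four medical-genetics
#' sources, and the four candidate-gene generators (animal models,
#' paralogues, interaction neighborhood, tissue expression). Every list
#' carries a per-gene multiplicity (how often the source supports the gene)
#' that downstream validity scoring consumes.
#' @name gene_discovery
NULL

.gene_list_sources <- c("king", "exphenosion", "mouse", "zebrafish",
                        "homology", "ppi", "expression", "user")

#' Construct a gene list
#'
#' @param source one of king, exphenosion, mouse, zebrafish, homology, ppi,
#'   expression, user.
#' @param per_gene_count named integer vector: gene -> multiplicity (>= 1).
#' @return A `gene_list`.
#' @export
gene_list <- function(source, per_gene_count = integer()) {
  source <- match.arg(source, .gene_list_sources)
  if (length(per_gene_count)) {
    stopifnot(!is.null(names(per_gene_count)), all(per_gene_count >= 1))
  }
  structure(list(source = source,
                 genes = names(per_gene_count) %||% character(),
                 per_gene_count = per_gene_count),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list: %s> %d genes\n", x$source, length(x$genes)))
  invisible(x)
}

.ontology_parents <- function(store) {
  ont <- store$ontology
  plists <- strsplit(ifelse(is.na(ont$parent_ids), "", ont$parent_ids), ";",
                     fixed = TRUE)
  plists <- lapply(plists, function(p) p[nzchar(p)])
  setNames(plists, ont$term_id)
}

#' Expand phenotype terms up the ontology and collect associated genes
#'
#' Walks up to `levels` superclass (parent) steps from the input terms;
#' descendants are never visited. The returned gene list's multiplicity is
#' the number of returned terms annotating each gene.
#'
#' @param term_ids character vector of phenotype term CURIEs.
#' @param levels nonnegative integer, number of parent steps to walk.
#' @param store an `evidence_store`.
#' @return list with `terms` (the expanded term set) and `genes`
#'   (a `gene_list` with source `exphenosion`).
#' @export
expand_phenotype <- function(term_ids, levels, store) {
  stopifnot(levels >= 0)
  parents <- .ontology_parents(store)
  unknown <- setdiff(term_ids, names(parents))
  if (length(unknown)) {
    ar_stop(sprintf("unknown phenotype term id(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  frontier <- unique(term_ids)
  seen <- frontier
  lvl <- 0L
  while (lvl < levels && length(frontier)) {
    frontier <- setdiff(unique(unlist(parents[frontier])), seen)
    seen <- c(seen, frontier)
    lvl <- lvl + 1L
  }
  tg <- store$term_genes[term_id %in% seen]
  counts <- if (nrow(tg)) {
    tab <- tg[, .(count = uniqueN(term_id)), by = gene]
    setNames(as.integer(tab$count), tab$gene)
  } else integer()
  list(terms = sort(seen), genes = gene_list("exphenosion", counts))
}

#' Query known disease genes across the four evidence sources
#'
#' Returns genes linked to any of the query diseases in the
#' OMIM/Orphanet/MedGen/ClinVar-style tables; multiplicity is the number of
#' distinct sources supporting the gene (1-4).
#'
#' @param disease_ids character vector of disease CURIEs (nonempty).
#' @param store an `evidence_store`.
#' @return A `gene_list` with source `king`.
#' @export
king_query <- function(disease_ids, store) {
  if (!length(disease_ids)) ar_stop("disease_ids must be nonempty")
  hit <- store$disease_genes[disease_id %in% disease_ids]
  missing <- setdiff(disease_ids, store$disease_genes$disease_id)
  if (length(missing)) {
    ar_warn(sprintf("disease id(s) absent from all known-gene sources: %s",
                    paste(missing, collapse = ", ")))
  }
  counts <- if (nrow(hit)) {
    tab <- hit[, .(count = uniqueN(source)), by = gene]
    setNames(as.integer(tab$count), tab$gene)
  } else integer()
  gene_list("king", counts)
}

#' Candidate genes from animal-model orthologue phenotypes
#'
#' @param disease_ids character vector of disease CURIEs.
#' @param organism `"mouse"` or `"zebrafish"`.
#' @param store an `evidence_store`.
#' @return A `gene_list` (source = organism); multiplicity is the number of
#'   matching orthologue-phenotype records per gene.
#' @export
cross_species_candidates <- function(disease_ids, organism, store) {
  organism <- match.arg(organism, c("mouse", "zebrafish"))
  hit <- store$orthologs[disease_id %in% disease_ids &
                           store$orthologs$organism == organism]
  counts <- if (nrow(hit)) {
    tab <- hit[, .(count = .N), by = human_gene]
    setNames(as.integer(tab$count), tab$human_gene)
  } else integer()
  gene_list(organism, counts)
}

#' Candidate genes homologous (paralogous) to known disease genes
#'
#' Returns the union of the paralogue sets of the known genes, minus the
#' known genes themselves; multiplicity is the number of known genes
#' pointing at each candidate.
#'
#' @param known_genes nonempty character vector of gene symbols.
#' @param store an `evidence_store`.
#' @return A `gene_list` with source `homology`.
#' @export
paralogue_candidates <- function(known_genes, store) {
  if (!length(known_genes)) ar_stop("known_genes must be nonempty")
  hit <- store$paralogues[gene %in% known_genes & !(paralogue %in% known_genes)]
  counts <- if (nrow(hit)) {
    tab <- hit[, .(count = uniqueN(gene)), by = paralogue]
    setNames(as.integer(tab$count), tab$paralogue)
  } else integer()
  gene_list("homology", counts)
}

#' Candidate genes in the interaction neighborhood of known genes
#'
#' All genes whose shortest-path distance in the undirected interaction
#' graph to any known gene lies in `[1, levels]`; the known (seed) genes
#' themselves are excluded. Multiplicity is the number of known genes within
#' `levels` of each candidate.
#'
#' @param known_genes nonempty character vector of seed gene symbols.
#' @param levels positive integer neighborhood radius.
#' @param store an `evidence_store`.
#' @return A `gene_list` with source `ppi`.
#' @export
ppi_candidates <- function(known_genes, levels, store) {
  stopifnot(levels >= 1)
  if (!length(known_genes)) ar_stop("known_genes must be nonempty")
  ppi <- store$interactions
  if (!nrow(ppi)) return(gene_list("ppi"))
  g <- igraph::graph_from_data_frame(ppi[, .(gene_a, gene_b)],
                                     directed = FALSE)
  seeds <- intersect(known_genes, igraph::V(g)$name)
  if (!length(seeds)) return(gene_list("ppi"))
  d <- igraph::distances(g, v = seeds, mode = "all")
  within <- d >= 1 & d <= levels
  counts <- colSums(within)
  counts <- counts[counts >= 1]
  counts <- counts[!(names(counts) %in% known_genes)]
  gene_list("ppi", setNames(as.integer(counts), names(counts)))
}

#' Candidate genes expressed in the affected tissue(s)
#'
#' Genes whose expression level meets `cutoff` in at least one requested
#' tissue; multiplicity is the number of qualifying tissues.
#'
#' @param tissues character vector of tissue names.
#' @param cutoff TPM threshold (>= 0).
#' @param store an `evidence_store`.
#' @return A `gene_list` with source `expression`.
#' @export
expression_candidates <- function(tissues, cutoff, store) {
  stopifnot(cutoff >= 0)
  known_tissues <- unique(store$expression$tissue)
  unknown <- setdiff(tissues, known_tissues)
  if (length(unknown)) {
    ar_warn(sprintf("tissue(s) absent from expression table: %s",
                    paste(unknown, collapse = ", ")))
  }
  hit <- store$expression[tissue %in% tissues & level >= cutoff]
  counts <- if (nrow(hit)) {
    tab <- hit[, .(count = uniqueN(tissue)), by = gene]
    setNames(as.integer(tab$count), tab$gene)
  } else integer()
  gene_list("expression", counts)
}
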