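#' @title Gene-disease validity scoring
#' @description
#' Consolidates the per-source gene lists into a genes-by-source evidence
#' matrix, computes a weighted validity score per gene
#' (score = sum over sources of weight x multiplicity), classifies each gene
#' as known / candidate / novel, and annotates variant records with the
#' scores. The score is linear in both weights and multiplicities; "known"
#' status follows the known-gene rule (membership in the known-gene query
#' output) regardless of weights.
#' @name validity_engine
NULL

#' Build the gene-by-source evidence matrix
#'
#' @param gene_lists list of `gene_list` objects, at most one per source.
#' @param weights named nonnegative numeric covering every source present
#'   (see [default_weights()]).
#' @return list of class `gene_evidence_matrix` with `genes`, `membership`
#'   (data.table gene x source counts) and `weights`.
#' @export
build_matrix <- function(gene_lists, weights = default_weights()) {
  srcs <- vapply(gene_lists, function(gl) gl$source, "")
  if (anyDuplicated(srcs)) {
    ar_stop(sprintf("duplicate gene list source '%s': ambiguous weighting",
                    srcs[duplicated(srcs)][1]))
  }
  missing_w <- setdiff(srcs, names(weights))
  if (length(missing_w)) {
    ar_stop(sprintf("no weight defined for source(s): %s",
                    paste(missing_w, collapse = ", ")))
  }
  genes <- sort(unique(unlist(lapply(gene_lists, function(gl) gl$genes))))
  membership <- data.table(gene = genes)
  for (gl in gene_lists) {
    cnt <- rep(0L, length(genes))
    idx <- match(gl$genes, genes)
    cnt[idx] <- as.integer(gl$per_gene_count)
    set(membership, j = gl$source, value = cnt)
  }
  structure(list(genes = genes, membership = membership,
                 sources = unname(srcs), weights = weights),
            class = "gene_evidence_matrix")
}

#' Score genes and classify them as known / candidate / novel
#'
#' score(g) = sum over sources of weight(source) x membership(g, source).
#' Under the default known-gene rule a gene is `known` iff it appears in the
#' known-gene query output (membership in source `king` >= 1); otherwise it
#' is `candidate` when its score reaches `candidate_threshold`, else
#' `novel`.
#'
#' @param matrix a `gene_evidence_matrix`.
#' @param known_rule only `"king"` implemented.
#' @param candidate_threshold nonnegative score threshold.
#' @return data.table with columns gene, score, status, and one
#'   `evidence_<source>` column per source (the weighted contribution).
#' @export
score_genes <- function(matrix, known_rule = "king",
                        candidate_threshold = 1) {
  stopifnot(inherits(matrix, "gene_evidence_matrix"),
            candidate_threshold >= 0)
  known_rule <- match.arg(known_rule, "king")
  res <- data.table(gene = matrix$genes, score = 0)
  for (s in matrix$sources) {
    contrib <- matrix$weights[[s]] * matrix$membership[[s]]
    set(res, j = paste0("evidence_", s), value = contrib)
    res[, score := score + contrib]
  }
  is_known <- if ("king" %in% matrix$sources) {
    matrix$membership[["king"]] >= 1L
  } else rep(FALSE, length(matrix$genes))
  res[, status := fifelse(is_known, "known",
                          fifelse(score >= candidate_threshold,
                                  "candidate", "novel"))]
  res[]
}

#' Annotate variant records with validity scores and gene status
#'
#' Records whose gene is absent from the results (or null) get score 0 and
#' status `novel`.
#'
#' @param records a `variant_table`.
#' @param results output of [score_genes()].
#' @return `records` with `validity_score` and `gene_status` columns added
#'   (the per-source evidence columns are carried in the attribute
#'   `validity_results` for serialization).
#' @export
annotate_validity <- function(records, results) {
  records <- copy(records)
  idx <- match(records$gene, results$gene)
  records[, validity_score := fifelse(is.na(idx), 0, results$score[idx])]
  records[, gene_status := fifelse(is.na(idx), "novel",
                                   results$status[idx])]
  records[is.na(gene_status), gene_status := "novel"]
  records[is.na(validity_score), validity_score := 0]
  setattr(records, "validity_results", results)
  records[]
}
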