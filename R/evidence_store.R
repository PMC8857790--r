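#' @title Local evidence store
#' @description
#' All external knowledge the pipeline consults — phenotype ontology,
#' disease-gene assertions from the four medical-genetics sources,
#' animal-model orthologue phenotypes, paralogues, protein-protein
#' interactions, tissue expression, gene constraint (pLI /
#' haploinsufficiency), known classified variants and protein domains —
#' lives in flat TSV tables inside one directory. This keeps the artifact
#' dependency-free, diffable and fully offline; every invariant is validated
#' at load time.
#' @name evidence_store
NULL

.store_tables <- list(
  ontology = c("term_id", "name", "parent_ids"),
  term_genes = c("term_id", "gene"),
  disease_genes = c("disease_id", "gene", "source"),
  orthologs = c("disease_id", "human_gene", "organism"),
  paralogues = c("gene", "paralogue"),
  interactions = c("gene_a", "gene_b"),
  expression = c("gene", "tissue", "level"),
  constraint = c("gene", "pli", "haploinsufficient"),
  known_variants = c("gene", "aa_ref", "aa_pos", "aa_alt", "chrom", "pos",
                     "ref", "alt", "significance", "star_quality"),
  domains = c("gene", "aa_start", "aa_end", "hotspot", "repeat_region")
)

.empty_table <- function(name) {
  cols <- .store_tables[[name]]
  dt <- data.table()
  int_cols <- c("aa_pos", "pos", "star_quality", "aa_start", "aa_end")
  num_cols <- c("level", "pli")
  lgl_cols <- c("haploinsufficient", "hotspot", "repeat_region")
  for (cn in cols) {
    set(dt, j = cn, value = if (cn %in% int_cols) integer() else
      if (cn %in% num_cols) numeric() else
        if (cn %in% lgl_cols) logical() else character())
  }
  dt
}

#' Construct an evidence store from tables in memory
#'
#' Missing tables default to empty; all invariants are validated.
#'
#' @param ... named data.frames, names among `ontology`, `term_genes`,
#'   `disease_genes`, `orthologs`, `paralogues`, `interactions`,
#'   `expression`, `constraint`, `known_variants`, `domains`.
#' @return An `evidence_store`.
#' @export
evidence_store <- function(...) {
  given <- list(...)
  unknown <- setdiff(names(given), names(.store_tables))
  if (length(unknown)) {
    ar_stop(sprintf("unknown evidence table(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  store <- lapply(names(.store_tables), function(nm) {
    if (nm %in% names(given)) {
      dt <- as.data.table(given[[nm]])
      missing_cols <- setdiff(.store_tables[[nm]], names(dt))
      if (length(missing_cols)) {
        ar_stop(sprintf("table '%s' is missing column(s): %s", nm,
                        paste(missing_cols, collapse = ", ")))
      }
      if (nm == "ontology" && nrow(dt)) {
        # "" and NA both mean "no parents" (a root term)
        dt[is.na(parent_ids), parent_ids := ""]
      }
      dt
    } else .empty_table(nm)
  })
  names(store) <- names(.store_tables)
  class(store) <- "evidence_store"
  validate_store(store)
  store
}

#' Validate every evidence-store invariant
#'
#' Checks: the ontology parent relation is a DAG with no dangling parent
#' ids; (disease, gene, source) / (disease, gene, organism) / (gene, tissue)
#' uniqueness; paralogue symmetry and irreflexivity; canonical undirected
#' interaction edges without self-loops; expression levels >= 0; pLI in
#' [0,1]; known variants carry a protein-change triple or a genomic key;
#' domain intervals ordered.
#'
#' @param store an `evidence_store`.
#' @return `store` invisibly; aborts with a message naming table and row on
#'   the first violation.
#' @export
validate_store <- function(store) {
  fail <- function(tab, row, msg) {
    ar_stop(sprintf("evidence store invariant violated [%s, row %s]: %s",
                    tab, row, msg), "store_invariant_error")
  }
  ont <- store$ontology
  if (nrow(ont)) {
    if (anyDuplicated(ont$term_id)) {
      fail("ontology", which(duplicated(ont$term_id))[1], "duplicate term_id")
    }
    plists <- strsplit(ifelse(is.na(ont$parent_ids), "", ont$parent_ids), ";",
                       fixed = TRUE)
    plists <- lapply(plists, function(p) p[nzchar(p)])
    all_parents <- unique(unlist(plists))
    dangling <- setdiff(all_parents, ont$term_id)
    if (length(dangling)) {
      row <- which(vapply(plists, function(p) dangling[1] %in% p, NA))[1]
      fail("ontology", row,
           sprintf("parent term '%s' not present in store", dangling[1]))
    }
    edges <- rbindlist(lapply(seq_along(plists), function(i) {
      if (length(plists[[i]])) {
        data.table(from = ont$term_id[i], to = plists[[i]])
      }
    }))
    if (!is.null(edges) && nrow(edges)) {
      g <- igraph::graph_from_data_frame(edges, directed = TRUE)
      if (!igraph::is_dag(g)) {
        comp <- igraph::components(g, mode = "strong")
        bad <- names(comp$membership)[comp$membership %in%
                                        which(comp$csize > 1)]
        fail("ontology", NA,
             sprintf("cycle in parent relation involving terms: %s",
                     paste(sort(bad), collapse = ", ")))
      }
    }
  }
  tg <- store$term_genes
  if (nrow(tg)) {
    bad <- which(is.na(tg$gene) | !nzchar(tg$gene))
    if (length(bad)) fail("term_genes", bad[1], "empty gene symbol")
  }
  dg <- store$disease_genes
  if (nrow(dg)) {
    if (!all(dg$source %in% c("omim", "orphanet", "medgen", "clinvar"))) {
      bad <- which(!dg$source %in% c("omim", "orphanet", "medgen", "clinvar"))[1]
      fail("disease_genes", bad, sprintf("unknown source '%s'", dg$source[bad]))
    }
    d <- which(duplicated(dg, by = c("disease_id", "gene", "source")))
    if (length(d)) fail("disease_genes", d[1], "duplicate (disease, gene, source)")
  }
  ortho <- store$orthologs
  if (nrow(ortho)) {
    if (!all(ortho$organism %in% c("mouse", "zebrafish"))) {
      bad <- which(!ortho$organism %in% c("mouse", "zebrafish"))[1]
      fail("orthologs", bad, sprintf("unknown organism '%s'",
                                     ortho$organism[bad]))
    }
    d <- which(duplicated(ortho, by = c("disease_id", "human_gene", "organism")))
    if (length(d)) fail("orthologs", d[1],
                        "duplicate (disease, gene, organism)")
  }
  par <- store$paralogues
  if (nrow(par)) {
    self <- which(par$gene == par$paralogue)
    if (length(self)) fail("paralogues", self[1], "gene is its own paralogue")
    fwd <- paste(par$gene, par$paralogue)
    rev <- paste(par$paralogue, par$gene)
    miss <- which(!(rev %in% fwd))
    if (length(miss)) {
      fail("paralogues", miss[1],
           sprintf("relation not symmetric: %s -> %s has no reverse record",
                   par$gene[miss[1]], par$paralogue[miss[1]]))
    }
  }
  ppi <- store$interactions
  if (nrow(ppi)) {
    self <- which(ppi$gene_a == ppi$gene_b)
    if (length(self)) fail("interactions", self[1], "self-loop")
    noncanon <- which(ppi$gene_a >= ppi$gene_b)
    if (length(noncanon)) {
      fail("interactions", noncanon[1],
           "edge not stored canonically (gene_a < gene_b)")
    }
  }
  expr <- store$expression
  if (nrow(expr)) {
    neg <- which(expr$level < 0)
    if (length(neg)) fail("expression", neg[1], "negative expression level")
    d <- which(duplicated(expr, by = c("gene", "tissue")))
    if (length(d)) fail("expression", d[1], "duplicate (gene, tissue)")
  }
  cons <- store$constraint
  if (nrow(cons)) {
    bad <- which(!is.na(cons$pli) & (cons$pli < 0 | cons$pli > 1))
    if (length(bad)) fail("constraint", bad[1], "pLI outside [0,1]")
  }
  kv <- store$known_variants
  if (nrow(kv)) {
    has_protein <- !is.na(kv$aa_ref) & !is.na(kv$aa_pos) & !is.na(kv$aa_alt)
    has_genomic <- !is.na(kv$chrom) & !is.na(kv$pos) & !is.na(kv$ref) &
      !is.na(kv$alt)
    bad <- which(!has_protein & !has_genomic)
    if (length(bad)) {
      fail("known_variants", bad[1],
           "record has neither protein-change triple nor genomic key")
    }
    tiers <- c("pathogenic", "likely_pathogenic", "uncertain",
               "likely_benign", "benign")
    bad <- which(!kv$significance %in% tiers)
    if (length(bad)) fail("known_variants", bad[1],
                          sprintf("unknown significance '%s'",
                                  kv$significance[bad[1]]))
    bad <- which(kv$star_quality < 0)
    if (length(bad)) fail("known_variants", bad[1], "negative star_quality")
  }
  dom <- store$domains
  if (nrow(dom)) {
    bad <- which(dom$aa_start < 1 | dom$aa_end < dom$aa_start)
    if (length(bad)) fail("domains", bad[1], "bad domain interval")
  }
  invisible(store)
}

#' Load an evidence store from a directory of TSV tables
#'
#' Each table is read from `<name>.tsv` (missing files yield empty tables).
#' An `ontology.obo`-style file is accepted as an alternative ontology input
#' when `ontology.tsv` is absent. All invariants are validated.
#'
#' @param directory path containing the TSV tables.
#' @return An `evidence_store`.
#' @export
load_store <- function(directory) {
  if (!dir.exists(directory)) {
    ar_stop(sprintf("evidence directory not found: %s", directory))
  }
  tabs <- list()
  for (nm in names(.store_tables)) {
    f <- file.path(directory, paste0(nm, ".tsv"))
    if (file.exists(f)) {
      dt <- fread(f, sep = "\t", colClasses = list(
        character = intersect(.store_tables[[nm]],
                              c("term_id", "name", "parent_ids", "gene",
                                "disease_id", "source", "human_gene",
                                "organism", "paralogue", "gene_a", "gene_b",
                                "tissue", "aa_ref", "aa_alt", "chrom", "ref",
                                "alt", "significance"))),
        na.strings = c("NA", ""))
      tabs[[nm]] <- dt
    } else if (nm == "ontology" &&
               file.exists(file.path(directory, "ontology.obo"))) {
      tabs[[nm]] <- read_obo(file.path(directory, "ontology.obo"))
    }
  }
  do.call(evidence_store, tabs)
}

#' Write an evidence store to a directory of TSV tables
#' @param store an `evidence_store`.
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_store <- function(store, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.store_tables)) {
    fwrite(store[[nm]], file.path(directory, paste0(nm, ".tsv")), sep = "\t",
           na = "NA", quote = FALSE)
  }
  invisible(directory)
}

#' Minimal OBO ontology reader
#'
#' Parses `[Term]` stanzas for `id:`, `name:` and `is_a:` lines into the
#' store's ontology table. Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return data.table(term_id, name, parent_ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <- data.table(
        term_id = cur$id, name = cur$name %||% NA_character_,
        parent_ids = paste(cur$parents, collapse = ";"))
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (startsWith(ln, "[")) {
      terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      if (startsWith(ln, "is_a:")) {
        cur$parents <- c(cur$parents,
                         trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
      }
      if (ln == "is_obsolete: true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (length(terms)) rbindlist(terms) else .empty_table("ontology")
}

#' @export
print.evidence_store <- function(x, ...) {
  cat("<evidence_store>\n")
  for (nm in names(.store_tables)) {
    cat(sprintf("  %-15s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
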