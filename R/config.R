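#' Default INFO key mapping (ANNOVAR refGene dialect)
#'
#' Maps the logical annotation fields the pipeline needs onto the VCF INFO
#' keys that carry them. Defaults follow ANNOVAR refGene conventions; override
#' any entry to adapt to a different annotation dialect.
#'
#' @return Named list mapping logical field -> INFO key.
#' @export
default_key_map <- function() {
  list(
    gene        = "Gene.refGene",
    func_class  = "Func.refGene",
    exonic_func = "ExonicFunc.refGene",
    aa_change   = "AAChange.refGene",
    pop_af      = "gnomAD_genome_ALL"
  )
}

#' Default evidence-source weights for validity scoring
#'
#' Known-gene evidence (the four medical-genetics databases) is weighted as
#' strong; every candidate-gene source and the user-supplied list count as
#' limited evidence.
#'
#' @return Named numeric vector of weights.
#' @export
default_weights <- function() {
  c(king = 3, exphenosion = 1, mouse = 1, zebrafish = 1,
    homology = 1, ppi = 1, expression = 1, user = 1)
}

#' Build a run configuration
#'
#' Central container for the analyst-tunable parameters of the pipeline:
#' frequency cutoffs for the PM2/BS1/BA1 criteria, the loss-of-function
#' intolerance cutoff (pLI) feeding PVS1, the tissue-expression cutoff,
#' neighborhood sizes for interaction and ontology expansion, source weights
#' for validity scoring and the known-gene rule.
#'
#' @param module_weights named nonnegative numeric, evidence-source weights.
#' @param known_gene_rule how a gene earns "known" status; only `"king"`
#'   (present in the known-gene query output) is implemented.
#' @param candidate_threshold minimum validity score for "candidate" status.
#' @param pm2_maf_cutoff PM2 fires when population MAF is absent or below
#'   this fraction (stringent default 1e-5).
#' @param ba1_maf_cutoff BA1 (stand-alone benign) MAF cutoff.
#' @param bs1_maf_cutoff BS1 (strong benign) MAF cutoff.
#' @param pli_cutoff pLI at or above which a gene counts as LOF-intolerant.
#' @param expression_cutoff TPM threshold for the expression candidate list.
#' @param ppi_levels interaction-neighborhood radius (edges).
#' @param exphenosion_levels number of ontology superclass levels to walk up.
#' @param ps2_from_denovo logical; when TRUE a trio-confirmed de novo variant
#'   sets PS2 (documented simplification: parentage is taken at face value).
#' @param info_key_map see [default_key_map()].
#' @param seed integer RNG seed for any stochastic step, or NULL.
#' @return A list of class `run_config`.
#' @export
run_config <- function(module_weights = default_weights(),
                       known_gene_rule = "king",
                       candidate_threshold = 1,
                       pm2_maf_cutoff = 1e-5,
                       ba1_maf_cutoff = 0.05,
                       bs1_maf_cutoff = 0.01,
                       pli_cutoff = 0.9,
                       expression_cutoff = 1.0,
                       ppi_levels = 1L,
                       exphenosion_levels = 1L,
                       ps2_from_denovo = TRUE,
                       info_key_map = default_key_map(),
                       seed = NULL) {
  stopifnot(all(module_weights >= 0), !is.null(names(module_weights)))
  for (cut in c(pm2_maf_cutoff, ba1_maf_cutoff, bs1_maf_cutoff, pli_cutoff)) {
    if (cut < 0 || cut > 1) ar_stop("frequency/pLI cutoffs must lie in [0,1]")
  }
  if (candidate_threshold < 0) ar_stop("candidate_threshold must be >= 0")
  if (expression_cutoff < 0) ar_stop("expression_cutoff must be >= 0")
  if (ppi_levels < 0 || exphenosion_levels < 0) {
    ar_stop("neighborhood levels must be nonnegative")
  }
  structure(list(
    module_weights = module_weights,
    known_gene_rule = match.arg(known_gene_rule, "king"),
    candidate_threshold = candidate_threshold,
    pm2_maf_cutoff = pm2_maf_cutoff,
    ba1_maf_cutoff = ba1_maf_cutoff,
    bs1_maf_cutoff = bs1_maf_cutoff,
    pli_cutoff = pli_cutoff,
    expression_cutoff = expression_cutoff,
    ppi_levels = as.integer(ppi_levels),
    exphenosion_levels = as.integer(exphenosion_levels),
    ps2_from_denovo = isTRUE(ps2_from_denovo),
    info_key_map = info_key_map,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Numeric values are
#' coerced; `module_weights` uses `weight.<source> = <w>` entries;
#' `info_key_map` uses `key.<field> = <INFO key>` entries.
#'
#' @param path file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) ar_stop(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- list()
  weights <- default_weights()
  key_map <- default_key_map()
  numeric_fields <- c("candidate_threshold", "pm2_maf_cutoff", "ba1_maf_cutoff",
                      "bs1_maf_cutoff", "pli_cutoff", "expression_cutoff",
                      "ppi_levels", "exphenosion_levels", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "weight.")) {
      weights[sub("^weight\\.", "", k)] <- as.numeric(v)
    } else if (startsWith(k, "key.")) {
      key_map[[sub("^key\\.", "", k)]] <- v
    } else if (k %in% numeric_fields) {
      args[[k]] <- as.numeric(v)
    } else if (k == "ps2_from_denovo") {
      args[[k]] <- toupper(v) %in% c("TRUE", "1", "YES")
    } else {
      args[[k]] <- v
    }
  }
  args$module_weights <- weights
  args$info_key_map <- key_map
  do.call(run_config, args)
}
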