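# Fixtures are built in code; independent oracles live here so the tests
# never re-use the code path they are checking.

vcf_header_lines <- function(extra_info = character()) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=Gene.refGene,Number=1,Type=String,Description="g">',
    '##INFO=<ID=Func.refGene,Number=1,Type=String,Description="f">',
    '##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description="e">',
    '##INFO=<ID=AAChange.refGene,Number=1,Type=String,Description="a">',
    '##INFO=<ID=gnomAD_genome_ALL,Number=1,Type=Float,Description="af">',
    extra_info,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">')
}

# rows: list of character vectors (already tab-joined bodies) or data rows
write_test_vcf <- function(body_rows, path = tempfile(fileext = ".vcf"),
                           samples = character(),
                           extra_info = character()) {
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", if (length(samples)) c("FORMAT", samples)),
               collapse = "\t")
  writeLines(c(vcf_header_lines(extra_info), hdr, body_rows), path)
  path
}

# small handcrafted evidence store used across discovery/VIP tests
tiny_store <- function() {
  evidence_store(
    ontology = data.frame(
      term_id = c("HP:1", "HP:2", "HP:3", "HP:4", "HP:5"),
      name = c("root", "conotruncal defect", "tetralogy of fallot",
               "other branch", "leaf"),
      parent_ids = c("", "HP:1", "HP:2", "HP:1", "HP:3;HP:4"),
      stringsAsFactors = FALSE),
    term_genes = data.frame(
      term_id = c("HP:2", "HP:2", "HP:3", "HP:4", "HP:5"),
      gene = c("NKX25", "GATA4", "SCN5A", "TBX1", "FLT4")),
    disease_genes = data.frame(
      disease_id = c(rep("MONDO:1", 6), "MONDO:2"),
      gene = c(rep("SCN5A", 4), "GATA4", "GATA4", "TBX1"),
      source = c("omim", "orphanet", "medgen", "clinvar", "omim", "clinvar",
                 "omim")),
    orthologs = data.frame(
      disease_id = c("MONDO:1", "MONDO:1", "MONDO:2"),
      human_gene = c("MYH7", "MYH7", "MYH6"),
      organism = c("mouse", "zebrafish", "mouse")),
    paralogues = data.frame(
      gene = c("SCN5A", "SCN10A", "SCN5A", "SCN1A", "GATA4", "GATA6"),
      paralogue = c("SCN10A", "SCN5A", "SCN1A", "SCN5A", "GATA6", "GATA4")),
    interactions = data.frame(
      gene_a = c("GATA4", "NKX25", "ABCC9", "SCN5A"),
      gene_b = c("NKX25", "TBX5", "KCNJ8", "SNTA1")),
    expression = data.frame(
      gene = c("SCN5A", "GATA4", "TTN", "TTN"),
      tissue = c("heart", "heart", "heart", "liver"),
      level = c(10, 0.5, 300, 2)),
    constraint = data.frame(
      gene = c("SCN5A", "GATA4", "TBX1", "FLT4", "TTN", "LOWPLI"),
      pli = c(0.99, 0.95, NA, 0.98, 0.1, 0.1),
      haploinsufficient = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    known_variants = data.frame(
      gene = c("SCN5A", "SCN5A", "GATA4"),
      aa_ref = c("R", "R", NA), aa_pos = c(50L, 50L, NA),
      aa_alt = c("C", "H", NA),
      chrom = c(NA, NA, "8"), pos = c(NA, NA, 1000L),
      ref = c(NA, NA, "G"), alt = c(NA, NA, "A"),
      significance = c("pathogenic", "pathogenic", "benign"),
      star_quality = c(2L, 1L, 2L)),
    domains = data.frame(
      gene = c("SCN5A", "SCN5A"),
      aa_start = c(40L, 200L), aa_end = c(60L, 260L),
      hotspot = c(TRUE, FALSE), repeat_region = c(FALSE, TRUE))
  )
}

# one fully-parsed variant row for evaluator unit tests
make_variant <- function(gene = "SCN5A", chrom = "1", pos = 100L, ref = "A",
                         alt = "T", func_class = "exonic",
                         exonic_func = "nonsynonymous", aa_ref = NA,
                         aa_pos = NA, aa_alt = NA, pop_af = NA_real_,
                         gts = NULL) {
  dt <- data.table::data.table(
    chrom = chrom, pos = as.integer(pos), id = NA_character_, ref = ref,
    alt = alt, qual = NA_character_, filter = NA_character_,
    info = ".", gene = gene, func_class = func_class,
    exonic_func = exonic_func, aa_change = NA_character_,
    pop_af = pop_af, aa_gene = gene, aa_transcript = NA_character_,
    aa_ref = as.character(aa_ref), aa_pos = as.integer(aa_pos),
    aa_alt = as.character(aa_alt))
  if (!is.null(gts)) {
    for (s in names(gts)) data.table::set(dt, j = paste0("gt_", s),
                                          value = gts[[s]])
  }
  data.table::setattr(dt, "samples", sub("^gt_", "", names(gts) %||% character()))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# naive recursive ancestor walk, depth-truncated
oracle_ancestors <- function(store, terms, levels) {
  ont <- store$ontology
  parents_of <- function(t) {
    p <- ont$parent_ids[ont$term_id == t]
    if (!length(p) || is.na(p) || !nzchar(p)) character() else
      strsplit(p, ";", fixed = TRUE)[[1]]
  }
  walk <- function(t, depth) {
    if (depth == 0) return(t)
    unique(c(t, unlist(lapply(parents_of(t), walk, depth = depth - 1))))
  }
  sort(unique(unlist(lapply(terms, walk, depth = levels))))
}

# Floyd-Warshall all-pairs shortest paths on an undirected edge list
oracle_fw_distances <- function(edges_a, edges_b) {
  nodes <- sort(unique(c(edges_a, edges_b)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_along(edges_a)) {
    a <- edges_a[i]; b <- edges_b[i]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# independently coded ACMG combining rules, exact counts per the guideline
oracle_combine <- function(flags) {
  g <- function(ids) sum(vapply(ids, function(i) isTRUE(flags[[i]]), NA))
  pvs <- isTRUE(flags[["PVS1"]])
  ps <- g(paste0("PS", 1:4)); pm <- g(paste0("PM", 1:6))
  pp <- g(paste0("PP", 1:5))
  ba <- isTRUE(flags[["BA1"]])
  bs <- g(paste0("BS", 1:4)); bp <- g(paste0("BP", 1:7))

  p_rules <- c(
    pvs && (ps >= 1),
    pvs && (pm >= 2),
    pvs && (pm == 1 && pp == 1),
    pvs && (pp >= 2),
    ps >= 2,
    ps == 1 && pm >= 3,
    ps == 1 && pm == 2 && pp >= 2,
    ps == 1 && pm == 1 && pp >= 4)
  lp_rules <- c(
    pvs && pm == 1,
    ps == 1 && (pm == 1 || pm == 2),
    ps == 1 && pp >= 2,
    pm >= 3,
    pm == 2 && pp >= 2,
    pm == 1 && pp >= 4)
  b_rules <- c(ba, bs >= 2)
  lb_rules <- c(bs == 1 && bp >= 1, bp >= 2)

  path_side <- any(p_rules) || any(lp_rules)
  ben_side <- any(b_rules) || any(lb_rules)
  if (path_side && ben_side) return("uncertain")
  if (any(p_rules)) return("pathogenic")
  if (any(lp_rules)) return("likely_pathogenic")
  if (any(b_rules)) return("benign")
  if (any(lb_rules)) return("likely_benign")
  "uncertain"
}

# brute-force de novo rule from the genotype truth table
oracle_de_novo <- function(child, father, mother) {
  tab <- expand.grid(c = c("hom_ref", "het", "hom_alt", "missing"),
                     f = c("hom_ref", "het", "hom_alt", "missing"),
                     m = c("hom_ref", "het", "hom_alt", "missing"),
                     stringsAsFactors = FALSE)
  tab$dn <- with(tab, (c == "het" | c == "hom_alt") &
                   f == "hom_ref" & m == "hom_ref")
  tab$dn[match(paste(child, father, mother),
               paste(tab$c, tab$f, tab$m))]
}

# winding-number point-in-polygon (simple polygons only)
oracle_winding_inside <- function(x, y, px, py) {
  n <- length(px)
  vapply(seq_along(x), function(p) {
    ang <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- atan2(py[i] - y[p], px[i] - x[p])
      a2 <- atan2(py[j] - y[p], px[j] - x[p])
      da <- a2 - a1
      while (da > pi) da <- da - 2 * pi
      while (da < -pi) da <- da + 2 * pi
      ang <- ang + da
    }
    abs(ang) > pi
  }, NA)
}
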