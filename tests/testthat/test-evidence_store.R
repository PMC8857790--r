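test_that("generate_store is deterministic and its manifest matches the tables", {
  g1 <- generate_store(11, n_genes = 80, n_terms = 20, n_diseases = 2)
  g2 <- generate_store(11, n_genes = 80, n_terms = 20, n_diseases = 2)
  for (nm in names(g1$store)) {
    expect_equal(as.data.frame(g1$store[[nm]]), as.data.frame(g2$store[[nm]]),
                 info = nm)
  }
  g3 <- generate_store(12, n_genes = 80, n_terms = 20, n_diseases = 2)
  expect_false(identical(as.data.frame(g1$store$disease_genes),
                         as.data.frame(g3$store$disease_genes)))

  # every planted known gene appears in >= 1 of the four sources, under the
  # right disease; the first in all four
  for (d in names(g1$manifest$diseases)) {
    kn <- g1$manifest$diseases[[d]]$known
    dg <- g1$store$disease_genes[g1$store$disease_genes$disease_id == d]
    expect_true(all(kn %in% dg$gene))
    expect_setequal(dg[dg$gene == kn[1]]$source,
                    c("omim", "orphanet", "medgen", "clinvar"))
  }
})

test_that("write_store / load_store round-trips the generated store", {
  g <- generate_store(5, n_genes = 50, n_terms = 12, n_diseases = 1)
  dir <- tempfile("store")
  write_store(g$store, dir)
  loaded <- load_store(dir)
  for (nm in names(g$store)) {
    a <- as.data.frame(g$store[[nm]])
    b <- as.data.frame(loaded[[nm]])
    expect_equal(a[order(do.call(paste, a)), , drop = FALSE],
                 b[order(do.call(paste, b)), , drop = FALSE],
                 ignore_attr = TRUE, info = nm)
  }
})

test_that("an empty directory loads as an empty store with empty query results", {
  dir <- tempfile("empty")
  dir.create(dir)
  store <- load_store(dir)
  expect_s3_class(store, "evidence_store")
  expect_equal(nrow(store$disease_genes), 0L)
  expect_length(suppressWarnings(king_query("MONDO:1", store))$genes, 0L)
  expect_warning(ex <- expression_candidates("heart", 1, store), "heart")
  expect_length(ex$genes, 0L)
})

test_that("load-time validation rejects each invariant violation", {
  base <- tiny_store()
  mutate_and_expect <- function(table, dt, pattern) {
    tabs <- lapply(names(base), function(nm) as.data.frame(base[[nm]]))
    names(tabs) <- names(base)
    tabs[[table]] <- dt
    expect_error(do.call(evidence_store, tabs), pattern)
  }
  # ontology cycle names both terms
  mutate_and_expect("ontology", data.frame(
    term_id = c("HP:A", "HP:B"), name = c("a", "b"),
    parent_ids = c("HP:B", "HP:A")), "cycle.*HP:A.*HP:B")
  # dangling parent
  mutate_and_expect("ontology", data.frame(
    term_id = "HP:A", name = "a", parent_ids = "HP:GONE"),
    "parent term 'HP:GONE'")
  # asymmetric paralogue
  mutate_and_expect("paralogues", data.frame(
    gene = "A", paralogue = "B"), "not symmetric")
  # self-paralogue
  mutate_and_expect("paralogues", data.frame(
    gene = c("A", "A"), paralogue = c("A", "A")), "own paralogue")
  # self-loop / non-canonical interaction edge
  mutate_and_expect("interactions", data.frame(
    gene_a = "A", gene_b = "A"), "self-loop")
  mutate_and_expect("interactions", data.frame(
    gene_a = "B", gene_b = "A"), "canonically")
  # bad pLI, negative expression, bad domain, bad known variant
  mutate_and_expect("constraint", data.frame(
    gene = "A", pli = 1.5, haploinsufficient = FALSE), "pLI")
  mutate_and_expect("expression", data.frame(
    gene = "A", tissue = "heart", level = -1), "negative")
  mutate_and_expect("domains", data.frame(
    gene = "A", aa_start = 10L, aa_end = 5L, hotspot = FALSE,
    repeat_region = FALSE), "interval")
  mutate_and_expect("known_variants", data.frame(
    gene = "A", aa_ref = NA, aa_pos = NA, aa_alt = NA, chrom = NA, pos = NA,
    ref = NA, alt = NA, significance = "pathogenic", star_quality = 1L),
    "neither")
  mutate_and_expect("disease_genes", data.frame(
    disease_id = c("MONDO:9", "MONDO:9"), gene = c("A", "A"),
    source = c("omim", "omim")), "duplicate")
})

test_that("OBO ontology input is accepted as an alternative", {
  dir <- tempfile("obo")
  dir.create(dir)
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: HP:0000001", "name: All", "",
               "[Term]", "id: HP:0000002", "name: Child",
               "is_a: HP:0000001 ! All", "",
               "[Term]", "id: HP:0000003", "name: Dead",
               "is_obsolete: true"),
             file.path(dir, "ontology.obo"))
  store <- load_store(dir)
  expect_equal(nrow(store$ontology), 2L)
  expect_equal(store$ontology$parent_ids[store$ontology$term_id == "HP:0000002"],
               "HP:0000001")
})

test_that("generated trio VCF is deterministic and rejects contradictory profiles", {
  g <- generate_store(3, n_genes = 60, n_terms = 10, n_diseases = 1)
  kn <- g$manifest$diseases[[1]]$known
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- generate_trio_vcf(21, g$store,
                          planted = list(list(gene = kn[1],
                                              profile = c("PVS1", "PM2"))),
                          n_background = 40, dir = d1)
  t2 <- generate_trio_vcf(21, g$store,
                          planted = list(list(gene = kn[1],
                                              profile = c("PVS1", "PM2"))),
                          n_background = 40, dir = d2)
  expect_identical(readLines(t1$vcf), readLines(t2$vcf))
  expect_identical(readLines(t1$ped), readLines(t2$ped))

  # PM2 with a common allele frequency contradicts the cutoff
  expect_error(generate_trio_vcf(1, g$store, planted = list(
    list(gene = kn[1], profile = "PM2", pop_af = 0.01)), n_background = 0),
    "contradictory")
  # PVS1 in a LOF-tolerant gene is impossible
  tolerant <- setdiff(g$manifest$genes, kn)
  tolerant <- tolerant[!tolerant %in%
                         g$store$constraint[pli >= 0.9 |
                                              haploinsufficient == TRUE]$gene]
  expect_error(generate_trio_vcf(1, g$store, planted = list(
    list(gene = tolerant[1], profile = "PVS1")), n_background = 0),
    "LOF-intolerant")
  # unknown gene
  expect_error(generate_trio_vcf(1, g$store, planted = list(
    list(gene = "NOPE", profile = "PM2")), n_background = 0),
    "not present")
})

test_that("planted criteria profiles are recovered exactly by the evaluators", {
  g <- generate_store(9, n_genes = 60, n_terms = 10, n_diseases = 1)
  kn <- g$manifest$diseases[[1]]$known
  cfg <- run_config()
  profiles <- list(
    c("PVS1", "PS2", "PM2"), c("PVS1", "PM2"), c("PVS1"),
    c("PS1"), c("PM1"), c("PM2"), c("PM4"), c("PS2"),
    c("BA1"), c("BS1"), c("BP7"), c("BS1", "BP7"), c("PS1", "PS2", "PM2"))
  for (prof in profiles) {
    trio <- generate_trio_vcf(31, g$store,
                              planted = list(list(gene = kn[1],
                                                  profile = prof)),
                              n_background = 0, dir = tempfile())
    recs <- read_vcf(trio$vcf)
    tctx <- find_trios(read_ped(trio$ped), attr(recs, "samples"))[[1]]
    a <- evaluate_variants(recs, g$store, cfg, trio = tctx)
    on_flags <- implemented_criteria[vapply(implemented_criteria,
                                            function(cr) isTRUE(a[[cr]][1]),
                                            NA)]
    expect_setequal(on_flags, prof)
  }
})
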