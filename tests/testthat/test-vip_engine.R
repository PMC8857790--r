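eval1 <- function(v, store = tiny_store(), cfg = run_config(), trio = NULL) {
  evaluate_variants(v, store, cfg, trio = trio)
}

test_that("PVS1 requires a null variant in a LOF-intolerant gene", {
  # frameshift + high pLI
  a <- eval1(make_variant(gene = "SCN5A", exonic_func = "frameshift"))
  expect_true(a$PVS1)
  expect_match(a$justification, "PVS1")
  # frameshift + low pLI, no HI -> false
  a <- eval1(make_variant(gene = "TTN", exonic_func = "frameshift"))
  expect_false(a$PVS1)
  # haploinsufficiency rescues a missing/low pLI
  a <- eval1(make_variant(gene = "TBX1", exonic_func = "stopgain"))
  expect_true(a$PVS1)
  # not a null variant
  a <- eval1(make_variant(gene = "GATA4", exonic_func = "nonsynonymous"))
  expect_false(a$PVS1)
  # splicing null via functional class
  a <- eval1(make_variant(gene = "SCN5A", func_class = "splicing",
                          exonic_func = NA))
  expect_true(a$PVS1)
  # no constraint record -> false, not an error
  a <- eval1(make_variant(gene = "UNKNOWN", exonic_func = "frameshift"))
  expect_false(a$PVS1)
})

test_that("frequency banding: PM2 / BS1 / BA1 are mutually exclusive", {
  cases <- list(
    list(af = NA_real_, pm2 = TRUE, bs1 = FALSE, ba1 = FALSE),
    list(af = 1e-6, pm2 = TRUE, bs1 = FALSE, ba1 = FALSE),
    list(af = 5e-4, pm2 = FALSE, bs1 = FALSE, ba1 = FALSE),
    list(af = 0.02, pm2 = FALSE, bs1 = TRUE, ba1 = FALSE),
    list(af = 0.06, pm2 = FALSE, bs1 = FALSE, ba1 = TRUE))
  for (cs in cases) {
    a <- eval1(make_variant(pop_af = cs$af))
    expect_equal(a$PM2, cs$pm2, info = paste("af", cs$af))
    expect_equal(a$BS1, cs$bs1, info = paste("af", cs$af))
    expect_equal(a$BA1, cs$ba1, info = paste("af", cs$af))
    expect_lte(a$PM2 + a$BS1 + a$BA1, 1L)
  }
  # analyst-tunable cutoff
  cfg <- run_config(pm2_maf_cutoff = 1e-3)
  a <- eval1(make_variant(pop_af = 5e-4), cfg = cfg)
  expect_true(a$PM2)
})

test_that("known-variant criteria: PS1 / PM5 on protein key, PP5 / BP6 on genomic key", {
  # exact protein match to an established pathogenic change
  a <- eval1(make_variant(gene = "SCN5A", aa_ref = "R", aa_pos = 50,
                          aa_alt = "C"))
  expect_true(a$PS1); expect_false(a$PM5)
  # different alt at the same pathogenic residue
  a <- eval1(make_variant(gene = "SCN5A", aa_ref = "R", aa_pos = 50,
                          aa_alt = "G"))
  expect_false(a$PS1); expect_true(a$PM5)
  # other residue: neither
  a <- eval1(make_variant(gene = "SCN5A", aa_ref = "R", aa_pos = 51,
                          aa_alt = "C"))
  expect_false(a$PS1); expect_false(a$PM5)
  # missing protein annotation silently disables PS1/PM5
  a <- eval1(make_variant(gene = "SCN5A"))
  expect_false(a$PS1); expect_false(a$PM5)
  # exact genomic key known benign
  a <- eval1(make_variant(gene = "GATA4", chrom = "8", pos = 1000, ref = "G",
                          alt = "A"))
  expect_true(a$BP6); expect_false(a$PP5)
})

test_that("conflicting records at one genomic key disable both PP5 and BP6", {
  store <- tiny_store()
  kv <- data.table::as.data.table(store$known_variants)
  kv <- rbind(kv, data.table::data.table(
    gene = "GATA4", aa_ref = NA_character_, aa_pos = NA_integer_,
    aa_alt = NA_character_, chrom = "8", pos = 1000L, ref = "G", alt = "A",
    significance = "pathogenic", star_quality = 2L))
  store$known_variants <- kv
  a <- eval1(make_variant(gene = "GATA4", chrom = "8", pos = 1000, ref = "G",
                          alt = "A"), store = store)
  expect_false(a$PP5); expect_false(a$BP6)
})

test_that("structural criteria: PM1 hotspot, PM4/BP7 class gates, BP3 repeats", {
  # missense at aa 50 inside hotspot domain [40,60]
  a <- eval1(make_variant(gene = "SCN5A", aa_ref = "L", aa_pos = 50,
                          aa_alt = "P", exonic_func = "nonsynonymous"))
  expect_true(a$PM1)
  a <- eval1(make_variant(gene = "SCN5A", aa_ref = "L", aa_pos = 70,
                          aa_alt = "P"))
  expect_false(a$PM1)
  # synonymous: BP7 only
  a <- eval1(make_variant(gene = "SCN5A", exonic_func = "synonymous"))
  expect_true(a$BP7); expect_false(a$PM1); expect_false(a$PM4)
  # stoploss / in-frame indel: PM4
  a <- eval1(make_variant(gene = "TTN", exonic_func = "stoploss"))
  expect_true(a$PM4)
  a <- eval1(make_variant(gene = "TTN", exonic_func = "nonframeshift"))
  expect_true(a$PM4)
  # in-frame indel inside the repeat (non-hotspot) domain [200,260]
  a <- eval1(make_variant(gene = "SCN5A", exonic_func = "nonframeshift",
                          aa_ref = "Q", aa_pos = 230, aa_alt = "del"))
  expect_true(a$BP3)
  a <- eval1(make_variant(gene = "SCN5A", exonic_func = "nonframeshift",
                          aa_ref = "Q", aa_pos = 50, aa_alt = "del"))
  expect_false(a$BP3)
})

test_that("de novo detection matches the 64-combination truth table", {
  gts <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(child = gts, father = gts, mother = gts,
                      stringsAsFactors = FALSE)
  recs <- data.table::rbindlist(lapply(seq_len(nrow(grid)), function(i) {
    make_variant(pos = i, gts = list(C = grid$child[i], F = grid$father[i],
                                     M = grid$mother[i]))
  }))
  trio <- list(child_id = "C", father_id = "F", mother_id = "M")
  got <- detect_de_novo(recs, trio)
  want <- oracle_de_novo(grid$child, grid$father, grid$mother)
  expect_equal(got, want)
  expect_equal(sum(got), 2L)  # het and hom_alt child over hom_ref parents

  expect_error(detect_de_novo(recs, list(child_id = "C", father_id = "X",
                                         mother_id = "M")), "X")
})

test_that("PS2 follows trio de novo status and is configurable off", {
  v <- make_variant(gene = "SCN5A", gts = list(C = "het", F = "hom_ref",
                                               M = "hom_ref"))
  trio <- list(child_id = "C", father_id = "F", mother_id = "M")
  a <- eval1(v, trio = trio)
  expect_true(a$PS2)
  expect_true(a$de_novo)
  a <- eval1(v, trio = trio, cfg = run_config(ps2_from_denovo = FALSE))
  expect_false(a$PS2)
  expect_true(a$de_novo)
  # no trio: PS2 false, de novo NA
  a <- eval1(v)
  expect_false(a$PS2)
  expect_true(is.na(a$de_novo))
})

test_that("combiner agrees with the independently coded guideline rules, exhaustively", {
  # exhaustive over the 13 implemented criteria
  n_impl <- length(implemented_criteria)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n_impl))
  names(grid) <- implemented_criteria
  got <- combine_criteria(data.table::as.data.table(grid))
  want <- vapply(seq_len(nrow(grid)), function(i) {
    oracle_combine(as.list(grid[i, , drop = FALSE]))
  }, "")
  expect_equal(got, want)
  # exactly the five tiers are reachable, no sixth label
  expect_setequal(unique(got),
                  c("pathogenic", "likely_pathogenic", "uncertain",
                    "likely_benign", "benign"))

  # random combinations over all 28 criteria (externally supplied included)
  set.seed(28)
  rnd <- as.data.frame(matrix(runif(2000 * 28) < 0.25, ncol = 28))
  names(rnd) <- acmg_criteria
  got <- combine_criteria(data.table::as.data.table(rnd))
  want <- vapply(seq_len(nrow(rnd)), function(i) {
    oracle_combine(as.list(rnd[i, , drop = FALSE]))
  }, "")
  expect_equal(got, want)
})

test_that("combiner handles spec examples and named-vector input", {
  expect_equal(combine_criteria(c(PVS1 = TRUE)), "uncertain")
  expect_equal(combine_criteria(c(PVS1 = TRUE, PS2 = TRUE)), "pathogenic")
  expect_equal(combine_criteria(c(PVS1 = TRUE, PM2 = TRUE)),
               "likely_pathogenic")
  expect_equal(combine_criteria(c(BS1 = TRUE, BP7 = TRUE)), "likely_benign")
  expect_equal(combine_criteria(c(BA1 = TRUE)), "benign")
  expect_equal(combine_criteria(c(PVS1 = TRUE, PS1 = TRUE, BA1 = TRUE)),
               "uncertain")  # conflicting evidence
  expect_equal(combine_criteria(logical()), "uncertain")
})

test_that("extra pathogenic flags never move a call toward benign (and vice versa)", {
  ord <- c(benign = 1, likely_benign = 2, uncertain = 3,
           likely_pathogenic = 4, pathogenic = 5)
  path_flags <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                  paste0("PP", 1:5))
  ben_flags <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  set.seed(99)
  for (rep in 1:200) {
    flags <- setNames(runif(28) < 0.2, acmg_criteria)
    base <- combine_criteria(flags)
    add <- sample(path_flags[!flags[path_flags]], 1)
    flags2 <- flags; flags2[add] <- TRUE
    more <- combine_criteria(flags2)
    conflict <- more == "uncertain" && ord[base] >= 4
    expect_true(ord[more] >= ord[base] || conflict,
                info = paste(names(which(flags)), collapse = ","))
    add_b <- sample(ben_flags[!flags[ben_flags]], 1)
    flags3 <- flags; flags3[add_b] <- TRUE
    less <- combine_criteria(flags3)
    conflict_b <- less == "uncertain" && ord[base] <= 2
    expect_true(ord[less] <= ord[base] || conflict_b)
  }
})

test_that("every true flag carries a justification", {
  a <- eval1(make_variant(gene = "SCN5A", exonic_func = "frameshift",
                          aa_ref = "R", aa_pos = 50, aa_alt = "C",
                          pop_af = NA_real_))
  for (cr in c("PVS1", "PS1", "PM2")) {
    expect_true(a[[cr]])
    expect_match(a$justification, cr)
  }
  b <- eval1(make_variant(pop_af = 0.5))
  expect_match(b$justification, "BA1")
})

test_that("classification writes the three VCF outputs with subset relations", {
  g <- generate_store(13, n_genes = 60, n_terms = 10, n_diseases = 1)
  kn <- g$manifest$diseases[[1]]$known[1]
  trio <- generate_trio_vcf(5, g$store,
                            planted = list(list(gene = kn,
                                                profile = c("PVS1", "PS2",
                                                            "PM2"))),
                            n_background = 60, dir = tempfile())
  recs <- read_vcf(trio$vcf)
  tctx <- find_trios(read_ped(trio$ped), attr(recs, "samples"))[[1]]
  stem <- file.path(tempfile("cls"), "out")
  dir.create(dirname(stem))
  res <- classify_vcf(recs, g$store, run_config(), trio = tctx,
                      out_stem = stem)
  expect_setequal(names(res$files), c("all", "plp", "denovo"))
  expect_true(all(file.exists(res$files)))

  all_keys <- with(read_vcf(res$files[["all"]]),
                   paste(chrom, pos, ref, alt))
  plp <- read_vcf(res$files[["plp"]])
  dn <- read_vcf(res$files[["denovo"]])
  expect_true(all(paste(plp$chrom, plp$pos, plp$ref, plp$alt) %in% all_keys))
  expect_true(all(paste(dn$chrom, dn$pos, dn$ref, dn$alt) %in% all_keys))
  # every record in the P/LP file carries a P/LP call annotation
  expect_true(all(grepl("ACMG_CALL=(pathogenic|likely_pathogenic)", plp$info)))
  # annotations present in the all-variants file
  expect_true(all(grepl("ACMG_CALL=", read_vcf(res$files[["all"]])$info)))

  # no trio: only two files, with a log note
  expect_message(res2 <- classify_vcf(recs, g$store, run_config(),
                                      out_stem = paste0(stem, "2")),
                 "skipped")
  expect_setequal(names(res2$files), c("all", "plp"))
})
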