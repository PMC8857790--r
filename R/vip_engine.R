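#' @title Variant pathogenicity assessment (ACMG criteria)
#' @description
#' Flags ACMG/AMP evidence criteria per variant with human-readable
#' justifications, detects de novo variants from trio genotypes, combines
#' the flags into the standard five-tier call, and writes the three output
#' VCFs (de novo subset, pathogenic/likely-pathogenic subset, all variants).
#'
#' Thirteen criteria have evaluators backed by the local evidence tables:
#' PVS1 (null variant in a LOF-intolerant gene), PS1/PM5/PP5/BP6 (known
#' classified variants), PS2 (trio de novo), PM1/BP3 (protein domains),
#' PM2/BA1/BS1 (population frequency banding), PM4/BP7 (consequence class).
#' The remaining 15 criteria (segregation, functional assays, case-control,
#' in-silico consensus, ...) need data the pipeline's inputs do not carry;
#' they are always FALSE from the evaluators but the combiner accepts them
#' when supplied externally.
#' @name vip_engine
NULL

#' The 28 ACMG criterion identifiers
#' @export
acmg_criteria <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' The 13 criteria with built-in evaluators
#' @export
implemented_criteria <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PM4", "PM5",
                          "PP5", "BA1", "BS1", "BP3", "BP6", "BP7")

.call_levels <- c("benign", "likely_benign", "uncertain",
                  "likely_pathogenic", "pathogenic")

#' Detect de novo status from trio genotypes
#'
#' TRUE iff the child carries the alternate allele (het or hom_alt) and both
#' parents are homozygous reference; any missing genotype gives FALSE.
#'
#' @param records a `variant_table` (or any data.table with `gt_<sample>`
#'   columns).
#' @param trio list with `child_id`, `father_id`, `mother_id`.
#' @return logical vector, one element per record.
#' @export
detect_de_novo <- function(records, trio) {
  cols <- paste0("gt_", c(trio$child_id, trio$father_id, trio$mother_id))
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    ar_stop(sprintf("trio sample(s) absent from VCF: %s",
                    paste(sub("^gt_", "", missing_cols), collapse = ", ")),
            "trio_config_error")
  }
  child <- records[[cols[1]]]
  father <- records[[cols[2]]]
  mother <- records[[cols[3]]]
  child %in% c("het", "hom_alt") & father == "hom_ref" & mother == "hom_ref"
}

#' Combine ACMG criterion flags into the five-tier call
#'
#' Implements the guideline combining rules. Pathogenic:
#' PVS1 with (>=1 strong, or >=2 moderate, or 1 moderate + 1 supporting, or
#' >=2 supporting); or >=2 strong; or 1 strong with (>=3 moderate, or
#' 2 moderate + >=2 supporting, or 1 moderate + >=4 supporting).
#' Likely pathogenic: PVS1 + 1 moderate; 1 strong + 1-2 moderate; 1 strong +
#' >=2 supporting; >=3 moderate; 2 moderate + >=2 supporting; 1 moderate +
#' >=4 supporting. Benign: BA1, or >=2 benign-strong. Likely benign: 1
#' benign-strong + 1 benign-supporting, or >=2 benign-supporting. When a
#' pathogenic-side and a benign-side rule both fire the call is `uncertain`
#' (conflicting evidence); with no rule firing it is `uncertain`.
#'
#' @param flags named logical vector over (a subset of) [acmg_criteria];
#'   missing names count as FALSE. A logical data.table/matrix with one
#'   column per criterion is also accepted for vectorized use.
#' @return character call(s): pathogenic / likely_pathogenic / uncertain /
#'   likely_benign / benign.
#' @export
combine_criteria <- function(flags) {
  if (is.vector(flags) && !is.list(flags)) {
    dt <- if (length(flags)) as.data.table(as.list(flags)) else
      data.table(PVS1 = FALSE)
    return(combine_criteria(dt))
  }
  dt <- as.data.table(flags)
  for (cr in setdiff(acmg_criteria, names(dt))) set(dt, j = cr, value = FALSE)
  n <- nrow(dt)
  cnt <- function(ids) {
    if (n == 0L) return(integer())
    Reduce(`+`, lapply(ids, function(cr) as.integer(dt[[cr]])))
  }
  pvs <- dt[["PVS1"]]
  nPS <- cnt(paste0("PS", 1:4))
  nPM <- cnt(paste0("PM", 1:6))
  nPP <- cnt(paste0("PP", 1:5))
  ba1 <- dt[["BA1"]]
  nBS <- cnt(paste0("BS", 1:4))
  nBP <- cnt(paste0("BP", 1:7))

  pathogenic <-
    (pvs & (nPS >= 1 | nPM >= 2 | (nPM >= 1 & nPP >= 1) | nPP >= 2)) |
    (nPS >= 2) |
    (nPS >= 1 & (nPM >= 3 | (nPM >= 2 & nPP >= 2) | (nPM >= 1 & nPP >= 4)))
  likely_path <-
    (pvs & nPM >= 1) |
    (nPS >= 1 & nPM >= 1) |
    (nPS >= 1 & nPP >= 2) |
    (nPM >= 3) |
    (nPM >= 2 & nPP >= 2) |
    (nPM >= 1 & nPP >= 4)
  benign <- ba1 | nBS >= 2
  likely_ben <- (nBS >= 1 & nBP >= 1) | nBP >= 2

  path_side <- pathogenic | likely_path
  ben_side <- benign | likely_ben
  out <- rep("uncertain", n)
  ok <- path_side & !ben_side
  out[ok & pathogenic] <- "pathogenic"
  out[ok & !pathogenic] <- "likely_pathogenic"
  ok <- ben_side & !path_side
  out[ok & benign] <- "benign"
  out[ok & !benign] <- "likely_benign"
  out
}

.justify <- function(active, texts) {
  paste(texts[active], collapse = "; ")
}

#' Evaluate the implemented ACMG criteria for every variant
#'
#' Pure function of (records, store, config, trio). Returns one row per
#' record with a logical column per criterion (the 15 criteria without
#' evaluators are FALSE), the combined five-tier `call`, `de_novo` status
#' (NA when no trio is given) and a `justification` string covering every
#' true flag.
#'
#' @param records a `variant_table`.
#' @param store an `evidence_store`.
#' @param config a `run_config`.
#' @param trio optional trio context (see [find_trios()]).
#' @param external_flags optional logical data.table/data.frame (one row per
#'   record) supplying criteria outside the implemented set, e.g. PP3 from
#'   an in-silico consensus the user computed elsewhere.
#' @return data.table of assessments aligned with `records`.
#' @export
evaluate_variants <- function(records, store, config = run_config(),
                              trio = NULL, external_flags = NULL) {
  n <- nrow(records)
  fl <- data.table(row_id = seq_len(max(n, 0L)))
  for (cr in acmg_criteria) set(fl, j = cr, value = rep(FALSE, n))
  just <- vector("list", n)
  if (n == 0L) {
    fl[, c("call", "de_novo", "justification") :=
         list(character(), logical(), character())]
    return(fl[])
  }

  # -- PVS1: null variant in a LOF-intolerant gene ------------------------
  null_var <- (!is.na(records$exonic_func) &
                 records$exonic_func %in% c("frameshift", "stopgain")) |
    (!is.na(records$func_class) & records$func_class == "splicing")
  cons <- store$constraint
  ci <- match(records$gene, cons$gene)
  pli <- cons$pli[ci]
  hi <- cons$haploinsufficient[ci]
  lof_intol <- (!is.na(pli) & pli >= config$pli_cutoff) |
    (!is.na(hi) & hi)
  fl[, PVS1 := null_var & lof_intol]
  pvs1_txt <- sprintf("PVS1: %s in LOF-intolerant gene %s (pLI=%s, HI=%s)",
                      ifelse(!is.na(records$exonic_func) &
                               records$exonic_func %in%
                               c("frameshift", "stopgain"),
                             records$exonic_func, "splicing variant"),
                      records$gene, ifelse(is.na(pli), "NA", pli),
                      ifelse(is.na(hi), "NA", hi))

  # -- frequency banding: BA1 >= ba1 cutoff > BS1 >= bs1 cutoff; PM2 ------
  af <- records$pop_af
  fl[, BA1 := !is.na(af) & af >= config$ba1_maf_cutoff]
  fl[, BS1 := !is.na(af) & af >= config$bs1_maf_cutoff & !fl$BA1]
  fl[, PM2 := is.na(af) | af < config$pm2_maf_cutoff]
  ba1_txt <- sprintf("BA1: population MAF %s >= %g", af, config$ba1_maf_cutoff)
  bs1_txt <- sprintf("BS1: population MAF %s >= %g", af, config$bs1_maf_cutoff)
  pm2_txt <- ifelse(is.na(af),
                    "PM2: absent from population controls",
                    sprintf("PM2: population MAF %s < %g", af,
                            config$pm2_maf_cutoff))

  # -- known classified variants: PS1, PM5 (protein), PP5, BP6 (genomic) --
  kv <- store$known_variants
  kv_path_prot <- kv[significance == "pathogenic" & star_quality >= 1 &
                       !is.na(aa_pos)]
  has_aa <- !is.na(records$aa_ref) & !is.na(records$aa_pos) &
    !is.na(records$aa_alt) & !is.na(records$gene)
  ps1 <- pm5 <- rep(FALSE, n)
  if (nrow(kv_path_prot)) {
    exact_keys <- paste(kv_path_prot$gene, kv_path_prot$aa_ref,
                        kv_path_prot$aa_pos, kv_path_prot$aa_alt)
    res_keys <- paste(records$gene, records$aa_ref, records$aa_pos,
                      records$aa_alt)
    ps1 <- has_aa & res_keys %in% exact_keys
    pos_keys <- paste(kv_path_prot$gene, kv_path_prot$aa_ref,
                      kv_path_prot$aa_pos)
    res_pos_keys <- paste(records$gene, records$aa_ref, records$aa_pos)
    pm5 <- has_aa & !ps1 & res_pos_keys %in% pos_keys
  }
  fl[, PS1 := ps1]
  fl[, PM5 := pm5]
  ps1_txt <- sprintf("PS1: same amino-acid change p.%s%s%s in %s previously established pathogenic",
                     records$aa_ref, records$aa_pos, records$aa_alt,
                     records$gene)
  pm5_txt <- sprintf("PM5: different missense change at pathogenic residue %s%s of %s",
                     records$aa_ref, records$aa_pos, records$gene)

  pp5 <- bp6 <- rep(FALSE, n)
  kv_gen <- kv[!is.na(chrom) & !is.na(pos) & !is.na(ref) & !is.na(alt) &
                 star_quality >= 1]
  if (nrow(kv_gen)) {
    gkeys <- paste(kv_gen$chrom, kv_gen$pos, kv_gen$ref, kv_gen$alt,
                   sep = ":")
    rkeys <- variant_keys(records)
    path_keys <- gkeys[kv_gen$significance %in%
                         c("pathogenic", "likely_pathogenic")]
    ben_keys <- gkeys[kv_gen$significance %in% c("benign", "likely_benign")]
    pp5 <- rkeys %in% path_keys
    bp6 <- rkeys %in% ben_keys
    conflict <- pp5 & bp6
    pp5[conflict] <- FALSE
    bp6[conflict] <- FALSE
  }
  fl[, PP5 := pp5]
  fl[, BP6 := bp6]
  pp5_txt <- "PP5: reputable source reports this exact variant pathogenic"
  bp6_txt <- "BP6: reputable source reports this exact variant benign"

  # -- domains: PM1 (hotspot), BP3 (in-frame indel in repeat region) ------
  dom <- store$domains
  pm1 <- bp3 <- rep(FALSE, n)
  if (nrow(dom)) {
    for (i in which(!is.na(records$aa_pos) & !is.na(records$gene))) {
      dsub <- dom[gene == records$gene[i] &
                    aa_start <= records$aa_pos[i] &
                    records$aa_pos[i] <= aa_end]
      if (any(dsub$hotspot)) pm1[i] <- TRUE
      if (!is.na(records$exonic_func[i]) &&
          records$exonic_func[i] == "nonframeshift" &&
          any(!dsub$hotspot & dsub$repeat_region)) {
        bp3[i] <- TRUE
      }
    }
  }
  fl[, PM1 := pm1]
  fl[, BP3 := bp3]
  pm1_txt <- sprintf("PM1: residue %s lies in a mutational hotspot domain of %s",
                     records$aa_pos, records$gene)
  bp3_txt <- sprintf("BP3: in-frame indel in a repetitive region of %s",
                     records$gene)

  # -- consequence-class criteria: PM4, BP7 -------------------------------
  fl[, PM4 := !is.na(records$exonic_func) &
       records$exonic_func %in% c("nonframeshift", "stoploss")]
  fl[, BP7 := !is.na(records$exonic_func) &
       records$exonic_func == "synonymous"]
  pm4_txt <- sprintf("PM4: protein length change (%s)", records$exonic_func)
  bp7_txt <- "BP7: synonymous variant with no predicted splice impact"

  # -- trio de novo: PS2 --------------------------------------------------
  de_novo <- rep(NA, n)
  if (!is.null(trio)) {
    de_novo <- detect_de_novo(records, trio)
    if (config$ps2_from_denovo) fl[, PS2 := de_novo]
  }
  ps2_txt <- "PS2: de novo in trio (both parents homozygous reference)"

  # -- external flags for the 15 criteria without evaluators --------------
  if (!is.null(external_flags)) {
    ef <- as.data.table(external_flags)
    for (cr in intersect(names(ef), setdiff(acmg_criteria,
                                            implemented_criteria))) {
      set(fl, j = cr, value = as.logical(ef[[cr]]))
    }
  }

  txts <- list(PVS1 = pvs1_txt, PS1 = ps1_txt, PS2 = rep(ps2_txt, n),
               PM1 = pm1_txt, PM2 = pm2_txt, PM4 = pm4_txt, PM5 = pm5_txt,
               PP5 = rep(pp5_txt, n), BA1 = ba1_txt, BS1 = bs1_txt,
               BP3 = bp3_txt, BP6 = rep(bp6_txt, n),
               BP7 = rep(bp7_txt, n))
  justification <- vapply(seq_len(n), function(i) {
    active <- implemented_criteria[vapply(implemented_criteria,
                                          function(cr) isTRUE(fl[[cr]][i]),
                                          NA)]
    ext <- setdiff(acmg_criteria[vapply(acmg_criteria,
                                        function(cr) isTRUE(fl[[cr]][i]),
                                        NA)], implemented_criteria)
    parts <- c(vapply(active, function(cr) txts[[cr]][i], ""),
               if (length(ext)) sprintf("%s: supplied externally", ext))
    paste(parts, collapse = "; ")
  }, "")

  fl[, call := combine_criteria(fl[, acmg_criteria, with = FALSE])]
  fl[, de_novo := de_novo]
  fl[, justification := justification]
  fl[]
}

#' Classify a variant table and write the three output VCFs
#'
#' Runs every evaluator, combines the criteria, annotates each record with
#' `ACMG_CALL`, `ACMG_CRITERIA` (comma list of true flags) and
#' `ACMG_JUSTIFICATION`, and writes: `<stem>.denovo.vcf` (only when a trio
#' is given), `<stem>.plp.vcf` (pathogenic / likely pathogenic subset) and
#' `<stem>.all.vcf` (every record).
#'
#' @param records a `variant_table`.
#' @param store an `evidence_store`.
#' @param config a `run_config`.
#' @param trio optional trio context; when NULL the de novo file is skipped
#'   with a message.
#' @param out_stem output path stem.
#' @param external_flags see [evaluate_variants()].
#' @return list with `assessments` and the written `files`.
#' @export
classify_vcf <- function(records, store, config = run_config(), trio = NULL,
                         out_stem = tempfile("vip"), external_flags = NULL) {
  assess <- evaluate_variants(records, store, config, trio, external_flags)
  crit_str <- vapply(seq_len(nrow(assess)), function(i) {
    on <- acmg_criteria[vapply(acmg_criteria,
                               function(cr) isTRUE(assess[[cr]][i]), NA)]
    if (length(on)) paste(on, collapse = ",") else "."
  }, "")
  ann <- list(
    ACMG_CALL = assess$call,
    ACMG_CRITERIA = crit_str,
    ACMG_JUSTIFICATION = gsub("[;=]", ",",
                              ifelse(nzchar(assess$justification),
                                     assess$justification, "."))
  )
  desc <- c(ACMG_CALL = "Five-tier ACMG pathogenicity call",
            ACMG_CRITERIA = "ACMG criteria invoked",
            ACMG_JUSTIFICATION = "Justification for the invoked criteria")
  files <- character()
  sub_ann <- function(idx) lapply(ann, function(v) v[idx])
  all_path <- paste0(out_stem, ".all.vcf")
  write_vcf(records, all_path, annotations = ann, descriptions = desc)
  files["all"] <- all_path
  plp_idx <- which(assess$call %in% c("pathogenic", "likely_pathogenic"))
  plp_path <- paste0(out_stem, ".plp.vcf")
  write_vcf(subset_variants(records, plp_idx), plp_path, annotations = sub_ann(plp_idx),
            descriptions = desc)
  files["plp"] <- plp_path
  if (!is.null(trio)) {
    dn_idx <- which(assess$de_novo %in% TRUE)
    dn_path <- paste0(out_stem, ".denovo.vcf")
    write_vcf(subset_variants(records, dn_idx), dn_path, annotations = sub_ann(dn_idx),
              descriptions = desc)
    files["denovo"] <- dn_path
  } else {
    message("no trio supplied: de novo output skipped")
  }
  list(assessments = assess, files = files)
}
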