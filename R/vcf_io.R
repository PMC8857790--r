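#' @title VCF and PED input/output
#' @description
#' Variants are held in a `variant_table`: a `data.table` with one row per
#' (VCF row, ALT allele) pair. Multi-allelic rows are split on read so that
#' every per-allele criterion downstream is well-defined. Parsed annotation
#' fields (gene, functional class, exonic consequence, protein change,
#' population allele frequency) are extracted from INFO via a configurable
#' key map; the raw INFO string is retained so untouched fields round-trip
#' byte-identically.
#' @name vcf_io
NULL

.gt_levels <- c("hom_ref", "het", "hom_alt", "missing")

#' Normalize an ANNOVAR-style exonic consequence string
#'
#' Collapses dialect variants (`frameshift insertion`, `frameshift_deletion`,
#' ...) onto the canonical classes used by the criteria evaluators:
#' frameshift, stopgain, stoploss, nonframeshift, nonsynonymous, synonymous.
#' Unrecognized strings are lowercased and passed through; "." becomes NA.
#'
#' @param x character vector.
#' @return character vector of canonical classes.
#' @export
normalize_exonic_func <- function(x) {
  y <- tolower(gsub("[ ]+", "_", trimws(x)))
  y[y %in% c(".", "", "unknown", "na")] <- NA_character_
  y[grepl("^frameshift", y) & !grepl("^nonframeshift", y)] <- "frameshift"
  y[grepl("^nonframeshift", y)] <- "nonframeshift"
  y[grepl("^stopgain", y)] <- "stopgain"
  y[grepl("^stoploss", y)] <- "stoploss"
  y[grepl("^nonsynonymous", y)] <- "nonsynonymous"
  y[grepl("^synonymous", y)] <- "synonymous"
  y
}

#' Parse an ANNOVAR-style protein change descriptor
#'
#' Accepts `GENE:TRANSCRIPT:exonN:c.X:p.R50C`-shaped strings (any subset of
#' the colon-separated parts) and extracts gene, transcript and the
#' (aa_ref, aa_pos, aa_alt) triple from the `p.` token.
#'
#' @param x character vector of descriptors (NA allowed).
#' @return data.table with columns aa_gene, aa_transcript, aa_ref, aa_pos,
#'   aa_alt (all NA when unparseable).
#' @export
parse_aa_change <- function(x) {
  n <- length(x)
  out <- data.table(
    aa_gene = NA_character_, aa_transcript = NA_character_,
    aa_ref = NA_character_, aa_pos = NA_integer_, aa_alt = NA_character_
  )[rep(1L, max(n, 1L))]
  if (n == 0L) return(out[0L])
  for (i in seq_len(n)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) next
    # multiple transcript annotations may be comma-separated; use the first
    s <- strsplit(s, ",", fixed = TRUE)[[1]][1]
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    ptok <- grep("^p\\.", parts, value = TRUE)
    gene_tok <- parts[!grepl("^(p\\.|c\\.|exon|NM_|ENST|XM_)", parts)]
    tr_tok <- grep("^(NM_|ENST|XM_)", parts, value = TRUE)
    if (length(gene_tok)) set(out, i, "aa_gene", gene_tok[1])
    if (length(tr_tok)) set(out, i, "aa_transcript", tr_tok[1])
    if (length(ptok)) {
      m <- regmatches(ptok[1],
        regexec("^p\\.\\(?([A-Za-z\\*]{1,3}?)(\\d+)([A-Za-z\\*]*)", ptok[1]))[[1]]
      if (length(m) == 4L) {
        set(out, i, "aa_ref", m[2])
        set(out, i, "aa_pos", as.integer(m[3]))
        if (nzchar(m[4])) set(out, i, "aa_alt", m[4])
      }
    }
  }
  out
}

.parse_info_string <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(character())
  toks <- strsplit(info, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", toks, fixed = TRUE)
  vals <- ifelse(eq > 0, substring(toks, eq + 1L), "")
  names(vals) <- ifelse(eq > 0, substring(toks, 1L, eq - 1L), toks)
  vals
}

.build_info_string <- function(vals) {
  if (!length(vals)) return(".")
  paste(ifelse(nzchar(vals), paste0(names(vals), "=", vals), names(vals)),
        collapse = ";")
}

.parse_gt <- function(gt, alt_index) {
  g <- strsplit(sub(":.*$", "", gt), "[/|]")[[1]]
  if (any(g == ".") || !length(g)) return("missing")
  nalt <- sum(g == as.character(alt_index))
  if (nalt == 0L) "hom_ref" else if (nalt == 1L) "het" else "hom_alt"
}

#' Read an annotated VCF into a variant table
#'
#' One output row per (VCF row, ALT allele); multi-allelic rows are split and
#' per-allele INFO values (comma-lists whose length matches the ALT count)
#' are subset to the matching allele. Missing INFO keys and "." values parse
#' to NA, never errors.
#'
#' @param path VCF file path.
#' @param key_map mapping of logical fields to INFO keys, see
#'   [default_key_map()].
#' @return A `variant_table` (data.table) with attributes `samples`,
#'   `header_meta` and `key_map`.
#' @export
read_vcf <- function(path, key_map = default_key_map()) {
  if (!file.exists(path)) ar_stop(sprintf("VCF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^##", lines)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (!length(hdr_idx)) {
    ar_stop("malformed VCF: missing #CHROM header line", "vcf_parse_error")
  }
  hdr_idx <- hdr_idx[1]
  meta <- lines[meta_idx[meta_idx < hdr_idx]]
  cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()

  declared <- regmatches(meta, regexec("^##INFO=<ID=([^,>]+)", meta))
  declared <- vapply(declared[lengths(declared) == 2],
                     `[`, "", 2)
  for (f in names(key_map)) {
    k <- key_map[[f]]
    if (!is.null(k) && length(meta) && !(k %in% declared)) {
      ar_warn(sprintf("INFO key '%s' (field '%s') not declared in VCF header",
                      k, f))
    }
  }

  body_idx <- setdiff(seq_along(lines), c(meta_idx, hdr_idx))
  body_idx <- body_idx[body_idx > hdr_idx & nzchar(lines[body_idx])]
  recs <- vector("list", length(body_idx))
  mapped_keys <- unlist(key_map, use.names = FALSE)
  for (j in seq_along(body_idx)) {
    ln <- body_idx[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      ar_stop(sprintf("malformed VCF row at line %d: expected >= 8 columns, got %d",
                      ln, length(f)), "vcf_parse_error")
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      ar_stop(sprintf("malformed VCF row at line %d: bad POS '%s'", ln, f[2]),
              "vcf_parse_error")
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    info_vals <- .parse_info_string(f[8])
    fmt_gts <- if (length(samples)) f[10:(9 + length(samples))] else character()
    rows <- vector("list", n_alt)
    for (a in seq_len(n_alt)) {
      iv <- info_vals
      if (n_alt > 1L && length(iv)) {
        for (k in intersect(names(iv), mapped_keys)) {
          pieces <- strsplit(iv[[k]], ",", fixed = TRUE)[[1]]
          if (length(pieces) == n_alt) iv[k] <- pieces[a]
        }
      }
      getv <- function(field) {
        k <- key_map[[field]]
        if (is.null(k) || !(k %in% names(iv))) return(NA_character_)
        v <- iv[[k]]
        if (v %in% c(".", "")) NA_character_ else v
      }
      af <- suppressWarnings(as.numeric(getv("pop_af")))
      row <- data.table(
        chrom = f[1], pos = pos, id = if (f[3] == ".") NA_character_ else f[3],
        ref = f[4], alt = alts[a],
        qual = if (f[6] == ".") NA_character_ else f[6],
        filter = if (f[7] == ".") NA_character_ else f[7],
        info = .build_info_string(iv),
        gene = getv("gene"),
        func_class = {
          v <- getv("func_class"); if (is.na(v)) v else tolower(v)
        },
        exonic_func = normalize_exonic_func(getv("exonic_func")),
        aa_change = getv("aa_change"),
        pop_af = af
      )
      for (si in seq_along(samples)) {
        set(row, 1L, paste0("gt_", samples[si]), .parse_gt(fmt_gts[si], a))
      }
      rows[[a]] <- row
    }
    recs[[j]] <- rbindlist(rows)
  }
  vt <- if (length(recs)) rbindlist(recs) else {
    base <- data.table(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), qual = character(),
      filter = character(), info = character(), gene = character(),
      func_class = character(), exonic_func = character(),
      aa_change = character(), pop_af = numeric()
    )
    for (s in samples) set(base, j = paste0("gt_", s), value = character())
    base
  }
  aa <- parse_aa_change(vt$aa_change)
  vt <- cbind(vt, aa)
  setattr(vt, "samples", samples)
  setattr(vt, "header_meta", meta)
  setattr(vt, "key_map", key_map)
  setattr(vt, "class", c("variant_table", class(vt)))
  vt[]
}

.gt_to_string <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                   missing = "./.")

#' Write a variant table to a VCF file
#'
#' Serializes one VCF row per record (records are already single-ALT). The
#' stored raw INFO string is emitted verbatim; `annotations` appends new
#' INFO keys, declared in the header with Description strings.
#'
#' @param records a `variant_table`.
#' @param path output file path.
#' @param annotations optional named list; each element is a vector with one
#'   value per record (NA values are omitted for that record).
#' @param descriptions optional named character, Description strings for the
#'   new INFO keys (defaults to the key name).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, annotations = NULL, descriptions = NULL) {
  meta <- attr(records, "header_meta") %||% "##fileformat=VCFv4.2"
  samples <- attr(records, "samples") %||% character()
  new_keys <- names(annotations) %||% character()
  for (k in new_keys) {
    if (length(annotations[[k]]) != nrow(records)) {
      ar_stop(sprintf("annotation '%s' length != number of records", k))
    }
    type <- if (is.numeric(annotations[[k]])) "Float" else "String"
    desc <- (descriptions %||% list())[[k]] %||% k
    line <- sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
                    k, type, desc)
    if (!any(grepl(sprintf("^##INFO=<ID=%s,", k), meta))) {
      meta <- c(meta, line)
    }
  }
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", if (length(samples)) c("FORMAT", samples)),
               collapse = "\t")
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    info <- records$info[i]
    if (is.na(info)) info <- "."
    extra <- character()
    for (k in new_keys) {
      v <- annotations[[k]][i]
      if (!is.na(v)) {
        extra <- c(extra, paste0(k, "=", format(v, scientific = FALSE,
                                                trim = TRUE)))
      }
    }
    if (length(extra)) {
      info <- if (info == ".") paste(extra, collapse = ";") else
        paste(c(info, extra), collapse = ";")
    }
    fields <- c(records$chrom[i], records$pos[i],
                records$id[i] %||% ".", records$ref[i], records$alt[i],
                records$qual[i], records$filter[i], info)
    fields[is.na(fields)] <- "."
    if (length(samples)) {
      gts <- vapply(samples, function(s) {
        .gt_to_string[[records[[paste0("gt_", s)]][i]]]
      }, "")
      fields <- c(fields, "GT", gts)
    }
    body[i] <- paste(fields, collapse = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, hdr, body), con)
  invisible(path)
}

#' Subset a variant table, preserving its VCF attributes
#'
#' `data.table` subsetting drops the `samples` / `header_meta` / `key_map`
#' attributes a `variant_table` needs for serialization; use this instead.
#'
#' @param records a `variant_table`.
#' @param idx integer or logical row index.
#' @return the subset, still a `variant_table`.
#' @export
subset_variants <- function(records, idx) {
  out <- records[idx]
  setattr(out, "samples", attr(records, "samples"))
  setattr(out, "header_meta", attr(records, "header_meta"))
  setattr(out, "key_map", attr(records, "key_map"))
  if (!inherits(out, "variant_table")) {
    setattr(out, "class", c("variant_table", class(out)))
  }
  out
}

#' Read a 6-column PED file
#'
#' Whitespace-delimited rows: family, sample, father, mother, sex, affection.
#' "0" in the parent columns parses to NA. Sample ids must be unique.
#'
#' @param path PED file path.
#' @return data.table with columns family_id, sample_id, father_id,
#'   mother_id, sex (male/female/unknown), affected
#'   (affected/unaffected/unknown).
#' @export
read_ped <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  rows <- lapply(lines_keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != 6L) {
      ar_stop(sprintf("malformed PED row at line %d: expected 6 columns, got %d",
                      ln, length(f)), "ped_parse_error")
    }
    data.table(
      family_id = f[1], sample_id = f[2],
      father_id = if (f[3] == "0") NA_character_ else f[3],
      mother_id = if (f[4] == "0") NA_character_ else f[4],
      sex = switch(f[5], "1" = "male", "2" = "female", "unknown"),
      affected = switch(f[6], "2" = "affected", "1" = "unaffected", "unknown")
    )
  })
  ped <- rbindlist(rows)
  if (nrow(ped) && anyDuplicated(ped$sample_id)) {
    dup <- ped$sample_id[duplicated(ped$sample_id)][1]
    ar_stop(sprintf("duplicate sample_id in PED: %s", dup), "ped_parse_error")
  }
  ped
}

#' Find complete trios in a pedigree
#'
#' A trio is a child whose father and mother ids both resolve to samples
#' present in the VCF sample set.
#'
#' @param ped data.table from [read_ped()].
#' @param vcf_samples character vector of VCF sample ids.
#' @return list of trio contexts, each `list(child_id, father_id, mother_id)`.
#' @export
find_trios <- function(ped, vcf_samples) {
  if (!nrow(ped)) return(list())
  idx <- which(!is.na(ped$father_id) & !is.na(ped$mother_id) &
                 ped$sample_id %in% vcf_samples &
                 ped$father_id %in% vcf_samples &
                 ped$mother_id %in% vcf_samples)
  lapply(idx, function(i) list(child_id = ped$sample_id[i],
                               father_id = ped$father_id[i],
                               mother_id = ped$mother_id[i]))
}

#' Read a gene list file (one symbol per line)
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list_file <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
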