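#' @title Causality binning, ranking and lasso filtering
#' @description
#' Integrates the five-tier pathogenicity call with the gene-validity status
#' into four review bins — (1) P/LP in a known gene, (2) P/LP in a candidate
#' gene, (3) P/LP in a novel gene, (4) VUS in a known gene — ranks variants
#' within and across bins by validity score, exports the
#' validity-vs-pathogenicity scatter, and applies a file-supplied polygon
#' (lasso) filter in that plane.
#' @name causality_ranker
NULL

.tier_ordinal <- c(benign = 1L, likely_benign = 2L, uncertain = 3L,
                   likely_pathogenic = 4L, pathogenic = 5L)
.tier_color <- c(benign = "darkgreen", likely_benign = "lightgreen",
                 uncertain = "yellow", likely_pathogenic = "orange",
                 pathogenic = "red")

#' Assign causality bins
#'
#' Bin 1: pathogenic/likely-pathogenic call in a known gene; bin 2: P/LP in
#' a candidate gene; bin 3: P/LP in a novel gene; bin 4: uncertain call in a
#' known gene. Every other (call, status) combination is unbinned (NA) and
#' excluded from ranking.
#'
#' @param records a `variant_table` annotated by [annotate_validity()] (or
#'   any table with `validity_score` and `gene_status` columns).
#' @param assessments output of [evaluate_variants()] aligned with
#'   `records`.
#' @return data.table with the variant key columns, call, validity_score,
#'   gene_status, bin (1-4 or NA) and rank (NA until [rank_variants()]).
#' @export
assign_bins <- function(records, assessments) {
  stopifnot(nrow(records) == nrow(assessments))
  rv <- data.table(
    chrom = records$chrom, pos = records$pos, ref = records$ref,
    alt = records$alt, gene = records$gene,
    call = assessments$call,
    validity_score = records$validity_score %||%
      rep(0, nrow(records)),
    gene_status = records$gene_status %||%
      rep("novel", nrow(records))
  )
  plp <- rv$call %in% c("pathogenic", "likely_pathogenic")
  rv[, bin := NA_integer_]
  rv[plp & gene_status == "known", bin := 1L]
  rv[plp & gene_status == "candidate", bin := 2L]
  rv[plp & gene_status == "novel", bin := 3L]
  rv[call == "uncertain" & gene_status == "known", bin := 4L]
  rv[, rank_ := NA_integer_]
  rv[]
}

#' Rank binned variants
#'
#' Global order: bin ascending, validity score descending within bin, then
#' (chrom, pos, ref, alt) lexicographic as a deterministic tie-break.
#' Ranks are 1..N over binned variants; unbinned variants are appended
#' after all binned ones, unranked.
#'
#' @param binned output of [assign_bins()].
#' @param sample_id optional sample/case label to carry through (cohort
#'   pooling ranks the pooled table with the same key).
#' @return the reordered table with `rank_` filled for binned variants.
#' @export
rank_variants <- function(binned, sample_id = NULL) {
  rv <- copy(binned)
  if (!is.null(sample_id) && !("sample" %in% names(rv))) {
    rv[, sample := sample_id]
  }
  rv[, `:=`(.b = fifelse(is.na(bin), 99L, bin))]
  setorder(rv, .b, -validity_score, chrom, pos, ref, alt)
  rv[, .b := NULL]
  n_binned <- sum(!is.na(rv$bin))
  rv[, rank_ := NA_integer_]
  if (n_binned) rv[seq_len(n_binned), rank_ := seq_len(n_binned)]
  rv[]
}

#' Export the validity-vs-pathogenicity scatter
#'
#' One point per variant: x = validity score, y = pathogenicity tier as an
#' ordinal (benign = 1 ... pathogenic = 5), with the conventional tier
#' colors. Writes a TSV and, optionally, a PNG scatter plot.
#'
#' @param ranked output of [rank_variants()] (or [assign_bins()]).
#' @param tsv_path output TSV path, or NULL to skip writing.
#' @param plot_path optional PNG path.
#' @return data.table of scatter points.
#' @export
scatter_export <- function(ranked, tsv_path = NULL, plot_path = NULL) {
  pts <- data.table(
    x = ranked$validity_score,
    y = unname(.tier_ordinal[ranked$call]),
    tier = ranked$call,
    color = unname(.tier_color[ranked$call])
  )
  # "key" is a reserved data.table() argument; add the column afterwards
  pts[, key := paste(ranked$chrom, ranked$pos, ranked$ref, ranked$alt,
                     sep = ":")]
  setcolorder(pts, c("key", "x", "y", "tier", "color"))
  if (!is.null(tsv_path)) fwrite(pts, tsv_path, sep = "\t")
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
    graphics::plot(pts$x, pts$y, col = pts$color, pch = 19,
         xlab = "gene validity score", ylab = "pathogenicity tier",
         yaxt = "n", main = "validity vs pathogenicity")
    graphics::axis(2, at = 1:5, labels = names(.tier_ordinal), las = 1,
                   cex.axis = 0.7)
  }
  pts[]
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' @param x,y point coordinates (vectors).
#' @param poly_x,poly_y polygon vertex coordinates (closed implicitly).
#' @param eps tolerance for the boundary test.
#' @return logical vector: inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, poly_x, poly_y, eps = 1e-9) {
  n <- length(poly_x)
  stopifnot(n >= 3, length(poly_y) == n)
  m <- length(x)
  inside <- logical(m)
  for (p in seq_len(m)) {
    px <- x[p]; py <- y[p]
    hit <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly_x[i]; yi <- poly_y[i]
      xj <- poly_x[j]; yj <- poly_y[j]
      # boundary: point within eps of segment (i,j)
      dx <- xj - xi; dy <- yj - yi
      seg_len2 <- dx * dx + dy * dy
      t <- if (seg_len2 > 0) ((px - xi) * dx + (py - yi) * dy) / seg_len2
      else 0
      t <- min(max(t, 0), 1)
      ddx <- px - (xi + t * dx); ddy <- py - (yi + t * dy)
      if (ddx * ddx + ddy * ddy <= eps * eps) on_edge <- TRUE
      # even-odd ray crossing
      if ((yi > py) != (yj > py)) {
        x_int <- xi + (py - yi) / (yj - yi) * (xj - xi)
        if (px < x_int) hit <- !hit
      }
      j <- i
    }
    inside[p] <- hit || on_edge
  }
  inside
}

#' Lasso-filter variants in the validity-pathogenicity plane
#'
#' Selects scatter points strictly inside or on the boundary of the polygon
#' (even-odd rule) and optionally writes a VCF restricted to the selected
#' variants. A zero-area polygon selects only boundary-coincident points,
#' with a warning.
#'
#' @param points scatter points from [scatter_export()].
#' @param polygon list/data.frame with `x` and `y` vertex coordinates
#'   (>= 3 vertices), or a path to a JSON file holding them.
#' @param records optional `variant_table` aligned with `points`, filtered
#'   and written to `vcf_path` when given.
#' @param vcf_path optional output VCF path.
#' @return list with `selected` (logical), `keys` (selected variant keys)
#'   and `vcf` (path or NULL).
#' @export
lasso_filter <- function(points, polygon, records = NULL, vcf_path = NULL) {
  if (is.character(polygon) && length(polygon) == 1L) {
    polygon <- jsonlite::read_json(polygon, simplifyVector = TRUE)
  }
  px <- as.numeric(polygon$x %||% polygon[["x"]])
  py <- as.numeric(polygon$y %||% polygon[["y"]])
  if (length(px) < 3 || length(px) != length(py)) {
    ar_stop("lasso polygon needs >= 3 (x, y) vertices")
  }
  area2 <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py))
  if (area2 == 0) {
    ar_warn("degenerate (zero-area) lasso polygon: only boundary points selected")
  }
  sel <- point_in_polygon(points$x, points$y, px, py)
  out_vcf <- NULL
  if (!is.null(records) && !is.null(vcf_path)) {
    stopifnot(nrow(records) == length(sel))
    write_vcf(subset_variants(records, which(sel)), vcf_path)
    out_vcf <- vcf_path
  }
  list(selected = sel, keys = points$key[sel], vcf = out_vcf)
}
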