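`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a classed condition
#' @noRd
ar_stop <- function(msg, class = "acmgrank_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ar_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a child RNG seed from a base seed, kept below 2^31
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Genomic key string for a variant row (chrom:pos:ref:alt)
#' @noRd
variant_keys <- function(dt) {
  paste(dt$chrom, dt$pos, dt$ref, dt$alt, sep = ":")
}

is_curie <- function(x, prefix) grepl(paste0("^", prefix, ":"), x)
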