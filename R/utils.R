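# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of sub-seeds from one master seed; keeps every stage's
# randomness a pure function of the pipeline seed while staying in 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# Validate a genes x samples expression matrix with unique dimnames.
check_expr <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix", arg))
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(expr))) {
    abort(sprintf("duplicate gene identifiers in `%s`", arg))
  }
  if (anyDuplicated(colnames(expr))) {
    abort(sprintf("duplicate sample identifiers in `%s`", arg))
  }
  invisible(expr)
}

# Coerce a labeling to a canonical tibble(sample_id, label).
as_labeling <- function(labels, arg = "labels") {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "label") %in% names(labels))) {
      abort(sprintf("`%s` must have columns sample_id and label", arg))
    }
    out <- tibble(
      sample_id = as.character(labels$sample_id),
      label = as.character(labels$label)
    )
  } else if (!is.null(names(labels))) {
    out <- tibble(sample_id = names(labels), label = as.character(labels))
  } else {
    abort(sprintf("`%s` must be a data frame or a named vector", arg))
  }
  if (anyDuplicated(out$sample_id)) {
    abort(sprintf("duplicate sample_id in `%s`", arg))
  }
  out
}

# Raw (unscaled) median absolute deviation, optionally with the 1.4826
# consistency factor used by stats::mad.
mad_raw <- function(x, scaled = FALSE) {
  stats::mad(x, constant = if (scaled) 1.4826 else 1)
}

row_mads <- function(x, scaled = FALSE) {
  apply(x, 1L, mad_raw, scaled = scaled)
}
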