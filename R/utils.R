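#' @keywords internal
"_PACKAGE"

# Round half away from zero. base::round() rounds half to even, which would
# send 100.5 test samples to 100; clinical-split bookkeeping wants 101.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
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
  force(expr)
}

# Stratified fold assignment: integer vector in 1..k, balanced within class.
stratified_folds <- function(labels, k) {
  if (any(table(labels) < k)) {
    stop("stratification error: a class has fewer samples than folds (k = ",
         k, ")", call. = FALSE)
  }
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
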