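# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

# Half-up rounding to `digits` significant figures, with a small relative
# guard so that decimal halves stored just below .5 in binary still round up.
signif_half_up <- function(x, digits) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    p <- 10^(floor(log10(abs(x[nz]))) + 1 - digits)
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / p + 0.5 + 1e-9) * p
  }
  out
}
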