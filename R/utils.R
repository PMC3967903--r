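# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. With seed = NULL the expression simply uses
# (and advances) the global stream.
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# max of a count vector laid out as a G x K matrix in `counts`, rows = groups
.row_max <- function(counts, G, K) {
  m <- matrix(counts, nrow = G, ncol = K)
  do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
}

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# stable paste key
.key <- function(...) paste(..., sep = "\r")
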