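# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates expr as-is.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# composite trapezoid integral of y over x (sorted, equally or unequally spaced)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

asBinaryLabels <- function(labels, what = "labels") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("sensitive", "resistant"))
  if (length(bad)) {
    stop(sprintf("%s must be 'sensitive'/'resistant' (found: %s)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  labels
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
}
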