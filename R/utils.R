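# internal helpers shared across modules

err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phylomic_error")))
}

# Run `expr` with the RNG seeded by `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# percentage with one printed decimal (round-half-even, R's round())
pct1 <- function(x) round(100 * x, 1)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)

# zero-padded sequential names: lab("g", 3, 1233) -> "g0003"
seq_names <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), seq_len(n))
}
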