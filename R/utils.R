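# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so every generator is a pure function of
# its seed.
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
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

# Add-one permutation p-value: never zero, never exactly one-sided biased.
perm_pvalue <- function(null, observed) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# Row-wise means by group label, returning a units-length vector.
group_mean <- function(mat, members) {
  if (length(members) == 0L) stop_arg("empty group")
  colMeans(mat[members, , drop = FALSE])
}
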