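# Internal helpers: seeded evaluation and 0-based half-open <-> IRanges
# conversion. All user-facing coordinates in this package are 0-based
# half-open; IRanges (1-based closed) appears only inside functions.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# 0-based half-open -> IRanges
ir0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# IRanges -> 0-based half-open data.frame
as_df0 <- function(x) {
  data.frame(start = BiocGenerics::start(x) - 1L,
             end   = BiocGenerics::end(x))
}

# width-sum of the merged union of 0-based half-open intervals
merged_bp <- function(start, end) {
  if (length(start) == 0L) return(0)
  sum(BiocGenerics::width(IRanges::reduce(ir0(start, end))))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single number")
  if (x < lower || x > upper || (strict_upper && x >= upper))
    stop("'", name, "' out of range [", lower, ", ", upper,
         if (strict_upper) ")" else "]")
  invisible(x)
}
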