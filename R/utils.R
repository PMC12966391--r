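#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state so package functions that take an explicit
# seed neither depend on nor disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

vnorm <- function(x) sqrt(sum(x^2))

# Row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m^2))

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == round(x)
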