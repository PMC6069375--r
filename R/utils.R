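#' @importFrom stats cor rnorm runif sd var predict
#' @importFrom rlang abort .data
NULL

# Deterministic sub-seed derivation so one top-level seed drives every
# stochastic stage (carriers, jitter, ICA/NMF init) independently.
# Keeps results < 2^31 so they are valid set.seed() inputs.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) {
    s <- (s * 69069 + as.double(k) %% 2147483647) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(msg, class = "fosemg_invalid_argument") {
  rlang::abort(msg, class = class)
}

check_numeric_vector <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be a finite numeric vector.", name))
  }
  invisible(x)
}

check_same_length <- function(x, y, nx = "x", ny = "y") {
  if (length(x) != length(y)) {
    stop_invalid(sprintf("`%s` (length %d) and `%s` (length %d) must have equal lengths.",
                         nx, length(x), ny, length(y)))
  }
  invisible(NULL)
}
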