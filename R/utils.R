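#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All randomness in the package funnels through this so that identical
# (params, n, seed) triples give byte-identical output.
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Cheap stable checksum for provenance stamps (not cryptographic).
param_checksum <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  raw <- utf8ToInt(txt)
  a <- 1L; b <- 0L
  for (v in raw) {
    a <- (a + v) %% 65521L
    b <- (b + a) %% 65521L
  }
  sprintf("%04x%04x", b, a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetrize and check a correlation matrix, error naming the block on failure.
check_psd <- function(R, what = "correlation matrix", tol = -1e-8) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 what, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

is_binary_type <- function(type) type == "binary"
is_ordinal_type <- function(type) grepl("^ordinal", type)
is_categorical_type <- function(type) is_binary_type(type) | is_ordinal_type(type)

ordinal_levels <- function(type) {
  k <- suppressWarnings(as.integer(sub("^ordinal\\((\\d+)\\)$", "\\1", type)))
  if (is.na(k)) stop("malformed ordinal type tag: ", type, call. = FALSE)
  k
}
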