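#' @useDynLib rumicol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor dist dnorm hclust as.dist cophenetic
#'   model.matrix pf pgamma pnorm pt quantile rmultinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table packageVersion head combn
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
# All simulation / permutation code funnels through this so that user sessions
# are never perturbed and identical seeds give bit-identical results.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# FNV-1a 32-bit hash of a deparsed R object; used to stamp output files with a
# configuration fingerprint without adding a digest dependency.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 21 bits (code points < 2^21); keep h a double mod 2^32
    h <- (h %/% 2097152) * 2097152 +
      bitwXor(as.integer(h %% 2097152), as.integer(b %% 2097152))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
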