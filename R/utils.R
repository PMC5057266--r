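# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Splits one master RNG seed into per-stage seeds by hashing a stage tag, so
#' stages can be re-run in isolation and still reproduce a full-pipeline run.
#'
#' @param master integer master seed.
#' @param tag character stage name.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  s <- (abs(as.double(master)) %% m)
  as.integer(((s * 48271) %% m + h) %% (m - 1) + 1)
}

# Evaluate `expr` under set.seed(seed) without clobbering the caller's RNG
# stream. All exported stochastic functions route through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Lightweight content fingerprint of a numeric matrix (dims, dimnames and a
# positionally weighted sum); used for provenance in ModuleCollection.
matrix_digest <- function(mat) {
  v <- as.vector(mat)
  w <- sum(v * seq_along(v) %% 997, na.rm = TRUE)
  sprintf("%dx%d:%.6e:%.6e", nrow(mat), ncol(mat), sum(v, na.rm = TRUE), w)
}

assert_log_ratio_matrix <- function(mat, arg = "matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(arg, " must carry gene rownames and condition colnames", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop(arg, " has duplicated gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop(arg, " has duplicated condition identifiers", call. = FALSE)
  invisible(mat)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
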