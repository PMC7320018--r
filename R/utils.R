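# Internal helpers: reproducible seed derivation and scoped RNG use.

#' @useDynLib tnbcscm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Derive a child seed from a master seed and a string key, so that e.g. each
# omics view or repeat index gets its own reproducible RNG substream that does
# not shift when unrelated streams are added. FNV-1a style hash folded into
# [1, 2^31 - 2].
derive_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  h <- 216613626
  for (b in utf8ToInt(paste0(key))) {
    # polynomial rolling hash modulo 2^31-1, exact in doubles
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h + abs(as.numeric(master_seed))) %% 2147483646 + 1)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Binary label check used across modules; returns an integer 0/1 vector.
check_binary_labels <- function(labels, n = NULL) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary (0 = non-TNBC, 1 = TNBC), with no missing values")
  }
  if (!is.null(n) && length(labels) != n) {
    stop(sprintf("expected %d labels, got %d", n, length(labels)))
  }
  as.integer(labels)
}
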