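# Internal helpers: seeded evaluation, hierarchical seed derivation, hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package functions do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a string key. Deterministic,
# stays below 2^31, and independent of how many other keys are drawn, so a
# cohort keeps its existing subjects when more are added.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

# MD5 of an R object via its serialized JSON-ish text form; used to stamp
# result files with the configuration that produced them.
hash_config <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(utils::capture.output(utils::str(x, digits.d = 15)),
                   collapse = "\n"), f)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
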