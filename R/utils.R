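# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a child seed from a master seed and a character key
#'
#' Deterministic 32-bit mixing (FNV-1a over the key, folded with the master
#' seed) so that every cell of a simulated cohort gets an independent,
#' reproducible random stream. The result is always a positive integer below
#' 2^31.
#'
#' @param master integer master seed.
#' @param ... character or numeric parts identifying the child stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- fnv1a32(key)
  as.integer(h %% 2147483647) + 1L
}

# FNV-1a 32-bit hash, done in double precision with explicit mod 2^32.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # h * 16777619 mod 2^32, split to stay inside double precision
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor needs integers; a may exceed .Machine$integer.max
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

#' Hash an R object to a short hexadecimal string
#'
#' Used to stamp every pipeline output table with a hash of the configuration
#' that produced it, so tables from different runs cannot be mixed silently.
#'
#' @param x any serialisable R object.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
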