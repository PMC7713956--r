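# Shared constants and small helpers.

#' Allele placeholder codes
#'
#' Genotypes are stored as integer fragment lengths (base pairs). Two special
#' codes are reserved: `NULL_ALLELE` (0) marks an allele slot that was inferred
#' to be a non-amplifying dropout, and `W_PLACEHOLDER` (-1) marks the W
#' chromosome slot of a ZW female at a Z-linked marker (which behaves like a
#' null allele in transmission analyses).
#'
#' @format Integer scalars.
#' @name allele-codes
NULL

#' @rdname allele-codes
#' @export
NULL_ALLELE <- 0L

#' @rdname allele-codes
#' @export
W_PLACEHOLDER <- -1L

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child RNG seed from a root seed
#'
#' Deterministically mixes a root seed with a stream label and an index so that
#' independent pipeline stages (and repeated broods within a stage) draw from
#' reproducible, distinct streams. The result is always a positive integer
#' below 2^31.
#'
#' @param root Integer root seed.
#' @param label Character stream label (e.g. `"meiosis"`).
#' @param index Optional integer index within the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(root, label = "", index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(root) %% m
  chars <- utf8ToInt(as.character(label))
  for (ch in chars) h <- (h * 31 + ch) %% m
  h <- (h * 48271 + as.numeric(index) * 2246822519 %% m) %% m
  as.integer(h %% (m - 1) + 1)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Format an allele pair/quad as a canonical signature string.
allele_signature <- function(alleles) {
  paste(sort(as.integer(alleles)), collapse = "/")
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
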