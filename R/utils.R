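# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' Vectorised over `x`; accepts only the alphabet `A,C,G,T,N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !ch %in% names(COMPLEMENT)
    if (any(bad)) stop("non-DNA character in sequence: ", s)
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  out <- unname(COMPLEMENT[b])
  out[is.na(b)] <- NA_character_
  out
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic sub-seed derivation, kept well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(offset) %% 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
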