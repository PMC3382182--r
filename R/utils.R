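# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' The caller's RNG state is saved and restored, so generators are
#' deterministic in `(spec, seed)` without perturbing the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA string at a target GC content
#' @param length number of bases.
#' @param gc target GC fraction in (0,1).
#' @return a single character string.
#' @keywords internal
random_dna <- function(length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' GC fraction of a DNA string (vectorised)
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions; NaN for empty strings.
#' @export
gc_content <- function(x) {
  s <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(s, "GC", as.prob = TRUE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Apply random substitutions at `rate` to a base vector; returns
# list(bases, positions) with 1-based changed positions.
mutate_bases <- function(bases, rate) {
  n <- length(bases)
  if (n == 0L || rate <= 0) return(list(bases = bases, positions = integer(0)))
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(list(bases = bases, positions = integer(0)))
  pos <- sort(sample.int(n, k))
  for (i in pos) {
    bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1L)
  }
  list(bases = bases, positions = pos)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
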