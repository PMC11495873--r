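# Shared low-level helpers: alphabet coding, seeded evaluation, validation.
# RNA is handled in the DNA alphabet throughout (U is stored as T).

BASES <- c("A", "C", "G", "T")

# 8 trace classes emitted by the basecaller network: 4 mono- + 4 di-nucleotide
TRACE_CLASSES <- c("A", "C", "G", "T", "AA", "CC", "GG", "TT")

#' Convert a sequence string to integer base codes
#'
#' @param seq character scalar over A/C/G/T (U is accepted and read as T).
#' @return integer vector of codes in 1..4 (A=1, C=2, G=3, T=4).
#' @keywords internal
seq_to_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  codes <- match(chars, BASES)
  if (anyNA(codes)) {
    stop("sequence contains non-ACGT(U) characters: ",
         paste(unique(chars[is.na(codes)]), collapse = ","))
  }
  codes
}

codes_to_seq <- function(codes) paste(BASES[codes], collapse = "")

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
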