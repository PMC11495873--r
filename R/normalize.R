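#' Median-based modified Z-score of a signal vector
#'
#' Robust per-read standardization of current intensities:
#' `0.6745 * (x - median(x)) / MAD(x)`, with MAD the (unscaled) median
#' absolute deviation. The constant 0.6745 is the 75th percentile of the
#' standard normal, making the score comparable to an ordinary Z-score for
#' Gaussian data while being insensitive to the current spikes common in
#' nanopore reads. Invariant under positive affine transforms of the input.
#'
#' @param x numeric signal vector, length >= 2.
#' @param mad_zero what to do when MAD is 0 (a constant read): `"error"`
#'   (default — such reads are degenerate) or `"epsilon"` (substitute the
#'   machine epsilon, yielding large finite scores).
#' @return numeric vector of standardized values, same length as `x`.
#' @examples
#' modified_zscore(c(1, 2, 3, 4, 5))  # -1.349 -0.6745 0 0.6745 1.349
#' @export
modified_zscore <- function(x, mad_zero = c("error", "epsilon")) {
  mad_zero <- match.arg(mad_zero)
  if (!is.numeric(x) || length(x) < 2L) {
    stop("signal must be a numeric vector of length >= 2", call. = FALSE)
  }
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))
  if (mad == 0) {
    if (mad_zero == "error") {
      stop("MAD is zero (constant signal); cannot standardize", call. = FALSE)
    }
    mad <- .Machine$double.eps
  }
  0.6745 * (x - med) / mad
}

#' Collapse 8-class basecaller trace rows into 4 normalized base probabilities
#'
#' The basecaller emits, per trace row, integer probabilities 0-255 for eight
#' classes (A, C, G, U and the doublet classes AA, CC, GG, UU). Each base's
#' mono- and di-nucleotide probabilities are summed, `q_i = p_i + p_ii`,
#' divided by 255 and clipped at 1, giving four values in \[0, 1\] per row.
#'
#' @param trace integer/numeric matrix with 8 columns (A,C,G,T,AA,CC,GG,TT),
#'   values in \[0, 255\]; a single row may be given as a length-8 vector.
#' @return numeric matrix with 4 columns (A, C, G, T), values in \[0, 1\].
#' @examples
#' normalize_trace(c(100, 0, 0, 0, 55, 0, 0, 0))  # q_A = 155/255
#' @export
normalize_trace <- function(trace) {
  if (is.vector(trace)) trace <- matrix(trace, nrow = 1L)
  if (!is.matrix(trace) || ncol(trace) != 8L) {
    stop("trace must have 8 columns (A,C,G,T,AA,CC,GG,TT)", call. = FALSE)
  }
  if (anyNA(trace) || any(trace < 0) || any(trace > 255)) {
    stop("trace values must lie in [0, 255]", call. = FALSE)
  }
  q <- (trace[, 1:4, drop = FALSE] + trace[, 5:8, drop = FALSE]) / 255
  q <- pmin(q, 1)
  colnames(q) <- BASES
  q
}

#' Normalize a raw read (signal + trace)
#'
#' Applies [modified_zscore()] to the whole signal and [normalize_trace()] to
#' the trace matrix, carrying moves and alignment info through.
#'
#' @param read a `raw_read`.
#' @inheritParams modified_zscore
#' @return object of class `normalized_read`: list with `signal` (normalized),
#'   `trace` (rows x 4 in \[0,1\]), `moves`, `ref_name`, `ref_start`,
#'   `ref_end`, plus simulator truth fields when present.
#' @export
normalize_read <- function(read, mad_zero = c("error", "epsilon")) {
  stopifnot(inherits(read, "raw_read"))
  if (length(read$signal) != 10L * nrow(read$trace)) {
    stop("signal length must be 10x the number of trace rows", call. = FALSE)
  }
  structure(
    list(signal = modified_zscore(read$signal, mad_zero),
         trace = normalize_trace(read$trace),
         moves = read$moves, ref_name = read$ref_name,
         ref_start = read$ref_start, ref_end = read$ref_end,
         truth_rows = read$truth_rows, modified = read$modified,
         mod_positions = read$mod_positions),
    class = "normalized_read"
  )
}
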