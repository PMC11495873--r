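#' Synthetic pore model: expected current level per 5-mer
#'
#' Builds the lookup table that drives signal simulation: one expected current
#' level and noise SD per canonical 5-mer, an additive level offset applied at
#' m6A-modified adenosines, and dwell-time parameters. Levels are drawn once
#' from a fixed internal seed, so the same arguments always yield the same
#' table; they stand in for pore chemistry rather than reproducing any vendor
#' calibration.
#'
#' @param level_mean grand mean current level (arbitrary current units).
#' @param level_spread SD of per-5-mer expected levels around `level_mean`.
#' @param level_sd within-5-mer noise SD (current units); the simulator scales
#'   this by the config's `noise_scale`.
#' @param m6a_offset additive current shift applied to dwell segments of
#'   modified adenosines. The default equals `2 * level_sd`.
#' @param dwell_rows_mean mean number of trace rows per base (1 trace row
#'   summarizes 10 signal samples, so the default 3 is 30 samples/base).
#' @return object of class `pore_model`: list with `levels` (named numeric,
#'   1024 entries), `level_sd`, `m6a_offset`, `dwell_rows_mean`.
#' @examples
#' pm <- pore_model()
#' pm$levels[["GGACT"]]
#' @export
pore_model <- function(level_mean = 100, level_spread = 12, level_sd = 2.5,
                       m6a_offset = 2 * level_sd, dwell_rows_mean = 3) {
  assert_scalar_number(level_mean, "level_mean")
  assert_scalar_number(level_spread, "level_spread", lower = 0)
  assert_scalar_number(level_sd, "level_sd", lower = 1e-12)
  assert_scalar_number(m6a_offset, "m6a_offset")
  assert_scalar_number(dwell_rows_mean, "dwell_rows_mean", lower = 1)

  kmers <- apply(expand.grid(BASES, BASES, BASES, BASES, BASES,
                             stringsAsFactors = FALSE)[, 5:1],
                 1L, paste, collapse = "")
  levels <- with_seed(20240601L, {
    level_mean + level_spread * stats::rnorm(length(kmers))
  })
  names(levels) <- kmers
  structure(
    list(levels = levels, level_sd = level_sd, m6a_offset = m6a_offset,
         dwell_rows_mean = dwell_rows_mean),
    class = "pore_model"
  )
}

validate_pore_model <- function(pm) {
  stopifnot(inherits(pm, "pore_model"))
  if (length(pm$levels) != 1024L || !all(is.finite(pm$levels))) {
    stop("pore model must give a finite level for each of the 1024 5-mers")
  }
  if (!is.finite(pm$level_sd) || pm$level_sd <= 0) stop("level_sd must be positive")
  if (!is.finite(pm$m6a_offset)) stop("m6a_offset must be finite")
  invisible(pm)
}

#' @export
print.pore_model <- function(x, ...) {
  cat("Synthetic pore model: 1024 5-mer levels,",
      sprintf("mean %.1f, level SD %.2f, m6A offset %+.2f, %.1f trace rows/base\n",
              mean(x$levels), x$level_sd, x$m6a_offset, x$dwell_rows_mean))
  invisible(x)
}
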