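# Trace-based resquiggling: realign basecaller trace rows to the reference
# by dynamic programming so every reference base owns a trace/signal interval.

new_segmentation <- function(pos, row_start, row_end) {
  seg <- data.frame(pos = as.integer(pos), row_start = as.integer(row_start),
                    row_end = as.integer(row_end))
  if (nrow(seg) > 0L) {
    stopifnot(all(seg$row_end > seg$row_start),
              all(diff(seg$row_start) > 0L),
              all(seg$row_start[-1L] == seg$row_end[-nrow(seg)]),
              all(diff(seg$pos) == 1L))
  }
  class(seg) <- c("segmentation", "data.frame")
  seg
}

#' Map basecaller move flags to initial segment boundaries
#'
#' The basecaller's CTC decoder emits a move flag per trace row marking where
#' a new base starts; those rows are the initial segmentation boundaries.
#'
#' @param moves 0/1 integer vector, one per trace row.
#' @return integer vector of 0-based boundary rows (one per move=1 row).
#' @export
map_moves <- function(moves) {
  stopifnot(is.numeric(moves), all(moves %in% c(0L, 1L)))
  b <- which(moves == 1L) - 1L
  if (length(b) == 0L) stop("read has no move=1 rows; unusable", call. = FALSE)
  b
}

#' Split over-long segments at their midpoint
#'
#' A single pass over the boundary list: any interval longer than 1.5x the
#' median interval length is split at its (floor) midpoint, adding candidate
#' boundaries for the realignment step. Intervals are half-open in trace-row
#' coordinates; the final interval ends at `n_rows`.
#'
#' @param boundaries 0-based boundary rows (from [map_moves()]).
#' @param n_rows total number of trace rows.
#' @return refined, sorted boundary vector.
#' @export
split_long_intervals <- function(boundaries, n_rows) {
  stopifnot(length(boundaries) >= 1L, all(boundaries < n_rows))
  len <- diff(c(boundaries, n_rows))
  med <- stats::median(len)
  long <- which(len > 1.5 * med)
  if (length(long) == 0L) return(boundaries)
  extra <- boundaries[long] + len[long] %/% 2L
  sort(unique(c(boundaries, extra)))
}

#' Mean 4-base trace per segment
#'
#' @param trace normalized trace matrix (rows x 4, from [normalize_trace()]).
#' @param boundaries 0-based segment start rows.
#' @return matrix (segments x 4): column means of the trace rows in each
#'   half-open segment.
#' @export
aggregate_trace <- function(trace, boundaries) {
  stopifnot(is.matrix(trace), ncol(trace) == 4L)
  n_rows <- nrow(trace)
  ends <- c(boundaries[-1L], n_rows)
  if (any(ends <= boundaries)) stop("empty segment", call. = FALSE)
  grp <- rep(seq_along(boundaries), ends - boundaries)
  out <- rowsum(trace[(boundaries[1L] + 1L):n_rows, , drop = FALSE], grp) /
    (ends - boundaries)
  colnames(out) <- BASES
  out
}

#' Realign trace segments to the reference by dynamic programming
#'
#' Fills a score matrix over (segment n, reference base m). The per-cell
#' match probability is `P(n, m) = <trace4[n], onehot(ref[m])>`. With
#' alignment score `A = W * (S_match - S_mismatch)` (defaults W = 1,
#' S_match = 1, S_mismatch = 0), a transition into base m at segment n scores
#' `A * P(n, m)` and remaining at base m scores `A * (1 - P(n, m + 1))` —
#' one Bernoulli decision about moving into the next base, with
#' `P(., M + 1) = 0` past the end of the aligned interval. Each cell keeps
#' `max(S_trans, S_non_trans)`; transitions win exact ties so the traceback,
#' run backward from the final cell, always covers the full reference
#' interval. The traceback yields a monotone segment-to-base assignment
#' advancing at most one base per segment.
#'
#' Segments beginning at a basecaller move boundary carry direct evidence of
#' a base start, while split-added boundaries are only candidates for dwell
#' intervals the basecaller merged. When `is_move` is supplied, transitions
#' whose segment starts at a move boundary therefore receive a score bonus
#' of `A * move_bonus`; because per-cell trace scores lie in \[0, A\], a
#' bonus above 1 makes the path place base transitions at move boundaries
#' whenever enough of them exist and lets the trace scores arbitrate among
#' them (and fall back to split candidates where moves are missing). Without
#' `is_move` the recursion is pure trace scoring.
#'
#' @param seg_trace matrix (segments x 4) of per-segment mean traces.
#' @param ref_seq reference sequence of the aligned interval.
#' @param s_match,s_mismatch,weight scoring constants; defaults give A = 1.
#' @param move_bonus transition bonus at move boundaries (in units of A).
#' @param is_move logical per segment: does it start at a move boundary?
#'   `NULL` disables the bonus.
#' @return integer vector: the 1-based reference index assigned to each
#'   segment (monotone non-decreasing, covering 1..M).
#' @export
realign_path <- function(seg_trace, ref_seq, s_match = 1, s_mismatch = 0,
                         weight = 1, move_bonus = 2, is_move = NULL) {
  stopifnot(is.matrix(seg_trace), ncol(seg_trace) == 4L)
  codes <- seq_to_codes(ref_seq)
  N <- nrow(seg_trace)
  M <- length(codes)
  if (M < 1L) stop("empty reference interval", call. = FALSE)
  if (N < M) {
    stop(sprintf("read has %d segments but the interval has %d bases; %s",
                 N, M, "cannot cover every base"), call. = FALSE)
  }
  if (all(seg_trace == 0)) stop("degenerate all-zero trace", call. = FALSE)
  A <- weight * (s_match - s_mismatch)

  bonus <- if (is.null(is_move)) numeric(N) else {
    stopifnot(length(is_move) == N)
    A * move_bonus * as.numeric(is_move)
  }
  P <- seg_trace[, codes, drop = FALSE]            # P[n, m] = match prob
  Pnext <- cbind(P[, -1L, drop = FALSE], 0)        # match with base m + 1
  S <- matrix(-Inf, N, M)
  from_trans <- matrix(FALSE, N, M)
  S[1L, 1L] <- A * P[1L, 1L] + bonus[1L]
  from_trans[1L, 1L] <- TRUE
  for (n in seq_len(N)[-1L]) {
    trans <- c(-Inf, S[n - 1L, -M]) + A * P[n, ] + bonus[n]
    stay <- S[n - 1L, ] + A * (1 - Pnext[n, ])
    take <- trans >= stay                          # prefer transition on ties
    S[n, ] <- ifelse(take, trans, stay)
    from_trans[n, ] <- take
  }
  path <- integer(N)
  m <- M
  for (n in rev(seq_len(N))) {
    path[n] <- m
    if (from_trans[n, m]) m <- m - 1L
  }
  if (m != 0L) stop("traceback failed to cover the reference", call. = FALSE)
  path
}

#' Resquiggle one read: moves -> split -> aggregate -> realign
#'
#' Full trace-based resquiggling of a normalized read against the reference
#' subsequence it aligns to, producing per-base trace-row intervals (signal
#' intervals are 10x the trace intervals).
#'
#' @param nread a `normalized_read`.
#' @param ref_seq the reference sequence of `[ref_start, ref_end)`.
#' @inheritParams realign_path
#' @return a `segmentation` data.frame: `pos` (0-based transcript
#'   coordinate), `row_start`, `row_end` (half-open trace-row interval).
#' @export
resquiggle_read <- function(nread, ref_seq, s_match = 1, s_mismatch = 0,
                            weight = 1, move_bonus = 2) {
  stopifnot(inherits(nread, "normalized_read"))
  n_rows <- nrow(nread$trace)
  mv <- map_moves(nread$moves)
  b <- split_long_intervals(mv, n_rows)
  seg_trace <- aggregate_trace(nread$trace, b)
  path <- realign_path(seg_trace, ref_seq, s_match, s_mismatch, weight,
                       move_bonus = move_bonus, is_move = b %in% mv)
  ends <- c(b[-1L], n_rows)
  first <- match(seq_len(max(path)), path)         # first segment of each base
  last <- length(path) + 1L - match(seq_len(max(path)), rev(path))
  new_segmentation(pos = nread$ref_start + seq_len(max(path)) - 1L,
                   row_start = b[first], row_end = ends[last])
}
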