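# DRACH site enumeration, 5-mer window extraction and read-feature assembly.

#' All 18 DRACH motifs
#'
#' D = A/G/T(U), R = A/G, then A, C, H = A/C/T(U): 3 x 2 x 1 x 1 x 3 = 18
#' motifs (DNA alphabet; U is written T).
#' @return character vector of the 18 motifs.
#' @export
drach_motifs <- function() {
  g <- expand.grid(D = c("A", "G", "T"), R = c("A", "G"), A = "A", C = "C",
                   H = c("A", "C", "T"), stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste, collapse = ""))
}

#' Find all DRACH sites in a sequence
#'
#' Degenerate-motif scan (IUPAC pattern `DRACH`) over the reference; returns
#' the 0-based position of each central A. Matches necessarily lie at least
#' 2 nt from either end because the full 5-mer must fit.
#'
#' @param seq reference sequence (A/C/G/T(U)).
#' @param transcript transcript id recorded in the output.
#' @return data.frame: `transcript`, `pos` (0-based central A), `motif`.
#' @examples
#' find_drach_sites("TTGGACTTT")  # one site at pos 4, motif GGACT
#' @export
find_drach_sites <- function(seq, transcript = "ref") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("Uu", "Tt", toupper(seq))
  if (nchar(seq) < 5L) {
    return(data.frame(transcript = character(), pos = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  m <- Biostrings::matchPattern("DRACH", Biostrings::DNAString(seq),
                                fixed = FALSE)
  starts <- Biostrings::start(m)
  data.frame(transcript = rep(transcript, length(starts)),
             pos = as.integer(starts + 1L),   # 0-based central A = start0 + 2
             motif = as.character(m), stringsAsFactors = FALSE)
}

#' Cut the raw 5-channel window of one read at one DRACH site
#'
#' Takes the 5 contiguous per-base segments centred on the site's A, the
#' corresponding normalized signal samples (10 per trace row), and the
#' normalized trace rows expanded 10x so all five channels share a common
#' length before resizing. Reads whose segmentation does not cover the full
#' 5-nt window are skipped (returns `NULL`).
#'
#' @param nread a `normalized_read`.
#' @param seg a `segmentation` for that read.
#' @param site_pos 0-based transcript coordinate of the central A.
#' @return list with `signal` (length `10 * rows`), `trace` (expanded
#'   `10 * rows` x 4 matrix) and `n_rows`, or `NULL` if the window is not
#'   fully covered.
#' @export
extract_window <- function(nread, seg, site_pos) {
  stopifnot(inherits(nread, "normalized_read"), inherits(seg, "segmentation"))
  idx <- match(site_pos + (-2L:2L), seg$pos)
  if (anyNA(idx)) return(NULL)
  rs <- seg$row_start[idx[1L]]
  re <- seg$row_end[idx[5L]]
  trace <- nread$trace[(rs + 1L):re, , drop = FALSE]
  list(signal = nread$signal[(10L * rs + 1L):(10L * re)],
       trace = trace[rep(seq_len(nrow(trace)), each = 10L), , drop = FALSE],
       n_rows = re - rs)
}

#' Standardize a channel to a fixed length by linear interpolation
#'
#' Shorter inputs are linearly interpolated up, longer inputs are
#' index-interpolated down (the same linear rule evaluated on a coarser
#' grid); a length-`n` input is returned unchanged. Endpoints are preserved.
#'
#' @param x numeric vector, length >= 1.
#' @param n target length (default 256).
#' @return numeric vector of length `n`.
#' @export
standardize_length <- function(x, n = 256L) {
  if (length(x) < 1L) stop("empty channel", call. = FALSE)
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n))$y
}

#' Assemble the 1280-float read-level feature
#'
#' Standardizes each of the five channels (signal, trace A, C, G, U) to
#' length 256 and concatenates them in that fixed order into one vector of
#' length 1280.
#'
#' @param window output of [extract_window()].
#' @return numeric vector of length 1280.
#' @export
assemble_feature <- function(window) {
  stopifnot(is.list(window), !is.null(window$signal), !is.null(window$trace))
  chans <- c(list(window$signal),
             lapply(1:4, function(j) window$trace[, j]))
  out <- unlist(lapply(chans, standardize_length, n = 256L), use.names = FALSE)
  if (length(out) != 1280L) stop("feature assembly did not yield 1280 values")
  out
}

#' Extract read features for every DRACH site a read covers
#'
#' @param nread a `normalized_read`.
#' @param seg its `segmentation`.
#' @param sites site table (`transcript`, `pos`, `motif`).
#' @return data.frame with site identity plus a `feature` list-column, one
#'   row per covered site (possibly 0 rows).
#' @export
featurize_read <- function(nread, seg, sites) {
  here <- sites[sites$transcript == nread$ref_name, , drop = FALSE]
  rows <- lapply(seq_len(nrow(here)), function(i) {
    w <- extract_window(nread, seg, here$pos[i])
    if (is.null(w)) return(NULL)
    list(transcript = here$transcript[i], pos = here$pos[i],
         motif = here$motif[i], feature = assemble_feature(w))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  data.frame(
    transcript = vapply(rows, `[[`, character(1), "transcript"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    motif = vapply(rows, `[[`, character(1), "motif"),
    feature = I(lapply(rows, `[[`, "feature")),
    stringsAsFactors = FALSE)
}

#' Group read features into site bags with coverage filtering
#'
#' Sites with fewer than `min_coverage` reads are dropped; sites with more
#' than `max_reads` are subsampled without replacement to `max_reads` using
#' the given seed (reproducibly).
#'
#' @param features data.frame from rbind-ing [featurize_read()] outputs;
#'   optional `read_label` column is carried into the bags.
#' @param min_coverage minimum reads per site (default 20).
#' @param max_reads maximum reads per site (default 1000).
#' @param seed subsampling seed.
#' @return list of `site_bag` objects (label/true_ratio `NA` unless
#'   `read_label` was supplied).
#' @export
build_bags <- function(features, min_coverage = 20L, max_reads = 1000L,
                       seed = 1L) {
  if (nrow(features) == 0L) return(list())
  key <- paste(features$transcript, features$pos, sep = ":")
  out <- lapply(unique(key), function(k) {
    rows <- which(key == k)
    if (length(rows) < min_coverage) return(NULL)
    if (length(rows) > max_reads) {
      rows <- with_seed(seed, sort(sample(rows, max_reads)))
    }
    labs <- if (!is.null(features$read_label)) {
      as.integer(features$read_label[rows])
    } else rep(NA_integer_, length(rows))
    frac <- if (anyNA(labs)) NA_real_ else mean(labs)
    structure(
      list(transcript = features$transcript[rows[1L]],
           pos = features$pos[rows[1L]], motif = features$motif[rows[1L]],
           features = do.call(rbind, features$feature[rows]),
           read_labels = labs,
           label = if (is.na(frac)) NA_integer_ else as.integer(frac > 0),
           true_ratio = frac),
      class = "site_bag")
  })
  out[!vapply(out, is.null, logical(1))]
}
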