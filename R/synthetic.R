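#' Configuration for the synthetic nanopore data generator
#'
#' Collects every knob of the simulator: reference geometry, DRACH site
#' density, per-site modification ratio, coverage, noise level, basecaller
#' trace sharpness and the RNG seed. Defaults describe a small but realistic
#' corpus: a few hundred-nt transcripts, one DRACH site per ~50 nt, 30 reads
#' per site, per-sample noise equal to the pore model's level SD and a
#' basecaller that puts 85% of its probability mass on the true base.
#'
#' @param n_refs number of reference transcripts.
#' @param ref_length transcript length in nt.
#' @param drach_density target DRACH sites per nt (placement spacing is
#'   `round(1/drach_density)`).
#' @param mod_ratio default per-site modification ratio in \[0, 1\].
#' @param reads_per_site reads simulated per site (site bags require 20-1000).
#' @param noise_scale multiplier on the pore model's level SD for the Gaussian
#'   signal noise; 0 gives noiseless signal.
#' @param trace_sharpness probability mass the simulated basecaller places on
#'   the true base of each trace row, in (0, 1\]; the rest is spread uniformly
#'   over the other classes.
#' @param trace_perturb fraction of the true-base trace mass lost at modified
#'   adenosine rows (the m6A trace perturbation); 0 disables it.
#' @param read_span flanking nt simulated on each side of a site when
#'   generating per-site read cohorts.
#' @param seed integer RNG seed governing the whole corpus.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_refs = 4L, ref_length = 400L, drach_density = 1 / 50,
                         mod_ratio = 0.5, reads_per_site = 30L,
                         noise_scale = 1, trace_sharpness = 0.85,
                         trace_perturb = 0.2, read_span = 15L, seed = 1L) {
  assert_scalar_number(n_refs, "n_refs", lower = 1)
  assert_scalar_number(ref_length, "ref_length", lower = 5)
  assert_scalar_number(drach_density, "drach_density", lower = 1e-6, upper = 0.2)
  assert_scalar_number(mod_ratio, "mod_ratio", lower = 0, upper = 1)
  assert_scalar_number(reads_per_site, "reads_per_site", lower = 1)
  assert_scalar_number(noise_scale, "noise_scale", lower = 0)
  assert_scalar_number(trace_sharpness, "trace_sharpness", lower = 1e-9, upper = 1)
  assert_scalar_number(trace_perturb, "trace_perturb", lower = 0, upper = 1)
  assert_scalar_number(read_span, "read_span", lower = 0)
  assert_scalar_number(seed, "seed")
  structure(
    list(n_refs = as.integer(n_refs), ref_length = as.integer(ref_length),
         drach_density = drach_density, mod_ratio = mod_ratio,
         reads_per_site = as.integer(reads_per_site),
         noise_scale = noise_scale, trace_sharpness = trace_sharpness,
         trace_perturb = trace_perturb, read_span = as.integer(read_span),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic reference set with planted DRACH sites
#'
#' Draws random transcript sequences and overwrites regularly spaced 5-mers
#' with DRACH motifs, cycling through all 18 motifs so each is represented
#' when length and density allow. The returned site table is produced by
#' re-scanning the finished sequences, so it also lists any DRACH motif that
#' arose by chance and is guaranteed consistent with [find_drach_sites()].
#'
#' @param config a [synth_config()].
#' @return object of class `reference_set`: list with `sequences` (named
#'   character vector) and `sites` (data.frame: transcript, pos \[0-based
#'   central A\], motif).
#' @seealso [write_reference_fasta()], [write_site_table()]
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  len <- config$ref_length
  spacing <- max(5L, as.integer(round(1 / config$drach_density)))
  # central A positions (0-based); motif occupies pos-2 .. pos+2
  slots <- seq.int(from = 2L, to = len - 3L, by = spacing)
  if (len < 5L || length(slots) == 0L) {
    stop("reference too short to place any DRACH site", call. = FALSE)
  }
  motifs <- drach_motifs()
  seqs <- character(config$n_refs)
  names(seqs) <- sprintf("synthref_%03d", seq_len(config$n_refs))
  k <- 0L
  for (r in seq_len(config$n_refs)) {
    codes <- sample.int(4L, len, replace = TRUE)
    for (p in slots) {
      k <- k + 1L
      codes[(p - 1L):(p + 3L)] <- seq_to_codes(motifs[(k - 1L) %% 18L + 1L])
    }
    seqs[r] <- codes_to_seq(codes)
  }
  sites <- do.call(rbind, lapply(names(seqs), function(nm) {
    find_drach_sites(seqs[[nm]], transcript = nm)
  }))
  if (nrow(sites) == 0L) stop("no DRACH site could be placed", call. = FALSE)
  structure(list(sequences = seqs, sites = sites), class = "reference_set")
}

#' Simulate one nanopore read (signal, trace, moves) from a reference
#'
#' Emulates the upstream sequencing + basecalling stack: each base dwells in
#' the pore for a random number of trace rows (10 raw samples per row), the
#' current level is the pore model's 5-mer level plus Gaussian noise, and the
#' basecaller emits one 8-class probability row (integers 0-255) per trace
#' row with a move flag on the first row of each base. On a modified read,
#' adenosines at `mod_positions` get the pore model's m6A current offset and
#' a trace perturbation.
#'
#' @param ref_seq sequence the read covers (A/C/G/T(U), length >= 5).
#' @param modified logical: does this molecule carry m6A?
#' @param pore a [pore_model()].
#' @param config a [synth_config()].
#' @param mod_positions 0-based transcript coordinates of the adenosines the
#'   modification applies to; default: every DRACH central A in `ref_seq`.
#' @param ref_name,ref_start alignment of the read on the transcript.
#' @param seed optional seed for this single read; default: continue the
#'   caller's RNG stream.
#' @return object of class `raw_read`: list with `signal` (numeric,
#'   10 samples/row), `trace` (integer matrix rows x 8, columns
#'   A,C,G,T,AA,CC,GG,TT in 0-255), `moves` (0/1 per trace row), `ref_name`,
#'   `ref_start`, `ref_end`, `truth_rows` (trace rows per base, simulator
#'   ground truth), `modified`, `mod_positions`.
#' @export
simulate_read <- function(ref_seq, modified, pore, config,
                          mod_positions = NULL, ref_name = "synthref_001",
                          ref_start = 0L, seed = NULL) {
  validate_pore_model(pore)
  stopifnot(inherits(config, "synth_config"), is.logical(modified))
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_read(ref_seq, modified, pore, config,
                                         mod_positions, ref_name, ref_start)))
  }
  codes <- seq_to_codes(ref_seq)
  L <- length(codes)
  if (L < 5L) stop("reference sequence must be at least 5 nt", call. = FALSE)
  if (is.null(mod_positions)) {
    mod_positions <- find_drach_sites(ref_seq, transcript = ref_name)$pos + ref_start
  }
  local_mod <- mod_positions - ref_start + 1L          # 1-based local indices
  local_mod <- local_mod[local_mod >= 1L & local_mod <= L]

  padded <- c(1L, 1L, codes, 1L, 1L)                   # clamp edge contexts with A
  ctx <- vapply(seq_len(L), function(i) {
    paste(BASES[padded[i:(i + 4L)]], collapse = "")
  }, character(1))
  level <- unname(pore$levels[ctx])
  is_mod_base <- rep(FALSE, L)
  if (isTRUE(modified) && length(local_mod)) is_mod_base[local_mod] <- TRUE
  level[is_mod_base] <- level[is_mod_base] + pore$m6a_offset

  rows <- 1L + stats::rpois(L, max(0, pore$dwell_rows_mean - 1))
  n_rows <- sum(rows)
  noise_sd <- pore$level_sd * config$noise_scale
  signal <- stats::rnorm(10L * n_rows, mean = rep(level, 10L * rows), sd = noise_sd)

  s_eff <- ifelse(is_mod_base, config$trace_sharpness * (1 - config$trace_perturb),
                  config$trace_sharpness)
  base_of_row <- rep(seq_len(L), rows)
  probs <- matrix(rep((1 - s_eff[base_of_row]) / 6, 8L), nrow = n_rows, ncol = 8L)
  idx <- cbind(seq_len(n_rows), codes[base_of_row])
  probs[idx] <- 0.6 * s_eff[base_of_row]               # mono-nucleotide class
  probs[cbind(idx[, 1L], idx[, 2L] + 4L)] <- 0.4 * s_eff[base_of_row]  # di class
  trace <- matrix(as.integer(round(255 * probs)), nrow = n_rows, ncol = 8L,
                  dimnames = list(NULL, TRACE_CLASSES))

  moves <- integer(n_rows)
  moves[cumsum(c(1L, rows[-L]))] <- 1L

  structure(
    list(signal = signal, trace = trace, moves = moves,
         ref_name = ref_name, ref_start = as.integer(ref_start),
         ref_end = as.integer(ref_start + L), truth_rows = rows,
         modified = isTRUE(modified),
         mod_positions = as.integer(mod_positions)),
    class = "raw_read"
  )
}

#' Per-base truth segmentation of a simulated read
#'
#' @param read a `raw_read` from [simulate_read()].
#' @return a `segmentation` data.frame (pos, row_start, row_end), trace-row
#'   intervals half-open, positions 0-based transcript coordinates.
#' @export
truth_segmentation <- function(read) {
  stopifnot(inherits(read, "raw_read"), !is.null(read$truth_rows))
  ends <- cumsum(read$truth_rows)
  new_segmentation(pos = read$ref_start + seq_along(ends) - 1L,
                   row_start = c(0L, ends[-length(ends)]), row_end = ends)
}

#' Simulate labelled site bags for training and evaluation
#'
#' Builds a reference set, then for each DRACH site simulates a cohort of
#' reads with the requested modified fraction and converts them into
#' fixed-length read features (a `site_bag`). Modified reads carry the m6A
#' current offset and trace perturbation only at the bag's own central A, so
#' bags are independent even when sites share a transcript. A bag's label is
#' 1 iff its realized modified fraction is positive; the realized fraction is
#' recorded as ground truth.
#'
#' @param config a [synth_config()]; `reads_per_site` must be in \[20, 1000\]
#'   (the pipeline's coverage rule).
#' @param pore a [pore_model()].
#' @param ratios per-site modification ratios, recycled over sites. Default:
#'   each site is unmodified (ratio 0) with probability 1/2, otherwise its
#'   ratio is drawn from \{0.2, 0.4, 0.6, 0.8, 1\} — the mixing scheme of an
#'   in-silico IVT mixture experiment.
#' @param n_sites number of sites to simulate (default: all sites in the
#'   generated reference set).
#' @param allocation `"exact"`: exactly `round(ratio * n)` modified reads per
#'   bag; `"binomial"`: each read modified independently with prob `ratio`.
#' @param featurize `"truth"`: cut feature windows with the simulator's own
#'   segmentation; `"resquiggle"`: run the full normalize/resquiggle path.
#' @return list of `site_bag` objects: each has `transcript`, `pos` (0-based
#'   central A), `motif`, `features` (reads x 1280 matrix), `read_labels`,
#'   `label` (0/1), `true_ratio`.
#' @export
simulate_site_bags <- function(config, pore = pore_model(), ratios = NULL,
                               n_sites = NULL,
                               allocation = c("exact", "binomial"),
                               featurize = c("truth", "resquiggle")) {
  stopifnot(inherits(config, "synth_config"))
  allocation <- match.arg(allocation)
  featurize <- match.arg(featurize)
  n <- config$reads_per_site
  if (n < 20L || n > 1000L) {
    stop("reads_per_site must be within [20, 1000] (site coverage rule)",
         call. = FALSE)
  }
  refs <- make_reference(config)          # seeds the corpus RNG stream
  sites <- refs$sites
  if (!is.null(n_sites)) {
    if (n_sites > nrow(sites)) {
      stop(sprintf("requested %d sites but the reference set only has %d; %s",
                   n_sites, nrow(sites),
                   "increase n_refs, ref_length or drach_density"), call. = FALSE)
    }
    sites <- sites[seq_len(n_sites), , drop = FALSE]
  }
  if (is.null(ratios)) {
    ratios <- ifelse(stats::runif(nrow(sites)) < 0.5, 0,
                     sample(c(0.2, 0.4, 0.6, 0.8, 1), nrow(sites), replace = TRUE))
  }
  ratios <- rep_len(ratios, nrow(sites))
  stopifnot(all(ratios >= 0 & ratios <= 1))

  bags <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    tx <- sites$transcript[s]
    pos <- sites$pos[s]
    full <- refs$sequences[[tx]]
    a <- max(0L, pos - 2L - config$read_span)
    b <- min(nchar(full), pos + 3L + config$read_span)
    sub <- substr(full, a + 1L, b)
    n_mod <- if (allocation == "exact") as.integer(round(ratios[s] * n)) else
      stats::rbinom(1L, n, ratios[s])
    flags <- c(rep(TRUE, n_mod), rep(FALSE, n - n_mod))
    feats <- matrix(NA_real_, nrow = n, ncol = 1280L)
    keep <- logical(n)
    for (j in seq_len(n)) {
      rd <- simulate_read(sub, flags[j], pore, config, mod_positions = pos,
                          ref_name = tx, ref_start = a)
      nr <- normalize_read(rd)
      seg <- if (featurize == "truth") truth_segmentation(rd) else
        tryCatch(resquiggle_read(nr, sub), error = function(e) NULL)
      if (is.null(seg)) next
      w <- extract_window(nr, seg, pos)
      if (is.null(w)) next
      feats[j, ] <- assemble_feature(w)
      keep[j] <- TRUE
    }
    if (sum(keep) < 20L) next             # bag fails the coverage rule
    frac <- mean(flags[keep])
    bags[[s]] <- structure(
      list(transcript = tx, pos = pos, motif = sites$motif[s],
           features = feats[keep, , drop = FALSE],
           read_labels = as.integer(flags[keep]),
           label = as.integer(frac > 0), true_ratio = frac),
      class = "site_bag")
  }
  bags[!vapply(bags, is.null, logical(1))]
}

#' Write a reference set to FASTA
#' @param refs a `reference_set`.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$sequences), path)
  invisible(path)
}

#' Read a reference transcriptome from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences (DNA alphabet, U read as T).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write / read the ground-truth site table (TSV)
#'
#' Columns: transcript, pos (0-based central A), motif, and for truth tables
#' written by the simulator, true_ratio.
#' @param sites data.frame of sites.
#' @param path TSV path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
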