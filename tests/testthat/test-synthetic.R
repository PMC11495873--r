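test_that("DRACH motif enumeration matches the combinatorial definition", {
  m <- drach_motifs()
  expect_length(m, 18L)
  expect_false(any(duplicated(m)))
  expect_true("GGACT" %in% m)
  expect_false("TTACT" %in% m)   # T is not a valid D
  expect_true(all(grepl("^[AGT][AG]AC[ACT]$", m)))
})

test_that("generated references carry a consistent DRACH site table", {
  refs <- fix_refs()
  expect_s3_class_ <- all(grepl("^[AGT][AG]AC[ACT]$", refs$sites$motif))
  expect_true(expect_s3_class_)
  expect_setequal(unique(refs$sites$motif), drach_motifs())
  for (i in sample(nrow(refs$sites), 10)) {
    s <- refs$sites[i, ]
    kmer <- substr(refs$sequences[[s$transcript]], s$pos - 1L, s$pos + 3L)
    expect_identical(kmer, s$motif)
  }
  # too short to place any DRACH site: rejected at config validation
  expect_error(synth_config(ref_length = 4L), "ref_length")
})

test_that("simulated reads satisfy the signal/trace/move geometry", {
  rd <- fix_noiseless_read()
  expect_identical(length(rd$signal), 10L * nrow(rd$trace))
  expect_identical(length(rd$moves), nrow(rd$trace))
  expect_identical(sum(rd$moves), rd$ref_end - rd$ref_start)
  # truth segmentation tiles the read contiguously
  tr <- truth_segmentation(rd)
  expect_identical(tr$row_start[1], 0L)
  expect_identical(tr$row_end[nrow(tr)], nrow(rd$trace))
  expect_true(all(tr$row_start[-1] == tr$row_end[-nrow(tr)]))
})

test_that("noiseless trace rows argmax to the true base", {
  rd <- fix_noiseless_read()
  refs <- fix_refs()
  codes <- nanodrach:::seq_to_codes(refs$sequences[[rd$ref_name]])
  q <- normalize_trace(rd$trace)
  base_of_row <- rep(codes, rd$truth_rows)
  expect_identical(max.col(q, ties.method = "first"), base_of_row)
})

test_that("simulation is deterministic under a fixed seed", {
  refs <- fix_refs()
  seqA <- refs$sequences[[1]]
  r1 <- simulate_read(seqA, TRUE, fix_pore(), synth_config(), seed = 77L)
  r2 <- simulate_read(seqA, TRUE, fix_pore(), synth_config(), seed = 77L)
  expect_identical(r1, r2)
  cfg <- synth_config(n_refs = 2L, ref_length = 150L, reads_per_site = 20L,
                      seed = 5L)
  b1 <- simulate_site_bags(cfg, fix_pore(), n_sites = 3L)
  b2 <- simulate_site_bags(cfg, fix_pore(), n_sites = 3L)
  expect_identical(b1, b2)
})

test_that("m6A offset shifts modified-A dwell segments by the configured amount", {
  pm <- pore_model()   # offset = 2 level SDs = 5 units
  cfg <- synth_config(trace_perturb = 0)
  refs <- fix_refs()
  nm <- names(refs$sequences)[1]
  seqA <- refs$sequences[[nm]]
  site <- refs$sites$pos[refs$sites$transcript == nm][3]
  grab <- function(modified, seed) {
    set.seed(seed)
    vals <- unlist(lapply(1:200, function(i) {
      rd <- simulate_read(seqA, modified, pm, cfg, mod_positions = site,
                          ref_name = nm)
      tr <- truth_segmentation(rd)
      j <- which(tr$pos == site)
      rd$signal[(10L * tr$row_start[j] + 1L):(10L * tr$row_end[j])]
    }))
  }
  v_mod <- grab(TRUE, 1)
  v_un <- grab(FALSE, 2)
  diff_obs <- mean(v_mod) - mean(v_un)
  se <- sqrt(var(v_mod) / length(v_mod) + var(v_un) / length(v_un))
  expect_lt(abs(diff_obs - pm$m6a_offset), 3 * se)
})

test_that("bag allocation and labels follow the mixing protocol", {
  cfg <- synth_config(n_refs = 2L, ref_length = 200L, reads_per_site = 100L,
                      seed = 11L)
  bags <- simulate_site_bags(cfg, fix_pore(), ratios = c(0, 1, 0.2),
                             n_sites = 3L, allocation = "exact")
  expect_identical(vapply(bags, `[[`, integer(1), "label"), c(0L, 1L, 1L))
  expect_identical(vapply(bags, function(b) sum(b$read_labels), integer(1)),
                   c(0L, 100L, 20L))   # exact allocation: round(ratio * n)
  expect_identical(vapply(bags, `[[`, numeric(1), "true_ratio"),
                   c(0, 1, 0.2))
  # coverage rule mirrored by the generator
  expect_error(
    simulate_site_bags(synth_config(reads_per_site = 19L), fix_pore()),
    "\\[20, 1000\\]")
  expect_error(
    simulate_site_bags(synth_config(reads_per_site = 1001L), fix_pore()),
    "\\[20, 1000\\]")
})

test_that("reads round-trip through the HDF5 container", {
  refs <- fix_refs()
  set.seed(31)
  reads <- lapply(1:3, function(i) {
    simulate_read(refs$sequences[[i]], i == 2L, fix_pore(), synth_config(),
                  ref_name = names(refs$sequences)[i])
  })
  h5 <- tempfile(fileext = ".h5")
  on.exit(unlink(h5))
  write_reads_h5(reads, h5)
  back <- read_reads_h5(h5)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$signal, reads[[i]]$signal)
    expect_identical(back[[i]]$trace, reads[[i]]$trace)
    expect_identical(back[[i]]$moves, reads[[i]]$moves)
    expect_identical(back[[i]]$ref_name, reads[[i]]$ref_name)
    expect_identical(back[[i]]$truth_rows, reads[[i]]$truth_rows)
  }
})
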