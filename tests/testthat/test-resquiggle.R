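# (the brute-force path enumeration/scoring oracle lives in helper-oracles.R)

test_that("move mapping places a boundary at every move=1 row", {
  expect_identical(map_moves(c(1, 0, 0, 1, 0, 1)), c(0L, 3L, 5L))
  expect_identical(map_moves(rep(1L, 7)), 0:6)
  expect_error(map_moves(rep(0L, 5)), "unusable")
})

test_that("interval splitting follows the 1.5x-median midpoint rule", {
  # lengths [2,2,2,9]: median 2, threshold 3 -> split the 9 into 4+5
  expect_identical(split_long_intervals(c(0L, 2L, 4L, 6L), 15L),
                   c(0L, 2L, 4L, 6L, 10L))
  # all equal: unchanged
  expect_identical(split_long_intervals(c(0L, 3L, 6L), 9L), c(0L, 3L, 6L))
  # single interval: its own median, never exceeded
  expect_identical(split_long_intervals(0L, 50L), 0L)
})

test_that("per-segment trace aggregation averages the rows in each segment", {
  tr <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0))
  agg <- aggregate_trace(tr, c(0L, 2L))
  expect_equal(unname(agg[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(agg[2, ]), c(0.5, 0.5, 0, 0))
})

test_that("single-cell scores follow the printed recursion", {
  # uniform trace at a mid-reference cell: transition scores 0.25 A,
  # staying scores 1 - P(next base) = 0.75 A
  seg <- rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), c(0, 1, 0, 0))
  codes <- nanodrach:::seq_to_codes("AC")
  stay_path <- c(1L, 1L, 2L)    # uniform segment stays at A: 1 + 0.75 + 1
  rush_path <- c(1L, 2L, 2L)    # advances early: 1 + 0.25 + 1
  expect_equal(score_path(stay_path, seg, codes), 2.75)
  expect_equal(score_path(rush_path, seg, codes), 2.25)
  expect_identical(realign_path(seg, "AC"), stay_path)
  # two one-hot segments must advance to cover both bases
  expect_identical(realign_path(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), "AC"),
                   c(1L, 2L))
})

test_that("one-hot segments realign perfectly to their matching bases", {
  seg <- diag(4)[1:3, ]          # A, C, G one-hot
  expect_identical(realign_path(seg, "ACG"), c(1L, 2L, 3L))
  expect_error(realign_path(matrix(0, 3, 4), "ACG"), "degenerate")
  expect_error(realign_path(diag(4)[1:2, ], "ACG"), "cannot cover")
})

test_that("dynamic programme equals brute-force enumeration on small instances", {
  set.seed(99)
  for (rep in 1:30) {
    N <- sample(2:6, 1)
    M <- sample(1:min(N, 4), 1)
    seg <- matrix(runif(N * 4), N, 4)
    seg <- seg / rowSums(seg)
    codes <- sample.int(4L, M, replace = TRUE)
    ref <- nanodrach:::codes_to_seq(codes)
    bonus_on <- rep %% 2 == 0
    is_move <- if (bonus_on) runif(N) < 0.5 else NULL
    bonus <- if (bonus_on) 2 * as.numeric(is_move) else NULL
    dp <- realign_path(seg, ref, move_bonus = 2, is_move = is_move)
    best <- max(vapply(enumerate_paths(N, M), score_path, numeric(1),
                       seg_trace = seg, codes = codes, bonus = bonus))
    expect_equal(score_path(dp, seg, codes, bonus = bonus), best)
  }
})

test_that("traceback paths are monotone with at most one advance per segment", {
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(5:40, 1)
    M <- sample(2:min(N, 12), 1)
    seg <- matrix(runif(N * 4), N, 4)
    seg <- seg / rowSums(seg)
    p <- realign_path(seg, nanodrach:::codes_to_seq(sample.int(4L, M, TRUE)))
    expect_identical(p[1], 1L)
    expect_identical(p[N], M)
    expect_true(all(diff(p) %in% c(0L, 1L)))
    expect_setequal(unique(p), seq_len(M))
  }
})

test_that("resquiggling recovers the simulator's segmentation on clean reads", {
  refs <- fix_refs()
  pm <- fix_pore()
  set.seed(61)
  hits <- unlist(lapply(1:10, function(i) {
    nm <- names(refs$sequences)[(i %% 4) + 1]
    rd <- simulate_read(refs$sequences[[nm]], i %% 2 == 0, pm,
                        noiseless_config(), ref_name = nm)
    seg <- resquiggle_read(normalize_read(rd), refs$sequences[[nm]])
    tr <- truth_segmentation(rd)
    expect_identical(seg$pos, tr$pos)
    abs(seg$row_start - tr$row_start) <= 1L
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("segmentations satisfy their structural invariants on noisy reads", {
  refs <- fix_refs()
  set.seed(71)
  for (i in 1:5) {
    nm <- names(refs$sequences)[(i %% 4) + 1]
    rd <- simulate_read(refs$sequences[[nm]], TRUE, fix_pore(),
                        synth_config(trace_sharpness = 0.6), ref_name = nm)
    seg <- resquiggle_read(normalize_read(rd), refs$sequences[[nm]])
    expect_true(all(seg$row_end > seg$row_start))
    expect_true(all(diff(seg$pos) == 1L))
    expect_true(all(seg$row_start[-1] == seg$row_end[-nrow(seg)]))
    expect_lte(seg$row_end[nrow(seg)], nrow(rd$trace))
  }
})
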