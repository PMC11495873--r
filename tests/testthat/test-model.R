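test_that("encoder emits 1024-dim embeddings deterministically", {
  model <- m6a_model(seed = 3L)
  set.seed(44)
  feats <- matrix(rnorm(3 * 1280), 3)
  H <- encode_read(feats, model)
  expect_identical(dim(H), c(3L, 1024L))
  expect_true(all(is.finite(H)))
  expect_identical(H, encode_read(feats, model))
  expect_identical(dim(encode_read(feats[1, ], model)), c(1L, 1024L))
  expect_error(encode_read(rnorm(100), model), "1280")
})

test_that("dilated stack receptive field matches the closed form", {
  # kernel 2 with dilations 1,2,4 per block: each block spans 1 + 7 steps;
  # an input change at position t must not affect outputs before t.
  enc <- tiny_encoder()
  model <- m6a_model(enc, tiny_heads(), seed = 7L)
  set.seed(1)
  f0 <- rnorm(1280)
  f1 <- f0
  t_hit <- 200L
  f1[t_hit] <- f1[t_hit] + 10        # bump the signal channel at one step
  X0 <- nanodrach:::features_to_input(matrix(f0, 1), enc)
  X1 <- nanodrach:::features_to_input(matrix(f1, 1), enc)
  layer_out <- function(X) {
    # post-conv activations, before pooling: causality visible per column
    fw <- nanodrach:::encoder_forward(model$params, X, 1L, enc, keep_cache = TRUE)
    fw$cache$P1
  }
  d <- colSums(abs(layer_out(X1) - layer_out(X0))) > 1e-12
  expect_false(any(d[seq_len(t_hit - 1L)]))      # strictly causal
  expect_true(d[t_hit])
  # receptive field: 2 blocks x (1+2+4) dilations = 14 steps back + self
  rf <- sum(rep(enc$dilations, enc$n_blocks)) + 1L
  expect_identical(max(which(d)) - t_hit + 1L, rf)
})

test_that("bag aggregation is permutation invariant with normalized weights", {
  model <- m6a_model(tiny_encoder(), tiny_heads(), seed = 11L)
  set.seed(21)
  H <- encode_read(matrix(rnorm(12 * 1280), 12), model)
  sc <- aggregate_bag(H, model)
  expect_equal(sum(sc$attention), 1)
  expect_equal(sum(sc$p), 1)
  expect_gte(sc$p_mod, 0)
  expect_lte(sc$p_mod, 1)
  for (i in 1:100) {
    o <- sample(nrow(H))
    sc2 <- aggregate_bag(H[o, , drop = FALSE], model)
    expect_equal(sc2$p_mod, sc$p_mod)
    expect_equal(sc2$C, sc$C)
    expect_equal(sc2$attention, sc$attention[o])
    expect_identical(o[sc2$critical_index], sc$critical_index)
  }
  # singleton bag: attention forced to 1, B = v_1
  s1 <- aggregate_bag(H[1, , drop = FALSE], model)
  expect_equal(s1$attention, 1)
  expect_equal(s1$bag_embedding,
               as.vector(model$params$Wv %*% H[1, ]))
  expect_error(aggregate_bag(H[0, , drop = FALSE], model), "empty")
})

test_that("averaged stream scores feed the final softmax", {
  model <- m6a_model(tiny_encoder(), tiny_heads(), seed = 13L)
  set.seed(5)
  H <- encode_read(matrix(rnorm(6 * 1280), 6), model)
  sc <- aggregate_bag(H, model)
  expect_equal(sc$C, (sc$C1 + sc$C2) / 2)
  expect_equal(sc$p, exp(sc$C) / sum(exp(sc$C)))
  expect_equal(sc$p_mod, sc$p[2])
})

test_that("stoichiometry is the exact mean of binary pseudo-labels", {
  model <- m6a_model(tiny_encoder(), tiny_heads(), seed = 17L)
  set.seed(31)
  H <- encode_read(matrix(rnorm(8 * 1280), 8), model)
  st <- estimate_stoichiometry(H, model)
  expect_true(all(st$pseudo_labels %in% 0:1))
  expect_identical(st$ratio, mean(st$pseudo_labels))
  # direct examples of the averaging contract
  expect_identical(mean(c(1, 0, 1, 1)), 0.75)
  expect_identical(estimate_stoichiometry(H[1, , drop = FALSE], model)$ratio,
                   as.numeric(st$pseudo_labels[1]))
})

test_that("analytic gradients match finite differences", {
  enc <- encoder_config(channels = 3L, skip_channels = 4L, post_channels = 4L,
                        embed_dim = 6L, pool_stride = 64L)
  heads <- head_config(q_dim = 3L, v_dim = 3L, stoich_hidden = 3L)
  model <- m6a_model(enc, heads, seed = 5L)
  set.seed(2)  # jitter biases off the ReLU kinks
  model$params <- lapply(model$params, function(p) p + rnorm(length(p), sd = 0.02))
  set.seed(9)
  feats <- matrix(rnorm(4 * 1280), 4)
  X <- nanodrach:::features_to_input(feats, enc)
  loss_and_crit <- function(params) {
    fwE <- nanodrach:::encoder_forward(params, X, 4L, enc)
    fw <- nanodrach:::dsmil_forward(params, fwE$E)
    c(-log(fw$p[2]), fw$m)
  }
  lg <- nanodrach:::bag_loss_grad(model, X, 4L, 1L)
  eps <- 1e-6
  for (nm in names(lg$grads)) {
    g <- lg$grads[[nm]]
    for (i in seq_len(min(4L, length(g)))) {
      p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- model$params; p3[[nm]][i] <- p3[[nm]][i] - eps
      a <- loss_and_crit(p2); b <- loss_and_crit(p3)
      if (a[2] != b[2]) next  # critical instance flipped: kink
      num <- (a[1] - b[1]) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training is reproducible and reduces the loss", {
  bags <- fix_training_bags()[1:24]
  enc <- tiny_encoder()
  run <- function() {
    m <- m6a_model(enc, tiny_heads(), seed = 31L)
    train_m6a_model(m, bags, epochs = 2L, seed = 31L)
  }
  m1 <- run()
  losses <- vapply(m1$log, `[[`, numeric(1), "mean_loss")
  expect_true(all(is.finite(losses)))
  expect_lt(losses[2], losses[1])
  m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
  # label-free bags refuse to train
  unlab <- lapply(bags[1:3], function(b) { b$label <- NA_integer_; b })
  expect_error(train_m6a_model(m6a_model(enc, tiny_heads()), unlab), "label")
})

test_that("checkpoints round-trip through disk", {
  bags <- fix_training_bags()[1:20]
  m <- train_m6a_model(m6a_model(tiny_encoder(), tiny_heads(), seed = 2L),
                       bags, epochs = 1L, seed = 2L)
  ck <- tempfile(fileext = ".rds")
  on.exit(unlink(ck))
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(m2$params, m$params)
  expect_identical(m2$enc, m$enc)
  set.seed(3)
  f <- matrix(rnorm(2 * 1280), 2)
  expect_identical(encode_read(f, m2), encode_read(f, m))
})

test_that("site calls respect inclusive thresholds at 0.5 and 0.9", {
  model <- m6a_model(tiny_encoder(), tiny_heads(), seed = 23L)
  bags <- fix_training_bags()[1:4]
  calls <- predict_sites(model, bags, threshold = 0.5)
  expect_s3_class(calls, "site_calls")
  expect_identical(nrow(calls), 4L)
  expect_true(all(calls$p_mod >= 0 & calls$p_mod <= 1))
  expect_true(all(calls$coverage >= 20L & calls$coverage <= 1000L))
  expect_identical(calls$call, as.integer(calls$p_mod >= 0.5))
  hi <- predict_sites(model, bags, threshold = 0.9)
  expect_identical(hi$call, as.integer(hi$p_mod >= 0.9))
  # boundary semantics: >= is inclusive
  expect_identical(as.integer(0.5 >= 0.5), 1L)
  expect_identical(as.integer(0.89 >= 0.9), 0L)
})
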