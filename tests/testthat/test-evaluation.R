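# (the double-loop silhouette and Mann-Whitney oracles live in
# helper-oracles.R)

test_that("silhouette matches hand evaluation on separated 1-D clusters", {
  x <- c(0, 0.1, 10, 10.1)
  res <- silhouette_scores(x, c("a", "a", "b", "b"))
  expect_equal(res$scores[1], (10.05 - 0.1) / 10.05, tolerance = 1e-12)
  expect_equal(res$average, mean(res$scores))
  expect_gt(res$average, 0.98)
})

test_that("silhouette agrees with the double-loop oracle on random data", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n)
    labels <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_scores(x, labels)$scores,
                 silhouette_oracle(x, labels))
  }
})

test_that("silhouette stays within [-1,1] and handles edge cases", {
  set.seed(6)
  x <- matrix(rnorm(60), 30)
  labels <- sample(c("a", "b"), 30, replace = TRUE)
  s <- silhouette_scores(x, labels)
  expect_true(all(s$scores >= -1 & s$scores <= 1))
  # identical overlapping clusters: average near 0
  y <- rbind(x, x)
  s2 <- silhouette_scores(y, rep(c("a", "b"), each = 30))
  expect_lt(abs(s2$average), 0.05)
  expect_error(silhouette_scores(x, rep("a", 30)), "2 clusters")
  expect_error(silhouette_scores(matrix(rnorm(6), 3), c("a", "b", "c")),
               "singleton")
  # per-object singleton scores 0 by convention
  s3 <- silhouette_scores(c(0, 0.2, 9), c("a", "a", "b"))
  expect_identical(s3$scores[3], 0)
})

test_that("ROC-AUC equals the pairwise-concordance (Mann-Whitney) oracle", {
  # 6-point hand-worked set
  truth <- c(1, 1, 1, 0, 0, 0)
  prob <- c(0.9, 0.6, 0.4, 0.5, 0.2, 0.1)
  m <- classification_metrics(truth, prob)
  expect_equal(m$roc_auc, mw_auc(truth, prob))   # 8/9
  expect_equal(m$roc_auc, 8 / 9)
  set.seed(13)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    prob <- round(runif(n), 2)   # ties included
    expect_equal(classification_metrics(truth, prob)$roc_auc,
                 mw_auc(truth, prob))
  }
})

test_that("threshold metrics follow their standard definitions", {
  truth <- c(1, 1, 0, 0, 1, 0)
  prob <- c(0.9, 0.5, 0.5, 0.1, 0.2, 0.3)
  m <- classification_metrics(truth, prob, threshold = 0.5)
  # calls at >= 0.5: 1,1,1,0,0,0 -> TP 2, FP 1, FN 1
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$pr_auc, 1)
  # chance level for label-independent scores
  set.seed(3)
  truth <- rbinom(4000, 1, 0.5)
  prob <- runif(4000)
  expect_lt(abs(classification_metrics(truth, prob)$roc_auc - 0.5), 0.05)
  # single-class truth: AUC undefined
  expect_true(is.na(classification_metrics(rep(1, 5), runif(5))$roc_auc))
})

test_that("metrics are invariant to input ordering", {
  set.seed(23)
  truth <- rbinom(50, 1, 0.4)
  prob <- runif(50)
  m1 <- classification_metrics(truth, prob)
  o <- sample(50)
  m2 <- classification_metrics(truth[o], prob[o])
  expect_equal(m1, m2)
})

test_that("motif frequency tables count all 18 motifs and sum to 1", {
  tab <- motif_frequency(rep("GGACT", 10))
  expect_identical(nrow(tab), 18L)
  expect_equal(tab$fraction[tab$motif == "GGACT"], 1)
  expect_equal(sum(tab$fraction), 1)
  expect_identical(nrow(motif_frequency(character())), 0L)
  expect_error(motif_frequency(c("GGACT", "TTACT")), "non-DRACH")
  # seeded multinomial proportions are recovered within sampling error
  set.seed(41)
  probs <- c(0.5, 0.3, 0.2)
  motifs <- sample(c("GGACT", "AAACA", "TGACC"), 3000, replace = TRUE,
                   prob = probs)
  tab2 <- motif_frequency(motifs)
  got <- tab2$fraction[match(c("GGACT", "AAACA", "TGACC"), tab2$motif)]
  expect_true(all(abs(got - probs) < 3 * sqrt(probs * (1 - probs) / 3000)))
  expect_equal(sum(tab2$count), 3000L)
})

test_that("metrics agree with independent reference implementations", {
  set.seed(91)
  truth <- rbinom(60, 1, 0.5)
  truth[1:2] <- 0:1
  prob <- runif(60)
  ours <- classification_metrics(truth, prob)$roc_auc
  expect_equal(ours, as.numeric(pROC::auc(pROC::roc(
    truth, prob, quiet = TRUE, direction = "<", levels = c("0", "1")))))
  x <- matrix(rnorm(40), 20)
  labels <- rep(1:2, each = 10)
  sil <- cluster::silhouette(labels, dist(x))
  expect_equal(silhouette_scores(x, labels)$scores,
               unname(sil[, "sil_width"]))
})
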