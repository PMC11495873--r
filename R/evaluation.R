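# Evaluation statistics: silhouette analysis, threshold/ROC/PR metrics and
# DRACH motif frequency tables.

#' Silhouette analysis of a clustering
#'
#' For each object, `s = (b - a) / max(a, b)` where `a` is its mean distance
#' to the other members of its own cluster and `b` the smallest mean distance
#' to any other cluster. Scores lie in \[-1, 1\]; near 1 means well
#' clustered, near 0 overlapping clusters. Objects that are alone in their
#' cluster score 0 by convention.
#'
#' @param x numeric matrix (objects x variables) or a `dist` object.
#' @param labels cluster label per object (>= 2 distinct clusters required).
#' @param metric distance metric passed to [stats::dist()] when `x` is a
#'   matrix (default `"euclidean"`).
#' @return list of class `silhouette_result`: `scores` (per object) and
#'   `average`.
#' @export
silhouette_scores <- function(x, labels, metric = "euclidean") {
  D <- if (inherits(x, "dist")) as.matrix(x) else {
    if (is.vector(x)) x <- matrix(x, ncol = 1L)
    as.matrix(stats::dist(x, method = metric))
  }
  n <- nrow(D)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  if (length(cl) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (all(tabulate(factor(labels)) == 1L)) {
    stop("all clusters are singletons; intra-cluster distance undefined",
         call. = FALSE)
  }
  # mean distance of every object to every cluster, in one pass
  member <- outer(labels, cl, "==")                 # n x k
  sums <- D %*% member
  sizes <- colSums(member)
  s <- vapply(seq_len(n), function(i) {
    k <- match(labels[i], cl)
    if (sizes[k] == 1L) return(0)                   # singleton convention
    a <- sums[i, k] / (sizes[k] - 1L)
    b <- min(sums[i, -k] / sizes[-k])
    (b - a) / max(a, b)
  }, numeric(1))
  structure(list(scores = s, average = mean(s)), class = "silhouette_result")
}

#' Binary classification metrics: threshold metrics, ROC-AUC and PR-AUC
#'
#' Accuracy, precision and recall at the given threshold (`>=` inclusive),
#' plus ROC-AUC and PR-AUC by trapezoidal integration over all score
#' thresholds. With single-class truth the AUCs are undefined and reported
#' as `NA`.
#'
#' @param truth 0/1 labels.
#' @param prob predicted probabilities in \[0, 1\].
#' @param threshold call threshold (default 0.5).
#' @return list: `accuracy`, `precision`, `recall`, `roc_auc`, `pr_auc`,
#'   `threshold`, `n`.
#' @export
classification_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(prob), all(truth %in% 0:1),
            all(prob >= 0 & prob <= 1))
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) {
    roc_auc <- NA_real_
    pr_auc <- NA_real_
  } else {
    ord <- order(prob, decreasing = TRUE)
    ts <- truth[ord]
    ps <- prob[ord]
    tpr <- cumsum(ts) / np
    fpr <- cumsum(1L - ts) / nn
    # collapse tied scores to one ROC point
    last <- c(ps[-1L] != ps[-length(ps)], TRUE)
    tpr <- c(0, tpr[last])
    fpr <- c(0, fpr[last])
    roc_auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
    prec_c <- (cumsum(ts) / seq_along(ts))[last]
    rec_c <- c(0, (cumsum(ts) / np)[last])
    prec_c <- c(prec_c[1L], prec_c)
    pr_auc <- sum(diff(rec_c) * (prec_c[-1L] + prec_c[-length(prec_c)]) / 2)
  }
  list(accuracy = acc, precision = prec, recall = rec, roc_auc = roc_auc,
       pr_auc = pr_auc, threshold = threshold, n = length(truth))
}

#' DRACH motif frequency table of a set of site calls
#'
#' @param calls a `site_calls` data.frame (or anything with a `motif`
#'   column), or a character vector of motifs.
#' @return data.frame with one row per DRACH motif observed context
#'   (all 18 motifs listed, zero counts included): `motif`, `count`,
#'   `fraction` (summing to 1). An empty input yields a 0-row table.
#' @export
motif_frequency <- function(calls) {
  motifs <- if (is.character(calls)) calls else calls$motif
  if (length(motifs) == 0L) {
    return(data.frame(motif = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  lv <- drach_motifs()
  bad <- setdiff(unique(motifs), lv)
  if (length(bad)) stop("non-DRACH motifs in calls: ",
                        paste(bad, collapse = ","), call. = FALSE)
  cnt <- table(factor(motifs, levels = lv))
  data.frame(motif = lv, count = as.integer(cnt),
             fraction = as.numeric(cnt) / length(motifs),
             stringsAsFactors = FALSE)
}
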