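# Independent brute-force oracles shared across test files. Deliberately
# naive implementations, kept free of any package internals they check.

# enumerate every monotone segment-to-base assignment (>= 1 segment per
# base, <= 1 base advance per segment)
enumerate_paths <- function(N, M) {
  grow <- function(path) {
    n <- length(path)
    if (n == N) {
      if (path[N] == M) return(list(path)) else return(list())
    }
    c(grow(c(path, path[n])), grow(c(path, path[n] + 1L)))
  }
  Filter(function(p) p[N] == M, grow(1L))
}

# score a monotone path by the same per-cell rule as the dynamic programme:
# transition into base m at segment n scores A*P[n,m] (+ move bonus), staying
# scores A*(1 - P[n, m+1]) with P past the reference end taken as 0
score_path <- function(path, seg_trace, codes, A = 1, bonus = NULL) {
  P <- seg_trace[, codes, drop = FALSE]
  Pnext <- cbind(P[, -1L, drop = FALSE], 0)
  if (is.null(bonus)) bonus <- numeric(nrow(seg_trace))
  s <- A * P[1L, 1L] + bonus[1L]
  for (n in seq_along(path)[-1L]) {
    s <- s + if (path[n] > path[n - 1L]) A * P[n, path[n]] + bonus[n] else
      A * (1 - Pnext[n, path[n]])
  }
  s
}

# double-loop silhouette
silhouette_oracle <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Mann-Whitney pairwise-concordance AUC
mw_auc <- function(truth, prob) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
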