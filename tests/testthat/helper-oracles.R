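# Independent oracles used to check the clustering implementation.
# These deliberately share no code with the package internals.

# Optimal 1-D k-means within-cluster sum of squares over at most k clusters,
# by dynamic programming over contiguous segments of the sorted values
# (the optimal 1-D SS partition is always contiguous).
oracle_kmeans_ss <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  k <- min(k, n)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  seg_ss <- function(i, j) {
    m <- j - i + 1
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / m, 0)
  }
  D <- matrix(Inf, nrow = k, ncol = n)
  for (j in 1:n) D[1, j] <- seg_ss(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        D[q, j] <- min(vapply(q:j, function(i) D[q - 1, i - 1] + seg_ss(i, j),
                              numeric(1)))
      }
    }
  }
  min(D[, n])
}

# Brute-force minimum SS over every assignment of n points to at most k
# clusters (k^n assignments); only usable for very small n. Validates the
# DP oracle.
oracle_bruteforce_ss <- function(values, k) {
  n <- length(values)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    a <- integer(n)
    c0 <- code
    for (i in 1:n) {
      a[i] <- c0 %% k
      c0 <- c0 %/% k
    }
    ss <- 0
    for (g in unique(a)) {
      grp <- values[a == g]
      ss <- ss + sum((grp - mean(grp))^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Mean silhouette width of the optimal contiguous k-partition, used as an
# independent criterion to decide the "true" cluster number on a value set.
oracle_silhouette_k <- function(values, k_range = 2:10) {
  v <- values
  n <- length(v)
  d <- as.matrix(dist(v))
  best_k <- k_range[1]
  best_sil <- -Inf
  for (k in k_range) {
    # optimal contiguous partition via the DP oracle, recovered greedily
    part <- oracle_partition(v, k)
    sil <- numeric(n)
    for (i in 1:n) {
      own <- which(part == part[i])
      a <- if (length(own) > 1) mean(d[i, setdiff(own, i)]) else 0
      b <- min(vapply(setdiff(unique(part), part[i]),
                      function(g) mean(d[i, part == g]), numeric(1)))
      sil[i] <- if (length(own) > 1) (b - a) / max(a, b) else 0
    }
    if (mean(sil) > best_sil) {
      best_sil <- mean(sil)
      best_k <- k
    }
  }
  best_k
}

# Recover one optimal contiguous k-partition (labels in original order).
oracle_partition <- function(values, k) {
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  k <- min(k, n)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  seg_ss <- function(i, j) {
    m <- j - i + 1
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / m, 0)
  }
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(1L, nrow = k, ncol = n)  # segment start backpointer
  for (j in 1:n) D[1, j] <- seg_ss(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        cand <- vapply(q:j, function(i) D[q - 1, i - 1] + seg_ss(i, j), numeric(1))
        pick <- which.min(cand)
        D[q, j] <- cand[pick]
        B[q, j] <- (q:j)[pick]
      }
    }
  }
  q_best <- which.min(D[, n])
  labels_sorted <- integer(n)
  j <- n
  for (q in q_best:1) {
    i <- B[q, j]
    labels_sorted[i:j] <- q
    j <- i - 1
    if (j < 1) break
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}
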