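# Independent brute-force oracles used by unit and acceptance tests. These
# deliberately re-derive the quantities from first principles and share no
# code with the package implementation.

# O(n^2) taxonomy oracle: a seizure is isolated iff no other seizure lies
# within the cutoff before or after it; clusters are connected components of
# the pairwise "within cutoff" relation (union-find over all pairs).
oracle_labels <- function(onset, offset, thr_s) {
  n <- length(onset)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && onset[j] - offset[i] <= thr_s) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  category <- rep("isolated", n)
  is_first <- rep(FALSE, n)
  for (r in unique(root)) {
    members <- which(root == r)
    if (length(members) > 1L) {
      last <- members[which.max(onset[members])]
      category[members] <- "cluster_non_last"
      category[last] <- "cluster_last"
      is_first[members[which.min(onset[members])]] <- TRUE
    }
  }
  list(category = category, is_cluster_first = is_first)
}

random_schedule <- function(n, seed) {
  set.seed(seed)
  dur <- runif(n, 30, 300)
  gap <- rexp(n, 1 / (12 * 3600))  # straddles both 8 h and 24 h cutoffs
  onset <- cumsum(gap + c(0, dur[-n]))
  data.frame(patient_id = "r", onset_s = onset, offset_s = onset + dur)
}

# direct histogram-KL REN oracle: shared equal-width edges over the pooled
# range, add-eps smoothing, explicit double sums, max of the two directions
oracle_ren <- function(x, y, n_bins = 10L, eps = 1e-10) {
  lo <- min(c(x, y)); hi <- max(c(x, y))
  edges <- lo + (hi - lo) * (0:n_bins) / n_bins
  count_bins <- function(v) {
    counts <- integer(n_bins)
    for (val in v) {
      k <- n_bins
      for (b in seq_len(n_bins - 1L)) {
        if (val < edges[b + 1L]) { k <- b; break }
      }
      counts[k] <- counts[k] + 1L
    }
    counts
  }
  p <- count_bins(x) / length(x) + eps; p <- p / sum(p)
  q <- count_bins(y) / length(y) + eps; q <- q / sum(q)
  klpq <- 0; klqp <- 0
  for (b in seq_len(n_bins)) {
    klpq <- klpq + p[b] * log(p[b] / q[b])
    klqp <- klqp + q[b] * log(q[b] / p[b])
  }
  max(klpq, klqp)
}

# Benjamini-Hochberg step-up oracle: find the largest k with
# p_(k) <= k q / m, reject all smaller; adjusted p by direct definition
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_max <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) k_max <- k
  reject <- logical(m)
  if (k_max > 0L) reject[ord[seq_len(k_max)]] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  list(reject = reject, adjusted = adj)
}

# exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(m+n, m) group assignments of the pooled values
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  combos <- combn(length(pooled), m)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- m * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
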