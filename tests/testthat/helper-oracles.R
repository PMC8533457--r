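# Independent brute-force oracles used to verify the package's statistics.
# Each one follows the textbook definition directly, with no code shared
# with the implementation it checks.

# Benjamini-Hochberg step-up, literally: sort, find the largest k with
# p_(k) <= k * q / m by scanning, report min over j >= k of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * p[o[i]] / i)
    adj_sorted[i] <- min(1, running_min)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

bonferroni_oracle <- function(p) pmin(1, length(p) * p)

# Hypergeometric upper tail by exhaustive summation with plain choose().
hyper_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# GSEA running score by an explicit position-by-position walk.
es_walk_oracle <- function(ranked_values, gene_set, weight_exponent) {
  labels <- names(ranked_values)
  hit <- labels %in% gene_set
  m <- sum(hit)
  N <- length(ranked_values)
  wsum <- sum(abs(ranked_values[hit])^weight_exponent)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      w <- abs(ranked_values[i])^weight_exponent
      run <- run + (if (wsum == 0) 1 / m else w / wsum)
    } else {
      run <- run - 1 / (N - m)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments, using the symmetric-deviation definition
# P(|W - E[W]| >= |w_obs - E[W]|).
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ew <- nx * (nx + length(y) + 1) / 2
  ws <- utils::combn(length(r), nx, function(i) sum(r[i]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}

# Connected components by union-find over an edge list of character node
# pairs; returns a named membership vector over `nodes`.
union_find_oracle <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

# DPI by exhaustive triangle enumeration over unordered node pairs.
dpi_oracle <- function(edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi_of <- tapply(edges$mi, key(edges$tf, edges$target), max)
  nodes <- sort(union(edges$tf, edges$target))
  drop <- character(0)
  if (length(nodes) >= 3) {
    trips <- utils::combn(nodes, 3)
    for (i in seq_len(ncol(trips))) {
      a <- trips[1, i]; b <- trips[2, i]; cc <- trips[3, i]
      ks <- c(key(a, b), key(a, cc), key(b, cc))
      if (all(ks %in% names(mi_of))) {
        m <- mi_of[ks]
        lo <- which(m == min(m))
        if (length(lo) == 1 && m[lo] < (1 - tolerance) * min(m[-lo])) {
          drop <- c(drop, ks[lo])
        }
      }
    }
  }
  edges[!key(edges$tf, edges$target) %in% drop, , drop = FALSE]
}

# Plug-in MI (bits) from a 2x2 joint count table by the hand formula.
mi2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  p <- c(a, b, c, d) / n
  px <- c(a + b, a + b, c + d, c + d) / n
  py <- c(a + c, b + d, a + c, b + d) / n
  terms <- ifelse(p > 0, p * log2(p / (px * py)), 0)
  sum(terms)
}
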