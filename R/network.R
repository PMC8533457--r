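# Default marginal bin count for the plug-in MI estimator.
default_bins <- function(n) max(2L, as.integer(floor(n^(1 / 3))))

# Equal-frequency (rank) bin indices in 1..n_bins; ties broken by original
# index order so the binning is stable and monotone-invariant.
bin_ranks <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n) + 1L)
}

# Plug-in mutual information (bits) from a joint count table.
mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1L]] * py[nz[, 2L]])))
}

# MI between two pre-binned integer vectors (values in 1..n_bins). Flat
# tabulation, no matrix allocation: this sits in the permutation-null inner
# loop.
mi_binned <- function(bx, by, n_bins) {
  n <- length(bx)
  counts <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins)
  nz <- which(counts > 0L)
  pj <- counts[nz] / n
  px <- tabulate(bx, n_bins) / n
  py <- tabulate(by, n_bins) / n
  ri <- (nz - 1L) %/% n_bins + 1L
  ci <- (nz - 1L) %% n_bins + 1L
  sum(pj * log2(pj / (px[ri] * py[ci])))
}

#' Mutual information between two expression profiles
#'
#' Plug-in estimator on the joint histogram of equal-frequency (rank-based)
#' bins, in bits. Rank binning makes the estimate invariant to monotone
#' transforms of either profile; ties in ranks are broken by original index
#' order. The estimate is symmetric, non-negative, and bounded by
#' `log2(n_bins)`.
#'
#' @param x,y Numeric vectors of equal length `n >= 2 * n_bins`; neither may
#'   be constant.
#' @param n_bins Number of marginal bins; defaults to `max(2, floor(n^(1/3)))`,
#'   the usual bias/variance compromise for plug-in estimators (the plug-in
#'   bias grows with the square of the bin count, so aggressive binning
#'   drowns moderate dependencies in the permutation null).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(n_bins)) n_bins <- default_bins(n)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (n < 2L * n_bins) stop(sprintf("need n >= 2 * n_bins (n=%d, n_bins=%d)", n, n_bins))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("mutual information is undefined for constant input")
  }
  mi_binned(bin_ranks(x, n_bins), bin_ranks(y, n_bins), n_bins)
}

#' Permutation-tested candidate regulatory edges
#'
#' Computes mutual information between every TF and every other gene, builds
#' a per-TF null by recomputing MI after permuting sample order (null draws
#' pooled across all genes and permutations for that TF), converts observed
#' MI to permutation p-values with the +1/+1 correction
#' `p = (1 + #\{null >= obs\}) / (1 + n_null)`, applies Benjamini-Hochberg
#' over all TF-gene pairs jointly, and retains pairs with `adj_p < alpha`.
#'
#' @param x An `ExpressionMatrix`. Zero-variance features are dropped with a
#'   warning before inference.
#' @param tf_list Character vector of TF symbols; TFs absent from the matrix
#'   are skipped with a warning.
#' @param n_permutations Number of sample-order permutations per TF.
#' @param alpha BH-adjusted significance threshold for retaining an edge.
#' @param n_bins Marginal bins for the MI estimator (default
#'   `max(2, floor(n_samples^(1/3)))`).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return data.frame with columns `tf`, `target`, `mi`, `p`, `adj_p`
#'   (possibly zero rows). TF-TF pairs are tested like any other pair.
#' @export
permutation_edge_test <- function(x, tf_list, n_permutations = 100L,
                                  alpha = 0.05, n_bins = NULL, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), n_permutations >= 1L)
  v <- x$values
  rv <- apply(v, 1L, function(r) length(unique(r)) > 1L)
  if (any(!rv)) {
    warning(sum(!rv), " zero-variance feature(s) dropped before inference")
    v <- v[rv, , drop = FALSE]
  }
  n <- ncol(v)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  n_bins <- as.integer(n_bins)
  if (n < 2L * n_bins) stop("too few samples for the requested binning")
  genes <- rownames(v)
  tfs <- intersect(tf_list, genes)
  absent <- setdiff(tf_list, genes)
  if (length(absent)) {
    warning("TF(s) absent from matrix skipped: ", paste(absent, collapse = ", "))
  }
  if (!length(tfs)) stop("no TF from tf_list present in the matrix")

  B <- t(vapply(seq_len(nrow(v)), function(i) bin_ranks(v[i, ], n_bins),
                integer(n)))
  rownames(B) <- genes

  withr::with_seed(seed, {
    perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)
    res <- vector("list", length(tfs))
    for (ti in seq_along(tfs)) {
      tf <- tfs[ti]
      bt <- B[tf, ]
      others <- setdiff(genes, tf)
      obs <- vapply(others, function(g) mi_binned(bt, B[g, ], n_bins),
                    numeric(1))
      null_mi <- numeric(n_permutations * length(others))
      k <- 0L
      for (p in perms) {
        btp <- bt[p]
        for (g in others) {
          k <- k + 1L
          null_mi[k] <- mi_binned(btp, B[g, ], n_bins)
        }
      }
      null_sorted <- sort(null_mi)
      n_lt <- findInterval(obs, null_sorted, left.open = TRUE)  # #{null < obs}
      pvals <- (1 + (length(null_sorted) - n_lt)) / (1 + length(null_sorted))
      res[[ti]] <- data.frame(tf = tf, target = others, mi = obs, p = pvals,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
    out <- do.call(rbind, res)
    out$adj_p <- stats::p.adjust(out$p, method = "BH")
    out <- out[out$adj_p < alpha, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Prune indirect edges with the data processing inequality
#'
#' ARACNe's defining step: in every triangle of edges (two regulators sharing
#' a gene, plus the regulator-regulator edge), the edge with strictly
#' smallest MI is presumed indirect and removed when its MI falls below
#' `(1 - tolerance)` times the smaller of the other two. Removal decisions
#' are computed simultaneously against the original table, not sequentially,
#' and a triangle with no strict minimum removes nothing.
#'
#' @param edges data.frame with columns `tf`, `target`, `mi` (as produced by
#'   [permutation_edge_test()]). TF-TF edges participate in triangles.
#' @param tolerance Non-negative DPI tolerance (default 0: strict).
#' @return The input data.frame minus pruned rows (a subset of the input).
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  stopifnot(tolerance >= 0)
  if (!nrow(edges)) return(edges)
  if (any(!is.finite(edges$mi))) stop("edge MI values must be finite")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keys <- pair_key(edges$tf, edges$target)
  # MI per unordered pair (duplicated directions carry the same MI; keep max)
  mi_of <- tapply(edges$mi, keys, max)
  nodes <- union(edges$tf, edges$target)
  idx <- stats::setNames(seq_along(nodes), nodes)
  ai <- idx[edges$tf]
  bi <- idx[edges$target]
  u <- pmin(ai, bi)
  w <- pmax(ai, bi)
  adj <- vector("list", length(nodes))
  for (e in seq_along(u)) {
    adj[[u[e]]] <- c(adj[[u[e]]], w[e])
    adj[[w[e]]] <- c(adj[[w[e]]], u[e])
  }
  adj <- lapply(adj, unique)
  removed <- character(0)
  ue <- unique(data.frame(u = u, w = w))
  for (e in seq_len(nrow(ue))) {
    a <- ue$u[e]; b <- ue$w[e]
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b]          # each triangle enumerated once
    for (cc in common) {
      na <- nodes[a]; nb <- nodes[b]; nc <- nodes[cc]
      m <- c(mi_of[pair_key(na, nb)], mi_of[pair_key(na, nc)],
             mi_of[pair_key(nb, nc)])
      lo <- which(m == min(m))
      if (length(lo) == 1L && m[lo] < (1 - tolerance) * min(m[-lo])) {
        removed <- c(removed, switch(lo, pair_key(na, nb), pair_key(na, nc),
                                     pair_key(nb, nc)))
      }
    }
  }
  out <- edges[!keys %in% removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared constructor: split an edge table into regulons / TF-TF edges and
# wrap as a RegulatoryNetwork. `edges` must have tf, target, mode, mi, p,
# adj_p columns.
assemble_network <- function(edges, universe, min_regulon_size, params) {
  tfs <- unique(edges$tf)
  is_tftf <- edges$target %in% tfs
  tf_tf <- edges[is_tftf, , drop = FALSE]
  reg_edges <- edges[!is_tftf, , drop = FALSE]
  all_regulons <- lapply(stats::setNames(tfs, tfs), function(tf) {
    r <- reg_edges[reg_edges$tf == tf,
                   c("target", "mode", "mi", "p", "adj_p"), drop = FALSE]
    rownames(r) <- NULL
    r
  })
  sizes <- vapply(all_regulons, nrow, integer(1))
  structure(list(
    regulons = all_regulons[sizes >= min_regulon_size],
    all_regulons = all_regulons,
    tf_tf_edges = if (nrow(tf_tf)) {
      rownames(tf_tf) <- NULL
      tf_tf
    } else NULL,
    universe = universe,
    params = params
  ), class = "RegulatoryNetwork")
}

#' Assemble regulons from pruned edges
#'
#' Groups surviving edges by TF, assigns each target a mode of action (+1
#' activating, -1 repressing) from the sign of the Spearman correlation
#' between TF and target expression, and keeps in the main regulon map only
#' TFs with at least `min_regulon_size` targets (TF-TF edges are excluded
#' from target counts but retained in the network record; undersized
#' regulons remain available in `all_regulons`).
#'
#' @param edges data.frame with columns `tf`, `target`, `mi`, `p`, `adj_p`.
#' @param x The `ExpressionMatrix` the edges were inferred from.
#' @param min_regulon_size Minimum regulon size (default 15).
#' @return A `RegulatoryNetwork`: list with `regulons` (TF -> data.frame of
#'   `target`, `mode`, `mi`, `p`, `adj_p`), `all_regulons`, `tf_tf_edges`,
#'   `universe`, `params`.
#' @export
build_regulons <- function(edges, x, min_regulon_size = 15L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  missing <- setdiff(union(edges$tf, edges$target), rownames(v))
  if (length(missing)) stop("edges reference genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  mode <- integer(nrow(edges))
  zero_rho <- FALSE
  for (i in seq_len(nrow(edges))) {
    rho <- stats::cor(v[edges$tf[i], ], v[edges$target[i], ],
                      method = "spearman")
    if (is.na(rho) || rho == 0) {
      zero_rho <- TRUE
      mode[i] <- 1L
    } else {
      mode[i] <- if (rho > 0) 1L else -1L
    }
  }
  if (zero_rho) warning("zero Spearman correlation: mode +1 assigned")
  edges$mode <- mode
  edges <- edges[, c("tf", "target", "mode", "mi", "p", "adj_p")]
  assemble_network(edges, universe = rownames(v),
                   min_regulon_size = as.integer(min_regulon_size),
                   params = list(min_regulon_size = as.integer(min_regulon_size)))
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d regulon(s) >= min size (of %d TFs), universe %d genes\n",
              length(x$regulons), length(x$all_regulons), length(x$universe)))
  invisible(x)
}
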