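#' GSEA-style running enrichment score
#'
#' Walks a descending-ranked, named value vector; positions belonging to the
#' gene set increment the running sum by `|value|^weight_exponent`
#' (normalised over the set's hits), other positions decrement it by
#' `1/(N - m)`. Returns the signed maximum-magnitude deviation of the
#' running sum (first such position on ties). With `weight_exponent = 0`
#' this is the classic Kolmogorov-Smirnov enrichment statistic.
#'
#' @param ranked_values Named numeric vector sorted in non-increasing order
#'   (e.g. one sample's gene z-scores).
#' @param gene_set Character vector, a non-empty strict subset of
#'   `names(ranked_values)`.
#' @param weight_exponent Non-negative hit weighting (default 1, the GSEA
#'   standard).
#' @return The signed enrichment score in \[-1, 1\].
#' @export
running_enrichment_score <- function(ranked_values, gene_set,
                                     weight_exponent = 1) {
  labels <- names(ranked_values)
  if (is.null(labels)) stop("ranked_values must be named")
  if (is.unsorted(rev(ranked_values))) {
    stop("ranked_values must be sorted in non-increasing order")
  }
  if (length(setdiff(gene_set, labels))) {
    stop("gene_set must be a subset of the ranked labels")
  }
  m <- length(unique(gene_set))
  N <- length(ranked_values)
  if (m < 1L || m >= N) stop("gene_set must be non-empty and smaller than the list")
  stopifnot(weight_exponent >= 0)
  hit <- labels %in% gene_set
  w <- abs(ranked_values[hit])^weight_exponent
  if (sum(w) == 0) w[] <- 1        # all-zero values degrade to equal weights
  inc <- numeric(N)
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / (N - m)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Enrichment score from hit positions only: pos (sorted positions in the
# ranking), w (non-negative weights in the same order), N list length.
# Candidate extrema occur just before and just after each hit; equals the
# full cumulative walk of running_enrichment_score.
es_from_positions <- function(pos, w, N) {
  m <- length(pos)
  W <- sum(w)
  if (W == 0) {
    w <- rep(1, m)
    W <- m
  }
  cw <- cumsum(w) / W
  miss <- (pos - seq_len(m)) / (N - m)
  after <- cw - miss
  before <- c(0, cw[-m]) - miss
  cand <- as.vector(rbind(before, after))   # walk order
  cand[which.max(abs(cand))]
}

#' Per-sample regulon activity (two-tailed GSEA)
#'
#' For every sample, genes are ranked by their cohort z-score in descending
#' order and each regulon is scored with the two-tailed enrichment
#' difference `dES = ES(positive-mode targets) - ES(negative-mode targets)`
#' (a side with no targets contributes 0, so negating every mode negates dES
#' exactly). A regulon is activated when its positively regulated genes are
#' up-ranked and its negatively regulated genes down-ranked, and inhibited
#' in the mirror situation. dES is standardised into an NES against
#' `n_null` size-matched random gene-set draws (shared across samples, so
#' one seed fixes the whole matrix), and each cell's status is called from
#' the NES sign plus the empirical two-sided null quantile at `sig_level`.
#'
#' @param z Z-scored gene x sample matrix from [zscore_by_gene()].
#' @param network A `RegulatoryNetwork`; regulons with no usable target in
#'   `z` are skipped with a warning.
#' @param n_null Number of size-matched null gene-set draws (default 1000).
#' @param seed Integer seed for the null draws.
#' @param weight_exponent GSEA hit weighting (default 1).
#' @param sig_level Two-sided empirical significance level for status calls
#'   (default 0.05).
#' @return An `ActivityMatrix`: list with matrices `nes`, `des` (regulons x
#'   samples) and `status` (character: `"activated"`, `"inhibited"`,
#'   `"neutral"`).
#' @export
regulon_activity <- function(z, network, n_null = 1000L, seed = 1L,
                             weight_exponent = 1, sig_level = 0.05) {
  stopifnot(is.matrix(z), inherits(network, "RegulatoryNetwork"))
  genes <- rownames(z)
  gene_idx <- stats::setNames(seq_along(genes), genes)
  regs <- list()
  for (tf in names(network$regulons)) {
    r <- network$regulons[[tf]]
    usable <- r$target %in% genes
    if (!any(usable)) {
      warning("regulon ", tf, " has no usable target in the z matrix; skipped")
      next
    }
    r <- r[usable, , drop = FALSE]
    regs[[tf]] <- list(pos = gene_idx[r$target[r$mode > 0]],
                       neg = gene_idx[r$target[r$mode < 0]])
  }
  if (!length(regs)) stop("no regulon with usable targets")
  nS <- ncol(z)
  N <- nrow(z)
  nes <- des <- matrix(NA_real_, length(regs), nS,
                       dimnames = list(names(regs), colnames(z)))
  status <- matrix("neutral", length(regs), nS,
                   dimnames = list(names(regs), colnames(z)))
  lo_q <- sig_level / 2
  hi_q <- 1 - sig_level / 2

  withr::with_seed(seed, {
    nulls <- lapply(regs, function(rg) {
      np <- length(rg$pos); nn <- length(rg$neg)
      lapply(seq_len(n_null), function(i) {
        pick <- sample.int(N, np + nn)
        list(pos = pick[seq_len(np)],
             neg = if (nn) pick[np + seq_len(nn)] else integer(0))
      })
    })
    for (j in seq_len(nS)) {
      ord <- order(z[, j], decreasing = TRUE)
      posn <- integer(N)
      posn[ord] <- seq_len(N)                 # ranking position of row i
      aw <- abs(z[, j])^weight_exponent
      score_pair <- function(ip, in_) {
        es_p <- if (length(ip)) {
          pp <- posn[ip]
          o <- order(pp)
          es_from_positions(pp[o], aw[ip][o], N)
        } else 0
        es_n <- if (length(in_)) {
          pn <- posn[in_]
          o <- order(pn)
          es_from_positions(pn[o], aw[in_][o], N)
        } else 0
        es_p - es_n
      }
      for (ri in seq_along(regs)) {
        d <- score_pair(regs[[ri]]$pos, regs[[ri]]$neg)
        nd <- vapply(nulls[[ri]], function(s) score_pair(s$pos, s$neg),
                     numeric(1))
        des[ri, j] <- d
        nes[ri, j] <- (d - mean(nd)) / stats::sd(nd)
        qs <- stats::quantile(nd, c(lo_q, hi_q), names = FALSE, type = 7)
        if (d > qs[2L] && nes[ri, j] > 0) status[ri, j] <- "activated"
        else if (d < qs[1L] && nes[ri, j] < 0) status[ri, j] <- "inhibited"
      }
    }
  })
  structure(list(nes = nes, des = des, status = status,
                 params = list(n_null = n_null, seed = seed,
                               weight_exponent = weight_exponent,
                               sig_level = sig_level)),
            class = "ActivityMatrix")
}

#' Regulon similarity within or across networks
#'
#' Shared-target counts and Jaccard indices. With one network, every pair of
#' regulons is compared (the association-map view, where edges depict mutual
#' regulation of genes by two TFs). With two networks, each TF present in
#' both is compared with itself across networks — how many genes the two
#' cohorts' versions of a regulon regulate in common.
#'
#' @param net1 A `RegulatoryNetwork`.
#' @param net2 Optional second `RegulatoryNetwork`.
#' @return data.frame with columns `tf1`, `tf2`, `shared`, `jaccard`.
#' @export
regulon_similarity <- function(net1, net2 = NULL) {
  stopifnot(inherits(net1, "RegulatoryNetwork"))
  targets_of <- function(net) lapply(net$regulons, function(r) unique(r$target))
  t1 <- targets_of(net1)
  if (is.null(net2)) {
    tfs <- names(t1)
    if (length(tfs) < 2L) {
      return(data.frame(tf1 = character(), tf2 = character(),
                        shared = integer(), jaccard = numeric()))
    }
    pairs <- utils::combn(tfs, 2L)
    rows <- apply(pairs, 2L, function(pr) {
      a <- t1[[pr[1L]]]; b <- t1[[pr[2L]]]
      sh <- length(intersect(a, b))
      data.frame(tf1 = pr[1L], tf2 = pr[2L], shared = sh,
                 jaccard = sh / length(union(a, b)), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    stopifnot(inherits(net2, "RegulatoryNetwork"))
    t2 <- targets_of(net2)
    tfs <- intersect(names(t1), names(t2))
    rows <- lapply(tfs, function(tf) {
      a <- t1[[tf]]; b <- t2[[tf]]
      sh <- length(intersect(a, b))
      data.frame(tf1 = tf, tf2 = tf, shared = sh,
                 jaccard = sh / length(union(a, b)), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(tf1 = character(), tf2 = character(),
                        shared = integer(), jaccard = numeric())
    }
  }
  rownames(out) <- NULL
  out
}

#' Case/control expression test of master-regulator genes
#'
#' Two-sided Wilcoxon rank-sum test per gene with Bonferroni correction over
#' the tested list. The p-value is exact (full enumeration of group
#' assignments, valid with ties) when the smaller group has at most 8
#' samples and the enumeration stays below 2e5 combinations; otherwise the
#' normal approximation with tie correction is used.
#'
#' @param x `ExpressionMatrix` with phenotype labels.
#' @param mr_genes Genes to test; absent genes are skipped with a warning.
#' @param alpha Bonferroni-adjusted significance threshold (default 0.01).
#' @return data.frame with columns `gene`, `median_case`, `median_control`,
#'   `p`, `adj_p`, `direction` (`"up_in_case"`, `"down_in_case"`, `"ns"`).
#' @export
mr_expression_test <- function(x, mr_genes, alpha = 0.01) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  grp <- case_control_ids(x, min_per_group = 1L)
  present <- intersect(mr_genes, rownames(x$values))
  absent <- setdiff(mr_genes, present)
  if (length(absent)) {
    warning("gene(s) absent from matrix skipped: ", paste(absent, collapse = ", "))
  }
  if (!length(present)) stop("none of mr_genes present in the matrix")
  rows <- lapply(present, function(g) {
    ca <- x$values[g, grp$case]
    co <- x$values[g, grp$control]
    data.frame(gene = g, median_case = stats::median(ca),
               median_control = stats::median(co),
               p = wilcox_rank_sum_p(ca, co), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_pvalues(out$p, "bonferroni")
  diff <- out$median_case - out$median_control
  out$direction <- ifelse(out$adj_p < alpha & diff > 0, "up_in_case",
                          ifelse(out$adj_p < alpha & diff < 0, "down_in_case",
                                 "ns"))
  rownames(out) <- NULL
  out
}

# Two-sided Wilcoxon rank-sum p-value. Exact path: enumerate all group
# assignments of the (mid)ranks and report the permutation two-sided p
# P(|W - E[W]| >= |w_obs - E[W]|); without ties the null is symmetric and
# this equals the classical 2 * min(tail) exact p. Large samples: normal
# approximation with tie correction via stats::wilcox.test.
wilcox_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  small <- min(nx, ny)
  if (small <= 8L && choose(nx + ny, small) <= 2e5) {
    take <- if (nx <= ny) nx else ny
    ws <- utils::combn(nx + ny, take, function(i) sum(r[i]))
    wt <- if (nx <= ny) w else sum(r) - w
    ew <- take * (nx + ny + 1) / 2
    mean(abs(ws - ew) >= abs(wt - ew) - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d regulon(s) x %d sample(s); %d activated, %d inhibited cells\n",
              nrow(x$nes), ncol(x$nes),
              sum(x$status == "activated"), sum(x$status == "inhibited")))
  invisible(x)
}
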