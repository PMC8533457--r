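#' Multiple-testing adjustment of p-values
#'
#' Thin validated wrapper around [stats::p.adjust()] exposing the two
#' corrections the pipeline uses: Benjamini-Hochberg step-up (edge and
#' regulon significance) and Bonferroni (master-regulator expression tests).
#' Output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Differential-expression gene signature
#'
#' Per-gene Welch two-sample t-test of case versus control, BH adjustment,
#' and membership at `adj_p < alpha`. Effects are `mean(case) -
#' mean(control)`, so genes higher in cases carry positive effects. Genes
#' with zero variance in both groups get p = 1 with a warning.
#'
#' @param x `ExpressionMatrix` with phenotype labels and at least 2 samples
#'   per group.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param condition Name recorded on the signature (default `"case"`).
#' @return A `GeneSignature`: list with `condition`, `genes` (character),
#'   `stats` (data.frame `gene`, `effect`, `p`, `adj_p`), `universe`,
#'   `alpha`.
#' @export
differential_signature <- function(x, alpha = 0.05, condition = "case") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  grp <- case_control_ids(x, min_per_group = 2L)
  v1 <- x$values[, grp$case, drop = FALSE]
  v0 <- x$values[, grp$control, drop = FALSE]
  n1 <- ncol(v1); n0 <- ncol(v0)
  m1 <- rowMeans(v1); m0 <- rowMeans(v0)
  s1 <- rowSums((v1 - m1)^2) / (n1 - 1)
  s0 <- rowSums((v0 - m0)^2) / (n0 - 1)
  se2 <- s1 / n1 + s0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance in both groups: p set to 1")
    p[degenerate] <- 1
  }
  adj <- adjust_pvalues(p, "BH")
  genes <- rownames(x$values)
  structure(list(
    condition = condition,
    genes = genes[adj < alpha],
    stats = data.frame(gene = genes, effect = m1 - m0, p = p, adj_p = adj,
                       stringsAsFactors = FALSE, row.names = NULL),
    universe = genes,
    alpha = alpha
  ), class = "GeneSignature")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked elements (out of `K` marked in a universe of `N`) in a
#' sample of size `n` without replacement. Terms are computed from log
#' binomial coefficients and combined with a log-sum-exp, so deep tails stay
#' accurate.
#'
#' @param N Universe size.
#' @param K Number of marked elements (e.g. regulon size).
#' @param n Sample size (e.g. signature size).
#' @param k Observed overlap.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (min(N, K, n, k) < 0L || K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent hypergeometric counts: N=%d K=%d n=%d k=%d",
                 N, K, n, k))
  }
  if (k <= max(0L, K + n - N)) return(1)
  j <- k:min(K, n)
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Master Regulator Analysis
#'
#' Tests, per regulon, whether the regulon's targets are over-represented in
#' a differential-expression signature, using the hypergeometric upper tail
#' on the intersection of the network and signature universes, with BH
#' adjustment across regulons. Regulons whose adjusted p falls below `alpha`
#' flag their TF as a candidate master regulator.
#'
#' @param network A `RegulatoryNetwork` (only the main regulon map, i.e.
#'   regulons at or above the minimum size, is tested).
#' @param signature A `GeneSignature`.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return An `mra_table` data.frame with columns `tf`, `regulon_size`,
#'   `signature_size`, `overlap`, `p`, `adj_p`, `is_mr`, and attributes
#'   `universe_size` and `alpha`.
#' @export
master_regulator_analysis <- function(network, signature, alpha = 0.05) {
  stopifnot(inherits(network, "RegulatoryNetwork"),
            inherits(signature, "GeneSignature"))
  universe <- intersect(network$universe, signature$universe)
  if (!length(universe)) stop("network and signature universes do not intersect")
  sig <- intersect(signature$genes, universe)
  tfs <- names(network$regulons)
  rows <- lapply(tfs, function(tf) {
    targets <- intersect(network$regulons[[tf]]$target, universe)
    k <- length(intersect(targets, sig))
    data.frame(tf = tf, regulon_size = length(targets),
               signature_size = length(sig), overlap = k,
               p = hypergeom_upper_tail(length(universe), length(targets),
                                        length(sig), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), regulon_size = integer(),
                      signature_size = integer(), overlap = integer(),
                      p = numeric(), adj_p = numeric(), is_mr = logical())
  } else {
    out$adj_p <- adjust_pvalues(out$p, "BH")
    out$is_mr <- out$adj_p < alpha
  }
  rownames(out) <- NULL
  attr(out, "universe_size") <- length(universe)
  attr(out, "alpha") <- alpha
  class(out) <- c("mra_table", "data.frame")
  out
}

#' Over-representation of a gene set against a collection
#'
#' Generic hypergeometric over-representation (the machinery behind Gene
#' Ontology style functional enrichment): each collection term is restricted
#' to the universe and tested for overlap with the query set, with BH
#' adjustment across terms. Typically run on the union of a TF's regulons
#' across cohorts.
#'
#' @param regulon_genes Character vector (the query set), must lie within
#'   `universe`.
#' @param collection A `GeneSetCollection` from [read_gene_sets()].
#' @param universe Character vector of testable genes.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.frame with columns `set_name`, `k` (overlap), `K` (term size
#'   in universe), `p`, `adj_p`, `significant`.
#' @export
overrepresentation <- function(regulon_genes, collection, universe,
                               alpha = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(setdiff(regulon_genes, universe))) {
    stop("regulon_genes must be a subset of the universe")
  }
  regulon_genes <- unique(regulon_genes)
  sets <- lapply(collection$sets, intersect, universe)
  keep <- vapply(sets, length, integer(1)) > 0L
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      p = numeric(), adj_p = numeric(), significant = logical()))
  }
  N <- length(universe)
  n <- length(regulon_genes)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(s, regulon_genes)), integer(1))
  p <- vapply(seq_along(sets), function(i) hypergeom_upper_tail(N, K[i], n, k[i]),
              numeric(1))
  adj <- adjust_pvalues(p, "BH")
  data.frame(set_name = names(sets), k = k, K = K, p = p, adj_p = adj,
             significant = adj < alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}
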