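#' Probe variability score for probe-to-gene collapsing
#'
#' Scores a probe's value vector as `geomSD(P) ^ (1 / geoMean(P))`, where the
#' geometric mean is `exp(mean(log P))` and the geometric SD is `exp(sd(log
#' P))`. The score is 1 for a constant probe and grows with multiplicative
#' spread, so collapsing keeps the most informative (most variable, moderate
#' intensity) probe per gene. The published formula's typography admits a
#' second reading, the plain ratio `geomSD / geoMean`, available as
#' `variant = "ratio"`; the power form is the default because it preserves
#' the score-1-for-constant-probes property.
#'
#' @param values Positive numeric vector, length >= 2.
#' @param variant `"power"` (default) for `geomSD^(1/geoMean)` or `"ratio"`
#'   for `geomSD / geoMean`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator) for the SD of log values.
#' @return The probe score (non-negative scalar).
#' @export
#'
#' @examples
#' probe_score(c(4, 4, 4))  # exactly 1
#' probe_score(c(2, 8))     # geoMean 4, geomSD ~2.665 -> ~1.2777
probe_score <- function(values, variant = c("power", "ratio"),
                        sd_type = c("sample", "population")) {
  variant <- match.arg(variant)
  sd_type <- match.arg(sd_type)
  if (length(values) < 2L) stop("probe_score needs at least 2 values")
  if (any(!is.finite(values) | values <= 0)) {
    stop("probe_score requires strictly positive finite values")
  }
  lv <- log(values)
  g <- exp(mean(lv))
  s <- stats::sd(lv)
  if (sd_type == "population") s <- s * sqrt((length(lv) - 1) / length(lv))
  gsd <- exp(s)
  if (variant == "power") gsd^(1 / g) else gsd / g
}

#' Collapse a probe-level matrix to gene level
#'
#' For each gene, all of its probes are scored with [probe_score()] and the
#' row of the highest-scoring probe is retained unchanged. Ties are broken by
#' the lexicographically smallest probe id. Gene rows appear in order of
#' first probe occurrence in the input matrix.
#'
#' @param x Probe-level `ExpressionMatrix`.
#' @param map Named character vector (probe id -> gene symbol); every feature
#'   of `x` must be present.
#' @param ... Passed on to [probe_score()] (`variant`, `sd_type`).
#' @return A gene-level `ExpressionMatrix`; the attribute `"chosen_probes"`
#'   is a data.frame recording, per gene, the retained probe and its score.
#' @export
collapse_probes <- function(x, map, ...) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  probes <- rownames(x$values)
  missing <- setdiff(probes, names(map))
  if (length(missing)) {
    stop("unmapped probe(s): ", paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  gene_of <- map[probes]
  genes <- unique(gene_of)                      # order of first occurrence
  scores <- vapply(probes, function(p) probe_score(x$values[p, ], ...),
                   numeric(1))
  chosen <- vapply(genes, function(g) {
    cand <- sort(probes[gene_of == g])          # lexicographic tie-break
    cand[which.max(scores[cand])]
  }, character(1))
  vals <- x$values[chosen, , drop = FALSE]
  rownames(vals) <- genes
  out <- expression_matrix(vals, phenotype = x$phenotype)
  attr(out, "chosen_probes") <- data.frame(
    gene = genes, probe = unname(chosen), score = unname(scores[chosen]),
    stringsAsFactors = FALSE)
  out
}

#' Row-wise z-scores of an expression matrix
#'
#' Centres and scales each gene across samples (sample SD, n-1 denominator),
#' expressing how each patient's value deviates from the cohort average for
#' that gene — the per-sample ranking input of the regulon-activity analysis.
#'
#' @param x An `ExpressionMatrix` or plain numeric matrix with dimnames.
#' @return A numeric matrix of the same shape with row mean 0 and SD 1.
#' @export
zscore_by_gene <- function(x) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  stopifnot(is.matrix(v), is.numeric(v))
  m <- rowMeans(v)
  s <- sqrt(rowSums((v - m)^2) / (ncol(v) - 1))
  zero <- which(s == 0)
  if (length(zero)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(v)[zero], 10), collapse = ", "))
  }
  (v - m) / s
}
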