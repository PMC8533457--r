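#' Construct an expression matrix
#'
#' Container for a features x samples matrix of log2-scale intensities, the
#' post-normalisation starting point of the whole pipeline. Values must be
#' strictly positive: the probe-collapsing score is built from geometric
#' statistics, which are undefined at or below zero.
#'
#' @param values Numeric matrix (features x samples) with unique, non-empty
#'   rownames (feature ids) and colnames (sample ids). All values must be
#'   finite and strictly positive.
#' @param phenotype Optional named character vector mapping sample ids to
#'   `"case"` or `"control"`. Names must be a subset of the sample ids.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `phenotype` (named character or `NULL`).
#' @export
#'
#' @examples
#' m <- matrix(c(4, 6, 8, 5, 7, 9), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- expression_matrix(m, phenotype = c(s1 = "case", s2 = "control"))
expression_matrix <- function(values, phenotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must have rownames (feature ids) and colnames (sample ids)")
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "expression values must be finite and strictly positive; offending value %s at feature '%s', sample '%s'",
      format(values[bad[1L]]), fid[i[1L, 1L]], sid[i[1L, 2L]]
    ))
  }
  if (!is.null(phenotype)) {
    phenotype <- validate_phenotype(phenotype, sid)
  }
  structure(list(values = values, phenotype = phenotype),
            class = "ExpressionMatrix")
}

validate_phenotype <- function(phenotype, sample_ids) {
  if (is.null(names(phenotype)) || any(!nzchar(names(phenotype)))) {
    stop("phenotype must be a named vector (names are sample ids)")
  }
  unknown <- setdiff(names(phenotype), sample_ids)
  if (length(unknown)) {
    stop("phenotype references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  nm <- names(phenotype)
  phenotype <- as.character(phenotype)
  names(phenotype) <- nm
  bad <- setdiff(unique(phenotype), c("case", "control"))
  if (length(bad)) {
    stop("phenotype groups must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  phenotype
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$phenotype)) {
    tb <- table(x$phenotype)
    cat("phenotype:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Split sample ids by phenotype group; errors if phenotype absent or a group
# has fewer than `min_per_group` samples.
case_control_ids <- function(x, min_per_group = 2L) {
  if (is.null(x$phenotype)) stop("ExpressionMatrix carries no phenotype labels")
  ca <- names(x$phenotype)[x$phenotype == "case"]
  co <- names(x$phenotype)[x$phenotype == "control"]
  if (length(ca) < min_per_group || length(co) < min_per_group) {
    stop(sprintf("need at least %d samples per group (case=%d, control=%d)",
                 min_per_group, length(ca), length(co)))
  }
  list(case = ca, control = co)
}
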