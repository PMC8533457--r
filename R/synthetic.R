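#' Plant a synthetic regulatory network with disease drivers
#'
#' Generates the ground truth every downstream stage is scored against: a set
#' of transcription factors, each driving a regulon of targets with signed
#' modes of action, plus per-condition "driver" TF subsets whose activity
#' shifts in case samples. Distinct conditions receive disjoint driver sets,
#' emulating a disease signature and an unrelated off-target inflammatory
#' condition.
#'
#' Targets belong to exactly one TF by default. With `overlap_frac > 0`, TFs
#' are split into two blocks and consecutive TFs within a block share
#' `round(overlap_frac * targets_per_tf)` targets, producing the two-cluster
#' regulon-overlap structure that cluster detection operates on.
#'
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Targets regulated by each TF (shared targets count
#'   towards both TFs' quota, so the edge count is exactly
#'   `n_tfs * targets_per_tf`).
#' @param frac_negative Expected fraction of repressive (mode -1) edges.
#' @param beta Positive effect size of each regulatory edge.
#' @param n_driver Drivers per condition; scalar (recycled) or one integer per
#'   condition. Driver sets across conditions are disjoint.
#' @param conditions Character vector of condition names.
#' @param noise_sd Standard deviation of measurement noise in the simulator.
#' @param delta Activity shift added to driver TFs in case samples.
#' @param overlap_frac Fraction of each TF's targets shared with its
#'   within-block predecessor (default 0 = disjoint regulons).
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @return A `SyntheticTruth`: list with `tf_ids`, `edges` (data.frame
#'   `tf`, `target`, `mode`, `beta`), `driver_sets`, `delta`, `noise_sd`.
#' @export
generate_network_truth <- function(n_tfs, targets_per_tf,
                                   frac_negative = 0.25, beta = 1,
                                   n_driver = 3L, conditions = "sepsis",
                                   noise_sd = 0.5, delta = 2,
                                   overlap_frac = 0, seed) {
  stopifnot(n_tfs >= 1L, targets_per_tf >= 1L, beta >= 0,
            frac_negative >= 0, frac_negative <= 1,
            overlap_frac >= 0, overlap_frac < 1)
  n_driver <- rep_len(as.integer(n_driver), length(conditions))
  if (sum(n_driver) > n_tfs) {
    stop(sprintf("disjoint driver sets need %d TFs but only %d exist",
                 sum(n_driver), n_tfs))
  }
  n_shared <- as.integer(round(overlap_frac * targets_per_tf))
  if (n_shared >= targets_per_tf) stop("overlap_frac leaves a TF no targets of its own")
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  blocks <- split(tf_ids, rep(1:2, c(ceiling(n_tfs / 2), floor(n_tfs / 2))))

  withr::with_seed(seed, {
    counter <- 0L
    new_targets <- function(k) {
      ids <- sprintf("G%04d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    own <- list()   # targets introduced by each TF (candidates for sharing)
    edges_tf <- character(0)
    edges_target <- character(0)
    for (blk in blocks) {
      prev <- NULL
      for (tf in blk) {
        shared <- if (!is.null(prev) && n_shared > 0L) {
          own[[prev]][seq_len(min(n_shared, length(own[[prev]])))]
        } else character(0)
        fresh <- new_targets(targets_per_tf - length(shared))
        own[[tf]] <- fresh
        edges_tf <- c(edges_tf, rep(tf, length(shared) + length(fresh)))
        edges_target <- c(edges_target, shared, fresh)
        prev <- tf
      }
    }
    modes <- ifelse(stats::runif(length(edges_tf)) < frac_negative, -1L, 1L)
    # Chain distance between TFs (Inf across blocks): used to keep driver
    # placements identifiable when regulons overlap. A non-driver flanked by
    # two drivers would have a genuinely signature-enriched regulon (its
    # shared targets shift with the drivers), so such placements are
    # rejected, as is chain adjacency between drivers of different
    # conditions (which would leak a condition's signature into the other
    # condition's driver regulon).
    chain_dist <- function(a, b) {
      for (blk in blocks) {
        if (a %in% blk && b %in% blk) return(abs(match(a, blk) - match(b, blk)))
      }
      Inf
    }
    placement_ok <- function(sets) {
      if (n_shared == 0L) return(TRUE)
      all_d <- unlist(sets, use.names = FALSE)
      cond_of <- rep(seq_along(sets), lengths(sets))
      if (length(all_d) < 2L) return(TRUE)
      for (i in seq_len(length(all_d) - 1L)) {
        for (j in seq(i + 1L, length(all_d))) {
          d <- chain_dist(all_d[i], all_d[j])
          if (d == 2) return(FALSE)                       # sandwiched middle TF
          if (d == 1 && cond_of[i] != cond_of[j]) return(FALSE)
        }
      }
      TRUE
    }
    driver_sets <- NULL
    for (try in seq_len(1000L)) {
      pool <- tf_ids
      cand <- list()
      for (i in seq_along(conditions)) {
        d <- sample(pool, n_driver[i])
        pool <- setdiff(pool, d)
        cand[[conditions[i]]] <- sort(d)
      }
      if (placement_ok(cand)) {
        driver_sets <- cand
        break
      }
    }
    if (is.null(driver_sets)) {
      stop("could not place driver sets under the overlap spacing constraints")
    }
    structure(list(
      tf_ids = tf_ids,
      edges = data.frame(tf = edges_tf, target = edges_target,
                         mode = modes, beta = beta, stringsAsFactors = FALSE),
      driver_sets = driver_sets,
      delta = delta, noise_sd = noise_sd,
      params = list(n_tfs = n_tfs, targets_per_tf = targets_per_tf,
                    frac_negative = frac_negative, overlap_frac = overlap_frac,
                    seed = seed)
    ), class = "SyntheticTruth")
  })
}

#' Describe one simulated case/control cohort
#'
#' @param n_case,n_control Samples per group (each at least 2).
#' @param condition_name Condition whose drivers shift in cases, or `"null"`
#'   for no shift.
#' @param baseline_offset Additive offset keeping intensities on a positive
#'   log2-microarray-like scale (default 8).
#' @param seed Integer seed for this cohort draw.
#' @return A `SimulationDesign` list.
#' @export
simulation_design <- function(n_case, n_control, condition_name = "sepsis",
                              baseline_offset = 8, seed = 1L) {
  stopifnot(n_case >= 2L, n_control >= 2L)
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 condition_name = condition_name,
                 baseline_offset = baseline_offset, seed = as.integer(seed)),
            class = "SimulationDesign")
}

#' Simulate an expression cohort from a planted truth
#'
#' Linear-Gaussian generative model: each sample draws a latent activity
#' `a ~ N(0, 1)` per TF, with `delta` added for driver TFs of the design's
#' condition in case samples. A target's value is the sum over its regulating
#' edges of `mode * beta * a(tf)` plus `N(0, noise_sd)` noise; a TF feature
#' reports its own activity plus the same measurement noise. Everything is
#' shifted by `baseline_offset` and floored at 0.01 so the strict-positivity
#' invariant holds.
#'
#' @param truth A `SyntheticTruth`.
#' @param design A `SimulationDesign`.
#' @return An [expression_matrix()] with phenotype labels (cases first).
#' @export
simulate_expression <- function(truth, design) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(design, "SimulationDesign"))
  cond <- design$condition_name
  if (!identical(cond, "null") && !cond %in% names(truth$driver_sets)) {
    stop("unknown condition name: ", cond)
  }
  n <- design$n_case + design$n_control
  tfs <- truth$tf_ids
  targets <- unique(truth$edges$target)
  sid <- sprintf("S%03d", seq_len(n))
  phenotype <- stats::setNames(
    rep(c("case", "control"), c(design$n_case, design$n_control)), sid)

  withr::with_seed(design$seed, {
    act <- matrix(stats::rnorm(length(tfs) * n), length(tfs), n,
                  dimnames = list(tfs, sid))
    if (!identical(cond, "null")) {
      drv <- truth$driver_sets[[cond]]
      act[drv, phenotype == "case"] <- act[drv, phenotype == "case"] + truth$delta
    }
    tf_rows <- act + matrix(stats::rnorm(length(act), sd = truth$noise_sd),
                            nrow(act), ncol(act))
    tgt_rows <- matrix(0, length(targets), n, dimnames = list(targets, sid))
    for (i in seq_len(nrow(truth$edges))) {
      e <- truth$edges[i, ]
      tgt_rows[e$target, ] <- tgt_rows[e$target, ] + e$mode * e$beta * act[e$tf, ]
    }
    tgt_rows <- tgt_rows + matrix(stats::rnorm(length(tgt_rows), sd = truth$noise_sd),
                                  nrow(tgt_rows), ncol(tgt_rows))
    vals <- pmax(design$baseline_offset + rbind(tf_rows, tgt_rows), 0.01)
    expression_matrix(vals, phenotype = phenotype)
  })
}

#' Expand a gene-level matrix to redundant probe level
#'
#' Emulates microarray platforms on which 1-3 probes represent the same gene:
#' each gene emits `k` probe rows equal to the gene row plus a per-probe
#' constant gain drawn from `N(0, gain_sd)` and small per-value noise (sd
#' `0.1 * gain_sd`, so `gain_sd = 0` reproduces the gene matrix exactly).
#' Probe ids are `"<gene>_p<j>"`.
#'
#' @param x Gene-level `ExpressionMatrix`.
#' @param probes_per_gene Integer range (length 1 or 2); each gene's probe
#'   count is drawn uniformly from it.
#' @param gain_sd SD of the per-probe constant gain.
#' @param seed Integer seed.
#' @return List with `matrix` (probe-level `ExpressionMatrix`) and `map`
#'   (named character, probe id -> gene symbol).
#' @export
expand_to_probes <- function(x, probes_per_gene = c(1L, 3L), gain_sd = 0.3,
                             seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), all(probes_per_gene >= 1L))
  rng <- range(as.integer(probes_per_gene))
  genes <- rownames(x$values)
  withr::with_seed(seed, {
    k <- if (rng[1L] == rng[2L]) rep(rng[1L], length(genes)) else
      sample(seq(rng[1L], rng[2L]), length(genes), replace = TRUE)
    rows <- vector("list", sum(k))
    probe_ids <- character(sum(k))
    map <- character(sum(k))
    idx <- 0L
    for (gi in seq_along(genes)) {
      base <- x$values[gi, ]
      for (j in seq_len(k[gi])) {
        idx <- idx + 1L
        gain <- stats::rnorm(1L, sd = gain_sd)
        noise <- stats::rnorm(length(base), sd = 0.1 * gain_sd)
        rows[[idx]] <- base + gain + noise
        probe_ids[idx] <- sprintf("%s_p%d", genes[gi], j)
        map[idx] <- genes[gi]
      }
    }
    vals <- pmax(do.call(rbind, rows), 0.01)
    dimnames(vals) <- list(probe_ids, colnames(x$values))
    list(matrix = expression_matrix(vals, phenotype = x$phenotype),
         map = stats::setNames(map, probe_ids))
  })
}

#' Build the exact regulatory network implied by a planted truth
#'
#' Converts a `SyntheticTruth` into a `RegulatoryNetwork` with the planted
#' modes, useful for testing downstream stages (enrichment, activity)
#' independently of network inference. Edge MI is set to the planted effect
#' size and p-values to zero.
#'
#' @param truth A `SyntheticTruth`.
#' @param min_regulon_size Minimum regulon size for the main map (default 1:
#'   the truth is exact, so no size filtering is usually wanted).
#' @return A `RegulatoryNetwork`.
#' @export
truth_to_network <- function(truth, min_regulon_size = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  edges <- data.frame(tf = truth$edges$tf, target = truth$edges$target,
                      mode = as.integer(truth$edges$mode),
                      mi = truth$edges$beta, p = 0, adj_p = 0,
                      stringsAsFactors = FALSE)
  assemble_network(edges,
                   universe = union(truth$tf_ids, unique(truth$edges$target)),
                   min_regulon_size = min_regulon_size,
                   params = list(source = "planted_truth"))
}

#' Write a complete synthetic two-cohort study to disk
#'
#' Materialises the full study layout the pipeline consumes: one planted
#' truth shared by two independent cohorts (cohort 1 at probe level with a
#' probe map, cohort 2 at gene level), a case/control dataset for the target
#' (disease) signature, and one dataset per off-target condition, plus the
#' TF list and a truth JSON. Returns a ready [pipeline_config()] pointing at
#' the files together with the truth, so planted drivers can be scored
#' against pipeline output.
#'
#' @param dir Output directory (created if absent).
#' @param seed Master seed; all dataset seeds are derived from it.
#' @param n_tfs,targets_per_tf,frac_negative,beta,noise_sd,delta,overlap_frac
#'   Passed to [generate_network_truth()].
#' @param n_driver Drivers per condition (default 3 disease + 2 off-target).
#' @param conditions Condition names; the first is the target disease.
#' @param cohort_n,signature_n,offtarget_n Two-element `c(case, control)`
#'   sample sizes for the network cohorts, the target-signature dataset and
#'   each off-target dataset.
#' @param ... Extra arguments passed to [pipeline_config()] (stage
#'   parameters).
#' @return List with `config` (a `PipelineConfig`) and `truth`
#'   (the `SyntheticTruth`).
#' @export
write_synthetic_study <- function(dir, seed, n_tfs = 10L, targets_per_tf = 30L,
                                  frac_negative = 0.25, beta = 1,
                                  noise_sd = 0.5, delta = 2,
                                  overlap_frac = 0.4,
                                  n_driver = c(3L, 2L),
                                  conditions = c("sepsis", "offtarget"),
                                  cohort_n = c(150L, 50L),
                                  signature_n = c(40L, 20L),
                                  offtarget_n = c(30L, 20L), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_network_truth(
    n_tfs = n_tfs, targets_per_tf = targets_per_tf,
    frac_negative = frac_negative, beta = beta, n_driver = n_driver,
    conditions = conditions, noise_sd = noise_sd, delta = delta,
    overlap_frac = overlap_frac, seed = derive_seed(seed, "truth"))
  target_cond <- conditions[1L]
  off_conds <- conditions[-1L]

  emit <- function(name, cond, n_case, n_control, probe_level = FALSE) {
    em <- simulate_expression(truth, simulation_design(
      n_case = n_case, n_control = n_control, condition_name = cond,
      seed = derive_seed(seed, name)))
    paths <- list(expression = file.path(dir, paste0(name, "_expression.tsv")),
                  phenotype = file.path(dir, paste0(name, "_phenotype.tsv")))
    if (probe_level) {
      pr <- expand_to_probes(em, probes_per_gene = c(1L, 3L), gain_sd = 0.3,
                             seed = derive_seed(seed, paste0(name, "_probes")))
      write_expression_matrix(pr$matrix, paths$expression,
                              phenotype_path = paths$phenotype)
      paths$probe_map <- file.path(dir, paste0(name, "_probe_map.tsv"))
      write_probe_map(pr$map, paths$probe_map)
    } else {
      write_expression_matrix(em, paths$expression,
                              phenotype_path = paths$phenotype)
    }
    paths
  }

  cohort1 <- emit("cohort1", target_cond, cohort_n[1L], cohort_n[2L],
                  probe_level = TRUE)
  cohort2 <- emit("cohort2", target_cond, cohort_n[1L], cohort_n[2L])
  signature <- c(name = target_cond,
                 emit("signature", target_cond, signature_n[1L], signature_n[2L]))
  offtargets <- lapply(off_conds, function(cond) {
    c(name = cond,
      emit(paste0("offtarget_", cond), cond, offtarget_n[1L], offtarget_n[2L]))
  })
  tf_path <- file.path(dir, "tf_list.txt")
  writeLines(truth$tf_ids, tf_path)
  jsonlite::write_json(
    list(edges = truth$edges, driver_sets = truth$driver_sets,
         delta = truth$delta, noise_sd = truth$noise_sd),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  config <- pipeline_config(cohort1 = cohort1, cohort2 = cohort2,
                            signature = signature, offtargets = offtargets,
                            tf_list = tf_path, seed = seed, ...)
  list(config = config, truth = truth)
}
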