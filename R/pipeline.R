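#' Detect regulon clusters from the overlap graph
#'
#' Builds the regulon-overlap graph (an edge joins two regulons whose target
#' sets have Jaccard index at or above the threshold) and takes its
#' connected components as clusters. The largest component is labeled A and
#' the second largest B, with ties broken by the lexicographically smallest
#' member TF; singleton components are left unlabeled. This is a
#' reproducible surrogate for delimiting the two main clusters on a
#' tree-and-leaf layout by eye.
#'
#' @param network A `RegulatoryNetwork`.
#' @param jaccard_threshold Edge threshold in (0, 1\] (default 0.1).
#' @return List with `membership` (named integer, TF -> component id; only
#'   TFs in non-singleton components), `A` and `B` (character vectors of
#'   member TFs, possibly empty), and `sizes` (component sizes).
#' @export
detect_clusters <- function(network, jaccard_threshold = 0.1) {
  stopifnot(inherits(network, "RegulatoryNetwork"),
            jaccard_threshold > 0, jaccard_threshold <= 1)
  tfs <- sort(names(network$regulons))
  if (!length(tfs)) {
    return(list(membership = stats::setNames(integer(0), character(0)),
                A = character(0), B = character(0), sizes = integer(0)))
  }
  sim <- regulon_similarity(network)
  sim <- sim[sim$jaccard >= jaccard_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = sim[, c("tf1", "tf2")], directed = FALSE,
    vertices = data.frame(name = tfs))
  comp <- igraph::components(g)
  membership <- comp$membership
  members <- split(names(membership), membership)
  sizes <- vapply(members, length, integer(1))
  members <- members[sizes > 1L]
  sizes <- sizes[sizes > 1L]
  if (length(members)) {
    smallest <- vapply(members, function(m) min(m), character(1))
    ord <- order(-sizes, smallest)
    members <- lapply(members[ord], sort)
    sizes <- sizes[ord]
  }
  memb_out <- integer(0)
  nm <- character(0)
  for (i in seq_along(members)) {
    memb_out <- c(memb_out, rep(i, length(members[[i]])))
    nm <- c(nm, members[[i]])
  }
  list(membership = stats::setNames(memb_out, nm),
       A = if (length(members) >= 1L) members[[1L]] else character(0),
       B = if (length(members) >= 2L) members[[2L]] else character(0),
       sizes = unname(sizes))
}

#' Cross-cohort, cross-disease specificity filter
#'
#' Implements the master-regulator funnel: a TF survives if and only if it
#' is flagged as an MR for the target signature in both networks, lies in
#' cluster A or B of both networks, and is not flagged as an MR for any
#' off-target (unrelated disease) signature in either network.
#'
#' @param mra_target_net1,mra_target_net2 `mra_table`s for the target
#'   signature against networks 1 and 2.
#' @param mra_offtargets List (possibly empty) of `mra_table`s for
#'   off-target signatures, over either network.
#' @param clusters_net1,clusters_net2 Outputs of [detect_clusters()] for the
#'   two networks.
#' @return A `SpecificityResult`: list with `flags` (per-TF logical
#'   data.frame), `final_mrs`, `funnel` (named counts: MRs per network, in
#'   both, in clusters, final), and `provenance` (the input tables).
#' @export
specificity_filter <- function(mra_target_net1, mra_target_net2,
                               mra_offtargets = list(),
                               clusters_net1, clusters_net2) {
  mrs_of <- function(tab) tab$tf[tab$is_mr]
  mr1 <- mrs_of(mra_target_net1)
  mr2 <- mrs_of(mra_target_net2)
  off <- unique(unlist(lapply(mra_offtargets, mrs_of)))
  in1 <- union(clusters_net1$A, clusters_net1$B)
  in2 <- union(clusters_net2$A, clusters_net2$B)
  tfs <- sort(unique(c(mra_target_net1$tf, mra_target_net2$tf,
                       unlist(lapply(mra_offtargets, function(t) t$tf)))))
  flags <- data.frame(
    tf = tfs,
    mr_in_net1 = tfs %in% mr1,
    mr_in_net2 = tfs %in% mr2,
    in_cluster_net1 = tfs %in% in1,
    in_cluster_net2 = tfs %in% in2,
    hit_offtarget_any = tfs %in% off,
    stringsAsFactors = FALSE
  )
  final <- flags$tf[flags$mr_in_net1 & flags$mr_in_net2 &
                      flags$in_cluster_net1 & flags$in_cluster_net2 &
                      !flags$hit_offtarget_any]
  both <- intersect(mr1, mr2)
  in_clusters <- intersect(both, intersect(in1, in2))
  structure(list(
    flags = flags,
    final_mrs = final,
    funnel = c(mrs_net1 = length(mr1), mrs_net2 = length(mr2),
               mrs_both = length(both), in_clusters = length(in_clusters),
               final = length(final)),
    provenance = list(target_net1 = mra_target_net1,
                      target_net2 = mra_target_net2,
                      offtargets = mra_offtargets)
  ), class = "SpecificityResult")
}

#' @export
print.SpecificityResult <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("SpecificityResult: %d / %d MRs -> %d in both -> %d in clusters -> %d final\n",
              f["mrs_net1"], f["mrs_net2"], f["mrs_both"], f["in_clusters"],
              f["final"]))
  if (length(x$final_mrs)) cat("final MRs:", paste(x$final_mrs, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble and validate a pipeline configuration
#'
#' @param cohort1,cohort2 Lists with elements `expression` and `phenotype`
#'   (TSV paths) and optionally `probe_map` (probe-level input collapsed to
#'   gene level before inference).
#' @param signature List with `name`, `expression`, `phenotype`: the dataset
#'   the target (disease) signature is inferred from.
#' @param offtargets List (possibly empty) of such lists for unrelated
#'   disease signatures.
#' @param tf_list Path to the TF list (one symbol per line).
#' @param n_permutations,alpha,n_bins,dpi_tolerance,min_regulon_size Network
#'   inference stage parameters.
#' @param sig_alpha,mra_alpha Signature and MRA significance thresholds.
#' @param jaccard_threshold Cluster-detection edge threshold.
#' @param n_null,weight_exponent Activity stage parameters.
#' @param mrexpr_alpha MR-expression Bonferroni threshold.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(cohort1, cohort2, signature, offtargets = list(),
                            tf_list, n_permutations = 100L, alpha = 0.05,
                            n_bins = NULL, dpi_tolerance = 0,
                            min_regulon_size = 15L, sig_alpha = 0.05,
                            mra_alpha = 0.05, jaccard_threshold = 0.1,
                            n_null = 200L, weight_exponent = 1,
                            mrexpr_alpha = 0.01, seed) {
  cfg <- list(cohort1 = cohort1, cohort2 = cohort2, signature = signature,
              offtargets = offtargets, tf_list = tf_list,
              n_permutations = as.integer(n_permutations), alpha = alpha,
              n_bins = n_bins, dpi_tolerance = dpi_tolerance,
              min_regulon_size = as.integer(min_regulon_size),
              sig_alpha = sig_alpha, mra_alpha = mra_alpha,
              jaccard_threshold = jaccard_threshold,
              n_null = as.integer(n_null), weight_exponent = weight_exponent,
              mrexpr_alpha = mrexpr_alpha, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("pipeline config must set a seed")
  datasets <- list(cohort1 = cfg$cohort1, cohort2 = cfg$cohort2,
                   signature = cfg$signature)
  for (i in seq_along(cfg$offtargets)) {
    datasets[[paste0("offtarget", i)]] <- cfg$offtargets[[i]]
  }
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    for (field in c("expression", "phenotype")) {
      if (is.null(d[[field]])) {
        stop(sprintf("config dataset '%s' is missing its %s file entry", nm, field))
      }
      if (!file.exists(d[[field]])) {
        stop(sprintf("config dataset '%s': %s file not found: %s",
                     nm, field, d[[field]]))
      }
    }
    if (!is.null(d$probe_map) && !file.exists(d$probe_map)) {
      stop(sprintf("config dataset '%s': probe_map file not found: %s",
                   nm, d$probe_map))
    }
  }
  if (!file.exists(cfg$tf_list)) stop("TF list file not found: ", cfg$tf_list)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]: one block per
#' dataset (`cohort1`, `cohort2`, `signature`, optional `offtargets` list)
#' plus flat stage parameters. A seed is mandatory.
#'
#' @param path YAML file path.
#' @return A validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

# Deterministic per-stage seed derived from the master seed and stage name
# (polynomial string hash mod a Mersenne prime, kept within 32-bit range).
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full master-regulator discovery pipeline
#'
#' Executes, in order: probe collapsing (where a probe map is configured),
#' network inference on both cohorts (permutation edge test, DPI pruning,
#' regulon assembly), differential signatures (target plus off-targets),
#' MRA of every network against every signature, cluster detection on both
#' networks, the specificity filter, per-sample regulon activity on both
#' cohorts, regulon similarity within and across networks, and the
#' case/control expression test of the final MRs. Every artifact is written
#' to `out_dir` as TSV/JSON/GraphML together with a manifest recording
#' parameters, the seed, and an md5 checksum per file; re-running the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A `PipelineConfig`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the result bundle: list with `networks`, `signatures`,
#'   `mra`, `clusters`, `specificity`, `activity`, `similarity`, `mrexpr`,
#'   `manifest`, `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  load_dataset <- function(d, nm) stage_run(paste0("read_", nm), {
    em <- read_expression_matrix(d$expression, phenotype_path = d$phenotype)
    if (!is.null(d$probe_map)) {
      map <- read_probe_map(d$probe_map)
      em <- stage_run(paste0("collapse_", nm), collapse_probes(em, map))
      note("collapsed %s to %d genes", nm, nrow(em$values))
    }
    em
  })
  coh <- list(load_dataset(config$cohort1, "cohort1"),
              load_dataset(config$cohort2, "cohort2"))
  tf_list <- stage_run("read_tf_list", read_tf_list(config$tf_list))
  note("loaded cohorts: %d x %d and %d x %d features x samples",
       nrow(coh[[1]]$values), ncol(coh[[1]]$values),
       nrow(coh[[2]]$values), ncol(coh[[2]]$values))

  networks <- lapply(1:2, function(i) stage_run(paste0("infer_net", i), {
    edges <- permutation_edge_test(
      coh[[i]], tf_list, n_permutations = config$n_permutations,
      alpha = config$alpha, n_bins = config$n_bins,
      seed = derive_seed(config$seed, paste0("infer", i)))
    note("network %d: %d candidate edges", i, nrow(edges))
    pruned <- apply_dpi(edges, tolerance = config$dpi_tolerance)
    note("network %d: %d edges after DPI", i, nrow(pruned))
    build_regulons(pruned, coh[[i]], min_regulon_size = config$min_regulon_size)
  }))

  sig_sets <- c(list(config$signature), config$offtargets)
  signatures <- lapply(sig_sets, function(d) stage_run(paste0("signature_", d$name), {
    em <- load_dataset(d, d$name)
    sg <- differential_signature(em, alpha = config$sig_alpha,
                                 condition = d$name)
    note("signature %s: %d DE genes of %d", d$name, length(sg$genes),
         length(sg$universe))
    sg
  }))
  names(signatures) <- vapply(sig_sets, `[[`, character(1), "name")

  mra <- list()
  for (i in 1:2) {
    for (sn in names(signatures)) {
      key <- sprintf("net%d_%s", i, sn)
      mra[[key]] <- stage_run(paste0("mra_", key),
        master_regulator_analysis(networks[[i]], signatures[[sn]],
                                  alpha = config$mra_alpha))
      note("MRA %s: %d MR(s)", key, sum(mra[[key]]$is_mr))
    }
  }

  clusters <- lapply(1:2, function(i) stage_run(paste0("clusters_net", i),
    detect_clusters(networks[[i]], jaccard_threshold = config$jaccard_threshold)))
  for (i in 1:2) {
    note("network %d clusters: A=%d, B=%d", i, length(clusters[[i]]$A),
         length(clusters[[i]]$B))
  }

  off_keys <- as.vector(outer(1:2, setdiff(names(signatures),
                                           config$signature$name),
                              function(i, sn) sprintf("net%d_%s", i, sn)))
  specificity <- stage_run("specificity_filter", specificity_filter(
    mra[[sprintf("net1_%s", config$signature$name)]],
    mra[[sprintf("net2_%s", config$signature$name)]],
    mra_offtargets = mra[off_keys],
    clusters_net1 = clusters[[1]], clusters_net2 = clusters[[2]]))
  note("specificity funnel: %s",
       paste(sprintf("%s=%d", names(specificity$funnel), specificity$funnel),
             collapse = ", "))

  # Activity is scored for the final MR panel (the regulons the study
  # focuses on); with no final MRs the whole regulon map is scored.
  activity <- lapply(1:2, function(i) stage_run(paste0("activity_net", i), {
    net <- networks[[i]]
    keep <- intersect(specificity$final_mrs, names(net$regulons))
    if (length(keep)) net$regulons <- net$regulons[keep]
    z <- zscore_by_gene(coh[[i]])
    regulon_activity(z, net, n_null = config$n_null,
                     seed = derive_seed(config$seed, paste0("activity", i)),
                     weight_exponent = config$weight_exponent)
  }))

  similarity <- stage_run("similarity", list(
    cross = regulon_similarity(networks[[1]], networks[[2]]),
    within_net1 = regulon_similarity(networks[[1]]),
    within_net2 = regulon_similarity(networks[[2]])))

  mrexpr <- lapply(1:2, function(i) {
    if (!length(specificity$final_mrs)) return(NULL)
    present <- intersect(specificity$final_mrs, rownames(coh[[i]]$values))
    if (!length(present)) return(NULL)
    stage_run(paste0("mrexpr_net", i),
              mr_expression_test(coh[[i]], present, alpha = config$mrexpr_alpha))
  })

  files <- write_pipeline_artifacts(out_dir, networks, signatures, mra,
                                    clusters, specificity, activity,
                                    similarity, mrexpr)
  writeLines(log, file.path(out_dir, "run.log"))
  files <- c(files, "run.log")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package = "regnetmr",
    seed = config$seed,
    params = config[setdiff(names(config),
                            c("cohort1", "cohort2", "signature", "offtargets"))],
    datasets = list(cohort1 = config$cohort1, cohort2 = config$cohort2,
                    signature = config$signature,
                    offtargets = config$offtargets),
    funnel = as.list(specificity$funnel),
    final_mrs = specificity$final_mrs,
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(networks = networks, signatures = signatures, mra = mra,
                 clusters = clusters, specificity = specificity,
                 activity = activity, similarity = similarity,
                 mrexpr = mrexpr, manifest = manifest, log = log))
}

# Fixed-format writers so pipeline outputs are byte-stable across runs.
write_tsv_fixed <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) "num" else "chr"
  }, character(1))
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(mapply(function(col, f) {
      if (f == "num") sprintf("%.8g", col[i]) else as.character(col[i])
    }, df, fmt), collapse = "\t")
  }, character(1))
  writeLines(c(paste(colnames(df), collapse = "\t"), body), path)
  invisible(path)
}

write_pipeline_artifacts <- function(out_dir, networks, signatures, mra,
                                     clusters, specificity, activity,
                                     similarity, mrexpr) {
  files <- character(0)
  put <- function(name, writer) {
    writer(file.path(out_dir, name))
    files <<- c(files, name)
  }
  for (i in 1:2) {
    put(sprintf("network%d_edges.tsv", i),
        function(p) write_network(networks[[i]], p))
    if (length(networks[[i]]$regulons) >= 2L) {
      put(sprintf("network%d_overlap.graphml", i),
          function(p) write_overlap_graphml(networks[[i]], p))
    }
    put(sprintf("network%d_nes.tsv", i), function(p) {
      nes <- activity[[i]]$nes
      df <- data.frame(regulon = rownames(nes), as.data.frame(nes),
                       check.names = FALSE)
      write_tsv_fixed(df, p)
    })
    put(sprintf("network%d_status.tsv", i), function(p) {
      st <- activity[[i]]$status
      df <- data.frame(regulon = rownames(st), as.data.frame(st),
                       check.names = FALSE)
      write_tsv_fixed(df, p)
    })
    if (!is.null(mrexpr[[i]])) {
      put(sprintf("network%d_mr_expression.tsv", i),
          function(p) write_tsv_fixed(mrexpr[[i]], p))
    }
  }
  for (sn in names(signatures)) {
    put(sprintf("signature_%s.tsv", sn),
        function(p) write_tsv_fixed(signatures[[sn]]$stats, p))
  }
  for (key in names(mra)) {
    put(sprintf("mra_%s.tsv", key),
        function(p) write_tsv_fixed(as.data.frame(mra[[key]]), p))
  }
  put("clusters.json", function(p) {
    jsonlite::write_json(
      lapply(clusters, function(cl) list(A = cl$A, B = cl$B,
                                         sizes = cl$sizes)),
      p, pretty = TRUE, digits = NA)
  })
  put("specificity.json", function(p) {
    jsonlite::write_json(list(flags = specificity$flags,
                              final_mrs = specificity$final_mrs,
                              funnel = as.list(specificity$funnel)),
                         p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  put("similarity_cross.tsv", function(p) write_tsv_fixed(similarity$cross, p))
  put("similarity_within_net1.tsv",
      function(p) write_tsv_fixed(similarity$within_net1, p))
  put("similarity_within_net2.tsv",
      function(p) write_tsv_fixed(similarity$within_net2, p))
  files
}
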