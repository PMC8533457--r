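# Shared fixtures, built in code and memoised so expensive simulations run
# once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Planted-network recovery run at the reference conditions: 10 TFs x 20
# disjoint targets, n = 200 samples, beta = 1, noise_sd = 0.5, 100
# permutations, no phenotype shift.
planted_recovery <- function() {
  memo("planted_recovery", {
    truth <- generate_network_truth(10, 20, frac_negative = 0.25, beta = 1,
                                    n_driver = 3, conditions = "sepsis",
                                    noise_sd = 0.5, delta = 2, seed = 7)
    em <- simulate_expression(truth, simulation_design(100, 100, "null", seed = 8))
    edges <- permutation_edge_test(em, truth$tf_ids, n_permutations = 100,
                                   alpha = 0.05, seed = 9)
    pruned <- apply_dpi(edges)
    net <- build_regulons(pruned, em, min_regulon_size = 15)
    list(truth = truth, em = em, edges = edges, pruned = pruned, net = net)
  })
}

# A small planted system reused by activity/enrichment tests.
small_system <- function() {
  memo("small_system", {
    truth <- generate_network_truth(8, 15, frac_negative = 0.3, beta = 1,
                                    n_driver = c(2, 2),
                                    conditions = c("sepsis", "offtarget"),
                                    noise_sd = 0.5, delta = 2, seed = 31)
    net <- truth_to_network(truth)
    em <- simulate_expression(truth, simulation_design(20, 20, "sepsis", seed = 32))
    list(truth = truth, net = net, em = em)
  })
}

# A toy RegulatoryNetwork with hand-chosen regulon target sets.
toy_network <- function(target_sets) {
  edges <- do.call(rbind, lapply(names(target_sets), function(tf) {
    data.frame(tf = tf, target = target_sets[[tf]], mode = 1L, mi = 1,
               p = 0, adj_p = 0, stringsAsFactors = FALSE)
  }))
  regnetmr:::assemble_network(
    edges, universe = union(names(target_sets), unique(edges$target)),
    min_regulon_size = 1L, params = list())
}

# A minimal GeneSignature object for MRA tests.
toy_signature <- function(genes, universe, condition = "toy", alpha = 0.05) {
  structure(list(condition = condition, genes = genes,
                 stats = data.frame(gene = universe,
                                    effect = as.numeric(universe %in% genes),
                                    p = NA_real_, adj_p = NA_real_),
                 universe = universe, alpha = alpha),
            class = "GeneSignature")
}

# A minimal mra_table for specificity-filter tests.
toy_mra <- function(tfs, mrs) {
  out <- data.frame(tf = tfs, regulon_size = 10L, signature_size = 5L,
                    overlap = 3L, p = 0.5, adj_p = 0.5,
                    is_mr = tfs %in% mrs, stringsAsFactors = FALSE)
  class(out) <- c("mra_table", "data.frame")
  out
}

# A small expression matrix with explicit case/control structure.
toy_expression <- function(case, control, genes = NULL) {
  v <- cbind(case, control)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(v)))
  colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  rownames(v) <- genes
  expression_matrix(v, phenotype = stats::setNames(
    rep(c("case", "control"), c(ncol(case), ncol(control))), colnames(v)))
}
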