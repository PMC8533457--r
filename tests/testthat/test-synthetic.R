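test_that("planted truth honours counts, modes, drivers and determinism", {
  tr <- generate_network_truth(10, 20, frac_negative = 0, n_driver = c(3, 2),
                               conditions = c("sepsis", "offtarget"), seed = 1)
  expect_equal(nrow(tr$edges), 200)
  expect_true(all(tr$edges$mode == 1L))
  expect_length(intersect(tr$driver_sets$sepsis, tr$driver_sets$offtarget), 0)
  expect_true(all(unlist(tr$driver_sets) %in% tr$tf_ids))
  expect_false(any(tr$edges$target %in% tr$tf_ids))

  tr2 <- generate_network_truth(10, 20, frac_negative = 0, n_driver = c(3, 2),
                                conditions = c("sepsis", "offtarget"), seed = 1)
  expect_identical(tr, tr2)

  tr3 <- generate_network_truth(10, 20, frac_negative = 1, n_driver = 1, seed = 2)
  expect_true(all(tr3$edges$mode == -1L))
  expect_error(generate_network_truth(4, 5, n_driver = c(3, 2),
                                      conditions = c("a", "b"), seed = 1),
               "driver sets")
})

test_that("overlapping regulons share the declared fraction of targets", {
  tr <- generate_network_truth(10, 20, n_driver = 1, overlap_frac = 0.3, seed = 3)
  expect_equal(nrow(tr$edges), 200)
  t01 <- tr$edges$target[tr$edges$tf == "TF01"]
  t02 <- tr$edges$target[tr$edges$tf == "TF02"]
  t06 <- tr$edges$target[tr$edges$tf == "TF06"]
  expect_length(intersect(t01, t02), 6)   # round(0.3 * 20) chained shares
  expect_length(intersect(t01, t06), 0)   # different blocks stay disjoint
})

test_that("null-condition cohorts show no case/control separation", {
  tr <- generate_network_truth(10, 20, n_driver = 3, seed = 4)
  em <- simulate_expression(tr, simulation_design(30, 30, "null", seed = 5))
  expect_equal(dim(em), c(210L, 60L))
  cm <- colMeans(em$values)
  pv <- stats::t.test(cm[em$phenotype == "case"],
                      cm[em$phenotype == "control"])$p.value
  expect_gt(pv, 0.01)
})

test_that("driver targets with positive modes rise in cases", {
  tr <- generate_network_truth(6, 15, frac_negative = 0, n_driver = 2,
                               noise_sd = 0.5, delta = 2, seed = 6)
  em <- simulate_expression(tr, simulation_design(25, 25, "sepsis", seed = 7))
  drv <- tr$driver_sets$sepsis
  tg <- tr$edges$target[tr$edges$tf %in% drv]
  diff <- rowMeans(em$values[tg, em$phenotype == "case"]) -
    rowMeans(em$values[tg, em$phenotype == "control"])
  expect_gt(min(diff), 0)

  em4 <- simulate_expression(tr, simulation_design(2, 2, "sepsis", seed = 8))
  expect_equal(ncol(em4$values), 4)
  expect_error(simulate_expression(tr, simulation_design(5, 5, "nonsense")),
               "unknown condition")
})

test_that("case/control contrast grows monotonically with delta", {
  diffs <- vapply(c(0.5, 1, 2, 4), function(delta) {
    tr <- generate_network_truth(6, 15, frac_negative = 0, n_driver = 2,
                                 noise_sd = 0.5, delta = delta, seed = 9)
    em <- simulate_expression(tr, simulation_design(25, 25, "sepsis", seed = 10))
    tg <- tr$edges$target[tr$edges$tf %in% tr$driver_sets$sepsis]
    mean(rowMeans(em$values[tg, em$phenotype == "case"]) -
           rowMeans(em$values[tg, em$phenotype == "control"]))
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("probe expansion is consistent, deterministic, and exact at zero gain", {
  tr <- generate_network_truth(3, 5, n_driver = 1, seed = 11)
  em <- simulate_expression(tr, simulation_design(5, 5, "null", seed = 12))

  pr1 <- expand_to_probes(em, probes_per_gene = 1, gain_sd = 0, seed = 13)
  expect_equal(unname(pr1$matrix$values), unname(em$values))
  expect_equal(rownames(pr1$matrix$values), paste0(rownames(em$values), "_p1"))

  pr3 <- expand_to_probes(em, probes_per_gene = 3, gain_sd = 0.3, seed = 14)
  expect_equal(nrow(pr3$matrix$values), 3 * nrow(em$values))
  expect_setequal(unique(unname(pr3$map)), rownames(em$values))
  expect_true(all(pr3$matrix$values > 0))

  pr3b <- expand_to_probes(em, probes_per_gene = 3, gain_sd = 0.3, seed = 14)
  expect_identical(pr3$matrix$values, pr3b$matrix$values)
})

test_that("truth-derived network carries the planted regulons and modes", {
  tr <- generate_network_truth(5, 12, frac_negative = 0.4, n_driver = 1, seed = 15)
  net <- truth_to_network(tr)
  expect_length(net$regulons, 5)
  r <- net$regulons$TF02
  planted <- tr$edges[tr$edges$tf == "TF02", ]
  expect_setequal(r$target, planted$target)
  expect_equal(r$mode[match(planted$target, r$target)], planted$mode)
})

test_that("synthetic study on disk yields a valid pipeline configuration", {
  dir <- tempfile()
  st <- write_synthetic_study(dir, seed = 77, n_tfs = 4, targets_per_tf = 6,
                              overlap_frac = 0, cohort_n = c(5, 5),
                              signature_n = c(4, 4), offtarget_n = c(4, 4),
                              n_driver = c(1, 1))
  expect_s3_class(st$config, "PipelineConfig")
  expect_true(file.exists(st$config$cohort1$probe_map))
  em <- read_expression_matrix(st$config$cohort2$expression,
                               st$config$cohort2$phenotype)
  expect_equal(ncol(em$values), 10)
  expect_equal(sum(em$phenotype == "case"), 5)
})
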