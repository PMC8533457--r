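test_that("running enrichment score handles the boundary hit patterns", {
  rv <- c(a = 3, b = 2, c = 1, d = 0.5)
  expect_equal(running_enrichment_score(rv, "a", weight_exponent = 0), 1.0)
  expect_equal(running_enrichment_score(rv, "d", weight_exponent = 0), -1.0)
  expect_error(running_enrichment_score(rv, character(0)), "non-empty")
  expect_error(running_enrichment_score(rv, names(rv)), "smaller")
  expect_error(running_enrichment_score(rv, "zzz"), "subset")
  expect_error(running_enrichment_score(rev(rv), "a"), "non-increasing")
})

test_that("running enrichment score equals the cumulative-walk oracle", {
  withr::with_seed(61, {
    for (i in 1:40) {
      N <- sample(10:40, 1)
      rv <- sort(stats::rnorm(N), decreasing = TRUE)
      names(rv) <- paste0("g", seq_len(N))
      set <- sample(names(rv), sample(seq_len(N - 1), 1))
      we <- sample(c(0, 0.5, 1, 2), 1)
      expect_equal(running_enrichment_score(rv, set, we),
                   es_walk_oracle(rv, set, we), tolerance = 1e-12)
    }
  })
})

test_that("hit-position scorer agrees with the full running sum", {
  withr::with_seed(62, {
    for (i in 1:25) {
      N <- sample(15:50, 1)
      rv <- sort(stats::rnorm(N), decreasing = TRUE)
      names(rv) <- paste0("g", seq_len(N))
      set <- sample(names(rv), sample(2:6, 1))
      pos <- sort(match(set, names(rv)))
      w <- abs(rv[pos])^1
      expect_equal(regnetmr:::es_from_positions(pos, w, N),
                   running_enrichment_score(rv, set, 1), tolerance = 1e-12)
    }
  })
})

test_that("regulon activity separates planted drivers and is mode-antisymmetric", {
  sys <- small_system()
  z <- zscore_by_gene(sys$em)
  act <- regulon_activity(z, sys$net, n_null = 100, seed = 63)
  ph <- sys$em$phenotype
  drv <- sys$truth$driver_sets$sepsis
  nes_diff <- rowMeans(act$nes[, ph == "case"]) -
    rowMeans(act$nes[, ph == "control"])
  expect_gt(min(nes_diff[drv]), 1)
  expect_gt(min(nes_diff[drv]) - max(nes_diff[setdiff(rownames(act$nes), drv)]), 0)

  # flipping every mode negates dES exactly, for every sample
  flipped <- sys$net
  flipped$regulons <- lapply(flipped$regulons, function(r) {
    r$mode <- -r$mode; r
  })
  act_f <- regulon_activity(z, flipped, n_null = 100, seed = 63)
  expect_equal(act_f$des, -act$des)

  # a regulon with only positive modes scores dES = ES_pos exactly
  pure <- names(which(vapply(sys$net$regulons,
                             function(r) all(r$mode == 1L), logical(1))))
  if (length(pure)) {
    tf <- pure[1]
    j <- colnames(z)[1]
    ord <- order(z[, j], decreasing = TRUE)
    rv <- z[ord, j]
    expect_equal(act$des[tf, j],
                 running_enrichment_score(rv, sys$net$regulons[[tf]]$target, 1),
                 tolerance = 1e-12)
  }

  # determinism: same seed reproduces the same nulls hence the same NES
  act2 <- regulon_activity(z, sys$net, n_null = 100, seed = 63)
  expect_identical(act$nes, act2$nes)
})

test_that("dES is rank-driven when hits are unweighted", {
  sys <- small_system()
  z <- zscore_by_gene(sys$em)[, 1:4]
  act0 <- regulon_activity(z, sys$net, n_null = 30, seed = 64,
                           weight_exponent = 0)
  # a strictly monotone transform of z preserves all rankings
  zt <- sign(z) * abs(z)^3
  act0t <- regulon_activity(zt, sys$net, n_null = 30, seed = 64,
                            weight_exponent = 0)
  expect_equal(act0$des, act0t$des, tolerance = 1e-12)
})

test_that("regulon similarity computes shared counts and Jaccard", {
  net_a <- toy_network(list(T1 = c("a", "b", "c"), T2 = c("a", "b", "c")))
  within <- regulon_similarity(net_a)
  expect_equal(within$shared, 3L)
  expect_equal(within$jaccard, 1.0)

  net1 <- toy_network(list(T1 = c("a", "b", "c"), T2 = c("x", "y")))
  net2 <- toy_network(list(T1 = c("b", "c", "d"), T2 = c("p", "q")))
  cross <- regulon_similarity(net1, net2)
  expect_equal(cross$shared[cross$tf1 == "T1"], 2L)
  expect_equal(cross$jaccard[cross$tf1 == "T1"], 0.5)
  expect_equal(cross$jaccard[cross$tf1 == "T2"], 0.0)
  expect_true(all(cross$jaccard >= 0 & cross$jaccard <= 1))
})

test_that("MR expression test is exact on small groups and directional", {
  em <- toy_expression(matrix(c(5, 6, 7), 1), matrix(c(1, 2, 3), 1),
                       genes = "TF1")
  tab <- mr_expression_test(em, "TF1", alpha = 0.05)
  expect_equal(tab$p, 2 / 20, tolerance = 1e-12)   # C(6,3) = 20 assignments
  expect_equal(tab$direction, "ns")                # 0.1 clears no threshold

  em4 <- toy_expression(matrix(5:8, 1), matrix(1:4, 1), genes = "TF1")
  tab4 <- mr_expression_test(em4, "TF1", alpha = 0.05)
  expect_equal(tab4$p, 2 / 70, tolerance = 1e-12)  # C(8,4) = 70 assignments
  expect_equal(tab4$direction, "up_in_case")

  em_eq <- toy_expression(matrix(c(4, 4, 4), 1), matrix(c(4, 4, 4), 1),
                          genes = "TF1")
  tab_eq <- mr_expression_test(em_eq, "TF1", alpha = 0.01)
  expect_equal(tab_eq$p, 1.0)
  expect_equal(tab_eq$direction, "ns")

  expect_warning(mr_expression_test(em, c("TF1", "NOPE"), alpha = 0.05),
                 "NOPE")
})

test_that("exact Wilcoxon p agrees with wilcox.test and the enumeration oracle", {
  withr::with_seed(65, {
    for (i in 1:20) {
      nx <- sample(3:6, 1); ny <- sample(3:6, 1)
      x <- sample(1:8, nx, replace = TRUE)   # ties across groups likely
      y <- sample(1:8, ny, replace = TRUE)
      expect_equal(regnetmr:::wilcox_rank_sum_p(x, y),
                   wilcox_enum_oracle(x, y), tolerance = 1e-12)
    }
    # tie-free case also matches stats::wilcox.test's exact p
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    expect_equal(regnetmr:::wilcox_rank_sum_p(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  })
})
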