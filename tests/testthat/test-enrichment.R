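test_that("p-value adjustment matches the step rules", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.2), "bonferroni"), c(0.02, 0.4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")

  withr::with_seed(51, {
    for (i in 1:25) {
      p <- stats::runif(sample(1:40, 1))
      expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p))
      expect_true(all(adjust_pvalues(p, "BH") >= p))
      o <- sample(length(p))
      expect_equal(adjust_pvalues(p, "BH")[o], adjust_pvalues(p[o], "BH"))
    }
  })
})

test_that("differential signature finds planted shifts and controls errors", {
  withr::with_seed(52, {
    n_shift <- 40; n_null <- 400
    case <- matrix(stats::rnorm(440 * 20, 8, 0.5), 440, 20)
    control <- matrix(stats::rnorm(440 * 20, 8, 0.5), 440, 20)
    case[seq_len(n_shift), ] <- case[seq_len(n_shift), ] + 2
  })
  em <- toy_expression(case, control, genes = sprintf("g%03d", 1:440))
  sig <- differential_signature(em, alpha = 0.05)
  shifted <- sprintf("g%03d", 1:40)
  expect_true(all(shifted %in% sig$genes))
  expect_lte(length(setdiff(sig$genes, shifted)), 0.05 * n_null)
  expect_true(all(sig$stats$effect[match(shifted, sig$stats$gene)] > 0))
  expect_equal(sig$universe, sprintf("g%03d", 1:440))

  # identical case and control columns -> empty signature
  em0 <- toy_expression(control[1:50, ], control[1:50, ])
  expect_length(differential_signature(em0, alpha = 0.05)$genes, 0)

  # a group with < 2 samples errors
  v <- matrix(1:10 + 0.5, 5, 2, dimnames = list(letters[1:5], c("s1", "s2")))
  em1 <- expression_matrix(v, phenotype = c(s1 = "case", s2 = "control"))
  expect_error(differential_signature(em1), "at least 2")
})

test_that("Welch statistics agree with stats::t.test per gene", {
  withr::with_seed(53, {
    case <- matrix(stats::rnorm(5 * 8, 8), 5, 8)
    control <- matrix(stats::rnorm(5 * 6, 8.5), 5, 6)
  })
  em <- toy_expression(case, control)
  sig <- differential_signature(em, alpha = 0.05)
  for (i in 1:5) {
    ref <- stats::t.test(case[i, ], control[i, ])
    expect_equal(sig$stats$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(sig$stats$effect[i],
                 unname(diff(rev(ref$estimate))), tolerance = 1e-12)
  }
})

test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeom_upper_tail(20, 5, 8, 5), 455 / 125970,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(20, 5, 8, 0), 1.0)
  expect_equal(hypergeom_upper_tail(10, 10, 3, 3), 1.0)
  expect_error(hypergeom_upper_tail(10, 12, 3, 3), "inconsistent")
  expect_error(hypergeom_upper_tail(10, 5, 3, 4), "inconsistent")
  # spot agreement with the survival function of stats::phyper
  expect_equal(hypergeom_upper_tail(1000, 40, 100, 12),
               stats::phyper(11, 40, 960, 100, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("MRA flags enriched regulons and respects degenerate cases", {
  universe <- sprintf("g%02d", 1:20)
  net <- toy_network(list(T1 = universe[1:5]))
  net$universe <- c("T1", universe)

  sig <- toy_signature(universe[c(1:5, 6:8)], c("T1", universe))
  tab <- master_regulator_analysis(net, sig, alpha = 0.05)
  # universe restricted to the 21 shared ids; K=5, n=8, k=5
  expect_equal(tab$overlap, 5L)
  expect_equal(tab$p, hyper_oracle(21, 5, 8, 5), tolerance = 1e-12)
  expect_true(tab$is_mr)

  empty <- master_regulator_analysis(net, toy_signature(character(0), universe))
  expect_equal(empty$overlap, 0L)
  expect_equal(empty$p, 1.0)
  expect_false(any(empty$is_mr))

  saturated <- master_regulator_analysis(net, toy_signature(universe, universe))
  expect_equal(saturated$p, 1.0)
})

test_that("MRA is invariant to a joint renaming of genes", {
  sys <- small_system()
  em <- sys$em
  sig <- differential_signature(em, alpha = 0.05)
  tab <- master_regulator_analysis(sys$net, sig, alpha = 0.05)

  rename <- function(x) paste0("X_", x)
  net2 <- sys$net
  net2$universe <- rename(net2$universe)
  net2$regulons <- lapply(net2$regulons, function(r) {
    r$target <- rename(r$target); r
  })
  names(net2$regulons) <- rename(names(net2$regulons))
  sig2 <- sig
  sig2$genes <- rename(sig2$genes)
  sig2$universe <- rename(sig2$universe)
  tab2 <- master_regulator_analysis(net2, sig2, alpha = 0.05)
  expect_equal(rename(tab$tf), tab2$tf)
  expect_equal(tab$p, tab2$p)
  expect_equal(tab$is_mr, tab2$is_mr)
})

test_that("over-representation matches exhaustive enumeration term by term", {
  withr::with_seed(54, {
    universe <- sprintf("u%03d", 1:100)
    query <- sample(universe, 12)
    sets <- lapply(1:10, function(i) sample(universe, sample(5:30, 1)))
    names(sets) <- paste0("term", 1:10)
  })
  coll <- structure(list(sets = sets,
                         descriptions = stats::setNames(names(sets), names(sets))),
                    class = "GeneSetCollection")
  tab <- overrepresentation(query, coll, universe, alpha = 0.05)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$p[i],
                 hyper_oracle(100, tab$K[i], 12, tab$k[i]), tolerance = 1e-10)
  }

  coll2 <- structure(list(sets = c(sets, list(exact = query,
                                              disjoint = setdiff(universe, query)[1:10])),
                          descriptions = character(0)),
                     class = "GeneSetCollection")
  tab2 <- overrepresentation(query, coll2, universe)
  expect_equal(tab2$set_name[which.min(tab2$p)], "exact")
  expect_equal(tab2$p[tab2$set_name == "disjoint"], 1.0)
})
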