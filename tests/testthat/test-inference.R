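test_that("mid-ranks follow the tie-sharing convention and conserve the rank sum", {
  expect_equal(midranks(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(midranks(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
  set.seed(5)
  for (i in 1:25) {
    x <- sample(round(rlnorm(sample(3:40, 1)), sample(0:2, 1)))
    N <- length(x)
    expect_identical(sum(midranks(x)), N * (N + 1) / 2)
  }
})

test_that("the H statistic matches hand values and a first-principles oracle", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$chi2, 2.4)
  expect_equal(kw$df, 1)

  set.seed(6)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      round(rlnorm(sample(2:8, 1)), sample(0:1, 1)))  # rounding induces ties
    if (length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    expect_equal(kw$chi2, kw_h_oracle(groups), tolerance = 1e-12)
  }
})

test_that("H and p agree with the standard library implementation", {
  set.seed(13)
  for (i in 1:50) {
    g <- sample(1:3, 30, replace = TRUE)
    x <- round(rlnorm(30), 1)
    kw <- kruskal_wallis(split(x, g))
    ref <- kruskal.test(x, g)
    expect_equal(kw$chi2, unname(ref$statistic))
    expect_equal(kw$p, ref$p.value)
    expect_equal(kw$df, unname(ref$parameter))
  }
})

test_that("the exact permutation p-value matches full enumeration for N <= 8", {
  cases <- list(list(c(1, 2), c(1, 2)),
                list(c(1, 5, 2), c(8, 9, 7)),
                list(c(0.1, 0.4), c(0.2, 0.3), c(0.9, 0.5)),
                list(c(1, 1, 2), c(2, 3, 3, 4)))
  for (g in cases) {
    kw <- kruskal_wallis(g, exact = TRUE)
    expect_equal(kw$p_exact, kw_perm_oracle(g), tolerance = 1e-12)
  }
  expect_gt(kruskal_wallis(list(c(1, 2), c(1, 2)), exact = TRUE)$p_exact, 0.9)
})

test_that("degenerate and malformed inputs error", {
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1, 1))), "degenerate")
  expect_error(kruskal_wallis(list(c(1, 2))), "length")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3")
})

test_that("a five-dose design yields four degrees of freedom", {
  set.seed(8)
  groups <- split(rlnorm(50), rep(c(0, 10, 50, 100, 200), each = 10))
  expect_equal(kruskal_wallis(groups)$df, 4)
})

test_that("Dunn comparisons match hand computation in the no-tie case", {
  d <- dunn_pairwise(list(`0` = c(1, 2), `10` = c(3, 4)))
  expect_equal(d$rank_mean_diff, -2)
  expect_equal(d$se, sqrt(20 / 12 * (1 / 2 + 1 / 2)))
  expect_equal(d$z, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(round(d$z, 3), -1.549)

  # with no ties the closed form holds exactly and z * se == diff
  set.seed(10)
  g <- split(runif(40), rep(c(0, 10, 50, 100), each = 10))
  dd <- dunn_pairwise(g)
  N <- 40
  expect_equal(dd$se, dunn_se(dd$n1, dd$n2, N), tolerance = 1e-12)
  expect_equal(dd$z * dd$se, dd$rank_mean_diff, tolerance = 1e-12)
})

test_that("rows are ordered low-dose-first so induced responses give negative diffs", {
  set.seed(14)
  g <- list(`0` = rlnorm(20, 0, 0.1), `200` = rlnorm(20, 2, 0.1),
            `50` = rlnorm(20, 1, 0.1))
  d <- dunn_pairwise(g)
  expect_equal(d$group1, c("0", "0", "50"))
  expect_equal(d$group2, c("50", "200", "200"))
  expect_true(all(d$rank_mean_diff < 0))
})

test_that("tie-corrected se shrinks and the Bonferroni chain is exact", {
  x <- c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(1:3, each = 4)
  d <- dunn_pairwise(split(x, g), adjust = "bonferroni")
  tie_sum <- sum(sapply(table(x), function(t) t^3 - t))
  expect_equal(d$se, dunn_se(d$n1, d$n2, 12, tie_sum))
  expect_true(all(d$se < dunn_se(d$n1, d$n2, 12)))

  m <- nrow(d)
  unsat <- d$p_adj < 1
  expect_equal(d$p_adj[unsat] / d$p[unsat], rep(m, sum(unsat)))
  expect_true(all(d$p_adj <= 1))
  expect_equal(dunn_standardize(1, 2, m = 10)$p_adj, 1)  # Bonferroni cap
  expect_error(dunn_pairwise(list(numeric(0), c(1, 2))), "non-empty")
})

test_that("the dose-response report screens, tests, and formats per panel", {
  set.seed(15)
  designs <- dekkera_designs(seed = 15)
  tab <- rbind(simulate_fmeasures(designs$bruxellensis_2PE),
               simulate_fmeasures(designs$anomalous_2PE))
  rep_ <- dose_response_report(tab)
  expect_equal(nrow(rep_$omnibus), 2)
  expect_equal(rep_$omnibus$df, c(4, 4))
  expect_equal(nrow(rep_$pairwise), 20)
  expect_true(all(c("pair", "rank_mean_diff", "se", "z", "p", "p_adj") %in%
                  names(rep_$pairwise)))
  expect_true(all(rep_$pairwise$p_adj >= rep_$pairwise$p))
  expect_equal(nrow(rep_$summaries), 10)

  single <- tab[tab$concentration_uM == 0 & tab$strain == "D. anomalous", ]
  expect_error(dose_response_report(single), "fewer than 2")
})

test_that("a strongly induced simulated panel is detected as significant", {
  tab <- simulate_fmeasures(dekkera_designs(seed = 99)$bruxellensis_2PE)
  rep_ <- dose_response_report(tab)
  expect_lt(rep_$omnibus$p, 0.001)
  row_0_100 <- rep_$pairwise[rep_$pairwise$pair == "0-100 uM", ]
  expect_lt(row_0_100$p_adj, 0.001)
  expect_lt(row_0_100$rank_mean_diff, 0)
})
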