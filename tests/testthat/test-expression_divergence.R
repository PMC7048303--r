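test_that("Pearson divergence calls use r-squared, sign-blind", {
  x <- c(1, 5, 2, 9, 3, 7, 4, 8)
  out <- expression_correlation(x, x)
  expect_equal(out$r, 1)
  expect_false(out$divergent)

  neg <- expression_correlation(x, max(x) - x)
  expect_equal(neg$r, -1)
  expect_equal(neg$r_squared, 1)
  expect_false(neg$divergent)

  flat <- expression_correlation(x, rep(2, 8))
  expect_true(is.na(flat$r))
  expect_true(is.na(flat$divergent))
})

test_that("Fisher exact matches fisher.test and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  set.seed(8)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p, oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("sex bias test pools counts and is invariant to swaps", {
  sex <- c("M", "F", "M", "F")
  a <- c(6, 0, 4, 0)
  b <- c(0, 5, 0, 5)
  out <- sex_bias_test(a, b, sex)
  expect_equal(unname(out$table), matrix(c(10, 0, 0, 10), 2))
  expect_equal(out$p, 2 / choose(20, 10), tolerance = 1e-12)
  # swap paralogs
  expect_equal(sex_bias_test(b, a, sex)$p, out$p)
  # swap sexes
  flipped <- ifelse(sex == "M", "F", "M")
  expect_equal(sex_bias_test(a, b, flipped)$p, out$p)
  # zero margin: degenerate, p = 1
  z <- sex_bias_test(c(0, 0), c(0, 0), c("M", "F"))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
})

test_that("fold bias flags >5-fold inter-paralog ratio differences", {
  sex <- c("M", "F")
  # paralog a 10x male-biased, b unbiased -> difference 1 > log10(5)
  out <- fold_bias(c(1000, 100), c(200, 200), sex, pseudocount = 0)
  expect_equal(out$log10_ratio_a, 1)
  expect_equal(out$log10_ratio_b, 0)
  expect_true(out$fold_flag)
  # 4x vs 1x stays under the cutoff
  out <- fold_bias(c(400, 100), c(200, 200), sex, pseudocount = 0)
  expect_false(out$fold_flag)
  # unbiased pair
  out <- fold_bias(c(200, 200), c(50, 50), sex, pseudocount = 0)
  expect_equal(out$log10_ratio_a, 0)
  expect_false(out$fold_flag)
})

test_that("the Fisher screen holds its size under a shared multinomial null", {
  set.seed(12)
  n <- 2000
  p <- numeric(n)
  for (i in seq_len(n)) {
    split_m <- runif(1, 0.2, 0.8)          # one shared male fraction
    ta <- rmultinom(1, rpois(1, 400) + 50, c(split_m, 1 - split_m))
    tb <- rmultinom(1, rpois(1, 400) + 50, c(split_m, 1 - split_m))
    p[i] <- fisher_exact_2x2(ta[1], ta[2], tb[1], tb[2])
  }
  expect_lte(mean(p < 0.01), 0.015)
})

test_that("pair-level analysis assembles all statistics and flags", {
  sim <- sim_expression(60, frac_divergent = 0.5, seed = 21,
                        n_bias_pairs = 5, bias_odds = 10)
  res <- pair_expression_analysis(sim$pairs, sim$expr, sim$stage_phase)
  expect_equal(nrow(res), 60L)
  expect_true(all(res$fisher_p_developing >= 0 & res$fisher_p_developing <= 1))
  expect_equal(res$divergent, res$r_squared < 0.3)
  expect_equal(res$significant_developing, res$fisher_p_developing < 0.01)
  sm <- summarize_expression_divergence(res)
  expect_equal(sm$n_divergent, sum(res$divergent, na.rm = TRUE))
  expect_equal(sm$pct_divergent, 100 * sm$n_divergent / sm$n_pairs)
})

test_that("divergence classification recovers the planted fraction", {
  sim <- sim_expression(800, frac_divergent = 0.4, seed = 31)
  res <- pair_expression_analysis(sim$pairs, sim$expr, sim$stage_phase)
  # per-pair recovery on well-separated effect sizes
  agree <- mean(res$divergent == sim$truth$divergent, na.rm = TRUE)
  expect_gte(agree, 0.9)
  frac <- mean(res$divergent, na.rm = TRUE)
  expect_lt(abs(frac - 0.4), 0.04)
})
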