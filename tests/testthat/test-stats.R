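mk_long <- function(n_genes = 8, effect_mode = 0, sd = 1, seed = 1) {
  grid <- tidyr::expand_grid(
    gene = sprintf("g%02d", seq_len(n_genes)),
    pair = sprintf("p%d", 1:5),
    mode = c("sexual", "asexual")
  )
  withr::with_seed(seed, {
    grid$y <- stats::rnorm(nrow(grid), sd = sd) +
      ifelse(grid$mode == "asexual", effect_mode, 0)
  })
  grid
}

test_that("a constant response yields p = 1 for every factor", {
  d <- mk_long(4)
  d$y <- 1
  out <- permutation_anova(d, "y", B = 99, seed = 3)
  expect_true(all(out$p_value == 1))
  expect_true(all(out$statistic == 0))
})

test_that("an overwhelming mode effect reaches the minimum attainable p", {
  d <- mk_long(6, effect_mode = 10, sd = 0.5, seed = 8)
  B <- 199
  out <- permutation_anova(d, "y", B = B, seed = 9)
  expect_equal(out$p_value[out$term == "mode"], 1 / (B + 1))
})

test_that("permutation p-values agree with classical ANOVA on Gaussian data", {
  d <- mk_long(10, effect_mode = 0.45, sd = 1, seed = 21)
  out <- permutation_anova(d, "y", B = 10000, seed = 22)
  classical <- stats::anova(stats::lm(
    y ~ gene + pair + mode + pair:mode,
    data = d
  ))
  p_mode_classical <- classical["mode", "Pr(>F)"]
  p_mode_perm <- out$p_value[out$term == "mode"]
  expect_lt(abs(p_mode_perm - p_mode_classical), 0.04)
  # F statistics themselves are identical (sequential SS)
  expect_equal(
    out$statistic[out$term == "mode"],
    classical["mode", "F value"],
    tolerance = 1e-8
  )
  expect_equal(
    out$statistic[out$term == "gene"],
    classical["gene", "F value"],
    tolerance = 1e-8
  )
})

test_that("single-level factors are skipped with a warning", {
  d <- mk_long(5)
  d$mode <- "sexual"
  expect_warning(
    out <- permutation_anova(d, "y", B = 49, seed = 1),
    "single level"
  )
  expect_false(any(grepl("mode", out$term)))
})

test_that("the Freedman-Lane scheme gives comparable answers", {
  d <- mk_long(6, effect_mode = 1, sd = 1, seed = 30)
  raw <- permutation_anova(d, "y", B = 499, seed = 31)
  fl <- permutation_anova(d, "y", B = 499, seed = 31, scheme = "freedman_lane")
  expect_lt(
    abs(raw$p_value[raw$term == "mode"] - fl$p_value[fl$term == "mode"]),
    0.1
  )
})

test_that("paired tests match closed forms and flag degeneracy", {
  same <- tibble::tibble(pair_id = 1:5, sexual = 1:5, asexual = 1:5)
  expect_error(paired_tests(same), class = "asexdiv_degenerate")
  shifted <- tibble::tibble(
    pair_id = 1:5, sexual = c(2, 3, 4, 5, 6), asexual = c(1, 2, 3, 4, 5)
  )
  expect_error(paired_tests(shifted), class = "asexdiv_degenerate")
  vals <- tibble::tibble(
    pair_id = 1:5,
    sexual = c(0.52, 0.61, 0.48, 0.55, 0.60),
    asexual = c(0.49, 0.55, 0.47, 0.50, 0.52)
  )
  out <- paired_tests(vals)
  d <- vals$sexual - vals$asexual
  t_manual <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(out$statistic, t_manual, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(
    out$p_value, 2 * stats::pt(-abs(t_manual), 4),
    tolerance = 1e-12
  )
  # long format is accepted
  long <- tidyr::pivot_longer(vals, -pair_id,
    names_to = "mode", values_to = "value"
  )
  expect_equal(paired_tests(long)$statistic, out$statistic)
})

test_that("bootstrap intervals are seeded, trivial on constants, calibrated", {
  expect_error(bootstrap_ci(1), class = "asexdiv_input")
  cc <- bootstrap_ci(rep(3.5, 10), B = 100, seed = 1)
  expect_equal(cc$lower, 3.5)
  expect_equal(cc$upper, 3.5)
  x <- c(1.2, 5.3, 2.2, 8.1, 0.4, 3.3, 9.9, 4.4)
  a <- bootstrap_ci(x, B = 500, seed = 7)
  b <- bootstrap_ci(x, B = 500, seed = 7)
  expect_identical(a, b)
  # coverage of the median CI near nominal on Gaussian samples
  hits <- 0
  withr::with_seed(99, {
    for (i in 1:300) {
      v <- stats::rnorm(25)
      ci <- bootstrap_ci(v, B = 400, seed = i)
      if (ci$lower <= 0 && ci$upper >= 0) hits <- hits + 1
    }
  })
  expect_gt(hits / 300, 0.88)
  expect_lt(hits / 300, 1.0)
})

test_that("age correlations recover order and warn on five pairs", {
  d <- tibble::tibble(effect = 1:5 / 10, age = 1:5)
  expect_warning(out <- age_correlation(d), "caution")
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_error(
    suppressWarnings(age_correlation(tibble::tibble(effect = rep(1, 5), age = 1:5))),
    class = "asexdiv_degenerate"
  )
  # shuffled labels: correlation centred on zero
  withr::with_seed(55, {
    rs <- replicate(200, {
      suppressWarnings(age_correlation(tibble::tibble(
        effect = sample(d$effect), age = d$age
      )))$r
    })
  })
  expect_lt(abs(mean(rs)), 0.15)
})
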