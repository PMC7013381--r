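test_that("fraction formula matches hand evaluation and is complementary", {
  expect_equal(phage_fraction(3e7, 1e7), 0.75)
  expect_equal(phage_fraction(5, 5), 0.5)
  expect_equal(phage_fraction(0, 10), 0)
  # complementarity over random quantities
  set.seed(11)
  q1 <- runif(50, 0, 1e8); q2 <- runif(50, 1, 1e8)
  expect_equal(phage_fraction(q1, q2) + phage_fraction(q2, q1), rep(1, 50))
  expect_error(phage_fraction(0, 0), "undefined")
  expect_error(phage_fraction(-1, 2), ">= 0")
})

test_that("relative fitness is the odds ratio between timepoints", {
  expect_equal(relative_fitness(0.5, 0.5), 1)
  expect_equal(relative_fitness(0.5, 0.8), 4)
  expect_equal(relative_fitness(0.2, 0.1), 4 / 9)
  # label-swap antisymmetry: the rival's fitness is the exact reciprocal
  set.seed(12)
  f0 <- runif(100, 0.01, 0.99); fx <- runif(100, 0.01, 0.99)
  expect_equal(relative_fitness(f0, fx) * relative_fitness(1 - f0, 1 - fx),
               rep(1, 100))
})

test_that("boundary fractions yield flagged sentinels, not silent division", {
  expect_warning(w <- relative_fitness(0.5, 1), "detection")
  expect_identical(as.numeric(w), Inf)
  expect_identical(attr(w, "boundary"), "fraction_tx=1")
  expect_warning(w0 <- relative_fitness(0.5, 0), "detection")
  expect_identical(as.numeric(w0), 0)
  expect_warning(wn <- relative_fitness(0, 0), "detection")
  expect_true(is.nan(as.numeric(wn)))
})

test_that("fitness from raw quantities equals fitness from fractions", {
  set.seed(13)
  obs <- generate_competition(true_fitness = 2.5, n_replicates = 6,
                              timepoints = c(0, 1, 3),
                              noise = noise_model(0.15), seed = 21)
  per_rep <- competition_fitness(obs, t0 = 0, tx = 3)
  for (i in seq_len(nrow(per_rep))) {
    r <- per_rep$replicate[i]
    q <- function(tp, comp) obs$quantity[obs$replicate == r &
                                           obs$timepoint == tp &
                                           obs$competitor == comp]
    f0 <- q(0, "competitor1") / (q(0, "competitor1") + q(0, "competitor2"))
    fx <- q(3, "competitor1") / (q(3, "competitor1") + q(3, "competitor2"))
    expect_equal(per_rep$fitness[i],
                 (fx * (1 - f0)) / (f0 * (1 - fx)))
  }
  # averaged-quantity variant returns a single pooled row
  pooled <- competition_fitness(obs, t0 = 0, tx = 3,
                                average_quantities = TRUE)
  expect_equal(nrow(pooled), 1L)
  expect_identical(pooled$replicate, "pooled")
})

test_that("ECOI and phi estimates match hand evaluation and scale invariance", {
  expect_equal(ecoi(200, 1e4, 1), 0.02)
  expect_equal(ecoi(0, 100, 2), 0)
  expect_equal(ecoi(5000, 1e4, 0.5), 1)
  expect_warning(ecoi(300, 100, 1), "ECOI > 1")
  expect_error(ecoi(10, 0, 1), "> 0")

  expect_equal(phi_estimate(0.02, 0.8), 0.025)
  expect_equal(phi_estimate(0.37, 0.37), 1)
  expect_equal(phi_estimate(0, 0.8), 0)
  expect_warning(phi_estimate(0.9, 0.3), "inconsistent")
  expect_error(phi_estimate(0.1, 0), "> 0")

  # proportional count inflation leaves both invariant
  for (c_mult in c(3, 10, 1000)) {
    expect_equal(ecoi(200 * c_mult, 1e4 * c_mult, 1), ecoi(200, 1e4, 1))
  }
})

test_that("one-sample test matches the hand t formula and df = n - 1", {
  vals <- c(1.8, 2.4, 2.1, 1.6, 2.8, 2.2)
  res <- one_sample_test(vals, null_value = 1, tail = "two",
                         log_scale = TRUE)
  x <- log(vals)
  t_hand <- (mean(x) - log(1)) / (sd(x) / sqrt(6))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 5L)  # 6 replicates -> t_5
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 5))
  ci_hw <- qt(0.975, 5) * sd(x) / sqrt(6)
  expect_equal(res$conf_int, exp(mean(x) + c(-1, 1) * ci_hw))
  expect_equal(res$estimate, exp(mean(x)))
  # CI contains the point estimate
  expect_true(res$conf_int[1] <= res$estimate &&
                res$estimate <= res$conf_int[2])

  # linear-scale textbook case
  res2 <- one_sample_test(1:6, null_value = 3.5, tail = "two",
                          log_scale = FALSE)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # one-tailed p halves the two-tailed p on the favourable side
  res3 <- one_sample_test(vals, null_value = 1, tail = "greater")
  expect_equal(res3$p_value, res$p_value / 2)
})

test_that("zero-variance inputs use the flagged exact-equality fast path", {
  eq <- one_sample_test(rep(2, 4), null_value = 2, tail = "two")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_match(eq$flag, "zero variance")
  up <- one_sample_test(rep(3, 4), null_value = 2, tail = "greater")
  expect_equal(up$p_value, 0)
  down <- one_sample_test(rep(3, 4), null_value = 2, tail = "less")
  expect_equal(down$p_value, 1)
})

test_that("test preconditions are enforced", {
  expect_error(one_sample_test(2), "at least 2")
  expect_error(one_sample_test(c(1, NA)), "finite")
  expect_error(one_sample_test(c(-1, 2), log_scale = TRUE), "positive")
})

test_that("Bonferroni threshold follows the 0.05/a rule", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 3), 0.05 / 3)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.2, 3), "\\(0, 1\\)")
})
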