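mk_results <- function(called, imputed, breed = "b1", locus = "L1",
                       k = 10, bf = NA_real_) {
  n <- length(called)
  data.frame(breed = breed, locus_id = locus, flank_k = k,
             method = "hmm", mode = "triallelic",
             animal_id = sprintf("v%03d", seq_len(n)),
             called_cn = called, imputed_cn = imputed,
             correct = called == imputed,
             bayes_factor = rep_len(bf, n),
             population_frequency = 30L, length_kb = 100,
             stringsAsFactors = FALSE)
}

test_that("per-state accuracy is an exact tally", {
  r <- mk_results(c(1, 1, 1), c(1, 2, 1))
  a <- imputation_accuracy(r)
  expect_equal(a$accuracy[a$called_state == 1], 2 / 3)
  expect_equal(a$n_called[a$called_state == 1], 3)

  r2 <- mk_results(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  a2 <- imputation_accuracy(r2)
  expect_equal(nrow(a2), 5)
  expect_true(all(a2$accuracy == 1))

  # all-validation denominator divides by the full validation count
  a3 <- imputation_accuracy(r2, denominator = "all_validation")
  expect_true(all(a3$accuracy == 1 / 5))

  # a state never called yields no record, not a zero
  expect_false(0 %in% imputation_accuracy(r)$called_state)

  # invariant to animal ordering
  perm <- sample(nrow(r2))
  expect_equal(imputation_accuracy(r2[perm, ]), imputation_accuracy(r2))

  # aggregate equals a brute-force tally on a random table
  set.seed(3)
  r4 <- mk_results(sample(0:4, 200, TRUE), sample(0:4, 200, TRUE))
  a4 <- imputation_accuracy(r4)
  for (i in seq_len(nrow(a4))) {
    sub <- r4[r4$called_cn == a4$called_state[i], ]
    expect_equal(a4$n_correct[i], sum(sub$called_cn == sub$imputed_cn))
    expect_equal(a4$n_called[i], nrow(sub))
  }
})

test_that("adjusted Rand index: endpoints, chance level, oracle, symmetry", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)

  set.seed(11)
  a <- sample(1:4, 1000, TRUE); b <- sample(1:4, 1000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)

  # exhaustive pair-counting oracle on small random instances
  for (i in 1:120) {
    n <- sample(3:12, 1)
    x <- sample(1:4, n, TRUE); y <- sample(1:4, n, TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_pair_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  }

  # independent cross-check against mclust's implementation
  skip_if_not_installed("mclust")
  for (i in 1:50) {
    x <- sample(1:5, 30, TRUE); y <- sample(1:5, 30, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }

  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  expect_warning(z <- adjusted_rand_index(rep(1, 5), rep(2, 5)), "single")
  expect_equal(z, 0)
})

test_that("ANOVA plus Tukey: degenerate and powered cases", {
  # identical groups: F = 0, nothing significant
  r0 <- anova_tukey(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(r0$anova_f, 0)
  expect_false(any(r0$tukey$significant))

  # three identical groups: all pairwise p-values are 1
  r1 <- anova_tukey(rep(2, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(abs(r1$tukey$p_adj - 1) < 1e-8))

  # a 3-sd shift at n = 30 per group is detected almost always
  set.seed(21)
  hits <- vapply(1:60, function(i) {
    v <- c(stats::rnorm(30), stats::rnorm(30, 3))
    g <- rep(c("a", "b"), each = 30)
    anova_tukey(v, g)$tukey$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_warning(anova_tukey(c(1, 2, 3, 4, 5, 7, 9),
                             c("a", "a", "a", "b", "b", "b", "c")),
                 "excluding")
  expect_error(suppressWarnings(anova_tukey(c(1, 2), c("a", "b"))),
               "2 groups")
})

test_that("Fisher r-to-z interval: closed form, boundaries, width", {
  # closed-form null interval at n = 103: tanh(1.96/10); x symmetric
  # about its mean makes cor(x, (x - mean)^2) exactly zero
  x <- seq_len(103)
  r0 <- pearson_fisher_ci(x, (x - mean(x))^2)
  expect_lt(abs(r0$r), 1e-12)
  expect_equal(r0$ci95, c(-tanh(stats::qnorm(0.975) / 10),
                          tanh(stats::qnorm(0.975) / 10)),
               tolerance = 1e-6)
  expect_false(r0$significant)

  # perfect correlation keeps the upper bound at exactly 1
  p1 <- pearson_fisher_ci(1:10, 1:10 * 2)
  expect_equal(p1$r, 1)
  expect_equal(p1$ci95[2], 1)
  expect_true(p1$significant)

  # interval width strictly decreases with n at fixed r
  widths <- vapply(c(10, 30, 100, 500), function(n) {
    set.seed(5)
    x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n)
    # fix r by construction-free route: use the transform directly
    z <- atanh(0.5); q <- stats::qnorm(0.975) / sqrt(n - 3)
    tanh(z + q) - tanh(z - q)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(pearson_fisher_ci(rep(1, 10), 1:10), "zero variance")
})

test_that("Fisher interval coverage is near nominal under the null", {
  set.seed(31)
  n <- 200
  cover <- vapply(1:400, function(i) {
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    ci <- pearson_fisher_ci(x, y)$ci95
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("Bayes-factor comparison: pooled equals concatenation,
           direction reported", {
  set.seed(41)
  r1 <- mk_results(rep(1, 40), rep(c(1, 2), 20), breed = "b1",
                   bf = stats::rnorm(40, 10))
  r2 <- mk_results(rep(1, 40), rep(c(1, 2), 20), breed = "b2",
                   bf = stats::rnorm(40, 10))
  both <- rbind(r1, r2)
  cmp <- compare_bayes_factors(both)
  pooled <- cmp[cmp$stratum == "pooled", ]
  direct <- stats::anova(stats::aov(both$bayes_factor ~ both$correct))
  expect_equal(pooled$f, direct[["F value"]][1])

  # a +3 shift for correct calls is detected with positive direction
  shift <- mk_results(rep(1, 100), rep(c(1, 2), 50),
                      bf = stats::rnorm(100, 10))
  shift$bayes_factor[shift$correct] <- shift$bayes_factor[shift$correct] + 3
  cs <- compare_bayes_factors(shift)
  expect_equal(cs$direction[cs$stratum == "b1"], "positive")
})

test_that("report tables follow the stated conventions", {
  acc <- data.frame(breed = "b1", locus_id = paste0("L", 1:4),
                    flank_k = 10, called_state = 1,
                    n_called = 12, n_correct = c(0, 0, 1, 2),
                    accuracy = c(0, 0, 0.083, 0.167),
                    population_frequency = 30L, length_kb = 100,
                    mean_bayes_factor = 5)
  rep_ <- render_reports(acc)
  # frozen type-7 quartiles of {0, 0, 0.083, 0.167}
  expect_equal(rep_$by_state_breed$q1_accuracy, 0)
  expect_equal(rep_$by_state_breed$median_accuracy, 0.0415)
  expect_equal(rep_$by_state_breed$q3_accuracy, 0.104)
  # no locus reaches 85%: the listing is empty but valid
  expect_equal(nrow(rep_$high_accuracy), 0)
  # scatter files conserve the record count
  expect_equal(nrow(rep_$scatter_frequency), nrow(acc))
  expect_equal(nrow(rep_$scatter_length), nrow(acc))

  acc$accuracy[1] <- 0.9
  expect_equal(nrow(render_reports(acc)$high_accuracy), 1)
  expect_equal(render_reports(acc)$high_accuracy$accuracy_pct, 90)
})
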