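# Cohort statistics against independent sums-of-squares / nested-OLS
# oracles on toy data, plus cohort generation bookkeeping.

test_that("mixed ANOVA matches the sums-of-squares oracle to 1e-6", {
  rec <- toy_records()
  got <- mixed_anova(rec)
  want <- mixed_anova_oracle(rec)
  expect_equal(got$F[got$effect == "group"], want$F_group,
               tolerance = 1e-6)
  expect_equal(got$F[got$effect == "frequency"], want$F_freq,
               tolerance = 1e-6)
  expect_equal(got$F[got$effect == "group:frequency"], want$F_gf,
               tolerance = 1e-6)
  expect_true(all(got$p >= 0 & got$p <= 1))
  expect_lt(got$p[got$effect == "group:frequency"], 0.01)
})

test_that("identical groups yield a null group effect", {
  set.seed(21)
  base <- data.frame(subject = 1:6, group = "a", seed = 0,
                     p20 = 10 + rnorm(6, sd = 1e-6),
                     p30 = 12 + rnorm(6, sd = 1e-6),
                     p40 = 15 + rnorm(6, sd = 1e-6), ok = TRUE, error = "")
  twin <- base; twin$group <- "b"
  out <- mixed_anova(rbind(base, twin))
  expect_lt(out$F[out$effect == "group"], 1e-3)
  expect_gt(out$p[out$effect == "group"], 0.9)
})

test_that("Greenhouse-Geisser epsilon is near 1 under compound symmetry", {
  set.seed(5)
  n <- 200
  subj <- rnorm(n, sd = 2) # shared subject effect => equal covariances
  rec <- data.frame(subject = 1:n, group = rep(c("a", "b"), each = n / 2),
                    seed = 0,
                    p20 = subj + rnorm(n), p30 = subj + rnorm(n),
                    p40 = subj + rnorm(n), ok = TRUE, error = "")
  out <- mixed_anova(rec)
  eps <- out$epsilon[out$effect == "frequency"]
  expect_gte(eps, 0.9)
  expect_lte(eps, 1.0)
  # epsilon is bounded below by 1/(k-1)
  expect_gt(eps, 0.5)
})

test_that("mixed ANOVA rejects unbalanced or missing data", {
  rec <- toy_records()
  rec$p30[3] <- NA
  expect_error(mixed_anova(rec), "missing|unbalanced")
  expect_error(mixed_anova(toy_records()[1:5, ]), "two groups")
})

test_that("hierarchical regression matches a normal-equations oracle", {
  set.seed(13)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), grp = rep(0:1, each = n / 2))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + 0.8 * d$grp + rnorm(n)
  got <- hierarchical_regression(d, "y", c("x1", "x2"), "grp")
  r2 <- function(Xc) {
    X <- cbind(1, as.matrix(Xc))
    b <- solve(t(X) %*% X, t(X) %*% d$y)
    fit <- X %*% b
    1 - sum((d$y - fit)^2) / sum((d$y - mean(d$y))^2)
  }
  r2a <- r2(d[, c("x1", "x2")]); r2b <- r2(d[, c("x1", "x2", "grp")])
  expect_equal(got$delta_r2, r2b - r2a, tolerance = 1e-6)
  dF <- (r2b - r2a) / 1 / ((1 - r2b) / (n - 4))
  expect_equal(got$delta_F, dF, tolerance = 1e-6)
})

test_that("redundant and null second-step predictors behave as expected", {
  set.seed(14)
  d <- data.frame(x1 = rnorm(30))
  d$dup <- d$x1
  d$y <- 2 * d$x1 + rnorm(30)
  expect_error(hierarchical_regression(d, "y", "x1", "dup"), "singular")
  set.seed(15)
  big <- data.frame(x1 = rnorm(500), z = rnorm(500))
  big$y <- big$x1 + rnorm(500)
  out <- hierarchical_regression(big, "y", "x1", "z")
  expect_lt(out$delta_r2, 0.01)
  expect_gt(out$p, 0.05)
})

test_that("factorial ANOVA recovers a planted single-factor effect", {
  g <- drug_grid(ampa_gmax = c(0, 40, 80), alpha2 = c(0, 30),
                 nmda = c(0, 40, 80), ampa_tau2 = c(1, 3),
                 cr_weight = c(0, 40))
  set.seed(16)
  g$score <- 0.5 + 0.004 * g$nmda + rnorm(nrow(g), sd = 0.02)
  out <- factorial_anova(g, drop_zero = FALSE)
  sig <- out$term[!is.na(out$p) & out$p < 0.001]
  expect_true("nmda" %in% sig)
  expect_false("ampa_gmax" %in% sig)
  expect_false("alpha2:cr_weight" %in% sig)
})

test_that("factorial term SS match sequential projections on balanced designs", {
  g <- drug_grid(ampa_gmax = c(0, 40), alpha2 = c(0, 30), nmda = c(0, 40),
                 ampa_tau2 = c(1, 3), cr_weight = c(0, 40))
  set.seed(17)
  g$score <- runif(nrow(g), 0.1, 1)
  out <- factorial_anova(g, drop_zero = FALSE)
  seq_tab <- anova(lm(score ~ (ampa_gmax + alpha2 + nmda + ampa_tau2 +
                                 cr_weight)^3, data = g))
  for (term in c("nmda", "ampa_gmax:nmda", "alpha2:nmda:cr_weight")) {
    expect_equal(out$sum_sq[out$term == term],
                 seq_tab[term, "Sum Sq"], tolerance = 1e-6)
  }
})

test_that("factorial type-II SS match a nested-RSS oracle off balance", {
  g <- drug_grid(ampa_gmax = c(0, 40, 80), alpha2 = c(0, 30),
                 nmda = c(0, 40), ampa_tau2 = c(1, 3), cr_weight = c(0, 40))
  set.seed(18)
  g$score <- runif(nrow(g), 0, 1)
  g <- g[-(1:7), ] # break the balance
  out <- factorial_anova(g, drop_zero = FALSE, max_order = 2)
  # type II for a main effect: all terms not containing it, with vs without
  others <- c("alpha2", "nmda", "ampa_tau2", "cr_weight")
  two_way <- combn(others, 2, paste, collapse = ":")
  rhs0 <- paste(c(others, two_way), collapse = " + ")
  rss <- function(f) sum(resid(lm(stats::as.formula(f), data = g))^2)
  ss_want <- rss(paste("score ~", rhs0)) -
    rss(paste("score ~ ampa_gmax +", rhs0))
  expect_equal(out$sum_sq[out$term == "ampa_gmax"], ss_want,
               tolerance = 1e-6)
})

test_that("the factorial table has the published term structure", {
  g <- drug_grid(ampa_gmax = c(0, 40), alpha2 = c(0, 30), nmda = c(0, 40),
                 ampa_tau2 = c(1, 3), cr_weight = c(0, 40))
  set.seed(19)
  g$score <- runif(nrow(g))
  out <- factorial_anova(g, drop_zero = FALSE)
  expect_equal(sum(out$order == 1), 5)
  expect_equal(sum(out$order == 2), 10)
  expect_equal(sum(out$order == 3), 10)
  expect_equal(nrow(out), 25)
  expect_error(factorial_anova(transform(g, score = 0)), "non-zero")
})

test_that("cohorts are reproducible with distinct per-subject realizations", {
  args <- list(n = 3, group = "control", master_seed = 5, pop = tiny_pop(),
               drive_args = short_args())
  a <- do.call(generate_cohort, args)
  b <- do.call(generate_cohort, args)
  expect_identical(a, b)
  expect_equal(nrow(a), 3)
  expect_true(all(a$ok))
  expect_equal(length(unique(a$seed)), 3)
  # different seeds -> different adjacency -> different powers
  expect_gt(length(unique(a$p40)), 1)
  one <- generate_cohort(1, "control", master_seed = 5, pop = tiny_pop(),
                         drive_args = short_args())
  expect_equal(nrow(one), 1)
})
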