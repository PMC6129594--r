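fake_meta <- function(n_bd, n_nc, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", seq_len(n_bd + n_nc)),
             group = rep(c("BD", "NC"), c(n_bd, n_nc)),
             age = sample(21:50, n_bd + n_nc, replace = TRUE),
             gender = sample(c("M", "F"), n_bd + n_nc, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("design coding: centered age, effect-coded gender and group", {
  meta <- fake_meta(4, 4)
  d <- build_design(meta)
  expect_equal(mean(d$agec), 0)
  expect_setequal(unique(d$gend), c(0.5, -0.5))
  expect_equal(d$axg, d$agec * d$gend)
  expect_equal(d$grp, ifelse(meta$group == "BD", 0.5, -0.5))
})

test_that("t-test wrappers match closed forms and reject degenerate input", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$value, 2 * sqrt(3), tolerance = 1e-9)  # 2 / (1/sqrt(3))
  expect_equal(r$df1, 2)
  expect_equal(one_sample_t(c(-2, -1, 0, 1, 2))$value, 0)
  expect_error(one_sample_t(5), "at least 2")
  expect_error(one_sample_t(c(2, 2, 2)), "zero variance")

  r2 <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$value, -sqrt(3 / 2), tolerance = 1e-9)  # pooled SD = 1
  expect_equal(r2$df1, 4)                                 # n1 + n2 - 2
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$value, 0)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")

  r3 <- paired_t(c(2, 3, 5), c(1, 1, 2))
  expect_equal(r3$value, one_sample_t(c(1, 2, 3))$value)
  expect_error(paired_t(c(2, 3), c(1, 2)), "zero variance")
})

test_that("pooled two-sample df matches the classical convention at 49 + 61", {
  set.seed(2)
  r <- two_sample_t(rnorm(49), rnorm(61))
  expect_equal(r$df1, 108)
})

test_that("GLM decomposition: degenerate and algebraic properties", {
  meta <- fake_meta(10, 12)
  d <- build_design(meta)
  set.seed(3)
  L <- runif(22, 0.3, 0.5)
  # R identical to L: hemisphere and interaction vanish
  res <- glm_group_by_hemisphere(data.frame(x_left = L, x_right = L), d)
  expect_equal(res$value[res$effect == "hemisphere"], 0)
  expect_equal(res$p[res$effect == "hemisphere"], 1)
  expect_equal(res$value[res$effect == "group_x_hemisphere"], 0)
  # F equals squared t from the equivalent difference regression
  R <- L + rnorm(22, 0.01, 0.02)
  res2 <- glm_group_by_hemisphere(data.frame(x_left = L, x_right = R), d)
  fit <- lm(I(R - L) ~ grp + agec + gend + axg, data = d)
  tv <- summary(fit)$coefficients["grp", "t value"]
  expect_equal(res2$value[res2$effect == "group_x_hemisphere"], tv^2,
               tolerance = 1e-9)
  expect_true(all(res2$value >= 0))
  expect_equal(res2$df1, rep(1, 3))
})

test_that("covariate-free GLM reproduces classical repeated-measures ANOVA", {
  meta <- fake_meta(9, 9, seed = 5)
  d <- build_design(meta)
  set.seed(6)
  L <- runif(18); R <- L + rnorm(18, 0.05, 0.1)
  mine <- glm_group_by_hemisphere(data.frame(x_left = L, x_right = R), d,
                                  covariates = character(0))
  long <- data.frame(y = c(L, R),
                     hemi = rep(c("L", "R"), each = 18),
                     group = rep(meta$group, 2),
                     id = rep(meta$subject_id, 2))
  av <- summary(aov(y ~ group * hemi + Error(id / hemi), data = long))
  f_between <- av[["Error: id"]][[1]]["group", "F value"]
  f_within <- av[["Error: id:hemi"]][[1]][c("hemi", "group:hemi"), "F value"]
  expect_equal(mine$value[mine$effect == "group"], f_between,
               tolerance = 1e-9)
  expect_equal(mine$value[mine$effect == "hemisphere"], f_within[1],
               tolerance = 1e-9)
  expect_equal(mine$value[mine$effect == "group_x_hemisphere"], f_within[2],
               tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with the offending column", {
  meta <- fake_meta(6, 6)
  d <- build_design(meta)
  d$dup <- d$agec
  expect_error(glm_group_by_hemisphere(
    data.frame(x_left = runif(12), x_right = runif(12)), d,
    covariates = c("agec", "gend", "axg", "dup")), "dup")
})

test_that("ANCOVA without covariates equals the squared pooled t", {
  meta <- fake_meta(10, 15, seed = 7)
  d <- build_design(meta)
  set.seed(8)
  as_v <- rnorm(25) + ifelse(meta$group == "BD", 0.4, 0)
  a <- ancova_on_as(as_v, d, covariates = character(0))
  t2 <- two_sample_t(as_v[meta$group == "BD"], as_v[meta$group == "NC"])
  expect_equal(a$value, t2$value^2, tolerance = 1e-9)
  expect_equal(a$p, t2$p, tolerance = 1e-9)
  # groups with identical AS and covariate patterns: group F vanishes
  twin <- data.frame(subject_id = sprintf("t%02d", 1:20),
                     group = rep(c("BD", "NC"), each = 10),
                     age = rep(31:40, 2),
                     gender = rep(rep(c("M", "F"), 5), 2))
  as_twin <- rep(rnorm(10), 2)
  a0 <- ancova_on_as(as_twin, build_design(twin))
  expect_lt(a0$value, 1e-12)
})

test_that("ANCOVA type-I error is calibrated under label permutation", {
  meta <- fake_meta(25, 30, seed = 9)
  set.seed(10)
  as_v <- rnorm(55)
  rej <- vapply(1:1000, function(i) {
    m2 <- meta
    m2$group <- sample(m2$group)
    ancova_on_as(as_v, build_design(m2))$p < 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 1000)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("Bonferroni arithmetic and monotonicity", {
  b <- bonferroni(0.01, m = 45)
  expect_false(b$significant)
  expect_equal(b$threshold, 0.05 / 45, tolerance = 1e-12)
  expect_true(bonferroni(0.0005, m = 45)$significant)
  expect_equal(bonferroni(0.03, m = 1)$significant, TRUE)
  expect_equal(bonferroni(0.03, m = 1)$p_adjusted, 0.03)
  set.seed(11)
  p <- runif(45)
  s1 <- bonferroni(p, alpha = 0.05, m = 45)$significant
  s2 <- bonferroni(p, alpha = 0.01, m = 45)$significant
  expect_true(all(which(s2) %in% which(s1)))
  expect_true(all(bonferroni(p)$p_adjusted <= 1))
})

test_that("partial correlation reduces to plain correlation and kills
           covariate-driven association", {
  set.seed(12)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r <- partial_correlation(x, y)
  expect_equal(r$value, cor(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(r$p, ct$p.value, tolerance = 1e-9)
  rs <- partial_correlation(x, y, method = "spearman")
  expect_equal(rs$value, cor(x, y, method = "spearman"), tolerance = 1e-12)
  # constant input has nothing left to correlate
  expect_error(partial_correlation(rep(1, 40), y), "constant")
  # y driven almost entirely by the covariates: partial r collapses
  z <- data.frame(z1 = rnorm(40), z2 = rnorm(40))
  y3 <- 2 * z$z1 - z$z2 + rnorm(40, 0, 1e-3)
  expect_lt(abs(partial_correlation(x, y3, z)$value), 0.35)
  expect_equal(partial_correlation(x, y, z)$df1, 40 - 2 - 2)
  expect_error(partial_correlation(x[1:4], y[1:4], z[1:4, ]), "too few")
})

test_that("chi-squared utility matches the base test without correction", {
  tab <- matrix(c(28, 21, 32, 29), 2)
  mine <- chisq_2x2(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(mine$value, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("run_statistics emits the full report for all seven global properties", {
  spec <- tiny_spec(n_patients = 8, n_controls = 8)
  co <- generate_cohort(spec)
  set.seed(13)
  m <- cohort_metrics(co$connectomes, co$parcellation, n_nulls = 10)
  a <- cohort_asymmetry(m)
  st <- run_statistics(m, a, co$metadata)
  expect_named(st, c("glm_global", "glm_nodal", "as_tests", "posthoc",
                     "correlations"))
  # all seven global properties present in AS tests
  expect_setequal(unique(st$as_tests$metric[is.na(st$as_tests$region)]),
                  c("Eg", "Eloc", "Cp", "Lp", "gamma", "lambda", "sigma"))
  expect_equal(sum(st$glm_global$effect == "group_x_hemisphere"), 7)
  expect_equal(unique(st$glm_nodal$family_size), 10)
  expect_true(all(st$glm_nodal$correction_method == "bonferroni"))
  expect_true(all(st$correlations$group == "BD"))
  expect_setequal(unique(st$correlations$method), c("pearson", "spearman"))
  expect_true(all(st$correlations$score %in% c("ymrs", "hamd")))
  # determinism for fixed inputs
  st2 <- run_statistics(m, a, co$metadata)
  expect_identical(st, st2)
})
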