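#' Group and hemisphere statistics
#'
#' The statistical battery for a two-group, two-hemisphere design:
#' a general linear model with hemisphere as a within-subject factor,
#' group as a between-subject factor and a group-by-hemisphere
#' interaction, with age, gender and age-by-gender as covariates; post hoc
#' pooled two-sample and paired t-tests; one-sample t-tests and a
#' univariate ANCOVA on asymmetry scores; Bonferroni correction for
#' regional families; and partial Pearson/Spearman correlations between
#' regional asymmetry and clinical scores.
#'
#' The two-level within-subject factor is solved by the exact
#' sum/difference decomposition: the group main effect is the regression
#' of the subject mean `(L + R)/2` on group plus covariates; the
#' hemisphere main effect and the interaction are the intercept and group
#' coefficient of the regression of the difference `R - L` on group plus
#' covariates. With age mean-centered and gender effect-coded, the
#' difference-model intercept is the covariate-adjusted hemisphere effect.
#' Each reported F equals the square of the corresponding regression t.
#'
#' @name group_stats
NULL

empty_stat_table <- function()
  stat_result("x", "t", 0, 0, NA_real_, 1)[0, ]

stat_result <- function(effect, statistic_type, value, df1, df2 = NA_real_,
                        p, metric = NA_character_, region = NA_character_,
                        group = NA_character_, n = NA_integer_,
                        corrected = FALSE, method = NA_character_,
                        family_size = NA_integer_) {
  data.frame(effect = effect, statistic_type = statistic_type,
             value = value, df1 = df1, df2 = df2, p = p, metric = metric,
             region = region, group = group, n = n, corrected = corrected,
             correction_method = method, family_size = family_size,
             stringsAsFactors = FALSE)
}

#' Build the covariate design from a metadata table
#'
#' Age is mean-centered; gender is effect-coded (`M = +1/2`,
#' `F = -1/2`); the age-by-gender product is formed after centering;
#' group is effect-coded (`BD = +1/2`, `NC = -1/2`).
#'
#' @param metadata data.frame with columns `group`, `age`, `gender`
#' @return data.frame with columns `grp`, `agec`, `gend`, `axg`
#' @export
build_design <- function(metadata) {
  stopifnot(all(c("group", "age", "gender") %in% names(metadata)),
            !anyNA(metadata$age), !anyNA(metadata$gender))
  agec <- metadata$age - mean(metadata$age)
  gend <- ifelse(metadata$gender == "M", 0.5, -0.5)
  data.frame(grp = ifelse(metadata$group == "BD", 0.5, -0.5),
             agec = agec, gend = gend, axg = agec * gend)
}

fit_term_f <- function(y, X, term) {
  keep <- stats::complete.cases(y, X)
  dat <- data.frame(.y = y[keep], X[keep, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  tval <- sm[term, "t value"]
  pval <- sm[term, "Pr(>|t|)"]
  if (!is.finite(tval)) {   # degenerate zero-residual fit
    est <- cf[term]
    tval <- if (abs(est) < 1e-12) 0 else sign(est) * Inf
    pval <- if (tval == 0) 1 else 0
  }
  list(t = unname(tval), F = unname(tval^2), df2 = fit$df.residual,
       p = unname(pval), n = sum(keep))
}

#' Repeated-measures GLM for one metric
#'
#' Tests the group main effect, hemisphere main effect and
#' group-by-hemisphere interaction for a paired (L, R) metric with
#' age/gender/age-by-gender covariates, via the sum/difference
#' decomposition described in [group_stats].
#'
#' @param values data.frame with columns `x_left`, `x_right`
#' @param design from [build_design()], same row order
#' @param metric metric label carried into the result
#' @param region optional region label
#' @param covariates design columns to adjust for (default age, gender
#'   and their product; pass `character(0)` for the unadjusted model)
#' @return data.frame of three `StatResult` rows (effects `group`,
#'   `hemisphere`, `group_x_hemisphere`), F statistics with `(1, df2)`
#' @export
glm_group_by_hemisphere <- function(values, design, metric = NA_character_,
                                    region = NA_character_,
                                    covariates = c("agec", "gend", "axg")) {
  stopifnot(nrow(values) == nrow(design),
            all(c("x_left", "x_right") %in% names(values)))
  m <- (values$x_left + values$x_right) / 2
  d <- values$x_right - values$x_left
  cols <- c("grp", covariates)
  grp_fit <- fit_term_f(m, design[cols], "grp")
  hem_fit <- fit_term_f(d, design[cols], "(Intercept)")
  int_fit <- fit_term_f(d, design[cols], "grp")
  rbind(
    stat_result("group", "F", grp_fit$F, 1, grp_fit$df2, grp_fit$p,
                metric, region, n = grp_fit$n),
    stat_result("hemisphere", "F", hem_fit$F, 1, hem_fit$df2, hem_fit$p,
                metric, region, n = hem_fit$n),
    stat_result("group_x_hemisphere", "F", int_fit$F, 1, int_fit$df2,
                int_fit$p, metric, region, n = int_fit$n))
}

#' One-sample t-test
#'
#' @param values numeric vector (`NA`s dropped)
#' @param mu0 null mean, default 0
#' @param ... labels (`metric`, `region`, `group`) carried into the result
#' @return one `StatResult` row with `t`, `df = n - 1`, two-sided `p`
#' @export
one_sample_t <- function(values, mu0 = 0, ...) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("one-sample t-test needs at least 2 observations")
  if (stats::sd(x) == 0) stop("one-sample t-test: zero variance")
  tt <- stats::t.test(x, mu = mu0)
  stat_result("AS_vs_zero", "t", unname(tt$statistic),
              unname(tt$parameter), NA_real_, tt$p.value,
              n = length(x), ...)
}

#' Pooled-variance two-sample t-test
#'
#' Student form with `df = n1 + n2 - 2` (not Welch), matching the
#' degrees-of-freedom convention of classical group comparisons.
#'
#' @param a,b numeric vectors (`NA`s dropped)
#' @param effect label for the result row
#' @param ... labels carried into the result
#' @return one `StatResult` row
#' @export
two_sample_t <- function(a, b, effect = "AS_group_diff", ...) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("two-sample t-test needs at least 2 observations per group")
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    stop("two-sample t-test: zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  stat_result(effect, "t", unname(tt$statistic), unname(tt$parameter),
              NA_real_, tt$p.value, n = length(a) + length(b), ...)
}

#' Paired t-test
#'
#' Equivalent to a one-sample t-test on the paired differences `x - y`.
#'
#' @param x,y paired numeric vectors
#' @param effect label for the result row
#' @param ... labels carried into the result
#' @return one `StatResult` row
#' @export
paired_t <- function(x, y, effect = "hemisphere_paired", ...) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("paired t-test needs at least 2 complete pairs")
  if (stats::sd(d) == 0) stop("paired t-test: zero variance of differences")
  tt <- stats::t.test(d, mu = 0)
  out <- stat_result(effect, "t", unname(tt$statistic),
                     unname(tt$parameter), NA_real_, tt$p.value,
                     n = length(d), ...)
  out
}

#' Univariate ANCOVA on asymmetry scores
#'
#' F-test for the group effect on AS after adjusting for age, gender and
#' age-by-gender. With no covariates this reduces exactly to the square
#' of the pooled two-sample t.
#'
#' @param as_values numeric AS vector
#' @param design from [build_design()] (column `grp` plus any covariates)
#' @param covariates character vector of design columns to adjust for
#' @param ... labels carried into the result
#' @return one `StatResult` row with `F`, `(1, df2)` df
#' @export
ancova_on_as <- function(as_values, design,
                         covariates = c("agec", "gend", "axg"), ...) {
  fit <- fit_term_f(as_values, design[c("grp", covariates)], "grp")
  stat_result("AS_group_diff", "F", fit$F, 1, fit$df2, fit$p,
              n = fit$n, ...)
}

#' Bonferroni correction
#'
#' Significance at family-wise level `alpha` requires `p < alpha / m`;
#' the adjusted p-values `min(1, m p)` are reported alongside.
#'
#' @param p_values vector of raw p-values in `[0, 1]`
#' @param alpha family-wise error level, default 0.05
#' @param m family size, default `length(p_values)`
#' @return list with `significant` (logical), `threshold`, `p_adjusted`,
#'   `m`
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  list(significant = !is.na(p_values) & p_values < alpha / m,
       threshold = alpha / m,
       p_adjusted = pmin(1, p_values * m), m = m)
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on the covariates (rank-transforming both
#' variables and covariates first for Spearman) and correlates the
#' residuals; `df = n - 2 - n_covariates`. Incomplete rows are dropped
#' pairwise.
#'
#' @param x,y numeric vectors
#' @param covariates data.frame of covariates, or `NULL` for a plain
#'   correlation
#' @param method `"pearson"` or `"spearman"`
#' @param ... labels carried into the result
#' @return one `StatResult` row with `r`, its df and two-sided `p`
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(x))
  keep <- if (ncol(covariates) > 0) stats::complete.cases(x, y, covariates)
          else stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  Z <- covariates[keep, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n <= k + 2) stop("too few complete observations for partial correlation")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    Z[] <- lapply(Z, rank)
  }
  resid_on <- function(v) {
    if (k == 0) return(v - mean(v))
    stats::lm.fit(cbind(1, as.matrix(Z)), v)$residuals
  }
  rx <- resid_on(x); ry <- resid_on(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant variable after residualization")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  cbind(stat_result("correlation", "r", r, df, NA_real_,
                    2 * stats::pt(-abs(tval), df), n = n, ...),
        method = method)
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Convenience wrapper (no continuity correction) for demographic
#' comparisons such as gender by group.
#'
#' @param tab 2x2 contingency table or matrix of counts
#' @return one `StatResult` row
#' @export
chisq_2x2 <- function(tab) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("chi_squared", "F", unname(ct$statistic),
              unname(ct$parameter), NA_real_, ct$p.value,
              n = sum(tab))
}

#' Run the full statistical battery
#'
#' Produces the report tables for a cohort: per-metric and per-region
#' repeated-measures GLMs, one-sample and ANCOVA tests on asymmetry
#' scores, conditional post hoc t-tests, and patient-only partial
#' correlations between regional asymmetry and clinical scores. Global
#' metrics are tested at `alpha`; regional (nodal-efficiency) families
#' are Bonferroni-corrected over the number of regions.
#'
#' @param metrics long metric table from [cohort_metrics()]
#' @param asymmetry AS table from [cohort_asymmetry()]
#' @param metadata cohort metadata (columns `subject_id`, `group`, `age`,
#'   `gender`, `ymrs`, `hamd`)
#' @param alpha significance level, default 0.05
#' @return list of data.frames: `glm_global`, `glm_nodal`, `as_tests`,
#'   `posthoc`, `correlations`
#' @export
run_statistics <- function(metrics, asymmetry, metadata, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  design_all <- build_design(metadata)
  rownames(design_all) <- metadata$subject_id

  wide <- function(keys) {
    sub <- asymmetry[asymmetry$metric %in% keys, , drop = FALSE]
    sub[match(metadata$subject_id, sub$subject_id), , drop = FALSE]
  }
  global_order <- c("Eg", "Eloc", "Cp", "Lp", "gamma", "lambda", "sigma")
  globals <- intersect(global_order, unique(asymmetry$metric))
  nodal_keys <- sort(unique(asymmetry$metric[startsWith(asymmetry$metric,
                                                        "Enodal:")]))
  n_regions <- length(nodal_keys)

  glm_for <- function(key, region = NA_character_) {
    w <- wide(key)
    keep <- !is.na(w$subject_id)
    glm_group_by_hemisphere(
      data.frame(x_left = w$x_left[keep], x_right = w$x_right[keep]),
      design_all[keep, , drop = FALSE],
      metric = sub(":.*", "", key), region = region)
  }
  glm_global <- do.call(rbind, lapply(globals, glm_for))
  glm_nodal <- do.call(rbind, lapply(nodal_keys, function(k)
    glm_for(k, region = sub("^Enodal:", "", k))))
  if (n_regions > 0) {
    for (eff in unique(glm_nodal$effect)) {
      i <- glm_nodal$effect == eff
      bc <- bonferroni(glm_nodal$p[i], alpha, n_regions)
      glm_nodal$corrected[i] <- TRUE
      glm_nodal$correction_method[i] <- "bonferroni"
      glm_nodal$family_size[i] <- n_regions
      glm_nodal$p_adjusted[i] <- bc$p_adjusted
      glm_nodal$significant[i] <- bc$significant
    }
  }

  as_tests_for <- function(key, region = NA_character_, m = 1) {
    w <- wide(key)
    as_v <- w$AS
    met <- sub(":.*", "", key)
    rows <- list()
    for (g in unique(metadata$group)) {
      v <- as_v[metadata$group == g]
      rows[[g]] <- tryCatch(
        one_sample_t(v, metric = met, region = region, group = g),
        error = function(e) NULL)
    }
    anc <- tryCatch(
      ancova_on_as(as_v, design_all, metric = met, region = region),
      error = function(e) NULL)
    out <- do.call(rbind, c(rows, list(anc)))
    if (!is.null(out)) {
      bc <- bonferroni(out$p, alpha, m)
      out$corrected <- m > 1
      out$correction_method <- if (m > 1) "bonferroni" else NA_character_
      out$family_size <- m
      out$p_adjusted <- bc$p_adjusted
      out$significant <- bc$significant
    }
    out
  }
  as_tests <- rbind(
    do.call(rbind, lapply(globals, as_tests_for)),
    do.call(rbind, lapply(nodal_keys, function(k)
      as_tests_for(k, region = sub("^Enodal:", "", k), m = n_regions))))

  posthoc <- posthoc_tests(glm_global, asymmetry, metadata, globals, alpha)

  correlations <- clinical_correlations(asymmetry, metadata, nodal_keys)

  list(glm_global = annotate_sig(glm_global, alpha),
       glm_nodal = glm_nodal, as_tests = as_tests, posthoc = posthoc,
       correlations = correlations)
}

annotate_sig <- function(df, alpha) {
  if (is.null(df) || nrow(df) == 0) return(df)
  if (!"p_adjusted" %in% names(df)) df$p_adjusted <- df$p
  if (!"significant" %in% names(df)) df$significant <- df$p < alpha
  df
}

# post hoc t-tests, run only for metrics whose omnibus effect is
# significant at alpha: two-sample t on subject means for group effects,
# paired t (R vs L, pooled and per group) for hemisphere/interaction.
posthoc_tests <- function(glm_global, asymmetry, metadata, globals, alpha) {
  rows <- list()
  for (met in globals) {
    sub <- asymmetry[asymmetry$metric == met, ]
    sub <- sub[match(metadata$subject_id, sub$subject_id), ]
    eff <- function(e)
      glm_global$p[glm_global$metric == met & glm_global$effect == e]
    if (length(eff("group")) && eff("group") < alpha) {
      m <- (sub$x_left + sub$x_right) / 2
      rows[[length(rows) + 1]] <- two_sample_t(
        m[metadata$group == "BD"], m[metadata$group == "NC"],
        effect = "group_posthoc", metric = met)
    }
    if (length(eff("hemisphere")) && eff("hemisphere") < alpha)
      rows[[length(rows) + 1]] <- paired_t(sub$x_right, sub$x_left,
                                           metric = met)
    if (length(eff("group_x_hemisphere")) &&
        eff("group_x_hemisphere") < alpha) {
      for (g in unique(metadata$group)) {
        i <- metadata$group == g
        rows[[length(rows) + 1]] <- tryCatch(
          paired_t(sub$x_right[i], sub$x_left[i], metric = met, group = g),
          error = function(e) NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_stat_table()
  out
}

# patient-only partial correlations of nodal AS with clinical scores,
# adjusted for age, gender and age-by-gender; uncorrected p-values.
clinical_correlations <- function(asymmetry, metadata, nodal_keys) {
  pat <- metadata[metadata$group == "BD", , drop = FALSE]
  rows <- list()
  if (nrow(pat) >= 8 && length(nodal_keys)) {
    dsn <- build_design(pat)[c("agec", "gend", "axg")]
    for (k in nodal_keys) {
      sub <- asymmetry[asymmetry$metric == k, ]
      as_v <- sub$AS[match(pat$subject_id, sub$subject_id)]
      for (score in c("ymrs", "hamd")) {
        if (all(is.na(pat[[score]]))) next
        for (meth in c("pearson", "spearman")) {
          rows[[length(rows) + 1]] <- tryCatch(
            cbind(partial_correlation(as_v, pat[[score]], dsn, meth,
                                      metric = "Enodal",
                                      region = sub("^Enodal:", "", k),
                                      group = "BD"),
                  score = score),
            error = function(e) NULL)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(empty_stat_table(), method = character(0),
                 score = character(0))
  out
}
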