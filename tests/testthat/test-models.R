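# Mixed logistic fit, crude ORs and report tables.

test_that("crude OR reproduces cross-products of printed count tables", {
  expect_equal(crude_or(10, 10, 10, 10)$or, 1)
  # SES Q4 vs Q1, whole study: cases 229 vs 152, controls 1135 vs 1135
  expect_equal(crude_or(229, 152, 1135, 1135)$or, 1.5066, tolerance = 5e-4)
  # industrial vs rural, whole study: cases 301 vs 88, controls 1837 vs 421
  expect_equal(crude_or(301, 88, 1837, 421)$or, 0.7839, tolerance = 5e-4)
  co <- crude_or(301, 88, 1837, 421)
  expect_lt(co$ci_lo, co$or); expect_gt(co$ci_hi, co$or)
  expect_error(crude_or(0, 5, 5, 5), "zero cell")
  h <- crude_or(0, 5, 5, 5, haldane = TRUE)
  expect_true(is.finite(h$or) && h$or > 0)
  expect_error(crude_or(-1, 5, 5, 5), "non-negative")
})

test_that("single-region data reduces to plain logistic regression", {
  d <- fake_analysis_data(n = 900, n_regions = 1, seed = 7, beta_gci10 = 0.15)
  fit <- fit_mixed_logistic(d)
  expect_equal(fit$method, "glm")
  ref <- glm(I(status == "case") ~ factor(env, levels = c("rural", "industrial",
               "intersection", "urban", "ring")) +
               factor(ses_q) + I(gci / 10) + factor(sex, levels = c("F", "M")) +
               I(birth_year - mean(birth_year)),
             family = binomial(), data = d)
  expect_equal(unname(sort(abs(coef(fit)))), unname(sort(abs(coef(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$sigma_region, 0)
})

test_that("null 2x2-style data gives an exposure CI covering 1", {
  d <- fake_analysis_data(n = 1500, n_regions = 3, seed = 11, beta_gci10 = 0)
  fit <- fit_mixed_logistic(d)
  tt <- fit$terms
  g <- tt[tt$variable == "gci", ]
  expect_lte(g$ci_lo, 1)
  expect_gte(g$ci_hi, 1)
})

test_that("a simulated crop effect is recovered by the fit", {
  d <- fake_analysis_data(n = 4000, n_regions = 3, seed = 13,
                          beta_gci10 = log(1.5), p0 = 0.15)
  fit <- fit_mixed_logistic(d)
  tt <- fit$terms
  g <- tt[tt$variable == "gci", ]
  expect_lt(abs(g$estimate - log(1.5)), 2.5 * g$se)
  expect_lt(g$ci_lo, g$or); expect_gt(g$ci_hi, g$or)
})

test_that("fit falls back to fixed-effects regions on boundary variance", {
  # regions generated with identical baselines: sigma-hat ~ 0 -> fallback
  d <- fake_analysis_data(n = 2000, n_regions = 4, seed = 17)
  fit <- fit_mixed_logistic(d)
  expect_true(fit$method %in% c("glmer", "glm_region_fixed"))
  if (fit$method == "glm_region_fixed")
    expect_true(any(grepl("singular|boundary", fit$notes)) ||
                length(fit$notes) > 0)
  # forcing the fixed-effects route works too
  fit2 <- fit_mixed_logistic(d, random_region = FALSE)
  expect_equal(fit2$method, "glm_region_fixed")
  expect_true("region" %in% fit2$terms$variable)
})

test_that("reference levels are omitted from terms and reported as OR 1", {
  d <- fake_analysis_data(n = 1200, n_regions = 2, seed = 23)
  fit <- fit_mixed_logistic(d)
  expect_false(any(fit$terms$variable == "env" & fit$terms$level == "rural"))
  expect_false(any(fit$terms$variable == "ses_q" & fit$terms$level == "Q1"))
  tab <- or_table(fit)
  expect_equal(tab$or[tab$variable == "env" & tab$level == "rural"], 1)
  expect_equal(tab$or[tab$variable == "ses_q" & tab$level == "Q1"], 1)
})

test_that("or_table percentages normalize and count positive exposure", {
  d <- fake_analysis_data(n = 1500, n_regions = 3, seed = 29)
  fit <- fit_mixed_logistic(d)
  tab <- or_table(list(total = fit))
  env <- tab[tab$variable == "env", ]
  expect_equal(sum(env$pct_controls), 100, tolerance = 1e-9)
  expect_equal(sum(env$pct_cases), 100, tolerance = 1e-9)
  gz <- tab[tab$variable == "gci", ]
  expect_equal(gz$n_cases + gz$n_controls, sum(d$gci > 0))
  # zero-crop data: the >0 counter is 0
  d0 <- d; d0$gci <- 0
  expect_equal(fit_mixed_logistic(d0, crop_only = TRUE)$counts$n_cases[1] +
               fit_mixed_logistic(d0, crop_only = TRUE)$counts$n_controls[1], 0)
})

test_that("crop-only models substitute the exposure column", {
  d <- fake_analysis_data(n = 1200, n_regions = 3, seed = 31)
  d$irrigated <- d$gci * 0.6
  fit <- fit_mixed_logistic(d, exposure = "irrigated")
  expect_equal(fit$exposure, "irrigated")
  expect_true(any(fit$terms$variable == "irrigated"))
  fit2 <- fit_mixed_logistic(d, exposure = "irrigated", crop_only = TRUE)
  expect_false(any(grepl("env|ses_q", fit2$terms$variable)))
})

test_that("ccfit methods expose coefficients and Wald intervals", {
  d <- fake_analysis_data(n = 1000, n_regions = 2, seed = 37)
  fit <- fit_mixed_logistic(d)
  expect_named(coef(fit), fit$terms$term)
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] <= coef(fit) & coef(fit) <= ci[, "upper"]))
  expect_output(print(fit), "OR")
  expect_output(print(summary(fit)), "Category counts")
})

test_that("rows with missing covariates are dropped and counted", {
  d <- fake_analysis_data(n = 1000, n_regions = 2, seed = 41)
  d$gci[1:25] <- NA
  fit <- fit_mixed_logistic(d)
  expect_equal(fit$dropped, 25)
  expect_equal(fit$n_cases + fit$n_controls, 975)
})
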