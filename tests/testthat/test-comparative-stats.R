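test_that("kruskal_conover reproduces the hand-computed H and degenerate cases", {
  kc <- kruskal_conover(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kc$H, 27 / 7, tolerance = 1e-10)
  expect_equal(kc$df, 1)

  same <- kruskal_conover(c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                          rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0, tolerance = 1e-10)
  expect_true(all(same$pairwise$P > 0.99))
  expect_error(kruskal_conover(rep(1, 6), rep(c("a", "b"), each = 3)),
               "identical")
})

test_that("Conover statistics match the brute-force rank oracle", {
  set.seed(17)
  for (i in 1:15) {
    g <- rep(c("a", "b", "c"), times = sample(3:7, 3, replace = TRUE))
    v <- round(rnorm(length(g)), 1)  # ties on purpose
    if (length(unique(v)) < 2) next
    kc <- kruskal_conover(v, g)
    expect_equal(kc$pairwise$t, unname(conover_oracle(v, g)),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(18)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  h0 <- kruskal_conover(v, g)$H
  expect_equal(kruskal_conover(exp(v), g)$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_conover(v^3, g)$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_conover(rank(v), g)$H, h0, tolerance = 1e-12)
})

test_that("type-III Wald chi-square reduces to z^2 for a 1-df term", {
  d <- sim_analysis_table(seed = 2)
  m <- suppressMessages(suppressWarnings(
    fit_thermal_lmm(d, "endothermy", log_transform = TRUE)))
  a <- anova_type3(m)
  sm <- summary(m$fit)$coefficients
  z_act <- sm[grep("^activity", rownames(sm)), "t value"]
  expect_equal(a$Chisq[a$term == "activity"], unname(z_act^2),
               tolerance = 1e-8)
  z_mass <- sm["mass", "t value"]
  expect_equal(a$Chisq[a$term == "mass"], unname(z_mass^2), tolerance = 1e-8)
  expect_setequal(a$term, c("habitat", "activity", "mass",
                            "habitat:activity"))
})

test_that("with zero species variance the mixed fit equals ordinary least squares", {
  # response carries no species effect, so the variance estimate hits the
  # boundary; condition on that singular fit and compare against lm()
  found <- FALSE
  for (seed in 1:10) {
    d <- sim_analysis_table(species_sd = 0, seed = seed)
    m <- suppressMessages(suppressWarnings(fit_thermal_lmm(d, "endothermy",
                                          log_transform = TRUE)))
    if (!m$singular) next
    found <- TRUE
    ols <- lm(.y ~ habitat * activity + mass, data = m$data)
    expect_equal(unname(lme4::fixef(m$fit)), unname(coef(ols)),
                 tolerance = 1e-6)
    break
  }
  expect_true(found)
})

test_that("a planted activity-by-habitat interaction is detected", {
  # diurnal open-pasture cell shifted down on the log scale
  cells <- expand.grid(h = 1:3, a = 1:2)
  eff <- ifelse(cells$h == 3 & cells$a == 1, -1.5, 0)
  hits <- 0
  for (r in 1:20) {
    d <- sim_analysis_table(species_sd = 0.2, cell_effects = eff,
                            seed = 100 + r)
    m <- suppressMessages(suppressWarnings(fit_thermal_lmm(d, "endothermy",
                                          log_transform = TRUE)))
    a <- anova_type3(m)
    hits <- hits + (a$P[a$term == "habitat:activity"] < 0.05)
  }
  expect_gte(hits / 20, 0.8)
})

test_that("Tukey contrasts: k = 2 equals the unadjusted z test, estimates mirror", {
  d <- sim_analysis_table(seed = 3)
  m <- suppressMessages(suppressWarnings(fit_thermal_lmm(d, "endothermy", log_transform = TRUE)))
  ct <- tukey_contrasts(m, within = "habitat")  # activity pairs: k = 2
  expect_equal(nrow(ct), 3)  # one diurnal-ENC contrast per habitat
  expect_equal(ct$P, 2 * pnorm(abs(ct$t), lower.tail = FALSE),
               tolerance = 1e-8)
  ct2 <- tukey_contrasts(m, within = "activity")  # habitat pairs: k = 3
  expect_equal(nrow(ct2), 6)
  # Tukey adjustment never reduces a p-value below the unadjusted one
  expect_true(all(ct2$P >= 2 * pnorm(abs(ct2$t), lower.tail = FALSE) - 1e-10))
})

test_that("log transform drops non-positive responses with a message", {
  d <- sim_analysis_table(seed = 4)
  d$endothermy[1] <- -0.5
  expect_message(m <- suppressWarnings(
    fit_thermal_lmm(d, "endothermy", log_transform = TRUE)), "non-positive")
  expect_equal(m$n_dropped, 1L)
})

test_that("pearson correlations behave at their fixed points", {
  d <- data.frame(slope_th = rnorm(30))
  d$slope_abd <- d$slope_th
  d$slope_diff <- -d$slope_th
  r <- correlate_physiology(d)
  expect_equal(r$r[r$var_1 == "slope_th" & r$var_2 == "slope_abd"], 1)
  expect_equal(r$r[r$var_1 == "slope_th" & r$var_2 == "slope_diff"], -1)
  expect_error(correlate_physiology(data.frame(slope_th = 1:2,
                                               slope_abd = 2:3,
                                               slope_diff = 0:1)),
               "at least 3")
})

test_that("simulated bivariate-normal correlation lands near its target", {
  set.seed(19)
  n <- 400; rho <- 0.59
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  d <- data.frame(slope_th = x, slope_abd = y)
  r <- correlate_physiology(d, pairs = list(c("slope_th", "slope_abd")))$r
  z <- atanh(r) - atanh(rho)
  expect_lt(abs(z), 4 / sqrt(n - 3))
})
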