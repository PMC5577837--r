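test_that("Poisson fits recover generative coefficients with an offset", {
  set.seed(30)
  beta <- c("(Intercept)" = -6.5, depth_std = -0.4, disp_std = 0.3)
  cover <- replicate(40, {
    d <- simulate_density_data(300, beta)
    fit <- fit_count_model(d, c("depth_std", "disp_std"), family = "poisson",
                           standardize = FALSE)
    td <- tidy(fit)
    ok <- abs(td$estimate - beta[td$term]) < 1.96 * td$std.error
    ok
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("overdispersion is ~1 for Poisson data and ~3 for NB data", {
  set.seed(31)
  beta <- c("(Intercept)" = -6.5, x = 0.3)
  dpois <- simulate_density_data(1000, beta)
  fp <- fit_count_model(dpois, "x", family = "poisson", standardize = FALSE)
  expect_equal(overdispersion(fp), 1, tolerance = 0.1)
  dnb <- simulate_density_data(1000, beta, theta = 1)
  # for NB(theta), var/mean = 1 + mu/theta; check it exceeds 2
  fnb <- fit_count_model(dnb, "x", family = "poisson", standardize = FALSE)
  expect_gt(overdispersion(fnb), 2)
  # all-zero response: undefined, flagged
  dz <- dpois; dz$pee_count <- 0L
  fz <- suppressWarnings(fit_count_model(dz, "x", family = "poisson",
                                         standardize = FALSE))
  expect_warning(th <- overdispersion(fz), "undefined")
  expect_true(is.na(th))
})

test_that("ZINB fits recover count, zero and dispersion parameters", {
  set.seed(32)
  beta <- c("(Intercept)" = -6.2, x1 = 0.5, x2 = -0.4)
  gamma <- c("(Intercept)" = -1, zx = 0.8)
  d <- simulate_density_data(1000, beta, gamma, theta = 3)
  fit <- fit_count_model(d, c("x1", "x2"), "zx", family = "zinb",
                         standardize = FALSE)
  td <- tidy(fit)
  count <- td[td$part == "count", ]
  expect_true(all(abs(count$estimate - beta[count$term]) < 2.5 * count$std.error))
  zero <- td[grepl("zero", td$part), ]
  expect_true(all(abs(zero$estimate - gamma[zero$term]) < 2.5 * zero$std.error))
  gl <- glance(fit)
  expect_gt(gl$theta, 1.5)
  expect_lt(gl$theta, 6)
  expect_true(is.finite(gl$aic))
})

test_that("with no zero inflation the ZINB reduces to the NB fit", {
  set.seed(33)
  beta <- c("(Intercept)" = -6.3, x = 0.5)
  d <- simulate_density_data(800, beta, gamma = NULL, theta = 3)
  nb <- fit_count_model(d, "x", family = "negbin", standardize = FALSE)
  zi <- fit_count_model(d, "x", "x", family = "zinb", standardize = FALSE)
  tnb <- tidy(nb); tzi <- tidy(zi)
  for (term in tnb$term) {
    dd <- abs(tzi$estimate[tzi$part == "count" & tzi$term == term] -
                tnb$estimate[tnb$term == term])
    expect_lt(dd, 2 * tnb$std.error[tnb$term == term])
  }
})

test_that("doubling the offset shifts only the intercept by -log 2", {
  set.seed(34)
  beta <- c("(Intercept)" = -6.5, x = 0.4)
  d <- simulate_density_data(800, beta)
  f1 <- fit_count_model(d, "x", family = "poisson", standardize = FALSE)
  d2 <- dplyr::mutate(d, volume = 2 * volume)
  f2 <- fit_count_model(d2, "x", family = "poisson", standardize = FALSE)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$estimate[t2$term == "x"], t1$estimate[t1$term == "x"],
               tolerance = 1e-8)
  expect_equal(t2$estimate[t2$term == "(Intercept)"],
               t1$estimate[t1$term == "(Intercept)"] - log(2), tolerance = 1e-8)
})

test_that("standardization makes coefficients invariant to covariate rescaling", {
  set.seed(35)
  beta <- c("(Intercept)" = -6.5, x = 0.4)
  d <- simulate_density_data(500, beta)
  f1 <- fit_count_model(d, "x", family = "poisson")
  d2 <- dplyr::mutate(d, x = 100 * x + 7)
  f2 <- fit_count_model(d2, "x", family = "poisson")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-8)
})

test_that("collinear covariates are rejected before fitting", {
  set.seed(36)
  d <- simulate_density_data(200, c("(Intercept)" = -6, x = 0.3))
  d$x_clone <- d$x + rnorm(200, 0, 0.01)
  expect_error(fit_count_model(d, c("x", "x_clone"), family = "poisson"),
               "collinear")
})

test_that("exhaustive selection keeps the informative covariates", {
  set.seed(37)
  beta <- c("(Intercept)" = -6.3, x1 = 0.6, x2 = -0.5)
  hits <- replicate(10, {
    d <- simulate_density_data(400, beta)
    for (nm in c("n1", "n2", "n3")) d[[nm]] <- rnorm(400)
    sel <- select_model(d, c("x1", "x2", "n1", "n2", "n3"), family = "poisson",
                        standardize = FALSE)
    all(c("x1", "x2") %in% sel$best$count_covariates)
  })
  expect_gte(mean(hits), 0.9)
  # single-covariate menu returns it trivially
  d <- simulate_density_data(200, beta)
  sel1 <- select_model(d, "x1", family = "poisson", standardize = FALSE)
  expect_equal(sel1$best$count_covariates, "x1")
  # pure-noise covariates: usually flagged non-conforming
  set.seed(38)
  flags <- replicate(10, {
    d0 <- simulate_density_data(200, c("(Intercept)" = -6))
    d0$noise1 <- rnorm(200); d0$noise2 <- rnorm(200)
    sel0 <- select_model(d0, c("noise1", "noise2"), family = "poisson",
                         standardize = FALSE)
    length(sel0$best$count_covariates) == 0
  })
  expect_gte(mean(flags), 0.7)
})

test_that("Vuong's test separates zero-inflated truth from Poisson", {
  set.seed(39)
  beta <- c("(Intercept)" = -6.2, x = 0.5)
  gamma <- c("(Intercept)" = -0.8)
  wins <- replicate(10, {
    d <- simulate_density_data(600, beta, gamma, theta = 3)
    fp <- fit_count_model(d, "x", family = "poisson", standardize = FALSE)
    fz <- fit_count_model(d, "x", NULL, family = "zinb", standardize = FALSE)
    v <- vuong_compare(fz, fp)
    v$z > 0 && v$p_value < 0.01
  })
  expect_gte(mean(wins), 0.9)
  # a fit against itself is exactly neutral
  d <- simulate_density_data(300, beta)
  f <- fit_count_model(d, "x", family = "poisson", standardize = FALSE)
  v0 <- vuong_compare(f, f)
  expect_equal(v0$z, 0)
  expect_equal(v0$p_value, 1)
  expect_equal(v0$preferred, "neither")
})

test_that("AIC prefers the zero-inflated NB on strongly zero-inflated NB data", {
  set.seed(40)
  beta <- c("(Intercept)" = -6.2, x = 0.5)
  gamma <- c("(Intercept)" = qlogis(0.3))
  better <- replicate(10, {
    d <- simulate_density_data(600, beta, gamma, theta = 3)
    fp <- fit_count_model(d, "x", family = "poisson", standardize = FALSE)
    fz <- fit_count_model(d, "x", NULL, family = "zinb", standardize = FALSE)
    glance(fz)$aic < glance(fp)$aic
  })
  expect_gte(mean(better), 0.95)
})

test_that("quadratic helper centres before squaring", {
  d <- tibble::tibble(speed_sd = c(1, 2, 3, 4))
  q <- add_quadratic(d, "speed_sd")
  expect_equal(q$speed_sd_sq, (d$speed_sd - 2.5)^2)
})
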