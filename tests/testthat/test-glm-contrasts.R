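# independent oracle: ordinary least squares via the normal equations
ols_oracle <- function(y, X) drop(solve(crossprod(X), crossprod(X, y)))

test_that("a noiseless linear response is reproduced exactly", {
  x <- rep(c(0, 1), each = 10)
  y <- 0.3 - 0.25 * x
  fit <- fit_glm_irls(y, cbind(1, x))
  expect_equal(unname(fit$coefficients), c(0.3, -0.25), tolerance = 1e-12)
  expect_lt(fit$metrics$deviance, 1e-20)
})

test_that("Gaussian-identity IRLS equals the normal-equations solution", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    fit <- fit_glm_irls(y, X)
    expect_lt(max(abs(fit$coefficients - ols_oracle(y, X))), 1e-8)
  }
})

test_that("the intercept-only model recovers the closed form", {
  set.seed(23)
  y <- rnorm(30, mean = 1.7)
  fit <- fit_glm_irls(y, matrix(1, 30, 1))
  expect_equal(unname(fit$coefficients), mean(y), tolerance = 1e-12)
  expect_equal(fit$metrics$deviance, sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(fit$metrics$pearson_chi2, fit$metrics$deviance)
})

test_that("rank-deficient and under-determined designs are refused with names", {
  set.seed(2)
  X <- cbind(a = 1, b = rnorm(10))
  X <- cbind(X, c = X[, "b"])          # exact collinearity
  expect_error(fit_glm_irls(rnorm(10), X), "rank deficient")
  expect_error(fit_glm_irls(rnorm(3), cbind(1, rnorm(3), rnorm(3), rnorm(3))),
               "more observations")
})

test_that("standard errors and p-values match the classical sampling theory", {
  set.seed(41)
  x <- rnorm(200)
  y <- 1 + 0.5 * x + rnorm(200)
  fit <- fit_glm_irls(y, cbind(1, x))
  ref <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(unname(fit$std_err), unname(ref[, "Std. Error"]),
               tolerance = 1e-10)
  # z-based p-values, not t-based
  expect_equal(unname(fit$p_value),
               unname(2 * pnorm(-abs(ref[, "Estimate"] / ref[, "Std. Error"]))),
               tolerance = 1e-10)
})

test_that("two-category rotation gives equal and opposite focal coefficients", {
  set.seed(3)
  scores <- data.frame(
    gene = "g1", station_class = rep(c("A", "B"), each = 40),
    layer = rep(c("epipelagic", "mesopelagic"), 40),
    log_delta = rnorm(80), stringsAsFactors = FALSE)
  ct <- one_vs_rest_rotation(scores, axes = "station_class", guilds = NULL)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$coef[1], -ct$coef[2], tolerance = 1e-10)
  expect_equal(ct$p_value[1], ct$p_value[2], tolerance = 1e-10)
})

test_that("focal coefficients reconstruct the per-category mean shifts", {
  set.seed(9)
  k <- 4L
  cats <- rep(LETTERS[1:k], each = 50)
  y <- rnorm(200) + rep(c(0, 0.3, -0.2, 0.1), each = 50)
  scores <- data.frame(gene = "g1", station_class = cats,
                       layer = "epipelagic", log_delta = y,
                       stringsAsFactors = FALSE)
  ct <- one_vs_rest_rotation(scores, axes = "station_class", guilds = NULL)
  for (i in seq_len(k)) {
    focal <- ct$focal[i]
    expect_equal(ct$coef[i],
                 mean(y[cats == focal]) - mean(y[cats != focal]),
                 tolerance = 1e-10)
  }
})

test_that("a sparse category is skipped while the rest are still reported", {
  scores <- data.frame(
    gene = "g1",
    station_class = c(rep("A", 30), rep("B", 30), "C"),
    layer = "epipelagic",
    log_delta = rnorm(61), stringsAsFactors = FALSE)
  expect_warning(
    ct <- one_vs_rest_rotation(scores, axes = "station_class",
                               guilds = NULL),
    "skipping")
  expect_setequal(ct$focal, c("A", "B"))
})

test_that("significance stars follow the documented thresholds and ordering", {
  ct <- data.frame(
    axis = c("layer", "station_class", "station_class"),
    focal = c("mesopelagic", "OMZ", "NAtl"),
    guild_class = "N_uptake",
    coef = c(0.26, -0.239, -0.105),
    std_err = c(0.10, 0.078, 0.078),
    p_value = c(0.2, 0.002, 0.0005),
    n = 100L, stringsAsFactors = FALSE)
  out <- summarize_table(ct, alpha = 0.05)
  expect_equal(out$signif[out$focal == "mesopelagic"], "")
  expect_equal(out$signif[out$focal == "OMZ"], "**")
  expect_equal(out$signif[out$focal == "NAtl"], "***")
  # stations come before layers
  expect_true(which(out$focal == "mesopelagic") >
                max(which(out$axis == "station_class")))
  expect_error(summarize_table(ct[0, ]), "empty")
})

test_that("a focal shift injected through the generator is estimated consistently", {
  # one station class carries multiplier 0.8 on richness; the focal GLM
  # coefficient estimates the implied log-delta shift within 3 SE
  for (s in 1:5) {
    n <- 600L
    cls <- rep(c("OMZ", "NAtl", "SAtl", "avg"), length.out = n)
    mult <- ifelse(cls == "OMZ", 0.8, 1)
    st <- simulate_strata(n, c_s = 2.5, gamma_s = 0.45, noise_sd = 0.2,
                          multiplier = mult, seed = 400L + s)
    st$station_class <- cls
    st$layer <- rep(layer_levels(), length.out = n)
    sc <- score_strata(st, fit_diversity_model(st, gene = "g1"))
    ct <- one_vs_rest_rotation(sc, axes = "station_class", guilds = NULL)
    omz <- ct[ct$focal == "OMZ", ]
    # mean shift of OMZ vs rest implied by the multiplier: log(0.8) scaled
    # by the fraction-weighted contrast (exact for a difference of means)
    expect_lt(abs(omz$coef - log(0.8)), 3 * omz$std_err + 0.03)
    expect_lt(omz$coef, 0)
  }
})
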