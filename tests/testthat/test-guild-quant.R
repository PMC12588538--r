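test_that("noiseless on-curve strata recover the power law to machine precision", {
  strata <- on_curve_strata(c_s = 2, gamma_s = 0.5, A = (1:20)^2)
  fit <- fit_diversity_model(strata)
  expect_equal(fit$c, 2, tolerance = 1e-10)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant richness is a flat fit with gamma = 0
  flat <- on_curve_strata(A = c(10, 100, 1000))
  flat$d_obs <- 7
  fit0 <- fit_diversity_model(flat)
  expect_equal(fit0$gamma, 0, tolerance = 1e-12)
  expect_equal(fit0$c, 7, tolerance = 1e-10)
})

test_that("the fit refuses under-determined or degenerate inputs", {
  s <- on_curve_strata(A = c(4, 16))
  expect_error(fit_diversity_model(s), "at least 3")
  same_A <- on_curve_strata(A = c(25, 25, 25))
  expect_error(fit_diversity_model(same_A), "zero variance")
})

test_that("noisy simulation recovers the generative constants within 3 SE", {
  s <- simulate_strata(500L, c_s = 3, gamma_s = 0.4, noise_sd = 0.2,
                       seed = 77L)
  fit <- fit_diversity_model(s, gene = "g1")
  expect_lt(abs(fit$gamma - 0.4), 3 * fit$se_gamma)
  expect_lt(abs(log(fit$c) - log(3)), 3 * fit$se_log_c)
})

test_that("gamma-hat is nearly unbiased across seeded replicates", {
  gam <- vapply(1:20, function(s) {
    st <- simulate_strata(500L, c_s = 3, gamma_s = 0.4, noise_sd = 0.2,
                          seed = 1000L + s)
    fit_diversity_model(st, gene = "g1")$gamma
  }, numeric(1))
  expect_lt(abs(mean(gam) - 0.4), 0.02)
})

test_that("delta and k follow their definitions and monotonicity", {
  strata <- on_curve_strata(A = (1:15)^2)
  fit <- fit_diversity_model(strata)

  one <- data.frame(gene = "amt", taxon = "t", station_class = "OMZ",
                    layer = "epipelagic", context = "OMZ.epipelagic",
                    A = 100, d_obs = 20L, stringsAsFactors = FALSE)
  sc <- score_strata(one, fit)
  expect_equal(sc$d_exp, 20, tolerance = 1e-9)
  expect_equal(sc$delta, 1, tolerance = 1e-9)
  expect_equal(sc$log_delta, 0, tolerance = 1e-9)
  expect_equal(sc$k, 100, tolerance = 1e-7)

  two <- one
  two$d_obs <- 40L
  sc2 <- score_strata(two, fit)
  expect_equal(sc2$delta, 2, tolerance = 1e-9)
  expect_equal(sc2$k, 200, tolerance = 1e-7)

  # delta > 1 rewards k above A; delta < 1 penalizes below A
  expect_gt(sc2$k, sc2$A)
  half <- one
  half$d_obs <- 10L
  expect_lt(score_strata(half, fit)$k, half$A)

  # k / A = delta identically
  expect_equal(sc2$k / sc2$A, sc2$delta)

  expect_error(score_strata(transform(one, gene = "zz"), fit), "zz")
})

test_that("on-curve data yield log delta zero within integer-rounding bounds", {
  s <- simulate_strata(300L, c_s = 2, gamma_s = 0.5, noise_sd = 0,
                       seed = 55L)
  s$context <- "average_ocean.epipelagic"
  fit <- fit_diversity_model(s, gene = "g1")
  sc <- score_strata(s, fit)
  expect_true(all(abs(sc$log_delta) <= log(1 + 1 / sc$d_obs) + 0.02))
})

test_that("an injected context multiplier moves mean log delta by log(m)", {
  m_true <- 0.7
  mult <- rep(1, 800)
  shifted <- seq_len(800) %% 4 == 0          # one context in four
  mult[shifted] <- m_true
  s <- simulate_strata(800L, c_s = 2.5, gamma_s = 0.45, noise_sd = 0.2,
                       multiplier = mult, seed = 66L)
  fit <- fit_diversity_model(s, gene = "g1")
  sc <- score_strata(s, fit)
  gap <- mean(sc$log_delta[shifted]) - mean(sc$log_delta[!shifted])
  expect_lt(abs(gap - log(m_true)), 0.06)
})

test_that("scoring commutes with permutation of strata", {
  s <- simulate_strata(100L, seed = 3L)
  fit <- fit_diversity_model(s, gene = "g1")
  sc <- score_strata(s, fit)
  perm <- sample(nrow(s))
  sc_perm <- score_strata(s[perm, ], fit)
  expect_equal(sc_perm$delta, sc$delta[perm])
})

test_that("per-taxon fits are exposed and score against the matching group", {
  s1 <- on_curve_strata(c_s = 2, gamma_s = 0.5, A = (2:10)^2)
  s1$taxon <- "taxA"
  s2 <- on_curve_strata(c_s = 4, gamma_s = 0.5, A = (2:10)^2 / 4)
  s2$taxon <- "taxB"
  s2$d_obs <- 4 * (s2$A)^0.5
  s <- rbind(s1, s2)
  fits <- fit_diversity_models(s, per_taxon = TRUE)
  expect_equal(nrow(fits), 2L)
  expect_equal(sort(fits$c), c(2, 4), tolerance = 1e-9)
  sc <- score_strata(s, fits)
  expect_equal(sc$delta, rep(1, nrow(s)), tolerance = 1e-9)
})

test_that("radial export pools taxa, orders by guild grouping, and round-trips", {
  set.seed(11)
  scores <- data.frame(
    gene = rep(c("amt", "nirK"), each = 30),
    taxon = rep(sprintf("tax%02d", 1:30), 2),
    station_class = "OMZ", layer = "mesopelagic",
    context = "OMZ.mesopelagic",
    A = runif(60, 1, 500), delta = runif(60, 0.5, 2),
    stringsAsFactors = FALSE)
  scores$k <- scores$delta * scores$A
  scores$log_delta <- log(scores$delta)
  scores$log_k <- log(scores$k)
  scores$d_obs <- 5L
  scores$d_exp <- 5

  rad <- radial_export(scores, top_n = 25L)
  expect_equal(nrow(rad), 52L)            # (25 + Others) per gene-cell
  expect_equal(unique(rad$guild_class[rad$gene == "amt"]), "N_uptake")
  # acquisition genes precede redox genes within the cell
  expect_lt(max(which(rad$gene == "amt")), min(which(rad$gene == "nirK")))

  single <- radial_export(scores[1, ], top_n = 25L)
  expect_equal(single$log_k, log(scores$k[1]))

  path <- tempfile(fileext = ".tsv")
  write_results(rad, path)
  expect_identical(read_results(path)$log_k, rad$log_k)

  odd <- scores
  odd$gene[1] <- "mysteryGene"
  expect_error(radial_export(odd), "mysteryGene")
})
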