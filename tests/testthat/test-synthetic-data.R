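test_that("the generator is byte-deterministic under a fixed seed", {
  a <- simulate_dataset(small_cruise(seed = 99L))
  b <- simulate_dataset(small_cruise(seed = 99L))
  expect_identical(a, b)
  c <- simulate_dataset(small_cruise(seed = 100L))
  expect_false(identical(a$records, c$records))

  pa <- simulate_placements("amoA", 6L, 4L, like_weight = c(0.7, 1), seed = 5L)
  pb <- simulate_placements("amoA", 6L, 4L, like_weight = c(0.7, 1), seed = 5L)
  expect_identical(pa, pb)
})

test_that("noiseless fixed-abundance strata land exactly on the richness curve", {
  # one gene, c = 2, gamma = 0.5; a stratum at A = 100 FPM must carry
  # exactly 2 * sqrt(100) = 20 distinct ORFs.
  # 3 stations x 3 layers x 6 taxa x 1 gene = 54 strata; integer FPM values
  # summing to exactly 1e6 keep realized FPM identical to the nominal ones.
  fpm <- c(100, 200, rep((1e6 - 300) / 52, 52))
  cfg <- sim_config(n_stations = 3L, taxa_per_layer = 6L,
                    genes = data.frame(gene = "amt", c = 2, gamma = 0.5),
                    occupancy = 1, noise_sd = 0,
                    abundance_law = "fixed", fpm_values = fpm,
                    total_reads = 1e6, seed = 3L)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$A[1], 100)
  expect_equal(sim$truth$d_true[1], 20L)
  n_orfs <- sum(sim$records$gene == sim$truth$gene[1] &
                  sim$records$taxon == sim$truth$taxon[1] &
                  sim$records$sample_id %in% sim$metadata$sample_id[
                    sim$metadata$layer == sim$truth$layer[1]])
  # the first context is unique in (class, layer) for this config row
  expect_gte(n_orfs, 20L)

  # every stratum sits on the curve (within integer rounding)
  expect_equal(sim$truth$d_true,
               as.integer(pmax(1, floor(2 * sim$truth$A^0.5 + 0.5))))
})

test_that("an injected multiplier scales on-curve richness by the stated factor", {
  fpm <- rep(1e6 / 200, 200)
  base <- sim_config(n_stations = 3L, taxa_per_layer = 8L,
                     genes = data.frame(gene = "nirK", c = 2, gamma = 0.5),
                     occupancy = 1, noise_sd = 0,
                     abundance_law = "fixed", fpm_values = fpm,
                     total_reads = 1e6, seed = 8L)
  shifted <- sim_config(n_stations = 3L, taxa_per_layer = 8L,
                        genes = data.frame(gene = "nirK", c = 2, gamma = 0.5),
                        occupancy = 1, noise_sd = 0,
                        delta_multipliers = c(OMZ = 0.5),
                        abundance_law = "fixed", fpm_values = fpm,
                        total_reads = 1e6, seed = 8L)
  t0 <- simulate_dataset(base)$truth
  t1 <- simulate_dataset(shifted)$truth
  omz <- t1$station_class == "OMZ"
  # off-OMZ strata identical; OMZ strata at half the on-curve richness
  expect_equal(t1$d_true[!omz], t0$d_true[!omz])
  expect_equal(t1$d_true[omz],
               as.integer(pmax(1, floor(0.5 * 2 * t1$A[omz]^0.5 + 0.5))))
})

test_that("log-log regression over many strata recovers the generative law", {
  s <- simulate_strata(200L, c_s = 3, gamma_s = 0.4, noise_sd = 0.2,
                       seed = 21L)
  fit <- fit_diversity_model(s, gene = "g1")
  expect_lt(abs(fit$gamma - 0.4), 3 * fit$se_gamma)
  expect_lt(abs(log(fit$c) - log(3)), 3 * fit$se_log_c)
})

test_that("taxon turnover between adjacent layers matches the configured sharing", {
  cfg <- sim_config(taxa_per_layer = 120L,
                    turnover_shared = c(epi_meso = 0.3, meso_bathy = 0.8),
                    occupancy = 0.6, seed = 13L)
  sim <- simulate_dataset(cfg)
  m <- sim$metadata[match(sim$records$sample_id, sim$metadata$sample_id), ]
  pools <- split(sim$records$taxon, m$layer)
  pools <- lapply(pools, unique)
  shared_em <- length(intersect(pools$epipelagic, pools$mesopelagic)) / 120
  shared_mb <- length(intersect(pools$mesopelagic, pools$bathypelagic)) / 120
  expect_lt(abs(shared_em - 0.3), 0.05)
  expect_lt(abs(shared_mb - 0.8), 0.05)
})

test_that("placement truth bookkeeping and degenerate cases behave", {
  sim <- simulate_placements("hzsA", 10L, 5L, seed = 2L)
  expect_equal(sum(sim$truth$status == "functional"), 10L)
  expect_equal(sum(sim$truth$status == "non_functional"), 5L)
  expect_setequal(sim$truth$query_id, sim$placements$placements$query_id)

  empty <- simulate_placements("hzsA", 0L, 0L, seed = 2L)
  expect_equal(nrow(empty$placements$placements), 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("N:P profile shapes place their mesopelagic maxima as configured", {
  cfg <- sim_config(seed = 17L)
  md <- simulate_np_profiles(cfg)
  profs <- np_profiles(md$metadata)
  shapes <- setNames(md$stations$shape, md$stations$station_id)

  omz_id <- names(shapes)[shapes == "omz_like"]
  mm <- mesopelagic_maximum(profs[[omz_id]])
  expect_equal(unname(mm["depth_m"]), 210)
  expect_equal(unname(mm["np_ratio"]), 12.4)

  natl_id <- names(shapes)[shapes == "natl_like"]
  mm2 <- mesopelagic_maximum(profs[[natl_id]])
  expect_equal(unname(mm2["np_ratio"]), 18.96)

  avg_ids <- names(shapes)[shapes == "average"]
  avg_max <- vapply(avg_ids, function(id)
    unname(mesopelagic_maximum(profs[[id]])["np_ratio"]), numeric(1))
  expect_true(all(avg_max > 12.4 & avg_max < 18.96))
})

test_that("a YAML config round-trips into the same simulation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_stations: 4",
    "taxa_per_layer: 10",
    "occupancy: 0.5",
    "noise_sd: 0.1",
    "genes:",
    "  - {gene: amt, c: 2.0, gamma: 0.45}",
    "  - {gene: nirK, c: 2.5, gamma: 0.5}",
    "delta_multipliers:",
    "  OMZ.mesopelagic: 0.8",
    "seed: 31"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$delta_multipliers[["OMZ.mesopelagic"]], 0.8)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})
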