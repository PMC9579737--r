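test_that("generated pools honour scales, screens and determinism", {
  cfg <- sim_config(seed = 40, n_pool = 80)
  pool <- generate_pool(cfg)
  expect_equal(nrow(pool), 80)
  expect_true(all(pool$ldmc >= 100 & pool$ldmc <= 400))
  expect_true(all(pool$grime_c >= 0 & pool$grime_c <= 100))
  expect_true(all(pool$regeneration_strategy %in% flordyn:::regen_levels()))

  sch <- trait_schema_of(pool)
  num <- sch$trait[sch$kind %in% c("numeric", "ordinal")]
  r <- stats::cor(as.matrix(tibble::as_tibble(pool)[, num]))
  diag(r) <- 0
  expect_lte(max(abs(r)), 0.70)

  expect_identical(tibble::as_tibble(generate_pool(cfg)),
                   tibble::as_tibble(pool))
  expect_false(identical(generate_pool(sim_config(seed = 41, n_pool = 80))$ldmc,
                         pool$ldmc))
  expect_equal(eval(formals(sim_config)$n_pool), 151)
})

test_that("requested missingness fractions are realized", {
  pool <- generate_pool(sim_config(seed = 42, n_pool = 100),
                        missingness = c(nectar_depth = 0.19))
  comp <- trait_completeness(pool)
  expect_equal(comp$completeness[comp$trait == "nectar_depth"], 0.81,
               tolerance = 0.005)
  expect_equal(comp$completeness[comp$trait == "ldmc"], 1)
})

test_that("null dynamics keep richness and evenness constant", {
  cfg <- sim_config(seed = 43, n_pool = 60,
                    richness_targets = c(low = 5, medium = 8, high = 12),
                    n_search = 30,
                    survival_base = 20, redundancy_effect = 0,
                    peripheral_loss = 0, ldmc_dominance = 0,
                    invasion_rate = 0, annual_penalty = 0,
                    biennial_penalty = 0, annual_boost = 1.2,
                    annual_decay = 1.2, biennial_boost = 1.2,
                    biennial_decay = 1.2,
                    growth_noise = 0, obs_noise = 0)
  b <- make_benchmark(cfg)
  m <- community_metrics(b$survey, b$pool, trait_subset = "all16")
  per_plot <- split(m, paste(m$transect, m$plot))
  for (pp in per_plot) {
    expect_equal(length(unique(pp$richness)), 1)
    expect_lt(diff(range(pp$evenness)), 1e-9)
    expect_lt(diff(range(pp$fdis)), 1e-9)
  }
})

test_that("the benchmark has the field layout and round-trips to disk", {
  b <- small_benchmark()
  expect_length(b$designs, 8)
  series <- dplyr::distinct(b$survey, transect, plot)
  expect_equal(nrow(series), 48)  # 8 assemblages x 6 replicate transects
  expect_equal(sort(unique(b$survey$block)), 1:3)
  expect_equal(sort(unique(b$survey$year)), 1:4)
  # each transect carries each assemblage exactly once
  per_t <- dplyr::distinct(b$survey, transect, plot, assemblage)
  expect_equal(nrow(per_t), 48)
  expect_true(all(table(per_t$transect) == 8))

  dir <- withr::local_tempdir()
  make_benchmark(b$config, dir = dir)
  pool2 <- read_trait_table(file.path(dir, "pool.csv"))
  expect_equal(pool2$ldmc, b$pool$ldmc, tolerance = 1e-9)
  surv2 <- read_survey(file.path(dir, "survey.csv"), years = 1:4,
                       designs = b$designs)
  expect_equal(nrow(surv2), nrow(b$survey))
  d2 <- read_design(file.path(dir, "designs", "HFHS1.json"))
  expect_equal(d2$species, b$designs$HFHS1$species)
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$seed, b$config$seed)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$seed, b$config$seed)
  expect_true(all(c("pool.csv", "survey.csv") %in% mf$outputs))
  expect_equal(mf$config_digest,
               run_manifest(b$config)$config_digest)
})

test_that("simulation is reproducible and responds to the missing-year flag", {
  cfg <- sim_config(seed = 44, n_pool = 60,
                    richness_targets = c(low = 5, medium = 8, high = 12),
                    n_search = 30)
  b1 <- make_benchmark(cfg)
  b2 <- make_benchmark(cfg)
  expect_identical(b1$survey$cover, b2$survey$cover)

  cfg_miss <- sim_config(seed = 44, n_pool = 60,
                         richness_targets = c(low = 5, medium = 8, high = 12),
                         n_search = 30, missing_year = TRUE)
  bm <- make_benchmark(cfg_miss)
  y2 <- bm$survey[bm$survey$year == 2, ]
  expect_equal(sort(unique(y2$transect)), 4:6)
  expect_equal(sort(unique(bm$survey$transect[bm$survey$year == 3])), 1:6)
})

test_that("invasion pressure declines with sown dispersion across replicates", {
  neg <- 0
  n_rep <- 12
  for (s in 1:n_rep) {
    cfg <- sim_config(seed = 400 + s, n_pool = 60,
                      richness_targets = c(low = 5, medium = 8, high = 12),
                      n_search = 40)
    b <- make_benchmark(cfg)
    sm <- community_metrics(b$survey, b$pool, sown_only = TRUE,
                            trait_subset = "all16")
    uns <- b$survey[b$survey$cover > 0, ] |>
      dplyr::count(transect, plot, year, wt = !sown, name = "ur") |>
      dplyr::left_join(sm, by = c("transect", "plot", "year"))
    sl <- stats::coef(stats::lm(ur ~ fdis + factor(year), data = uns))[["fdis"]]
    if (sl < 0) neg <- neg + 1
  }
  expect_gte(neg, ceiling(0.8 * n_rep))
})

test_that("an annual-flush succession reproduces a ~60% first-year annual share", {
  # fixture parameterized for a strong first-year annual flush: seed mixes
  # rich in annuals plus weed colonization dominating the open year-1 sward
  cfg <- sim_config(seed = 11, annual_boost = 30,
                    design_weights = c(annual = 0.6, biennial = 0.7))
  b <- make_benchmark(cfg)
  sp <- strategy_proportions(b$survey, b$pool)
  ann1 <- sp$cover_share[sp$year == 1 & sp$strategy == "annual"]
  expect_gt(ann1, 0.45)
  expect_lt(ann1, 0.75)
  # the flush fades: annual share declines in later years
  ann4 <- sp$cover_share[sp$year == 4 & sp$strategy == "annual"]
  expect_lt(ann4, ann1)
})

test_that("year-4 sown persistence sits in the calibrated range", {
  b <- small_benchmark()
  pers <- sown_persistence(b$survey, b$designs)
  expect_equal(nrow(pers), 8)
  expect_true(all(pers$persistence > 0.25 & pers$persistence < 0.95))
})
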