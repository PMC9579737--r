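test_that("Simpson diversity and evenness match their closed forms", {
  expect_equal(simpson_diversity(c(a = 5)), 0)
  expect_equal(simpson_diversity(stats::setNames(rep(1, 4), letters[1:4])), 0.75)
  expect_equal(simpson_diversity(c(a = 0.9, b = 0.1)), 0.18)

  expect_equal(simpson_evenness(stats::setNames(rep(3, 7), letters[1:7])), 1)
  expect_equal(simpson_evenness(c(a = 0.9, b = 0.1)), (1 / 0.82) / 2)
  expect_equal(simpson_evenness(c(a = 2)), 1)

  expect_error(simpson_diversity(c(a = 0, b = 0)), "empty")
})

test_that("Rao's Q and redundancy match closed forms and limits", {
  sp <- letters[1:5]
  ones <- matrix(1, 5, 5, dimnames = list(sp, sp)); diag(ones) <- 0
  comm <- stats::setNames(rep(1, 5), sp)
  d1 <- as_dissim(ones)
  expect_equal(rao_q(comm, d1), 1 - 1 / 5)              # equals Gini-Simpson
  expect_equal(functional_redundancy(comm, d1), 0)      # no redundancy

  zeros <- as_dissim(matrix(0, 5, 5, dimnames = list(sp, sp)))
  expect_equal(functional_redundancy(comm, zeros), simpson_diversity(comm))

  two <- as_dissim(matrix(c(0, 0.4, 0.4, 0), 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(rao_q(c(a = 1, b = 1), two), 0.2)
  expect_equal(rao_q(c(a = 3), two), 0)
  expect_error(rao_q(c(z = 1), two), "missing from dissimilarity")
})

test_that("FDis matches the two-point closed form and errors cleanly", {
  two <- as_dissim(matrix(c(0, 0.4, 0.4, 0), 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))
  e <- trait_embedding(two)
  expect_equal(fdis(c(a = 1, b = 1), e), 0.2)
  expect_equal(fdis(c(a = 5), e), 0)
  expect_error(fdis(c(q = 1), e), "missing from embedding")
})

test_that("single-trait FDis agrees with direct computation in scaled space", {
  # with one numeric trait the Gower matrix is Euclidean (a line), so the
  # embedding route must equal FDis computed straight from scaled values
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    v <- runif(n)
    tt <- trait_table(
      data.frame(species = letters[1:n], t1 = v),
      trait_schema("t1", "numeric")
    )
    comm <- stats::setNames(rexp(n), letters[1:n])
    p <- comm / sum(comm)
    x <- (v - min(v)) / diff(range(v))
    direct <- sum(p * abs(x - sum(p * x)))
    e <- trait_embedding(gower_distance(tt))
    expect_false(e$negative_eigenvalues)
    expect_equal(fdis(comm, e), direct, tolerance = 1e-8)
  }
})

test_that("metric inequalities hold over random communities", {
  set.seed(4)
  pool <- generate_pool(sim_config(seed = 4, n_pool = 40))
  d <- gower_distance(prepare_traits(pool, "all16"))
  e <- trait_embedding(d)
  for (i in 1:200) {
    S <- sample(1:12, 1)
    comm <- stats::setNames(rexp(S) + 0.01, sample(pool$species, S))
    D <- simpson_diversity(comm)
    Q <- rao_q(comm, d)
    FR <- functional_redundancy(comm, d)
    expect_gte(Q, 0)
    expect_lte(Q, D + 1e-12)
    expect_lte(D, 1 - 1 / S + 1e-12)
    expect_gte(FR, -1e-12)
    if (S == 1) expect_equal(fdis(comm, e), 0)
  }
})

test_that("FDis and Q are invariant to splitting a species into clones", {
  pool <- generate_pool(sim_config(seed = 5, n_pool = 30))
  # duplicate species 1's trait vector under a new id
  clone <- pool[1, ]
  clone$species <- "clone"
  pool2 <- trait_table(dplyr::bind_rows(tibble::as_tibble(pool),
                                        tibble::as_tibble(clone)),
                       trait_schema_of(pool))
  d2 <- gower_distance(prepare_traits(pool2, "all16"))
  # duplicated objects share coordinates in the uncorrected embedding;
  # the Cailliez constant would inflate the zero self-distance
  e2 <- suppressWarnings(trait_embedding(d2, correction = "none"))
  sp <- pool$species[1:5]
  comm <- stats::setNames(c(4, 1, 1, 1, 1), sp)
  split <- stats::setNames(c(2, 2, 1, 1, 1, 1), c(sp[1], "clone", sp[2:5]))
  expect_equal(rao_q(split, d2), rao_q(comm, d2), tolerance = 1e-10)
  expect_equal(fdis(split, e2), fdis(comm, e2), tolerance = 1e-8)
})

test_that("CWM is the abundance-weighted mean with missing-value exclusion", {
  tt <- trait_table(
    data.frame(species = c("a", "b", "c"), ldmc = c(100, 200, NA)),
    trait_schema("ldmc", "numeric")
  )
  expect_equal(cwm(c(a = 1), tt, "ldmc"), 100)
  expect_equal(cwm(c(a = 0.25, b = 0.75), tt, "ldmc"), 175)
  # c excluded, weights renormalized over a and b
  expect_equal(cwm(c(a = 1, b = 3, c = 4), tt, "ldmc"), 175)
  expect_error(cwm(c(c = 1), tt, "ldmc"), "missing")

  # a sown mixture built to the typical leaf-economics range: equal seed
  # shares of three meadow species put the community LDMC in 185-220 mg/g
  meadow <- trait_table(
    data.frame(species = c("m1", "m2", "m3"), ldmc = c(190, 210, 220)),
    trait_schema("ldmc", "numeric")
  )
  cwm_sown <- cwm(c(m1 = 1, m2 = 1, m3 = 1), meadow, "ldmc")
  expect_gte(cwm_sown, 185)
  expect_lte(cwm_sown, 220)

  set.seed(6)
  vals <- c(a = 100, b = 200)
  for (i in 1:20) {
    comm <- stats::setNames(rexp(2), c("a", "b"))
    x <- cwm(comm, tt, "ldmc")
    expect_gte(x, 100); expect_lte(x, 200)
  }
})

test_that("strategy proportions sum to one and handle edge cases", {
  tt <- trait_table(
    data.frame(species = c("a", "b", "c"),
               regeneration_strategy = c("annual", "annual", NA)),
    trait_schema("regeneration_strategy", "categorical")
  )
  surv <- survey_rows(c(a = 10, b = 30), year = 1) |>
    dplyr::bind_rows(survey_rows(c(a = 5, b = 5), year = 2))
  p <- strategy_proportions(surv, tt)
  expect_equal(p$cover_share, c(1, 1))  # all-annual every year

  two <- trait_table(
    data.frame(species = c("a", "b"),
               regeneration_strategy = c("annual", "biennial")),
    trait_schema("regeneration_strategy", "categorical")
  )
  p2 <- strategy_proportions(survey_rows(c(a = 20, b = 20)), two)
  expect_equal(sort(p2$cover_share), c(0.5, 0.5))

  surv3 <- survey_rows(c(a = 10, b = 10, c = 20))
  expect_warning(p3 <- strategy_proportions(surv3, tt), "lack the strategy")
  expect_equal(attr(p3, "excluded_cover_share"), 0.5)
  expect_equal(sum(p3$cover_share), 1)
})

test_that("community_metrics produces one keyed row per plot-year", {
  b <- small_benchmark()
  m <- community_metrics(b$survey, b$pool, cwm_traits = c("ldmc", "sla"))
  keys <- dplyr::distinct(b$survey[b$survey$cover > 0, ],
                          transect, plot, year)
  expect_equal(nrow(m), nrow(keys))
  expect_true(all(c("richness", "simpson", "evenness", "rao_q", "redundancy",
                    "fdis", "total_cover", "cwm_ldmc", "cwm_sla") %in% names(m)))
  expect_true(all(m$redundancy >= 0))
  expect_true(all(m$evenness > 0 & m$evenness <= 1 + 1e-9))

  ms <- community_metrics(b$survey, b$pool, sown_only = TRUE)
  expect_lte(max(ms$richness), max(m$richness))
})
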