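test_that("prepare_traits applies natural logs to the flagged traits only", {
  n <- 4
  dat <- tibble::tibble(
    species = letters[1:n],
    flowering_height = c(10, 100, 50, 20),
    flowering_onset = c(15, 20, 25, 30),
    ldmc = c(150, 250, 300, 200)
  )
  sch <- default_trait_schema()
  sch <- sch[sch$trait %in% names(dat), ]
  tt <- trait_table(dat, sch)
  out <- prepare_traits(tt, c("flowering_height", "flowering_onset", "ldmc"))
  expect_equal(out$flowering_height, log(c(10, 100, 50, 20)))
  expect_equal(out$flowering_onset, c(15, 20, 25, 30))  # not flagged
  expect_equal(out$ldmc, dat$ldmc)

  dat2 <- dat; dat2$flowering_height[2] <- 0
  tt2 <- trait_table(dat2, sch)
  expect_error(prepare_traits(tt2, "flowering_height"), "b")
  expect_error(prepare_traits(tt, c("flowering_height", "hieght")),
               "valid names")
})

test_that("trait presets have the documented sizes", {
  p <- trait_presets()
  expect_length(p$arthropod10, 10)
  expect_length(p$arthropod11, 11)
  expect_length(p$competition9, 9)
  expect_length(p$all16, 16)
  expect_true("raunkiaer_life_form" %in% p$arthropod11)
  expect_false("raunkiaer_life_form" %in% p$arthropod10)
  expect_true(all(c("grime_c", "grime_r") %in% p$competition9))
})

test_that("Gower distance matches hand computation on mixed traits", {
  d <- gower_distance(toy_traits())
  expect_equal(d["a", "b"], 0.25)   # (0.5 + 0) / 2
  expect_equal(d["a", "c"], 1.0)    # (1 + 1) / 2
  expect_equal(d["b", "c"], 0.75)   # (0.5 + 1) / 2
  expect_equal(diag(unclass(d)), c(a = 0, b = 0, c = 0))
})

test_that("Gower hits its bounds for identical and maximally different pairs", {
  tt <- trait_table(
    data.frame(species = c("p", "q", "r"),
               size = c(1, 1, 9), color = c("red", "red", "blue"),
               efn = c(0, 0, 1)),
    trait_schema(c("size", "color", "efn"),
                 c("numeric", "categorical", "binary"))
  )
  d <- gower_distance(tt)
  expect_equal(d["p", "q"], 0)
  expect_equal(d["p", "r"], 1)
})

test_that("missing values use per-pair weight renormalization", {
  tt <- trait_table(
    data.frame(species = c("a", "b"),
               t1 = c(0, 10), t2 = c(NA, 3), t3 = c("x", "y")),
    trait_schema(c("t1", "t2", "t3"),
                 c("numeric", "numeric", "categorical"))
  )
  # t2 unusable for the pair: d = (1 + 1) / 2 over t1, t3 only
  expect_equal(gower_distance(tt)["a", "b"], 1)

  none <- trait_table(
    data.frame(species = c("a", "b"), t1 = c(1, NA), t2 = c(NA, 2)),
    trait_schema(c("t1", "t2"), c("numeric", "numeric"))
  )
  expect_error(suppressWarnings(gower_distance(none)),
               "no shared non-missing trait")
})

test_that("zero-range traits contribute zero with a warning", {
  tt <- trait_table(
    data.frame(species = c("a", "b"), t1 = c(5, 5), t2 = c(0, 1)),
    trait_schema(c("t1", "t2"), c("numeric", "numeric"))
  )
  expect_warning(d <- gower_distance(tt), "zero range")
  expect_equal(d["a", "b"], 0.5)  # mean of 0 and 1
})

test_that("Gower is invariant to affine rescaling and row permutation", {
  set.seed(1)
  n <- 6
  dat <- tibble::tibble(species = letters[1:n],
                        t1 = runif(n), t2 = rnorm(n),
                        t3 = sample(c("u", "v"), n, replace = TRUE))
  sch <- trait_schema(c("t1", "t2", "t3"),
                      c("numeric", "numeric", "categorical"))
  d1 <- gower_distance(trait_table(dat, sch))
  scaled <- dat
  scaled$t1 <- 100 * dat$t1 - 7
  scaled$t2 <- -3 * dat$t2 + 2
  d2 <- gower_distance(trait_table(scaled, sch))
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)

  perm <- sample(n)
  d3 <- gower_distance(trait_table(dat[perm, ], sch))
  expect_equal(unclass(d3), unclass(d1)[perm, perm], tolerance = 1e-12)
})

test_that("all-numeric complete Gower equals the brute-force oracle and daisy", {
  set.seed(2)
  n <- 6
  dat <- tibble::tibble(species = letters[1:n],
                        t1 = runif(n), t2 = rnorm(n), t3 = rexp(n))
  sch <- trait_schema(c("t1", "t2", "t3"), rep("numeric", 3))
  d <- gower_distance(trait_table(dat, sch))

  # brute force: mean of per-trait range-normalized L1 distances
  oracle <- matrix(0, n, n)
  for (tr in c("t1", "t2", "t3")) {
    v <- dat[[tr]]
    oracle <- oracle + abs(outer(v, v, `-`)) / diff(range(v)) / 3
  }
  expect_equal(unclass(d), oracle, tolerance = 1e-12, ignore_attr = TRUE)

  ref <- as.matrix(cluster::daisy(as.data.frame(dat[, -1]), metric = "gower"))
  expect_equal(unclass(d), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two-point embedding is a segment of the right length", {
  d <- as_dissim(matrix(c(0, 0.4, 0.4, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
  e <- trait_embedding(d)
  expect_equal(ncol(e$points), 1)
  expect_equal(sort(e$points[, 1]), c(-0.2, 0.2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Euclidean inputs are reproduced exactly by the embedding", {
  x <- c(a = 0, b = 1, c = 3, d = 7)
  dm <- as_dissim(abs(outer(x, x, `-`)) / 10)
  e <- trait_embedding(dm)
  expect_false(e$negative_eigenvalues)
  expect_equal(embedding_distances(e), unclass(dm), tolerance = 1e-10)
})

test_that("Cailliez correction makes a non-Euclidean matrix embeddable", {
  # non-Euclidean toy: three mutually distant points plus a near-hub
  # violates the triangle inequality (0.1 + 0.1 < 1)
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[lower.tri(m)] <- c(1, 1, 0.1, 1, 0.1, 0.1)
  m <- m + t(m)
  d <- as_dissim(m)
  expect_warning(e0 <- trait_embedding(d, correction = "none"),
                 "negative eigenvalues")
  expect_true(e0$negative_eigenvalues)

  e <- trait_embedding(d, correction = "cailliez")
  corrected <- unclass(d) + e$cailliez_constant
  diag(corrected) <- 0
  b <- eigen(flordyn:::double_centre(-0.5 * corrected^2),
             symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(b >= -1e-8 * max(abs(b))))
  expect_equal(embedding_distances(e), corrected, tolerance = 1e-8)

  # independent oracle for the additive constant (reported in pcoa's note)
  ref <- ape::pcoa(stats::as.dist(unclass(d)), correction = "cailliez")
  c_ref <- as.numeric(sub(".*D \\+ ([0-9.e+-]+) .*", "\\1", ref$note))
  expect_equal(e$cailliez_constant, c_ref, tolerance = 1e-6)

  # sqrt correction: squared line distances become Euclidean under sqrt
  x <- c(a = 0, b = 1, c = 2)
  dsq <- as_dissim(outer(x, x, `-`)^2 / 4)
  es <- trait_embedding(dsq, correction = "sqrt")
  expect_equal(es$correction, "sqrt")
  expect_equal(embedding_distances(es), sqrt(unclass(dsq)), tolerance = 1e-8)
})
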