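fake_candidate <- function(aic, terms = character(), coefs = NULL, k = 2) {
  structure(
    list(terms = terms, formula = NULL, family = "gaussian", flat = TRUE,
         converged = TRUE, note = NA_character_,
         logLik = -(aic - 2 * k) / 2, k = k, aic = aic,
         coefs = coefs %||% tibble::tibble(term = "(Intercept)",
                                           estimate = 0, std_error = 1),
         fit = NULL),
    class = "fd_candidate"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("candidate enumeration respects marginality and counts", {
  expect_equal(nrow(enumerate_candidates(character(), time = NULL)), 1)
  expect_equal(nrow(enumerate_candidates(character(), time = "time")), 2)
  expect_equal(nrow(enumerate_candidates("a", time = "time")), 5)
  cands <- enumerate_candidates(c("a", "b"), time = "time")
  expect_equal(nrow(cands), 13)
  for (terms in cands$terms) {
    for (int in grep(":", terms, value = TRUE)) {
      parents <- strsplit(int, ":", fixed = TRUE)[[1]]
      expect_true(all(parents %in% terms))
    }
  }
  # no duplicated models
  sig <- vapply(cands$terms, function(t) paste(sort(t), collapse = "+"), "")
  expect_equal(anyDuplicated(sig), 0)
})

test_that("flat Gaussian fits recover exact lines and closed-form AIC", {
  dat <- data.frame(x = 1:5, y = 2 + 3 * (1:5))
  f <- fit_candidate("x", dat, "y", family = "gaussian", flat = TRUE)
  expect_equal(unname(f$coefs$estimate[f$coefs$term == "x"]), 3,
               tolerance = 1e-10)

  set.seed(30)
  dat2 <- data.frame(x = rnorm(40))
  dat2$y <- 1 + 0.5 * dat2$x + rnorm(40)
  f2 <- fit_candidate("x", dat2, "y", flat = TRUE)
  # closed-form Gaussian ML: logLik = -n/2 (log(2 pi sigma2_ml) + 1)
  n <- nrow(dat2)
  res <- stats::resid(stats::lm(y ~ x, dat2))
  s2 <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(f2$logLik, ll, tolerance = 1e-8)
  expect_equal(f2$k, 3)  # slope, intercept, sigma
  expect_equal(f2$aic, -2 * ll + 2 * 3, tolerance = 1e-8)
  expect_equal(f2$aic, stats::AIC(stats::lm(y ~ x, dat2)), tolerance = 1e-8)
  # OLS closed form for the slope
  beta <- stats::cov(dat2$x, dat2$y) / stats::var(dat2$x)
  expect_equal(unname(f2$coefs$estimate[f2$coefs$term == "x"]), beta,
               tolerance = 1e-8)
})

test_that("flat Poisson intercept-only fit is the log of the mean", {
  dat <- data.frame(y = c(1L, 2L, 3L))
  f <- fit_candidate(character(), dat, "y", family = "poisson", flat = TRUE)
  expect_equal(unname(f$coefs$estimate), log(2), tolerance = 1e-8)
  expect_error(fit_candidate(character(), data.frame(y = c(1.5, 2)), "y",
                             family = "poisson", flat = TRUE),
               "non-negative integers")
})

test_that("ranking uses strict delta-AIC selection and renormalized weights", {
  cands <- list(fake_candidate(100), fake_candidate(104), fake_candidate(102))
  sel <- rank_and_select(cands, delta_threshold = 4)
  expect_equal(sel$model_id, c(1, 3, 2))
  expect_equal(sel$delta, c(0, 2, 4))
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE))  # 4.0 excluded, strict <
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(sel$weight[1:2], w)
  expect_true(is.na(sel$weight[3]))

  tie <- rank_and_select(list(fake_candidate(100, k = 3),
                              fake_candidate(100, k = 2)))
  expect_equal(tie$model_id[1], 2)  # fewer parameters wins the tie
  expect_equal(tie$weight, c(0.5, 0.5))
})

test_that("full averaging substitutes zero where a term is absent", {
  with_b <- fake_candidate(
    100, terms = "x",
    coefs = tibble::tibble(term = c("(Intercept)", "x"),
                           estimate = c(1, 0.8), std_error = c(0.1, 0.2))
  )
  without_b <- fake_candidate(
    100, terms = character(),
    coefs = tibble::tibble(term = "(Intercept)", estimate = 1.2,
                           std_error = 0.1)
  )
  avg <- full_average(list(with_b, without_b))
  cf <- avg$coefficients
  expect_equal(cf$estimate[cf$term == "x"], 0.4)  # 0.8 * 0.5 + 0 * 0.5
  # averaged SE blends sampling and between-model variance
  se <- sqrt(0.5 * (0.2^2 + 0.4^2) + 0.5 * (0 + 0.4^2))
  expect_equal(cf$std_error[cf$term == "x"], se)
  expect_equal(cf$conf_low[cf$term == "x"], 0.4 - 1.96 * se)
  expect_equal(cf$abs_z[cf$term == "x"], 0.4 / se)
  expect_equal(cf$n_models[cf$term == "x"], 1)

  single <- full_average(list(with_b))
  expect_equal(single$coefficients$estimate,
               with_b$coefs$estimate)
  expect_equal(single$coefficients$std_error,
               with_b$coefs$std_error)

  # averaged coefficient never exceeds its largest single-model magnitude
  expect_lte(abs(cf$estimate[cf$term == "x"]), 0.8)
})

test_that("averaged-model tidiers expose the reporting table shape", {
  set.seed(31)
  dat <- data.frame(x = rnorm(60), time = rep(1:4, 15),
                    transect = rep(1:3, each = 20),
                    plot = rep(1:4, 15))
  dat$y <- 0.5 + 0.3 * dat$x + rnorm(60, 0, 0.5)
  avg <- fit_multimodel(dat, "y", "x", time = "time", flat = TRUE)
  td <- tidy(avg)
  expect_true(all(c("term", "estimate", "abs_z", "conf_low", "conf_high")
                  %in% names(td)))
  gl <- glance(avg)
  expect_equal(gl$n_candidates, 5)
  expect_true(gl$n_selected >= 1)
  expect_true(is.finite(gl$r2_marginal))
  p <- autoplot(avg)
  expect_s3_class(p, "ggplot")
})

test_that("pseudo-R2 recovers known variance components", {
  expect_warning(
    r2p <- r_squared(fit_candidate(character(),
                                   data.frame(y = c(1L, 2L),
                                              transect = 1:2, plot = 1:2),
                                   "y", family = "poisson", flat = TRUE)),
    "gaussian"
  )
  expect_true(is.na(r2p$marginal))

  # flat fit: marginal equals conditional
  set.seed(32)
  dat <- data.frame(x = rnorm(100))
  dat$y <- dat$x + rnorm(100)
  f <- fit_candidate("x", dat, "y", flat = TRUE)
  r2 <- r_squared(f)
  expect_equal(r2$marginal, r2$conditional)

  # mixed simulation: var(fixed) = 1, var(group) = 1, var(resid) = 2
  set.seed(33)
  g <- rep(1:100, each = 20)
  x <- rnorm(2000)
  y <- x + rnorm(100, 0, 1)[g] + rnorm(2000, 0, sqrt(2))
  dat2 <- data.frame(y = y, x = x, transect = g, plot = g)
  fm <- lme4::lmer(y ~ x + (1 | transect), data = dat2, REML = FALSE)
  cand <- structure(list(fit = fm, family = "gaussian"),
                    class = "fd_candidate")
  r2m <- r_squared(cand)
  expect_equal(r2m$marginal, 0.25, tolerance = 0.05)
  expect_equal(r2m$conditional, 0.5, tolerance = 0.07)
})

test_that("mixed fits against flat grouping agree with ordinary regression", {
  set.seed(34)
  dat <- data.frame(x = rnorm(48), transect = rep(1:4, each = 12),
                    plot = rep(rep(1:4, each = 3), 4))
  dat$y <- 1 + 0.4 * dat$x + rnorm(48, 0, 0.3)
  flat <- fit_candidate("x", dat, "y", flat = TRUE)
  ref <- stats::lm(y ~ x, dat)
  expect_equal(unname(flat$coefs$estimate), unname(stats::coef(ref)),
               tolerance = 1e-8)
  mixed <- fit_candidate("x", dat, "y")
  expect_true(mixed$converged)
  expect_gte(mixed$k, flat$k + 1)  # extra variance components counted
})
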