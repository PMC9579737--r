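#' Enumerate marginality-respecting candidate models
#'
#' All fixed-effect structures built from a set of predictors, a time term,
#' and predictor-by-time interactions, under marginality: an interaction may
#' appear only when both its parents do. The intercept-only model is always
#' included. With 2 predictors and a time term this yields 13 candidates.
#'
#' @param predictors character vector of predictor column names (may be
#'   factors in the data).
#' @param time name of the time term, or `NULL` for no time axis.
#' @return tibble with columns `model_id` and `terms` (list-column of
#'   character vectors; `character(0)` is the intercept-only model).
#' @export
enumerate_candidates <- function(predictors = character(), time = "time") {
  subsets <- function(x) {
    if (length(x) == 0) return(list(character(0)))
    unlist(lapply(0:length(x), function(k) {
      utils::combn(x, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  out <- list()
  for (main in subsets(predictors)) {
    out[[length(out) + 1]] <- main
    if (!is.null(time)) {
      for (ints in subsets(main)) {
        out[[length(out) + 1]] <-
          c(main, time, if (length(ints) > 0) paste0(ints, ":", time))
      }
    }
  }
  tibble::tibble(
    model_id = seq_along(out),
    terms = out
  )
}

candidate_formula <- function(response, terms, grouping = NULL) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  if (!is.null(grouping)) {
    rhs <- paste0(rhs, " + (1 | ", grouping[1], "/", grouping[2], ")")
  }
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit one candidate model
#'
#' Maximum-likelihood fit of a fixed-effect structure, either as a mixed
#' model with plot nested in transect as random intercepts (the default,
#' via lme4 with `REML = FALSE`) or, with `flat = TRUE`, as an ordinary
#' (generalized) linear model -- the degenerate case used to validate the
#' AIC machinery against closed forms.
#'
#' The parameter count `k` follows the likelihood's degrees of freedom:
#' fixed effects plus variance components (plus the residual variance for
#' Gaussian fits), so `aic = -2 logLik + 2 k` matches `stats::AIC()`.
#'
#' @param terms character vector of fixed-effect terms (empty = intercept
#'   only).
#' @param data data frame with the response, predictors and grouping
#'   columns.
#' @param response response column name.
#' @param family `"gaussian"` (identity link) or `"poisson"` (log link;
#'   response must be non-negative integers).
#' @param grouping length-2 character vector `c(outer, inner)` naming the
#'   nesting columns (default transect/plot).
#' @param flat drop the random effects entirely.
#' @return an `fd_candidate` list: `terms`, `formula`, `converged`,
#'   `logLik`, `k`, `aic`, `coefs` (tibble of term/estimate/std_error) and
#'   the underlying `fit`.
#' @export
fit_candidate <- function(terms, data, response,
                          family = c("gaussian", "poisson"),
                          grouping = c("transect", "plot"), flat = FALSE) {
  family <- match.arg(family)
  if (family == "poisson") {
    y <- data[[response]]
    if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
      stop("poisson response must be non-negative integers", call. = FALSE)
    }
  } else if (any(!is.finite(data[[response]]))) {
    stop("gaussian response must be finite", call. = FALSE)
  }
  fml <- candidate_formula(response, terms,
                           grouping = if (flat) NULL else grouping)
  converged <- TRUE
  note <- NA_character_
  fit <- withCallingHandlers(
    tryCatch({
      if (flat) {
        if (family == "gaussian") stats::lm(fml, data = data)
        else stats::glm(fml, data = data, family = stats::poisson())
      } else {
        if (family == "gaussian") {
          lme4::lmer(fml, data = data, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
        } else {
          lme4::glmer(fml, data = data, family = stats::poisson(),
                      control = lme4::glmerControl(calc.derivs = FALSE))
        }
      }
    }, error = function(e) {
      converged <<- FALSE
      note <<- conditionMessage(e)
      NULL
    }),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|unidentifiable|Hessian", msg, ignore.case = TRUE)) {
        converged <<- FALSE
        note <<- msg
      }
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit)) {
    return(structure(list(terms = terms, formula = fml, family = family,
                          flat = flat, converged = FALSE, note = note,
                          logLik = NA_real_, k = NA_real_, aic = NA_real_,
                          coefs = tibble::tibble(term = character(),
                                                 estimate = numeric(),
                                                 std_error = numeric()),
                          fit = NULL),
                     class = "fd_candidate"))
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  cf <- if (inherits(fit, "merMod")) {
    s <- summary(fit)$coefficients
    tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                   std_error = s[, "Std. Error"])
  } else {
    s <- summary(fit)$coefficients
    tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2])
  }
  structure(
    list(terms = terms, formula = fml, family = family, flat = flat,
         converged = converged, note = note,
         logLik = as.numeric(ll), k = k,
         aic = -2 * as.numeric(ll) + 2 * k,
         coefs = cf, fit = fit),
    class = "fd_candidate"
  )
}

#' Rank candidates by AIC and select the confidence set
#'
#' Computes `delta = AIC - min(AIC)` over converged candidates, selects
#' models with `delta < threshold` (strict inequality, so a model at
#' exactly the threshold is excluded) and renormalizes Akaike weights
#' `exp(-delta/2)` over the selected set. AIC ties are broken by ascending
#' parameter count, then model id, so ranking is deterministic.
#'
#' @param candidates list of `fd_candidate` fits.
#' @param delta_threshold selection cutoff on delta-AIC (default 4).
#' @return tibble with one row per converged candidate: `model_id`,
#'   `terms` (list-column), `k`, `logLik`, `aic`, `delta`, `weight`
#'   (NA outside the selected set), `selected`. Non-converged candidates
#'   are dropped; their count is in the `n_dropped` attribute.
#' @export
rank_and_select <- function(candidates, delta_threshold = 4) {
  tab <- tibble::tibble(
    model_id = seq_along(candidates),
    terms = lapply(candidates, `[[`, "terms"),
    k = vapply(candidates, `[[`, numeric(1), "k"),
    logLik = vapply(candidates, `[[`, numeric(1), "logLik"),
    aic = vapply(candidates, `[[`, numeric(1), "aic"),
    converged = vapply(candidates, `[[`, logical(1), "converged")
  )
  n_dropped <- sum(!tab$converged)
  if (n_dropped > 0) {
    message(n_dropped, " candidate(s) dropped for non-convergence")
  }
  tab <- tab[tab$converged, ]
  if (nrow(tab) == 0) stop("no converged candidate model", call. = FALSE)
  tab <- tab[order(tab$aic, tab$k, tab$model_id), ]
  tab$delta <- tab$aic - tab$aic[1]
  tab$selected <- tab$delta < delta_threshold
  w <- exp(-tab$delta[tab$selected] / 2)
  tab$weight <- NA_real_
  tab$weight[tab$selected] <- w / sum(w)
  tab$converged <- NULL
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Full (zero-substitution) model averaging
#'
#' Averages each coefficient over *all* selected models, substituting 0
#' (with zero standard error) in models where the term is absent; the
#' averaged standard error combines within-model sampling variance with
#' between-model spread,
#' `se = sqrt(sum_i w_i (se_i^2 + (b_i - b_bar)^2))`. 95% confidence
#' limits use the normal 1.96 multiplier, and `abs_z` is
#' `|estimate / se|`.
#'
#' @param candidates list of `fd_candidate` fits (as passed to
#'   [rank_and_select()]).
#' @param selection the tibble returned by [rank_and_select()].
#' @return an `fd_avg` object with a coefficient table (`term`,
#'   `estimate`, `std_error`, `abs_z`, `conf_low`, `conf_high`,
#'   `n_models`), the selection table, and the best candidate.
#' @export
full_average <- function(candidates, selection = rank_and_select(candidates)) {
  sel <- selection[selection$selected, ]
  sel_fits <- candidates[sel$model_id]
  all_terms <- unique(unlist(lapply(sel_fits, function(f) f$coefs$term)))
  est <- se <- matrix(0, nrow = length(all_terms), ncol = nrow(sel),
                      dimnames = list(all_terms, NULL))
  present <- matrix(FALSE, length(all_terms), nrow(sel),
                    dimnames = list(all_terms, NULL))
  for (j in seq_along(sel_fits)) {
    cf <- sel_fits[[j]]$coefs
    est[cf$term, j] <- cf$estimate
    se[cf$term, j] <- cf$std_error
    present[cf$term, j] <- TRUE
  }
  w <- sel$weight
  b_bar <- drop(est %*% w)
  se_bar <- sqrt(drop((se^2 + (est - b_bar)^2) %*% w))
  coefs <- tibble::tibble(
    term = all_terms,
    estimate = unname(b_bar),
    std_error = unname(se_bar),
    abs_z = abs(unname(b_bar) / unname(se_bar)),
    conf_low = unname(b_bar - 1.96 * se_bar),
    conf_high = unname(b_bar + 1.96 * se_bar),
    n_models = unname(rowSums(present))
  )
  best <- sel_fits[[1]]
  structure(
    list(coefficients = coefs, selection = selection, best = best,
         family = best$family, response = all.vars(best$formula)[1],
         n_candidates = length(candidates), n_selected = nrow(sel)),
    class = "fd_avg"
  )
}

#' Marginal and conditional pseudo-R-squared of a Gaussian fit
#'
#' Variance-partition R2 for Gaussian mixed models: the marginal value is
#' the fixed-effect variance over the total (fixed + random intercepts +
#' residual); the conditional value adds the random-intercept variance to
#' the numerator. For a flat (ordinary least squares) fit the random
#' variance is zero and the two coincide. Poisson fits are not supported
#' and return `NA` with a warning.
#'
#' @param candidate an `fd_candidate`.
#' @return named list with `marginal` and `conditional`.
#' @export
r_squared <- function(candidate) {
  fit <- candidate$fit
  if (candidate$family != "gaussian") {
    warning("pseudo-R2 implemented for gaussian fits only", call. = FALSE)
    return(list(marginal = NA_real_, conditional = NA_real_))
  }
  if (inherits(fit, "merMod")) {
    var_f <- stats::var(drop(stats::model.matrix(fit) %*% lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    var_e <- stats::sigma(fit)^2
  } else {
    var_f <- stats::var(stats::fitted(fit))
    var_r <- 0
    var_e <- stats::sigma(fit)^2
  }
  tot <- var_f + var_r + var_e
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Multimodel inference in one call
#'
#' Enumerates all marginality-respecting candidates from `predictors` and
#' `time`, fits each by maximum likelihood, ranks by AIC, selects the
#' `delta < delta_threshold` set, and returns the full averaged model.
#'
#' @inheritParams fit_candidate
#' @param predictors character vector of predictor columns.
#' @param time time column name or `NULL`.
#' @param delta_threshold delta-AIC selection cutoff (default 4).
#' @return an `fd_avg` with an `r2` element (marginal/conditional of the
#'   best model, Gaussian fits only).
#' @export
fit_multimodel <- function(data, response, predictors, time = "time",
                           family = c("gaussian", "poisson"),
                           grouping = c("transect", "plot"), flat = FALSE,
                           delta_threshold = 4) {
  family <- match.arg(family)
  cand_tab <- enumerate_candidates(predictors, time)
  fits <- lapply(cand_tab$terms, fit_candidate, data = data,
                 response = response, family = family, grouping = grouping,
                 flat = flat)
  sel <- rank_and_select(fits, delta_threshold = delta_threshold)
  avg <- full_average(fits, sel)
  avg$r2 <- if (family == "gaussian") r_squared(avg$best)
            else list(marginal = NA_real_, conditional = NA_real_)
  avg
}

#' @export
print.fd_avg <- function(x, ...) {
  cat("<full averaged model: ", x$response, " (", x$family, "), ",
      x$n_selected, "/", x$n_candidates, " candidates selected>\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fd_avg <- function(x, ...) {
  x$coefficients
}

#' @exportS3Method generics::glance
glance.fd_avg <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    family = x$family,
    n_candidates = x$n_candidates,
    n_selected = x$n_selected,
    min_aic = min(x$selection$aic),
    best_weight = max(x$selection$weight, na.rm = TRUE),
    r2_marginal = if (is.null(x$r2)) NA_real_ else x$r2$marginal,
    r2_conditional = if (is.null(x$r2)) NA_real_ else x$r2$conditional
  )
}

#' Coefficient forest plot for an averaged model
#'
#' @param object an `fd_avg`.
#' @param ... unused.
#' @return a ggplot: averaged estimates with 95% confidence intervals,
#'   intercept excluded.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_avg <- function(object, ...) {
  dat <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(
      x = "full averaged estimate (95% CI)", y = NULL,
      title = paste0(object$response, " (", object$family, ")")
    ) +
    ggplot2::theme_minimal()
}
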