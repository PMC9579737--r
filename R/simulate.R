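#' Configuration of the synthetic succession benchmark
#'
#' Bundles every knob of the generator: pool size and trait families,
#' experimental layout (assemblage richness targets, replicate transects,
#' survey years), and the three succession mechanisms the generator encodes
#' -- progressive loss of sown species moderated by functional redundancy,
#' dominance shifts toward high-LDMC (resource-conservative) species, and
#' invasion by unsown species at a rate declining with the sown community's
#' functional dispersion.
#'
#' Defaults emulate the reference field layout: a 151-species pool, eight
#' assemblages (two disjoint species lists crossing low/high functional
#' dispersion with 9/14/29 sown species), six replicate transects in three
#' blocks, four annual surveys, equal initial seed proportions.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_pool species-pool size.
#' @param richness_targets sown species counts for the low/medium/high
#'   richness levels.
#' @param n_lists number of disjoint dicot lists.
#' @param replicates replicate transects (each carries every assemblage
#'   once; two consecutive transects form a block).
#' @param years number of annual surveys after sowing.
#' @param total_cover per-year total plant cover schedule (percent; eye
#'   estimates may exceed 100).
#' @param survival_base,redundancy_effect per-year persistence of an
#'   established species follows
#'   `plogis(survival_base + redundancy_effect * FR)` with `FR` the
#'   assemblage's sown functional redundancy.
#' @param annual_penalty,biennial_penalty logit penalties applied to the
#'   persistence of annuals (from year 2) and biennials (from year 3).
#' @param peripheral_loss selectivity of competitive exclusion: a sown
#'   species' survival logit is reduced by `peripheral_loss` per standard
#'   deviation of its distance from its assemblage's trait-space centroid
#'   (functionally extreme species are excluded first, which is what makes
#'   species loss erode dispersion).
#' @param annual_boost year-1 cover multiplier for annual species (fast
#'   establishment), and `annual_decay`/`biennial_decay` the multipliers
#'   once their life cycle closes; `biennial_boost` applies to biennials in
#'   their first two years.
#' @param ldmc_dominance selection gradient: surviving species' cover is
#'   multiplied by `exp(ldmc_dominance * z(LDMC) + noise)` each year.
#' @param growth_noise lognormal sd of the yearly per-species cover change
#'   (a process drift: it accumulates over years).
#' @param obs_noise lognormal sd of the per-species eye-estimate error at
#'   survey time (does not accumulate).
#' @param invasion_rate,invasion_fd_effect unsown arrivals per plot-year are
#'   `Poisson(invasion_rate * exp(-invasion_fd_effect * sown FDis))`, with
#'   FDis the realized dispersion of the sown survivors (so
#'   `invasion_rate` is the hypothetical rate at zero dispersion).
#' @param invasion_year_decay multiplier on the arrival rate per additional
#'   year (sward closure progressively shuts colonization windows).
#' @param unsown_penalty logit penalty on the yearly persistence of unsown
#'   plants in the established sward.
#' @param invader_weight_annual sampling weight of annual species among
#'   arrivals (spontaneous colonists of arable land are mostly annual
#'   weeds); perennials and biennials have weight 1.
#' @param invader_cover_meanlog,invader_cover_sdlog lognormal initial cover
#'   of arrivals.
#' @param design_weights named sampling weights by regeneration strategy
#'   for the assemblage design search (seed mixtures for perennial strips
#'   favor perennials); strategies not named have weight 1.
#' @param cover_noise lognormal sd of the plot-year observation error on
#'   total cover.
#' @param sd_transect,sd_plot random-intercept sds (log-cover scale) for
#'   transects and plots.
#' @param extinction_cover cover (percent) below which a species is lost.
#' @param missing_year if `TRUE`, only transects 4-6 are surveyed in year 2
#'   (a mid-study partial campaign).
#' @param n_search subsets scored per assemblage in the design search.
#' @param trait_subset trait preset used for design scoring and the
#'   simulator's redundancy/dispersion mechanisms.
#' @return a `fd_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_pool = 151,
                       richness_targets = c(low = 9, medium = 14, high = 29),
                       n_lists = 2, replicates = 6, years = 4,
                       total_cover = c(70, 85, 95, 100),
                       survival_base = -2.8, redundancy_effect = 10,
                       peripheral_loss = 3.5,
                       annual_penalty = -0.6, biennial_penalty = -0.6,
                       annual_boost = 10, annual_decay = 0.35,
                       biennial_boost = 1.5, biennial_decay = 0.35,
                       ldmc_dominance = 0.25, growth_noise = 0.25,
                       obs_noise = 0.15,
                       invasion_rate = 80, invasion_fd_effect = 3,
                       invasion_year_decay = 0.3, unsown_penalty = -0.8,
                       invader_weight_annual = 6,
                       invader_cover_meanlog = log(5), invader_cover_sdlog = 0.6,
                       design_weights = c(annual = 0.15, biennial = 0.7),
                       cover_noise = 0.25, sd_transect = 0.15, sd_plot = 0.1,
                       extinction_cover = 0.02, missing_year = FALSE,
                       n_search = 200, trait_subset = "all16") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pool > 0, cfg$years >= 1, cfg$replicates >= 1,
            length(cfg$total_cover) >= cfg$years,
            cfg$extinction_cover >= 0)
  structure(cfg, class = "fd_sim_config")
}

regen_levels <- function() {
  c("annual", "biennial", "stationary_perennial",
    "aboveground_creeping_perennial", "belowground_creeping_perennial")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic species pool with realistic mixed-type traits
#'
#' Draws `n_pool` species with the full 16-trait schema. Numeric traits come
#' from lognormal/normal families bracketing field scales (LDMC 100-400
#' mg/g, SLA 5-45 mm2/mg, flowering heights tens of cm, onset around
#' early summer); categorical traits use the standard level sets, and the
#' composite regeneration strategy couples life span with Grime C/R scores,
#' Raunkiaer life form and LDMC (perennials lean conservative). Pairwise
#' correlations between numeric traits are screened at |r| <= 0.70 by
#' rejection; failure after `max_attempts` raises an error reporting the
#' best achieved maximum.
#'
#' @param config a [sim_config()].
#' @param missingness optional named fractions of values to blank per trait
#'   (e.g. `c(nectar_depth = 0.19)`).
#' @param max_attempts rejection-sampling attempts for the correlation
#'   screen.
#' @return a `fd_traits` table of `n_pool` species (`sp001`, ...).
#' @export
generate_pool <- function(config = sim_config(), missingness = NULL,
                          max_attempts = 20) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_pool
  best_r <- Inf
  for (attempt in seq_len(max_attempts)) {
    strat <- sample(regen_levels(), n, replace = TRUE,
                    prob = c(0.30, 0.15, 0.27, 0.14, 0.14))
    perennial <- !strat %in% c("annual", "biennial")
    raunk <- ifelse(strat == "annual", "therophyte",
             ifelse(strat == "biennial", "hemicryptophyte",
                    sample(c("hemicryptophyte", "geophyte", "chamaephyte"),
                           n, replace = TRUE, prob = c(0.6, 0.25, 0.15))))
    mu_c <- c(annual = 30, biennial = 50)[strat]
    mu_c[is.na(mu_c)] <- 65
    mu_r <- c(annual = 70, biennial = 40)[strat]
    mu_r[is.na(mu_r)] <- 20
    mu_ldmc <- c(annual = 180, biennial = 200)[strat]
    mu_ldmc[is.na(mu_ldmc)] <- 230

    dat <- tibble::tibble(
      species = sprintf("sp%03d", seq_len(n)),
      nectar_amount = sample(0:2, n, replace = TRUE, prob = c(0.3, 0.45, 0.25)),
      extrafloral_nectar = stats::rbinom(n, 1, 0.15),
      flower_diameter = clamp(stats::rlnorm(n, log(1.5), 0.7), 0.1, 15),
      flower_color = sample(c("white", "yellow", "purple", "pink", "blue",
                              "green"), n, replace = TRUE,
                            prob = c(0.28, 0.30, 0.16, 0.12, 0.08, 0.06)),
      uv_pattern = sample(c("present", "absent"), n, replace = TRUE,
                          prob = c(0.35, 0.65)),
      flowering_onset = round(clamp(stats::rnorm(n, 22, 5), 10, 35)),
      flowering_duration = clamp(stats::rlnorm(n, log(8), 0.5), 2, 40),
      nectar_depth = clamp(stats::rlnorm(n, log(0.3), 0.7), 0.02, 3),
      leaf_distribution = sample(c("rosette", "semi_rosette", "along_stem"),
                                 n, replace = TRUE,
                                 prob = c(0.30, 0.35, 0.35)),
      flowering_height = clamp(stats::rlnorm(n, log(50), 0.6), 5, 250),
      raunkiaer_life_form = raunk,
      grime_c = clamp(stats::rnorm(n, mu_c, 15), 0, 100),
      grime_r = clamp(stats::rnorm(n, mu_r, 15), 0, 100),
      sla = clamp(stats::rnorm(n, 25, 6), 5, 45),
      ldmc = clamp(stats::rnorm(n, mu_ldmc, 35), 100, 400),
      regeneration_strategy = strat
    )
    sch <- default_trait_schema()
    num_traits <- sch$trait[sch$kind %in% c("numeric", "ordinal")]
    r <- stats::cor(as.matrix(dat[, num_traits]))
    diag(r) <- 0
    max_r <- max(abs(r))
    if (max_r <= 0.70) {
      tt <- trait_table(dat, sch)
      if (!is.null(missingness)) {
        for (tr in names(missingness)) {
          blank <- sample(n, round(missingness[[tr]] * n))
          tt[[tr]][blank] <- NA
        }
      }
      return(tt)
    }
    best_r <- min(best_r, max_r)
  }
  stop("correlation screen failed after ", max_attempts,
       " attempts; best max |r| = ", signif(best_r, 3), call. = FALSE)
}

strategy_growth <- function(strategy, year, config) {
  dplyr::case_when(
    strategy == "annual" & year == 1 ~ config$annual_boost,
    strategy == "annual" ~ config$annual_decay,
    strategy == "biennial" & year <= 2 ~ config$biennial_boost,
    strategy == "biennial" ~ config$biennial_decay,
    TRUE ~ 1.2
  )
}

strategy_logit_penalty <- function(strategy, year, config) {
  dplyr::case_when(
    strategy == "annual" & year >= 2 ~ config$annual_penalty,
    strategy == "biennial" & year >= 3 ~ config$biennial_penalty,
    TRUE ~ 0
  )
}

#' Simulate multi-year succession of sown assemblages
#'
#' Mechanistic generator of survey records. Each plot starts from its
#' design's equal sown proportions; every year, (1) each established
#' species persists with probability
#' `plogis(survival_base + redundancy_effect * FR)` plus a life-cycle
#' penalty for annuals and biennials, (2) survivors' cover is multiplied by
#' `exp(ldmc_dominance * z(LDMC) + noise)` and a strategy-specific factor
#' (annuals boom in year 1 and fade after), (3) unsown arrivals enter as a
#' Poisson draw whose rate decays with the realized functional dispersion
#' of the sown survivors, and (4) covers are rescaled to the total-cover
#' schedule with multiplicative observation noise plus transect and plot
#' random intercepts on the log scale. Species falling below
#' `extinction_cover` are lost.
#'
#' @param designs named list of `fd_design` objects.
#' @param pool a `fd_traits` table covering all design species plus the
#'   invader pool.
#' @param config a [sim_config()].
#' @return a survey tibble (`plot`, `transect`, `block`, `assemblage`,
#'   `year`, `species`, `cover`, `sown`) with the config attached as the
#'   `config` attribute.
#' @export
simulate_succession <- function(designs, pool, config = sim_config()) {
  miss <- setdiff(unique(unlist(lapply(designs, `[[`, "species"))),
                  pool$species)
  if (length(miss) > 0) {
    stop("design species absent from pool: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed + 2L)

  prepped <- prepare_traits(pool, config$trait_subset)
  d <- gower_distance(prepped)
  emb <- trait_embedding(d)
  z_ldmc <- stats::setNames(as.numeric(scale(pool$ldmc)), pool$species)
  strat <- stats::setNames(pool$regeneration_strategy, pool$species)
  fr_design <- vapply(designs, function(dg) {
    functional_redundancy(dg$sown_proportion, d)
  }, numeric(1))
  # standardized distance of each sown species from its design's centroid
  periph <- lapply(designs, function(dg) {
    x <- emb$points[dg$species, , drop = FALSE]
    dev <- sweep(x, 2, colMeans(x))
    stats::setNames(as.numeric(scale(sqrt(rowSums(dev^2)))), dg$species)
  })

  n_assemblage <- length(designs)
  layout <- purrr::map_dfr(seq_len(config$replicates), function(t) {
    tibble::tibble(
      transect = t,
      block = ceiling(t / 2),
      plot = seq_len(n_assemblage),
      assemblage = sample(names(designs))
    )
  })
  u_t <- stats::setNames(stats::rnorm(config$replicates, 0, config$sd_transect),
                         seq_len(config$replicates))
  records <- vector("list", nrow(layout))

  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    dg <- designs[[row$assemblage]]
    u_p <- stats::rnorm(1, 0, config$sd_plot)
    s0 <- length(dg$species)
    state <- tibble::tibble(
      species = dg$species,
      cover = 100 * unname(dg$sown_proportion[dg$species]),
      sown = TRUE
    )
    plot_rec <- vector("list", config$years)
    for (y in seq_len(config$years)) {
      # persistence, moderated by redundancy and life cycle
      pz <- periph[[row$assemblage]][state$species]
      pz[is.na(pz)] <- 0  # unsown species carry no design-periphery score
      logit_s <- config$survival_base +
        config$redundancy_effect * fr_design[[row$assemblage]] +
        strategy_logit_penalty(strat[state$species], y, config) -
        config$peripheral_loss * pz +
        ifelse(state$sown, 0, config$unsown_penalty)
      survive <- stats::runif(nrow(state)) < stats::plogis(logit_s)
      state <- state[survive, , drop = FALSE]

      if (nrow(state) > 0) {
        # dominance shift toward resource-conservative (high-LDMC) species
        gr <- exp(config$ldmc_dominance * z_ldmc[state$species] +
                    stats::rnorm(nrow(state), 0, config$growth_noise)) *
          strategy_growth(strat[state$species], y, config)
        state$cover <- state$cover * gr
      }

      # invasion declines with realized sown dispersion
      sown_alive <- state[state$sown, ]
      fdis_sown <- if (nrow(sown_alive) > 0) {
        fdis(stats::setNames(sown_alive$cover, sown_alive$species), emb)
      } else 0
      rate <- config$invasion_rate *
        exp(-config$invasion_fd_effect * fdis_sown) *
        config$invasion_year_decay^(y - 1)
      n_new <- stats::rpois(1, rate)
      candidates <- setdiff(pool$species, c(state$species, dg$species))
      if (n_new > 0 && length(candidates) > 0) {
        w_inv <- ifelse(strat[candidates] == "annual",
                        config$invader_weight_annual, 1)
        newcomers <- sample(candidates, min(n_new, length(candidates)),
                            prob = w_inv)
        state <- dplyr::bind_rows(state, tibble::tibble(
          species = newcomers,
          cover = stats::rlnorm(length(newcomers),
                                config$invader_cover_meanlog,
                                config$invader_cover_sdlog),
          sown = FALSE
        ))
      }

      if (nrow(state) == 0 || sum(state$cover) == 0) {
        warning("plot ", row$plot, " transect ", row$transect,
                " empty in year ", y, call. = FALSE)
        next
      }
      target <- config$total_cover[y] *
        exp(u_t[[row$transect]] + u_p + stats::rnorm(1, 0, config$cover_noise))
      state$cover <- state$cover * target / sum(state$cover)
      state <- state[state$cover >= config$extinction_cover, , drop = FALSE]

      if (nrow(state) > 0) {
        observed <- state$cover *
          exp(stats::rnorm(nrow(state), 0, config$obs_noise))
        plot_rec[[y]] <- tibble::tibble(
          plot = row$plot, transect = row$transect, block = row$block,
          assemblage = row$assemblage, year = y,
          species = state$species,
          cover = round(observed, 3),
          sown = state$sown
        )
      }
    }
    records[[i]] <- dplyr::bind_rows(plot_rec)
  }

  survey <- dplyr::bind_rows(records)
  if (config$missing_year && config$years >= 2) {
    keep_t <- seq(ceiling(config$replicates / 2) + 1, config$replicates)
    survey <- survey[survey$year != 2 | survey$transect %in% keep_t, ]
  }
  attr(survey, "config") <- config
  survey
}

#' Fraction of sown species persisting to a given year
#'
#' @param survey a survey tibble.
#' @param designs the design list that produced it.
#' @param year survey year (default the last).
#' @return tibble: `assemblage`, `persistence` (mean over replicate plots
#'   of the fraction of the sown list still present).
#' @export
sown_persistence <- function(survey, designs, year = max(survey$year)) {
  s_tot <- stats::setNames(
    vapply(designs, function(d) length(d$species), numeric(1)),
    vapply(designs, function(d) d$assemblage_id, character(1))
  )
  survey |>
    dplyr::filter(.data$year == !!year, .data$sown, .data$cover > 0) |>
    dplyr::group_by(.data$assemblage, .data$transect, .data$plot) |>
    dplyr::summarise(n_present = dplyr::n_distinct(.data$species),
                     .groups = "drop") |>
    dplyr::mutate(frac = .data$n_present / s_tot[.data$assemblage]) |>
    dplyr::group_by(.data$assemblage) |>
    dplyr::summarise(persistence = mean(.data$frac), .groups = "drop")
}

#' Build the full synthetic benchmark bundle
#'
#' Generates the pool, searches the eight designs (three mandatory
#' "grass-analogue" perennials shared by all assemblages, two disjoint
#' dicot lists), and simulates the multi-year survey. Optionally writes
#' everything to disk in the package's standard dialects (pool CSV, one
#' design JSON each, survey CSV, config YAML) so the bundle round-trips
#' through the readers.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list with `pool`, `designs`, `survey`, `config`.
#' @export
make_benchmark <- function(config = sim_config(), dir = NULL) {
  pool <- generate_pool(config)
  perennials <- pool$species[pool$regeneration_strategy == "stationary_perennial"]
  mandatory <- utils::head(perennials, 3)
  w <- config$design_weights[pool$regeneration_strategy]
  w[is.na(w)] <- 1
  spec <- design_spec(
    pool,
    richness_targets = config$richness_targets,
    n_lists = config$n_lists,
    mandatory = mandatory,
    trait_subset = config$trait_subset,
    n_search = config$n_search,
    sample_weights = stats::setNames(w, pool$species)
  )
  designs <- design_assemblages(spec, seed = config$seed + 1L)
  survey <- simulate_succession(designs, pool, config)
  bundle <- list(pool = pool, designs = designs, survey = survey,
                 config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(pool, file.path(dir, "pool.csv"))
    dir.create(file.path(dir, "designs"), showWarnings = FALSE)
    for (dg in designs) {
      write_design(dg, file.path(dir, "designs",
                                 paste0(dg$assemblage_id, ".json")))
    }
    write_survey(survey, file.path(dir, "survey.csv"))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
    outputs <- c("pool.csv", "survey.csv", "config.yaml",
                 file.path("designs", paste0(names(designs), ".json")))
    jsonlite::write_json(run_manifest(config, outputs), 
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Reproducibility manifest for a pipeline run
#'
#' Records what is needed to rerun a stochastic stage bit-identically: the
#' package version, the master seed, a digest of the configuration, and the
#' output files produced.
#'
#' @param config a [sim_config()] (or any list of parameters).
#' @param outputs character vector of output paths.
#' @return a list suitable for JSON serialization.
#' @export
run_manifest <- function(config, outputs = character()) {
  cfg <- unclass(config)
  serialized <- paste(names(cfg),
                      vapply(cfg, function(x)
                        paste(format(x, digits = 15), collapse = ","), ""),
                      sep = "=", collapse = ";")
  # positional checksum: order- and value-sensitive, dependency-free
  bytes <- utf8ToInt(serialized)
  digest <- sum(bytes * seq_along(bytes)) %% 2147483647
  list(
    package = "flordyn",
    version = as.character(utils::packageVersion("flordyn")),
    seed = cfg$seed,
    config_digest = unname(digest),
    outputs = outputs,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
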