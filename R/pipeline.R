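#' Per plot-year summary of the unsown (spontaneous) flora
#'
#' Richness and total cover of unsown species per plot-year, alongside the
#' realized richness and functional dispersion (competition-trait preset)
#' of the sown fraction. Plot-years with no unsown species score zero on
#' both unsown columns.
#'
#' @param survey survey tibble with sown flags.
#' @param traits `fd_traits` covering the surveyed species.
#' @param designs design list (for the initial-characteristics factors).
#' @param competition_subset trait preset for the sown-dispersion column.
#' @return tibble keyed by (assemblage, transect, plot, block, year).
#' @export
invasion_table <- function(survey, traits, designs,
                           competition_subset = "competition9") {
  if (!is.logical(survey$sown)) stop("sown flags required", call. = FALSE)
  unsown <- survey |>
    dplyr::filter(.data$cover > 0) |>
    dplyr::group_by(.data$assemblage, .data$transect, .data$plot,
                    .data$block, .data$year) |>
    dplyr::summarise(
      unsown_richness = sum(!.data$sown),
      unsown_cover = sum(.data$cover[!.data$sown]),
      sown_richness = sum(.data$sown),
      .groups = "drop"
    )
  sown_metrics <- community_metrics(survey, traits,
                                    trait_subset = competition_subset,
                                    sown_only = TRUE) |>
    dplyr::select("assemblage", "transect", "plot", "block", "year",
                  sown_fdis = "fdis")
  unsown |>
    dplyr::left_join(sown_metrics,
                     by = c("assemblage", "transect", "plot", "block",
                            "year")) |>
    attach_design_factors(designs)
}

#' Join design metadata onto a per plot-year table
#'
#' Adds `initial_richness` (ordered low/medium/high), `initial_fd`
#' (low/high) and `time` (= survey year, years since sowing) from the
#' design list.
#'
#' @param tab tibble with an `assemblage` column and a `year` column.
#' @param designs list of `fd_design` objects.
#' @return the tibble with factors attached.
#' @export
attach_design_factors <- function(tab, designs) {
  ds <- design_summary(designs)
  missing_ids <- setdiff(unique(tab$assemblage), ds$assemblage)
  if (length(missing_ids) > 0) {
    stop("no design for assemblage id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  tab |>
    dplyr::left_join(ds, by = "assemblage") |>
    dplyr::mutate(
      initial_richness = factor(.data$richness_level,
                                levels = c("low", "medium", "high")),
      initial_fd = factor(.data$fd_level, levels = c("low", "high")),
      time = as.numeric(.data$year)
    ) |>
    dplyr::select(-"richness_level", -"fd_level")
}

#' Temporal-dynamics analysis of realized diversity
#'
#' The first-line analysis: per plot-year community metrics, then one
#' multimodel inference per response -- realized functional dispersion
#' (Gaussian), species richness (Poisson) and Simpson's evenness
#' (Gaussian) -- against initial species richness (3-level factor),
#' initial functional dispersion (2-level factor) and time since sowing
#' (continuous), with all predictor-by-time interactions and plot nested in
#' transect as random intercepts. Two robustness subsets rerun the
#' analysis on (a) medium-richness assemblages only (isolating the
#' functional-dispersion contrast) and (b) high-dispersion assemblages only
#' (isolating the richness gradient).
#'
#' @param survey survey tibble.
#' @param traits `fd_traits` table covering all surveyed species.
#' @param designs list of `fd_design` objects for every surveyed
#'   assemblage.
#' @param trait_subset preset for the distance-based metrics (default the
#'   11-trait plant-arthropod set).
#' @param delta_threshold delta-AIC cutoff.
#' @param subsets run the two robustness subsets too.
#' @return list of class `fd_dynamics`: `metrics` (per plot-year tibble
#'   with design factors), `models` (named list of `fd_avg`:
#'   `fdis`, `richness`, `evenness`), and when requested
#'   `subset_medium_richness` / `subset_high_fd` lists of the same shape.
#' @export
run_dynamics_analysis <- function(survey, traits, designs,
                                  trait_subset = "arthropod11",
                                  delta_threshold = 4, subsets = TRUE) {
  metrics <- community_metrics(survey, traits, trait_subset = trait_subset,
                               cwm_traits = "ldmc") |>
    attach_design_factors(designs)
  fit_three <- function(dat, predictors) {
    list(
      fdis = fit_multimodel(dat, "fdis", predictors,
                            family = "gaussian",
                            delta_threshold = delta_threshold),
      richness = fit_multimodel(dat, "richness", predictors,
                                family = "poisson",
                                delta_threshold = delta_threshold),
      evenness = fit_multimodel(dat, "evenness", predictors,
                                family = "gaussian",
                                delta_threshold = delta_threshold)
    )
  }
  out <- list(
    metrics = metrics,
    models = fit_three(metrics, c("initial_richness", "initial_fd"))
  )
  if (subsets) {
    med <- dplyr::filter(metrics, .data$initial_richness == "medium")
    hf <- dplyr::filter(metrics, .data$initial_fd == "high")
    out$subset_medium_richness <- fit_three(med, "initial_fd")
    out$subset_high_fd <- fit_three(hf, "initial_richness")
  }
  class(out) <- "fd_dynamics"
  out
}

#' @export
print.fd_dynamics <- function(x, ...) {
  cat("<temporal-dynamics analysis: ", nrow(x$metrics), " plot-years>\n",
      sep = "")
  for (nm in names(x$models)) {
    cat("\n--", nm, "--\n")
    print(x$models[[nm]])
  }
  invisible(x)
}

#' Standardized-dispersion analysis with a categorical year axis
#'
#' Computes the name-shuffling SES of functional dispersion for every
#' plot-year (see [ses_table()]), then relates it to the initial assemblage
#' characteristics by multimodel inference in which the time axis enters as
#' a categorical year factor (indicator terms, no slope), reflecting the
#' non-linear temporal profile of standardized dispersion. Plot-years with
#' an undefined SES (degenerate null) are excluded; their count is
#' reported in the `n_undefined` element.
#'
#' @inheritParams run_dynamics_analysis
#' @param pool shuffle pool (default: every species in `traits`).
#' @param n_iter shuffles per plot-year (default 1000).
#' @param seed master seed; per plot-year seeds are derived from it and
#'   recorded in the SES table.
#' @return list of class `fd_ses_analysis`: `ses` (per plot-year tibble
#'   with seeds), `model` (`fd_avg`), `n_undefined`.
#' @export
run_ses_analysis <- function(survey, traits, designs,
                             pool = traits$species,
                             trait_subset = "arthropod11",
                             n_iter = 1000, seed = 1L,
                             delta_threshold = 4) {
  ses <- ses_table(survey, traits, pool = pool, trait_subset = trait_subset,
                   n_iter = n_iter, seed = seed) |>
    attach_design_factors(designs)
  n_undefined <- sum(!ses$ses_defined)
  usable <- dplyr::filter(ses, .data$ses_defined)
  usable$year_f <- factor(usable$year)
  model <- fit_multimodel(usable, "ses",
                          c("initial_richness", "initial_fd"),
                          time = "year_f", family = "gaussian",
                          delta_threshold = delta_threshold)
  structure(list(ses = ses, model = model, n_undefined = n_undefined),
            class = "fd_ses_analysis")
}

#' Invasion-resistance analysis of the spontaneous vegetation
#'
#' Summarizes the unsown (spontaneously arriving) fraction of each
#' plot-year -- species richness and total cover -- and relates both to the
#' sown community, twice: once against the *initial* assemblage
#' characteristics (richness level, dispersion level, time), and once
#' against the *realized* sown community (observed sown richness and sown
#' functional dispersion computed on the 9-trait competition preset,
#' continuous, plus time). Plot-years whose sown fraction is empty are
#' dropped from the realized run.
#'
#' @inheritParams run_dynamics_analysis
#' @param competition_subset preset for the sown-dispersion predictor.
#' @return list of class `fd_invasion`: `table` (per plot-year tibble),
#'   `initial` and `realized` (named lists of `fd_avg` for `unsown_richness`
#'   (Poisson) and `unsown_cover` (Gaussian)).
#' @export
run_invasion_analysis <- function(survey, traits, designs,
                                  competition_subset = "competition9",
                                  delta_threshold = 4) {
  tab <- invasion_table(survey, traits, designs,
                        competition_subset = competition_subset)

  fit_two <- function(dat, predictors) {
    list(
      unsown_richness = fit_multimodel(dat, "unsown_richness", predictors,
                                       family = "poisson",
                                       delta_threshold = delta_threshold),
      unsown_cover = fit_multimodel(dat, "unsown_cover", predictors,
                                    family = "gaussian",
                                    delta_threshold = delta_threshold)
    )
  }
  realized_dat <- dplyr::filter(tab, !is.na(.data$sown_fdis),
                                .data$sown_richness > 0)
  structure(
    list(
      table = tab,
      initial = fit_two(tab, c("initial_richness", "initial_fd")),
      realized = fit_two(realized_dat, c("sown_richness", "sown_fdis"))
    ),
    class = "fd_invasion"
  )
}
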