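#' Community diversity metrics
#'
#' A community is a named non-negative abundance vector (percent cover or
#' seed proportions); relative abundances `p_j = a_j / sum(a)` are formed
#' internally, so totals above 100 are fine (cover overlap convention).
#'
#' * `simpson_diversity()` is the Gini-Simpson index `D = 1 - sum(p^2)`:
#'   the probability that two randomly drawn individuals belong to
#'   different species.
#' * `simpson_evenness()` is inverse-Simpson over richness,
#'   `E = (1 / sum(p^2)) / S`, equal to 1 for perfectly even abundances.
#' * `rao_q()` is Rao's quadratic entropy `Q = sum_ij d_ij p_i p_j`, the
#'   expected trait dissimilarity between two random individuals.
#' * `functional_redundancy()` is `FR = D - Q`, non-negative whenever
#'   `d_ij <= 1`; high values mean abundant species are functionally
#'   similar.
#' * `fdis()` is functional dispersion: the abundance-weighted mean
#'   distance of species from the abundance-weighted community centroid in
#'   the trait-space embedding.
#'
#' @param community named numeric vector of abundances `a_j >= 0` with at
#'   least one positive entry.
#' @return a single number.
#' @name diversity_metrics
NULL

community_p <- function(community) {
  if (length(community) == 0 || is.null(names(community))) {
    stop("community must be a non-empty named abundance vector", call. = FALSE)
  }
  if (any(community < 0)) stop("negative abundance", call. = FALSE)
  community <- community[community > 0]
  if (length(community) == 0) stop("empty community (all zero)", call. = FALSE)
  community / sum(community)
}

#' @rdname diversity_metrics
#' @export
simpson_diversity <- function(community) {
  p <- community_p(community)
  1 - sum(p^2)
}

#' @rdname diversity_metrics
#' @export
simpson_evenness <- function(community) {
  p <- community_p(community)
  (1 / sum(p^2)) / length(p)
}

#' @rdname diversity_metrics
#' @param d an `fd_dissim` Gower matrix covering the community's species.
#' @export
rao_q <- function(community, d) {
  p <- community_p(community)
  miss <- setdiff(names(p), rownames(d))
  if (length(miss) > 0) {
    stop("species missing from dissimilarity matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dm <- unclass(d)[names(p), names(p), drop = FALSE]
  as.numeric(p %*% dm %*% p)
}

#' @rdname diversity_metrics
#' @export
functional_redundancy <- function(community, d) {
  simpson_diversity(community) - rao_q(community, d)
}

#' @rdname diversity_metrics
#' @param embedding an `fd_embedding` (see [trait_embedding()]) covering the
#'   community's species.
#' @export
fdis <- function(community, embedding) {
  p <- community_p(community)
  miss <- setdiff(names(p), embedding$species)
  if (length(miss) > 0) {
    stop("species missing from embedding: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- embedding$points[names(p), , drop = FALSE]
  centroid <- colSums(x * p)
  dev <- sweep(x, 2, centroid)
  sum(p * sqrt(rowSums(dev^2)))
}

#' Community-weighted mean of a numeric trait
#'
#' `CWM = sum(p_j t_j)`, the mean trait value weighted by relative
#' abundance. Species with a missing trait value are excluded and the
#' weights renormalized over the rest.
#'
#' @inheritParams diversity_metrics
#' @param traits a `fd_traits` table.
#' @param trait name of a numeric or ordinal trait.
#' @return weighted mean on the trait's scale.
#' @export
cwm <- function(community, traits, trait) {
  sch <- trait_schema_of(traits)
  if (!trait %in% sch$trait) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  if (!sch$kind[sch$trait == trait] %in% c("numeric", "ordinal")) {
    stop("CWM requires a numeric or ordinal trait", call. = FALSE)
  }
  p <- community_p(community)
  vals <- traits[[trait]][match(names(p), traits$species)]
  ok <- !is.na(vals)
  if (!any(ok)) {
    stop("all values of '", trait, "' missing for this community",
         call. = FALSE)
  }
  sum(p[ok] * vals[ok]) / sum(p[ok])
}

#' Per plot-year community metrics
#'
#' Computes the full metric report for every plot-year of a survey:
#' richness, Gini-Simpson diversity, Simpson's evenness, Rao's quadratic
#' entropy, functional redundancy (both on the raw Gower matrix) and
#' functional dispersion (on the corrected trait-space embedding), plus
#' community-weighted means of any requested numeric traits.
#'
#' The embedding and the Gower matrix are built once from all species in
#' `traits` restricted to the chosen preset, so metrics are comparable
#' across plots and years.
#'
#' @param survey a survey tibble (see [read_survey()]).
#' @param traits a `fd_traits` table covering every surveyed species.
#' @param trait_subset preset name or character vector of traits used for
#'   the distance-based metrics (default the 11-trait plant-arthropod set).
#' @param cwm_traits character vector of numeric traits to summarize as
#'   community-weighted means (on raw trait scales, untransformed).
#' @param correction embedding correction passed to [trait_embedding()].
#' @param sown_only if `TRUE`, metrics are computed on the sown fraction of
#'   each community only.
#' @return tibble keyed by (assemblage, transect, plot, block, year) with
#'   columns `richness`, `simpson`, `evenness`, `rao_q`, `redundancy`,
#'   `fdis`, `total_cover`, and one `cwm_<trait>` column per requested
#'   trait. Plot-years with no (retained) cover are dropped.
#' @export
community_metrics <- function(survey, traits, trait_subset = "arthropod11",
                              cwm_traits = character(),
                              correction = "cailliez",
                              sown_only = FALSE) {
  if (sown_only) survey <- dplyr::filter(survey, .data$sown)
  survey <- dplyr::filter(survey, .data$cover > 0)
  miss <- setdiff(unique(survey$species), traits$species)
  if (length(miss) > 0) {
    stop("surveyed species absent from trait table: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  }
  prepped <- prepare_traits(traits, trait_subset)
  d <- gower_distance(prepped)
  emb <- trait_embedding(d, correction = correction)

  survey |>
    dplyr::group_by(.data$assemblage, .data$transect, .data$plot,
                    .data$block, .data$year) |>
    dplyr::group_modify(function(rows, key) {
      comm <- stats::setNames(rows$cover, rows$species)
      out <- tibble::tibble(
        richness = length(comm),
        simpson = simpson_diversity(comm),
        evenness = simpson_evenness(comm),
        rao_q = rao_q(comm, d),
        redundancy = functional_redundancy(comm, d),
        fdis = fdis(comm, emb),
        total_cover = sum(comm)
      )
      for (tr in cwm_traits) {
        out[[paste0("cwm_", tr)]] <- cwm(comm, traits, tr)
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Cover share of regeneration-strategy categories per year
#'
#' Fraction of total cover held, each year, by species of each regeneration
#' strategy (annual, biennial, stationary perennial, aboveground creeping
#' perennial, belowground creeping perennial). Species lacking the strategy
#' trait are excluded with a warning; their cover share is reported in the
#' `excluded_cover_share` attribute.
#'
#' @param survey a survey tibble.
#' @param traits a `fd_traits` table with the strategy trait.
#' @param strategy_trait name of the categorical strategy trait.
#' @return tibble with columns `year`, `strategy`, `cover_share`; shares sum
#'   to 1 within each year.
#' @export
strategy_proportions <- function(survey, traits,
                                 strategy_trait = "regeneration_strategy") {
  sch <- trait_schema_of(traits)
  if (!strategy_trait %in% sch$trait ||
      sch$kind[sch$trait == strategy_trait] != "categorical") {
    stop("'", strategy_trait, "' must be a categorical trait", call. = FALSE)
  }
  strat <- stats::setNames(traits[[strategy_trait]], traits$species)
  survey <- dplyr::filter(survey, .data$cover > 0)
  survey$strategy <- unname(strat[survey$species])
  excl <- survey[is.na(survey$strategy), ]
  excl_share <- 0
  if (nrow(excl) > 0) {
    excl_share <- sum(excl$cover) / sum(survey$cover)
    warning(length(unique(excl$species)),
            " species lack the strategy trait; ",
            signif(100 * excl_share, 3), "% of cover excluded", call. = FALSE)
    survey <- survey[!is.na(survey$strategy), ]
  }
  out <- survey |>
    dplyr::group_by(.data$year, .data$strategy) |>
    dplyr::summarise(cover = sum(.data$cover), .groups = "drop_last") |>
    dplyr::mutate(cover_share = .data$cover / sum(.data$cover)) |>
    dplyr::ungroup() |>
    dplyr::select("year", "strategy", "cover_share")
  attr(out, "excluded_cover_share") <- excl_share
  out
}
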