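#' Name-shuffling null model for functional dispersion
#'
#' The null model permutes species names over entire rows of the trait
#' matrix within a species pool: each species keeps its abundance but
#' inherits the full trait vector of another pool member, so trait
#' covariance and community structure are both preserved exactly. Repeating
#' the shuffle gives the null distribution of functional dispersion at the
#' observed richness, from which a standardized effect size
#' `SES = (observed - null mean) / null sd` is computed.
#'
#' @name null_models
NULL

#' @describeIn null_models permute whole trait vectors among the pool's
#'   species labels. Species outside the pool are untouched.
#' @param traits a `fd_traits` table.
#' @param pool character vector of species ids (subset of the table).
#' @export
shuffle_names <- function(traits, pool = traits$species) {
  if (length(pool) < 2) stop("pool must have at least 2 species", call. = FALSE)
  miss <- setdiff(pool, traits$species)
  if (length(miss) > 0) {
    stop("pool species absent from trait table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(pool, traits$species)
  perm <- sample(length(idx))
  out <- traits
  sch <- trait_schema_of(traits)
  out[idx, sch$trait] <- out[idx[perm], sch$trait]
  out
}

# FDis of a community under a relabelling of pool species: rather than
# recomputing Gower + PCoA per shuffle, the precomputed embedding rows are
# relabelled (mathematically identical, since permuting trait vectors
# permutes the distance matrix and hence the embedding rows). Tested against
# the naive recomputation.
fdis_relabelled <- function(p, species, pool, perm, embedding) {
  relabel <- stats::setNames(pool[perm], pool)
  x <- embedding$points[relabel[species], , drop = FALSE]
  centroid <- colSums(x * p)
  dev <- sweep(x, 2, centroid)
  sum(p * sqrt(rowSums(dev^2)))
}

#' @describeIn null_models standardized effect size of functional
#'   dispersion against the name-shuffling null.
#' @param community named abundance vector; its species must belong to
#'   `pool`.
#' @param trait_subset preset or trait names used for the distance space.
#' @param n_iter number of shuffles (default 1000).
#' @param seed integer seed; together with the inputs it fully determines
#'   the result.
#' @param embedding optional precomputed `fd_embedding` of the pool's
#'   prepared traits (an optimization for batch callers; must match
#'   `traits`/`trait_subset`).
#' @param correction embedding correction (see [trait_embedding()]).
#' @return an `fd_ses` list: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `ses_defined`, `n_iter`, `seed`. When the null distribution is
#'   degenerate (`null_sd = 0`), `ses` is `NA` and `ses_defined` is
#'   `FALSE` rather than an infinite value.
#' @export
ses_fdis <- function(community, traits, pool = traits$species,
                     trait_subset = "arthropod11", n_iter = 1000, seed = 1L,
                     embedding = NULL, correction = "cailliez") {
  if (n_iter < 2) stop("n_iter must be >= 2", call. = FALSE)
  p <- community_p(community)
  outside <- setdiff(names(p), pool)
  if (length(outside) > 0) {
    stop("community species outside the pool: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  if (is.null(embedding)) {
    prepped <- prepare_traits(traits, trait_subset)
    prepped <- prepped[match(pool, prepped$species), ]
    embedding <- trait_embedding(gower_distance(prepped),
                                 correction = correction)
  }
  observed <- fdis(p, embedding)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  nulls <- vapply(seq_len(n_iter), function(i) {
    fdis_relabelled(p, names(p), pool, sample(length(pool)), embedding)
  }, numeric(1))

  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  defined <- null_sd > 0
  structure(
    list(
      observed = observed,
      null_mean = null_mean,
      null_sd = null_sd,
      ses = if (defined) (observed - null_mean) / null_sd else NA_real_,
      ses_defined = defined,
      n_iter = n_iter,
      seed = as.integer(seed),
      rng = "Mersenne-Twister"
    ),
    class = "fd_ses"
  )
}

#' @export
print.fd_ses <- function(x, ...) {
  cat("<SES of functional dispersion>\n")
  cat(sprintf("  observed %.4f, null %.4f +/- %.4f, SES %s (%d iterations, seed %d)\n",
              x$observed, x$null_mean, x$null_sd,
              if (x$ses_defined) sprintf("%.3f", x$ses) else "undefined",
              x$n_iter, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fd_ses <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
    ses = x$ses, ses_defined = x$ses_defined,
    n_iter = x$n_iter, seed = x$seed
  )
}

#' Standardized effect sizes for every plot-year of a survey
#'
#' Runs [ses_fdis()] per plot-year, with one shared trait-space embedding
#' and per-record seeds derived deterministically from `seed`. The shuffle
#' pool defaults to the whole trait table (all observed species), the
#' study-wide convention; a per-assemblage pool can be supplied instead.
#'
#' @inheritParams ses_fdis
#' @param survey a survey tibble.
#' @return tibble keyed by (assemblage, transect, plot, block, year) with
#'   the columns of [tidy()] applied to each `fd_ses`.
#' @export
ses_table <- function(survey, traits, pool = traits$species,
                      trait_subset = "arthropod11", n_iter = 1000, seed = 1L,
                      correction = "cailliez") {
  prepped <- prepare_traits(traits, trait_subset)
  prepped <- prepped[match(pool, prepped$species), ]
  embedding <- trait_embedding(gower_distance(prepped),
                               correction = correction)
  survey <- dplyr::filter(survey, .data$cover > 0)
  keys <- survey |>
    dplyr::distinct(.data$assemblage, .data$transect, .data$plot,
                    .data$block, .data$year) |>
    dplyr::arrange(.data$transect, .data$plot, .data$year)
  res <- purrr::map_dfr(seq_len(nrow(keys)),
    function(i) {
      k <- keys[i, ]
      rows <- survey |>
        dplyr::filter(.data$transect == k$transect, .data$plot == k$plot,
                      .data$year == k$year)
      comm <- stats::setNames(rows$cover, rows$species)
      s <- (as.integer(seed) + i * 10007L) %% .Machine$integer.max
      tidy(ses_fdis(comm, traits, pool = pool, trait_subset = trait_subset,
                    n_iter = n_iter, seed = s, embedding = embedding))
    })
  dplyr::bind_cols(keys, res)
}
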