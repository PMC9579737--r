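#' Specification for an assemblage-design search
#'
#' @param pool a `fd_traits` table for the candidate species; species ids
#'   doubling as the design universe. Grass (Poaceae) ids listed in
#'   `mandatory` are forced into every assemblage.
#' @param richness_targets named or unnamed counts for the low/medium/high
#'   richness levels (default 9, 14, 29, including the mandatory species).
#' @param n_lists number of disjoint dicot species lists (default 2).
#' @param mandatory species included in every assemblage (default none;
#'   supply the three grasses to mirror the published design).
#' @param sowing_density seeds per square metre (default 240).
#' @param trait_subset trait preset used to score candidate subsets.
#' @param n_search number of random subsets scored per assemblage
#'   (best-of-N search).
#' @param sample_weights optional named per-species sampling weights for the
#'   subset search (e.g. down-weighting annuals, which seed mixtures for
#'   perennial strips rarely emphasize); default uniform.
#' @return an `fd_design_spec` list.
#' @export
design_spec <- function(pool, richness_targets = c(low = 9, medium = 14, high = 29),
                        n_lists = 2, mandatory = character(),
                        sowing_density = 240, trait_subset = "all16",
                        n_search = 200, sample_weights = NULL) {
  if (is.null(names(richness_targets))) {
    names(richness_targets) <- c("low", "medium", "high")[seq_along(richness_targets)]
  }
  if (any(richness_targets < length(mandatory) + 1)) {
    stop("richness targets must exceed the number of mandatory species",
         call. = FALSE)
  }
  if (sowing_density <= 0) stop("density must be > 0", call. = FALSE)
  structure(
    list(pool = pool, richness_targets = richness_targets, n_lists = n_lists,
         mandatory = mandatory, sowing_density = sowing_density,
         trait_subset = trait_subset, n_search = n_search,
         sample_weights = sample_weights),
    class = "fd_design_spec"
  )
}

#' Design seed assemblages crossing richness with functional diversity
#'
#' Builds the four realized design cells -- low-FD at medium richness, and
#' high-FD at low, medium and high richness -- for each of `n_lists`
#' disjoint dicot species lists, by best-of-N random subset search:
#' candidate subsets (always containing the mandatory species) are scored by
#' equal-abundance functional dispersion in the pool's trait-space
#' embedding, maximized for high-FD assemblages and minimized for low-FD
#' ones. High-FD assemblages are nested across richness levels within a
#' list, which makes functional redundancy grow mechanically with richness
#' at comparable dispersion.
#'
#' The returned set is verified against the design gradient: every low-FD
#' assemblage must have a lower sown FDis than every high-FD assemblage of
#' equal richness, and redundancy must increase strictly with richness
#' within each list's high-FD series. If the search cannot satisfy these
#' after `n_search` draws, an error reports the best achieved margin.
#'
#' @param spec an [design_spec()].
#' @param seed integer seed; (spec, seed) fully determine the output.
#' @param max_restarts if a draw of lists fails the gradient verification,
#'   the search restarts with a seed derived from `seed` up to this many
#'   times before giving up.
#' @return named list of `fd_design` objects (`LFMS1`, `HFLS1`, ...,
#'   per list), with a `verification` attribute holding the recomputed sown
#'   FDis and redundancy of every design.
#' @export
design_assemblages <- function(spec, seed = 1L, max_restarts = 5L) {
  last_err <- NULL
  for (restart in 0:max_restarts) {
    out <- tryCatch(
      design_assemblages_once(spec, seed = seed + restart * 997L),
      error = function(e) e
    )
    if (!inherits(out, "error")) return(out)
    last_err <- out
  }
  stop(conditionMessage(last_err), " (after ", max_restarts + 1,
       " search restarts)", call. = FALSE)
}

design_assemblages_once <- function(spec, seed) {
  stopifnot(inherits(spec, "fd_design_spec"))
  pool <- spec$pool
  prepped <- prepare_traits(pool, spec$trait_subset)
  d <- gower_distance(prepped)
  emb <- trait_embedding(d)
  all_sp <- pool$species
  dicots <- setdiff(all_sp, spec$mandatory)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_dicot_high <- max(spec$richness_targets) - length(spec$mandatory)
  if (length(dicots) < spec$n_lists * n_dicot_high) {
    stop("pool too small for ", spec$n_lists, " disjoint lists of ",
         n_dicot_high, " dicots", call. = FALSE)
  }
  # partition the dicots into disjoint per-list universes
  shuffled <- sample(dicots)
  per_list <- floor(length(dicots) / spec$n_lists)
  lists <- split(shuffled[seq_len(per_list * spec$n_lists)],
                 rep(seq_len(spec$n_lists), each = per_list))

  score <- function(sp) {
    fdis(stats::setNames(rep(1, length(sp)), sp), emb)
  }
  red <- function(sp) {
    functional_redundancy(stats::setNames(rep(1, length(sp)), sp), d)
  }
  best_subset <- function(universe, size, maximize, base = character()) {
    pick_n <- size - length(spec$mandatory) - length(base)
    if (pick_n < 0) stop("richness target below mandatory+base size",
                         call. = FALSE)
    free <- setdiff(universe, base)
    if (pick_n >= length(free)) {
      return(c(base, free, spec$mandatory))  # degenerate: whole universe
    }
    w <- if (is.null(spec$sample_weights)) NULL else spec$sample_weights[free]
    best <- NULL
    best_val <- if (maximize) -Inf else Inf
    for (i in seq_len(spec$n_search)) {
      cand <- c(base, sample(free, pick_n, prob = w), spec$mandatory)
      v <- score(cand)
      if ((maximize && v > best_val) || (!maximize && v < best_val)) {
        best_val <- v
        best <- cand
      }
    }
    best
  }

  rl <- names(spec$richness_targets)
  designs <- list()
  for (l in seq_len(spec$n_lists)) {
    universe <- lists[[l]]
    # nested high-FD series: low -> medium -> high richness
    hf <- list()
    base <- character()
    for (lev in rl) {
      hf[[lev]] <- setdiff(
        best_subset(universe, spec$richness_targets[[lev]],
                    maximize = TRUE, base = base),
        spec$mandatory
      )
      base <- hf[[lev]]
    }
    lf_med <- setdiff(
      best_subset(universe, spec$richness_targets[["medium"]],
                  maximize = FALSE),
      spec$mandatory
    )
    mk <- function(id, sp, fd_level, richness_level) {
      assemblage_design(
        assemblage_id = id, species = c(sp, spec$mandatory),
        fd_level = fd_level, richness_level = richness_level, list_id = l,
        sowing_density = spec$sowing_density
      )
    }
    designs[[paste0("LFMS", l)]] <- mk(paste0("LFMS", l), lf_med, "low", "medium")
    designs[[paste0("HFLS", l)]] <- mk(paste0("HFLS", l), hf$low, "high", "low")
    designs[[paste0("HFMS", l)]] <- mk(paste0("HFMS", l), hf$medium, "high", "medium")
    designs[[paste0("HFHS", l)]] <- mk(paste0("HFHS", l), hf$high, "high", "high")
  }

  verification <- design_verification(designs, pool, spec$trait_subset)
  check_design_gradient(verification)
  attr(designs, "verification") <- verification
  designs
}

#' Recompute the sown functional metrics of a design set
#'
#' Equal-proportion FDis and functional redundancy for each design, using
#' the same trait preset as the analysis.
#'
#' @param designs list of `fd_design` objects.
#' @param traits trait table covering all design species.
#' @param trait_subset preset or trait names.
#' @param correction embedding correction for FDis.
#' @return tibble: assemblage, fd_level, richness_level, list_id,
#'   n_species, fdis, redundancy, simpson, evenness.
#' @export
design_verification <- function(designs, traits, trait_subset = "all16",
                                correction = "cailliez") {
  prepped <- prepare_traits(traits, trait_subset)
  d <- gower_distance(prepped)
  emb <- trait_embedding(d, correction = correction)
  purrr::map_dfr(designs, function(dg) {
    comm <- dg$sown_proportion
    tibble::tibble(
      assemblage = dg$assemblage_id,
      fd_level = dg$fd_level,
      richness_level = dg$richness_level,
      list_id = dg$list_id,
      n_species = length(dg$species),
      fdis = fdis(comm, emb),
      redundancy = functional_redundancy(comm, d),
      simpson = simpson_diversity(comm),
      evenness = simpson_evenness(comm)
    )
  })
}

check_design_gradient <- function(v) {
  margin <- Inf
  for (lev in unique(v$richness_level)) {
    lf <- v$fdis[v$fd_level == "low" & v$richness_level == lev]
    hf <- v$fdis[v$fd_level == "high" & v$richness_level == lev]
    if (length(lf) > 0 && length(hf) > 0) {
      margin <- min(margin, min(hf) - max(lf))
    }
  }
  ord <- c(low = 1, medium = 2, high = 3)
  for (l in unique(v$list_id)) {
    hv <- v[v$fd_level == "high" & v$list_id == l, ]
    hv <- hv[order(ord[hv$richness_level]), ]
    if (nrow(hv) > 1) {
      margin <- min(margin, min(diff(hv$redundancy)))
    }
  }
  if (is.finite(margin) && margin <= 0) {
    stop("design gradient not achieved: best margin ", signif(margin, 3),
         " (increase n_search or enlarge the pool)", call. = FALSE)
  }
  invisible(margin)
}

#' Sowing recipe for an assemblage
#'
#' Converts a design's equal seed-number rule into per-species sowing rates:
#' `density / S` seeds per square metre each, and the corresponding mass
#' using the thousand-seed weight.
#'
#' @param design an `fd_design` with thousand-seed weights.
#' @return tibble: `species`, `seeds_per_m2`, `mass_g_per_m2`.
#' @export
seed_mix <- function(design) {
  tsw <- design$thousand_seed_weight
  if (is.null(tsw)) {
    stop("no thousand-seed weights on design ", design$assemblage_id,
         call. = FALSE)
  }
  missing_tsw <- setdiff(design$species, names(tsw)[!is.na(tsw) & tsw > 0])
  if (length(missing_tsw) > 0) {
    stop("missing or non-positive thousand-seed weight for: ",
         paste(missing_tsw, collapse = ", "), call. = FALSE)
  }
  s <- length(design$species)
  seeds <- design$sowing_density * design$sown_proportion[design$species]
  tibble::tibble(
    species = design$species,
    seeds_per_m2 = unname(seeds),
    mass_g_per_m2 = unname(seeds * tsw[design$species] / 1000)
  )
}
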