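# Shared fixtures, all built in code.

toy_schema <- function() {
  trait_schema(c("size", "color"), c("numeric", "categorical"))
}

toy_traits <- function() {
  trait_table(
    data.frame(species = c("a", "b", "c"),
               size = c(0, 5, 10),
               color = c("red", "red", "blue")),
    toy_schema()
  )
}

# survey rows for one plot-year from a named cover vector
survey_rows <- function(comm, plot = 1, transect = 1, block = 1,
                        assemblage = "A1", year = 1, sown = TRUE) {
  tibble::tibble(
    plot = plot, transect = transect, block = block,
    assemblage = assemblage, year = year,
    species = names(comm), cover = unname(comm),
    sown = rep_len(sown, length(comm))
  )
}

# small, fast benchmark reused by pipeline-shape tests (memoized per session)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7, n_pool = 60,
                        richness_targets = c(low = 5, medium = 8, high = 12),
                        n_search = 30)
      cache <<- make_benchmark(cfg)
    }
    cache
  }
})

# A synthetic stand-in trait table for the published assemblage species.
# The original study's own per-species trait measurements are not shipped
# here; these values are drawn from the same synthetic trait families as
# generate_pool() and carry no information about the real species.
synthetic_reference_traits <- function(seed = 99) {
  designs <- published_assemblages()
  sp <- unique(unlist(lapply(designs, function(d) d$species)))
  cfg <- sim_config(seed = seed, n_pool = length(sp))
  pool <- generate_pool(cfg)
  pool$species <- sp
  pool
}
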