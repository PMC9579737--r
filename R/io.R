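#' Read and write trait tables
#'
#' CSV dialect: UTF-8, comma separated, `.` decimal, one row per species,
#' header matching the schema trait names plus a `species` column. Empty
#' cells are read as missing, never as zero.
#'
#' @param path file path.
#' @param schema trait schema (see [trait_schema()]).
#' @return [read_trait_table()] returns a validated `fd_traits` tibble;
#'   completeness is available through [trait_completeness()].
#' @export
read_trait_table <- function(path, schema = default_trait_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  types <- stats::setNames(
    ifelse(schema$kind %in% c("numeric", "ordinal", "binary"), "d", "c"),
    schema$trait
  )
  dat <- readr::read_csv(
    path,
    col_types = do.call(readr::cols,
                        c(list(species = readr::col_character()),
                          as.list(types)))
  )
  trait_table(dat, schema)
}

#' @param traits a `fd_traits` table.
#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  readr::write_csv(tibble::as_tibble(traits), path, na = "")
  invisible(path)
}

#' Read and write vegetation surveys
#'
#' Long-format survey CSV with columns `plot`, `transect`, `block`,
#' `assemblage`, `year`, `species`, `cover`, `sown`. One row per species
#' observed in a plot-year; `cover` is percent ground cover estimated by
#' eye, so per plot-year totals may exceed 100 (species overlap).
#'
#' @param path file path.
#' @param years optional integer range; records outside it raise a warning.
#' @param designs optional list of assemblage designs; when given, the sown
#'   flag is cross-checked against design membership and inconsistencies
#'   raise a warning.
#' @return a validated survey tibble.
#' @export
read_survey <- function(path, years = NULL, designs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, col_types = readr::cols(
    plot = readr::col_integer(),
    transect = readr::col_integer(),
    block = readr::col_integer(),
    assemblage = readr::col_character(),
    year = readr::col_integer(),
    species = readr::col_character(),
    cover = readr::col_double(),
    sown = readr::col_logical()
  ))
  validate_survey(dat, years = years, designs = designs)
}

#' @param survey a survey tibble.
#' @rdname read_survey
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path)
  invisible(path)
}

validate_survey <- function(dat, years = NULL, designs = NULL) {
  needed <- c("plot", "transect", "block", "assemblage", "year", "species",
              "cover", "sown")
  missing_cols <- setdiff(needed, names(dat))
  if (length(missing_cols) > 0) {
    stop("survey lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(dat$cover < 0, na.rm = TRUE)) {
    stop("negative cover value(s) in survey", call. = FALSE)
  }
  key <- paste(dat$transect, dat$plot, dat$year, dat$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (plot, year, species) record(s) in survey", call. = FALSE)
  }
  if (!is.null(years) && any(!dat$year %in% years)) {
    warning("survey contains year(s) outside the declared range: ",
            paste(sort(unique(dat$year[!dat$year %in% years])), collapse = ", "),
            call. = FALSE)
  }
  if (!is.null(designs)) {
    by_id <- stats::setNames(
      lapply(designs, function(d) d$species),
      vapply(designs, function(d) d$assemblage_id, character(1))
    )
    known <- dat$assemblage %in% names(by_id)
    in_design <- mapply(function(a, s) s %in% by_id[[a]],
                        dat$assemblage[known], dat$species[known])
    if (any(dat$sown[known] != in_design)) {
      warning("sown flag inconsistent with assemblage design for ",
              sum(dat$sown[known] != in_design), " record(s)", call. = FALSE)
    }
  }
  tibble::as_tibble(dat)
}

#' Assemblage designs
#'
#' An assemblage design records the species list of a seed mixture, its sown
#' proportions (in terms of seed numbers), and the design-category labels:
#' functional-diversity level (`low`/`high`), richness level
#' (`low`/`medium`/`high`) and species-list id (1 or 2).
#'
#' @param assemblage_id label, e.g. `"HFHS1"`.
#' @param species character vector of species ids.
#' @param fd_level `"low"` or `"high"`.
#' @param richness_level `"low"`, `"medium"` or `"high"`.
#' @param list_id integer 1 or 2.
#' @param sown_proportion optional named numeric summing to 1; defaults to
#'   equal proportions (the equal-seed-number rule).
#' @param sowing_density seeds per square metre (default 240).
#' @param thousand_seed_weight optional named numeric, grams per 1000 seeds.
#' @return an `fd_design` list object.
#' @export
assemblage_design <- function(assemblage_id, species,
                              fd_level = c("high", "low"),
                              richness_level = c("medium", "low", "high"),
                              list_id = 1L,
                              sown_proportion = NULL,
                              sowing_density = 240,
                              thousand_seed_weight = NULL) {
  fd_level <- match.arg(fd_level)
  richness_level <- match.arg(richness_level)
  species <- as.character(species)
  if (anyDuplicated(species)) {
    stop("duplicate species in assemblage ", assemblage_id, call. = FALSE)
  }
  if (is.null(sown_proportion)) {
    sown_proportion <- stats::setNames(rep(1 / length(species), length(species)),
                                       species)
  }
  sown_proportion <- sown_proportion[species]
  if (abs(sum(sown_proportion) - 1) > 1e-9) {
    stop("sown proportions must sum to 1 (got ", sum(sown_proportion), ")",
         call. = FALSE)
  }
  if (sowing_density <= 0) stop("sowing density must be > 0", call. = FALSE)
  structure(
    list(
      assemblage_id = assemblage_id,
      fd_level = fd_level,
      richness_level = richness_level,
      list_id = as.integer(list_id),
      species = species,
      sown_proportion = sown_proportion,
      sowing_density = sowing_density,
      thousand_seed_weight = thousand_seed_weight
    ),
    class = "fd_design"
  )
}

#' @export
print.fd_design <- function(x, ...) {
  cat("<assemblage design ", x$assemblage_id, ">\n", sep = "")
  cat("  FD level: ", x$fd_level, ", richness: ", x$richness_level,
      " (", length(x$species), " species), list ", x$list_id, "\n", sep = "")
  invisible(x)
}

#' Read and write assemblage designs (JSON)
#'
#' @param design an `fd_design` (or list of them for `write_designs()`).
#' @param path file path.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    list(
      assemblage_id = design$assemblage_id,
      fd_level = design$fd_level,
      richness_level = design$richness_level,
      list_id = design$list_id,
      species = design$species,
      sown_proportion = as.list(design$sown_proportion),
      sowing_density = design$sowing_density,
      thousand_seed_weight = if (is.null(design$thousand_seed_weight)) NULL
        else as.list(design$thousand_seed_weight)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assemblage_design(
    assemblage_id = x$assemblage_id,
    species = x$species,
    fd_level = x$fd_level,
    richness_level = x$richness_level,
    list_id = x$list_id,
    sown_proportion = unlist(x$sown_proportion),
    sowing_density = x$sowing_density,
    thousand_seed_weight = if (is.null(x$thousand_seed_weight)) NULL
      else unlist(x$thousand_seed_weight)
  )
}

#' Tidy view of a list of designs
#'
#' @param designs list of `fd_design` objects.
#' @return tibble with one row per design: id, levels, richness, species
#'   count.
#' @export
design_summary <- function(designs) {
  tibble::tibble(
    assemblage = vapply(designs, function(d) d$assemblage_id, character(1)),
    fd_level = vapply(designs, function(d) d$fd_level, character(1)),
    richness_level = vapply(designs, function(d) d$richness_level, character(1)),
    list_id = vapply(designs, function(d) d$list_id, integer(1)),
    n_species = vapply(designs, function(d) length(d$species), integer(1))
  )
}
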