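#' Trait schemas and trait tables
#'
#' A trait table is a tibble with a `species` key column and one column per
#' trait, carrying a *schema* attribute that declares, for every trait, its
#' measurement kind (`numeric`, `ordinal`, `categorical` or `binary`), whether
#' it is log-transformed before distance computation, and an optional valid
#' range. All downstream machinery (Gower distances, functional dispersion,
#' community-weighted means, null models) reads trait kinds from the schema,
#' never from column classes.
#'
#' @param trait character vector of trait names.
#' @param kind per-trait kind, one of `"numeric"`, `"ordinal"`,
#'   `"categorical"`, `"binary"`.
#' @param log_transform logical; natural log is applied by [prepare_traits()]
#'   where `TRUE`.
#' @param min,max optional numeric bounds enforced at validation time
#'   (e.g. 0-100 for Grime strategy scores).
#' @return `trait_schema()` returns a tibble with columns `trait`, `kind`,
#'   `log_transform`, `min`, `max`.
#' @examples
#' trait_schema(c("ldmc", "flower_color"), c("numeric", "categorical"))
#' @export
trait_schema <- function(trait, kind, log_transform = FALSE,
                         min = NA_real_, max = NA_real_) {
  kinds <- c("numeric", "ordinal", "categorical", "binary")
  bad <- setdiff(unique(kind), kinds)
  if (length(bad) > 0) {
    stop("unknown trait kind(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    trait = as.character(trait),
    kind = as.character(kind),
    log_transform = rep_len(as.logical(log_transform), length(trait)),
    min = rep_len(as.numeric(min), length(trait)),
    max = rep_len(as.numeric(max), length(trait))
  )
}

#' Default 16-trait schema
#'
#' The standard trait set used throughout the package: floral-resource traits
#' (nectar amount on a 0/1/2 ordinal scale, presence of extrafloral nectar,
#' flower or inflorescence diameter in cm, nectar depth in cm, basic flower
#' color, UV reflectance pattern), phenology (calendar week of flowering
#' onset, flowering duration in weeks), architecture (flowering height in cm,
#' leaf distribution, Raunkiaer life form), resource-strategy markers (SLA in
#' mm2/mg, LDMC in mg/g, Grime C and R scores as percentages) and the
#' composite regeneration strategy (lifespan crossed with propagation mode).
#' Flower diameter, flowering duration, nectar depth and flowering height are
#' flagged for log transformation before computing functional diversity.
#'
#' @return a trait schema tibble (see [trait_schema()]).
#' @export
default_trait_schema <- function() {
  dplyr::bind_rows(
    trait_schema("nectar_amount", "ordinal"),
    trait_schema("extrafloral_nectar", "binary"),
    trait_schema("flower_diameter", "numeric", log_transform = TRUE),
    trait_schema("flower_color", "categorical"),
    trait_schema("uv_pattern", "categorical"),
    trait_schema("flowering_onset", "numeric"),
    trait_schema("flowering_duration", "numeric", log_transform = TRUE),
    trait_schema("nectar_depth", "numeric", log_transform = TRUE),
    trait_schema("leaf_distribution", "categorical"),
    trait_schema("flowering_height", "numeric", log_transform = TRUE),
    trait_schema("raunkiaer_life_form", "categorical"),
    trait_schema("grime_c", "numeric", min = 0, max = 100),
    trait_schema("grime_r", "numeric", min = 0, max = 100),
    trait_schema("sla", "numeric"),
    trait_schema("ldmc", "numeric"),
    trait_schema("regeneration_strategy", "categorical")
  )
}

#' Named trait subsets (presets)
#'
#' Preset trait lists for the two analysis angles: plant-arthropod
#' interaction traits (shipped both as the 10-trait list and an 11-trait
#' variant that adds the Raunkiaer life form) and the 9 traits involved in
#' plant-plant competitive interactions (Grime C and R counted separately).
#' `"all16"` is the full default schema.
#'
#' @return named list of character vectors of trait names.
#' @export
trait_presets <- function() {
  arthropod10 <- c(
    "nectar_amount", "extrafloral_nectar", "flower_diameter", "flower_color",
    "uv_pattern", "flowering_onset", "flowering_duration", "nectar_depth",
    "flowering_height", "leaf_distribution"
  )
  list(
    arthropod10 = arthropod10,
    arthropod11 = c(arthropod10, "raunkiaer_life_form"),
    competition9 = c(
      "flowering_height", "leaf_distribution", "raunkiaer_life_form",
      "grime_c", "grime_r", "flowering_onset", "flowering_duration",
      "sla", "ldmc"
    ),
    all16 = default_trait_schema()$trait
  )
}

#' Construct and validate a trait table
#'
#' @param data data frame with a `species` column and one column per schema
#'   trait. Missing values stay missing (they are never imputed here; the
#'   distance layer handles them pairwise).
#' @param schema a [trait_schema()] tibble covering every trait column used.
#' @return a `fd_traits` tibble (species + traits, schema attached).
#' @export
trait_table <- function(data, schema = default_trait_schema()) {
  stopifnot(is.data.frame(data), is.data.frame(schema))
  if (!"species" %in% names(data)) {
    stop("trait data must have a 'species' column", call. = FALSE)
  }
  missing_cols <- setdiff(schema$trait, names(data))
  if (length(missing_cols) > 0) {
    stop("trait column(s) absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- data$species[duplicated(data$species)]
  if (length(dup) > 0) {
    stop("duplicate species id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)[, c("species", schema$trait)]
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    if (schema$kind[i] %in% c("numeric", "ordinal")) {
      v <- out[[tr]]
      if (!is.numeric(v)) {
        stop("trait '", tr, "' is declared ", schema$kind[i],
             " but is not numeric", call. = FALSE)
      }
      if (any(!is.finite(v) & !is.na(v))) {
        stop("trait '", tr, "' has non-finite values", call. = FALSE)
      }
      if (!is.na(schema$min[i]) && any(v < schema$min[i], na.rm = TRUE) ||
          !is.na(schema$max[i]) && any(v > schema$max[i], na.rm = TRUE)) {
        stop("trait '", tr, "' outside declared range [",
             schema$min[i], ", ", schema$max[i], "]", call. = FALSE)
      }
    } else if (schema$kind[i] == "binary") {
      v <- out[[tr]]
      if (is.logical(v)) v <- as.numeric(v)
      if (!all(v %in% c(0, 1) | is.na(v))) {
        stop("binary trait '", tr, "' must be 0/1", call. = FALSE)
      }
      out[[tr]] <- v
    } else {
      out[[tr]] <- as.character(out[[tr]])
    }
  }
  attr(out, "schema") <- tibble::as_tibble(schema)
  class(out) <- c("fd_traits", class(tibble::tibble()))
  out
}

#' @export
#' @rdname trait_table
trait_schema_of <- function(traits) {
  sch <- attr(traits, "schema", exact = TRUE)
  if (is.null(sch)) stop("not a trait table: no schema attached", call. = FALSE)
  sch
}

#' Per-trait completeness
#'
#' Fraction of species with a non-missing value, per trait. Field trait
#' compilations are rarely complete (nectar depth is the classic gap), and
#' the pairwise Gower rule depends on knowing where the holes are.
#'
#' @param traits a `fd_traits` table.
#' @return tibble with columns `trait`, `n_species`, `completeness`.
#' @export
trait_completeness <- function(traits) {
  sch <- trait_schema_of(traits)
  tibble::tibble(
    trait = sch$trait,
    n_species = nrow(traits),
    completeness = vapply(sch$trait,
                          function(tr) mean(!is.na(traits[[tr]])), numeric(1),
                          USE.NAMES = FALSE)
  )
}

#' Restrict a trait table to a subset and apply declared log transforms
#'
#' Returns a copy restricted to `trait_subset` with the natural logarithm
#' applied to the traits flagged `log_transform` in the schema (flower
#' diameter, flowering duration, nectar depth, flowering height in the
#' default schema). All other values are untouched. Log-flagged traits must
#' be strictly positive where present.
#'
#' @param traits a `fd_traits` table.
#' @param trait_subset character vector of trait names, or the name of a
#'   preset from [trait_presets()].
#' @return a `fd_traits` table restricted to the subset, log-applied, with
#'   the `log_transform` flags cleared (so the transform is never applied
#'   twice).
#' @export
prepare_traits <- function(traits, trait_subset = "all16") {
  sch <- trait_schema_of(traits)
  if (length(trait_subset) == 1 && trait_subset %in% names(trait_presets())) {
    trait_subset <- trait_presets()[[trait_subset]]
  }
  unknown <- setdiff(trait_subset, sch$trait)
  if (length(unknown) > 0) {
    stop("unknown trait(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(sch$trait, collapse = ", "), call. = FALSE)
  }
  sub <- sch[match(trait_subset, sch$trait), ]
  out <- tibble::as_tibble(traits)[, c("species", trait_subset)]
  for (i in seq_len(nrow(sub))) {
    if (isTRUE(sub$log_transform[i])) {
      tr <- sub$trait[i]
      v <- out[[tr]]
      bad <- !is.na(v) & v <= 0
      if (any(bad)) {
        stop("non-positive value(s) under log transform for trait '", tr,
             "' in species: ", paste(out$species[bad], collapse = ", "),
             call. = FALSE)
      }
      out[[tr]] <- log(v)
      # range bounds no longer meaningful on the log scale
      sub$min[i] <- NA_real_
      sub$max[i] <- NA_real_
    }
  }
  sub$log_transform <- FALSE
  trait_table(out, sub)
}
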