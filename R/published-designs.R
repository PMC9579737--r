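#' The eight published flower-strip seed assemblages
#'
#' Species compositions of the eight assemblages of the 4-year flower-strip
#' experiment: two low-functional-diversity mixtures at medium richness
#' (LFMS1/2, 14 species), and high-functional-diversity mixtures at low
#' (HFLS1/2, 9 species), medium (HFMS1/2, 14 species) and high (HFHS1/2,
#' 29 species) richness. Dicot lists 1 and 2 are disjoint; every assemblage
#' shares the same three grasses (*Arrhenatherum elatius*, *Dactylis
#' glomerata*, *Schedonorus arundinaceus*). Proportions are equal in terms
#' of seed numbers; density is 240 seeds per square metre.
#'
#' Thousand-seed weights of the original seed batches were never published;
#' designs are returned without them unless `placeholder_tsw = TRUE`, in
#' which case a clearly synthetic constant 1 g placeholder is attached (for
#' exercising the sowing-recipe arithmetic only).
#'
#' @param placeholder_tsw attach a synthetic 1 g thousand-seed weight to
#'   every species (default `FALSE`).
#' @return named list of eight `fd_design` objects, in the order LFMS1,
#'   LFMS2, HFLS1, HFLS2, HFMS1, HFMS2, HFHS1, HFHS2.
#' @seealso [published_species_names()] for the full binomials.
#' @export
published_assemblages <- function(placeholder_tsw = FALSE) {
  grasses <- c("arrhenatherum_elatius", "dactylis_glomerata",
               "schedonorus_arundinaceus")

  # list-1 dicot blocks, keyed by which assemblages contain them
  lfms1_hfhs1 <- c("anthriscus_sylvestris", "arctium_minus",
                   "foeniculum_vulgare", "hesperis_matronalis",
                   "leucanthemum_vulgare", "medicago_sativa",
                   "coronilla_varia", "trifolium_pratense")
  shared1 <- c("achillea_millefolium", "alliaria_petiolata",
               "heracleum_sphondylium")
  hfls1_up <- c("cyanus_segetum", "trifolium_repens", "veronica_hederifolia")
  hfms1_up <- c("centaurea_scabiosa", "euphorbia_cyparissias",
                "hypericum_perforatum", "tanacetum_vulgare",
                "verbascum_densiflorum")
  hfhs1_only <- c("ajuga_reptans", "bellis_perennis",
                  "capsella_bursa_pastoris", "echium_vulgare",
                  "galium_odoratum", "malva_sylvestris", "potentilla_reptans")

  # list-2 dicot blocks
  lfms2_hfhs2 <- c("carum_carvi", "cynoglossum_officinale", "daucus_carota",
                   "hypochaeris_radicata", "jacobaea_vulgaris",
                   "lotus_corniculatus", "onobrychis_viciifolia",
                   "melilotus_altissimus")
  shared2 <- c("barbarea_vulgaris", "cota_tinctoria", "pastinaca_sativa")
  hfls2_up <- c("medicago_lupulina", "stellaria_media", "vicia_sativa")
  hfms2_up <- c("cichorium_intybus", "galium_mollugo", "knautia_arvensis",
                "plantago_lanceolata", "verbascum_lychnitis")
  hfhs2_only <- c("geum_urbanum", "glechoma_hederacea", "lamium_album",
                  "ranunculus_repens", "reseda_luteola",
                  "taraxacum_ruderalia", "veronica_persica")

  comp <- list(
    LFMS1 = c(lfms1_hfhs1, shared1, grasses),
    LFMS2 = c(lfms2_hfhs2, shared2, grasses),
    HFLS1 = c(shared1, hfls1_up, grasses),
    HFLS2 = c(shared2, hfls2_up, grasses),
    HFMS1 = c(shared1, hfls1_up, hfms1_up, grasses),
    HFMS2 = c(shared2, hfls2_up, hfms2_up, grasses),
    HFHS1 = c(lfms1_hfhs1, shared1, hfls1_up, hfms1_up, hfhs1_only, grasses),
    HFHS2 = c(lfms2_hfhs2, shared2, hfls2_up, hfms2_up, hfhs2_only, grasses)
  )
  meta <- list(
    LFMS1 = c("low", "medium", 1L), LFMS2 = c("low", "medium", 2L),
    HFLS1 = c("high", "low", 1L), HFLS2 = c("high", "low", 2L),
    HFMS1 = c("high", "medium", 1L), HFMS2 = c("high", "medium", 2L),
    HFHS1 = c("high", "high", 1L), HFHS2 = c("high", "high", 2L)
  )
  out <- lapply(names(comp), function(id) {
    sp <- comp[[id]]
    assemblage_design(
      assemblage_id = id,
      species = sp,
      fd_level = meta[[id]][1],
      richness_level = meta[[id]][2],
      list_id = as.integer(meta[[id]][3]),
      sowing_density = 240,
      thousand_seed_weight = if (placeholder_tsw) {
        stats::setNames(rep(1, length(sp)), sp)  # synthetic placeholder
      } else NULL
    )
  })
  stats::setNames(out, names(comp))
}

#' Synonym map for the published assemblage species
#'
#' Maps the normalized species ids used as keys throughout the package
#' (genus_species, lowercase) to the full binomials of the national
#' taxonomic referential under which the assemblages were published.
#'
#' @return tibble with columns `species` (normalized id) and `name`
#'   (binomial with authority).
#' @export
published_species_names <- function() {
  tibble::tribble(
    ~species, ~name,
    "anthriscus_sylvestris", "Anthriscus sylvestris (L.) Hoffm.",
    "arctium_minus", "Arctium minus (Hill) Bernh.",
    "foeniculum_vulgare", "Foeniculum vulgare Mill.",
    "hesperis_matronalis", "Hesperis matronalis L.",
    "leucanthemum_vulgare", "Leucanthemum vulgare Lam.",
    "medicago_sativa", "Medicago sativa L.",
    "coronilla_varia", "Coronilla varia L.",
    "trifolium_pratense", "Trifolium pratense L.",
    "achillea_millefolium", "Achillea millefolium L.",
    "alliaria_petiolata", "Alliaria petiolata Cavara & Grande",
    "heracleum_sphondylium", "Heracleum sphondylium L.",
    "cyanus_segetum", "Cyanus segetum L.",
    "trifolium_repens", "Trifolium repens L.",
    "veronica_hederifolia", "Veronica hederifolia L.",
    "centaurea_scabiosa", "Centaurea scabiosa L.",
    "euphorbia_cyparissias", "Euphorbia cyparissias L.",
    "hypericum_perforatum", "Hypericum perforatum L.",
    "tanacetum_vulgare", "Tanacetum vulgare L.",
    "verbascum_densiflorum", "Verbascum densiflorum Bertol.",
    "ajuga_reptans", "Ajuga reptans L.",
    "bellis_perennis", "Bellis perennis L.",
    "capsella_bursa_pastoris", "Capsella bursa-pastoris (L.) Med.",
    "echium_vulgare", "Echium vulgare L.",
    "galium_odoratum", "Galium odoratum (L.) Scop.",
    "malva_sylvestris", "Malva sylvestris L.",
    "potentilla_reptans", "Potentilla reptans L.",
    "carum_carvi", "Carum carvi L.",
    "cynoglossum_officinale", "Cynoglossum officinale L.",
    "daucus_carota", "Daucus carota L.",
    "hypochaeris_radicata", "Hypochaeris radicata L.",
    "jacobaea_vulgaris", "Jacobaea vulgaris L.",
    "lotus_corniculatus", "Lotus corniculatus L.",
    "onobrychis_viciifolia", "Onobrychis viciifolia Scop.",
    "melilotus_altissimus", "Melilotus altissimus Thuill.",
    "barbarea_vulgaris", "Barbarea vulgaris R. Br.",
    "cota_tinctoria", "Cota tinctoria (L.) J.Gay ex Guss.",
    "pastinaca_sativa", "Pastinaca sativa L.",
    "medicago_lupulina", "Medicago lupulina L.",
    "stellaria_media", "Stellaria media (L.) Vill.",
    "vicia_sativa", "Vicia sativa L.",
    "cichorium_intybus", "Cichorium intybus L.",
    "galium_mollugo", "Galium mollugo L.",
    "knautia_arvensis", "Knautia arvensis (L.) Coult.",
    "plantago_lanceolata", "Plantago lanceolata L.",
    "verbascum_lychnitis", "Verbascum lychnitis L.",
    "geum_urbanum", "Geum urbanum L.",
    "glechoma_hederacea", "Glechoma hederacea L.",
    "lamium_album", "Lamium album L.",
    "ranunculus_repens", "Ranunculus repens L.",
    "reseda_luteola", "Reseda luteola L.",
    "taraxacum_ruderalia", "Taraxacum sect. Ruderalia Wiggers",
    "veronica_persica", "Veronica persica Poir.",
    "arrhenatherum_elatius", "Arrhenatherum elatius (L.) P.Beauv.",
    "dactylis_glomerata", "Dactylis glomerata L.",
    "schedonorus_arundinaceus", "Schedonorus arundinaceus Schreb."
  )
}
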