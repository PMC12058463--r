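#' Trait schema for the eight-trait functional trait table
#'
#' The trait model covers eight vegetative and regenerative traits commonly
#' scored for Mediterranean floras: five nominal traits (life form, clonality,
#' nutrient uptake strategy, leaf phenology, dispersal strategy), one interval
#' trait (flowering duration, in months), and two ordinal traits (floral
#' longevity in months; spinescence, a graded 0-6 severity scale). Nominal
#' traits may be multi-valued: a taxon can fit more than one subcategory.
#'
#' Two traits are structurally inapplicable for parts of the flora: leaf
#' phenology is not scored for herbaceous taxa, and floral longevity and
#' flowering duration are not scored for gymnosperms. Structural missingness
#' is represented by an empty cell on disk and `NULL`/`NA` in memory.
#'
#' @param name Trait name; one of the eight canonical names.
#' @return `trait_definition()` returns a list with fields `name`, `kind`
#'   (`"nominal"`, `"interval"` or `"ordinal"`), `codes` (allowed integer
#'   codes), and `not_applicable` (`"herbaceous"`, `"gymnosperm"` or `NA`).
#'   `default_trait_schema()` returns the named list of all eight definitions.
#' @export
default_trait_schema <- function() {
  defs <- list(
    trait_definition("life_form"),
    trait_definition("clonality"),
    trait_definition("nutrient_uptake"),
    trait_definition("spinescence"),
    trait_definition("leaf_phenology"),
    trait_definition("floral_longevity"),
    trait_definition("flowering_duration"),
    trait_definition("dispersal_strategy")
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' @rdname default_trait_schema
#' @export
trait_definition <- function(name) {
  tab <- list(
    life_form          = list(kind = "nominal",  codes = 1:7,  na = NA_character_),
    clonality          = list(kind = "nominal",  codes = 1:7,  na = NA_character_),
    nutrient_uptake    = list(kind = "nominal",  codes = 1:9,  na = NA_character_),
    spinescence        = list(kind = "ordinal",  codes = 0:6,  na = NA_character_),
    leaf_phenology     = list(kind = "nominal",  codes = 1:3,  na = "herbaceous"),
    floral_longevity   = list(kind = "ordinal",  codes = 1:12, na = "gymnosperm"),
    flowering_duration = list(kind = "interval", codes = 1:12, na = "gymnosperm"),
    dispersal_strategy = list(kind = "nominal",  codes = 1:7,  na = NA_character_)
  )
  fdg_assert(name %in% names(tab),
             sprintf("unknown trait '%s'", name), "fdg_schema_error")
  d <- tab[[name]]
  structure(list(name = name, kind = d$kind, codes = d$codes,
                 not_applicable = d$na),
            class = "trait_definition")
}

trait_names <- function(schema = default_trait_schema()) names(schema)
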