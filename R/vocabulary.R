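# Controlled vocabulary for cytological feature profiles.
#
# Each feature of a Nissl-stained cell profile takes one value from a closed
# enum.  The vocabulary is the single source of truth for validation, the
# classifier, the generator and all file I/O.

#' Controlled vocabulary of cytological features
#'
#' Returns the closed set of admissible values for every categorical feature
#' of a cytological profile: overall nuclear staining intensity, nuclear
#' shape, the cytoplasmic rim, the three heterochromatin compartments
#' (peripheral, net, perinucleolar), the nucleolus, euchromatin texture,
#' cytoplasmic inclusions, accessory context flags and species.
#'
#' @return Named list; each element is a character vector of admissible
#'   tokens for that feature (logical features are represented by
#'   `c("TRUE", "FALSE")` for validation purposes).
#' @export
#' @examples
#' cyto_vocabulary()$nuclear_shape
cyto_vocabulary <- function() {
  list(
    nucleus_stain = c("dark", "light"),
    nuclear_shape = c("round", "ovoid", "potato", "elongated", "comma",
                      "polylobular", "molded_to_vessel"),
    cytoplasm_rim = c("continuous_thick", "continuous_thin", "crescent",
                      "not_visible"),
    envelope_folding = c("TRUE", "FALSE"),
    het_peripheral = c("not_visible", "few_granules", "rim_with_granules",
                       "many_small_granules"),
    het_net = c("not_visible", "few_granules_variable_size",
                "rounded_granules_one_larger", "several_granules_same_size",
                "grid_many_small"),
    het_perinucleolar = c("none", "thin_granules", "thick_clumps",
                          "single_thick_granule"),
    nucleolus = c("prominent_large", "medium", "faint", "not_visible"),
    euchromatin_texture = c("empty_unstained", "light_homogeneous",
                            "light_watery", "dark_obscured"),
    inclusions = c("none", "yellow", "greenish"),
    accessory_flags = c("perinuclear_halo", "pinkish_crescent",
                        "neuropil_threads", "molded_to_vessel",
                        "satellite_to_neuron", "satellite_to_vessel"),
    species = c("monkey", "human")
  )
}

#' Fine and rating cell-type label sets
#'
#' The classifier distinguishes six fine types; rating experiments group
#' cells into five types, collapsing large and small neurons into "neuron".
#'
#' @return Character vector of labels, in canonical order.
#' @export
fine_labels <- function() {
  c("large_neuron", "small_neuron", "astrocyte", "oligodendrocyte",
    "microglia", "endothelial")
}

#' @rdname fine_labels
#' @export
rating_labels <- function() {
  c("neuron", "astrocyte", "oligodendrocyte", "microglia", "endothelial")
}

#' Collapse a fine label to its five-category rating label
#'
#' Large and small neurons map to "neuron"; the four non-neuronal types map
#' to themselves.  Vectorized.
#'
#' @param fine Character vector of fine labels.
#' @return Character vector of rating labels.
#' @export
#' @examples
#' collapse_to_rating(c("large_neuron", "microglia"))
collapse_to_rating <- function(fine) {
  bad <- setdiff(unique(fine), fine_labels())
  if (length(bad) > 0) {
    stop("unknown fine label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(fine %in% c("large_neuron", "small_neuron"), "neuron", fine)
}

# Free-text synonyms accepted on input, mapped to canonical tokens.
# Shipped as data in inst/extdata/feature_aliases.csv; this built-in copy is
# the fallback when the package data file is unavailable (e.g. during
# development loads).
.builtin_aliases <- data.frame(
  field = c("nuclear_shape", "nuclear_shape", "nuclear_shape",
            "euchromatin_texture", "euchromatin_texture",
            "euchromatin_texture", "euchromatin_texture",
            "cytoplasm_rim", "cytoplasm_rim",
            "nucleus_stain", "nucleus_stain",
            "nucleolus", "nucleolus"),
  alias = c("potato-shaped", "ovoid with shallow concavities", "comma-shaped",
            "dark blue", "light blue",
            "watery", "empty",
            "thick rim", "thin rim",
            "darkly stained", "lightly stained",
            "large", "not visible"),
  canonical = c("potato", "potato", "comma",
                "dark_obscured", "light_homogeneous",
                "light_watery", "empty_unstained",
                "continuous_thick", "continuous_thin",
                "dark", "light",
                "prominent_large", "not_visible"),
  stringsAsFactors = FALSE
)

#' Alias table mapping free-text feature tokens to canonical vocabulary
#'
#' @return Data frame with columns `field`, `alias`, `canonical`.
#' @export
feature_aliases <- function() {
  path <- system.file("extdata", "feature_aliases.csv", package = "nisslcyto")
  if (nzchar(path) && file.exists(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    .builtin_aliases
  }
}

# Canonicalize one token for a given field: trim, lower-case, map spaces and
# hyphens to underscores, then resolve aliases.
canonicalize_token <- function(field, token, aliases = feature_aliases()) {
  tok <- trimws(as.character(token))
  hit <- aliases$field == field & tolower(aliases$alias) == tolower(tok)
  if (any(hit)) return(aliases$canonical[which(hit)[1]])
  tok <- tolower(gsub("[ -]+", "_", tok))
  hit <- aliases$field == field & tolower(aliases$alias) == tok
  if (any(hit)) return(aliases$canonical[which(hit)[1]])
  tok
}
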