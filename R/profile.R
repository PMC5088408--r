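# Cytological profiles: construction, validation, prototypes, enumeration.

profile_fields <- function() {
  c("nucleus_stain", "nuclear_shape", "cytoplasm_rim", "envelope_folding",
    "het_peripheral", "het_net", "het_perinucleolar", "nucleolus",
    "nucleolus_count", "euchromatin_texture", "inclusions",
    "accessory_flags", "species")
}

new_cyto_profile <- function(x) {
  structure(x[profile_fields()], class = "cyto_profile")
}

#' Validate a raw feature record into a cytological profile
#'
#' Takes a raw key-value record (named list, or one-row data frame) of text
#' tokens, canonicalizes token spelling/case against the controlled
#' vocabulary (including the shipped alias table), and checks every
#' cross-field invariant:
#'
#' * a darkly stained nucleus implies `euchromatin_texture = "dark_obscured"`;
#'   a light nucleus implies one of the three light textures;
#' * `nucleolus = "not_visible"` implies `nucleolus_count = 0`, a visible
#'   nucleolus implies a count of 1 or 2;
#' * `nuclear_shape = "molded_to_vessel"` implies the `molded_to_vessel`
#'   accessory flag.
#'
#' Records carrying a `context` field equal to `"within_basal_membrane"`
#' are rejected: cells inside the endothelial basal membrane (pericytes)
#' cannot be distinguished in thick Nissl-stained sections and are not a
#' classifier output.
#'
#' @param record Named list or one-row data frame.  `accessory_flags` may be
#'   a character vector, a single `";"`-separated string, or absent (empty
#'   set).  `species` defaults to `"monkey"`.
#' @return A `cyto_profile` object satisfying all invariants.
#' @export
#' @examples
#' validate_profile(list(
#'   nucleus_stain = "dark", nuclear_shape = "round",
#'   cytoplasm_rim = "not_visible", envelope_folding = FALSE,
#'   het_peripheral = "few_granules",
#'   het_net = "rounded_granules_one_larger",
#'   het_perinucleolar = "single_thick_granule",
#'   nucleolus = "not_visible", nucleolus_count = 0,
#'   euchromatin_texture = "dark_obscured", inclusions = "none"))
validate_profile <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  voc <- cyto_vocabulary()
  aliases <- feature_aliases()

  ctx <- record[["context"]]
  if (!is.null(ctx) && identical(tolower(trimws(ctx)), "within_basal_membrane")) {
    stop("record rejected: cells within the endothelial basal membrane ",
         "(pericytes) cannot be classified in thick sections")
  }

  flags <- record[["accessory_flags"]]
  if (is.null(flags) || (length(flags) == 1 && is.na(flags))) flags <- character(0)
  if (length(flags) == 1 && is.character(flags) && grepl(";", flags)) {
    flags <- strsplit(flags, ";")[[1]]
  }
  flags <- flags[nzchar(trimws(flags))]
  flags <- vapply(flags, function(f) canonicalize_token("accessory_flags", f, aliases),
                  character(1), USE.NAMES = FALSE)
  bad <- setdiff(flags, voc$accessory_flags)
  if (length(bad) > 0) {
    stop("validation error in field 'accessory_flags': unknown token(s) ",
         paste(sQuote(bad), collapse = ", "))
  }
  flags <- sort(unique(flags))

  if (is.null(record[["species"]])) record$species <- "monkey"

  enum_fields <- c("nucleus_stain", "nuclear_shape", "cytoplasm_rim",
                   "het_peripheral", "het_net", "het_perinucleolar",
                   "nucleolus", "euchromatin_texture", "inclusions", "species")
  out <- list()
  for (f in enum_fields) {
    val <- record[[f]]
    if (is.null(val) || is.na(val)) {
      stop("validation error: required field '", f, "' is missing")
    }
    tok <- canonicalize_token(f, val, aliases)
    if (!(tok %in% voc[[f]])) {
      stop("validation error in field '", f, "': unknown token ", sQuote(val))
    }
    out[[f]] <- tok
  }

  fold <- record[["envelope_folding"]]
  if (is.null(fold) || is.na(fold)) {
    stop("validation error: required field 'envelope_folding' is missing")
  }
  if (is.character(fold)) {
    fold <- toupper(trimws(fold))
    if (!fold %in% c("TRUE", "FALSE", "T", "F", "YES", "NO")) {
      stop("validation error in field 'envelope_folding': unknown token ",
           sQuote(record[["envelope_folding"]]))
    }
    fold <- fold %in% c("TRUE", "T", "YES")
  }
  out$envelope_folding <- isTRUE(as.logical(fold))

  cnt <- record[["nucleolus_count"]]
  if (is.null(cnt) || is.na(cnt)) {
    # default consistent with the visibility invariant
    cnt <- if (out$nucleolus == "not_visible") 0L else 1L
  }
  cnt <- as.integer(cnt)
  if (is.na(cnt) || cnt < 0L || cnt > 2L) {
    stop("validation error in field 'nucleolus_count': must be 0, 1 or 2")
  }
  out$nucleolus_count <- cnt
  out$accessory_flags <- flags

  # cross-field invariants
  if (out$nucleus_stain == "dark" && out$euchromatin_texture != "dark_obscured") {
    stop("consistency error: a darkly stained nucleus obscures euchromatin ",
         "(euchromatin_texture must be 'dark_obscured', got '",
         out$euchromatin_texture, "')")
  }
  if (out$nucleus_stain == "light" && out$euchromatin_texture == "dark_obscured") {
    stop("consistency error: euchromatin_texture 'dark_obscured' requires a ",
         "darkly stained nucleus")
  }
  if (out$nucleolus == "not_visible" && out$nucleolus_count != 0L) {
    stop("consistency error: nucleolus 'not_visible' requires nucleolus_count 0")
  }
  if (out$nucleolus != "not_visible" && !(out$nucleolus_count %in% c(1L, 2L))) {
    stop("consistency error: a visible nucleolus requires nucleolus_count 1 or 2")
  }
  if (out$nuclear_shape == "molded_to_vessel" &&
      !("molded_to_vessel" %in% out$accessory_flags)) {
    stop("consistency error: nuclear_shape 'molded_to_vessel' requires the ",
         "'molded_to_vessel' accessory flag")
  }

  new_cyto_profile(out)
}

#' @export
print.cyto_profile <- function(x, ...) {
  cat("Cytological profile (", x$species, ")\n", sep = "")
  for (f in setdiff(profile_fields(), c("accessory_flags", "species"))) {
    cat(sprintf("  %-20s %s\n", f, as.character(x[[f]])))
  }
  cat(sprintf("  %-20s %s\n", "accessory_flags",
              if (length(x$accessory_flags) == 0) "(none)"
              else paste(x$accessory_flags, collapse = ", ")))
  invisible(x)
}

#' Prototype profiles of the six cortical cell types
#'
#' Returns the modal feature profile for each fine cell type in thick
#' Nissl-stained sections: large neurons (thick cytoplasmic rim, empty
#' euchromatin, prominent nucleolus with at most a few thin perinucleolar
#' granules), small neurons (thin rim, thick perinucleolar heterochromatin
#' clumps, a few net granules of variable size), astrocytes (potato-shaped
#' nucleus, peripheral heterochromatin rim with attached granules,
#' homogeneous light euchromatin), oligodendrocytes (dark round nucleus,
#' 2--4 net granules with one larger than the others), microglia (dark
#' irregular nucleus, many small granules forming a grid) and endothelial
#' cells (nucleus molded to the vessel, peripheral rim with granules, watery
#' euchromatin; transcribed from the prose description, as the feature table
#' has no endothelial column).
#'
#' @param species `"monkey"` (default) or `"human"`; metadata only, the
#'   prototype features are identical.
#' @return Named list of `cyto_profile` objects, one per fine label.
#' @export
prototype_profiles <- function(species = c("monkey", "human")) {
  species <- match.arg(species)
  p <- list(
    large_neuron = list(
      nucleus_stain = "light", nuclear_shape = "round",
      cytoplasm_rim = "continuous_thick", envelope_folding = FALSE,
      het_peripheral = "not_visible", het_net = "not_visible",
      het_perinucleolar = "thin_granules",
      nucleolus = "prominent_large", nucleolus_count = 1,
      euchromatin_texture = "empty_unstained", inclusions = "yellow",
      accessory_flags = character(0)),
    small_neuron = list(
      nucleus_stain = "light", nuclear_shape = "round",
      cytoplasm_rim = "continuous_thin", envelope_folding = FALSE,
      het_peripheral = "few_granules", het_net = "few_granules_variable_size",
      het_perinucleolar = "thick_clumps",
      nucleolus = "medium", nucleolus_count = 1,
      euchromatin_texture = "light_homogeneous", inclusions = "yellow",
      accessory_flags = character(0)),
    astrocyte = list(
      nucleus_stain = "light", nuclear_shape = "potato",
      cytoplasm_rim = "not_visible", envelope_folding = FALSE,
      het_peripheral = "rim_with_granules",
      het_net = "several_granules_same_size",
      het_perinucleolar = "thin_granules",
      nucleolus = "faint", nucleolus_count = 1,
      euchromatin_texture = "light_homogeneous", inclusions = "yellow",
      accessory_flags = character(0)),
    oligodendrocyte = list(
      nucleus_stain = "dark", nuclear_shape = "round",
      cytoplasm_rim = "not_visible", envelope_folding = FALSE,
      het_peripheral = "few_granules",
      het_net = "rounded_granules_one_larger",
      het_perinucleolar = "single_thick_granule",
      nucleolus = "not_visible", nucleolus_count = 0,
      euchromatin_texture = "dark_obscured", inclusions = "none",
      accessory_flags = character(0)),
    microglia = list(
      nucleus_stain = "dark", nuclear_shape = "elongated",
      cytoplasm_rim = "not_visible", envelope_folding = FALSE,
      het_peripheral = "many_small_granules", het_net = "grid_many_small",
      het_perinucleolar = "thin_granules",
      nucleolus = "not_visible", nucleolus_count = 0,
      euchromatin_texture = "dark_obscured", inclusions = "greenish",
      accessory_flags = character(0)),
    endothelial = list(
      nucleus_stain = "light", nuclear_shape = "molded_to_vessel",
      cytoplasm_rim = "not_visible", envelope_folding = FALSE,
      het_peripheral = "rim_with_granules",
      het_net = "several_granules_same_size",
      het_perinucleolar = "none",
      nucleolus = "faint", nucleolus_count = 1,
      euchromatin_texture = "light_watery", inclusions = "none",
      accessory_flags = "molded_to_vessel")
  )
  lapply(p, function(x) {
    x$species <- species
    validate_profile(x)
  })
}

#' Enumerate the decision-relevant profile space
#'
#' Enumerates every valid combination of the features the classifier
#' consults, as a data frame with one row per profile.  The stain/texture
#' pair is enumerated jointly within its valid strata (dark nuclei obscure
#' euchromatin); the nucleolus count is fixed at its canonical value (0 when
#' not visible, 1 otherwise) since the count never changes a decision.
#' Accessory flags are enumerated as the empty set plus each singleton flag
#' (`flags = "singletons"`, default) or restricted to the flags forced by
#' invariants (`flags = "forced"`); the full 2^6 flag power set is
#' available with `flags = "all"` but multiplies the space 64-fold.
#'
#' @param flags One of `"forced"`, `"singletons"`, `"all"`.
#' @param species Species metadata attached to every row.
#' @return Data frame, one row per profile; `accessory_flags` is a
#'   `";"`-separated string column.
#' @export
enumerate_profiles <- function(flags = c("singletons", "forced", "all"),
                               species = "monkey") {
  flags <- match.arg(flags)
  voc <- cyto_vocabulary()
  stain_texture <- rbind(
    data.frame(nucleus_stain = "dark", euchromatin_texture = "dark_obscured",
               stringsAsFactors = FALSE),
    data.frame(nucleus_stain = "light",
               euchromatin_texture = c("empty_unstained", "light_homogeneous",
                                       "light_watery"),
               stringsAsFactors = FALSE))
  flag_sets <- switch(flags,
    forced = list(character(0)),
    singletons = c(list(character(0)), as.list(voc$accessory_flags)),
    all = {
      n <- length(voc$accessory_flags)
      lapply(seq_len(2^n) - 1L, function(m) {
        voc$accessory_flags[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
      })
    })
  grid <- expand.grid(
    st = seq_len(nrow(stain_texture)),
    nuclear_shape = voc$nuclear_shape,
    cytoplasm_rim = voc$cytoplasm_rim,
    envelope_folding = c(TRUE, FALSE),
    het_peripheral = voc$het_peripheral,
    het_net = voc$het_net,
    het_perinucleolar = voc$het_perinucleolar,
    nucleolus = voc$nucleolus,
    inclusions = voc$inclusions,
    flag_set = seq_along(flag_sets),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$nucleus_stain <- stain_texture$nucleus_stain[grid$st]
  grid$euchromatin_texture <- stain_texture$euchromatin_texture[grid$st]
  grid$st <- NULL
  grid$nucleolus_count <- ifelse(grid$nucleolus == "not_visible", 0L, 1L)
  fl <- vapply(flag_sets, paste, character(1), collapse = ";")
  grid$accessory_flags <- fl[grid$flag_set]
  grid$flag_set <- NULL
  # molded shape forces its flag; add it where missing
  need <- grid$nuclear_shape == "molded_to_vessel" &
    !grepl("molded_to_vessel", grid$accessory_flags)
  grid$accessory_flags[need] <- ifelse(
    nzchar(grid$accessory_flags[need]),
    paste0(grid$accessory_flags[need], ";molded_to_vessel"),
    "molded_to_vessel")
  # the forced flag can duplicate an enumerated singleton; drop duplicates
  grid <- grid[!duplicated(grid), , drop = FALSE]
  grid$species <- species
  rownames(grid) <- NULL
  grid[, profile_fields()]
}

# Fast internal constructor from a row of an enumerate_profiles()-style data
# frame: trusts the values, splits the flag string.  Used by the generator
# and bulk classification, which only produce valid combinations.
profile_from_row <- function(row) {
  x <- as.list(row)
  fl <- x$accessory_flags
  x$accessory_flags <- if (is.character(fl) && nzchar(fl)) {
    strsplit(fl, ";")[[1]]
  } else if (is.character(fl)) character(0) else fl
  x$envelope_folding <- as.logical(x$envelope_folding)
  x$nucleolus_count <- as.integer(x$nucleolus_count)
  new_cyto_profile(x)
}
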