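# Four-question decision algorithm over cytological profiles.
#
# Q1  Is the nucleus darkly stained?        -> dark branch (glia) / light
# Q2  Is there a continuous cytoplasm rim?  -> neuron / non-neuron
# Q3  How is heterochromatin distributed?   -> resolves within each branch
# Q4  How is euchromatin stained?           -> astrocyte vs endothelial
#
# Every branch of the published algorithm is applied as a hard rule;
# profiles not matched by any rule are flagged with the candidate set of the
# nearest branch and routed through disambiguate(), with a deterministic
# tie-break so the classifier is a total function.

# Accessory evidence supporting each fine label, used both to report
# supporting features and to break ties.
supporting_evidence <- function(profile, label) {
  fl <- profile$accessory_flags
  ev <- character(0)
  if (label == "microglia") {
    if (profile$inclusions == "greenish") ev <- c(ev, "greenish_inclusions")
    if ("neuropil_threads" %in% fl) ev <- c(ev, "neuropil_threads")
  } else if (label == "oligodendrocyte") {
    if ("perinuclear_halo" %in% fl) ev <- c(ev, "perinuclear_halo")
    if ("pinkish_crescent" %in% fl) ev <- c(ev, "pinkish_crescent")
    if ("satellite_to_neuron" %in% fl) ev <- c(ev, "satellite_to_neuron")
  } else if (label == "astrocyte") {
    if (profile$inclusions == "yellow") ev <- c(ev, "yellow_inclusions")
  } else if (label == "endothelial") {
    if ("molded_to_vessel" %in% fl || profile$nuclear_shape == "molded_to_vessel")
      ev <- c(ev, "molded_to_vessel")
  } else if (label == "small_neuron") {
    if (profile$envelope_folding) ev <- c(ev, "envelope_folding")
  } else if (label == "large_neuron") {
    if (profile$nucleolus == "prominent_large") ev <- c(ev, "prominent_nucleolus")
  }
  ev
}

# Deterministic fallback preference within each recognized ambiguous pair.
.tiebreak_order <- list(
  c("astrocyte", "small_neuron"),
  c("oligodendrocyte", "microglia"),
  c("astrocyte", "endothelial"),
  c("small_neuron", "large_neuron")
)

tiebreak_fallback <- function(candidates) {
  for (ord in .tiebreak_order) {
    if (setequal(candidates, ord)) return(ord[1])
  }
  sort(candidates)[1]
}

make_result <- function(profile, fine, path, ambiguity = "unambiguous",
                        candidates = NULL) {
  structure(list(
    label = list(fine = fine, rating = collapse_to_rating(fine)),
    question_path = path,
    supporting_features = supporting_evidence(profile, fine),
    ambiguity = ambiguity,
    candidates = candidates
  ), class = "cyto_classification")
}

# Resolve a candidate pair left unresolved by the pitfall rules: prefer the
# candidate with more accessory support, then the fixed fallback order.
resolve_tie <- function(profile, candidates, path, tiebreak) {
  support <- vapply(candidates, function(l)
    length(supporting_evidence(profile, l)), integer(1))
  if (max(support) > min(support)) {
    fine <- candidates[which.max(support)]
  } else {
    fine <- tiebreak_fallback(candidates)
  }
  amb <- if (tiebreak) "resolved_by_tiebreak" else "flagged"
  make_result(profile, fine, path, ambiguity = amb, candidates = candidates)
}

#' Disambiguate one of the recognized pitfall pairs
#'
#' Applies the published disambiguation rules for the three hard pairs:
#'
#' * **small neuron vs astrocyte** — heterochromatin centrality: thick
#'   perinucleolar clumps or central net granules of variable size indicate
#'   a small neuron, as does nuclear envelope folding; a peripheral
#'   heterochromatin rim with attached granules indicates an astrocyte.
#' * **microglia vs oligodendrocyte** — many small grains forming a grid
#'   across the nucleus indicate microglia; one or two thicker stand-out
#'   grains (net with one granule larger, or a single thick perinucleolar
#'   granule) indicate an oligodendrocyte.
#' * **astrocyte vs endothelial** — euchromatin texture: homogeneous
#'   staining indicates an astrocyte, watery staining an endothelial cell.
#'
#' @param profile A `cyto_profile`.
#' @param candidates Character vector of exactly two fine labels forming one
#'   of the pairs above.
#' @return The winning fine label, or `NA_character_` when the rules do not
#'   decide (callers then fall back to the tie-break).
#' @export
disambiguate <- function(profile, candidates) {
  pairs <- list(c("small_neuron", "astrocyte"),
                c("microglia", "oligodendrocyte"),
                c("astrocyte", "endothelial"))
  ok <- any(vapply(pairs, function(p) setequal(candidates, p), logical(1)))
  if (!ok) {
    stop("unsupported candidate pair: ", paste(candidates, collapse = ", "))
  }
  if (setequal(candidates, c("small_neuron", "astrocyte"))) {
    if (profile$het_perinucleolar == "thick_clumps") return("small_neuron")
    if (profile$envelope_folding) return("small_neuron")
    if (profile$het_peripheral == "rim_with_granules") return("astrocyte")
    if (profile$het_net == "few_granules_variable_size") return("small_neuron")
    return(NA_character_)
  }
  if (setequal(candidates, c("microglia", "oligodendrocyte"))) {
    if (profile$het_net == "grid_many_small" ||
        profile$het_peripheral == "many_small_granules") return("microglia")
    if (profile$het_net %in% c("rounded_granules_one_larger",
                               "few_granules_variable_size") ||
        profile$het_perinucleolar == "single_thick_granule")
      return("oligodendrocyte")
    return(NA_character_)
  }
  # astrocyte vs endothelial: question 4
  if (profile$euchromatin_texture == "light_watery") return("endothelial")
  if (profile$euchromatin_texture == "light_homogeneous") return("astrocyte")
  NA_character_
}

#' Classify a cytological profile
#'
#' Deterministic, total classification of a valid profile into one of the
#' six fine cell types by the four-question algorithm (see the package
#' vignette for the full rule flow).  The result records the questions
#' traversed, accessory evidence supporting the decision, and whether the
#' profile was unambiguous, resolved by the deterministic tie-break, or
#' flagged.
#'
#' With `tiebreak = FALSE` profiles whose evidence remains balanced after
#' the pitfall rules are labelled by the same deterministic fallback but
#' marked `ambiguity = "flagged"` with their candidate set, for interactive
#' review.
#'
#' @param profile A `cyto_profile` from [validate_profile()].
#' @param tiebreak Logical; apply the deterministic tie-break (default
#'   `TRUE`, the setting used for simulated raters).
#' @return A `cyto_classification` with elements `label` (list with `fine`
#'   and `rating`), `question_path`, `supporting_features`, `ambiguity`, and
#'   `candidates` (non-`NULL` only when the profile was not unambiguous).
#' @export
#' @examples
#' classify(prototype_profiles()$oligodendrocyte)
classify <- function(profile, tiebreak = TRUE) {
  stopifnot(inherits(profile, "cyto_profile"))
  p <- profile

  if (p$nucleus_stain == "dark") {
    # Q1 dark branch: shape separates most microglia immediately
    if (p$nuclear_shape %in% c("elongated", "comma", "polylobular")) {
      return(make_result(p, "microglia", "Q1"))
    }
    # round/ovoid (and any other dark shape): Q3 on heterochromatin
    path <- c("Q1", "Q3")
    grid_like <- p$het_peripheral == "many_small_granules" ||
      p$het_net == "grid_many_small"
    oligo_like <- p$het_net %in% c("rounded_granules_one_larger",
                                   "few_granules_variable_size") &&
      p$het_peripheral %in% c("not_visible", "few_granules")
    if (grid_like && !oligo_like) return(make_result(p, "microglia", path))
    if (oligo_like && !grid_like) return(make_result(p, "oligodendrocyte", path))
    cand <- c("microglia", "oligodendrocyte")
    fine <- disambiguate(p, cand)
    if (!is.na(fine)) {
      return(make_result(p, fine, path, ambiguity = "resolved_by_tiebreak",
                         candidates = cand))
    }
    return(resolve_tie(p, cand, path, tiebreak))
  }

  # Q2: light nucleus -- continuous cytoplasmic rim?
  if (p$cytoplasm_rim %in% c("continuous_thick", "continuous_thin")) {
    # neuron; Q3 separates large from small
    path <- c("Q1", "Q2", "Q3")
    if (p$euchromatin_texture == "empty_unstained" &&
        p$het_perinucleolar %in% c("none", "thin_granules") &&
        p$nucleolus == "prominent_large") {
      return(make_result(p, "large_neuron", path))
    }
    if (p$het_perinucleolar == "thick_clumps" &&
        p$het_net == "few_granules_variable_size") {
      return(make_result(p, "small_neuron", path))
    }
    # residual neuron profiles: the empty-looking nucleus is the large-neuron
    # hallmark, any stained euchromatin points to a small neuron
    cand <- c("large_neuron", "small_neuron")
    fine <- if (p$euchromatin_texture == "empty_unstained")
      "large_neuron" else "small_neuron"
    amb <- if (tiebreak) "resolved_by_tiebreak" else "flagged"
    return(make_result(p, fine, path, ambiguity = amb, candidates = cand))
  }

  # light nucleus, no continuous rim: small neuron with an indiscernible rim,
  # astrocyte, or endothelial cell
  path <- c("Q1", "Q2", "Q3")
  central_het <- p$het_perinucleolar == "thick_clumps" || p$envelope_folding
  if (p$het_peripheral == "rim_with_granules" && !central_het) {
    # Q4: euchromatin texture separates astrocyte from endothelial
    path <- c(path, "Q4")
    if (p$euchromatin_texture == "light_homogeneous") {
      return(make_result(p, "astrocyte", path))
    }
    if (p$euchromatin_texture == "light_watery") {
      return(make_result(p, "endothelial", path))
    }
    cand <- c("astrocyte", "endothelial")
    return(resolve_tie(p, cand, path, tiebreak))
  }
  if (central_het) {
    cand <- c("small_neuron", "astrocyte")
    fine <- disambiguate(p, cand)
    if (!is.na(fine)) {
      return(make_result(p, fine, path, ambiguity = "resolved_by_tiebreak",
                         candidates = cand))
    }
    return(resolve_tie(p, cand, path, tiebreak))
  }
  # low-information light profile without a peripheral rim: decide between
  # astrocyte and endothelial on euchromatin texture
  path <- c(path, "Q4")
  cand <- c("astrocyte", "endothelial")
  fine <- disambiguate(p, cand)
  if (!is.na(fine)) {
    amb <- if (tiebreak) "resolved_by_tiebreak" else "flagged"
    return(make_result(p, fine, path, ambiguity = amb, candidates = cand))
  }
  resolve_tie(p, cand, path, tiebreak)
}

#' @export
print.cyto_classification <- function(x, ...) {
  cat("Classification:", x$label$fine,
      sprintf("(rating: %s)\n", x$label$rating))
  cat("  path:", paste(x$question_path, collapse = " -> "), "\n")
  cat("  ambiguity:", x$ambiguity, "\n")
  if (!is.null(x$candidates)) {
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  }
  if (length(x$supporting_features) > 0) {
    cat("  supporting:", paste(x$supporting_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify every row of a profile table
#'
#' @param profiles Data frame in the [enumerate_profiles()] dialect (one row
#'   per cell), or a list of `cyto_profile` objects.
#' @param tiebreak Passed to [classify()].
#' @return Data frame with columns `fine`, `rating`, `ambiguity`,
#'   `question_path` (collapsed with `"+"`).
#' @export
classify_profiles <- function(profiles, tiebreak = TRUE) {
  if (is.data.frame(profiles)) {
    # column-wise extraction: far cheaper than slicing rows of a data frame
    cols <- lapply(profiles[profile_fields()], function(x) x)
    cols$accessory_flags <- strsplit(
      ifelse(is.na(cols$accessory_flags), "", cols$accessory_flags), ";",
      fixed = TRUE)
    cols$envelope_folding <- as.logical(cols$envelope_folding)
    cols$nucleolus_count <- as.integer(cols$nucleolus_count)
    profiles <- lapply(seq_len(nrow(profiles)), function(i) {
      new_cyto_profile(lapply(cols, `[[`, i))
    })
  }
  res <- lapply(profiles, classify, tiebreak = tiebreak)
  data.frame(
    fine = vapply(res, function(r) r$label$fine, character(1)),
    rating = vapply(res, function(r) r$label$rating, character(1)),
    ambiguity = vapply(res, function(r) r$ambiguity, character(1)),
    question_path = vapply(res, function(r)
      paste(r$question_path, collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
}
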