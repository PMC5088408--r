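# Synthetic data: labeled profile generation with biological variability,
# rater perturbation models (experimental noise), and simulation of the
# two-test rating experiment.

# Deterministic child-seed expansion: one master seed yields a reproducible
# stream of sub-seeds for the independent stages (profile generation, each
# rater's perturbations), so that results are identical across runs and do
# not depend on evaluation order.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

norm_dist <- function(x) {
  if (any(x < 0) || sum(x) <= 0) stop("config error: invalid distribution")
  x / sum(x)
}

#' Configuration of the labeled-profile generator
#'
#' Per-type feature distributions emulating biological variability around
#' the modal profile of each cell type.  Defaults put 0.8 of the mass on the
#' modal feature value and spread the rest over documented variants (e.g.
#' microglial nuclei are mostly elongated/comma/polylobular but some are
#' round or ovoid; some oligodendrocyte nuclei, particularly human ones, are
#' lightly stained; the thin cytoplasmic rim of some small neurons is not
#' discernible).  All rates are exposed; `prototype_mode = TRUE` collapses
#' every distribution onto its modal value so that generation reproduces the
#' six prototype profiles exactly.
#'
#' @param species `"monkey"` or `"human"`; shifts a few priors (light
#'   oligodendrocytes and astrocytic inclusions are more common in human
#'   tissue).  Never affects the decision rules.
#' @param outlier_rates Named list overriding any of
#'   `microglia_round_ovoid` (probability a microglial nucleus is round or
#'   ovoid; default 0.35), `oligo_light_stain` (probability an
#'   oligodendrocyte nucleus is lightly stained; default 0.03 monkey, 0.10
#'   human), `small_neuron_rim_not_visible` (probability a small neuron's
#'   rim cannot be seen; default 0.15).
#' @param prototype_mode Logical; all mass on modal values.
#' @return A `profile_generator_config`: list of per-type, per-feature
#'   probability tables.
#' @export
profile_generator_config <- function(species = c("monkey", "human"),
                                     outlier_rates = list(),
                                     prototype_mode = FALSE) {
  species <- match.arg(species)
  rates <- list(microglia_round_ovoid = 0.35,
                oligo_light_stain = if (species == "human") 0.10 else 0.03,
                small_neuron_rim_not_visible = 0.15)
  rates[names(outlier_rates)] <- outlier_rates
  for (r in rates) {
    if (r < 0 || r >= 1) stop("config error: outlier rates must be in [0, 1)")
  }

  d <- function(...) norm_dist(c(...))
  mg_ro <- rates$microglia_round_ovoid
  types <- list(
    large_neuron = list(
      nucleus_stain = d(light = 1),
      nuclear_shape = d(round = 0.5, ovoid = 0.5),
      cytoplasm_rim = d(continuous_thick = 0.9, continuous_thin = 0.1),
      envelope_folding = d("TRUE" = 0.3, "FALSE" = 0.7),
      het_peripheral = d(not_visible = 0.9, few_granules = 0.1),
      het_net = d(not_visible = 0.9, few_granules_variable_size = 0.1),
      het_perinucleolar = d(thin_granules = 0.8, none = 0.2),
      nucleolus = d(prominent_large = 1),
      nucleolus_count = d("1" = 0.9, "2" = 0.1),
      euchromatin_texture = d(empty_unstained = 1),
      inclusions = d(yellow = 0.8, none = 0.2),
      flag_rates = c()),
    small_neuron = list(
      nucleus_stain = d(light = 1),
      nuclear_shape = d(round = 0.5, ovoid = 0.5),
      cytoplasm_rim = d(continuous_thin = 1 - rates$small_neuron_rim_not_visible,
                        not_visible = rates$small_neuron_rim_not_visible),
      envelope_folding = d("TRUE" = 0.3, "FALSE" = 0.7),
      het_peripheral = d(few_granules = 0.8, not_visible = 0.2),
      het_net = d(few_granules_variable_size = 0.8, not_visible = 0.2),
      het_perinucleolar = d(thick_clumps = 0.8, single_thick_granule = 0.1,
                            thin_granules = 0.1),
      nucleolus = d(medium = 0.8, faint = 0.2),
      nucleolus_count = d("1" = 1),
      euchromatin_texture = d(light_homogeneous = 1),
      inclusions = d(yellow = 0.6, none = 0.4),
      flag_rates = c()),
    astrocyte = list(
      nucleus_stain = d(light = 1),
      nuclear_shape = d(potato = 0.8, ovoid = 0.2),
      cytoplasm_rim = d(not_visible = 0.95, crescent = 0.05),
      envelope_folding = d("TRUE" = 0.1, "FALSE" = 0.9),
      het_peripheral = d(rim_with_granules = 0.8, few_granules = 0.2),
      het_net = d(several_granules_same_size = 0.8,
                  few_granules_variable_size = 0.2),
      het_perinucleolar = d(thin_granules = 0.7, none = 0.3),
      nucleolus = if (species == "human") d(faint = 0.7, not_visible = 0.3)
                  else d(not_visible = 0.6, faint = 0.4),
      nucleolus_count = d("1" = 1),
      euchromatin_texture = d(light_homogeneous = 1),
      inclusions = if (species == "human") d(yellow = 0.8, none = 0.2)
                   else d(yellow = 0.5, none = 0.5),
      flag_rates = c(neuropil_threads = 0.1, satellite_to_neuron = 0.15,
                     satellite_to_vessel = 0.15)),
    oligodendrocyte = list(
      nucleus_stain = d(dark = 1 - rates$oligo_light_stain,
                        light = rates$oligo_light_stain),
      nuclear_shape = d(round = 0.9, ovoid = 0.1),
      cytoplasm_rim = d(not_visible = 0.7, crescent = 0.3),
      envelope_folding = d("FALSE" = 1),
      het_peripheral = d(few_granules = 0.8, not_visible = 0.2),
      het_net = if (species == "human")
                  d(rounded_granules_one_larger = 0.6,
                    several_granules_same_size = 0.4)
                else d(rounded_granules_one_larger = 0.8,
                       several_granules_same_size = 0.2),
      het_perinucleolar = d(single_thick_granule = 0.7, thin_granules = 0.3),
      nucleolus = d(not_visible = 0.6, faint = 0.4),
      nucleolus_count = d("1" = 1),
      euchromatin_texture = d(dark_obscured = 1),
      inclusions = d(none = 1),
      flag_rates = c(perinuclear_halo = 0.3, pinkish_crescent = 0.2,
                     satellite_to_neuron = 0.3)),
    microglia = list(
      nucleus_stain = if (species == "human") d(dark = 0.95, light = 0.05)
                      else d(dark = 1),
      nuclear_shape = d(elongated = (1 - mg_ro) * 35 / 65,
                        comma = (1 - mg_ro) * 15 / 65,
                        polylobular = (1 - mg_ro) * 15 / 65,
                        round = mg_ro * 4 / 7,
                        ovoid = mg_ro * 3 / 7),
      cytoplasm_rim = d(not_visible = 1),
      envelope_folding = d("TRUE" = 0.1, "FALSE" = 0.9),
      het_peripheral = d(many_small_granules = 0.9, rim_with_granules = 0.1),
      het_net = d(grid_many_small = 0.9, several_granules_same_size = 0.1),
      het_perinucleolar = d(thin_granules = 0.8, none = 0.2),
      nucleolus = d(not_visible = 0.8, faint = 0.2),
      nucleolus_count = d("1" = 1),
      euchromatin_texture = d(dark_obscured = 1),
      inclusions = d(greenish = 0.4, none = 0.6),
      flag_rates = c(neuropil_threads = 0.3, satellite_to_neuron = 0.1,
                     satellite_to_vessel = 0.1)),
    endothelial = list(
      nucleus_stain = d(light = 1),
      nuclear_shape = d(molded_to_vessel = 0.7, ovoid = 0.3),
      cytoplasm_rim = d(not_visible = 1),
      envelope_folding = d("FALSE" = 1),
      het_peripheral = d(rim_with_granules = 0.7, few_granules = 0.3),
      het_net = d(several_granules_same_size = 0.6,
                  rounded_granules_one_larger = 0.4),
      het_perinucleolar = d(none = 0.7, thin_granules = 0.3),
      nucleolus = d(not_visible = 0.6, faint = 0.4),
      nucleolus_count = d("1" = 1),
      euchromatin_texture = d(light_watery = 1),
      inclusions = d(none = 1),
      flag_rates = c())
  )

  if (prototype_mode) {
    proto <- prototype_profiles(species)
    types <- lapply(names(types), function(ty) {
      tl <- types[[ty]]
      pp <- proto[[ty]]
      for (f in setdiff(names(tl), "flag_rates")) {
        val <- if (f == "nucleolus_count") as.character(pp[[f]])
               else as.character(pp[[f]])
        dd <- 1
        names(dd) <- val
        tl[[f]] <- dd
      }
      tl$flag_rates <- c()
      pr_flags <- pp$accessory_flags
      if (length(pr_flags) > 0) {
        tl$flag_rates <- stats::setNames(rep(1, length(pr_flags)), pr_flags)
      }
      tl
    })
    names(types) <- fine_labels()
  }

  structure(list(species = species, outlier_rates = rates,
                 prototype_mode = prototype_mode, types = types),
            class = "profile_generator_config")
}

sample_token <- function(dist) {
  if (length(dist) == 1) return(names(dist))
  sample(names(dist), 1, prob = dist)
}

# Repair cross-field invariants after independent feature draws or
# perturbation; the euchromatin texture follows the stain stratum.
repair_profile <- function(x) {
  if (x$nucleus_stain == "dark") {
    x$euchromatin_texture <- "dark_obscured"
  } else if (x$euchromatin_texture == "dark_obscured") {
    x$euchromatin_texture <- "light_homogeneous"
  }
  if (x$nucleolus == "not_visible") {
    x$nucleolus_count <- 0L
  } else if (x$nucleolus_count == 0L) {
    x$nucleolus_count <- 1L
  }
  if (x$nuclear_shape == "molded_to_vessel" &&
      !("molded_to_vessel" %in% x$accessory_flags)) {
    x$accessory_flags <- sort(c(x$accessory_flags, "molded_to_vessel"))
  }
  x
}

#' Generate labeled cytological profiles
#'
#' Draws each feature independently from the per-type distributions of the
#' configuration, repairs cross-field invariants, and attaches the
#' ground-truth fine label.  Reproducible under a fixed seed.
#'
#' @param config A [profile_generator_config()].
#' @param counts Named integer vector of profiles per fine type, e.g.
#'   `c(large_neuron = 10, microglia = 5)`.
#' @param seed Integer seed.
#' @return Data frame in the [enumerate_profiles()] dialect with an extra
#'   `true_fine` column (and `true_rating`, its five-way collapse).
#' @export
#' @examples
#' cfg <- profile_generator_config(prototype_mode = TRUE)
#' generate_profiles(cfg, c(oligodendrocyte = 1), seed = 1)
generate_profiles <- function(config, counts, seed = 1) {
  stopifnot(inherits(config, "profile_generator_config"))
  bad <- setdiff(names(counts), fine_labels())
  if (length(bad) > 0) stop("config error: unknown cell type(s) ",
                            paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("config error: counts must be >= 0")
  set.seed(as.integer(seed %% .Machine$integer.max))
  rows <- list()
  for (ty in names(counts)) {
    tl <- config$types[[ty]]
    for (i in seq_len(counts[[ty]])) {
      x <- list(
        nucleus_stain = sample_token(tl$nucleus_stain),
        nuclear_shape = sample_token(tl$nuclear_shape),
        cytoplasm_rim = sample_token(tl$cytoplasm_rim),
        envelope_folding = sample_token(tl$envelope_folding) == "TRUE",
        het_peripheral = sample_token(tl$het_peripheral),
        het_net = sample_token(tl$het_net),
        het_perinucleolar = sample_token(tl$het_perinucleolar),
        nucleolus = sample_token(tl$nucleolus),
        nucleolus_count = as.integer(sample_token(tl$nucleolus_count)),
        euchromatin_texture = sample_token(tl$euchromatin_texture),
        inclusions = sample_token(tl$inclusions),
        species = config$species)
      fr <- tl$flag_rates
      flags <- character(0)
      if (length(fr) > 0) {
        on_ <- stats::runif(length(fr)) < fr
        flags <- names(fr)[on_]
      }
      x$accessory_flags <- sort(flags)
      x <- repair_profile(x)
      x$accessory_flags <- paste(x$accessory_flags, collapse = ";")
      x$true_fine <- ty
      rows[[length(rows) + 1]] <- as.data.frame(x, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("config error: no profiles requested")
  }
  out <- do.call(rbind, rows)
  out$true_rating <- collapse_to_rating(out$true_fine)
  rownames(out) <- NULL
  out[, c(profile_fields(), "true_fine", "true_rating")]
}

#' Default confusable-value map
#'
#' For each feature value, the set of values a rater may mis-see it as under
#' experimental noise: staining intensity can flip (darkly stained nuclei
#' may appear light and vice versa), a thin cytoplasmic rim may be missed, a
#' watery euchromatin texture mistaken for a homogeneous one, a net granule
#' pattern misread, and so on.  Perturbation only ever substitutes within
#' this map, so perturbed profiles stay valid after invariant repair.
#'
#' @return Named list (per feature) of named lists (per value) of character
#'   vectors of confusable values.
#' @export
default_confusable_map <- function() {
  list(
    nucleus_stain = list(dark = "light", light = "dark"),
    nuclear_shape = list(round = "ovoid",
                         ovoid = c("round", "potato"),
                         potato = "ovoid",
                         elongated = "comma",
                         comma = "elongated",
                         polylobular = "elongated",
                         molded_to_vessel = "ovoid"),
    # omission is easier than hallucination: a thin rim can be missed, but
    # an absent rim is at most mistaken for a partial crescent
    cytoplasm_rim = list(continuous_thick = "continuous_thin",
                         continuous_thin = "not_visible",
                         crescent = "not_visible",
                         not_visible = "crescent"),
    envelope_folding = list("TRUE" = "FALSE", "FALSE" = "TRUE"),
    het_peripheral = list(not_visible = "few_granules",
                          few_granules = c("not_visible", "rim_with_granules"),
                          rim_with_granules = "few_granules",
                          many_small_granules = "rim_with_granules"),
    het_net = list(not_visible = "few_granules_variable_size",
                   few_granules_variable_size =
                     c("not_visible", "several_granules_same_size"),
                   rounded_granules_one_larger = "grid_many_small",
                   several_granules_same_size =
                     c("rounded_granules_one_larger",
                       "few_granules_variable_size"),
                   grid_many_small = "rounded_granules_one_larger"),
    het_perinucleolar = list(none = "thin_granules",
                             thin_granules = c("none", "thick_clumps"),
                             thick_clumps = c("thin_granules",
                                              "single_thick_granule"),
                             single_thick_granule = "thin_granules"),
    nucleolus = list(prominent_large = "medium",
                     medium = c("prominent_large", "faint"),
                     faint = c("medium", "not_visible"),
                     not_visible = "faint"),
    euchromatin_texture = list(empty_unstained = "light_homogeneous",
                               light_homogeneous = c("empty_unstained",
                                                     "light_watery"),
                               light_watery = "light_homogeneous",
                               dark_obscured = character(0)),
    inclusions = list(none = character(0), yellow = "none",
                      greenish = "none")
  )
}

#' Rater perturbation model
#'
#' A simulated rater mis-sees each feature of a profile independently with
#' probability `theta`, substituting a uniform draw from that value's
#' confusable set.  `theta = 0` reproduces ground truth exactly.  Default
#' calibration: experienced raters `theta = 0.04`, inexperienced
#' `theta = 0.10`.
#'
#' @param id Rater identifier.
#' @param theta Per-feature perturbation probability in `[0, 1]`.
#' @param experience `"experienced"` or `"inexperienced"`; when `theta` is
#'   missing it defaults from the experience tag.
#' @param confusable Confusable-value map; see [default_confusable_map()].
#' @param feature_weights Optional named numeric vector scaling the flip
#'   probability per feature (`theta * weight`); features not named keep
#'   weight 1.  The calibrated default panel down-weights the overall
#'   staining-intensity judgment (see [default_rater_panel()]); a bare
#'   `rater_model()` perturbs every feature at the same rate `theta`.
#' @return A `rater_model`.
#' @export
rater_model <- function(id, theta = NULL,
                        experience = c("experienced", "inexperienced"),
                        confusable = default_confusable_map(),
                        feature_weights = NULL) {
  experience <- match.arg(experience)
  if (is.null(theta)) {
    theta <- if (experience == "experienced") 0.04 else 0.10
  }
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  w <- stats::setNames(rep(1, length(confusable)), names(confusable))
  if (!is.null(feature_weights)) {
    bad <- setdiff(names(feature_weights), names(confusable))
    if (length(bad) > 0) stop("unknown feature(s) in weights: ",
                              paste(bad, collapse = ", "))
    w[names(feature_weights)] <- feature_weights
  }
  structure(list(id = id, theta = theta, experience = experience,
                 confusable = confusable, feature_weights = w),
            class = "rater_model")
}

#' Default eight-rater panel
#'
#' Three experienced raters (`theta = 0.04`) and five inexperienced raters
#' (`theta = 0.10`), mirroring the composition of the rating experiment the
#' simulator emulates.  The panel down-weights flips of the overall
#' staining-intensity judgment (weight 0.3): dark-vs-light is a coarse
#' gestalt call misjudged less often than fine granule patterns, and an
#' unweighted flip rate would let whole-branch switches dominate the
#' disagreement structure.
#'
#' @param theta_experienced,theta_inexperienced Override the default rates.
#' @param feature_weights Per-feature flip-rate weights shared by the panel.
#' @return List of [rater_model()] objects named `R1`..`R8`.
#' @export
default_rater_panel <- function(theta_experienced = 0.04,
                                theta_inexperienced = 0.10,
                                feature_weights = c(nucleus_stain = 0.3)) {
  panel <- c(
    lapply(1:3, function(i) rater_model(paste0("R", i),
                                        theta = theta_experienced,
                                        experience = "experienced",
                                        feature_weights = feature_weights)),
    lapply(4:8, function(i) rater_model(paste0("R", i),
                                        theta = theta_inexperienced,
                                        experience = "inexperienced",
                                        feature_weights = feature_weights)))
  names(panel) <- vapply(panel, `[[`, character(1), "id")
  panel
}

#' Perturb a profile through a rater's eyes
#'
#' @param profile A `cyto_profile` (or a one-row data frame in the table
#'   dialect).
#' @param rater A [rater_model()].
#' @return A valid `cyto_profile`; identical to the input when
#'   `rater$theta = 0`.
#' @export
perturb_profile <- function(profile, rater) {
  stopifnot(inherits(rater, "rater_model"))
  if (!inherits(profile, "cyto_profile")) {
    profile <- profile_from_row(profile)
  }
  x <- unclass(profile)
  cm <- rater$confusable
  feats <- names(cm)
  w <- rater$feature_weights[feats]
  w[is.na(w)] <- 1
  flips <- stats::runif(length(feats)) < rater$theta * w
  for (k in which(flips)) {
    f <- feats[k]
    cur <- as.character(x[[f]])
    set <- cm[[f]][[cur]]
    if (length(set) == 0) next
    pick <- if (length(set) == 1) set else sample(set, 1)
    x[[f]] <- if (f == "envelope_folding") pick == "TRUE" else pick
  }
  x <- repair_profile(x)
  new_cyto_profile(x)
}

#' Design of a rating experiment
#'
#' @param tests Named list; each element has `n_units` (cells in the test)
#'   and `raters` (rater IDs participating).  The default mirrors the
#'   two-test structure the simulator emulates: test 1 with 236 cells rated
#'   by all eight raters, test 2 with 114 cells rated by seven (one
#'   inexperienced rater unavailable).
#' @param composition Per-rating-category unit proportions; default uniform
#'   over the five categories, neurons split evenly between large and small.
#' @return A `rating_design`.
#' @export
rating_design <- function(tests = NULL, composition = NULL) {
  if (is.null(tests)) {
    all_r <- paste0("R", 1:8)
    tests <- list(test1 = list(n_units = 236, raters = all_r),
                  test2 = list(n_units = 114, raters = setdiff(all_r, "R8")))
  }
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 5, 5), rating_labels())
  }
  composition <- norm_dist(composition)
  structure(list(tests = tests, composition = composition),
            class = "rating_design")
}

# Deterministic per-test fine-type counts realizing the design composition:
# largest-remainder apportionment over rating categories, neurons split
# between large and small (large gets the ceiling).
design_type_counts <- function(n_units, composition) {
  quota <- n_units * composition
  base <- floor(quota)
  rem <- n_units - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  counts <- stats::setNames(integer(length(fine_labels())), fine_labels())
  for (cat in names(base)) {
    if (cat == "neuron") {
      counts["large_neuron"] <- ceiling(base[[cat]] / 2)
      counts["small_neuron"] <- base[[cat]] - counts["large_neuron"]
    } else {
      counts[cat] <- base[[cat]]
    }
  }
  counts
}

#' Simulate a panel of raters applying the algorithm
#'
#' Generates ground-truth profiles for each test per the design composition,
#' then, for every assigned rater and unit, perturbs the profile through the
#' rater's noise model, classifies the perturbed profile with tie-breaking
#' enabled, and records the five-way rating label.  Units of a test are
#' missing (`NA`) for raters not assigned to that test.
#'
#' @param config A [profile_generator_config()].
#' @param raters List of [rater_model()] objects (e.g.
#'   [default_rater_panel()]).
#' @param design A [rating_design()].
#' @param seed Master seed; expands deterministically into per-stage and
#'   per-rater child seeds.
#' @return List with `ratings` (a [ratings_table()] with experience and test
#'   metadata) and `profiles` (the ground-truth profile table with
#'   `true_fine`/`true_rating` and a `test` column).
#' @export
simulate_ratings <- function(config = profile_generator_config(),
                             raters = default_rater_panel(),
                             design = rating_design(),
                             seed = 1) {
  stopifnot(inherits(design, "rating_design"))
  if (length(raters) < 2) stop("need at least two raters")
  rater_ids <- unname(vapply(raters, `[[`, character(1), "id"))
  names(raters) <- rater_ids
  n_tests <- length(design$tests)
  seeds <- derive_seeds(seed, n_tests * (1 + length(raters)))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  prof_list <- list()
  rating_rows <- list()
  unit_test <- character(0)
  for (tn in names(design$tests)) {
    tt <- design$tests[[tn]]
    counts <- design_type_counts(tt$n_units, design$composition)
    profs <- generate_profiles(config, counts, seed = nxt())
    profs$test <- tn
    # shuffle unit order within the test so type blocks are not contiguous
    profs <- profs[sample(nrow(profs)), , drop = FALSE]
    prof_list[[tn]] <- profs
    lab <- matrix(NA_character_, nrow(profs), length(raters),
                  dimnames = list(NULL, rater_ids))
    for (rid in rater_ids) {
      rseed <- nxt()
      if (!(rid %in% tt$raters)) next
      set.seed(as.integer(rseed %% .Machine$integer.max))
      for (u in seq_len(nrow(profs))) {
        p <- perturb_profile(profs[u, , drop = FALSE], raters[[rid]])
        lab[u, rid] <- classify(p, tiebreak = TRUE)$label$rating
      }
    }
    rating_rows[[tn]] <- lab
    unit_test <- c(unit_test, rep(tn, nrow(profs)))
  }
  profiles <- do.call(rbind, prof_list)
  profiles$cell_id <- sprintf("cell%03d", seq_len(nrow(profiles)))
  rownames(profiles) <- profiles$cell_id
  values <- do.call(rbind, rating_rows)
  rownames(values) <- profiles$cell_id
  experience <- vapply(raters, `[[`, character(1), "experience")
  names(experience) <- rater_ids
  list(
    ratings = ratings_table(values, rater_experience = experience,
                            unit_test = unit_test),
    profiles = profiles)
}
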