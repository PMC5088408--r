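# Independent oracles used to cross-check the package implementation.
#
# oracle_classify() is a second, flat transcription of the four-question
# decision flow, coded as vectorized logical expressions over a profile
# table rather than the staged per-profile rule engine in the package.
# oracle_alpha() computes nominal Krippendorff's alpha by direct per-pair
# enumeration from the raw ratings, never touching the coincidence matrix.

oracle_classify <- function(df) {
  has_flag <- function(x) grepl(x, df$accessory_flags, fixed = TRUE)

  dark <- df$nucleus_stain == "dark"
  irregular <- df$nuclear_shape %in% c("elongated", "comma", "polylobular")
  grid <- df$het_peripheral == "many_small_granules" |
    df$het_net == "grid_many_small"
  oligo_pat <- df$het_net %in% c("rounded_granules_one_larger",
                                 "few_granules_variable_size") &
    df$het_peripheral %in% c("not_visible", "few_granules")
  sup_mic <- (df$inclusions == "greenish") + has_flag("neuropil_threads")
  sup_oli <- has_flag("perinuclear_halo") + has_flag("pinkish_crescent") +
    has_flag("satellite_to_neuron")

  dark_label <- ifelse(irregular, "microglia",
    ifelse(grid & !oligo_pat, "microglia",
    ifelse(oligo_pat & !grid, "oligodendrocyte",
    ifelse(grid, "microglia",  # conflicting grid + oligo pattern
    ifelse(df$het_net %in% c("rounded_granules_one_larger",
                             "few_granules_variable_size") |
             df$het_perinucleolar == "single_thick_granule",
           "oligodendrocyte",
    ifelse(sup_mic > sup_oli, "microglia", "oligodendrocyte"))))))

  rimmed <- df$cytoplasm_rim %in% c("continuous_thick", "continuous_thin")
  large1 <- df$euchromatin_texture == "empty_unstained" &
    df$het_perinucleolar %in% c("none", "thin_granules") &
    df$nucleolus == "prominent_large"
  small1 <- df$het_perinucleolar == "thick_clumps" &
    df$het_net == "few_granules_variable_size"
  neuron_label <- ifelse(large1, "large_neuron",
    ifelse(small1, "small_neuron",
    ifelse(df$euchromatin_texture == "empty_unstained",
           "large_neuron", "small_neuron")))

  central <- df$het_perinucleolar == "thick_clumps" |
    as.logical(df$envelope_folding)
  sup_astro <- as.integer(df$inclusions == "yellow")
  sup_endo <- as.integer(has_flag("molded_to_vessel") |
                           df$nuclear_shape == "molded_to_vessel")
  ae_label <- ifelse(df$euchromatin_texture == "light_homogeneous", "astrocyte",
    ifelse(df$euchromatin_texture == "light_watery", "endothelial",
    ifelse(sup_endo > sup_astro, "endothelial", "astrocyte")))
  norim_label <- ifelse(central, "small_neuron", ae_label)

  ifelse(dark, dark_label, ifelse(rimmed, neuron_label, norim_label))
}

oracle_alpha <- function(values) {
  n <- 0
  disagree_w <- 0
  cats <- sort(unique(values[!is.na(values)]))
  marg <- stats::setNames(numeric(length(cats)), cats)
  for (u in seq_len(nrow(values))) {
    vals <- values[u, ]
    vals <- vals[!is.na(vals)]
    m_u <- length(vals)
    if (m_u < 2) next
    n <- n + m_u
    for (cc in vals) marg[cc] <- marg[cc] + 1
    d <- 0
    for (i in seq_len(m_u)) {
      for (j in seq_len(m_u)) {
        if (i != j && vals[i] != vals[j]) d <- d + 1
      }
    }
    disagree_w <- disagree_w + d / (m_u - 1)
  }
  if (n < 2) return(NA_real_)
  D_o <- disagree_w / n
  D_e <- (n^2 - sum(marg^2)) / (n * (n - 1))
  if (D_e <= 0) return(NA_real_)
  1 - D_o / D_e
}

# Random ratings table with optional missingness, for property tests.
random_ratings <- function(n_units, n_raters, miss = 0, n_cat = 5,
                           agree_bias = 0) {
  cats <- rating_labels()[seq_len(n_cat)]
  vals <- matrix(sample(cats, n_units * n_raters, replace = TRUE),
                 n_units, n_raters)
  if (agree_bias > 0) {
    truth <- sample(cats, n_units, replace = TRUE)
    keep <- matrix(runif(n_units * n_raters) < agree_bias, n_units, n_raters)
    vals[keep] <- truth[row(vals)[keep]]
  }
  if (miss > 0) vals[runif(length(vals)) < miss] <- NA_character_
  ratings_table(vals, categories = cats)
}
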