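test_that("prototype mode reproduces the six prototype profiles exactly", {
  cfg <- profile_generator_config(prototype_mode = TRUE)
  counts <- stats::setNames(rep(1L, 6), fine_labels())
  out <- generate_profiles(cfg, counts, seed = 1)
  protos <- prototype_profiles()
  expect_equal(nrow(out), 6)
  for (i in seq_len(6)) {
    ty <- out$true_fine[i]
    got <- out[i, , drop = FALSE]
    want <- protos[[ty]]
    for (f in setdiff(names(want), "accessory_flags")) {
      expect_equal(as.character(got[[f]]), as.character(want[[f]]),
                   info = paste(ty, f))
    }
    want_fl <- paste(want$accessory_flags, collapse = ";")
    expect_equal(got$accessory_flags, want_fl, info = ty)
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- profile_generator_config()
  counts <- c(astrocyte = 25, microglia = 25)
  expect_identical(generate_profiles(cfg, counts, seed = 42),
                   generate_profiles(cfg, counts, seed = 42))
  # and differs (somewhere) under another seed
  expect_false(identical(generate_profiles(cfg, counts, seed = 42),
                         generate_profiles(cfg, counts, seed = 43)))
})

test_that("generated profiles are valid and carry their true label", {
  cfg <- profile_generator_config(species = "human")
  counts <- stats::setNames(rep(20L, 6), fine_labels())
  out <- generate_profiles(cfg, counts, seed = 9)
  expect_equal(nrow(out), 120)
  expect_equal(sort(unique(out$true_fine)), sort(fine_labels()))
  expect_equal(out$true_rating, collapse_to_rating(out$true_fine))
  for (i in seq_len(nrow(out))) {
    expect_s3_class(validate_profile(out[i, , drop = FALSE]), "cyto_profile")
  }
})

test_that("the microglial shape outlier rate is respected within binomial error", {
  rate <- 0.2
  cfg <- profile_generator_config(
    outlier_rates = list(microglia_round_ovoid = rate))
  out <- generate_profiles(cfg, c(microglia = 4000), seed = 13)
  frac <- mean(out$nuclear_shape %in% c("round", "ovoid"))
  ci <- rate + c(-4, 4) * sqrt(rate * (1 - rate) / 4000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("a noise-free rater reproduces the profile exactly", {
  r0 <- rater_model("r0", theta = 0)
  protos <- prototype_profiles()
  set.seed(1)
  for (p in protos) {
    expect_identical(perturb_profile(p, r0), p)
  }
})

test_that("theta = 1 with singleton confusable sets is a deterministic swap", {
  # restrict the map to features whose sets are singletons for the values
  # of the oligodendrocyte prototype
  cmap <- list(
    nucleus_stain = list(dark = "light", light = "dark"),
    het_net = list(rounded_granules_one_larger = "grid_many_small")
  )
  r1 <- rater_model("r1", theta = 1, confusable = cmap)
  p <- prototype_profiles()$oligodendrocyte
  set.seed(2)
  q <- perturb_profile(p, r1)
  expect_equal(q$nucleus_stain, "light")
  expect_equal(q$het_net, "grid_many_small")
  # repair keeps the profile valid: texture follows the flipped stain
  expect_equal(q$euchromatin_texture, "light_homogeneous")
  expect_s3_class(validate_profile(unclass(q)), "cyto_profile")
})

test_that("per-feature flip rates match theta within binomial error", {
  theta <- 0.1
  r <- rater_model("r", theta = theta)
  p <- prototype_profiles()$astrocyte
  set.seed(3)
  n <- 4000
  flips <- 0
  for (i in seq_len(n)) {
    q <- perturb_profile(p, r)
    # nuclear shape: potato -> ovoid is the only confusable move
    if (q$nuclear_shape != p$nuclear_shape) flips <- flips + 1
  }
  frac <- flips / n
  ci <- theta + c(-4, 4) * sqrt(theta * (1 - theta) / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("perturbed profiles always remain valid", {
  r <- rater_model("r", theta = 0.5)
  cfg <- profile_generator_config()
  out <- generate_profiles(cfg, stats::setNames(rep(10L, 6), fine_labels()),
                           seed = 4)
  set.seed(5)
  for (i in seq_len(nrow(out))) {
    q <- perturb_profile(out[i, , drop = FALSE], r)
    expect_s3_class(validate_profile(unclass(q)), "cyto_profile")
  }
})

test_that("the default design yields 236 fully rated and 114 seven-rater units", {
  sim <- simulate_ratings(seed = 6)
  v <- sim$ratings$values
  expect_equal(dim(v), c(350, 8))
  rated <- rowSums(!is.na(v))
  tt <- sim$ratings$unit_test
  expect_equal(sum(tt == "test1"), 236)
  expect_equal(sum(tt == "test2"), 114)
  expect_true(all(rated[tt == "test1"] == 8))
  expect_true(all(rated[tt == "test2"] == 7))
  # the missing rater in test 2 is inexperienced
  missing_rater <- colnames(v)[colSums(is.na(v[tt == "test2", ])) == 114]
  expect_length(missing_rater, 1)
  expect_equal(unname(sim$ratings$rater_experience[missing_rater]),
               "inexperienced")
})

test_that("simulation is reproducible end to end under one master seed", {
  s1 <- simulate_ratings(seed = 17)
  s2 <- simulate_ratings(seed = 17)
  expect_identical(s1$ratings$values, s2$ratings$values)
  expect_identical(s1$profiles, s2$profiles)
})

test_that("noise-free raters agree perfectly and give alpha 1", {
  panel <- default_rater_panel(theta_experienced = 0,
                               theta_inexperienced = 0)
  sim <- simulate_ratings(raters = panel, seed = 8)
  expect_identical(alpha_from_ratings(sim$ratings)$alpha, 1)
})

test_that("downstream alpha decreases as rater noise grows", {
  thetas <- c(0, 0.05, 0.15, 0.3, 0.6)
  alphas <- vapply(thetas, function(th) {
    panel <- default_rater_panel(theta_experienced = th,
                                 theta_inexperienced = th)
    design <- rating_design(tests = list(
      test1 = list(n_units = 120, raters = paste0("R", 1:8))))
    alpha_from_ratings(simulate_ratings(raters = panel, design = design,
                                        seed = 31)$ratings)$alpha
  }, numeric(1))
  expect_identical(alphas[1], 1)
  expect_true(all(diff(alphas) < 0))
})
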