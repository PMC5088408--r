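test_that("coincidence pair counting follows the permutation rule", {
  # two raters agreeing on one neuron: 2 on the diagonal
  cm <- build_coincidence_matrix(ratings_table(
    matrix(c("neuron", "neuron"), 1, 2)))
  expect_equal(cm$counts["neuron", "neuron"], 2)
  expect_equal(sum(cm$counts), 2)

  # a neuron/astrocyte split: 1 in each symmetric off-diagonal cell
  cm2 <- build_coincidence_matrix(ratings_table(
    matrix(c("neuron", "astrocyte"), 1, 2)))
  expect_equal(cm2$counts["neuron", "astrocyte"], 1)
  expect_equal(cm2$counts["astrocyte", "neuron"], 1)

  # no missing data: total = N * m * (m - 1)
  set.seed(3)
  N <- 17; m <- 5
  rt <- random_ratings(N, m)
  cm3 <- build_coincidence_matrix(rt)
  expect_equal(cm3$n_pairs, N * m * (m - 1))

  # a unit rated once contributes nothing; alone it is an error
  one <- matrix(c("neuron", NA, "neuron", "neuron"), 2, 2, byrow = TRUE)
  cm4 <- build_coincidence_matrix(ratings_table(one))
  expect_equal(cm4$n_pairs, 2)
  expect_equal(cm4$n_units_excluded, 1L)
  expect_error(
    build_coincidence_matrix(ratings_table(matrix(c("neuron", NA), 1, 2))),
    "empty-data")
})

test_that("coincidence matrices are symmetric and conserve pair totals", {
  set.seed(4)
  for (i in 1:25) {
    rt <- random_ratings(sample(3:30, 1), sample(2:8, 1),
                         miss = runif(1, 0, 0.4))
    cm <- tryCatch(build_coincidence_matrix(rt), error = function(e) NULL)
    if (is.null(cm)) next
    expect_equal(cm$counts, t(cm$counts))
    m_u <- rowSums(!is.na(rt$values))
    expect_equal(cm$n_pairs, sum(m_u[m_u >= 2] * (m_u[m_u >= 2] - 1)))
    expect_equal(unname(cm$marginals), unname(rowSums(cm$counts)))
    expect_equal(sum(cm$marginals), cm$n_pairs)
    expect_equal(cm$n_values, sum(m_u[m_u >= 2]))
  }
})

test_that("alpha endpoints: perfect agreement gives 1, one category is undefined", {
  vals <- matrix(rep(rep(c("neuron", "astrocyte"), each = 10), 4), 20, 4)
  expect_identical(alpha_from_ratings(ratings_table(vals))$alpha, 1)

  uni <- matrix("neuron", 10, 3)
  res <- alpha_from_ratings(ratings_table(uni))
  expect_true(is.na(res$alpha))
  expect_match(res$undefined_reason, "single category")
})

test_that("alpha matches hand-computed closed-form values", {
  # 2 raters, 3 units (a,a) (b,b) (a,b): D_o = 1/3, D_e = 3/5, alpha = 4/9
  rt <- ratings_table(matrix(c("neuron", "neuron",
                               "astrocyte", "astrocyte",
                               "neuron", "astrocyte"), 3, 2, byrow = TRUE))
  res <- alpha_from_ratings(rt)
  expect_equal(res$alpha, 4 / 9, tolerance = 1e-12)
  expect_equal(res$D_o, 1 / 3, tolerance = 1e-12)
  expect_equal(res$D_e, 3 / 5, tolerance = 1e-12)

  # six 2-rater units realizing the coincidence matrix [[4,2],[2,4]]
  rt2 <- ratings_table(matrix(c("neuron", "neuron", "neuron", "neuron",
                                "astrocyte", "astrocyte",
                                "astrocyte", "astrocyte",
                                "neuron", "astrocyte",
                                "astrocyte", "neuron"), 6, 2, byrow = TRUE))
  cm2 <- build_coincidence_matrix(rt2)
  expect_equal(unname(cm2$counts[1:2, 1:2]),
               matrix(c(4, 2, 2, 4), 2, 2))
  # by hand: n = 12 values, D_o = 4/12, D_e = 72/132, alpha = 7/18
  expect_equal(krippendorff_alpha(cm2)$alpha, 7 / 18, tolerance = 1e-12)
  expect_equal(oracle_alpha(rt2$values), 7 / 18, tolerance = 1e-12)
})

test_that("alpha equals the brute-force pair-enumeration oracle on random tables", {
  set.seed(5)
  checked <- 0
  for (i in 1:60) {
    rt <- random_ratings(sample(4:40, 1), sample(2:8, 1),
                         miss = runif(1, 0, 0.35),
                         n_cat = sample(2:5, 1),
                         agree_bias = runif(1, 0, 0.9))
    a1 <- tryCatch(alpha_from_ratings(rt)$alpha, error = function(e) NA_real_)
    a2 <- oracle_alpha(rt$values)
    if (is.na(a1) || is.na(a2)) next
    expect_equal(a1, a2, tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("alpha is invariant under permutation of the category list", {
  set.seed(6)
  rt <- random_ratings(30, 5, miss = 0.15)
  a0 <- alpha_from_ratings(rt)$alpha
  perm <- ratings_table(rt$values, categories = rev(rt$categories))
  expect_equal(alpha_from_ratings(perm)$alpha, a0, tolerance = 1e-12)
})

test_that("moving mass off the diagonal strictly lowers alpha", {
  agree <- matrix(rep(rep(c("neuron", "astrocyte"), each = 8), 2), 16, 2)
  a_perfect <- alpha_from_ratings(ratings_table(agree))$alpha
  worse <- agree
  worse[1, 2] <- "astrocyte"
  a_worse <- alpha_from_ratings(ratings_table(worse))$alpha
  expect_identical(a_perfect, 1)
  expect_lt(a_worse, a_perfect)
})

test_that("pairwise percent agreement matches direct counting", {
  # all raters identical
  same <- matrix(rep(c("neuron", "astrocyte", "microglia"), 4), 3, 4)
  pa <- pairwise_percent_agreement(ratings_table(same))
  expect_equal(pa$mean, 100)
  expect_equal(pa$sem, 0)

  # 2 raters, 4 units, 3 equal labels: 75%, single pair so sem 0
  two <- matrix(c("neuron", "neuron", "astrocyte", "astrocyte",
                  "microglia", "microglia", "neuron", "astrocyte"),
                4, 2, byrow = TRUE)
  pa2 <- pairwise_percent_agreement(ratings_table(two))
  expect_equal(pa2$mean, 75)
  expect_equal(pa2$sem, 0)
  expect_equal(pa2$n_pairs_of_raters, 1)

  # 8 raters: mean equals a naive double loop over all 28 pairs
  set.seed(7)
  rt <- random_ratings(25, 8, miss = 0.1, agree_bias = 0.5)
  pa3 <- pairwise_percent_agreement(rt)
  v <- rt$values
  acc <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    co <- !is.na(v[, i]) & !is.na(v[, j])
    if (any(co)) acc <- c(acc, 100 * mean(v[co, i] == v[co, j]))
  }
  expect_equal(pa3$mean, mean(acc), tolerance = 1e-12)
  expect_equal(pa3$sem, sd(acc) / sqrt(length(acc)), tolerance = 1e-12)
})

test_that("disagreement ranking sorts unordered pairs with both count conventions", {
  # diagonal-only matrix: empty ranking
  cm <- build_coincidence_matrix(ratings_table(
    matrix(rep(c("neuron", "astrocyte"), each = 2), 2, 2, byrow = TRUE)))
  expect_equal(nrow(disagreement_ranking(cm)), 0)

  # synthetic matrix with known off-diagonal structure
  fake <- cm
  K <- length(fake$categories)
  counts <- matrix(0, K, K, dimnames = dimnames(cm$counts))
  counts["astrocyte", "endothelial"] <- counts["endothelial", "astrocyte"] <- 341
  counts["neuron", "astrocyte"] <- counts["astrocyte", "neuron"] <- 327
  counts["oligodendrocyte", "microglia"] <-
    counts["microglia", "oligodendrocyte"] <- 267
  fake$counts <- counts
  rk <- disagreement_ranking(fake)
  expect_equal(rk$count, c(682, 654, 534))
  expect_equal(rk$category_a[1], "astrocyte")
  expect_equal(rk$category_b[1], "endothelial")
  expect_equal(rk$category_a[2], "neuron")
  rk_half <- disagreement_ranking(fake, half_counts = TRUE)
  expect_equal(rk_half$count, c(341, 327, 267))

  # random symmetric matrices agree with a brute-force sort
  set.seed(8)
  for (i in 1:10) {
    rt <- random_ratings(20, 4, agree_bias = 0.4)
    cmi <- build_coincidence_matrix(rt)
    rki <- disagreement_ranking(cmi)
    brute <- c()
    cats <- cmi$categories
    for (a in seq_len(4)) for (b in seq(a + 1, 5)) {
      cnt <- cmi$counts[a, b] + cmi$counts[b, a]
      if (cnt > 0) brute[paste(cats[a], cats[b])] <- cnt
    }
    expect_equal(nrow(rki), length(brute))
    expect_equal(rki$count, unname(sort(brute, decreasing = TRUE)))
  }
})

test_that("experience and test subsets drive grouped alphas", {
  set.seed(9)
  vals <- matrix(sample(c("neuron", "astrocyte"), 40, TRUE), 10, 4,
                 dimnames = list(NULL, paste0("R", 1:4)))
  rt <- ratings_table(vals,
                      rater_experience = c(R1 = "experienced",
                                           R2 = "experienced",
                                           R3 = "inexperienced",
                                           R4 = "inexperienced"),
                      unit_test = rep(c("test1", "test2"), each = 5))
  a_exp <- alpha_from_ratings(rt, raters = "experienced")$alpha
  a_direct <- alpha_from_ratings(
    ratings_table(vals[, 1:2], categories = rt$categories))$alpha
  expect_equal(a_exp, a_direct, tolerance = 1e-12)
  a_t1 <- alpha_from_ratings(rt, tests = "test1")$alpha
  a_t1_direct <- alpha_from_ratings(
    ratings_table(vals[1:5, ], categories = rt$categories))$alpha
  expect_equal(a_t1, a_t1_direct, tolerance = 1e-12)
  rep <- reliability_report(rt)
  expect_named(rep$alpha_by_experience, c("experienced", "inexperienced"))
  expect_named(rep$alpha_by_test, c("test1", "test2"))
})
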