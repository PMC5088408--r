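# Inter-rater reliability: coincidence matrices, Krippendorff's alpha for
# nominal data with missing ratings, pairwise percent agreement and
# disagreement rankings.
#
# The coincidence matrix is displayed and ranked in raw permutation-pair
# counts (each unordered pair of ratings of one cell counted once in each
# direction, so a unit rated by m_u raters contributes m_u*(m_u-1) pairs).
# Alpha itself follows the canonical estimator: each unit's pair counts are
# weighted by 1/(m_u-1) so that every pairable *value* -- not pair --
# carries equal weight, which is what makes the statistic comparable across
# units with different numbers of raters.

#' Construct a ratings table
#'
#' @param values Character matrix (or data frame) of category labels, units
#'   in rows, raters in columns; `NA` marks a missing rating.  Row names (or
#'   a `cell_id` column) identify units, column names identify raters.
#' @param categories Category vocabulary; defaults to the five rating
#'   labels in canonical order.
#' @param rater_experience Optional named character vector
#'   (`"experienced"`/`"inexperienced"`) per rater.
#' @param unit_test Optional character vector (`"test1"`/`"test2"`) per unit.
#' @return A `ratings_table` object.
#' @export
ratings_table <- function(values,
                          categories = rating_labels(),
                          rater_experience = NULL,
                          unit_test = NULL) {
  if (is.data.frame(values)) {
    if ("cell_id" %in% names(values)) {
      rownames(values) <- values$cell_id
      values$cell_id <- NULL
    }
    values <- as.matrix(values)
  }
  storage.mode(values) <- "character"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("rater", seq_len(ncol(values)))
  }
  obs <- values[!is.na(values)]
  bad <- setdiff(unique(obs), categories)
  if (length(bad) > 0) {
    stop("ratings contain token(s) outside the category set: ",
         paste(sQuote(bad), collapse = ", "))
  }
  if (!is.null(rater_experience)) {
    rater_experience <- rater_experience[colnames(values)]
  }
  if (!is.null(unit_test)) {
    stopifnot(length(unit_test) == nrow(values))
    names(unit_test) <- rownames(values)
  }
  structure(list(values = values, categories = categories,
                 rater_experience = rater_experience,
                 unit_test = unit_test),
            class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("Ratings table: %d units x %d raters, %d missing entries\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

# Apply rater/unit subsetting used by the reliability operations.
subset_ratings <- function(ratings, raters = NULL, tests = NULL, units = NULL) {
  v <- ratings$values
  if (!is.null(raters)) {
    if (length(raters) == 1 && raters %in% c("experienced", "inexperienced")) {
      if (is.null(ratings$rater_experience)) {
        stop("no rater experience metadata available for subset '", raters, "'")
      }
      raters <- colnames(v)[ratings$rater_experience == raters]
    }
    v <- v[, raters, drop = FALSE]
  }
  if (!is.null(tests)) {
    if (is.null(ratings$unit_test)) {
      stop("no unit test metadata available for test subset")
    }
    v <- v[ratings$unit_test[rownames(v)] %in% tests, , drop = FALSE]
  }
  if (!is.null(units)) v <- v[units, , drop = FALSE]
  v
}

#' Build the coincidence matrix of pairwise rater categorizations
#'
#' For each unit rated by at least two raters, every ordered pair of labels
#' assigned by two distinct raters contributes one count: two raters who
#' agree a cell is a neuron add 2 to the neuron-neuron diagonal term (one
#' for each direction), while a neuron/astrocyte split adds 1 to each of the
#' two symmetric off-diagonal cells.  Units with fewer than two ratings are
#' excluded (no pair exists).  With no missing data over N units and m
#' raters the counts total N*m*(m-1).
#'
#' The returned object also carries the (m_u-1)-normalized coincidences used
#' by [krippendorff_alpha()] (see the vignette for why the two scales are
#' kept side by side).
#'
#' @param ratings A [ratings_table()].
#' @param raters Optional rater subset: vector of rater IDs, or
#'   `"experienced"` / `"inexperienced"`.
#' @param tests Optional unit subset by test tag (e.g. `"test1"`).
#' @return A `coincidence_matrix` with elements `categories`, `counts` (raw
#'   symmetric K x K integer pair counts), `coincidence` (normalized),
#'   `marginals` and `marginals_norm`, `n_pairs` (= sum of counts),
#'   `n_values` (total pairable values), `n_units_included`,
#'   `n_units_excluded`.
#' @export
#' @examples
#' rt <- ratings_table(matrix(c("neuron", "neuron"), 1, 2))
#' build_coincidence_matrix(rt)$counts["neuron", "neuron"]  # 2
build_coincidence_matrix <- function(ratings, raters = NULL, tests = NULL) {
  stopifnot(inherits(ratings, "ratings_table"))
  v <- subset_ratings(ratings, raters = raters, tests = tests)
  K <- length(ratings$categories)
  counts <- matrix(0, K, K, dimnames = list(ratings$categories,
                                            ratings$categories))
  coin <- counts
  n_inc <- 0L
  n_exc <- 0L
  for (u in seq_len(nrow(v))) {
    vals <- v[u, ]
    vals <- vals[!is.na(vals)]
    m_u <- length(vals)
    if (m_u < 2) {
      n_exc <- n_exc + 1L
      next
    }
    n_inc <- n_inc + 1L
    tab <- tabulate(match(vals, ratings$categories), nbins = K)
    pair <- outer(tab, tab) - diag(tab, K)
    counts <- counts + pair
    coin <- coin + pair / (m_u - 1)
  }
  if (n_inc == 0L) {
    stop("empty-data error: no unit has two or more ratings after filtering")
  }
  structure(list(categories = ratings$categories,
                 counts = counts,
                 coincidence = coin,
                 marginals = rowSums(counts),
                 marginals_norm = rowSums(coin),
                 n_pairs = sum(counts),
                 n_values = sum(coin),
                 n_units_included = n_inc,
                 n_units_excluded = n_exc),
            class = "coincidence_matrix")
}

#' @export
print.coincidence_matrix <- function(x, ...) {
  cat(sprintf("Coincidence matrix (%d units, %d pairable pairs)\n",
              x$n_units_included, x$n_pairs))
  if (x$n_units_excluded > 0) {
    cat(sprintf("  (%d unit(s) with fewer than 2 ratings excluded)\n",
                x$n_units_excluded))
  }
  print(x$counts)
  invisible(x)
}

#' Krippendorff's alpha for nominal categories
#'
#' Chance-corrected agreement `alpha = 1 - D_o / D_e`, where the observed
#' disagreement `D_o` is the off-diagonal mass of the normalized coincidence
#' matrix divided by the number of pairable values `n`, and the expected
#' disagreement `D_e = sum_{c != k} n_c n_k / (n (n - 1))` is what chance
#' assignment with the observed category totals would produce.  Alpha is 1
#' for perfect agreement, 0 at chance level.  The nominal difference
#' function (0 if equal, 1 otherwise) is fixed: cell types are unordered.
#'
#' @param coincidence A `coincidence_matrix` from
#'   [build_coincidence_matrix()].
#' @return List with `alpha`, `D_o`, `D_e`, `n_values`, `n_pairs`.  When all
#'   ratings fall in a single category `D_e = 0` and `alpha` is `NA` with an
#'   explanatory `undefined_reason`.
#' @export
krippendorff_alpha <- function(coincidence) {
  stopifnot(inherits(coincidence, "coincidence_matrix"))
  o <- coincidence$coincidence
  n <- coincidence$n_values
  nc <- coincidence$marginals_norm
  off <- sum(o) - sum(diag(o))
  D_o <- off / n
  D_e <- (sum(nc)^2 - sum(nc^2)) / (n * (n - 1))
  if (D_e <= 0 || sum(nc > 0) < 2) {
    return(list(alpha = NA_real_, D_o = D_o, D_e = 0,
                n_values = n, n_pairs = coincidence$n_pairs,
                undefined_reason = "all ratings fall in a single category"))
  }
  list(alpha = 1 - D_o / D_e, D_o = D_o, D_e = D_e,
       n_values = n, n_pairs = coincidence$n_pairs)
}

#' Alpha straight from a ratings table
#'
#' Convenience composition of [build_coincidence_matrix()] and
#' [krippendorff_alpha()].
#'
#' @inheritParams build_coincidence_matrix
#' @return As [krippendorff_alpha()].
#' @export
alpha_from_ratings <- function(ratings, raters = NULL, tests = NULL) {
  krippendorff_alpha(build_coincidence_matrix(ratings, raters = raters,
                                              tests = tests))
}

#' Average pairwise percent agreement
#'
#' For every unordered pair of raters, the percentage of co-rated units on
#' which they assigned the same label; returns the mean and the standard
#' error of that mean across rater pairs (the SEM is 0 when only one rater
#' pair exists).
#'
#' @inheritParams build_coincidence_matrix
#' @return List with `mean` and `sem` (percent scale), `n_pairs_of_raters`,
#'   and `per_pair` (data frame of per-pair agreements).
#' @export
pairwise_percent_agreement <- function(ratings, raters = NULL, tests = NULL) {
  stopifnot(inherits(ratings, "ratings_table"))
  v <- subset_ratings(ratings, raters = raters, tests = tests)
  m <- ncol(v)
  if (m < 2) stop("empty-data error: need at least two raters")
  pairs <- utils::combn(colnames(v), 2)
  agree <- rep(NA_real_, ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- v[, pairs[1, i]]
    b <- v[, pairs[2, i]]
    co <- !is.na(a) & !is.na(b)
    if (any(co)) agree[i] <- 100 * mean(a[co] == b[co])
  }
  if (all(is.na(agree))) {
    stop("empty-data error: no rater pair shares a rated unit")
  }
  agree_ok <- agree[!is.na(agree)]
  sem <- if (length(agree_ok) > 1) {
    stats::sd(agree_ok) / sqrt(length(agree_ok))
  } else 0
  list(mean = mean(agree_ok), sem = sem,
       n_pairs_of_raters = length(agree_ok),
       per_pair = data.frame(rater_a = pairs[1, ], rater_b = pairs[2, ],
                             agreement = agree, stringsAsFactors = FALSE))
}

#' Rank category pairs by disagreement count
#'
#' Off-diagonal unordered category pairs sorted by pair count, descending;
#' ties broken by canonical category order.  By default the count for a pair
#' (c, k) is `o_ck + o_kc` (each permutation counted); with
#' `half_counts = TRUE` each unordered disagreement is counted once, the
#' convention used when a study quotes "n = 341 pairs" for a single
#' direction.
#'
#' @param coincidence A `coincidence_matrix`.
#' @param half_counts Logical; report `o_ck` instead of `o_ck + o_kc`.
#' @return Data frame with columns `category_a`, `category_b`, `count`,
#'   sorted descending; zero-count pairs are dropped.
#' @export
disagreement_ranking <- function(coincidence, half_counts = FALSE) {
  stopifnot(inherits(coincidence, "coincidence_matrix"))
  cats <- coincidence$categories
  K <- length(cats)
  out <- list()
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      cnt <- coincidence$counts[i, j] + coincidence$counts[j, i]
      if (half_counts) cnt <- cnt / 2
      if (cnt > 0) {
        out[[length(out) + 1]] <- data.frame(
          category_a = cats[i], category_b = cats[j], count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(category_a = character(0), category_b = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  }
  rk <- do.call(rbind, out)
  # stable sort: descending count, ties by canonical order of the pair
  ord <- order(-rk$count, match(rk$category_a, cats), match(rk$category_b, cats))
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  rk
}

#' Full reliability report for a ratings table
#'
#' Bundles Krippendorff's alpha, observed and expected disagreement, the
#' coincidence matrix, percent agreement and the disagreement ranking, plus
#' per-group alphas when rater experience or test metadata are present.
#'
#' @inheritParams build_coincidence_matrix
#' @param half_counts Passed to [disagreement_ranking()].
#' @return A `reliability_report` list.
#' @export
reliability_report <- function(ratings, raters = NULL, tests = NULL,
                               half_counts = FALSE) {
  cm <- build_coincidence_matrix(ratings, raters = raters, tests = tests)
  al <- krippendorff_alpha(cm)
  pa <- pairwise_percent_agreement(ratings, raters = raters, tests = tests)
  rep <- list(alpha = al$alpha, D_o = al$D_o, D_e = al$D_e,
              n_values = al$n_values, n_pairs = al$n_pairs,
              coincidence = cm,
              percent_agreement_mean = pa$mean,
              percent_agreement_sem = pa$sem,
              disagreement_ranking = disagreement_ranking(cm, half_counts))
  if (!is.null(ratings$rater_experience) && is.null(raters)) {
    rep$alpha_by_experience <- sapply(c("experienced", "inexperienced"),
      function(g) {
        if (!g %in% ratings$rater_experience) return(NA_real_)
        alpha_from_ratings(ratings, raters = g, tests = tests)$alpha
      })
  }
  if (!is.null(ratings$unit_test) && is.null(tests)) {
    rep$alpha_by_test <- sapply(sort(unique(ratings$unit_test)), function(tt)
      alpha_from_ratings(ratings, raters = raters, tests = tt)$alpha)
  }
  class(rep) <- "reliability_report"
  rep
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Inter-rater reliability\n")
  cat(sprintf("  Krippendorff's alpha: %.2f  (D_o = %.4f, D_e = %.4f)\n",
              x$alpha, x$D_o, x$D_e))
  cat(sprintf("  pairable pairs: %d\n", x$n_pairs))
  cat(sprintf("  percent agreement: %.2f +/- %.2f%%\n",
              x$percent_agreement_mean, x$percent_agreement_sem))
  if (!is.null(x$alpha_by_experience)) {
    cat("  alpha by experience:",
        paste(sprintf("%s %.2f", names(x$alpha_by_experience),
                      x$alpha_by_experience), collapse = ", "), "\n")
  }
  if (!is.null(x$alpha_by_test)) {
    cat("  alpha by test:",
        paste(sprintf("%s %.2f", names(x$alpha_by_test), x$alpha_by_test),
              collapse = ", "), "\n")
  }
  if (nrow(x$disagreement_ranking) > 0) {
    top <- utils::head(x$disagreement_ranking, 4)
    cat("  top disagreements:",
        paste(sprintf("%s-%s (%g)", top$category_a, top$category_b, top$count),
              collapse = ", "), "\n")
  }
  invisible(x)
}
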