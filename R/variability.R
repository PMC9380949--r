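PERM_STATISTICS <- c("q25", "median", "q75", "iqr")

# Type-7 quantile (linear interpolation between order statistics) on an
# already-sorted vector; the estimator is recorded in outputs because IQR
# values depend on it.
.sorted_q <- function(xs, p) {
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

.stat_from_sorted <- function(xs, statistic) {
  switch(statistic,
    q25 = .sorted_q(xs, 0.25),
    median = .sorted_q(xs, 0.5),
    q75 = .sorted_q(xs, 0.75),
    iqr = .sorted_q(xs, 0.75) - .sorted_q(xs, 0.25),
    abort(paste0("unknown statistic: ", statistic)))
}

#' Robust dispersion summary
#'
#' Quartiles, median, interquartile range and median absolute deviation of a
#' set of values — the robust variability surface appropriate for
#' positively skewed speed distributions, where variance-based spread is
#' dominated by the tail. The MAD is the plain median of absolute
#' deviations from the median, `median(|x_i - median(x)|)`, with *no*
#' normal-consistency constant. Quantiles use linear interpolation between
#' order statistics (the default "type 7" rule), recorded in the output.
#'
#' @param values Numeric vector, `n >= 1`.
#' @param label Optional group label carried into the output.
#' @return One-row tibble of class `reef_dispersion`: `group`, `n`, `q25`,
#'   `median`, `q75`, `iqr`, `mad`, `percentile_method`.
#' @examples
#' dispersion_summary(c(1, 2, 3, 4, 100)) # median 3, mad 1
#' @export
dispersion_summary <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("`values` must be non-empty.")
  xs <- sort(values)
  med <- .sorted_q(xs, 0.5)
  out <- tibble::tibble(
    group = label, n = length(values),
    q25 = .sorted_q(xs, 0.25), median = med, q75 = .sorted_q(xs, 0.75),
    iqr = .sorted_q(xs, 0.75) - .sorted_q(xs, 0.25),
    mad = median(abs(values - med)),
    percentile_method = "type7")
  class(out) <- c("reef_dispersion", class(out))
  out
}

# Shared permutation engine: one pass over permutations computing every
# requested percentile statistic, so multi-statistic comparisons do not
# re-permute. Full enumeration when the relabelling count is small.
.perm_engine <- function(a, b, statistics, n_perm, seed, enumeration_cap) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  n <- na + nb
  obs <- vapply(statistics, function(s)
    .stat_from_sorted(sort(a), s) - .stat_from_sorted(sort(b), s), numeric(1))
  n_comb <- choose(n, na)
  exact <- is.finite(n_comb) && n_comb <= enumeration_cap
  if (exact) {
    idx <- combn(n, na)
    K <- ncol(idx)
    hits <- setNames(numeric(length(statistics)), statistics)
    for (j in seq_len(K)) {
      pa <- sort(pool[idx[, j]])
      pb <- sort(pool[-idx[, j]])
      for (s in statistics) {
        t_perm <- .stat_from_sorted(pa, s) - .stat_from_sorted(pb, s)
        if (abs(t_perm) >= abs(obs[[s]]) - 1e-12) hits[[s]] <- hits[[s]] + 1
      }
    }
    p <- hits / K
    n_used <- K
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    hits <- setNames(numeric(length(statistics)), statistics)
    for (j in seq_len(n_perm)) {
      perm <- sample.int(n)
      pa <- sort(pool[perm[seq_len(na)]])
      pb <- sort(pool[perm[(na + 1):n]])
      for (s in statistics) {
        t_perm <- .stat_from_sorted(pa, s) - .stat_from_sorted(pb, s)
        if (abs(t_perm) >= abs(obs[[s]]) - 1e-12) hits[[s]] <- hits[[s]] + 1
      }
    }
    p <- (1 + hits) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble::tibble(statistic = statistics, observed_diff = unname(obs),
                 p_value = unname(p), n_perm = n_used, exact = exact,
                 seed = seed)
}

.check_perm_sizes <- function(a, b, statistics) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty.")
  needs2 <- intersect(statistics, c("q25", "q75", "iqr"))
  if (length(needs2) && min(length(a), length(b)) < 2) {
    abort(paste0("statistic(s) ", paste(needs2, collapse = ", "),
                 " undefined for a group of size 1."))
  }
}

#' Two-group permutation test on a percentile statistic
#'
#' Tests the difference in a percentile statistic (25th/75th percentile,
#' median, or IQR) between two groups by permuting group labels while
#' holding group sizes fixed. The two-sided p-value uses the add-one rule
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, which is strictly
#' positive and valid under exchangeability. When the number of distinct
#' relabellings is at most `enumeration_cap`, every relabelling is evaluated
#' and the exact p-value is reported (`exact = TRUE`).
#'
#' @param a,b Numeric vectors (e.g. daily average speeds of two reef types).
#' @param statistic One of `"q25"`, `"median"`, `"q75"`, `"iqr"`.
#' @param n_perm Number of sampled permutations (default 5000).
#' @param seed RNG seed; p-values are deterministic given the seed.
#' @param enumeration_cap Maximum relabelling count for full enumeration.
#' @return One-row tibble of class `reef_perm_test`: `statistic`,
#'   `group_a`, `group_b`, `observed_diff` (stat(a) - stat(b)), `p_value`,
#'   `n_perm`, `exact`, `seed`.
#' @export
percentile_permutation_test <- function(a, b, statistic = "median",
                                        n_perm = 5000, seed = 1,
                                        enumeration_cap = 10000) {
  statistic <- match.arg(statistic, PERM_STATISTICS)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  .check_perm_sizes(a, b, statistic)
  res <- .perm_engine(a, b, statistic, n_perm, seed, enumeration_cap)
  out <- dplyr::mutate(res, group_a = "a", group_b = "b",
                       .after = "statistic")
  class(out) <- c("reef_perm_test", class(out))
  out
}

#' Pairwise permutation tests across groups
#'
#' Runs [percentile_permutation_test()] for every unordered pair of groups
#' and every requested statistic. Raw p-values mirror unadjusted pairwise
#' reporting; Holm-adjusted p-values (within each statistic's family of
#' pairs) are added when `adjust = "holm"`, since three pairwise tests per
#' statistic inflate the family-wise error rate.
#'
#' @param data Data frame of values with a grouping column.
#' @param value,group Column names (strings) of the value and group
#'   variables.
#' @param statistic Character vector from `c("q25", "median", "q75",
#'   "iqr")`; all are computed on a shared set of permutations per pair.
#' @param n_perm,seed,enumeration_cap As in
#'   [percentile_permutation_test()]; each pair gets a distinct seed derived
#'   from `seed`.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble of class `reef_perm_test`, one row per (statistic, pair):
#'   `statistic`, `group_a`, `group_b`, `observed_diff`, `p_value`,
#'   (`p_holm`,) `n_perm`, `exact`, `seed`.
#' @export
pairwise_group_tests <- function(data, value, group,
                                 statistic = PERM_STATISTICS,
                                 n_perm = 5000, seed = 1,
                                 enumeration_cap = 10000,
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  statistic <- match.arg(statistic, PERM_STATISTICS, several.ok = TRUE)
  vals <- data[[value]]
  grps <- as.character(data[[group]])
  labels <- sort(unique(grps))
  if (length(labels) < 2) abort("need at least two groups.")
  pairs <- combn(labels, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    a <- vals[grps == ga & !is.na(vals)]
    b <- vals[grps == gb & !is.na(vals)]
    .check_perm_sizes(a, b, statistic)
    pair_seed <- (as.numeric(seed) + 7919 * k) %% 2147483647
    .perm_engine(a, b, statistic, n_perm, as.integer(pair_seed),
                 enumeration_cap) |>
      dplyr::mutate(group_a = ga, group_b = gb, .after = "statistic")
  })
  if (adjust == "holm") {
    res <- res |>
      dplyr::group_by(.data$statistic) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup() |>
      dplyr::relocate("p_holm", .after = "p_value")
  }
  class(res) <- c("reef_perm_test", class(res))
  res
}
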