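#' @title Rank-based statistical layer
#' @name stats_layer
#' @description
#' Friedman tests with Kendall's W effect size, Wilcoxon signed-rank post
#' hocs with Bonferroni correction, Spearman/MAE length agreement, and the
#' 2D-vs-3D method-agreement analysis. Small-sample p-values are exact:
#' the Friedman null is enumerated over within-row permutations and the
#' signed-rank null over sign assignments (dynamic programming with
#' midranks), rather than relying on asymptotics.
NULL

# long tibble -> participants x conditions matrix (no missing cells)
.condition_matrix <- function(data, value, condition, participant) {
  w <- tidyr::pivot_wider(data[, c(participant, condition, value)],
                          names_from = dplyr::all_of(condition),
                          values_from = dplyr::all_of(value))
  m <- as.matrix(w[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing cells in the condition table", call. = FALSE)
  rownames(m) <- w[[1]]
  m
}

# tie-corrected Friedman chi-square from a ranks-within-rows matrix
.friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) return(NA_real_)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
}

#' Friedman test with Kendall's W
#'
#' Within-row midranks with tie correction; `W = chi2 / (n (k - 1))`. The
#' p-value is exact (full enumeration of within-row permutations of the
#' observed values) when `(k!)^n` is small, otherwise from the chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param data long tibble of one outcome.
#' @param value,condition,participant column names (strings).
#' @param exact_max maximum enumeration size for the exact null.
#' @return a `friedman_test` object; see [glance.friedman_test()].
#' @export
friedman_kendall <- function(data, value = "value", condition = "condition",
                             participant = "participant", exact_max = 1e5) {
  m <- .condition_matrix(data, value, condition, participant)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need n >= 2 participants and k >= 2 conditions", call. = FALSE)
  stat <- .friedman_stat(m)
  if (is.na(stat)) {
    # fully tied table (identical columns): no evidence of a condition effect
    return(structure(list(statistic = 0, df = k - 1, p.value = 1,
                          kendall_w = 0, n = n, k = k,
                          method = "degenerate (all rows constant)"),
                     class = "friedman_test"))
  }
  n_perm <- factorial(k)^n
  if (n_perm <= exact_max) {
    perms <- .permutations(k)
    np <- nrow(perms)
    combos <- as.matrix(expand.grid(rep(list(seq_len(np)), n)))
    r <- t(apply(m, 1, rank))
    Rj <- matrix(0, nrow(combos), k)
    for (i in seq_len(n)) {
      Rj <- Rj + r[i, ][perms[combos[, i], , drop = FALSE]]
    }
    A <- sum(r^2); C <- n * k * (k + 1)^2 / 4
    stats_all <- (k - 1) * rowSums((Rj - n * (k + 1) / 2)^2) / (A - C)
    p <- mean(stats_all >= stat - 1e-9)
    method <- "exact (within-row permutation)"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "chi-square asymptotic"
  }
  structure(list(statistic = stat, df = k - 1, p.value = p,
                 kendall_w = stat / (n * (k - 1)), n = n, k = k,
                 method = method), class = "friedman_test")
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(rep(k, nrow(sub)), sub)[, order(c(pos, seq_len(k - 1) + (seq_len(k - 1) >= pos))), drop = FALSE]
  }))
}

#' @export
print.friedman_test <- function(x, ...) {
  cat("Friedman test: chi2(", x$df, ") = ", format(x$statistic, digits = 5),
      ", p = ", format(x$p.value, digits = 4),
      ", Kendall's W = ", format(x$kendall_w, digits = 3),
      " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' One-row summary of a Friedman test
#' @param x a `friedman_test`. @param ... unused.
#' @return tibble: statistic, df, p.value, kendall_w, n, k, method.
#' @export
glance.friedman_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 kendall_w = x$kendall_w, n = x$n, k = x$k, method = x$method)
}

# exact signed-rank distribution: P(V = v) over sign assignments, with
# midranks doubled to keep integer support; returns doubled-scale CDF info
.signed_rank_p <- function(d, exact_n = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined test: all paired differences are zero", call. = FALSE)
  r2 <- round(2 * rank(abs(d)))            # doubled midranks (integers)
  v2 <- sum(r2[d > 0])
  if (n <= exact_n) {
    key <- paste(sort(r2), collapse = ",")
    dist <- .wilcox_cache_get(key)
    if (is.null(dist)) {
      dist <- c(1)
      for (w in r2) dist <- .shift_add(dist, w)
      .wilcox_cache_set(key, dist)
    }
    tot <- sum(dist)
    lo <- sum(dist[seq_len(v2 + 1L)]) / tot          # P(V2 <= v2)
    hi <- sum(dist[(v2 + 1L):length(dist)]) / tot    # P(V2 >= v2)
    min(1, 2 * min(lo, hi))
  } else {
    mu <- n * (n + 1) / 4
    tie_term <- sum(tapply(abs(d), abs(d), length)^3 -
                      tapply(abs(d), abs(d), length)) / 48
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
    v <- v2 / 2
    z <- (v - mu - sign(v - mu) * 0.5) / sig
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

.shift_add <- function(dist, w) {
  out <- c(dist, numeric(w))
  out[(w + 1L):length(out)] <- out[(w + 1L):length(out)] + dist
  out
}

.wilcox_env <- new.env(parent = emptyenv())
.wilcox_cache_get <- function(key) .wilcox_env[[key]]
.wilcox_cache_set <- function(key, val) assign(key, val, envir = .wilcox_env)

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Two-sided signed-rank test for every condition pair (exact
#' sign-assignment enumeration for n <= 25 after dropping zero differences,
#' midranks for tied magnitudes; tie-corrected normal approximation beyond).
#' Corrected p = min(1, m * p) with `m` the number of comparisons.
#'
#' @inheritParams friedman_kendall
#' @param m number of comparisons for the correction; defaults to the
#'   number of pairs.
#' @param alpha significance level for the flags (on corrected p).
#' @return tibble: `cond_a`, `cond_b`, `n`, `p_raw`, `p_corr`,
#'   `significant`.
#' @export
wilcoxon_pairwise <- function(data, value = "value", condition = "condition",
                              participant = "participant", m = NULL,
                              alpha = 0.05) {
  mat <- .condition_matrix(data, value, condition, participant)
  pairs <- utils::combn(colnames(mat), 2)
  if (is.null(m)) m <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- mat[, a] - mat[, b]
    p <- .signed_rank_p(d)
    tibble::tibble(cond_a = a, cond_b = b, n = sum(d != 0), p_raw = p)
  })
  out$p_corr <- pmin(1, m * out$p_raw)
  out$significant <- out$p_corr < alpha
  out
}

#' Agreement between marker-based and model-based tibial lengths
#'
#' Spearman rank correlation (midranks), mean absolute error and a paired
#' two-sided Wilcoxon signed-rank test.
#'
#' @param marker_mm,model_mm paired length vectors (mm), n >= 5.
#' @return one-row tibble: `rho`, `p_rho`, `mae_mm`, `p_wilcoxon`, `n`.
#' @export
length_agreement <- function(marker_mm, model_mm) {
  stopifnot(length(marker_mm) == length(model_mm))
  if (length(marker_mm) < 5) stop("need n >= 5 pairs", call. = FALSE)
  if (stats::sd(marker_mm) == 0 || stats::sd(model_mm) == 0) {
    stop("undefined correlation: constant length vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(marker_mm, model_mm, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_rho = ct$p.value,
                 mae_mm = mean(abs(marker_mm - model_mm)),
                 p_wilcoxon = .signed_rank_p(marker_mm - model_mm),
                 n = length(marker_mm))
}

#' Percentage change between two conditions
#'
#' `100 * (to - from) / from`; a zero baseline yields NA with a warning
#' (reported, never silently dropped).
#'
#' @param from,to paired values.
#' @return percentage changes.
#' @export
percent_change <- function(from, to) {
  bad <- from == 0
  if (any(bad)) {
    warning("undefined percentage change for ", sum(bad),
            " observation(s) with zero baseline (returned NA)")
  }
  ifelse(bad, NA_real_, 100 * (to - from) / from)
}

#' Between-method agreement of per-participant percentage changes
#'
#' Compares participant-wise percentage changes computed with two methods
#' (e.g. 2D beam theory vs 3D finite elements): mean and SD of the absolute
#' between-method difference, the fraction of participants whose changes
#' share a sign (directional concordance), and the identity-line table.
#'
#' @param pct_a,pct_b per-participant percentage changes for each method.
#' @param id optional participant labels.
#' @return a `method_agreement` list: `summary` (one-row tibble) and
#'   `table` (per-participant tibble).
#' @export
method_agreement <- function(pct_a, pct_b, id = NULL) {
  stopifnot(length(pct_a) == length(pct_b))
  if (is.null(id)) id <- sprintf("P%02d", seq_along(pct_a))
  tab <- tibble::tibble(participant = id, pct_a = pct_a, pct_b = pct_b,
                        abs_diff = abs(pct_a - pct_b),
                        concordant = sign(pct_a) == sign(pct_b))
  ok <- stats::complete.cases(tab[, c("pct_a", "pct_b")])
  structure(list(
    summary = tibble::tibble(
      mean_abs_diff = mean(tab$abs_diff[ok]),
      sd_abs_diff = stats::sd(tab$abs_diff[ok]),
      concordance = mean(tab$concordant[ok]),
      n = sum(ok), n_undefined = sum(!ok)),
    table = tab), class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  s <- x$summary
  cat("Method agreement over", s$n, "participants:\n")
  cat("  mean |delta %| =", format(s$mean_abs_diff, digits = 3),
      "+/-", format(s$sd_abs_diff, digits = 3), "\n")
  cat("  directional concordance =", format(100 * s$concordance, digits = 4), "%\n")
  invisible(x)
}

#' Per-group descriptive statistics
#'
#' Mean and SD (n - 1 denominator) per group; purely descriptive, with an
#' optional Shapiro-Wilk normality p-value as a supplementary check (no
#' branching depends on it).
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @param shapiro include Shapiro-Wilk p per group (needs 3 <= n <= 5000).
#' @return tibble: `group`, `n`, `mean`, `sd` (and `shapiro_p`).
#' @export
group_descriptives <- function(values, groups, shapiro = FALSE) {
  stopifnot(length(values) == length(groups))
  if (is.factor(groups) && any(table(groups) == 0) || length(values) == 0) {
    stop("empty group", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = as.character(groups), value = values), group),
    n = dplyr::n(), mean = mean(value), sd = stats::sd(value), .groups = "drop")
  if (shapiro) {
    out$shapiro_p <- purrr::map_dbl(out$group, function(g) {
      v <- values[groups == g]
      if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0) {
        stats::shapiro.test(v)$p.value
      } else NA_real_
    })
  }
  out
}

#' Condition comparison report (main effect + post hocs)
#'
#' The full nonparametric comparison used for every loading outcome:
#' Friedman main effect with Kendall's W, then pairwise Wilcoxon signed-rank
#' post hocs with Bonferroni correction over the condition pairs.
#'
#' @inheritParams friedman_kendall
#' @return a `condition_comparison`: `main` (glanced Friedman row) and
#'   `pairwise` (see [wilcoxon_pairwise()]).
#' @export
compare_conditions <- function(data, value = "value", condition = "condition",
                               participant = "participant") {
  fr <- friedman_kendall(data, value, condition, participant)
  pw <- wilcoxon_pairwise(data, value, condition, participant)
  structure(list(main = glance(fr), pairwise = pw), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Main effect: chi2 =", format(x$main$statistic, digits = 5),
      "p =", format(x$main$p.value, digits = 4),
      "W =", format(x$main$kendall_w, digits = 3), "\n")
  print(x$pairwise)
  invisible(x)
}
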