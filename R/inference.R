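#' Mid-ranks of a pooled sample
#'
#' Ranks with tied values sharing the average of the ranks they span, so
#' the rank sum is exactly `N (N + 1) / 2`.
#'
#' @param values numeric vector.
#' @return numeric vector of mid-ranks.
#' @export
midranks <- function(values) {
  if (!length(values)) stop("empty input")
  rank(values, ties.method = "average")
}

# Sum over tie groups of (t^3 - t), the tie-correction numerator shared
# by the Kruskal-Wallis divisor and the Dunn standard error.
tie_correction_sum <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

as_group_list <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  stopifnot(is.list(groups), length(groups) >= 2)
  lapply(groups, as.numeric)
}

# H statistic from a list of groups: the tie-adjusted Kruskal-Wallis
# statistic H = [12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2] / C with
# C = 1 - sum(t^3 - t) / (N^3 - N).
kw_statistic <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- midranks(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  h0 <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_correction_sum(pooled) / (N^3 - N)
  if (C <= 0) stop("degenerate: no variation (all pooled values identical)")
  h0 / C
}

# Exact permutation p-value for H by enumerating all distinct
# assignments of the pooled mid-ranks to groups of the observed sizes.
kw_permutation_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(pooled)
  r <- midranks(pooled)
  C <- 1 - tie_correction_sum(pooled) / (N^3 - N)
  h_from_sums <- function(sums) {
    rbar <- sums / n
    (12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)) / C
  }
  obs <- h_from_sums(vapply(split(r, rep(seq_along(n), n)), sum, numeric(1)))
  count <- c(ge = 0, total = 0)
  recurse <- function(remaining, gi, sums) {
    if (gi > length(n)) {
      count["total"] <<- count["total"] + 1
      if (h_from_sums(sums) >= obs - 1e-9) count["ge"] <<- count["ge"] + 1
      return(invisible())
    }
    if (gi == length(n)) {                 # last group is forced
      sums[gi] <- sum(remaining)
      return(recurse(numeric(0), gi + 1, sums))
    }
    picks <- combn(length(remaining), n[gi], simplify = FALSE)
    for (p in picks) {
      sums[gi] <- sum(remaining[p])
      recurse(remaining[-p], gi + 1, sums)
    }
  }
  recurse(r, 1, numeric(length(n)))
  unname(count["ge"] / count["total"])
}

#' Tie-adjusted Kruskal--Wallis omnibus test
#'
#' Computes `H = [12/(N(N+1)) sum n_i (Rbar_i - (N+1)/2)^2] / C` on pooled
#' mid-ranks, with the tie-correction divisor
#' `C = 1 - sum(t^3 - t)/(N^3 - N)` over tie groups of size `t`, and refers
#' H to a chi-square distribution with `k - 1` degrees of freedom. For
#' small samples an exact permutation p-value (enumeration of all
#' distinct group assignments) can be requested instead of the
#' chi-square approximation.
#'
#' @param groups list of numeric vectors (one per group), or a numeric
#'   vector when `g` gives group labels.
#' @param g optional grouping vector aligned with `groups`.
#' @param exact compute the exact permutation p-value (feasible for
#'   total N up to about 10); stored as `p_exact` alongside the
#'   asymptotic `p`.
#' @return object of class `kw_result`: list with `total_n`, `chi2`,
#'   `df`, `p`, and optionally `p_exact`.
#' @export
kruskal_wallis <- function(groups, g = NULL, exact = FALSE) {
  groups <- as_group_list(groups, g)
  N <- sum(lengths(groups))
  if (N < 3) stop("need a total of at least 3 observations")
  h <- kw_statistic(groups)
  res <- list(total_n = N, chi2 = h, df = length(groups) - 1,
              p = pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
  if (exact) {
    if (N > 10) stop("exact permutation enumeration is limited to N <= 10")
    res$p_exact <- kw_permutation_p(groups)
  }
  structure(res, class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (tie-adjusted): chi2(%d) = %.3f, N = %d, p = %.4g\n",
              x$df, x$chi2, x$total_n, x$p))
  if (!is.null(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g\n", x$p_exact))
  invisible(x)
}

#' Dunn pairwise standard error
#'
#' `se = sqrt[(N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)]` with
#' `T = sum(t^3 - t)` over tie groups; `T = 0` (the default) gives the
#' no-tie closed form, which is what published rank tables print when
#' ties are negligible.
#'
#' @param n_i,n_j sizes of the two compared groups (vectorized).
#' @param N pooled sample size.
#' @param tie_sum tie-correction sum `T`.
#' @return standard error(s) on the rank scale.
#' @export
dunn_se <- function(n_i, n_j, N, tie_sum = 0) {
  sqrt((N * (N + 1) / 12 - tie_sum / (12 * (N - 1))) * (1 / n_i + 1 / n_j))
}

#' Standardize a rank-mean difference and adjust its p-value
#'
#' Utility for recomputing the standardized statistic, two-sided normal
#' p-value, and Bonferroni-adjusted p-value from a reported rank-mean
#' difference and its standard error (e.g. to check published pairwise
#' tables).
#'
#' @param diff rank-mean difference(s).
#' @param se standard error(s), as from [dunn_se()].
#' @param m number of pairwise comparisons in the family (Bonferroni
#'   multiplier), default 1.
#' @return data frame with `z`, `p`, `p_adj`.
#' @export
dunn_standardize <- function(diff, se, m = 1) {
  z <- diff / se
  p <- 2 * pnorm(-abs(z))
  data.frame(z = z, p = p, p_adj = pmin(1, m * p))
}

#' Dunn's pairwise post hoc comparisons
#'
#' For every unordered pair of groups, computes the difference in mean
#' pooled mid-ranks, its tie-corrected standard error (see [dunn_se()]),
#' the standardized statistic `z = diff / se`, the two-sided standard
#' normal p-value, and the adjusted p-value. Groups are ordered by
#' concentration (numeric group labels ascending), and the difference is
#' `Rbar_low - Rbar_high`, so a dose that raises the response yields a
#' negative difference.
#'
#' @param groups list of numeric vectors named by concentration, or a
#'   numeric vector with labels in `g`.
#' @param g optional grouping vector.
#' @param adjust `"bonferroni"` (multiply by the number of comparisons,
#'   capped at 1 -- the conventional choice), `"holm"`, or `"none"`.
#' @return data frame of class `dunn_result`: one row per pair with
#'   `group1`, `group2`, `n1`, `n2`, `rank_mean_diff`, `se`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_pairwise <- function(groups, g = NULL,
                          adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(groups, g)
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  labels <- names(groups) %||% as.character(seq_along(groups))
  num <- suppressWarnings(as.numeric(labels))
  ord <- if (!anyNA(num)) order(num) else seq_along(groups)
  groups <- groups[ord]; labels <- labels[ord]

  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- midranks(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  tie_sum <- tie_correction_sum(pooled)

  k <- length(groups)
  pairs <- combn(k, 2)
  diff <- rbar[pairs[1, ]] - rbar[pairs[2, ]]
  se <- dunn_se(n[pairs[1, ]], n[pairs[2, ]], N, tie_sum)
  z <- diff / se
  p <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p, method = if (adjust == "none") "none" else adjust)
  out <- data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
                    n1 = n[pairs[1, ]], n2 = n[pairs[2, ]],
                    rank_mean_diff = as.numeric(diff), se = se,
                    z = as.numeric(z), p = as.numeric(p),
                    p_adj = as.numeric(p_adj), row.names = NULL)
  class(out) <- c("dunn_result", class(out))
  out
}

#' Dose-response inference report for a measurement table
#'
#' For each panel (strain x compound): screens every concentration group
#' for outliers with [filter_outliers()], then runs the tie-adjusted
#' Kruskal--Wallis omnibus test and Dunn's pairwise comparisons on the
#' surviving values. Mirrors the layout of published summary tables: an
#' omnibus table (panel, N, chi2, df, p) and a pairwise table (panel,
#' pair, rank-mean difference, se, z, p, adjusted p).
#'
#' @param table measurement table with columns `strain`, `compound`,
#'   `concentration_uM`, `f`.
#' @param threshold modified z-score cutoff for the outlier screen;
#'   `NULL` disables screening.
#' @param adjust p-value adjustment passed to [dunn_pairwise()].
#' @param alpha significance level used for the `significant` flags.
#' @return list with `omnibus` (data frame, one row per panel), `pairwise`
#'   (data frame, one row per panel pair), and `summaries` (the
#'   [summarize_groups()] output).
#' @export
dose_response_report <- function(table, threshold = 3.5,
                                 adjust = "bonferroni", alpha = 0.05) {
  stopifnot(all(c("strain", "compound", "concentration_uM", "f") %in% names(table)))
  panel_key <- interaction(table$strain, table$compound, drop = TRUE, sep = " x ")
  omnibus <- list(); pairwise <- list()
  for (pn in levels(panel_key)) {
    sub <- table[panel_key == pn, , drop = FALSE]
    concs <- sort(unique(sub$concentration_uM))
    if (length(concs) < 2)
      stop("panel '", pn, "' has fewer than 2 concentration groups")
    groups <- lapply(concs, function(cc) {
      v <- sub$f[sub$concentration_uM == cc]
      if (!is.null(threshold) && length(v) >= 3)
        v <- filter_outliers(v, threshold)$kept
      v
    })
    names(groups) <- as.character(concs)
    kw <- kruskal_wallis(groups)
    dn <- dunn_pairwise(groups, adjust = adjust)
    omnibus[[pn]] <- data.frame(panel = pn, total_n = kw$total_n,
                                chi2 = kw$chi2, df = kw$df, p = kw$p,
                                significant = kw$p < alpha)
    dn$panel <- pn
    dn$pair <- paste0(dn$group1, "-", dn$group2, " uM")
    dn$significant <- dn$p_adj < alpha
    pairwise[[pn]] <- dn
  }
  summaries <- if (!is.null(threshold)) summarize_groups(table, threshold) else
    summarize_groups(table, Inf)
  list(omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))),
       summaries = summaries)
}
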