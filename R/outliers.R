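#' Modified z-scores (Iglewicz--Hoaglin)
#'
#' `M_i = 0.6745 (x_i - median) / MAD`, with MAD the median absolute
#' deviation about the median. When the MAD is zero (more than half the
#' values tied at the median) the scale falls back to
#' `1.253314 x mean absolute deviation` about the median, i.e.
#' `M_i = (x_i - median) / (1.253314 MeanAD)`; if that is also zero (all
#' values identical) every score is 0. Scores are invariant under
#' positive affine transformation of the data.
#'
#' @param values numeric vector, length >= 3 (a median/MAD screen on
#'   fewer points is not meaningful).
#' @return numeric vector of scores, same length as `values`.
#' @export
modified_z <- function(values) {
  if (length(values) < 3)
    stop("modified z-scores require at least 3 values")
  med <- median(values)
  dev <- values - med
  mad_ <- median(abs(dev))
  if (mad_ > 0) return(0.6745 * dev / mad_)
  meanad <- mean(abs(dev))
  if (meanad > 0) return(dev / (1.253314 * meanad))
  rep(0, length(values))
}

#' Screen a group for outliers by modified z-score
#'
#' Values with `|M_i| > threshold` are removed in a single pass (the
#' default; the screen is not re-applied to the surviving values).
#' Iterative re-screening until stable is available behind a flag.
#'
#' @param values numeric vector, length >= 3.
#' @param threshold score cutoff; the conventional 3.5, with strict
#'   inequality.
#' @param iterate re-apply the screen to the kept values until no
#'   further removals (stops early if fewer than 3 values remain).
#' @return list with `kept`, `removed`, `scores` (first-pass scores) and
#'   `removed_idx` (indices into the input).
#' @export
filter_outliers <- function(values, threshold = 3.5, iterate = FALSE) {
  scores <- modified_z(values)
  out <- abs(scores) > threshold
  if (iterate) {
    repeat {
      kept_idx <- which(!out)
      if (length(kept_idx) < 3) break
      s <- modified_z(values[kept_idx])
      new_out <- abs(s) > threshold
      if (!any(new_out)) break
      out[kept_idx[new_out]] <- TRUE
    }
  }
  list(kept = values[!out], removed = values[out],
       scores = scores, removed_idx = which(out))
}

#' Per-group descriptive summaries after outlier exclusion
#'
#' Splits a measurement table by experimental group (strain x compound x
#' concentration), screens each group separately with
#' [filter_outliers()], and reports post-exclusion group size, sample
#' mean, and sample standard deviation (n - 1 denominator). Groups with
#' fewer than 3 raw values are summarized without exclusion and flagged.
#'
#' @param table measurement table: data frame with columns `strain`,
#'   `compound`, `concentration_uM`, `f` (and ideally `colony_id`).
#' @param threshold modified z-score cutoff passed to [filter_outliers()].
#' @param iterate passed to [filter_outliers()].
#' @return data frame with one row per group: `strain`, `compound`,
#'   `concentration_uM`, `n`, `mean_f`, `sd_f`, `n_excluded`, `flagged`.
#'   The per-colony exclusion log (`colony_id`, `strain`, `compound`,
#'   `concentration_uM`, `f`, `score`) is attached as attribute
#'   `"exclusions"`.
#' @export
summarize_groups <- function(table, threshold = 3.5, iterate = FALSE) {
  stopifnot(all(c("strain", "compound", "concentration_uM", "f") %in% names(table)))
  if (!nrow(table)) stop("empty measurement table")
  key <- interaction(table$strain, table$compound, table$concentration_uM,
                     drop = TRUE)
  rows <- list(); logs <- list()
  for (g in levels(key)) {
    sub <- table[key == g, , drop = FALSE]
    flagged <- nrow(sub) < 3
    if (flagged) {
      kept <- sub$f; removed_idx <- integer(0); scores <- rep(NA_real_, nrow(sub))
    } else {
      fo <- filter_outliers(sub$f, threshold = threshold, iterate = iterate)
      kept <- fo$kept; removed_idx <- fo$removed_idx; scores <- fo$scores
    }
    rows[[g]] <- data.frame(
      strain = sub$strain[1], compound = sub$compound[1],
      concentration_uM = sub$concentration_uM[1],
      n = length(kept), mean_f = mean(kept),
      sd_f = if (length(kept) >= 2) sd(kept) else NA_real_,
      n_excluded = length(removed_idx), flagged = flagged)
    if (length(removed_idx))
      logs[[g]] <- data.frame(
        colony_id = if ("colony_id" %in% names(sub))
          sub$colony_id[removed_idx] else NA_character_,
        strain = sub$strain[1], compound = sub$compound[1],
        concentration_uM = sub$concentration_uM[1],
        f = sub$f[removed_idx], score = scores[removed_idx])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- order(out$strain, out$compound, out$concentration_uM)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(logs)) do.call(rbind, c(logs, list(make.row.names = FALSE))) else
    data.frame(colony_id = character(0), strain = character(0),
               compound = character(0), concentration_uM = numeric(0),
               f = numeric(0), score = numeric(0))
  out
}
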