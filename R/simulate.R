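#' Dose-response simulation design
#'
#' A design lists, per concentration group, the group size and the target
#' mean and standard deviation of the f-measure, plus the positive-support
#' family used to draw values. Families are moment-matched to
#' `(mean_f, sd_f)`: lognormal and gamma in closed form, truncated normal
#' (left-truncated at 0) by numerically solving for the parent mean and
#' SD. A zero `sd_f` yields constant draws for any family.
#'
#' @param groups data frame with columns `concentration_uM`, `n`,
#'   `mean_f`, `sd_f`.
#' @param family one of `"lognormal"`, `"gamma"`, `"truncated-normal"`.
#'   Lognormal is the default: observed group SDs scale with group means
#'   and f-measures are nonnegative, both natural under a lognormal.
#' @param outlier_rate fraction of draws multiplied by `outlier_scale`
#'   (contamination used to exercise outlier screening).
#' @param outlier_scale multiplier applied to contaminated draws.
#' @param strain,compound metadata carried into simulated records.
#' @param seed integer seed, or `NULL`.
#' @return an object of class `dose_design`.
#' @export
dose_design <- function(groups,
                        family = c("lognormal", "gamma", "truncated-normal"),
                        outlier_rate = 0, outlier_scale = 1,
                        strain = "synthetic", compound = "synthetic",
                        seed = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(groups),
            all(c("concentration_uM", "n", "mean_f", "sd_f") %in% names(groups)))
  if (any(groups$mean_f <= 0)) stop("all mean_f must be > 0")
  if (any(groups$sd_f < 0)) stop("all sd_f must be >= 0")
  if (any(groups$n < 2)) stop("all group sizes must be >= 2")
  if (any(groups$concentration_uM < 0)) stop("concentrations must be >= 0")
  if (anyDuplicated(groups$concentration_uM))
    stop("concentrations must be unique within a design")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0, 1]")
  structure(list(groups = groups[order(groups$concentration_uM), , drop = FALSE],
                 family = family, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale,
                 strain = strain, compound = compound, seed = seed),
            class = "dose_design")
}

#' Reference dose-response designs for Dekkera filamentation assays
#'
#' Published post-exclusion group sizes, f-measure means and standard
#' deviations for *Dekkera anomalous* and *D. bruxellensis* exposed to
#' 0/10/50/100/200 uM of the quorum-sensing aromatic alcohols
#' 2-phenylethanol and tryptophol. These quadruples parameterize
#' [simulate_fmeasures()] so that simulated panels have the statistical
#' structure of the real assays.
#'
#' @param family,outlier_rate,outlier_scale,seed passed to [dose_design()].
#' @return named list of four [dose_design()] objects
#'   (`anomalous_2PE`, `bruxellensis_2PE`, `anomalous_TRP`,
#'   `bruxellensis_TRP`).
#' @export
dekkera_designs <- function(family = "lognormal", outlier_rate = 0,
                            outlier_scale = 1, seed = NULL) {
  conc <- c(0, 10, 50, 100, 200)
  mk <- function(n, m, s, strain, compound)
    dose_design(data.frame(concentration_uM = conc, n = n, mean_f = m, sd_f = s),
                family = family, outlier_rate = outlier_rate,
                outlier_scale = outlier_scale,
                strain = strain, compound = compound, seed = seed)
  list(
    anomalous_2PE = mk(c(47, 46, 53, 59, 53),
                       c(0.467, 0.489, 1.109, 0.969, 1.570),
                       c(0.270, 0.350, 0.932, 0.946, 1.206),
                       "D. anomalous", "2-phenylethanol"),
    bruxellensis_2PE = mk(c(99, 62, 106, 91, 77),
                          c(0.330, 0.398, 0.847, 1.776, 1.770),
                          c(0.217, 0.192, 0.810, 1.299, 1.319),
                          "D. bruxellensis", "2-phenylethanol"),
    anomalous_TRP = mk(c(85, 44, 76, 77, 80),
                       c(0.310, 0.341, 0.964, 1.443, 0.657),
                       c(0.190, 0.197, 0.663, 0.996, 0.442),
                       "D. anomalous", "tryptophol"),
    bruxellensis_TRP = mk(c(88, 49, 79, 79, 53),
                          c(0.721, 0.723, 0.856, 2.085, 1.373),
                          c(0.459, 0.498, 0.435, 1.547, 1.222),
                          "D. bruxellensis", "tryptophol")
  )
}

# Truncated-normal (left-truncated at 0) moments for parent N(mu, sigma).
tnorm_moments <- function(mu, sigma) {
  a <- -mu / sigma
  Z <- pnorm(a, lower.tail = FALSE)
  lam <- dnorm(a) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Solve for parent (mu, sigma) so the truncated normal has the target
# mean and SD. The attainable coefficient of variation is < 1 (the deep-
# truncation limit is exponential-like); infeasible targets error.
tnorm_solve <- function(mean_f, sd_f, label = "group") {
  cv <- sd_f / mean_f
  fail <- function()
    stop("truncated-normal not moment-matchable for ", label,
         " (mean ", mean_f, ", sd ", sd_f,
         "): coefficient of variation must be < 1", call. = FALSE)
  if (cv >= 0.99) fail()
  obj <- function(par) {
    mo <- tnorm_moments(par[1], exp(par[2]))
    (mo["mean"] - mean_f)^2 + (mo["sd"] - sd_f)^2
  }
  fit <- optim(c(mean_f, log(sd_f)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > (1e-5 * mean_f)^2) fail()
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtnorm0 <- function(n, mu, sigma) {
  p0 <- pnorm(0, mu, sigma)
  qnorm(p0 + runif(n) * (1 - p0), mu, sigma)
}

draw_group <- function(n, mean_f, sd_f, family, label) {
  if (sd_f == 0) return(rep(mean_f, n))
  switch(family,
    "lognormal" = {
      s2 <- log(1 + (sd_f / mean_f)^2)
      rlnorm(n, meanlog = log(mean_f) - s2 / 2, sdlog = sqrt(s2))
    },
    "gamma" = {
      shape <- (mean_f / sd_f)^2
      rgamma(n, shape = shape, rate = shape / mean_f)
    },
    "truncated-normal" = {
      par <- tnorm_solve(mean_f, sd_f, label)
      rtnorm0(n, par["mu"], par["sigma"])
    })
}

#' Simulate per-colony f-measures from a dose design
#'
#' Draws each group's values from the design's positive-support family,
#' moment-matched to the group's target mean and SD, optionally
#' contaminating draws at `outlier_rate` by multiplying them by
#' `outlier_scale`. Reproducible for a fixed seed.
#'
#' @param design a [dose_design()].
#' @param seed overrides the design's seed when non-`NULL`.
#' @return a measurement table: data frame with columns `colony_id`,
#'   `strain`, `compound`, `concentration_uM`, `f`, and a logical
#'   `contaminated` column marking planted outliers.
#' @export
simulate_fmeasures <- function(design, seed = NULL) {
  stopifnot(inherits(design, "dose_design"))
  seed <- seed %||% design$seed
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design$groups)), function(i) {
      g <- design$groups[i, ]
      label <- sprintf("%s / %s / %g uM", design$strain, design$compound,
                       g$concentration_uM)
      f <- draw_group(g$n, g$mean_f, g$sd_f, design$family, label)
      contaminated <- rep(FALSE, g$n)
      if (design$outlier_rate > 0 && design$outlier_scale != 1) {
        contaminated <- runif(g$n) < design$outlier_rate
        f[contaminated] <- f[contaminated] * design$outlier_scale
      }
      data.frame(
        colony_id = sprintf("%s_%s_%guM_%03d",
                            gsub("[^A-Za-z0-9]+", "", design$strain),
                            gsub("[^A-Za-z0-9]+", "", design$compound),
                            g$concentration_uM, seq_len(g$n)),
        strain = design$strain, compound = design$compound,
        concentration_uM = g$concentration_uM, f = f,
        contaminated = contaminated)
    })
    do.call(rbind, rows)
  })
}
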