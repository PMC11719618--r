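test_that("rendered ground truth matches the per-pixel brute-force oracle", {
  specs <- list(
    colony_spec(120, 120, inner_radius = 30, noise_sd = 0),
    colony_spec(120, 120, inner_radius = 30,
                filaments = radial_filaments(4, 15, 5), noise_sd = 0),
    colony_spec(140, 110, center = c(60, 50), inner_radius = 25,
                filaments = radial_filaments(7, 18, 3, jitter = 0.2, seed = 3),
                noise_sd = 0),
    colony_spec(120, 120, inner_radius = 28,
                filaments = data.frame(angle = c(0, 0.25, 2), length = c(20, 22, 9),
                                       width = c(4, 6, 3)), noise_sd = 0))
  for (s in specs) {
    got <- render_colony(s)$truth
    want <- slow_colony_truth(s)
    expect_identical(got$a_inner_true, want$a_inner_true)
    expect_identical(got$a_outer_true, want$a_outer_true)
    expect_equal(got$f_true, want$f_true)
  }
})

test_that("degenerate colonies have zero filamentation index", {
  disc <- render_colony(colony_spec(300, 300, inner_radius = 100, noise_sd = 0))
  expect_identical(disc$truth$f_true, 0)
  zero_len <- render_colony(colony_spec(
    300, 300, inner_radius = 100,
    filaments = data.frame(angle = 0, length = 0, width = 10), noise_sd = 0))
  expect_identical(zero_len$truth$f_true, 0)
})

test_that("eight 50x10 spokes on a r=100 disc give f_true near 8*500/(pi r^2)", {
  s <- colony_spec(420, 420, inner_radius = 100,
                   filaments = radial_filaments(8, 50, 10), noise_sd = 0)
  truth <- render_colony(s)$truth
  expect_equal(truth$f_true, 8 * 500 / (pi * 100^2), tolerance = 0.05)
})

test_that("adding a non-overlapping filament never decreases f_true", {
  angles <- seq(0, 2 * pi, length.out = 13)[1:12]
  set.seed(11)
  for (rep in 1:5) {
    lens <- runif(12, 5, 28)
    widths <- sample(3:7, 12, replace = TRUE)
    f_prev <- -1
    for (k in seq(2, 12, by = 2)) {
      fil <- data.frame(angle = angles[1:k], length = lens[1:k],
                        width = widths[1:k])
      s <- colony_spec(200, 200, inner_radius = 40, filaments = fil,
                       noise_sd = 0)
      f_now <- render_colony(s)$truth$f_true
      expect_gte(f_now, f_prev)
      f_prev <- f_now
    }
  }
})

test_that("rendering is deterministic and validation rejects bad specs", {
  s <- demo_spec(noise_sd = 5, seed = 99)
  expect_identical(render_colony(s)$image, render_colony(s)$image)
  s0 <- demo_spec(noise_sd = 0)
  expect_identical(render_colony(s0)$image, render_colony(s0)$image)

  expect_error(colony_spec(100, 100, inner_radius = -1), "inner_radius")
  expect_error(colony_spec(100, 100, inner_radius = 20,
                           filaments = data.frame(angle = 0, length = 5, width = 25)),
               "width")
  expect_error(colony_spec(100, 100, inner_radius = 20,
                           foreground_level = 50, background_level = 90),
               "foreground")
  # a colony pushed off-frame leaves its filament with no disc attachment
  s_bad <- demo_spec(n_spokes = 1)
  s_bad$center <- c(500, 500)
  expect_error(render_colony(s_bad), "detached")
})

test_that("inverted-contrast rendering flips intensities but not ground truth", {
  s <- demo_spec()
  normal <- render_colony(s)
  inverted <- render_colony(s, invert = TRUE)
  expect_identical(normal$truth, inverted$truth)
  # the colony interior is bright in normal rendering, dark when inverted
  ctr <- as.integer(s$center) + 1L
  expect_gt(unclass(normal$image)[ctr[1], ctr[2], 1],
            unclass(inverted$image)[ctr[1], ctr[2], 1])
})

test_that("simulated f-measures honor zero variance, the seed, and contamination", {
  d0 <- dose_design(data.frame(concentration_uM = 0, n = 5, mean_f = 1, sd_f = 0))
  expect_identical(simulate_fmeasures(d0, seed = 1)$f, rep(1, 5))

  d <- dekkera_designs(seed = 7)$bruxellensis_TRP
  expect_identical(simulate_fmeasures(d), simulate_fmeasures(d))
  tab <- simulate_fmeasures(d)
  g100 <- tab$f[tab$concentration_uM == 100]
  expect_length(g100, 79)
  expect_lt(abs(mean(g100) - 2.085), 3 * 1.547 / sqrt(79))

  dc <- dose_design(data.frame(concentration_uM = 0, n = 200, mean_f = 1, sd_f = 0.3),
                    outlier_rate = 0.1, outlier_scale = 30, seed = 5)
  tabc <- simulate_fmeasures(dc)
  expect_gt(sum(tabc$contaminated), 0)
  expect_gt(min(tabc$f[tabc$contaminated]), max(tabc$f[!tabc$contaminated]))
})

test_that("each family recovers its target moments within 2% at n = 10000", {
  for (fam in c("lognormal", "gamma", "truncated-normal")) {
    d <- dose_design(data.frame(concentration_uM = c(0, 50), n = 10000,
                                mean_f = c(0.8, 1.6), sd_f = c(0.4, 0.9)),
                     family = fam, seed = 31)
    tab <- simulate_fmeasures(d)
    for (cc in c(0, 50)) {
      v <- tab$f[tab$concentration_uM == cc]
      tgt <- d$groups[d$groups$concentration_uM == cc, ]
      expect_lt(abs(mean(v) - tgt$mean_f) / tgt$mean_f, 0.02)
      expect_lt(abs(sd(v) - tgt$sd_f) / tgt$sd_f, 0.02)
    }
  }
})

test_that("infeasible truncated-normal moment matching errors with the group name", {
  d <- dose_design(data.frame(concentration_uM = 10, n = 10, mean_f = 1, sd_f = 1.5),
                   family = "truncated-normal", strain = "S", compound = "C")
  expect_error(simulate_fmeasures(d, seed = 1), "10 uM")
})

test_that("design validation enforces its invariants", {
  base <- data.frame(concentration_uM = c(0, 10), n = c(5, 5),
                     mean_f = c(1, 1), sd_f = c(0.1, 0.1))
  expect_error(dose_design(transform(base, mean_f = c(-1, 1))), "mean_f")
  expect_error(dose_design(transform(base, n = c(1, 5))), "group sizes")
  expect_error(dose_design(transform(base, concentration_uM = c(5, 5))), "unique")
  expect_s3_class(dose_design(base), "dose_design")
})
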