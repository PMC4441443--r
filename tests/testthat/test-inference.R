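# binning, ddG, split-sample errors, permutation p-values, parabola fits

test_that("bin assignment rounds to integer kelvin then looks up ranges", {
  cases <- c("298" = "297-299", "264.4" = NA, "290.7" = "291-296",
             "265" = "265-290", "290.4" = "265-290", "340.4" = "306-340",
             "341" = NA, "299.7" = "300-305")
  got <- assign_bin(as.numeric(names(cases)))
  expect_equal(got, unname(cases))
  # ranges are disjoint and ordered: every integer kelvin maps to <= 1 bin
  bins <- temperature_bins()
  expect_true(all(bins$low <= bins$high))
  expect_true(all(diff(bins$low) > 0))
  kk <- 260:345
  hits <- vapply(kk, function(k)
    sum(k >= bins$low & k <= bins$high), 0L)
  expect_true(all(hits <= 1L))
})

test_that("split_by_bin conserves chains", {
  counts <- chain_counts(make_test_chains(20, seed = 8,
                                          temps = runif(20, 260, 345)))
  sp <- split_by_bin(counts)
  expect_equal(sum(vapply(sp$by_bin, nrow, 0L)) + nrow(sp$excluded),
               nrow(counts))
})

test_that("ddG is room minus low and antisymmetric in its bins", {
  chains_low <- make_test_chains(6, seed = 41, temps = rep(280, 6))
  chains_room <- make_test_chains(6, seed = 42, temps = rep(298, 6))
  counts <- chain_counts(c(chains_low, chains_room))
  sp <- split_by_bin(counts)
  tab <- energy_table(sp$bin_counts, entities = "hydrophobic",
                      methods = "surface", corrected = FALSE)
  dd <- delta_delta_g(tab, "hydrophobic", "surface")
  g <- function(b) tab$dG_kT[tab$bin == b]
  expect_equal(dd, g("297-299") - g("265-290"))
  expect_equal(delta_delta_g(tab, "hydrophobic", "surface",
                             bin_low = "297-299", bin_room = "265-290"), -dd)
  expect_error(delta_delta_g(tab, "hydrophobic", "contact"), "MissingCell")

  # identical counts in both bins give exactly zero
  same <- make_test_chains(5, seed = 43, temps = rep(280, 5))
  shifted <- lapply(same, function(ch) {
    ch$temperature <- 298; ch
  })
  expect_equal(ddg_counts(chain_counts(same), chain_counts(shifted),
                          "hydrophobic", "surface"), 0)
  # and ddg_counts agrees with the table route
  expect_equal(ddg_counts(sp$by_bin[["265-290"]], sp$by_bin[["297-299"]],
                          "hydrophobic", "surface"), dd, tolerance = 1e-12)
})

test_that("split SE is zero for homogeneous data and seed-reproducible", {
  ch <- make_chain("ID1", 280, c("ALA", "LEU", "SER", "LYS"),
                   c(0.02, 0.4, 0.6, 0.9))
  clones <- lapply(1:10, function(i) {
    ch$structure_id <- sprintf("ID%02d", i); ch
  })
  counts <- chain_counts(clones)
  est <- function(rows) surface_energy(bin_counts(rows), "hydrophobic")
  res <- split_standard_error(counts, est, k = 5, seed = 1)
  expect_equal(res$se, 0)

  counts2 <- chain_counts(
    sample_dataset(generator_config(n_chains = 40), seed = 51))
  r1 <- split_standard_error(counts2, est, k = 5, seed = 10)
  r2 <- split_standard_error(counts2, est, k = 5, seed = 10)
  r3 <- split_standard_error(counts2, est, k = 5, seed = 11)
  expect_identical(r1$se, r2$se)
  expect_false(identical(r1$se, r3$se))
  expect_error(split_standard_error(counts2[1:3, ], est, k = 5),
               "TooFewChains")
})

test_that("2-SE split intervals cover a known truth at t(4)-like rates", {
  # Parts of a 5-way split give a t-statistic with 4 df, so +-2 SE covers
  # ~88%, not the nominal 95%; 120 reps at the known generator truth.
  cfg <- generator_config(n_chains = 60, length_mean = 60, length_sd = 10,
                          bin_occupancy = c(0, 0, 1, 0, 0))
  truth <- truth_report(cfg, entities = "hydrophobic")
  truth <- truth$dG_surface[truth$bin == "297-299"]
  reps <- 120
  cover <- logical(reps)
  set.seed(314)
  for (i in seq_len(reps)) {
    counts <- chain_counts(sample_dataset(cfg, seed = 5000 + i))
    est <- function(rows) surface_energy(bin_counts(rows), "hydrophobic")
    se <- split_standard_error(counts, est, k = 5)$se
    cover[i] <- abs(est(counts) - truth) <= 2 * se
  }
  expect_gt(mean(cover), 0.78)
  expect_lte(mean(cover), 1.0)
})

test_that("permutation p-values degenerate correctly and are reproducible", {
  # label-invariant statistic: every resample ties the observation -> p = 1
  ch <- make_chain("P1", 280, c("ALA", "LEU", "SER", "LYS"),
                   c(0.02, 0.4, 0.6, 0.9))
  clones <- function(ids, temp) lapply(ids, function(i) {
    ch$structure_id <- sprintf("CL%02d", i); ch$temperature <- temp; ch
  })
  low <- chain_counts(clones(1:6, 280))
  room <- chain_counts(clones(7:12, 298))
  r <- resample_pvalue(low, room, "hydrophobic", "surface", n = 200, seed = 2)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)

  # reproducibility and range on heterogeneous data
  sp <- split_by_bin(chain_counts(make_test_chains(
    24, seed = 77, temps = rep(c(280, 298), each = 12))))
  a <- resample_pvalue(sp$by_bin[["265-290"]], sp$by_bin[["297-299"]],
                       "hydrophobic", "surface", n = 300, seed = 5)
  b <- resample_pvalue(sp$by_bin[["265-290"]], sp$by_bin[["297-299"]],
                       "hydrophobic", "surface", n = 300, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 0)
  expect_lte(a$p_value, 1)

  # relabelling chain ids leaves the p-value unchanged
  relab <- sp$by_bin[["265-290"]]
  relab$structure_id <- rev(relab$structure_id)
  c2 <- resample_pvalue(relab, sp$by_bin[["297-299"]],
                        "hydrophobic", "surface", n = 300, seed = 5)
  expect_identical(a$p_value, c2$p_value)
  expect_error(resample_pvalue(low[0, ], room, "hydrophobic", "surface"),
               "EmptyBin")
})

test_that("the fast resampling path equals a naive ddg_counts loop", {
  sp <- split_by_bin(chain_counts(make_test_chains(
    16, seed = 63, temps = rep(c(285, 298), each = 8))))
  low <- sp$by_bin[["265-290"]]; room <- sp$by_bin[["297-299"]]
  for (corr in c(FALSE, TRUE)) {
    r <- resample_pvalue(low, room, "hydrophobic", "surface",
                         corrected = corr, n = 25, seed = 9)
    pooled <- rbind(as.data.frame(low), as.data.frame(room))
    set.seed(9)
    naive <- vapply(1:25, function(b) {
      idx <- sample.int(nrow(pooled), nrow(low))
      ddg_counts(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE],
                 "hydrophobic", "surface", corrected = corr)
    }, 0)
    expect_equal(r$resamples, naive, tolerance = 1e-12)
  }
})

test_that("parabola fits interpolate, reduce to OLS, and match the normal equations", {
  tt <- c(278, 293, 298, 302, 322)
  # exact interpolation of y = (T - 310)^2
  f <- fit_parabola(tt, (tt - 310)^2, weights = c(5, 1, 9, 2, 7))
  expect_equal(unname(f$coefficients["a2"]), 1, tolerance = 1e-8)
  expect_equal(f$vertex, 310, tolerance = 1e-6)
  expect_false(f$is_max)  # upward parabola: vertex is not a maximum
  expect_equal(f$S, 0, tolerance = 1e-10)

  set.seed(19)
  y <- -2e-3 * (tt - 315)^2 + 1 + rnorm(5, 0, 0.05)
  w <- c(3919, 6800, 20287, 10681, 8087)
  # equal weights = ordinary least squares (stats::lm as oracle)
  f_ols <- fit_parabola(tt, y)
  lm_fit <- lm(y ~ tt + I(tt^2))
  expect_equal(unname(f_ols$coefficients), unname(coef(lm_fit)),
               tolerance = 1e-8)
  # weighted: direct normal-equation solve as independent oracle
  f_w <- fit_parabola(tt, y, w)
  X <- cbind(1, tt, tt^2)
  beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  expect_equal(unname(f_w$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_true(f_w$is_max)
  expect_equal(f_w$vertex, -f_w$coefficients[["a1"]] /
                 (2 * f_w$coefficients[["a2"]]))

  expect_error(fit_parabola(c(280, 298), c(1, 2)), "DegenerateFit")
  expect_error(fit_parabola(c(280, 280, 280), c(1, 2, 3)), "DegenerateFit")
})

test_that("weighted residual sum never increases when a point is dropped", {
  set.seed(23)
  for (rep in 1:10) {
    tt <- sort(runif(6, 270, 330))
    y <- rnorm(6)
    w <- runif(6, 0.5, 5)
    S_full <- fit_parabola(tt, y, w)$S
    for (drop in 1:6) {
      S_sub <- fit_parabola(tt[-drop], y[-drop], w[-drop])$S
      expect_lte(S_sub, S_full + 1e-10)
    }
  }
})
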