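test_that("normalized CSP combines proton and nitrogen shifts correctly", {
  expect_identical(csp(0, 0), 0)
  expect_identical(csp(0.1, 0), 0.1)
  expect_equal(csp(0, 1), 0.2)
  expect_equal(csp(3, 4), sqrt(9 + 0.64))
  # sign symmetry over a grid of inputs
  set.seed(7)
  h <- runif(50, -2, 2); n <- runif(50, -10, 10)
  expect_equal(csp(h, n), csp(-h, -n))
  expect_true(all(csp(h, n) >= 0))
  expect_error(csp(NA_real_, 0), "finite")
  expect_error(csp(0, Inf), "finite")
})

test_that("one-site isotherm reproduces closed-form values", {
  # at Pt = Lt = Kd the bound fraction is (3 - sqrt(5))/2
  k <- 0.05
  expect_equal(one_site_shift(k, k, k, 1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # ligand-excess (Langmuir) limit: Lt = Kd gives half-saturation
  expect_equal(one_site_shift(0.05, 1e-4, 0.05, 0.2), 0.1, tolerance = 1e-3)
  # stoichiometric discriminant does not go negative by round-off
  expect_gte(one_site_shift(0.1, 0.1, 1e-9, 1), 0)
})

make_track <- function(kd, ddmax, pt, lts, dir = c(1, 0.3)) {
  dd <- one_site_shift(lts, pt, kd, ddmax)
  u <- dir / sqrt(sum(c(dir[1], 0.2 * dir[2])^2))
  tibble::tibble(residue_id = 1L, atom_label = "HN", ligand_conc_mM = lts,
                 dH_ppm = 8 + dd * u[1], dN_ppm = 120 + dd * u[2])
}

test_that("noiseless one-site data are recovered essentially exactly", {
  tr <- make_track(0.05, 0.2, 0.1, c(0, standard_schedule))
  f <- fit_one_site(tr, 0.1)
  expect_true(f$converged)
  expect_equal(f$kd, 0.05, tolerance = 1e-5)
  expect_equal(f$ddmax, 0.2, tolerance = 1e-5)
  expect_lt(max(abs(f$data$residual)), 1e-6)
  # also identifiable without the apo reference point
  f2 <- fit_one_site(make_track(0.05, 0.2, 0.1, standard_schedule), 0.1)
  expect_equal(f2$kd, 0.05, tolerance = 1e-4)
})

test_that("fit is scale-consistent under concentration rescaling", {
  for (c_scale in c(0.1, 10)) {
    tr <- make_track(0.05 * c_scale, 0.2, 0.1 * c_scale,
                     c(0, standard_schedule) * c_scale)
    f <- fit_one_site(tr, 0.1 * c_scale)
    expect_equal(f$kd, 0.05 * c_scale, tolerance = 1e-3)
  }
})

test_that("optimizer agrees with a grid-search SSE oracle", {
  # oracle: exhaustive search on a 400 x 400 (log-kd, ddmax) lattice
  tr <- make_track(0.08, 0.25, 0.1, c(0, standard_schedule))
  set.seed(3)
  tr$dH_ppm <- tr$dH_ppm + rnorm(nrow(tr), 0, 0.002)
  dd_obs <- csp(tr$dH_ppm - tr$dH_ppm[1], tr$dN_ppm - tr$dN_ppm[1])
  kds <- exp(seq(log(1e-3), log(5), length.out = 400))
  dms <- seq(0.05, 0.6, length.out = 400)
  pred0 <- outer(kds, tr$ligand_conc_mM,
                 function(k, l) one_site_shift(l, 0.1, k[1], 1))
  pred0 <- t(vapply(seq_along(kds), function(i)
    one_site_shift(tr$ligand_conc_mM, 0.1, kds[i], 1), numeric(nrow(tr))))
  sse <- vapply(seq_along(kds), function(i) {
    r2 <- vapply(dms, function(dm) sum((dd_obs - dm * pred0[i, ])^2),
                 numeric(1))
    min(r2)
  }, numeric(1))
  kd_oracle <- kds[which.min(sse)]
  f <- fit_one_site(tr, 0.1)
  expect_equal(f$kd, kd_oracle, tolerance = 0.02)
})

test_that("parameter recovery over noisy replicates is unbiased", {
  # 200 noisy replicates at the standard 7-point schedule
  kds <- numeric(200); dms <- numeric(200)
  base <- make_track(0.05, 0.2, 0.1, c(0, standard_schedule))
  set.seed(11)
  for (r in 1:200) {
    tr <- base
    tr$dH_ppm <- tr$dH_ppm + rnorm(nrow(tr), 0, 0.002)
    tr$dN_ppm <- tr$dN_ppm + rnorm(nrow(tr), 0, 0.002)
    f <- fit_one_site(tr, 0.1)
    kds[r] <- f$kd; dms[r] <- f$ddmax
  }
  expect_lt(abs(median(kds) - 0.05) / 0.05, 0.15)
  expect_lt(abs(median(dms) - 0.2) / 0.2, 0.05)
})

test_that("sub-noise-floor residues are flagged non-binding, not fitted", {
  tr <- make_track(0.05, 0.002, 0.1, c(0, standard_schedule))
  f <- fit_one_site(tr, 0.1, noise_floor = 0.005)
  expect_true(f$nonbinding)
  expect_true(is.na(f$kd))
  g <- glance(f)
  expect_true(g$nonbinding)
})

test_that("fit_kd maps over residues and broom methods work", {
  tr1 <- make_track(0.05, 0.2, 0.1, c(0, standard_schedule))
  tr2 <- make_track(0.3, 0.15, 0.1, c(0, standard_schedule))
  tr2$residue_id <- 2L
  fits <- fit_kd(dplyr::bind_rows(tr1, tr2), 0.1)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$kd_mM, c(0.05, 0.3), tolerance = 1e-3)
  f <- fit_one_site(tr1, 0.1)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "kd_mM"], 0.05, tolerance = 1e-4)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("peak-list validation rejects malformed tracks", {
  tr <- make_track(0.05, 0.2, 0.1, c(0, standard_schedule))
  expect_error(fit_one_site(tr[1:3, ], 0.1), "at least 4")
  bad <- tr; bad$ligand_conc_mM[3] <- bad$ligand_conc_mM[2]
  expect_error(fit_one_site(bad, 0.1), "increasing")
  bad2 <- tr; bad2$dH_ppm[2] <- NaN
  expect_error(fit_one_site(bad2, 0.1), "non-finite")
})

test_that("collinear tracks give zero turn angles and no nonlinearity call", {
  tr <- make_track(0.05, 0.2, 0.1, c(0, standard_schedule))
  m <- detect_migration(tr, 0.1)
  expect_lt(m$max_turn_deg, 1e-3)
  expect_false(m$is_nonlinear)
  # any single-site track stays linear at thresholds >= 20 degrees
  for (kd in c(0.01, 0.1, 1)) {
    m2 <- detect_migration(make_track(kd, 0.3, 0.1, c(0, standard_schedule)), 0.1,
                           angle_threshold = 20)
    expect_false(m2$is_nonlinear)
  }
})

test_that("a sign reversal of the step vectors gives a 180 degree turn", {
  tr <- tibble::tibble(residue_id = 1L, atom_label = "HN",
                       ligand_conc_mM = c(0, 0.1, 0.2, 0.3),
                       dH_ppm = c(8, 8.1, 8.2, 8.1),
                       dN_ppm = c(120, 120.5, 121, 120.5))
  m <- detect_migration(tr, 0.1)
  expect_equal(m$max_turn_deg, 180, tolerance = 1e-9)
  expect_true(m$is_nonlinear)
  expect_equal(m$turn_ratio, 2)   # Lt/Pt at the reversal point
})

test_that("zero-length steps are skipped and logged", {
  tr <- tibble::tibble(residue_id = 1L, atom_label = "HN",
                       ligand_conc_mM = c(0, 0.1, 0.2, 0.3),
                       dH_ppm = c(8, 8.1, 8.1, 8.2),
                       dN_ppm = c(120, 121, 121, 122))
  expect_message(m <- detect_migration(tr, 0.1), "zero-length")
  expect_equal(m$n_skipped, 2L)
})
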