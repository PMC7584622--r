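std_protocol <- titration_protocol()

test_that("quadratic complex solver agrees with an independent root-finder", {
  set.seed(202)
  for (i in 1:200) {
    nM <- 10^runif(1, -9, -2)
    L <- 10^runif(1, -9, -2)
    Kd <- 10^runif(1, -12, -1)
    pl <- bound_complex(nM, L, Kd)
    oracle <- oracle_complex(nM, L, Kd)
    expect_lt(abs(pl - oracle) / oracle, 1e-12)
    expect_true(pl >= 0 && pl <= min(nM, L))
  }
  expect_equal(bound_complex(0, 1e-6, 1e-6), 0)
  expect_equal(bound_complex(1e-6, 0, 1e-6), 0)
})

test_that("simulated cumulative heat matches the mole-balance oracle", {
  for (kd in c(1e-8, 1e-6, 1e-4)) {
    params <- one_site_params(Kd = kd, n = 1.2, dH = -40e3)
    tg <- simulate_titration(std_protocol, params)
    expect_equal(sum(tg$heat_uJ), oracle_cumulative_heat(std_protocol, params),
                 tolerance = 1e-9)
  }
})

test_that("zero-enthalpy and tight-binding limits behave analytically", {
  zero <- simulate_titration(std_protocol,
                             one_site_params(Kd = 1e-6, n = 1, dH = 0))
  expect_equal(zero$heat_uJ, rep(0, 25))

  params <- one_site_params(Kd = 1e-15, n = 1, dH = -40e3, q_offset = 0.5)
  tg <- simulate_titration(std_protocol, params)
  # pre-saturation: all injected ligand binds, q ~= dH * Ls * v (+ offset)
  expected <- params$dH * std_protocol$Ls * std_protocol$injections[1] * 1e6 +
    params$q_offset
  pre <- which(tg$molar_ratio < 0.8)
  expect_equal(tg$heat_uJ[pre], rep(expected, length(pre)), tolerance = 0.02)
  # post-saturation: only the background offset remains
  post <- which(tg$molar_ratio > 1.3)
  expect_equal(tg$heat_uJ[post], rep(params$q_offset, length(post)),
               tolerance = 1e-6)
})

test_that("bound fraction is non-decreasing over injections without noise", {
  tg <- simulate_titration(std_protocol,
                           one_site_params(Kd = 2e-6, n = 1, dH = -40e3))
  frac <- tg$PL / tg$M_total
  expect_true(all(diff(frac) > -1e-12))
})

test_that("simulation with a seed is reproducible and restores global RNG state", {
  set.seed(42)
  before <- .Random.seed
  a <- simulate_titration(std_protocol, one_site_params(Kd = 1e-6),
                          noise_sd = 1, seed = 7)
  expect_identical(.Random.seed, before)
  b <- simulate_titration(std_protocol, one_site_params(Kd = 1e-6),
                          noise_sd = 1, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_titration(std_protocol, one_site_params(Kd = 1e-6),
                                  noise_sd = 1), "seed")
})

test_that("dilution subtraction is elementwise with validated lengths", {
  tg <- simulate_titration(std_protocol, one_site_params(Kd = 1e-6))
  expect_equal(subtract_dilution(tg$heat_uJ, tg$heat_uJ), rep(0, 25))
  expect_equal(subtract_dilution(tg$heat_uJ, rep(0, 25)), tg$heat_uJ)
  expect_error(subtract_dilution(tg$heat_uJ, rep(0, 24)), "length mismatch")

  # simulated signal+dilution minus simulated dilution recovers the signal
  params <- one_site_params(Kd = 1e-6, n = 1, dH = -40e3, q_offset = 2)
  nsd <- 0.5
  rep1 <- generate_itc_dataset(std_protocol, params, nsd, 1, seed = 9)[[1]]
  corrected <- subtract_dilution(rep1$sample, rep1$control)
  clean <- simulate_titration(std_protocol,
                              one_site_params(Kd = 1e-6, n = 1, dH = -40e3))
  expect_true(all(abs(corrected$heat_uJ - clean$heat_uJ) < 2 * nsd * 4))
})

test_that("noise-free fit at c = 10 recovers parameters to 4 significant figures", {
  prot <- titration_protocol(Ls = 1e-4, M0 = 1e-5)
  truth <- one_site_params(Kd = 1e-6, n = 1.05, dH = -35e3, q_offset = 0.4)
  expect_equal(as.numeric(wiseman_c(prot, truth)), 10.5)
  tg <- simulate_titration(prot, truth)
  fit <- fit_one_site(tg$heat_uJ, prot, seed = 5)
  expect_true(fit$converged)
  expect_equal(fit$params$Kd, truth$Kd, tolerance = 1e-4)
  expect_equal(fit$params$n, truth$n, tolerance = 1e-4)
  expect_equal(fit$params$dH, truth$dH, tolerance = 1e-4)
  expect_equal(fit$params$q_offset, truth$q_offset, tolerance = 1e-3)
  expect_equal(fit$c, truth$n * prot$M0 / fit$params$Kd, tolerance = 1e-6)
})

test_that("fit is invariant to unit rescaling of heats", {
  prot <- titration_protocol(Ls = 1e-4, M0 = 1e-5)
  truth <- one_site_params(Kd = 5e-7, n = 1, dH = -40e3)
  q <- simulate_titration(prot, truth)$heat_uJ
  to_ucal <- 1 / 4.184
  fit_uj <- fit_one_site(q, prot, seed = 3)
  fit_ucal <- fit_one_site(q * to_ucal, prot, seed = 3)
  expect_equal(fit_ucal$params$Kd, fit_uj$params$Kd, tolerance = 1e-5)
  expect_equal(fit_ucal$params$dH, fit_uj$params$dH * to_ucal,
               tolerance = 1e-5)
})

test_that("fixing n clamps the stoichiometry and low-data fits fail hard", {
  prot <- titration_protocol(Ls = 1e-4, M0 = 1e-5)
  tg <- simulate_titration(prot, one_site_params(Kd = 1e-6, n = 1, dH = -40e3))
  fit <- fit_one_site(tg$heat_uJ, prot, fix_n = 1, seed = 2)
  expect_equal(fit$params$n, 1)
  expect_true(fit$n_fixed)
  expect_equal(tidy(fit)$std.error[tidy(fit)$term == "n"], 0)

  short <- titration_protocol(injections = rep(10e-6, 5))
  expect_error(fit_one_site(rep(-1, 5), short, seed = 1),
               "at least 6")
})

test_that("parameter recovery bias is small across the identifiable c range", {
  # c = 5 and c = 500 at 1% noise
  for (c_target in c(5, 500)) {
    kd <- 1 * 70e-6 / c_target
    prot <- titration_protocol()
    truth <- one_site_params(Kd = kd, n = 1, dH = -40e3)
    nsd <- noise_sd_for(prot, truth, 0.01)
    reps <- generate_itc_dataset(prot, truth, nsd, 24, seed = 61)
    kds <- vapply(reps, function(r) {
      fit_one_site(subtract_dilution(r$sample, r$control), prot,
                   seed = r$seed_used)$params$Kd
    }, 0)
    expect_lt(abs(median(kds) / kd - 1), 0.05)
  }
})

test_that("wiseman c reproduces the experimental design diagnostics", {
  expect_equal(as.numeric(wiseman_c(titration_protocol(M0 = 70e-6),
                                    one_site_params(Kd = 0.14e-6, n = 1))),
               500)
  expect_equal(as.numeric(wiseman_c(titration_protocol(Ls = 13e-6, M0 = 1.3e-6),
                                    one_site_params(Kd = 26e-9, n = 1))),
               50)
  huge <- wiseman_c(titration_protocol(), one_site_params(Kd = 1, n = 1))
  expect_lt(as.numeric(huge), 1e-4)
  expect_equal(attr(huge, "regime"), "low")
})

test_that("tidy and glance expose estimates, propagated errors and diagnostics", {
  prot <- titration_protocol(Ls = 1e-4, M0 = 1e-5)
  truth <- one_site_params(Kd = 1e-6, n = 1, dH = -40e3)
  nsd <- noise_sd_for(prot, truth, 0.01)
  tg <- simulate_titration(prot, truth, nsd, seed = 8)
  fit <- fit_one_site(tg$heat_uJ, prot, seed = 8)
  td <- tidy(fit)
  expect_equal(td$term, c("Kd", "n", "dH", "q_offset"))
  expect_true(all(td$std.error >= 0, na.rm = TRUE))
  kd_se <- td$std.error[td$term == "Kd"]
  expect_lt(abs(td$estimate[td$term == "Kd"] - truth$Kd), 5 * kd_se)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_injections, 25L)
  expect_gt(gl$rss, 0)
})
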