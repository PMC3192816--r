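test_that("tRNA allocation is proportional with exact total", {
  expect_identical(allocate_trna_counts(c(1, 1), 100), c(50L, 50L))
  expect_identical(allocate_trna_counts(c(3, 1), 100), c(75L, 25L))
  x <- allocate_trna_counts(c(1, 1, 1), 100)
  expect_identical(sort(x), c(33L, 33L, 34L))
  expect_identical(sum(x), 100L)
  expect_error(allocate_trna_counts(c(1, 1, 1), 2), "smaller than the number")
  expect_error(allocate_trna_counts(c(0, 1), 10), "positive")
  # property: the total is always met exactly and every species gets >= 1
  set.seed(1)
  for (i in 1:25) {
    g <- sample(1:16, sample(2:41, 1), replace = TRUE)
    Tt <- sample(length(g):5000, 1)
    x <- allocate_trna_counts(g, Tt)
    expect_identical(sum(x), as.integer(Tt))
    expect_true(all(x >= 1))
  }
})

test_that("kappa calibration reproduces the target mean hopping rate", {
  expect_equal(calibrate_kappa(c(50, 150), 10), 0.1)
  expect_error(calibrate_kappa(c(50, 150), 0), "positive")
  g <- synthetic_trna_table()$gene_copy_number
  Tc <- allocate_trna_counts(g, 3712)
  kap <- calibrate_kappa(Tc, 10)
  expect_equal(mean(kap * Tc), 10)
  # usage-weighted variant: mean over codon positions hits the target
  f <- g / sum(g)
  kap_u <- calibrate_kappa(Tc, 10, usage = f)
  expect_equal(sum(f * kap_u * Tc), 10)
})

test_that("enzyme kinetics build V = kcat*E and K in molecule units", {
  kin <- enzyme_kinetics(1, 0.1, c(100L, 200L), 1e-6, 1e-15)
  expect_identical(kin$E, c(10L, 20L))
  expect_equal(kin$V, c(10, 20))
  expect_equal(kin$K[1], 602.214076, tolerance = 1e-6)  # 1 uM in 1 um^3
  # floor: at least one enzyme molecule per species
  expect_identical(enzyme_kinetics(1, 0.01, 50L, 1e-6, 1e-15)$E, 1L)
})

test_that("doubling the system size leaves intensive quantities unchanged", {
  trna <- extdata_trna()
  orfs <- synthetic_orfs(trna)
  m1 <- orfs[[1]]; m1$copies <- 20L
  m2 <- orfs[[1]]; m2$copies <- 40L
  s1 <- build_system(list(m1), trna, alpha = 0.1)
  s2 <- build_system(list(m2), trna, alpha = 0.1)
  expect_equal(s2$T_tot, 2 * s1$T_tot, tolerance = 1e-3)
  expect_equal(s2$v_eff_L, 2 * s1$v_eff_L)
  expect_equal(s2$trna$K[1], 2 * s1$trna$K[1])
  expect_equal(s2$kappa * s2$T_tot, s1$kappa * s1$T_tot, tolerance = 1e-3)
  # intensive predictions: supply, demand, Q, and critical alphas agree up
  # to the molecule-count discretization (counts and enzyme numbers are
  # integers, so each sigma_i can move by ~1/T_tot and V_i/T_i by one
  # rounding step of E_i)
  sd1 <- supply_demand(s1); sd2 <- supply_demand(s2)
  expect_lt(max(abs(sd2$sigma - sd1$sigma)), 2 / s1$T_tot)
  expect_equal(sd2$f, sd1$f)
  ca1 <- critical_alphas(s1); ca2 <- critical_alphas(s2)
  expect_equal(attr(ca2, "alpha_c"), attr(ca1, "alpha_c"), tolerance = 0.08)
})

test_that("build_system validates inputs and fills rates", {
  trna <- toy_trna()
  bad <- list(list(name = "short", species = rep(1L, 3), copies = 1L))
  expect_error(build_system(bad, trna, alpha = 0.1), "shorter")
  bad2 <- list(list(name = "x", species = rep(9L, 30), copies = 1L))
  expect_error(build_system(bad2, trna, alpha = 0.1), "unknown tRNA species")
  ok <- build_system(list(list(name = "x", species = rep(1L, 30), copies = 2L)),
                     trna, alpha = 0.1)
  expect_gt(ok$mrnas[[1]]$beta, max(ok$kappa * ok$trna$T))
  expect_identical(ok$N, 60)
})
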