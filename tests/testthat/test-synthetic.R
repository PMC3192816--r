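test_that("designer mRNAs put one distinct codon at the centre", {
  d <- make_designer_mrna(5, 1L, 2L)
  expect_identical(d$species, c(1L, 1L, 2L, 1L, 1L))
  expect_identical(make_designer_mrna(1, 1L, 2L)$species, 2L)
  expect_identical(sum(make_designer_mrna(31, 1L, 2L)$species == 1L), 30L)
  expect_error(make_designer_mrna(5, 1L, 2L, w = 10), "shorter")
})

test_that("mixtures hit the requested codon shares with integer copies", {
  a <- list(name = "A", species = rep(1L, 100))
  b <- list(name = "B", species = rep(1L, 400))
  m50 <- make_mixture(list(a, b), c(0.5, 0.5), 4000)
  expect_identical(vapply(m50, `[[`, integer(1), "copies"), c(20L, 5L))
  m80 <- make_mixture(list(a, b), c(0.8, 0.2), 4000)
  expect_identical(vapply(m80, `[[`, integer(1), "copies"), c(32L, 2L))
  ach <- attr(m80, "achieved_shares")
  expect_lt(max(abs(ach - c(0.8, 0.2))), 400 / 4000)  # off by < one long copy
  expect_error(make_mixture(list(a, b), c(0.99, 0.01), 4000), "no full copy")
  expect_error(make_mixture(list(a, b), c(0.7, 0.7), 4000), "sum to 1")
})

test_that("random gene sets are reproducible and bias-controlled", {
  trna <- extdata_trna(); map <- extdata_map(trna)
  g1 <- make_random_gene_set(10, c(50, 100), bias = 0.3, seed = 5,
                             trna = trna, map = map)
  g2 <- make_random_gene_set(10, c(50, 100), bias = 0.3, seed = 5,
                             trna = trna, map = map)
  expect_identical(g1, g2)
  g3 <- make_random_gene_set(10, c(50, 100), bias = 0.3, seed = 6,
                             trna = trna, map = map)
  expect_false(identical(g1, g3))
  # bias = 1: per-gene demand tracks supply, so Q ~ 1 on long genes
  gb <- make_random_gene_set(1, c(20000, 20000), bias = 1, seed = 2,
                             trna = trna, map = map)
  sys <- build_system(list(c(gb[[1]][c("name", "species")], copies = 1L)),
                      trna, alpha = 0.1)
  sd <- supply_demand(sys)
  used <- sd$f > 0
  expect_lt(mean(abs(sd$Q[used] - 1)), 0.15)
  # mean QLI decreases as usage bias increases
  qs <- vapply(c(0, 0.5, 1), function(b) {
    gs <- make_random_gene_set(40, c(150, 300), bias = b, seed = 7,
                               trna = trna, map = map)
    mean(vapply(gs, function(g) qli(g$species, sd$Q), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("the enumeration oracle is a proper stationary solution", {
  oi <- make_oracle_instance("two_site")
  expect_equal(sum(oi$exact$pi), 1)
  expect_true(all(oi$exact$pi >= 0))
  # generator rows sum to zero
  expect_lt(max(abs(Matrix::rowSums(oi$exact$generator))), 1e-12)
  # global balance: pi^T Q = 0
  expect_lt(max(abs(as.numeric(oi$exact$pi %*% oi$exact$generator))), 1e-10)
  expect_error(exact_stationary(fixture_mono(0.1)), "state space too large")
})

test_that("the infinite-recharge oracle equals the fixed-rate enumeration", {
  # two independent enumerations: fixed_rates=TRUE vs finite V so large the
  # charged pool never visibly departs from T
  fx <- make_oracle_instance("fixed_small")
  sys_v <- fx$system
  sys_v$trna$V <- 1e9
  finite <- exact_stationary(sys_v, fixed_rates = FALSE)
  expect_equal(fx$exact$J, finite$J, tolerance = 1e-4)
  expect_equal(fx$exact$reader_profile[[1]], finite$reader_profile[[1]],
               tolerance = 1e-3)
})

test_that("packaged surrogate transcripts carry their designed structure", {
  trna <- extdata_trna()
  orfs <- synthetic_orfs(trna)
  names(orfs) <- vapply(orfs, `[[`, "", "name")
  dom <- which(trna$label == "Glu1")
  a_sp <- orfs[["YDR382W"]]$species
  expect_identical(sum(a_sp == dom), 22L)             # a fifth of 110 codons
  expect_true(all(a_sp[c(70:74, 78:82, 86:89)] == dom))  # clusters near 80
  slow <- which(trna$label == "Leu5")
  b_sp <- orfs[["YLR378C"]]$species
  expect_identical(which(b_sp == slow), c(60L, 140L, 221L, 300L, 380L, 432L))
  expect_true(all(diff(which(b_sp == slow)) > 10))    # separated beyond w
  # generators are pure functions: repeated calls give identical sequences
  expect_identical(synthetic_orfs(trna), unname(orfs))
})

test_that("cell-cycle panel switches the documented High/Low pattern", {
  p <- synthetic_cellcycle_panel()
  high_in_G1 <- c("Cln3", "Cdh1", "Clb6", "Sic1", "Cln1", "Cln2", "Clb5")
  low_in_G1 <- c("Cdc20", "Clb1", "Clb2")
  expect_true(all(p$copies_G1[high_in_G1] == 3L))
  expect_true(all(p$copies_G1[low_in_G1] == 1L))
  expect_true(all(p$copies_G2[high_in_G1] == 1L))
  expect_true(all(p$copies_G2[low_in_G1] == 3L))
  # constitutive genes unchanged between phases
  const <- grep("^const", names(p$copies_G1), value = TRUE)
  expect_identical(p$copies_G1[const], p$copies_G2[const])
})
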