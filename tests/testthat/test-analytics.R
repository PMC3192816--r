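test_that("supply and demand are normalized shares with Q = f/sigma", {
  sys <- toy_system(L = 20, copies = 2, T_counts = c(25L, 25L),
                    species = rep(1L, 20))           # mono-codon usage
  sd <- supply_demand(sys)
  expect_equal(sd$sigma, c(0.5, 0.5))
  expect_equal(sd$f, c(1, 0))                        # unused species: f = 0
  expect_equal(sum(sd$sigma), 1)
  expect_equal(sum(sd$f), 1)
  # f == sigma => Q == 1
  sys2 <- toy_system(L = 20, copies = 2, T_counts = c(30L, 10L),
                     species = rep(c(1L, 1L, 1L, 2L), 5))
  sd2 <- supply_demand(sys2)
  expect_equal(sd2$Q, c(1, 1))
  # permuting codon order changes nothing
  sys3 <- sys2
  sys3$mrnas[[1]]$species <- rev(sys2$mrnas[[1]]$species)
  expect_equal(supply_demand(sys3)$f, sd2$f)
})

test_that("LD closed forms behave in the dilute limit and are monotone", {
  th <- ld_theory(1e-6, 10, 10)
  expect_equal(th$J, 1e-6, tolerance = 1e-3)         # J -> alpha
  expect_equal(th$rho_cov / th$rho, 10)
  alphas <- seq(0.01, 2.4, length.out = 40)          # within the LD domain
  Js <- vapply(alphas, function(a) ld_theory(a, 10, 10)$J, numeric(1))
  expect_true(all(diff(Js) > 0))
  expect_false(ld_theory(5, 10, 10)$ld_valid)
  expect_true(ld_theory(1, 10, 10)$ld_valid)
})

test_that("LD theory matches a high-precision uniform-lattice run within 2%", {
  # L = 60, alpha = 0.1 k, fast recharging so rates stay at kappa*T
  k <- 10
  sys <- make_system_manual(
    list(list(name = "u", species = rep(1L, 60), copies = 20L)),
    T_counts = 500L, V = 1e6, K = 10, kappa = k / 500, w = 3,
    alpha = 0.1 * k, beta = 5 * k)
  obs <- run_simulation(sys, burn_in = 60, measure = 250, seed = 12)
  expect_equal(obs$species$J, ld_theory(1, k, 3)$J, tolerance = 0.02)
})

test_that("critical alphas identify the max-Q species as the bottleneck", {
  # equal V and T across species; usage gives Q = (2, 1, 0.5)
  species <- rep(c(1L, 1L, 1L, 1L, 2L, 2L, 3L), 4)   # 16:8:4 counts
  sys <- make_system_manual(
    list(list(name = "m", species = species, copies = 5L)),
    T_counts = c(100L, 100L, 100L), V = 50, K = 10, kappa = 0.05, w = 3,
    alpha = 0.1, beta = 20)
  sd <- supply_demand(sys)
  expect_equal(sd$Q[order(sd$species_id)], c(16, 8, 4) / 28 * 3,
               tolerance = 1e-9)
  ca <- critical_alphas(sys)
  expect_identical(which.min(ca$alpha_c), 1L)
  expect_identical(attr(ca, "bottleneck"), "sp1")
  # ranking: descending Q == ascending first-order alpha_c
  expect_identical(order(-ca$Q), order(ca$alpha_c_first_order))
})

test_that("doubling all copy numbers halves alpha_c to first order", {
  sys1 <- fixture_system("mrna_A", alpha = 0.1, n_codons_target = 2000)
  sys2 <- sys1
  sys2$mrnas[[1]]$copies <- 2L * sys1$mrnas[[1]]$copies
  sys2$N <- 2L * sys1$N
  ca1 <- critical_alphas(sys1)
  ca2 <- critical_alphas(sys2)
  used <- is.finite(ca1$alpha_c_first_order)
  expect_equal(ca2$alpha_c_first_order[used],
               ca1$alpha_c_first_order[used] / 2)
})

test_that("mono-codon critical alpha coincides with the uniform-lattice rate", {
  sys <- fixture_mono(0.1)
  ca <- critical_alphas(sys)
  alpha_star <- attr(ca, "alpha_c")
  # independent computation straight from the defining balance:
  # N * J_LD(alpha*) = V T / (K + T), inverted through the LD current
  k <- sys$kappa * sys$trna$T[1]
  R <- sys$trna$V[1] * sys$trna$T[1] / (sys$trna$K[1] + sys$trna$T[1])
  f <- function(a) sys$N * ld_theory(a, k, sys$w)$J - R
  root <- uniroot(f, c(1e-6, k / (1 + sqrt(sys$w)) * 0.999))$root
  expect_equal(alpha_star, root, tolerance = 1e-6)
})

test_that("the QP threshold is monotone in q and continuous at q = k", {
  k <- 10; w <- 10
  qs <- seq(0.05, k / (1 + 2 * sqrt(w)), length.out = 15)  # defect-limited range
  a <- vapply(qs, function(q) qp_threshold(q, k, w), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_equal(qp_threshold(k, k, w), k / (1 + sqrt(w)))
  expect_identical(qp_threshold(2 * k, k, w), Inf)     # not a bottleneck
  expect_true(all(vapply(seq(0.05, k, length.out = 30), function(q)
    qp_threshold(q, k, w), numeric(1)) <= k / (1 + sqrt(w)) + 1e-12))
})

test_that("simulated queue onset brackets the QP threshold within 25%", {
  # L = 30, w = 3 designer lattice with a central slow site, fixed rates
  k <- 10; q <- 0.5; w <- 3
  mr <- make_designer_mrna(30, 1L, 2L, copies = 60L, w = w)
  sys <- make_system_manual(list(mr), T_counts = c(1000L, 50L), V = 1e6,
                            K = 10, kappa = k / 1000, w = w,
                            alpha = 0.1, beta = 3 * k)
  aqp <- qp_threshold(q, k, w)
  grid <- aqp * c(0.4, 0.55, 0.7, 0.85, 1.0, 1.15, 1.3)
  dev <- vapply(grid, function(a) {
    s <- sys; s$mrnas[[1]]$alpha <- a
    obs <- run_simulation(s, burn_in = 300, measure = 500, seed = 2,
                          fixed_rates = TRUE)
    1 - obs$species$J / ld_theory(a, k, w)$J
  }, numeric(1))
  # onset = first alpha whose current falls > 15% below the LD line
  onset <- grid[which(dev > 0.15)[1]]
  expect_false(is.na(onset))
  expect_lt(abs(onset - aqp) / aqp, 0.25)
})

test_that("designer-regime classification compares the three thresholds", {
  for (rg in c("LR1", "QP", "LR2")) {
    fx <- fixture_designer(rg)
    expect_identical(sub("_.*", "", fx$classification$region), rg)
  }
  cl <- fixture_designer("LR1")$classification
  expect_lt(cl$alpha_c_center, cl$alpha_qp)
  expect_lt(cl$alpha_c_center, cl$alpha_c_bulk)
})

test_that("RSCU weights follow the synonymous-family definition", {
  # 2-codon family with counts (30, 10): RSCU (1.5, 0.5), weights (1, 1/3)
  wt <- suppressMessages(rscu_weights(c(GAA = 30, GAG = 10)))
  glu <- wt[wt$amino_acid == "E", ]
  expect_equal(glu$rscu[glu$codon == "GAA"], 1.5)
  expect_equal(glu$rscu[glu$codon == "GAG"], 0.5)
  expect_equal(glu$weight[glu$codon == "GAA"], 1)
  expect_equal(glu$weight[glu$codon == "GAG"], 1 / 3)
  # unseen codons get the 0.5 pseudocount, with a message
  expect_message(rscu_weights(c(GAA = 30)), "pseudocount")
})

test_that("QLI and CAI behave on degenerate inputs", {
  Q <- c(0.5, 2, 1)
  expect_equal(qli(rep(2L, 50), Q), 2)                  # uniform mRNA: QLI = Q_s
  expect_equal(qli(c(1L, 2L), Q), 1)                    # geometric mean
  expect_message(qli(c(1L, 3L), c(0.5, 2, 0)), "pseudocount")
  # a gene built only of maximal-RSCU codons has CAI 1
  wt <- suppressMessages(rscu_weights(c(GAA = 30, GAG = 10, AAA = 5, AAG = 20)))
  expect_equal(cai(c("GAA", "AAG", "GAA"), wt), 1)
  expect_lt(cai(c("GAG", "AAA"), wt), 1)
  # single-codon families are excluded from the geometric mean
  expect_equal(cai(c("AUG", "UGG", "GAA"), wt), 1)
})

test_that("QLI anticorrelates with CAI across a usage-bias gradient", {
  trna <- extdata_trna(); map <- extdata_map(trna)
  genes <- make_random_gene_set(60, c(120, 240),
                                bias = seq(0, 1, length.out = 60),
                                seed = 11, trna = trna, map = map)
  gsys <- lapply(genes, function(g)
    list(name = g$name, species = g$species, copies = 1L))
  sd <- supply_demand(build_system(gsys, trna, alpha = 0.1))
  top <- genes[order(-vapply(genes, `[[`, numeric(1), "bias"))[1:8]]
  wt <- suppressMessages(rscu_weights(table(unlist(lapply(top, `[[`, "codons")))))
  qlis <- vapply(genes, function(g) qli(g$species, sd$Q), numeric(1))
  cais <- vapply(genes, function(g) cai(g$codons, wt), numeric(1))
  expect_lt(cor(qlis, cais, method = "spearman"), -0.5)
})
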