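test_that("initial state is empty lattices with fully charged pools", {
  sys <- toy_system(T_counts = c(5L, 7L), V = c(5, 5))
  st <- init_state(sys)
  expect_identical(sum(lengths(st$pos)), 0L)
  expect_identical(st$a, c(5L, 7L))
  expect_identical(st$b, c(0L, 0L))
  expect_true(all(st$a + st$b == sys$trna$T))
  expect_identical(st$t, 0)
})

test_that("the event catalogue implements exclusion, blocking and recharging", {
  sys <- toy_system(L = 20, copies = 3, w = 3, alpha = 0.5)
  st <- init_state(sys)
  ev <- enabled_events(st, sys)
  # empty lattices: one initiation event per lattice, nothing else
  expect_identical(sum(ev$type == "init"), 3L)
  expect_equal(sum(ev$rate), 3 * 0.5)
  # a single ribosome with clear road elongates at kappa * a
  st$pos[[1]] <- 5L
  ev <- enabled_events(st, sys)
  el <- ev[ev$type == "elong", ]
  expect_identical(nrow(el), 1L)
  sp <- sys$mrnas[[1]]$species[5]
  expect_equal(el$rate, sys$kappa * st$a[sp])
  # trailing ribosome exactly w behind is blocked
  st$pos[[1]] <- c(5L, 8L)
  ev <- enabled_events(st, sys)
  expect_identical(nrow(ev[ev$type == "elong" & ev$ribosome == 1, ]), 0L)
  # reader at a position <= w blocks initiation on that lattice
  st$pos[[1]] <- 3L
  ev <- enabled_events(st, sys)
  expect_identical(sum(ev$type == "init" & ev$lattice == 1), 0L)
  expect_identical(sum(ev$type == "init"), 2L)
  # no charged tRNA, no elongation; bare tRNAs open a recharge channel
  st$pos[[1]] <- 5L
  st$a[sp] <- 0L; st$b[sp] <- sys$trna$T[sp]
  ev <- enabled_events(st, sys)
  expect_identical(sum(ev$type == "elong"), 0L)
  rc <- ev[ev$type == "recharge" & ev$species == sp, ]
  b <- sys$trna$T[sp]
  expect_equal(rc$rate, sys$trna$V[sp] * b / (sys$trna$K[sp] + b))
  # termination at L with rate beta
  st <- init_state(sys)
  st$pos[[2]] <- 20L
  ev <- enabled_events(st, sys)
  expect_equal(ev$rate[ev$type == "term"], sys$mrnas[[1]]$beta)
})

test_that("single steps preserve conservation and book-keeping", {
  sys <- toy_system(L = 15, copies = 2, w = 3, alpha = 1)
  set.seed(99)
  st <- init_state(sys)
  Tc <- sys$trna$T
  for (i in 1:400) {
    res <- step_state(st, sys)
    st <- res$state
    expect_identical(st$a + st$b, as.integer(Tc))
    if (res$event$type == "elong") {
      expect_true(st$b[res$event$species] >= 1)
    }
  }
  # exclusion held throughout (spot-check the final configuration)
  expect_true(gaps_ok(st$pos, sys$w))
})

test_that("waiting times are exponential with the total rate", {
  # single enabled event: an empty 1-copy lattice only offers initiation
  sys <- toy_system(L = 12, copies = 1, w = 3, alpha = 2)
  st <- init_state(sys)
  set.seed(5)
  dts <- replicate(3000, step_state(st, sys)$dt)
  se <- sd(dts) / sqrt(length(dts))
  expect_lt(abs(mean(dts) - 1 / 2), 3 * se)
})

test_that("the engine reproduces the exact stationary law of a micro-CTMC", {
  oi <- make_oracle_instance("two_site")
  expect_identical(oi$exact$n_states, 8L)
  obs <- run_simulation(oi$system, burn_in = 100, measure = 4000, seed = 7,
                        track_states = TRUE)
  emp <- obs$state_time$time
  expect_lt(total_variation(emp / sum(emp), oi$exact$pi), 0.02)
  expect_lt(abs(obs$species$J - oi$exact$J), 3 * obs$species$J_se + 1e-9)
  # absorbing empty system: zero current, full charging
  oi0 <- make_oracle_instance("two_site_alpha0")
  expect_equal(oi0$exact$J, 0)
  obs0 <- run_simulation(oi0$system, burn_in = 5, measure = 50, seed = 1)
  expect_identical(obs0$species$J, 0)
  expect_equal(obs0$charging$c, 1)
})

test_that("R reference engine and compiled engine sample the same law", {
  oi <- make_oracle_instance("two_site")
  sys <- oi$system
  set.seed(31)
  st <- init_state(sys)
  acc <- numeric(0)
  # time-weighted state occupancy from the reference engine
  for (i in 1:6000) {
    key <- ribotraffic:::state_key_r(st$pos, st$a, FALSE)
    res <- step_state(st, sys)
    acc[key] <- if (is.na(acc[key])) res$dt else acc[key] + res$dt
    st <- res$state
  }
  expect_lt(total_variation(acc / sum(acc), oi$exact$pi), 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- toy_system(alpha = 0.8)
  o1 <- run_simulation(sys, burn_in = 20, measure = 60, seed = 123)
  o2 <- run_simulation(sys, burn_in = 20, measure = 60, seed = 123)
  expect_identical(o1$species, o2$species)
  expect_identical(o1$profiles, o2$profiles)
  expect_identical(o1$charging, o2$charging)
  o3 <- run_simulation(sys, burn_in = 20, measure = 60, seed = 124)
  expect_false(identical(o1$species$J, o3$species$J))
})

test_that("alpha = 0 gives an empty steady state", {
  sys <- toy_system(alpha = 0)
  obs <- run_simulation(sys, burn_in = 10, measure = 50, seed = 1)
  expect_identical(obs$species$J, 0)
  expect_true(all(obs$profiles$toy$reader_density == 0))
  expect_equal(obs$charging$c, rep(1, 2))
})

test_that("simulated LD current matches the exact small-system oracle", {
  oi <- make_oracle_instance("uniform_small")
  obs <- run_simulation(oi$system, burn_in = 150, measure = 2500, seed = 3)
  expect_lt(abs(obs$species$J - oi$exact$J), 3 * obs$species$J_se)
  # reader profile close to exact site-wise
  expect_lt(max(abs(obs$profiles[[1]]$reader_density -
                      oi$exact$reader_profile[[1]])), 0.02)
})

test_that("flux is conserved along the lattice", {
  sys <- toy_system(L = 30, copies = 4, w = 3, alpha = 0.4,
                    T_counts = c(60L, 60L), V = c(40, 40), kappa = 0.1)
  obs <- run_simulation(sys, burn_in = 100, measure = 1000, seed = 8)
  pr <- obs$profiles$toy
  J <- obs$species$J
  m <- sys$mrnas[[1]]$copies
  counts <- pr$hop_rate * obs$measure * m
  # every site's hop count within 3 Poisson SE of the mean current
  expect_true(all(abs(counts - J * obs$measure * m) <=
                    3 * sqrt(pmax(counts, 1)) + 3))
})

test_that("infinite-recharge mode matches a very fast recharging system", {
  sys <- toy_system(L = 40, copies = 4, w = 3, alpha = 0.6,
                    T_counts = c(80L, 40L), V = c(30, 15), kappa = 0.1)
  fixed <- run_simulation(sys, burn_in = 100, measure = 800, seed = 21,
                          fixed_rates = TRUE)
  sys_big <- sys
  sys_big$trna$V <- sys$trna$V * 1e6
  bigV <- run_simulation(sys_big, burn_in = 100, measure = 800, seed = 22)
  expect_gt(min(bigV$charging$c), 0.999)
  se <- sqrt(fixed$species$J_se^2 + bigV$species$J_se^2)
  expect_lt(abs(fixed$species$J - bigV$species$J), 3 * se)
})

test_that("conservation a_i + b_i = T_i holds at the end of any run", {
  sys <- toy_system(alpha = 1.5, V = c(3, 1))  # slow recharging: pools swing
  obs <- run_simulation(sys, burn_in = 50, measure = 200, seed = 6)
  expect_identical(obs$final$a + obs$final$b, as.integer(sys$trna$T))
  expect_true(gaps_ok(obs$final$pos, sys$w))
})
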