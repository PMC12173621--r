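test_that("network energy evaluates its eight terms correctly", {
  w0 <- rep(0, 8); ws0 <- rep(0, 8)
  expect_equal(cann_energy(w0, ws0, c(3, 3.2), c(3, 3.1)), c(0, 0))

  # term 1 alone is a neo-Hookean energy with c1 = 2 w1 w1*
  w <- w0; ws <- ws0; w[1] <- 1; ws[1] <- 0.5
  expect_equal(cann_energy(w, ws, 4, 3), 0.5)
  set.seed(51)
  l1 <- runif(10, 1, 1.2); l2 <- runif(10, 1, 1.2)
  a <- cann_stress(w, ws, l1, l2)
  b <- nh_stress(2 * 1 * 0.5, l1, l2)
  expect_equal(a$P11, b$P11, tolerance = 1e-12)

  # exponential term closed form: e - 1 at I1 = 4
  w <- w0; ws <- ws0; w[2] <- 1; ws[2] <- 1
  expect_equal(cann_energy(w, ws, 4, 3), exp(1) - 1)

  # reference state is always energy free
  set.seed(52)
  expect_equal(cann_energy(runif(8), runif(8), 3, 3), 0)

  expect_error(cann_energy(c(-1, rep(0, 7)), ws0, 3, 3), "non-negative")
  expect_error(cann_energy(rep(1, 8), rep(60, 8), 13, 13), "overflow")
})

test_that("terms {1, 5} embed the Mooney-Rivlin model exactly", {
  set.seed(53)
  l1 <- runif(20, 1, 1.25); l2 <- runif(20, 1, 1.25)
  w <- rep(0, 8); ws <- rep(0, 8)
  w[1] <- 3.1; ws[1] <- 2.0     # c1 = 2 w1 w1* = 12.4
  w[5] <- 1.7; ws[5] <- 0.9     # c2 = 2 w5 w5* = 3.06
  a <- cann_stress(w, ws, l1, l2)
  b <- mr_stress(2 * 3.1 * 2.0, 2 * 1.7 * 0.9, l1, l2)
  expect_equal(a$P11, b$P11, tolerance = 1e-12)
  expect_equal(a$P22, b$P22, tolerance = 1e-12)
})

test_that("network stresses match the finite-difference oracle", {
  set.seed(54)
  for (rep in 1:5) {
    m <- energy_cann(runif(8) * 4, runif(8))
    l1 <- runif(1, 1, 1.25); l2 <- runif(1, 1, 1.25)
    a <- piola_biaxial(m, l1, l2)
    o <- fd_piola_oracle(m, l1, l2)
    scale <- max(abs(c(o$P11, o$P22)), 1e-3)
    expect_lt(abs(a$P11 - o$P11), 1e-6 * scale)
    expect_lt(abs(a$P22 - o$P22), 1e-6 * scale)
  }
})

test_that("energy is non-negative over the tested stretch range for
           non-negative weights", {
  set.seed(55)
  grid <- expand.grid(l1 = seq(1, 1.25, length.out = 8),
                      l2 = seq(1, 1.25, length.out = 8))
  inv <- invariants(grid$l1, grid$l2)
  for (rep in 1:10) {
    psi <- cann_energy(runif(8) * 5, runif(8) * 2, inv$I1, inv$I2)
    expect_true(all(psi >= -1e-12))
  }
})

test_that("unpenalized training drives the loss down on clean two-term data", {
  w_true <- rep(0, 8); ws_true <- rep(0, 8)
  w_true[1] <- 6; ws_true[1] <- 8      # I1 linear
  w_true[2] <- 3; ws_true[2] <- 3      # I1 exponential
  d <- closed_form_dataset(0, 0)       # grid only; overwrite stresses
  states <- delimech:::paired_states(d)
  p <- cann_stress(w_true, ws_true, states$l1, states$l2)
  states$P11 <- p$P11; states$P22 <- p$P22

  ctl <- cann_control(seed = 2)
  fit <- train_cann(states, ctl, alpha = 0)
  expect_lt(fit$loss, 1e-3 * fit$trajectory[1])
  r2 <- goodness_of_fit(energy_cann(fit$w, fit$ws), states)
  expect_gt(r2$mean, 0.999)

  # overwhelming penalty drives every term below the activity threshold
  dead <- train_cann(states, cann_control(seed = 2, epochs = 3000),
                     alpha = 1e6)
  expect_length(delimech:::active_terms(dead$w, dead$ws, 1e-3), 0)
})

test_that("training on neo-Hookean data reproduces its stresses", {
  d <- closed_form_dataset(50)
  states <- delimech:::paired_states(d)
  fit <- train_cann(states, cann_control(seed = 4), alpha = 0)
  pred <- cann_stress(fit$w, fit$ws, states$l1, states$l2)
  truth <- nh_stress(50, states$l1, states$l2)
  # weights are not identifiable, predicted stresses are
  expect_lt(max(abs(pred$P11 - truth$P11)), 0.02 * max(truth$P11))
  expect_lt(max(abs(pred$P22 - truth$P22)), 0.02 * max(truth$P11))
})

test_that("discovery selects the generating Mooney-Rivlin pair on clean data", {
  d <- closed_form_dataset(30, 15, max_stretch = 1.25)
  disc <- discover_model(d, cann_control(seed = 6))
  expect_equal(disc$active, c(1L, 5L))
  expect_equal(disc$term_labels, c("I1 linear", "I2 linear"))
  expect_gt(disc$r2$mean, 0.99)
  # refit weights reproduce the generating coefficients as products
  expect_equal(2 * disc$w[1] * disc$ws[1], 30, tolerance = 0.05)
  expect_equal(2 * disc$w[5] * disc$ws[5], 15, tolerance = 0.05)
  expect_output(print(disc), "two-term")
})

test_that("discovery reports the active-term profile when no penalty yields
           two terms", {
  d <- closed_form_dataset(30, 15)
  expect_error(discover_model(d, cann_control(alpha_sweep = 1e7,
                                              epochs = 2000)),
               "profile")
})

test_that("the average number of active terms does not increase with the
           penalty", {
  d <- deli_meat_means("PD")
  ctl_lo <- function(s) cann_control(seed = s, epochs = 6000)
  n_lo <- n_hi <- numeric(3)
  for (s in 1:3) {
    lo <- train_cann(d, ctl_lo(s), alpha = 1e-3)
    hi <- train_cann(d, ctl_lo(s), alpha = 1)
    n_lo[s] <- length(delimech:::active_terms(lo$w, lo$ws, 1e-3))
    n_hi[s] <- length(delimech:::active_terms(hi$w, hi$ws, 1e-3))
  }
  expect_lte(mean(n_hi), mean(n_lo))
})

test_that("the term library admits 28 distinct two-term models", {
  expect_length(cann_terms(), 8)
  expect_equal(n_term_models(2), 28)
})
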