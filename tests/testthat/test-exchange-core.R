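# Bloch-McConnell core: rate matrices, CEST/CPMG propagation, closed-form
# cross-checks.

test_that("rate matrix columns sum to zero and stationary populations match", {
  m2 <- two_state_model(100, 0.11, 2)
  K2 <- build_rate_matrix(m2)
  expect_equal(colSums(K2), c(A = 0, B = 0), tolerance = 1e-12)
  # null-space eigenvector oracle: stationary distribution of K
  ev <- eigen(K2)
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  v <- v / sum(v)
  expect_equal(v, c(0.89, 0.11), tolerance = 1e-10)

  m3 <- three_state_model(104, 0.11, 2, 2600, 0.05, 1.5)
  K3 <- build_rate_matrix(m3)
  expect_equal(colSums(K3), c(A = 0, B = 0, C = 0), tolerance = 1e-10)
  expect_equal(as.numeric(K3 %*% model_populations(m3)), rep(0, 3),
               tolerance = 1e-10)
  # linear topology: no direct B <-> C exchange
  expect_identical(K3["B", "C"], 0)
  expect_identical(K3["C", "B"], 0)
})

test_that("no exchange gives a zero rate matrix; reduction pads with zeros", {
  expect_true(all(build_rate_matrix(two_state_model(0, 0.1, 1)) == 0))
  m2 <- two_state_model(104, 0.11, 2)
  m3 <- three_state_model(104, 0.11, 2, 0, 0, 0)
  K3 <- build_rate_matrix(m3)
  expect_equal(unname(K3[1:2, 1:2]), unname(build_rate_matrix(m2)))
  expect_true(all(K3[3, ] == 0) && all(K3[, 3] == 0))
})

test_that("model constructors reject invalid fields by name", {
  expect_error(two_state_model(-1, 0.1, 1), "kex")
  expect_error(two_state_model(100, 0.6, 1), "pB")
  expect_error(two_state_model(100, 0.1, 1, R2A = -2), "R2A")
  expect_error(three_state_model(100, 0.3, 1, 100, 0.25, 1), "pB")
  expect_error(residue_probe(1, Inf), "omega_major")
  expect_error(cest_acquisition(0, 0.4, 1:10), "b1_field")
  expect_error(cest_acquisition(25, 0.4, c(1, 3, 2)), "offsets")
  expect_error(cpmg_acquisition(0.04, c(30)), "nu_cpmg")  # 1.2 blocks
})

test_that("CEST profile with pB = 0 is the single-state reference", {
  probe <- std_probe(); acq <- std_cest_acq()
  p0 <- simulate_cest(probe, two_state_model(0, 0, 0, R1 = 1.2, R2A = 10), acq)
  expect_true(all(p0$intensity >= -1 & p0$intensity <= 1))
  # one dip, centered at omega_A
  expect_equal(acq$offsets[which.min(p0$intensity)], 118, tolerance = 0.21)
  # exchange-free two-state equals exchange-free reference exactly
  pB0 <- simulate_cest(probe, two_state_model(500, 0, 2, R1 = 1.2, R2A = 10), acq)
  expect_equal(pB0$intensity, p0$intensity, tolerance = 1e-12)
})

test_that("far off-resonance CEST tends to exp(-R1 t_sat)", {
  probe <- std_probe()
  acq <- cest_acquisition(25, 0.4, c(-2000, -1000, 1000, 2000) + 118)
  p <- simulate_cest(probe, group1_model(), acq)
  expect_equal(p$intensity, rep(exp(-1.2 * 0.4), 4), tolerance = 1e-3)
})

test_that("slow-exchange CEST shows a resolvable minor dip at omega_A + dW", {
  probe <- std_probe(); acq <- std_cest_acq()
  p <- simulate_cest(probe, group1_model(dW = 2), acq)
  i_minor <- which(acq$offsets == 120)
  # local minimum at the minor-state position, well below its neighbours
  expect_lt(p$intensity[i_minor], p$intensity[i_minor - 3])
  expect_lt(p$intensity[i_minor], p$intensity[i_minor + 3])
  expect_lt(p$intensity[i_minor], 0.5 * exp(-1.2 * 0.4))
})

test_that("matrix-exponential CEST matches a brute-force ODE integration", {
  skip_if_not_installed("deSolve")
  probe <- std_probe()
  model <- group1_model(dW = 2)
  acq <- cest_acquisition(25, 0.4, c(116, 118, 120))
  # independent generator assembled in R from the model definition
  K <- build_rate_matrix(model)
  w1 <- 2 * pi * 25
  shifts <- 118 + c(0, model$dW)
  r2 <- c(model$R2A, model$R2B)
  for (k in seq_along(acq$offsets)) {
    L <- matrix(0, 6, 6)
    for (s in 1:2) {
      dw <- 2 * pi * probe$nucleus_freq * (shifts[s] - acq$offsets[k])
      i <- 3 * (s - 1) + 1
      L[i, i] <- -r2[s]; L[i, i + 1] <- -dw
      L[i + 1, i] <- dw; L[i + 1, i + 1] <- -r2[s]; L[i + 1, i + 2] <- -w1
      L[i + 2, i + 1] <- w1; L[i + 2, i + 2] <- -model$R1
    }
    L <- L + kronecker(K, diag(3))
    m0 <- c(0, 0, 0.89, 0, 0, 0.11)
    sol <- deSolve::lsoda(m0, c(0, 0.4), function(t, y, p) list(L %*% y),
                          rtol = 1e-11, atol = 1e-13, maxsteps = 1e5)
    ode_val <- unname(sol[2, 4]) / 0.89
    sim <- simulate_cest(probe, model, acq)$intensity[k]
    expect_equal(sim, ode_val, tolerance = 1e-6)
  }
})

test_that("CPMG dispersion is flat at R2 when dW = 0", {
  p <- simulate_cpmg(std_probe(), two_state_model(500, 0.1, 0, R2A = 12),
                     std_cpmg_acq())
  expect_equal(as.numeric(p$r2eff), rep(12, 14), tolerance = 1e-10)
})

test_that("low-nu Rex approaches the fast-exchange limit pA pB dW^2 / kex", {
  probe <- std_probe()
  model <- two_state_model(6000, 0.05, 0.8, R2A = 10)
  acq <- std_cpmg_acq()
  dw <- 2 * pi * probe$nucleus_freq * 0.8
  rex_limit <- 0.95 * 0.05 * dw^2 / 6000
  rex_sim <- simulate_cpmg(probe, model, acq)$r2eff[1] - 10
  expect_lt(abs(rex_sim - rex_limit) / rex_limit, 0.05)
})

test_that("closed form matches the numerical propagator over 100 random draws", {
  probe <- std_probe(); acq <- std_cpmg_acq()
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    md <- two_state_model(kex = exp(runif(1, log(100), log(8000))),
                          pB = runif(1, 0.01, 0.2),
                          dW = runif(1, 0.5, 4), R2A = runif(1, 8, 20))
    d <- max(abs(simulate_cpmg(probe, md, acq)$r2eff -
                   carver_richards(md, acq, probe)))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-2)
})

test_that("classical Carver-Richards branch tracks the exact form in fast exchange", {
  probe <- std_probe(); acq <- std_cpmg_acq()
  md <- two_state_model(4000, 0.03, 1.5, R2A = 10)
  expect_equal(carver_richards(md, acq, probe, exact = FALSE),
               carver_richards(md, acq, probe), tolerance = 0.02)
  # degenerate cases are flat
  expect_equal(carver_richards(two_state_model(0, 0.1, 2, R2A = 9), acq, probe),
               rep(9, 14))
  expect_equal(carver_richards(two_state_model(500, 0, 2, R2A = 9), acq, probe),
               rep(9, 14))
  # exchange fully quenched: flat at the population-averaged R2
  mq <- two_state_model(5e6, 0.2, 1, R2A = 10, R2B = 20)
  expect_equal(carver_richards(mq, acq, probe), rep(0.8 * 10 + 0.2 * 20, 14),
               tolerance = 0.05)
  expect_error(carver_richards(three_state_model(100, .1, 1, 0, 0, 0), acq),
               "two-state")
})

test_that("Rex from the closed form is non-increasing with nu", {
  probe <- std_probe(); acq <- std_cpmg_acq()
  set.seed(7)
  for (i in 1:20) {
    md <- two_state_model(exp(runif(1, log(500), log(8000))),
                          runif(1, 0.01, 0.15), runif(1, 0.5, 3),
                          R2A = 12)
    r <- carver_richards(md, acq, probe)
    expect_true(all(diff(r) <= 1e-6))
  }
})

test_that("three-state generator with kex_AC = 0 matches the two-state observables", {
  probe <- std_probe()
  m2 <- group1_model(dW = 2)
  m3 <- three_state_model(104, 0.11, 2, 0, 0, 0, R1 = 1.2, R2 = 10)
  expect_identical(simulate_cest(probe, m3, std_cest_acq())$intensity,
                   simulate_cest(probe, m2, std_cest_acq())$intensity)
  expect_identical(as.numeric(simulate_cpmg(probe, m3, std_cpmg_acq())$r2eff),
                   as.numeric(simulate_cpmg(probe, m2, std_cpmg_acq())$r2eff))
})
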