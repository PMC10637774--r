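test_that("simulated sensorgrams honour the phase schedule and limits", {
  sch <- bli_schedule()
  expect_equal(sch$baseline, 120)
  expect_equal(sch$association, 180)
  expect_equal(sch$dissociation, 180)
  sg <- simulate_sensorgram(1e5, 1e-3, 2, conc = 1e-8)
  expect_equal(unique(sg$phase), c("baseline", "association", "dissociation"))
  expect_true(all(is.finite(sg$response)))
  # no analyte: flat zero before drift/noise
  sg0 <- simulate_sensorgram(1e5, 1e-3, 2, conc = 0)
  expect_true(all(sg0$response == 0))
  # no off-rate: dissociation is constant
  sgk <- simulate_sensorgram(1e5, 0, 2, conc = 1e-8)
  dis <- sgk$response[sgk$phase == "dissociation"]
  expect_equal(diff(range(dis)), 0)
  expect_error(simulate_sensorgram(-1, 1e-3, 2, 1e-8), "nonnegative")
})

test_that("association approaches the closed-form equilibrium plateau", {
  kon <- 1e5; koff <- 1e-3; Rmax <- 2
  Kd <- koff / kon
  for (conc in c(Kd / 2, Kd, 4 * Kd)) {
    sch <- bli_schedule(association = 2e5, dissociation = 10, dt = 50)
    sg <- simulate_sensorgram(kon, koff, Rmax, conc, schedule = sch)
    plateau <- max(sg$response[sg$phase == "association"])
    expect_equal(plateau, Rmax * conc / (conc + Kd), tolerance = 1e-8)
  }
})

test_that("the exponential solution solves the binding ODE", {
  kon <- 2e5; koff <- 5e-3; Rmax <- 1.5; conc <- 4e-8
  sch <- bli_schedule(baseline = 0, association = 180, dissociation = 180,
                      dt = 1)
  sg <- simulate_sensorgram(kon, koff, Rmax, conc, schedule = sch)
  # numerically integrate dR/dt = kon C (Rmax - R) - koff R through both
  # phases (C = 0 after association)
  rhs <- function(t, y, p) {
    C <- if (t < 180) conc else 0
    list(kon * C * (Rmax - y[1]) - koff * y[1])
  }
  num <- deSolve::ode(c(R = 0), seq(0, 360, by = 1), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(sg$response, unname(num[, "R"]), tolerance = 1e-8)
})

test_that("double referencing is the exact four-sensor algebra", {
  sch <- bli_schedule(dt = 1)
  mk <- function(vals, role) fragforge:::new_sensorgram(
    seq(0, 480, by = 1), vals, 1e-8, role, sch)
  n <- length(seq(0, 480, by = 1))
  a <- mk(rnorm(n), "a"); b <- mk(rnorm(n), "b")
  c_ <- mk(rnorm(n), "c"); d <- mk(rnorm(n), "d")
  ref <- double_reference(a, b, c_, d)
  expect_equal(ref$response,
               (a$response - c_$response) - (b$response - d$response))
  # b = c = d = 0 returns a unchanged
  z <- rep(0, n)
  expect_equal(double_reference(a, mk(z, "b"), mk(z, "c"), mk(z, "d"))$response,
               a$response)
  # common additive drift cancels exactly
  g <- 0.02 * seq(0, 480, by = 1)
  ref2 <- double_reference(mk(a$response + g, "a"), mk(b$response + g, "b"),
                           mk(c_$response + g, "c"), mk(d$response + g, "d"))
  expect_equal(ref2$response, ref$response)
  # a = b, c = d: specificity null
  ref3 <- double_reference(a, mk(a$response, "b"), c_, mk(c_$response, "d"))
  expect_equal(ref3$response, rep(0, n))
  # role and grid violations are errors
  expect_error(double_reference(b, a, c_, d), "roles")
  short <- fragforge:::new_sensorgram(seq(0, 479, by = 1),
                                      rnorm(480), 1e-8, "b", sch)
  expect_error(double_reference(a, short, c_, d), "time grid")
})

test_that("noiseless global fits recover rates within 1% across the Kd range", {
  for (Kd in c(1e-11, 1e-9, 1e-8)) {
    kon <- 1e6; koff <- Kd * kon
    plate <- generate_sensorgram_plate(kon, koff, Rmax = 2, seed = 3)
    fit <- fit_kinetics(plate$referenced)
    expect_true(fit$converged)
    expect_equal(fit$kon, kon, tolerance = 0.01)
    expect_equal(fit$koff, koff, tolerance = 0.01)
    expect_equal(fit$Kd, koff / kon, tolerance = 1e-12)
  }
})

test_that("the kinetic Kd agrees with the equilibrium-only route", {
  kon <- 1e5; koff <- 1e-3
  sch <- bli_schedule(association = 3600, dissociation = 120, dt = 5)
  plate <- generate_sensorgram_plate(kon, koff, 2, schedule = sch, seed = 6)
  kin <- fit_kinetics(plate$referenced)
  eq <- fit_equilibrium(plate$referenced)
  expect_equal(eq$Kd, kin$Kd, tolerance = 0.05)
})

test_that("fitting demands at least three concentrations", {
  plate <- generate_sensorgram_plate(1e5, 1e-3, 2,
                                     concentrations = c(1e-8, 2e-8),
                                     seed = 2)
  expect_error(fit_kinetics(plate$referenced), ">= 3")
})

test_that("plates are seed-reproducible and round-trip through CSV", {
  p1 <- generate_sensorgram_plate(1e5, 1e-3, 2, noise_sd = 0.05,
                                  drift_rate = 0.002,
                                  nonspecific_rate = 50, seed = 9)
  p2 <- generate_sensorgram_plate(1e5, 1e-3, 2, noise_sd = 0.05,
                                  drift_rate = 0.002,
                                  nonspecific_rate = 50, seed = 9)
  expect_identical(p1$referenced, p2$referenced)
  d <- tempfile("plate")
  write_plate_csv(p1, d)
  p3 <- read_plate_csv(d)
  expect_equal(p3$referenced[[1]]$response, p1$referenced[[1]]$response,
               tolerance = 1e-12)
  expect_equal(p3$concentrations, p1$concentrations)
})
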