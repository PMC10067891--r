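sphere <- function(x) sum(x^2)

small_ctrl <- function(...) {
  mfos_control(pop_size = 10, iterations = 40, seed = 1, ...)
}

test_that("initialization draws the population inside the box", {
  st <- mfos_init(sphere, lower = -100, upper = 100, v = 10,
                  control = mfos_control(seed = 1))
  expect_equal(dim(st$Q), c(50, 10))
  expect_true(all(st$Q >= -100 & st$Q <= 100))
  expect_equal(st$Qf, apply(st$Q, 1, sphere))
  # flames are the sorted population
  expect_equal(st$Rf, sort(st$Qf))
  # constant objective: every fitness identical
  st2 <- mfos_init(function(x) 7, -1, 1, v = 3,
                   control = mfos_control(pop_size = 5, seed = 2))
  expect_true(all(st2$Qf == 7))
  # determinism: same seed, same state
  st3 <- mfos_init(sphere, -100, 100, v = 10,
                   control = mfos_control(seed = 1))
  expect_identical(st$Q, st3$Q)
})

test_that("spiral move contracts onto the flame and obeys its closed form", {
  flame <- c(1, 2); moth <- c(0, 0)
  # moth on the flame stays on the flame for any t
  expect_equal(spiral_move(flame, flame, t = 0.3), flame)
  # t = -1, b = 1: displacement magnitude D * exp(-1)
  got <- spiral_move(moth, flame, t = -1, b = 1)
  D <- abs(flame - moth)
  expect_equal(abs(got - flame), D * exp(-1))
  # |new - flame| <= D * exp(b t) for random draws
  set.seed(4)
  for (rep in 1:50) {
    m <- runif(3, -5, 5); f <- runif(3, -5, 5); t <- runif(1, -2, 1)
    new <- spiral_move(m, f, t)
    expect_true(all(abs(new - f) <= abs(f - m) * exp(t) + 1e-12))
  }
})

test_that("Levy steps use the Mantegna constant and heavy tails", {
  # closed-form sigma_u at beta = 1.5
  s <- (gamma(2.5) * sin(0.75 * pi) / (gamma(1.25) * 1.5 * 2^0.25))^(1 / 1.5)
  expect_equal(dnacodes:::levy_sigma_u(1.5), s, tolerance = 1e-12)
  expect_equal(round(s, 4), 0.6966)
  expect_error(levy_step(5, beta = 0.9), "beta")
  expect_error(levy_step(5, beta = 2.5), "beta")
  set.seed(8)
  steps <- replicate(20000, levy_step(1, 1.5))
  # heavy tail: tail fraction beyond k decays roughly like k^(-1.5),
  # so the empirical tail exponent fitted between k=2 and k=20 should
  # be near 1.5 (far from the Gaussian's super-polynomial decay)
  p2 <- mean(abs(steps) > 2); p20 <- mean(abs(steps) > 20)
  slope <- -(log(p20) - log(p2)) / (log(20) - log(2))
  expect_gt(slope, 1.0)
  expect_lt(slope, 2.0)
  # beta = 2 collapses to finite-variance (Gaussian-like) steps
  set.seed(9)
  g <- replicate(5000, levy_step(1, 2))
  expect_lt(mean(abs(g) > 20), 1e-3)
})

test_that("opposition point is the box reflection and an involution", {
  expect_equal(obl_opposite(0.3, 0, 1), 0.7)
  mid <- (2 + 10) / 2
  expect_equal(obl_opposite(mid, 2, 10), mid)
  set.seed(10)
  x <- runif(6, -3, 5)
  expect_equal(obl_opposite(obl_opposite(x, -3, 5), -3, 5), x)
})

test_that("iteration preserves elitism and box bounds", {
  st <- mfos_init(sphere, -100, 100, v = 5,
                  control = mfos_control(pop_size = 15, iterations = 60,
                                         seed = 3))
  prev <- st$best_value
  for (i in 1:60) {
    st <- mfos_step(st)
    expect_lte(st$best_value, prev)
    prev <- st$best_value
    expect_true(all(st$Q >= -100 & st$Q <= 100))
  }
  expect_equal(st$trace, cummin(st$trace))
})

test_that("full runs are deterministic under a seed and variant flags work", {
  a <- mfos(sphere, -10, 10, v = 4, control = small_ctrl())
  b <- mfos(sphere, -10, 10, v = 4, control = small_ctrl())
  expect_identical(a$par, b$par)
  expect_identical(a$trace, b$trace)
  # plain-MFO switch disables all three strategies
  ctrl <- mfos_control(variant = "mfo")
  expect_false(ctrl$use_levy || ctrl$use_obl || ctrl$use_crossover)
  m1 <- mfos(sphere, -10, 10, v = 4,
             control = mfos_control(pop_size = 10, iterations = 30,
                                    seed = 5, variant = "mfo"))
  m2 <- mfos(sphere, -10, 10, v = 4,
             control = mfos_control(pop_size = 10, iterations = 30,
                                    seed = 5, use_levy = FALSE,
                                    use_obl = FALSE, use_crossover = FALSE))
  expect_identical(m1$par, m2$par)
})

test_that("returned value is never below the true optimum and trace has length T", {
  fit <- mfos(sphere, -5, 5, v = 3, control = small_ctrl())
  expect_gte(fit$value, 0)
  expect_length(fit$trace, 40)
  expect_equal(fit$value, min(fit$trace))
})

test_that("evaluation counts stay within the per-iteration budget", {
  ctrl <- mfos_control(pop_size = 12, iterations = 25, seed = 6)
  fit <- mfos(sphere, -5, 5, v = 3, control = ctrl)
  # N initial + per iteration: N spiral + <= N OBL + <= 1 crossover
  expect_lte(fit$n_evals, 12 + 25 * (2 * 12 + 1))
  expect_gte(fit$n_evals, 12 + 25 * 12)
})

test_that("optimizer converges on a low-dimensional sphere", {
  finals <- vapply(1:5, function(s) {
    mfos(sphere, -100, 100, v = 2,
         control = mfos_control(pop_size = 20, iterations = 150,
                                seed = s))$value
  }, 0)
  expect_true(all(finals < 1e-6))
})

test_that("fit object methods print, summarize, and expose coefficients", {
  fit <- mfos(sphere, -5, 5, v = 2, control = small_ctrl())
  expect_output(print(fit), "MFOS run")
  expect_output(print(summary(fit)), "best-so-far")
  expect_length(coef(fit), 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("control validation rejects bad settings", {
  expect_error(mfos_control(pop_size = 1), "pop_size")
  expect_error(mfos_control(crossover_prob = 1.2), "probabilities")
  expect_error(mfos_control(levy_beta = 1), "levy_beta")
  expect_error(mfos_init(sphere, 5, 5, v = 2), "lower < upper")
})
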