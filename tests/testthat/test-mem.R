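test_that("state_energy matches the displayed formula and its symmetries", {
  # zero parameters: every pattern has zero energy
  p0 <- mem_params(h = rep(0, 4))
  expect_equal(state_energy(state_patterns(4), p0), rep(0, 16))

  # N = 2 hand computation: E = -(h1*s1 + h2*s2) - J12*s1*s2
  p <- mem_params(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(state_energy(c(1, 1), p), -0.5)

  # global spin flip leaves energy unchanged when h = 0
  pj <- random_params(5, seed = 11)
  pj$h <- rep(0, 5)
  S <- state_patterns(5)
  expect_equal(state_energy(S, pj), state_energy(-S, pj))

  # agreement with a loop-based oracle on random parameters
  pr <- random_params(5, seed = 3)
  expect_equal(
    state_energy(S, pr),
    apply(S, 1, oracle_energy, h = pr$h, J = pr$J)
  )

  expect_error(state_energy(c(1, 0), p), "\\+1/-1")
})

test_that("exact_distribution is the normalized Boltzmann law", {
  # zero parameters at N = 9: uniform over all 512 states
  tab <- exact_distribution(mem_params(h = rep(0, 9)))
  expect_equal(tab$prob, rep(1 / 512, 512))

  # probabilities normalize and moments match brute-force enumeration
  for (s in 1:5) {
    pr <- random_params(4, seed = s)
    tab <- exact_distribution(pr)
    expect_lt(abs(sum(tab$prob) - 1), 1e-12)
    orc <- oracle_moments(pr$h, pr$J)
    expect_equal(tab$prob, orc$prob)
    m <- exact_moments(pr)
    expect_equal(m$first, orc$first, tolerance = 1e-12)
    expect_equal(m$second, orc$second, tolerance = 1e-12)
  }

  expect_error(exact_distribution(mem_params(h = rep(0, 17))), "enumeration")
})

test_that("-log P and E agree up to the common normalizing shift", {
  for (s in 1:5) {
    pr <- random_params(6, seed = 100 + s)
    tab <- exact_distribution(pr)
    nlp <- -log(tab$prob)
    expect_lt(
      max(abs((nlp - min(nlp)) - (tab$energy - min(tab$energy)))), 1e-10
    )
  }
})

test_that("empirical moments are the time averages of activities and products", {
  # identical all-ones rows
  m <- empirical_moments(matrix(1, 5, 3))
  expect_equal(m$first, rep(1, 3))
  expect_equal(m$second, matrix(1, 3, 3))

  # hand-computed two-row case
  m2 <- empirical_moments(rbind(c(1, -1), c(-1, 1)))
  expect_equal(m2$first, c(0, 0))
  expect_equal(m2$second[1, 2], -1)

  # unit diagonal always (sigma_i^2 = 1)
  X <- as.matrix(sample_mem_series(random_params(4, seed = 9), 200, seed = 1))
  expect_equal(diag(empirical_moments(X)$second), rep(1, 4))

  expect_error(empirical_moments(matrix(numeric(0), 0, 3)), "time point")
})

test_that("pairwise fit recovers parameters from exact moments", {
  # no constraints beyond uniformity: maximum entropy is h = J = 0
  flat <- new_moments_for_test(first = rep(0, 4), second = diag(4))
  fit0 <- fit_pairwise(flat)
  expect_lt(max(abs(fit0$h), abs(fit0$J)), 1e-4)

  # recovery oracle: exact moments of known parameters
  for (s in 1:3) {
    truth <- random_params(6, seed = 40 + s)
    fit <- fit_pairwise(exact_moments(truth), tol = 1e-5)
    expect_lt(max(abs(fit$h - truth$h), abs(fit$J - truth$J)), 1e-4)
  }
})

test_that("converged fits satisfy the moment-matching stopping condition", {
  truth <- random_params(6, seed = 77)
  target <- exact_moments(truth)
  fit <- fit_pairwise(target, tol = 1e-5)
  got <- exact_moments(fit)
  expect_lt(max(abs(got$first - target$first)), 1e-5)
  expect_lt(max(abs(got$second - target$second)), 1e-5)
  expect_true(attr(fit, "converged"))
  expect_error(
    fit_pairwise(target, max_iter = 3),
    class = "elscape_fit_nonconvergence"
  )
})

test_that("parameter error shrinks as the sample grows", {
  truth <- random_params(7, seed = 5, range = 0.4)
  err <- sapply(c(1e3, 1e4, 1e5), function(T) {
    fit <- fit_pairwise(empirical_moments(sample_mem_series(truth, T, seed = 21)))
    stats::median(abs(c(fit$h - truth$h, fit$J[upper.tri(fit$J)] -
                          truth$J[upper.tri(truth$J)])))
  })
  expect_true(all(diff(err) < 0))
})

test_that("independent fit is the closed-form atanh of the means", {
  m0 <- new_moments_for_test(first = rep(0, 3), second = diag(3))
  expect_equal(fit_independent(m0)$h, rep(0, 3))

  m5 <- new_moments_for_test(first = c(0.5, -0.25), second = diag(2))
  ind <- fit_independent(m5)
  expect_equal(ind$h, atanh(c(0.5, -0.25)))
  # the marginal P(sigma = +1) = e^h / (e^h + e^-h) reproduces (1 + m)/2
  expect_equal(exp(ind$h[1]) / (exp(ind$h[1]) + exp(-ind$h[1])), 0.75)

  # independent model factorizes: <s_i s_j>_m = <s_i>_m <s_j>_m
  mm <- exact_moments(ind)
  expect_equal(mm$second[1, 2], mm$first[1] * mm$first[2], tolerance = 1e-12)
})

test_that("r_D is the KL-divergence proportion and the pairwise model nests", {
  # strong couplings, large sample: pairwise model removes >90% of the misfit
  strong <- make_regime_params("polarized", seed = 1)
  X <- as.matrix(sample_mem_series(strong, 1e5, seed = 2))
  mom <- empirical_moments(X)
  acc <- fit_accuracy(X, fit_pairwise(mom), fit_independent(mom))
  expect_gt(acc$r_d, 0.9)
  expect_false(acc$undefined)

  # D2 <= D1 and r_D in [0, 1] across random instances
  for (s in 1:4) {
    truth <- random_params(4, seed = 200 + s)
    X <- as.matrix(sample_mem_series(truth, 5000, seed = s))
    mom <- empirical_moments(X)
    acc <- fit_accuracy(X, fit_pairwise(mom), fit_independent(mom))
    expect_lte(acc$d2, acc$d1 + 1e-10)
    expect_gte(acc$r_d, 0)
    expect_lte(acc$r_d, 1)
  }

  # a series whose empirical law is exactly the independent fit: D1 = 0
  X0 <- oracle_patterns(2)
  mom0 <- empirical_moments(X0)
  expect_message(
    acc0 <- fit_accuracy(X0, fit_pairwise(mom0), fit_independent(mom0)),
    "undefined"
  )
  expect_true(acc0$undefined)
  expect_true(is.na(acc0$r_d))
})
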