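make_theta <- function(spec, phi = c(N = .7, L = .7, H = .7),
                       psi = psi_from_success(.8, .8), p = .5,
                       gamma = .9, pi = .6) {
  real_to_theta(spec, list(strata = list(all = list(phi = phi, psi = psi)),
                           p = p, gamma = gamma, pi = pi))
}

test_that("single-capture and two-occasion histories match hand chains", {
  spec <- build_spec(1)
  th <- make_theta(spec)
  # first capture at the final occasion, event 2: only the initial-state term
  expect_equal(history_loglik(c(0, 0, 2), spec, th), log(0.6 / 2))
  expect_equal(history_loglik(c(0, 0, 1), spec, th), log(0.4))
  # two occasions, events (2, 2): pi/2 * phi_L * psi_LL * p
  expect_equal(history_loglik(c(2, 2), spec, th),
               log(0.3 * 0.7 * 0.4 * 0.5))
  # not captured at the second occasion: survive-and-miss plus die
  expect_equal(history_loglik(c(2, 0), spec, th),
               log(0.3 * (0.7 * 0.5 + 0.3)))
})

test_that("likelihood validates its inputs", {
  spec <- build_spec(1)
  th <- make_theta(spec)
  expect_error(history_loglik(integer(0), spec, th), "at least one capture")
  expect_error(history_loglik(c(0, 0, 0), spec, th), "at least one capture")
  expect_error(encounter_histories(matrix(c(4L, 1L), 1), measure = "size"),
               "alphabet")
  hm <- encounter_histories(matrix(c(2L, 4L), 1), measure = "mass")
  expect_error(total_loglik(hm, spec, th), "measure")
})

test_that("forward algorithm equals exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    measure <- sample(c("size", "mass"), 1)
    spec <- build_spec(sample(1:12, 1), measure = measure)
    theta <- rnorm(count_parameters(spec), sd = 1.5)
    T <- sample(2:6, 1)
    hist <- random_history(T, measure)
    pp <- real_params(spec, theta)
    expect_equal(history_loglik(hist, spec, theta),
                 oracle_history_loglik(hist, pp$phi, pp$psi, pp$p, pp$gamma,
                                       pp$pi, measure),
                 tolerance = 1e-10)
  }
})

test_that("total log-likelihood is additive over histories", {
  spec <- build_spec(6)
  th <- make_theta(spec, phi = c(N = .55, L = .65, H = .75),
                   psi = psi_from_success(.8, .55))
  ev <- rbind(c(2L, 0L, 3L, 0L), c(0L, 1L, 1L, 2L))
  h1 <- encounter_histories(ev, measure = "size")
  single <- encounter_histories(ev[1, , drop = FALSE], measure = "size")
  expect_equal(total_loglik(single, spec, th),
               history_loglik(ev[1, ], spec, th))
  doubled <- encounter_histories(ev[c(1, 2, 1, 2), ], measure = "size")
  expect_equal(total_loglik(doubled, spec, th), 2 * total_loglik(h1, spec, th))
  # weights reproduce duplication exactly
  expect_equal(total_loglik(h1, spec, th, weights = c(2, 2)),
               total_loglik(doubled, spec, th))
})

test_that("appending an unobserved occasion strictly decreases likelihood when p > 0 and survival < 1", {
  spec <- build_spec(1)
  th <- make_theta(spec)
  base <- history_loglik(c(2, 2), spec, th)
  padded <- history_loglik(c(2, 2, 0), spec, th)
  expect_lt(padded, base)
  # with p -> 0 and phi -> 1 the padding factor tends to 1
  th_sure <- make_theta(spec, phi = c(N = 1 - 1e-12, L = 1 - 1e-12, H = 1 - 1e-12),
                        p = 1e-12)
  expect_equal(history_loglik(c(2, 2, 0), spec, th_sure),
               history_loglik(c(2, 2), spec, th_sure), tolerance = 1e-9)
})

test_that("with certain assignment the mass model reduces to the size model", {
  spec_s <- build_spec(9, measure = "size")
  spec_m <- build_spec(9, measure = "mass")
  phi <- c(N = .5, L = .6, H = .7)
  psi <- psi_from_success(.75, .5)
  th_s <- real_to_theta(spec_s, list(strata = list(all = list(phi = phi, psi = psi)),
                                     p = .45, pi = .55))
  th_m <- real_to_theta(spec_m, list(strata = list(all = list(phi = phi, psi = psi)),
                                     p = .45, gamma = 1 - 1e-14, pi = .55))
  set.seed(5)
  for (rep in 1:10) {
    hist <- random_history(6, "size")  # no event-4 codes
    expect_equal(history_loglik(hist, spec_m, th_m),
                 history_loglik(hist, spec_s, th_s), tolerance = 1e-8)
  }
})

test_that("stratified likelihoods route histories to their stratum", {
  spec <- build_spec(1, covariate = "sex")
  real <- list(strata = list(F = list(phi = c(N = .8, L = .8, H = .8),
                                      psi = psi_from_success(.7, .7)),
                             M = list(phi = c(N = .4, L = .4, H = .4),
                                      psi = psi_from_success(.7, .7))),
               p = c(F = .6, M = .3), pi = .5)
  th <- real_to_theta(spec, real)
  ev <- matrix(c(2L, 2L), 1)
  hF <- encounter_histories(ev, sex = "F", measure = "size")
  hM <- encounter_histories(ev, sex = "M", measure = "size")
  expect_equal(total_loglik(hF, spec, th), log(.25 * .8 * .35 * .6))
  expect_equal(total_loglik(hM, spec, th), log(.25 * .4 * .35 * .3))
  hU <- encounter_histories(ev, measure = "size")
  expect_error(total_loglik(hU, spec, th), "unsexed")
  spec_age <- build_spec(1, covariate = "age")
  expect_error(total_loglik(hU, spec_age, real_to_theta(spec_age, real)),
               "unknown-age")
})

test_that("age classes advance with occasions and cap at 4", {
  spec <- build_spec(3, covariate = "age")
  phis <- list(age1 = c(N = .9, L = .9, H = .9), age2 = c(N = .2, L = .2, H = .2),
               age3 = c(N = .5, L = .5, H = .5), age4 = c(N = .7, L = .7, H = .7))
  real <- list(strata = lapply(phis, function(ph)
    list(phi = ph, psi = psi_from_success(.8, .8))), p = .5, pi = .6)
  th <- real_to_theta(spec, real)
  # entry at class 3 and three occasions: first interval uses class 3
  # survival, the second uses class 4 (capped)
  h <- encounter_histories(matrix(c(2L, 2L, 2L), 1), age_entry = 3,
                           measure = "size")
  expect_equal(total_loglik(h, spec, th),
               log(.3 * (.5 * .4 * .5) * (.7 * .4 * .5)))
})
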