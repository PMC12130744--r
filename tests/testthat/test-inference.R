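sim_small <- function(n = 500, T = 8, seed = 1, ...) {
  simulate_histories(sim_config(
    n_individuals = n, n_occasions = T, seed = seed,
    phi = c(N = 0.55, L = 0.65, H = 0.75),
    psi = psi_from_success(sb = 0.8, n = 0.55),
    p_capture = 0.5, pi_sb = 0.6, ...))$histories
}

test_that("aic applies the definition", {
  expect_equal(aic(-100, 4), 208)
  expect_equal(aic(0, 1), 2)
  expect_error(aic(-10, 0), ">= 1")
})

test_that("select_best implements lowest AIC with the parsimony window", {
  tab <- data.frame(model = c("A", "B"), K = c(6, 5), aic = c(100, 101.5))
  expect_equal(select_best(tab)$chosen, "B")
  expect_equal(select_best(tab)$rule_applied, "fewest_params_within_2")
  tab2 <- data.frame(model = c("A", "B"), K = c(6, 5), aic = c(100, 103))
  expect_equal(select_best(tab2)$chosen, "A")
  expect_equal(select_best(tab2)$rule_applied, "lowest_aic")
  single <- data.frame(model = "M3", K = 6, aic = 50)
  expect_equal(select_best(single)$chosen, "M3")
  # K ties break by lower AIC; selection ignores supply order
  tab3 <- data.frame(model = c("M2", "M5"), K = c(5, 5), aic = c(100.5, 100))
  expect_equal(select_best(tab3)$chosen, "M5")
  expect_equal(select_best(tab3[2:1, ])$chosen, "M5")
  expect_error(select_best(list()), "no fits")
  # table invariants: delta >= 0 with exactly one zero
  s <- select_best(data.frame(model = paste0("M", 1:4), K = c(4, 5, 6, 7),
                              aic = c(104, 101, 100, 103)))
  expect_true(all(s$table$delta >= 0))
  expect_equal(sum(s$table$delta == 0), 1)
})

test_that("fits are deterministic under a fixed seed and match nested ordering", {
  h <- sim_small(400, 8, seed = 4)
  opt <- fit_options(n_restarts = 2, seed = 11)
  f1 <- fit_model(h, build_spec(2), opt)
  f2 <- fit_model(h, build_spec(2), opt)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$aic, f2$aic)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$K)
  # nesting: the more general M3 cannot fit worse than M2
  f3 <- fit_model(h, build_spec(3), opt)
  expect_gte(f3$loglik, f1$loglik - 1e-6)
})

test_that("M6 parameter recovery lands inside Wald intervals", {
  truth <- c(phi_N = 0.55, phi_L = 0.65, phi_H = 0.75,
             psi_SB = 0.8, psi_N = 0.55, p = 0.5, pi_SB = 0.6)
  h <- sim_small(2000, 12, seed = 7)
  f <- fit_model(h, build_spec(6), fit_options(n_restarts = 2, seed = 1))
  est <- f$estimates
  for (nm in names(truth)) {
    row <- est[est$parameter == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 0.06)
    expect_true(row$lower < row$upper)
    expect_true(row$lower >= 0 && row$upper <= 1)
  }
})

test_that("Wald intervals shrink with sample size", {
  opt <- fit_options(n_restarts = 2, seed = 3)
  f_small <- fit_model(sim_small(300, 10, seed = 13), build_spec(1), opt)
  f_big <- fit_model(sim_small(3000, 10, seed = 13), build_spec(1), opt)
  w_small <- f_small$estimates$upper - f_small$estimates$lower
  w_big <- f_big$estimates$upper - f_big$estimates$lower
  expect_true(all(w_big < w_small))
})

test_that("fixing the assignment probability at 1 reproduces the size-model fit", {
  sim <- simulate_histories(sim_config(n_individuals = 500, n_occasions = 8,
                                       seed = 19, measure = "size"))
  h_size <- sim$histories
  h_mass <- encounter_histories(h_size$events, sex = h_size$sex,
                                age_entry = h_size$age_entry, measure = "mass",
                                occasion_years = h_size$occasion_years,
                                ids = h_size$ids)
  opt <- fit_options(n_restarts = 2, seed = 2)
  f_size <- fit_model(h_size, build_spec(5, measure = "size"), opt)
  f_mass <- fit_model(h_mass, build_spec(5, measure = "mass"), opt,
                      fixed = c(gamma_B = 1))
  expect_equal(f_mass$loglik, f_size$loglik, tolerance = 1e-6)
  expect_equal(f_mass$K, f_size$K)  # the fixed parameter is not counted
  expect_false("gamma_B" %in% f_mass$estimates$parameter)
})

test_that("run_model_set produces a complete, bookkept table", {
  h <- sim_small(350, 8, seed = 29)
  rs <- run_model_set(h, "none", options = fit_options(n_restarts = 1, seed = 1),
                      model_ids = 1:12)
  expect_equal(nrow(rs$table), 12)
  expect_equal(rs$table$K,
               sapply(1:12, function(m) count_parameters(build_spec(m))))
  expect_true(all(rs$table$delta >= 0))
  expect_equal(sum(rs$table$delta == 0), 1)
  expect_s3_class(rs$selection, "owlcmr_selection")
})

test_that("selection favours state-dependent survival when it generated the data", {
  # reduced-size check of selection consistency under an M6-type truth
  wins <- 0L
  for (s in 1:3) {
    h <- sim_small(1500, 12, seed = 100 + s)
    rs <- run_model_set(h, "none", options = fit_options(n_restarts = 1, seed = s))
    if (rs$selection$chosen %in% c("M3", "M6", "M9", "M12")) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("unsexed histories are rejected by sex-stratified fits", {
  h <- sim_small(200, 6, seed = 3, prop_unsexed = 0.5)
  expect_error(fit_model(h, build_spec(1, covariate = "sex"),
                         fit_options(n_restarts = 1)),
               "unsexed")
  # run_model_set subsets instead
  rs <- run_model_set(h, "sex", options = fit_options(n_restarts = 1),
                      model_ids = 1)
  expect_equal(nrow(rs$table), 1)
})
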