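#' Akaike information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of free parameters (>= 1).
#' @return `-2 * loglik + 2 * K`.
#' @export
aic <- function(loglik, K) {
  if (any(K < 1)) stop("K must be >= 1")
  -2 * loglik + 2 * K
}

#' Fitting options
#'
#' @param n_restarts Number of seeded starts; the first is at the link-scale
#'   origin (all probabilities 0.5), the rest jitter it by N(0, 1). Multievent
#'   likelihoods can be multimodal in small data, so a handful of restarts is
#'   kept as the default.
#' @param seed Seed for the start jitter.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @param maxit Maximum BFGS iterations.
#' @return List of options.
#' @export
fit_options <- function(n_restarts = 5, seed = 1, tol = 1e-8, maxit = 500) {
  list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
       tol = tol, maxit = as.integer(maxit))
}

# Collapse identical (history, covariate) rows to weights: the likelihood is
# a weighted sum over unique rows, which speeds up optimization considerably.
collapse_for_fit <- function(h, spec) {
  keys <- paste(apply(h$events, 1L, paste, collapse = ""),
                if (spec$covariate == "sex") h$sex else "",
                if (spec$covariate == "age") h$age_entry else "")
  idx <- !duplicated(keys)
  w <- as.numeric(table(factor(keys, levels = keys[idx])))
  list(h = subset_histories(h, idx), weights = w)
}

# Probability-scale value of each free parameter, keyed by par_info rows.
prob_values <- function(spec, theta) {
  r <- theta_to_real(spec, theta)
  info <- spec$par_info
  vapply(seq_len(nrow(info)), function(j) {
    nm <- sub("\\[.*\\]$", "", info$name[j])
    s <- info$stratum[j]
    st <- if (s %in% spec$strata) r$strata[[s]] else r$strata[[1L]]
    sb_of <- function(x) st$psi[x, "L"] + st$psi[x, "H"]
    switch(info$block[j],
      phi = switch(nm, phi = st$phi[["N"]], phi_SB = st$phi[["L"]],
                   phi_N = st$phi[["N"]], phi_L = st$phi[["L"]],
                   phi_H = st$phi[["H"]]),
      psi = switch(nm, psi = sb_of("N"), psi_SB = sb_of("L"),
                   psi_N = sb_of("N"), psi_L = sb_of("L"), psi_H = sb_of("H"),
                   st$psi[substr(nm, 5, 5), substr(nm, 6, 6)]),
      p = if (s %in% spec$strata) r$p[[s]] else r$p[[1L]],
      gamma = r$gamma,
      pi = r$pi)
  }, numeric(1))
}

#' Maximize the likelihood of one model
#'
#' Quasi-Newton (BFGS) maximization on the unconstrained link scale from
#' several jittered starts; the best optimum is kept. Standard errors come
#' from the numerically differentiated Hessian at the optimum; 95% intervals
#' for each probability-scale parameter are Wald intervals on the logit of
#' the parameter (delta method), back-transformed, so they always lie inside
#' `[0, 1]`. A parameter pushed to the boundary (`|link value| > 15`) or
#' lying along a near-null Hessian direction (curvature `< 1e-8`) is flagged
#' `not_estimated`: the data carry no information on it (for example a
#' transition cell with no supporting transitions).
#'
#' @param h An `owlcmr_histories` set compatible with `spec`.
#' @param spec An `owlcmr_spec`.
#' @param options See [fit_options()].
#' @param fixed Optional named vector of probability-scale parameters to hold
#'   fixed (logit-linked parameters only, e.g. `c(gamma_B = 1)`); fixed
#'   parameters are excluded from the free count K.
#' @return An object of class `owlcmr_fit`: the MLE, log-likelihood, K, AIC,
#'   and the estimate table with intervals.
#' @export
fit_model <- function(h, spec, options = fit_options(), fixed = NULL) {
  stopifnot(inherits(h, "owlcmr_histories"), inherits(spec, "owlcmr_spec"))
  if (h$measure != spec$measure)
    stop(sprintf("histories carry measure '%s' but spec is for '%s'",
                 h$measure, spec$measure))
  stratum_matrix(h, spec)  # fail early on unsexed / unknown-age histories
  cf <- collapse_for_fit(h, spec)
  npar_all <- count_parameters(spec)
  fixed_idx <- integer(0)
  fixed_theta <- numeric(0)
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% spec$par_names))
      stop("unknown fixed parameter(s): ",
           paste(setdiff(names(fixed), spec$par_names), collapse = ", "))
    if (any(spec$par_info$link[match(names(fixed), spec$par_names)] != "logit"))
      stop("only logit-linked parameters can be fixed")
    fixed_idx <- match(names(fixed), spec$par_names)
    fixed_theta <- qlogis(unname(fixed))
  }
  free_idx <- setdiff(seq_len(npar_all), fixed_idx)
  expand <- function(th_free) {
    th <- numeric(npar_all)
    th[free_idx] <- th_free
    th[fixed_idx] <- fixed_theta
    th
  }
  negll <- function(th_free) {
    th <- expand(th_free)
    v <- -total_loglik(cf$h, spec, th, weights = cf$weights)
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(options$seed)
  n_free <- length(free_idx)
  starts <- vector("list", options$n_restarts)
  starts[[1L]] <- rep(0, n_free)
  for (r in seq_len(options$n_restarts)[-1L]) starts[[r]] <- rnorm(n_free)
  best <- NULL; n_conv <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, negll, method = "BFGS",
            control = list(maxit = options$maxit, reltol = options$tol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || n_conv == 0L)
    stop(sprintf("no restart converged for %s (%d attempted)",
                 spec$label, options$n_restarts))
  theta_hat <- expand(best$par)
  loglik <- -best$value
  K <- n_free

  H <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
  V <- matrix(NA_real_, n_free, n_free)
  low_curv <- rep(FALSE, n_free)
  if (!is.null(H)) {
    low_curv <- diag(H) < 1e-8
    eg <- eigen(H, symmetric = TRUE)
    pos <- eg$values > 1e-8
    if (any(pos))
      V <- eg$vectors[, pos, drop = FALSE] %*%
        (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  }

  est <- prob_values(spec, theta_hat)
  # Delta-method SE of logit(estimate): gradient of qlogis(value(theta)) over
  # the free parameters, central differences.
  lo <- hi <- rep(NA_real_, npar_all)
  hstep <- 1e-5
  for (j in seq_len(npar_all)) {
    grad <- numeric(n_free)
    for (k in seq_len(n_free)) {
      thp <- best$par; thp[k] <- thp[k] + hstep
      thm <- best$par; thm[k] <- thm[k] - hstep
      vp <- prob_values(spec, expand(thp))[j]
      vm <- prob_values(spec, expand(thm))[j]
      grad[k] <- (qlogis(vp) - qlogis(vm)) / (2 * hstep)
    }
    se2 <- drop(t(grad) %*% V %*% grad)
    if (is.finite(se2) && se2 >= 0) {
      se <- sqrt(se2)
      lo[j] <- plogis(qlogis(est[j]) - qnorm(0.975) * se)
      hi[j] <- plogis(qlogis(est[j]) + qnorm(0.975) * se)
    }
  }
  not_est <- rep(FALSE, npar_all)
  not_est[free_idx] <- abs(theta_hat[free_idx]) > 15 | low_curv | is.na(lo[free_idx])
  estimates <- data.frame(
    parameter = spec$par_names, stratum = spec$par_info$stratum,
    estimate = unname(est), lower = lo, upper = hi,
    not_estimated = not_est, stringsAsFactors = FALSE)
  estimates <- estimates[free_idx, , drop = FALSE]
  rownames(estimates) <- NULL

  structure(list(
    spec = spec, theta = setNames(theta_hat, spec$par_names),
    loglik = loglik, K = K, aic = aic(loglik, K),
    estimates = estimates,
    convergence = list(code = best$convergence, n_restarts = options$n_restarts,
                       n_converged = n_conv),
    seed = options$seed, fixed = fixed
  ), class = "owlcmr_fit")
}

#' @export
print.owlcmr_fit <- function(x, ...) {
  cat(sprintf("<owlcmr_fit> %s (%s, covariate = %s): logLik = %.3f, K = %d, AIC = %.2f\n",
              x$spec$label, x$spec$measure, x$spec$covariate,
              x$loglik, x$K, x$aic))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Select the most parsimonious model by AIC
#'
#' The retained model has the lowest AIC, except that when several models lie
#' within 2 AIC units of the minimum the one with the fewest parameters is
#' retained. Ties on the parameter count break toward lower AIC, then toward
#' model order M1..M12; selection is invariant to the order fits are
#' supplied.
#'
#' @param fits List of `owlcmr_fit` objects, or a data frame with columns
#'   `model`, `K`, `aic` (rows with missing AIC are treated as failed fits
#'   and excluded from selection but kept in the table).
#' @return An object of class `owlcmr_selection`: the AIC table (`model`,
#'   `K`, `aic`, `delta`, `chosen`), the chosen model id, and which rule
#'   applied (`lowest_aic` or `fewest_params_within_2`).
#' @export
select_best <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits[, c("model", "K", "aic")]
  } else {
    if (length(fits) == 0L) stop("no fits supplied")
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$spec$label, K = f$K, aic = f$aic,
                 stringsAsFactors = FALSE)))
  }
  if (nrow(tab) == 0L || all(is.na(tab$aic))) stop("no successful fits to select from")
  ord <- order(suppressWarnings(as.integer(sub("^[Mm]", "", tab$model))),
               tab$model)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  amin <- min(tab$aic, na.rm = TRUE)
  tab$delta <- tab$aic - amin
  cand <- which(!is.na(tab$delta) & tab$delta < 2)
  pick <- cand[order(tab$K[cand], tab$aic[cand], cand)][1L]
  tab$chosen <- seq_len(nrow(tab)) == pick
  structure(list(
    table = tab, chosen = tab$model[pick],
    rule_applied = if (tab$delta[pick] == 0) "lowest_aic" else "fewest_params_within_2"
  ), class = "owlcmr_selection")
}

#' @export
print.owlcmr_selection <- function(x, ...) {
  cat(sprintf("<owlcmr_selection> chosen: %s (rule: %s)\n", x$chosen, x$rule_applied))
  print(x$table, digits = 6)
  invisible(x)
}

#' Fit and compare the full twelve-model set
#'
#' Fits M1..M12 under one covariate scheme and measure, assembles the AIC
#' table, and applies the selection rule. For `covariate = "age"` the data
#' are restricted to known-age histories, for `"sex"` to sexed histories
#' (mirroring the study's three analysis steps). A model whose fit fails is
#' kept in the table with missing AIC; selection runs on the rest.
#'
#' @param h An `owlcmr_histories` set.
#' @param covariate `"none"`, `"age"`, or `"sex"`.
#' @param measure `"size"` or `"mass"` (defaults to the measure the
#'   histories were encoded with).
#' @param options See [fit_options()].
#' @param model_ids Models to fit (default 1:12).
#' @return List with `$selection` (an `owlcmr_selection`), `$fits` (named
#'   list, `NULL` where a fit failed), and `$table`.
#' @export
run_model_set <- function(h, covariate = c("none", "age", "sex"),
                          measure = NULL, options = fit_options(),
                          model_ids = 1:12) {
  covariate <- match.arg(covariate)
  measure <- measure %||% h$measure
  if (covariate == "age") {
    keep <- !is.na(h$age_entry)
    if (!any(keep)) stop("no known-age individuals for covariate = 'age'")
    h <- subset_histories(h, keep)
  }
  if (covariate == "sex") {
    keep <- !is.na(h$sex)
    if (!any(keep)) stop("no known-sex individuals for covariate = 'sex'")
    h <- subset_histories(h, keep)
  }
  fits <- setNames(vector("list", length(model_ids)), paste0("M", model_ids))
  rows <- list()
  for (m in model_ids) {
    spec <- build_spec(m, covariate, measure)
    f <- tryCatch(fit_model(h, spec, options), error = function(e) {
      warning(sprintf("%s failed: %s", spec$label, conditionMessage(e)))
      NULL
    })
    fits[[paste0("M", m)]] <- f
    rows[[length(rows) + 1L]] <- data.frame(
      model = spec$label, K = count_parameters(spec),
      aic = if (is.null(f)) NA_real_ else f$aic, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  sel <- select_best(tab)
  list(selection = sel, fits = fits, table = sel$table)
}
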