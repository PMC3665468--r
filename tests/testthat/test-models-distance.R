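# Distance-based, phi-component and weighted distance-based models:
# normalizing constants, normalization, nesting, recovery, goodness of
# fit, model selection.

test_that("log_C worked values and limits hold", {
  expect_equal(exp(log_C(3, lambda = log(2))), 2.625)
  expect_equal(exp(log_C(3, lambda = log(2), method = "enumerate")), 2.625)
  expect_equal(exp(log_C(4, lambda = 50)), 1, tolerance = 1e-12) # only pi0
  expect_equal(exp(log_C(4, lambda = 0)), factorial(4))
  expect_equal(exp(log_C(5, lambda = 0, dtype = "foot")), factorial(5))
  expect_error(log_C(12, lambda = 1, dtype = "foot"), "cap")
})

test_that("closed-form constants agree with enumeration (Mallows and phi)", {
  set.seed(61)
  for (k in 3:6) {
    for (r in 1:10) {
      lam <- runif(1, 0.05, 3)
      expect_equal(log_C(k, lambda = lam),
                   log_C(k, lambda = lam, method = "enumerate"),
                   tolerance = 1e-10)
      lams <- runif(k - 1, 0.05, 3)
      expect_equal(log_C(k, lambdas = lams),
                   log_C(k, lambdas = lams, method = "enumerate"),
                   tolerance = 1e-10)
    }
  }
})

test_that("every model family normalizes to one over S_k", {
  set.seed(62)
  for (k in 3:5) {
    pi0 <- sample(k)
    expect_equal(sum(rankery:::probs_luce(runif(k, 0.2, 5), k)), 1,
                 tolerance = 1e-10)
    for (dt in c("tau", "rho", "rho2", "foot")) {
      expect_equal(sum(rankery:::probs_dbm(pi0, runif(1, 0.1, 2), dt)), 1,
                   tolerance = 1e-10)
      expect_equal(sum(rankery:::probs_wdbm(pi0, runif(k, 0.1, 2), dt)), 1,
                   tolerance = 1e-10)
    }
    expect_equal(sum(rankery:::probs_phicom(pi0, runif(k - 1, 0.1, 2))), 1,
                 tolerance = 1e-10)
  }
})

test_that("fit_dbm recovers a Mallows model and handles edge cases", {
  tab <- sample_dbm(1000, pi0 = c(2, 1, 4, 3), lambda = 1, seed = 71)
  fit <- fit_dbm(tab)
  expect_equal(fit$pi0, c(2, 1, 4, 3))
  expect_lt(abs(fit$lambda - 1) / 1, 0.15)
  # balanced data: dispersion collapses to zero (every modal ranking ties)
  expect_warning(fit0 <- fit_dbm(balanced_table(4)), "co-optimal")
  expect_lt(fit0$lambda, 1e-3)
  # a single observed ranking: dispersion runs to the bound
  one <- tibble::tibble(a = 1, b = 2, c = 3, n = 50)
  expect_warning(fit1 <- fit_dbm(one), "bound")
  expect_gt(fit1$lambda, 29)
})

test_that("label equivariance: relabeling items relabels the modal ranking", {
  tab <- sample_dbm(400, pi0 = c(1, 2, 3, 4), lambda = 1.2, seed = 72)
  gam <- c(4, 1, 3, 2)
  rel <- tab[, gam]
  names(rel) <- names(tab)
  f0 <- fit_dbm(tab)
  f1 <- fit_dbm(rel)
  expect_equal(f1$pi0, f0$pi0[gam])
  expect_equal(f1$lambda, f0$lambda, tolerance = 1e-6)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6)
})

test_that("fit_phicom recovers stagewise dispersions and nests Mallows", {
  tab <- sample_dbm(2000, pi0 = 1:4, lambdas = c(2, 0.5, 0.5), seed = 73)
  fit <- fit_phicom(tab)
  expect_equal(fit$pi0, 1:4)
  expect_gt(fit$lambdas[1], fit$lambdas[2])
  expect_lt(abs(fit$lambdas[1] - 2) / 2, 0.2)
  # nesting: the Mallows loglik equals the phi-component likelihood
  # evaluated at equal stage dispersions
  tab2 <- sample_dbm(500, pi0 = c(3, 1, 2, 4), lambda = 0.8, seed = 74)
  fd <- fit_dbm(tab2)
  probs_eq <- rankery:::probs_phicom(fd$pi0, rep(fd$lambda, 3))
  p <- rankery:::rt_parts(tab2)
  idx <- match(
    apply(p$R, 1, paste, collapse = ","),
    apply(permutations_of(4), 1, paste, collapse = ",")
  )
  ll_eq <- sum(p$freq * log(probs_eq[idx]))
  expect_equal(ll_eq, fd$loglik, tolerance = 1e-6)
  # and the unconstrained phi-component fit can only do better
  expect_gte(fit_phicom(tab2)$loglik, fd$loglik - 1e-6)
})

test_that("fit_wdbm nests the unweighted model and orders weights correctly", {
  tab <- sample_dbm(800, pi0 = 1:4, lambda = 0.7, dtype = "foot", seed = 75)
  fd <- fit_dbm(tab, dtype = "foot")
  fw <- fit_wdbm(tab, dtype = "foot")
  expect_gte(fw$loglik, fd$loglik - 1e-6)
  # equal weights matched to the fitted dispersion reproduce the
  # unweighted loglik exactly (the weighted family contains Mallows)
  probs_eq <- rankery:::probs_wdbm(fd$pi0, rep(fd$lambda, 4), "foot")
  p <- rankery:::rt_parts(tab)
  idx <- match(
    apply(p$R, 1, paste, collapse = ","),
    apply(permutations_of(4), 1, paste, collapse = ",")
  )
  expect_equal(sum(p$freq * log(probs_eq[idx])), fd$loglik, tolerance = 1e-6)
  # strong agreement only on rank 1 -> first weight dominates
  # with near-zero lower weights the modal ranking is only identified at
  # rank 1 (pairs among ranks 2..4 barely contribute to the distance), so
  # assert the identified features: the top item and the dominant weight
  tabw <- sample_dbm(2000, pi0 = 1:4, weights = c(3, 0.2, 0.2, 0.2),
                     dtype = "tau", seed = 76)
  fw2 <- fit_wdbm(tabw, dtype = "tau")
  expect_equal(fw2$pi0[1], 1) # item 1 is still ranked first
  expect_true(all(fw2$weights[1] > fw2$weights[-1]))
})

test_that("goodness of fit matches hand arithmetic", {
  # single ranking observed twice, uniform expectation over 3! cells:
  # chi2 = (2 - 1/3)^2 / (1/3) + 5 * (1/3) = 10
  gof <- goodness_of_fit(tiny_table(), rep(1 / 6, 6))
  expect_equal(gof$chi2, 10)
  expect_equal(gof$df, 5)
  # O = E exactly: balanced table under the uniform model
  gof0 <- goodness_of_fit(balanced_table(3, freq = 2), rep(1 / 6, 6))
  expect_equal(gof0$chi2, 0)
  # fitted-model route agrees with the fit's stored gof
  tab <- sample_dbm(300, pi0 = 1:4, lambda = 0.6, seed = 77)
  fit <- fit_dbm(tab)
  expect_equal(goodness_of_fit(tab, fit)$chi2, fit$gof$chi2)
  expect_equal(fit$gof$df, factorial(4) - 1 - 1)
})

test_that("select_model picks the largest loglikelihood", {
  tab <- sample_dbm(400, pi0 = 1:4, lambda = 1, seed = 78)
  fits <- list(fit_dbm(tab, "tau"), fit_dbm(tab, "rho2"),
               fit_phicom(tab))
  best <- select_model(fits)
  expect_s3_class(best, "rank_fit")
  cmp <- attr(best, "comparison")
  expect_equal(nrow(cmp), 3)
  expect_equal(best$loglik, max(cmp$logLik))
  # single fit returns itself
  expect_equal(select_model(fits[[1]])$loglik, fits[[1]]$loglik)
  expect_error(select_model(list()), "no fitted models")
})

test_that("the generating distance family usually wins model selection", {
  set.seed(79)
  wins <- 0
  for (r in 1:60) {
    tab <- sample_dbm(300, pi0 = 1:4, lambda = 1)
    f_tau <- fit_dbm(tab, "tau")
    f_rho2 <- fit_dbm(tab, "rho2")
    wins <- wins + (f_tau$loglik > f_rho2$loglik)
  }
  expect_gte(wins / 60, 0.9)
})
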