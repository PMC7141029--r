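test_that("optimal cutoffs maximize balanced accuracy with the stated tie-break", {
  r <- optimal_cutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 3.5)
  expect_equal(r$score, 1.0)

  r <- optimal_cutoff(rep(2.2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(r$score, 0.5)
  expect_lt(r$cutoff, 2.2)

  r <- optimal_cutoff(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 1.5)
  expect_equal(r$score, 0.75)

  expect_error(optimal_cutoff(1:4, rep(TRUE, 4)), "both classes")

  # exhaustive-search oracle on random instances
  withr::with_seed(77, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      v <- round(rlnorm(n, 2, 1), sample(0:2, 1))
      got <- optimal_cutoff(v, y)
      want <- brute_force_cutoff(v, y)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_equal(got$cutoff, want$cutoff, tolerance = 1e-12)
    }
  })
})

test_that("binarization is strict and idempotent", {
  rules <- tibble::tibble(feature = c("a", "b"), cutoff = c(2, 0.5))
  cov <- tibble::tibble(sample_id = c("s1", "s2"), a = c(2, 2 + 1e-9),
                        b = c(0, 1))
  out <- binarize(cov, rules)
  expect_equal(out$a, c(0L, 1L))   # equality -> 0, epsilon above -> 1
  expect_equal(out$b, c(0L, 1L))
  # 0/1 input with cutoff 0.5 is a fixed point
  rules05 <- tibble::tibble(feature = c("a", "b"), cutoff = 0.5)
  expect_equal(binarize(out, rules05)[, c("a", "b")], out[, c("a", "b")])
  expect_error(binarize(cov, rules[1, ], features = c("a", "b")),
               "no discretization rule")
})

test_that("logistic fits match the saturated closed form and flag separation", {
  x <- matrix(c(rep(0, 4), rep(1, 4)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$intercept - qlogis(0.25)), 1e-4)
  expect_lt(abs(fit$coefficients[["f"]] - (qlogis(0.75) - qlogis(0.25))), 1e-4)
  expect_false(fit$separation)

  # intercept-only model recovers the prevalence
  fit0 <- fit_logistic(matrix(nrow = 10, ncol = 0),
                       c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_lt(abs(fit0$intercept - qlogis(0.3)), 1e-8)

  # perfectly separating feature
  xs <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1,
               dimnames = list(NULL, "s"))
  expect_warning(fits <- fit_logistic(xs, c(rep(FALSE, 5), rep(TRUE, 5))),
                 "separation")
  expect_true(fits$separation)
  expect_lte(abs(fits$coefficients[["s"]]), 15 + 1e-9)

  # constant features are dropped with a warning
  xc <- cbind(x, k = 1)
  expect_warning(fitc <- fit_logistic(xc, y), "constant")
  expect_named(fitc$coefficients, "f")

  # property: random single-binary-feature designs without separation
  withr::with_seed(13, {
    for (i in 1:25) {
      n0 <- sample(4:20, 1)
      n1 <- sample(4:20, 1)
      y0 <- sample(c(TRUE, TRUE, FALSE, FALSE,
                     sample(c(TRUE, FALSE), n0 - 4, replace = TRUE)))
      y1 <- sample(c(TRUE, TRUE, FALSE, FALSE,
                     sample(c(TRUE, FALSE), n1 - 4, replace = TRUE)))
      xx <- matrix(c(rep(0, n0), rep(1, n1)), ncol = 1,
                   dimnames = list(NULL, "f"))
      ff <- fit_logistic(xx, c(y0, y1))
      expect_lt(abs(ff$intercept - qlogis(mean(y0))), 1e-4)
      expect_lt(abs(ff$coefficients[["f"]] -
                      (qlogis(mean(y1)) - qlogis(mean(y0)))), 1e-4)
    }
  })
})

test_that("stepwise AIC selection finds signal, respects the cap, and resists noise", {
  withr::with_seed(5, {
    y <- rep(c(TRUE, FALSE), 30)
    x <- matrix(rbinom(60 * 20, 1, 0.5), nrow = 60,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    x[, "f07"] <- as.numeric(y)  # one feature identical to the label
  })
  sel <- suppressWarnings(stepwise_select(x, y))
  expect_equal(sel[1], "f07")
  expect_identical(stepwise_select(x, y, max_features = 0), character())

  # pure-noise designs: the AIC penalty keeps most noise features out
  # (and the search behaves exactly like the conventional stepwise below)
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      yn <- rep(c(TRUE, FALSE), 30)
      xn <- matrix(rbinom(60 * 20, 1, 0.5), nrow = 60,
                   dimnames = list(NULL, sprintf("n%02d", 1:20)))
    })
    expect_lte(length(suppressWarnings(stepwise_select(xn, yn))), 10)
  }
})

test_that("stepwise agrees with stats::step on a reference design", {
  withr::with_seed(29, {
    n <- 80
    x <- matrix(rbinom(n * 6, 1, 0.5), nrow = n,
                dimnames = list(NULL, paste0("g", 1:6)))
    lp <- -0.5 + 2 * x[, "g2"] - 1.5 * x[, "g5"]
    y <- runif(n) < plogis(lp)
  })
  mine <- sort(stepwise_select(x, y))
  df <- data.frame(y = y, x)
  ref <- stats::step(stats::glm(y ~ 1, data = df, family = binomial),
                     scope = list(lower = ~1,
                                  upper = stats::reformulate(colnames(x))),
                     direction = "both", trace = 0)
  ref_terms <- sort(attr(stats::terms(ref), "term.labels"))
  expect_equal(mine, ref_terms)
})

test_that("LOOCV refits per fold, is order-invariant, and honest on null data", {
  withr::with_seed(2, {
    y <- rep(c(TRUE, FALSE), 10)
    x <- matrix(rbinom(20 * 3, 1, 0.5), nrow = 20,
                dimnames = list(NULL, c("a", "b", "c")))
    x[, "a"] <- as.numeric(y)
  })
  p <- suppressWarnings(loocv_probabilities(x, y, features = "a"))
  expect_true(all((p > 0.5) == y))

  # permuting samples permutes the probabilities
  perm <- withr::with_seed(8, sample(20))
  p2 <- suppressWarnings(
    loocv_probabilities(x[perm, ], y[perm], features = "a"))
  expect_equal(p2, p[perm], tolerance = 1e-6)

  # labels independent of features: LOOCV AUC stays near chance
  withr::with_seed(9, {
    yn <- rep(c(TRUE, FALSE), 20)
    xn <- matrix(rbinom(40 * 5, 1, 0.5), nrow = 40,
                 dimnames = list(NULL, paste0("z", 1:5)))
  })
  pn <- suppressWarnings(loocv_probabilities(xn, yn))
  auc <- roc_analysis(pn, yn)$auc
  expect_gte(auc, 0.3)
  expect_lte(auc, 0.7)

  expect_error(loocv_probabilities(x[1:2, ], y[1:2]), "at least 3")
})
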