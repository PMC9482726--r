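test_that("Cauchy prior keeps coefficients finite on separable data", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "v1"))
  fit <- fit_risk_model(x, c("mild", "mild", "severe", "severe"))
  expect_true(all(is.finite(coef(fit))))
  expect_true(fit$converged)
  expect_gt(coef(fit)[["v1"]], 0)
  expect_error(fit_risk_model(x, rep("severe", 4)), "single class",
               class = "rg_validation_error")
  x[1] <- NA
  expect_error(fit_risk_model(x, c("mild", "mild", "severe", "severe")),
               "non-finite", class = "rg_validation_error")
})

test_that("a flat prior recovers the unpenalized maximum-likelihood fit", {
  set.seed(42)
  n <- 60
  x <- matrix(rbinom(n * 3, 2, 0.4), n, dimnames = list(NULL, c("v1", "v2", "v3")))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  fit <- fit_risk_model(x, y, prior_scale = 1e6, prior_scale_intercept = 1e6)
  # oracle: direct numeric maximization of the log-likelihood
  nll <- function(b) {
    eta <- b[1] + x %*% b[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, 4), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(coef(fit) - opt$par)), 1e-3)
})

test_that("known coefficients are recovered from simulated logistic data", {
  set.seed(2024)
  n <- 2000
  beta <- c(-0.5, 0.6, -0.4, 0.8, 0, 0.3)
  x <- matrix(rbinom(n * 5, 2, 0.35), n,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- rbinom(n, 1, plogis(beta[1] + drop(x %*% beta[-1])))
  fit <- fit_risk_model(x, y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
})

test_that("fit symmetry, monotone deviance and column-order invariance hold", {
  set.seed(9)
  n <- 50
  x <- matrix(rbinom(n * 4, 2, 0.3), n, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(n, 1, plogis(0.5 * x[, 1] - 0.7 * x[, 3]))
  f1 <- fit_risk_model(x, y)
  f2 <- fit_risk_model(x, 1 - y)
  expect_lt(max(abs(coef(f1) + coef(f2))), 1e-6)
  expect_true(all(diff(f1$deviance) <= 1e-9))

  xp <- x[, c(3, 1, 4, 2)]
  fp <- fit_risk_model(xp, y)
  expect_lt(max(abs(predict(f1, x) - predict(fp, x))), 1e-8)
})

test_that("a constant predictor is shrunk out and the intercept carries the base rate", {
  set.seed(3)
  n <- 40
  x <- matrix(1, n, 1, dimnames = list(NULL, "flat"))
  y <- rep(c(0, 1), each = n / 2)  # balanced
  fit <- fit_risk_model(x, y)
  expect_lt(abs(coef(fit)[["flat"]]), 1e-6)
  expect_lt(abs(plogis(fit$intercept) - 0.5), 1e-6)
  # unbalanced: weak prior shrinkage leaves the base rate nearly intact
  y2 <- rep(c(0, 1), times = c(25, 15))
  fit2 <- fit_risk_model(matrix(1, 40, 1, dimnames = list(NULL, "flat")), y2)
  expect_lt(abs(plogis(fit2$intercept) - 15 / 40), 1e-3)
})

test_that("prediction follows the inverse-logit closed form with ties to severe", {
  m <- structure(list(intercept = 0,
                      coefficients = c(v1 = 0),
                      standardization = list(center = c(v1 = 0), scale = c(v1 = 1))),
                 class = "risk_model")
  x <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("s1", "s2", "s3"), "v1"))
  pr <- predict_risk(m, x)
  expect_equal(pr$risk, rep(0.5, 3))
  expect_equal(pr$predicted_class, rep("severe", 3))  # tie rule

  m$coefficients <- c(v1 = log(3))
  expect_equal(unname(predict(m, matrix(1, 1, 1, dimnames = list(NULL, "v1")))),
               0.75)
  # monotone in the linear predictor
  risks <- predict(m, x)
  expect_true(all(diff(risks) > 0))
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list(NULL, "v9"))),
               "v1", class = "rg_validation_error")
})

test_that("risk models serialize to JSON and back losslessly enough to predict", {
  set.seed(5)
  x <- matrix(rbinom(60, 2, 0.4), 20, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(20, 1, 0.5)
  y[1:2] <- c(0, 1)
  fit <- fit_risk_model(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(fit, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$intercept, fit$intercept)
  expect_equal(unlist(doc$coefficients), fit$coefficients)
})
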