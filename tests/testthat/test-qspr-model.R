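# Independent hand evaluation of the published coefficient set, spelled
# out term by term so it shares no code with predict_log10_dk().
hand_log10_dk <- function(mw, cse, csp, pka, logp) {
  -2.052 + 2.923e-3 * mw - 9.067e-1 * log10(cse) + 2.788e-3 * csp -
    3.196e-2 * pka + 4.872e-2 * logp
}

test_that("published model carries the frozen coefficients and transforms", {
  m <- published_model()
  expect_equal(m$coefficients[["cse"]], -0.9067)
  expect_equal(m$coefficients[["mw"]], 2.923e-3)
  expect_equal(m$intercept, -2.052)
  expect_equal(m$transforms$cse$transform, "logarithm")
  for (p in c("mw", "csp", "pka", "logp"))
    expect_equal(m$transforms[[p]]$transform, "raw")
  expect_equal(m$adjusted_r2, 0.75)
})

test_that("published-model predictions match hand evaluation", {
  m <- published_model()
  ftc <- data.frame(mw = 247.2, csp = 165.6, pka = 2.65, logp = -0.43)
  expect_equal(predict_log10_dk(m, ftc, 0.906), -0.934, tolerance = 1e-3)
  expect_equal(predict_log10_dk(m, ftc, 0.906),
               hand_log10_dk(247.2, 0.906, 165.6, 2.65, -0.43),
               tolerance = 1e-12)
  lng <- data.frame(mw = 312.5, csp = 0.0071, pka = 17.9, logp = 3.8)
  expect_equal(predict_log10_dk(m, lng, 0.59), -1.318, tolerance = 1e-3)
  # at CsE = 1 the CsE term contributes exactly zero
  expect_equal(predict_log10_dk(m, ftc, 1),
               -2.052 + 2.923e-3 * 247.2 + 2.788e-3 * 165.6 -
                 3.196e-2 * 2.65 + 4.872e-2 * (-0.43))
  expect_equal(predict_dk(m, ftc, 0.906), 10^predict_log10_dk(m, ftc, 0.906))
  expect_error(predict_log10_dk(m, ftc, 0), "domain")
  # pure deterministic function: repeated calls agree bitwise
  expect_identical(predict_log10_dk(m, ftc, 0.906),
                   predict_log10_dk(m, ftc, 0.906))
})

test_that("transform selection prefers the generating functional form", {
  set.seed(7)
  x <- runif_log(50, 0.01, 100)
  y <- 2 - 0.9 * log10(x) + rnorm(50, 0, 0.05)
  expect_equal(as.character(select_transform(x, y)), "logarithm")
  # perfect linearity wins ties by the fixed priority order
  x2 <- 1:20
  expect_equal(as.character(select_transform(x2, 3 * x2)), "raw")
  expect_error(select_transform(rep(2, 10), rnorm(10)), "degenerate")
  expect_error(select_transform(1:2, c(1, 2)), "insufficient")
  # non-positive predictors keep only raw/exponential candidates
  x3 <- seq(-5, 5, length.out = 40)
  sel <- select_transform(x3, 2 * x3 + rnorm(40, 0, 0.1))
  expect_true(as.character(sel) %in% c("raw", "exponential"))
  expect_false(any(c("logarithm", "reciprocal") %in%
                     names(attr(sel, "correlations"))))
})

test_that("transform machinery round-trips through the exponential scaling", {
  x <- c(229, 312, 449, 535)
  tx <- apply_transform(x, "exponential", center = 380, scale = 120)
  expect_equal(tx, exp((x - 380) / 120))
  expect_error(apply_transform(c(-1, 2), "logarithm"), "positive")
  expect_error(apply_transform(c(0, 2), "reciprocal"), "positive")
})

test_that("noiseless tables are recovered exactly with the generating spec", {
  tab <- generate_qspr_table(noise_sd_log10 = 0, seed = 7)
  m <- suppressWarnings(fit_qspr(tab, transforms = published_transforms()))
  expect_lt(max(abs(m$coefficients - published_model()$coefficients)), 1e-6)
  expect_lt(abs(m$intercept - (-2.052)), 1e-6)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-9)
  expect_lt(m$mse, 1e-12)
})

test_that("coefficient bias shrinks as the table grows", {
  err_at <- function(n_drugs, seed) {
    tab <- generate_qspr_table(n_drugs = n_drugs, excipients_per_drug = 6,
                               noise_sd_log10 = 0.3, seed = seed)
    m <- fit_qspr(tab, transforms = published_transforms())
    max(abs(m$full$coefficients - published_model()$coefficients) /
          abs(published_model()$coefficients))
  }
  e40 <- mean(sapply(1:5, function(s) err_at(7, s)))
  e200 <- mean(sapply(1:5, function(s) err_at(34, s)))
  e1000 <- mean(sapply(1:5, function(s) err_at(167, s)))
  expect_lt(e200, e40)
  expect_lt(e1000, e200)
})

test_that("a pure-noise predictor is eliminated in most replicates", {
  reps <- 200
  dropped <- logical(reps)
  trs <- c(published_transforms(), list(junk = "raw"))
  for (r in seq_len(reps)) {
    tab <- generate_qspr_table(noise_sd_log10 = 0.3, seed = 5000 + r)
    set.seed(5000 + r)
    tab$junk <- rnorm(nrow(tab))
    m <- fit_qspr(tab, predictors = c("mw", "cse", "csp", "pka", "logp", "junk"),
                  transforms = trs)
    dropped[r] <- "junk" %in% m$eliminated
  }
  expect_gte(mean(dropped), 0.9)
})

test_that("backward elimination never raises training R^2 above the full model", {
  for (s in 1:5) {
    tab <- generate_qspr_table(noise_sd_log10 = 0.4, seed = 100 + s)
    m <- fit_qspr(tab, transforms = published_transforms())
    # unadjusted R^2 ordering: the full design fits training data at least
    # as well, i.e. final-model mse >= full-model mse
    expect_gte(m$mse, m$full$mse - 1e-12)
  }
})

test_that("stored mse is reproduced by predicting on the training rows", {
  tab <- generate_qspr_table(noise_sd_log10 = 0.3, seed = 21)
  m <- fit_qspr(tab, transforms = published_transforms())
  pred <- predict_log10_dk(m, m$training)
  expect_equal(mean((pred - m$training$log10_dk)^2), m$mse, tolerance = 1e-12)
})

test_that("Wald p-values match brute-force normal-equations computation", {
  # 6 distinct drugs so the four drug-level predictors stay full rank
  tab <- generate_qspr_table(n_drugs = 6, excipients_per_drug = 2,
                             noise_sd_log10 = 0.3, seed = 3)
  m <- fit_qspr(tab, transforms = published_transforms())
  X <- cbind(1, tab$mw_da, log10(tab$cse_mg_ml), tab$csp_mg_ml, tab$pka,
             tab$logp)
  y <- tab$log10_dk
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  p_brute <- 2 * pt(abs(beta / se), df, lower.tail = FALSE)[-1]
  expect_equal(unname(wald_pvalues(m, "full")), p_brute, tolerance = 1e-10)
})

test_that("Wald p-values are invariant to positive rescaling of a predictor", {
  tab <- generate_qspr_table(noise_sd_log10 = 0.3, seed = 13)
  m1 <- fit_qspr(tab, transforms = published_transforms())
  tab2 <- tab
  tab2$mw_da <- tab2$mw_da * 1000
  m2 <- fit_qspr(tab2, transforms = published_transforms())
  expect_equal(wald_pvalues(m1, "full"), wald_pvalues(m2, "full"),
               tolerance = 1e-9)
})

test_that("an exactly orthogonal null predictor gets p = 1", {
  set.seed(5)
  x1 <- rnorm(30)
  y <- 1 + 2 * x1 + rnorm(30, 0, 0.5)
  # orthogonalize a probe against both the design and the outcome
  z <- residuals(lm(rnorm(30) ~ x1 + y))
  fit <- lm(y ~ x1 + z)
  expect_equal(unname(coef(fit)["z"]), 0, tolerance = 1e-12)
  expect_equal(summary(fit)$coefficients["z", "Pr(>|t|)"], 1, tolerance = 1e-9)
})

test_that("rank-deficient designs raise a collinearity error naming predictors", {
  tab <- generate_qspr_table(noise_sd_log10 = 0.3, seed = 17)
  tab$dup <- tab$mw_da
  expect_error(
    fit_qspr(tab, predictors = c("mw", "cse", "csp", "pka", "logp", "dup"),
             transforms = c(published_transforms(), list(dup = "raw"))),
    "collinearity")
})

test_that("model serialization round-trips exactly", {
  tab <- generate_qspr_table(noise_sd_log10 = 0.3, seed = 29)
  m <- fit_qspr(tab, transforms = published_transforms())
  path <- tempfile(fileext = ".json")
  write_qspr_model(m, path)
  m2 <- read_qspr_model(path)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(predict_log10_dk(m2, tab), predict_log10_dk(m, tab))
  expect_identical(m2$mse, m$mse)
  # published model survives a round trip too
  pm <- published_model()
  write_qspr_model(pm, path)
  pm2 <- read_qspr_model(path)
  ftc <- data.frame(mw = 247.2, csp = 165.6, pka = 2.65, logp = -0.43)
  expect_identical(predict_log10_dk(pm2, ftc, 0.906),
                   predict_log10_dk(pm, ftc, 0.906))
})
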