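# Mixed-model engine: closed forms, the dense-covariance oracle, the
# cholesky-root embedding of kinship, Wald/LRT machinery and variance
# explained.

test_that("intercept-only model recovers the sample variance in closed form", {
  set.seed(101)
  y <- rnorm(40, 5, 2)
  X <- matrix(1, 40, dimnames = list(NULL, "(Intercept)"))
  fr <- fitLMM(lmmSpec(y, X), "REML")
  fm <- fitLMM(lmmSpec(y, X), "ML")
  expect_equal(unname(fr@varcomp[["residual"]]), var(y), tolerance = 1e-10)
  expect_equal(unname(fm@varcomp[["residual"]]), var(y) * 39 / 40,
               tolerance = 1e-10)
  expect_equal(unname(fr@beta[["(Intercept)"]]), mean(y), tolerance = 1e-10)
})

test_that("balanced one-way REML matches the ANOVA closed form", {
  set.seed(102)
  a <- 8L; m <- 6L
  g <- factor(rep(seq_len(a), each = m))
  y <- 3 + rnorm(a, 0, 1.3)[g] + rnorm(a * m, 0, 0.7)
  X <- matrix(1, a * m, dimnames = list(NULL, "(Intercept)"))
  Z <- stats::model.matrix(~ 0 + g)
  fit <- fitLMM(lmmSpec(y, X, list(iidBlock(Z, "grp"))), "REML")
  msb <- m * var(tapply(y, g, mean))
  msw <- sum((y - ave(y, g))^2) / (a * (m - 1))
  expect_equal(unname(fit@varcomp[["residual"]]), msw, tolerance = 1e-6)
  expect_equal(unname(fit@varcomp[["grp"]]), (msb - msw) / m,
               tolerance = 1e-6)
})

test_that("direct log-likelihood oracle has the right closed form at V = I", {
  n <- 25L
  spec <- lmmSpec(rep(0, n), matrix(1, n, dimnames = list(NULL, "i")))
  ll <- directLogLik(spec, list(residual = 1), "ML")
  expect_equal(ll, -n / 2 * log(2 * pi), tolerance = 1e-12)
  expect_error(directLogLik(spec, list(residual = 1), "ML", maxN = 10),
               "small problems")
})

test_that("engine objective equals the dense oracle at random parameter points", {
  rs <- randomSmallSpec(201)
  for (k in 1:20) {
    vc <- randomVarcomp(rs$spec, 300 + k)
    for (m in c("REML", "ML")) {
      expect_equal(ryeassoc:::engineLogLik(rs$spec, vc, m),
                   directLogLik(rs$spec, vc, m), tolerance = 1e-9)
    }
  }
})

test_that("cholesky-root embedding reproduces the direct K covariance", {
  for (seed in c(211, 212, 213)) {
    rs <- randomSmallSpec(seed)
    vc <- randomVarcomp(rs$spec, seed + 1000)
    for (m in c("REML", "ML")) {
      llRoot <- directLogLik(rs$spec, vc, m, kinshipAs = "root")
      llDirect <- directLogLik(rs$spec, vc, m, kinshipAs = "direct")
      expect_equal(llRoot, llDirect, tolerance = 1e-10)
    }
  }
})

test_that("fitted optimum agrees with the dense oracle and with lme4", {
  skip_if_not_installed("lme4")
  set.seed(105)
  n <- 150L
  g <- factor(sample(sprintf("g%02d", 1:15), n, TRUE))
  x <- rnorm(n)
  y <- 2 + 0.6 * x + rnorm(15, 0, 1.2)[g] + rnorm(n, 0, 0.9)
  X <- cbind(`(Intercept)` = 1, x = x)
  Z <- stats::model.matrix(~ 0 + g)
  spec <- lmmSpec(y, X, list(iidBlock(Z, "grp")))
  for (m in c("REML", "ML")) {
    fit <- fitLMM(spec, m)
    vc <- list(residual = fit@varcomp[["residual"]],
               grp = max(fit@varcomp[["grp"]], 1e-10))
    expect_equal(fit@loglik, directLogLik(spec, vc, m), tolerance = 1e-6)
    lf <- lme4::lmer(y ~ x + (1 | g), REML = m == "REML")
    expect_equal(fit@loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
    expect_equal(unname(fit@beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
    vcl <- as.data.frame(lme4::VarCorr(lf))$vcov
    expect_equal(unname(c(fit@varcomp[["grp"]], fit@varcomp[["residual"]])),
                 vcl, tolerance = 1e-4)
  }
})

test_that("REML is invariant to translating y along fixed-effect columns", {
  rs <- randomSmallSpec(220, withUs2 = FALSE)
  spec <- rs$spec
  fit1 <- fitLMM(spec, "REML")
  spec2 <- lmmSpec(spec$y + 3 * spec$X[, "marker"], spec$X, spec$blocks)
  fit2 <- fitLMM(spec2, "REML")
  expect_equal(fit1@loglik, fit2@loglik, tolerance = 1e-6)
  expect_equal(fit1@varcomp, fit2@varcomp, tolerance = 1e-4)
  expect_equal(unname(fit2@beta[["marker"]] - fit1@beta[["marker"]]), 3,
               tolerance = 1e-5)
})

test_that("Wald tests use the stated reference distributions", {
  rs <- randomSmallSpec(230, withUs2 = FALSE)
  fit <- fitLMM(rs$spec, "REML")
  w <- waldTest(fit, "marker")
  expect_equal(w$t, w$estimate / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$t)))
  wt <- waldTest(fit, "marker", pReference = "tresid")
  expect_equal(wt$p, 2 * pt(-abs(w$t), df = fit@n - fit@p))
  expect_error(waldTest(fit, "absent"), "not estimable|not in the model")
})

test_that("likelihood-ratio tests enforce nesting rules", {
  set.seed(107)
  n <- 80L
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n)
  Xf <- cbind(`(Intercept)` = 1, x = x)
  Xr <- Xf[, 1, drop = FALSE]
  full <- fitLMM(lmmSpec(y, Xf), "ML")
  red <- fitLMM(lmmSpec(y, Xr), "ML")
  out <- lrt(full, red)
  expect_equal(out$df, 1L)
  expect_gt(out$statistic, 0)
  expect_equal(out$p, pchisq(out$statistic, 1, lower.tail = FALSE))

  same <- lrt(full, full, df = 1L)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  fullR <- fitLMM(lmmSpec(y, Xf), "REML")
  redR <- fitLMM(lmmSpec(y, Xr), "REML")
  expect_error(lrt(fullR, redR), "REML")
  expect_error(lrt(full, redR), "same estimation method")
  expect_error(lrt(full, fitLMM(lmmSpec(y + 1, Xf), "ML"), df = 1), "nested")

  # ML LRT is invariant to reparameterizing the nested fixed effects
  Xf2 <- cbind(`(Intercept)` = 1, x2 = 2 * x - 1)
  full2 <- fitLMM(lmmSpec(y, Xf2), "ML")
  expect_equal(lrt(full2, red)$statistic, out$statistic, tolerance = 1e-8)
})

test_that("variance explained is the relative drop in genotype variance, zero-truncated", {
  expect_equal(as.numeric(varianceExplained(fakeGenotypeFit(2), fakeGenotypeFit(1))), 50)
  ve <- varianceExplained(fakeGenotypeFit(1), fakeGenotypeFit(1.2))
  expect_equal(as.numeric(ve), 0)
  v0 <- varianceExplained(fakeGenotypeFit(0), fakeGenotypeFit(0))
  expect_equal(as.numeric(v0), 0)
  expect_true(isTRUE(attr(v0, "undefined")))
  expect_error(varianceExplained(fakeGenotypeFit(1, y = 1:3),
                                 fakeGenotypeFit(1, y = 2:4)),
               "share the response")
})

test_that("boundary variance components are reported as zero with a flag", {
  set.seed(108)
  n <- 60L
  g <- factor(rep(1:6, each = 10))
  y <- rnorm(n)                       # no group signal at all
  X <- matrix(1, n, dimnames = list(NULL, "(Intercept)"))
  Z <- stats::model.matrix(~ 0 + g)
  fit <- fitLMM(lmmSpec(y, X, list(iidBlock(Z, "grp"))), "REML")
  if (fit@diagnostics$boundary[["grp"]])
    expect_identical(unname(fit@varcomp[["grp"]]), 0)
  expect_true(all(fit@varcomp >= 0))
})

test_that("rank-deficient fixed designs error with the aliased columns named", {
  set.seed(109)
  n <- 30L
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x, xdup = x)
  expect_error(fitLMM(lmmSpec(rnorm(n), X)), "xdup")
  Xp <- dropAliased(X)
  expect_equal(colnames(Xp), c("(Intercept)", "x"))
  expect_equal(attr(Xp, "dropped"), "xdup")
  expect_error(dropAliased(X, protect = "xdup"), "protected")
})
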