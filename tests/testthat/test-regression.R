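# IRLS GLM core and cluster-robust sandwich covariance.

test_that("intercept-only fits recover closed forms", {
  set.seed(51)
  y <- rbinom(400, 1, 0.25)
  d <- data.frame(y = y)
  f_log <- fit_glm(y ~ 1, d, link = "log")
  expect_equal(unname(exp(f_log$coefficients)), mean(y), tolerance = 1e-10)
  y2 <- rep(c(0L, 1L), 100)
  f_logit <- fit_glm(y ~ 1, data.frame(y = y2), link = "logit")
  expect_equal(unname(f_logit$coefficients), 0, tolerance = 1e-10)
})

test_that("saturated modified Poisson equals the 2x2-table prevalence ratio", {
  set.seed(52)
  x <- rbinom(600, 1, 0.5)
  y <- rbinom(600, 1, ifelse(x == 1, 0.15, 0.30))
  d <- data.frame(y = y, x = x)
  fit <- fit_glm(y ~ x, d, link = "log")
  p1 <- mean(y[x == 1]); p0 <- mean(y[x == 0])
  expect_equal(unname(exp(fit$coefficients[["x"]])), p1 / p0,
               tolerance = 1e-8)
  expect_equal(unname(exp(sum(fit$coefficients))), p1, tolerance = 1e-8)
})

test_that("separation and degenerate responses produce explicit errors", {
  d <- data.frame(y = c(rep(0L, 50), rep(1L, 50)),
                  x = c(rep(0, 50), rep(1, 50)))
  expect_error(fit_glm(y ~ x, d, link = "logit"),
               "converge|separation|diverged")
  expect_error(fit_glm(y ~ x, data.frame(y = rep(0L, 20), x = rnorm(20)),
                       link = "log"), "no events")
  d2 <- data.frame(y = rbinom(30, 1, 0.5), a = rnorm(30))
  d2$b <- d2$a
  expect_error(fit_glm(y ~ a + b, d2, link = "logit"), "rank deficient")
})

test_that("each observation its own cluster reduces to HC0", {
  set.seed(53)
  d <- data.frame(y = rbinom(300, 1, 0.35), x = rnorm(300))
  fit <- fit_glm(y ~ x, d, link = "log", cluster = seq_len(300))
  g <- glm(y ~ x, data = d, family = poisson)
  hc0 <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(sqrt(diag(fit$vcov_robust_uncorrected))),
               unname(sqrt(diag(hc0))), tolerance = 1e-6)
})

test_that("cluster duplication leaves coefficients fixed and halves the sandwich", {
  set.seed(54)
  d <- data.frame(y = rbinom(400, 1, 0.3), x = rnorm(400),
                  cl = sample(paste0("g", 1:20), 400, TRUE))
  f1 <- fit_glm(y ~ x, d, link = "log", cluster = d$cl)
  d2 <- rbind(d, transform(d, cl = paste0(cl, "_copy")))
  f2 <- fit_glm(y ~ x, d2, link = "log", cluster = d2$cl)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  # duplicating every cluster doubles both bread and meat, so the plain
  # sandwich exactly halves; only the G/(G-1) factor differs beyond that
  expect_equal(f2$vcov_robust_uncorrected, f1$vcov_robust_uncorrected / 2,
               tolerance = 1e-8)
  G <- f1$n_clusters
  expect_equal(f2$vcov_robust,
               f1$vcov_robust * (G - 1) / G * (2 * G) / (2 * G - 1) / 2,
               tolerance = 1e-8)
})

test_that("matrix sandwich equals brute-force per-cluster score accumulation", {
  set.seed(55)
  d <- data.frame(y = rbinom(500, 1, 0.3), x1 = rnorm(500),
                  x2 = factor(sample(3, 500, TRUE)),
                  cl = sample(paste0("g", 1:12), 500, TRUE))
  fit <- fit_glm(y ~ x1 + x2, d, link = "log", cluster = d$cl)
  A <- solve(fit$info)
  p <- length(fit$coefficients)
  B <- matrix(0, p, p)
  for (g in unique(d$cl)) {
    idx <- which(d$cl == g)
    s <- colSums(fit$x[idx, , drop = FALSE] * (fit$y[idx] - fit$mu[idx]))
    B <- B + outer(s, s)
  }
  G <- fit$n_clusters
  V <- A %*% B %*% A * G / (G - 1)
  expect_lt(max(abs(V - fit$vcov_robust)), 1e-10)
  expect_error(cluster_robust_vcov(fit, rep("only", fit$n)), ">= 2 clusters")
})

test_that("IRLS agrees with the external-library oracle on random designs", {
  set.seed(56)
  for (i in 1:20) {
    n <- 250 + sample(250, 1)
    d <- data.frame(y = rbinom(n, 1, runif(1, 0.15, 0.5)),
                    x1 = rnorm(n),
                    x2 = factor(sample(3, n, TRUE)),
                    x3 = rbinom(n, 1, 0.4),
                    cl = sample(paste0("g", 1:25), n, TRUE))
    if (sum(d$y) < 5 || sum(d$y) > n - 5) next
    link <- if (i %% 2 == 0) "log" else "logit"
    fam <- if (link == "log") poisson() else binomial()
    fit <- fit_glm(y ~ x1 + x2 + x3, d, link = link, cluster = d$cl)
    g <- glm(y ~ x1 + x2 + x3, data = d, family = fam)
    expect_lt(max(abs(fit$coefficients - coef(g))), 1e-6)
    vcl <- sandwich::vcovCL(g, cluster = d$cl, type = "HC0", cadjust = TRUE)
    expect_lt(max(abs(sqrt(diag(fit$vcov_robust)) - sqrt(diag(vcl)))), 1e-4)
    # robust covariance is PSD on every fit
    expect_gte(min(eigen(fit$vcov_robust, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
    # log link: fitted means above 1 are allowed but counted
    if (link == "log") expect_true(is.numeric(fit$n_mu_above_1))
  }
})

test_that("risk ratios exponentiate the requested term with robust CI", {
  set.seed(57)
  d <- data.frame(y = rbinom(500, 1, 0.3), x = rbinom(500, 1, 0.5),
                  cl = sample(paste0("g", 1:20), 500, TRUE))
  fit <- fit_glm(y ~ x, d, link = "log", cluster = d$cl)
  rr <- risk_ratio_from_model(fit, "x")
  expect_equal(rr$estimate, unname(exp(fit$coefficients[["x"]])))
  se <- sqrt(fit$vcov_robust["x", "x"])
  expect_equal(rr$lower,
               unname(exp(fit$coefficients[["x"]] - qnorm(0.975) * se)))
  expect_true(rr$lower < rr$estimate && rr$estimate < rr$upper)
  expect_error(risk_ratio_from_model(fit, "zz"), "not in model")
  # a null coefficient maps to RR 1 (intercept-only on balanced outcome)
  f0 <- fit_glm(y ~ 1, data.frame(y = rep(c(0L, 1L), 50)), link = "log",
                cluster = rep(1:10, 10))
  expect_equal(risk_ratio_from_model(f0, "(Intercept)")$estimate, 0.5,
               tolerance = 1e-8)
})

test_that("interaction screen flags untestable products and detects real ones", {
  set.seed(58)
  d <- data.frame(y = rbinom(400, 1, 0.3), arm = rep(c(0L, 1L), each = 200),
                  cl = rep(1:40, each = 10))
  d$rf <- d$arm  # risk factor identical to arm: product collinear
  out <- interaction_screen(y ~ arm + rf, d, risk_factor = "rf",
                            cluster = d$cl)
  expect_false(out$testable)
  # power: a strong built-in arm-specific risk-factor effect is found
  hits <- vapply(1:40, function(s) {
    set.seed(800 + s)
    n <- 2400
    cl <- sample(paste0("g", 1:60), n, TRUE)
    arm <- rbinom(n, 1, 0.5)
    rf <- rbinom(n, 1, 0.4)
    p <- 0.18 * exp(log(0.8) * arm + log(1.3) * rf + 0.8 * arm * rf)
    y <- rbinom(n, 1, pmin(p, 0.99))
    dd <- data.frame(y = y, arm = arm, rf = rf, cl = cl)
    interaction_screen(y ~ arm + rf, dd, risk_factor = "rf",
                       cluster = dd$cl)$flag
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
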