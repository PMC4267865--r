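make_design <- function(n = 400, beta = c(0.5, -0.5), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  eta <- X[, 1] * beta[1] + X[, 2] * beta[2]
  d <- as.data.frame(X)
  d$invasive <- rbinom(n, 1, plogis(eta))
  d
}

test_that("nearest-native contrasts follow the stated conventions", {
  sp <- data.frame(
    species = c("al1", "nat1"),
    status = c("invasive alien", "native"),
    alien_group = c("neophyte", NA),
    L = c(5, 5), F = c(6, 4), N = c(7, 5), R = c(5, 5), S = c(0, 0),
    height = c(10, 100), life_form = c("therophyte", "therophyte"),
    clonal = c(0, 1), stringsAsFactors = FALSE)
  rec <- data.frame(species = "al1", pnnd = 12, mpd = 30,
                    nearest_native = "nat1", invasive = TRUE,
                    alien_group = "neophyte")
  des <- trait_contrasts(sp, rec)
  expect_equal(des$d_N, -2)              # native 5 minus alien 7
  expect_equal(des$d_F, -2)
  expect_equal(des$d_L, 0)
  expect_equal(des$d_log_height, log(100) - log(10))
  expect_equal(des$d_life_form, 0)       # same class -> 0
  expect_equal(des$d_clonal, 1)          # different class -> 1
  expect_equal(attr(des, "difference_convention"), "native minus alien")

  # alien identical to its nearest native: all differences zero
  sp2 <- sp
  sp2[1, c("L", "F", "N", "R", "S", "height", "clonal")] <-
    sp2[2, c("L", "F", "N", "R", "S", "height", "clonal")]
  des2 <- trait_contrasts(sp2, rec)
  expect_true(all(abs(unlist(
    des2[c("d_L", "d_F", "d_N", "d_R", "d_S", "d_log_height",
           "d_clonal", "d_life_form")])) < 1e-12))

  # missing nearest-native trait: row excluded and counted
  sp3 <- sp
  sp3$N[2] <- NA
  des3 <- trait_contrasts(sp3, rec)
  expect_equal(nrow(des3), 0)
  expect_equal(attr(des3, "n_excluded"), 1)
})

test_that("binomial GLM recovers closed forms and simulated effects", {
  # intercept-only on a balanced response: logit(0.5) = 0
  d <- data.frame(invasive = rep(c(0, 1), 50))
  f <- fit_binomial_glm(d)
  expect_equal(unname(f$coef["(Intercept)"]), 0, tolerance = 1e-8)

  # lone binary predictor equals the 2x2 log odds ratio
  set.seed(3)
  d2 <- data.frame(x = rbinom(500, 1, 0.4))
  d2$invasive <- rbinom(500, 1, ifelse(d2$x == 1, 0.7, 0.35))
  tab <- table(d2$x, d2$invasive)
  lor <- log(tab["1", "1"] * tab["0", "0"] /
               (tab["1", "0"] * tab["0", "1"]))
  f2 <- fit_binomial_glm(d2, "x")
  expect_equal(unname(f2$coef["x"]), lor, tolerance = 1e-8)

  # consistency at n = 2000
  set.seed(4)
  d3 <- make_design(2000, beta = c(0.5, -0.5), seed = 4)
  f3 <- fit_binomial_glm(d3, c("x1", "x2"))
  se <- sqrt(diag(f3$vcov))
  expect_lt(abs(f3$coef["x1"] - 0.5), 2 * se["x1"])
  expect_lt(abs(f3$coef["x2"] + 0.5), 2 * se["x2"])

  # AICc formula
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46)
  expect_equal(aicc(-100, 3, Inf), 206)  # large-n limit: plain AIC
})

test_that("candidate enumeration counts follow binomial sums", {
  expect_length(enumerate_candidates(paste0("v", 1:3), 5), 8)
  expect_length(enumerate_candidates(paste0("v", 1:6), 2), 22)
  expect_length(enumerate_candidates(paste0("v", 1:17), 5),
                sum(choose(17, 0:5)))
  cand <- enumerate_candidates(c("a", "b"), 2)
  expect_identical(cand,
                   list(character(), "a", "b", c("a", "b")))
})

test_that("model averaging reduces to the identity on one model and
           splits equal weights evenly", {
  d <- make_design(300, seed = 5)
  f1 <- fit_binomial_glm(d, c("x1", "x2"))
  ma1 <- model_average(list(f1))
  expect_equal(
    setNames(ma1$coefficients$estimate, ma1$coefficients$term)[names(f1$coef)],
    f1$coef)
  expect_equal(
    setNames(ma1$coefficients$adjusted_se,
             ma1$coefficients$term)[names(f1$coef)],
    sqrt(diag(f1$vcov)))
  expect_true(all(ma1$coefficients$importance == 1))

  # two models with identical AICc: weights (0.5, 0.5); a variable in
  # only one model is averaged as mean(beta, 0)
  f2 <- f1
  f2$variables <- "x1"
  f2$coef <- f1$coef[c("(Intercept)", "x1")]
  f2$vcov <- f1$vcov[c("(Intercept)", "x1"), c("(Intercept)", "x1")]
  f2$aicc <- f1$aicc
  ma2 <- model_average(list(f1, f2))
  expect_equal(ma2$weights, c(0.5, 0.5))
  x2row <- ma2$coefficients[ma2$coefficients$term == "x2", ]
  expect_equal(x2row$estimate, unname(f1$coef["x2"]) / 2)
  expect_equal(x2row$importance, 0.5)

  # full averaging shrinks towards zero relative to conditional
  ma_cond <- model_average(list(f1, f2), conditional = TRUE)
  x2cond <- ma_cond$coefficients[ma_cond$coefficients$term == "x2", ]
  expect_lt(abs(x2row$estimate), abs(x2cond$estimate))
})

test_that("model-averaged importance separates true from null predictors", {
  d <- make_design(1500, beta = c(0.5, -0.4), seed = 6)
  ma <- invasiveness_model(d, variables = paste0("x", 1:8), max_size = 3)
  co <- ma$coefficients
  imp <- setNames(co$importance, co$term)
  expect_gt(min(imp[c("x1", "x2")]), max(imp[paste0("x", 3:8)]))
  expect_true(all(co$significant[co$term %in% c("x1", "x2")]))
})

test_that("country-scale group model equals the pooled t-test", {
  rec <- data.frame(species = letters[1:6],
                    pnnd = c(4, 5, 6, 5, 6, 7),
                    mpd = c(10, 11, 12, 11, 12, 13),
                    invasive = rep(c(TRUE, FALSE), each = 3))
  out <- country_group_lm(rec)
  tt <- t.test(pnnd ~ invasive, data = rec, var.equal = TRUE)
  expect_equal(out$t[out$response == "pnnd"], unname(-tt$statistic),
               tolerance = 1e-12)
  expect_equal(out$p[out$response == "pnnd"], tt$p.value,
               tolerance = 1e-12)
  expect_equal(out$df2, c(4, 4))

  # identical group means: t = 0, p = 1
  rec2 <- rec
  rec2$pnnd <- rep(c(1, 2, 3), 2)
  out2 <- country_group_lm(rec2, responses = "pnnd")
  expect_equal(out2$t, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1, tolerance = 1e-12)
  expect_error(country_group_lm(rec[1:4, ][rec$invasive[1:4], ]), "group")
})

test_that("nested LMM matches OLS in the zero-variance limit and
           recovers group means", {
  rec <- simulate_lmm_survey(n_species = 30, n_squares = 6,
                             obs_per_square = 4, var_species = 0,
                             var_square = 0, var_res = 25,
                             effect = -10, seed = 7)
  fit <- fit_nested_lmm(rec, "pnnd")
  ols <- lm(pnnd ~ 0 + factor(ifelse(invasive, "invasive",
                                     "non-invasive")), data = rec)
  expect_equal(sort(fit$means$estimate), sort(unname(coef(ols))),
               tolerance = 0.05)
  expect_equal(fit$varcomp$component,
               c("species", "square_in_species", "residual"))
  expect_true(all(fit$varcomp$variance >= 0))

  # balanced design: estimated group means near weighted group means
  gm <- tapply(rec$pnnd, rec$invasive, mean)
  est <- setNames(fit$means$estimate, fit$means$group)
  expect_equal(unname(est["invasive"]), unname(gm["TRUE"]),
               tolerance = 0.5)
  expect_equal(unname(est["non-invasive"]), unname(gm["FALSE"]),
               tolerance = 0.5)
})

test_that("rank-sum test reproduces exact small-sample enumeration", {
  # x entirely above y with n1 = n2 = 3: W at its maximum 9, exact
  # one-sided p = 1 / choose(6, 3) = 0.05
  res <- wilcoxon_rank_sum(c(7, 8, 9), c(1, 2, 3),
                           alternative = "greater")
  expect_equal(res$W, 9)
  expect_equal(res$p, 0.05)
  # identical multisets: two-sided p = 1
  res2 <- wilcoxon_rank_sum(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_gt(res2$p, 0.99)
  # small case matches the brute-force permutation distribution
  x <- c(2.3, 4.1, 6.8)
  y <- c(1.1, 3.9, 5.2, 7.4)
  res3 <- wilcoxon_rank_sum(x, y, alternative = "greater")
  pooled <- c(x, y)
  combos <- combn(7, 3)
  stats <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - 3 * 4 / 2
  })
  expect_equal(res3$p, mean(stats >= res3$W), tolerance = 1e-12)
})
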