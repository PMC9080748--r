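make_morpho <- function(n = 40, seed = 1, sd = 0.02) {
  set.seed(seed)
  svl <- 10^runif(n, 1.2, 1.9)
  data.frame(id = sprintf("i%02d", 1:n),
             sex = rep(c("F", "M"), length.out = n),
             age_class = ifelse(svl >= 40, "adult", "juvenile"),
             svl_cm = svl,
             width50_cm = 0.055 * svl * 10^rnorm(n, 0, sd))
}

test_that("outlier screen flags isolated extreme residuals only", {
  d <- make_morpho(40, seed = 2, sd = 0)
  # exactly collinear: no flags
  expect_length(detect_outliers(d, "width50_cm"), 0)
  d2 <- make_morpho(40, seed = 3, sd = 0.02)
  d2$width50_cm[7] <- d2$width50_cm[7] * 10^0.4  # far off the line
  fl <- detect_outliers(d2, "width50_cm")
  expect_equal(fl, "i07")
  # brute-force oracle: recompute standardized residuals directly
  grp <- d2[d2$age_class == d2$age_class[7], ]
  z <- rstandard(lm(log10(width50_cm) ~ log10(svl_cm) + sex, data = grp))
  zi <- abs(z[grp$id == "i07"])
  expect_gt(zi, 3)
  expect_gt(zi - sort(abs(z), decreasing = TRUE)[2], 1)
  # single-pass screen: nothing left to flag once the outlier is removed
  expect_length(detect_outliers(d2[d2$id != "i07", ], "width50_cm"), 0)
})

test_that("the and/or variants of the outlier rule differ for paired extremes", {
  d <- make_morpho(60, seed = 4, sd = 0.02)
  d$age_class <- "adult"                       # one group for clarity
  base <- log10(0.055) + log10(d$svl_cm)
  d$width50_cm <- 10^(base + rnorm(60, 0, 0.02))
  d$width50_cm[c(5, 6)] <- 10^(base[c(5, 6)] + 0.105 + c(0.004, 0))
  grp_z <- abs(rstandard(lm(log10(width50_cm) ~ log10(svl_cm) + sex, data = d)))
  # preconditions: both extreme (> 3), separated from each other by < 1
  expect_true(all(sort(grp_z, decreasing = TRUE)[1:2] > 3))
  expect_lt(diff(sort(grp_z, decreasing = TRUE)[2:1]), 1)
  expect_length(detect_outliers(d, "width50_cm", rule = "and"), 0)
  expect_equal(sort(detect_outliers(d, "width50_cm", rule = "or")),
               c("i05", "i06"))
})

test_that("AICc reduces to AIC for large n and penalizes extra parameters", {
  set.seed(8)
  n <- 2e5
  x <- rnorm(n); y <- x + rnorm(n)
  f1 <- lm(y ~ x)
  expect_lt(abs(aicc(f1) - AIC(f1)), 1e-3)
  # an uninformative extra parameter cannot beat the smaller model by AICc
  z <- rnorm(50); yy <- rnorm(50)
  m0 <- lm(yy ~ 1); m1 <- lm(yy ~ z)
  expect_lt(aicc(m0), aicc(m1) + 2)
})

test_that("ANCOVA search detects generating predictors", {
  set.seed(15)
  n <- 200
  svl <- 10^runif(n, 1.2, 1.9)
  sex <- sample(rep(c("F", "M"), n / 2))
  d <- data.frame(id = 1:n, sex = sex,
                  age_class = ifelse(svl >= 40, "adult", "juvenile"),
                  svl_cm = svl)
  # pure SVL effect: SVL is always retained and dominates the Type III table
  d$trait <- 0.1 * svl * 10^rnorm(n, 0, 0.04)
  s1 <- ancova_search(d, "trait")
  expect_true("svl" %in% s1$terms)
  expect_lt(s1$type3["svl", "Pr(>F)"], 1e-10)
  # SVL + sex offset (0.2 log-units = 5 residual SDs) is detected
  d$trait2 <- 0.1 * svl * 10^(0.2 * (sex == "M") + rnorm(n, 0, 0.04))
  s2 <- ancova_search(d, "trait2")
  expect_true(all(c("svl", "sex") %in% s2$terms))
  p_sex <- s2$type3["sex", "Pr(>F)"]
  expect_lt(p_sex, 0.01)
  # the richer-within-2 tie rule never returns fewer terms
  s3 <- ancova_search(d, "trait2", tie_rule = "richer_within_2")
  expect_gte(length(s3$terms), length(s2$terms))
})

test_that("RMA slope, symmetry and CI match the closed form", {
  x <- c(1, 2, 3, 4, 5)
  y <- 2 * x
  f <- suppressWarnings(rma_fit(x, y))  # OLS CI on an exact fit warns
  expect_equal(f$slope, 2)
  expect_equal(f$ci, c(2, 2), tolerance = 1e-6)
  set.seed(9)
  xr <- rnorm(50); yr <- 1.3 * xr + rnorm(50, 0, 0.5)
  a <- rma_fit(xr, yr); b <- rma_fit(yr, xr)
  expect_equal(a$slope, 1 / b$slope, tolerance = 1e-12)
  # brute-force formula
  r <- cor(xr, yr)
  expect_equal(a$slope, sign(r) * sd(yr) / sd(xr))
  B <- qt(0.975, 48)^2 * (1 - r^2) / 48
  expect_equal(a$ci, a$slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  expect_error(rma_fit(rep(1, 5), 1:5), "zero variance")
})

test_that("isometry verdicts follow the confidence interval", {
  expect_equal(isometry_test(list(slope = 1.0, ci = c(0.9, 1.1)), 1), "isometric")
  expect_equal(isometry_test(list(slope = 1.17, ci = c(1.05, 1.30)), 1),
               "positive allometry")
  expect_equal(isometry_test(list(slope = 0.8, ci = c(0.7, 0.95)), 1),
               "negative allometry")
  expect_equal(isometry_test(list(slope = 3.05, ci = c(2.8, 3.3)), 3), "isometric")
})

test_that("group tests: ANOVA, Levene (mean-centered), Welch with Satterthwaite df", {
  g <- rep(c("a", "b"), each = 6)
  v <- c(1:6, 1:6)  # identical groups
  out <- aux_tests(v, g)
  expect_equal(out$levene$F, 0)
  expect_equal(out$anova$F, 0)
  expect_equal(out$welch$p, 1)
  set.seed(10)
  x <- c(rnorm(100), rnorm(100, 2))
  gg <- rep(c("a", "b"), each = 100)
  w <- aux_tests(x, gg)
  expect_lt(w$welch$p, 1e-10)
  # Satterthwaite df by hand
  s1 <- var(x[1:100]) / 100; s2 <- var(x[101:200]) / 100
  df_hand <- (s1 + s2)^2 / (s1^2 / 99 + s2^2 / 99)
  expect_equal(w$welch$df, df_hand, tolerance = 1e-9)
  expect_error(aux_tests(1:3, c("a", "a", "b")), "at least 2")
})

test_that("handedness summary reproduces counts, proportions and expectation", {
  trials <- data.frame(
    individual = rep(sprintf("s%02d", 1:10), each = 3),
    handedness = c(rep("left", 30)))
  h <- handedness_summary(trials)
  expect_equal(h$prop_consistent_pct, 100)
  expect_equal(h$expected_pct, 25)
  # mixed cohort: 4 of 10 consistent
  set.seed(1)
  hv <- c(rep(c("left", "left", "left"), 2), rep(c("right", "right", "right"), 2),
          rep(c("left", "right", "left"), 6))
  trials$handedness <- hv
  h2 <- handedness_summary(trials)
  expect_equal(h2$n_individuals, 10)
  expect_equal(h2$n_consistent, 4)
  expect_equal(unname(h2$counts["left"]), sum(hv == "left"))
})
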