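test_that("model specs validate structure and count df correctly", {
  expect_error(path_model_spec(c("a", "b"), paths = c("a -> b", "b -> a")),
               "cycle")
  expect_error(path_model_spec("a", paths = "a -> z"), "unknown")
  spec <- sidewinding_path_spec()
  expect_equal(path_model_df(spec), 2L)
  # df + free parameters = p(p+1)/2 for every menu model
  for (m in sidewinding_path_menu()) {
    p <- length(m$variables)
    nfree <- nrow(m$paths) + nrow(m$covariances) + p
    expect_equal(path_model_df(m) + nfree, p * (p + 1) / 2)
  }
  expect_length(sidewinding_path_menu(), 16)
})

test_that("plain-text model specs round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# demo", "variables: x, y, z", "path: x -> y",
               "path: z -> y", "cov: x ~~ z"), f)
  spec <- read_path_spec(f)
  expect_equal(spec$variables, c("x", "y", "z"))
  expect_equal(nrow(spec$paths), 2)
  expect_equal(path_model_df(spec), 0L)
})

test_that("a single standardized path equals the Pearson correlation", {
  set.seed(3)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  S <- cor(cbind(x = x, y = y))
  f <- fit_path_model(path_model_spec(c("x", "y"), paths = "x -> y"), S, 300)
  expect_true(f$converged)
  expect_equal(f$estimates$estimate[f$estimates$label == "x -> y"],
               S["x", "y"], tolerance = 1e-6)
  expect_equal(f$df, 0L)
  expect_lt(f$chi_square, 1e-6)
})

test_that("just-identified models reproduce the sample covariance exactly", {
  set.seed(4)
  X <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] + X[, 2]
  X[, 3] <- 0.5 * X[, 2] + X[, 3]
  S <- cov(X)
  spec <- path_model_spec(c("a", "b", "c"),
                          paths = c("a -> b", "b -> c"),
                          covariances = "a ~~ c")
  expect_equal(path_model_df(spec), 0L)
  f <- fit_path_model(spec, S, 300)
  m <- sidewindr:::path_theta_to_matrices(f$theta, spec, f$idx)
  Sigma <- sidewindr:::implied_sigma(m$A, m$Sres)
  expect_lt(max(abs(Sigma - S)), 1e-6)
  expect_lt(f$chi_square, 1e-6)
})

test_that("saturated two-variable model fits perfectly", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  f <- fit_path_model(path_model_spec(c("x", "y"), covariances = "x ~~ y"),
                      S, 100)
  expect_equal(f$df, 0L)
  expect_lt(f$chi_square, 1e-8)
})

test_that("fitting a correlation matrix equals fitting standardized data", {
  truth <- fig_truth_sigma()
  set.seed(21)
  X <- MASS::mvrnorm(400, rep(0, 7), truth$Sigma)
  colnames(X) <- truth$spec$variables
  f_cor <- fit_path_model(truth$spec, cor(X), 400)
  Z <- scale(X)
  f_cov <- fit_path_model(truth$spec, cov(Z), 400)
  expect_equal(f_cor$estimates$estimate, f_cov$estimates$estimate,
               tolerance = 1e-5)
})

test_that("RMSEA follows its closed form", {
  expect_equal(rmsea(2, 2, 26), 0)
  expect_equal(rmsea(1.148, 2, 26), 0)
  expect_equal(rmsea(6, 2, 26), sqrt(4 / 50))
  expect_error(rmsea(5, 0, 26), "df")
})

test_that("path likelihood ratio tests behave as nested tests", {
  truth <- fig_truth_sigma()
  set.seed(31)
  X <- MASS::mvrnorm(500, rep(0, 7), truth$Sigma)
  colnames(X) <- truth$spec$variables
  f <- fit_path_model(truth$spec, cor(X), 500)
  strong <- lrt_path(f, "frequency -> speed")
  expect_gte(strong$chi_square_diff, 0)
  expect_lt(strong$p_value, 1e-6)
  null_path <- lrt_path(f, "skew -> speed")
  expect_gte(null_path$chi_square_diff, 0)
  expect_gt(null_path$p_value, 0.001)
})

test_that("the model menu rejects misfit and selects the generating model", {
  truth <- fig_truth_sigma()
  set.seed(41)
  X <- MASS::mvrnorm(500, rep(0, 7), truth$Sigma)
  colnames(X) <- truth$spec$variables
  # a rival model without the dominant frequency -> speed path
  paths2 <- truth$spec$paths
  paths2 <- paths2[!(paths2[, 1] == "frequency"), , drop = FALSE]
  rival <- path_model_spec(truth$spec$variables, paths = paths2,
                           covariances = default_path_covariances(
                             truth$spec$variables, paths2))
  res <- model_menu_search(list(true_model = truth$spec, no_freq = rival),
                           cor(X), 500)
  expect_equal(res$selected, "true_model")
  expect_true(res$table$rejected[res$table$model == "no_freq"])
})

test_that("residualization is orthogonal to its covariates", {
  set.seed(51)
  n <- 120
  svl <- 10^runif(n, 1.2, 1.9)
  d <- data.frame(svl_cm = svl, sex = sample(c("F", "M"), n, TRUE),
                  age_class = "adult")
  d$exact <- svl^2                        # log10 exact = 2 log10 svl
  # exactly orthogonal to log SVL: residuals must equal the centered values
  d$free <- 10^residuals(lm(rnorm(n) ~ log10(svl)))
  d$allo <- svl^1.2 * 10^rnorm(n, 0, 0.05)
  r <- residualize(d, c("exact", "free", "allo"))
  expect_lt(max(abs(r$exact)), 1e-10)
  expect_equal(r$free, log10(d$free) - mean(log10(d$free)), tolerance = 1e-9)
  expect_lt(abs(cor(r$allo, log10(svl))), 1e-10)
  expect_error(residualize(transform(d, k = 1), "k"), "constant")
})

test_that("pearson matrix handles signs and sampling error", {
  set.seed(61)
  x <- rnorm(5000)
  z <- 0.6 * x + sqrt(1 - 0.36) * rnorm(5000)
  pm <- pearson_matrix(data.frame(x = x, neg = -x, z = z))
  expect_equal(pm$r["x", "x"], 1)
  expect_equal(pm$r["x", "neg"], -1)
  expect_lt(abs(pm$r["x", "z"] - 0.6), 0.03)
  expect_lt(pm$p["x", "z"], 1e-10)
})

test_that("the bundled model-spec file matches the default model", {
  f <- system.file("extdata", "speed_path_model.txt", package = "sidewindr")
  spec <- read_path_spec(f)
  ref <- sidewinding_path_spec()
  expect_identical(spec$variables, ref$variables)
  expect_identical(spec$paths, ref$paths)
  expect_equal(path_model_df(spec), 2L)
})
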