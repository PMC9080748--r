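#' Specify an observed-variable path model
#'
#' A path model over p observed variables consists of directed paths (one-way
#' arrows, regression coefficients), free covariances between variable
#' residuals (two-way arrows), and a free (residual) variance for every
#' variable. Covariances not listed and not implied by paths are fixed to
#' zero. The directed graph must be acyclic.
#'
#' @param variables Character vector of variable names (at most 12).
#' @param paths Two-column matrix or data frame (from, to), or character
#'   vector like `"a -> b"`.
#' @param covariances Optional two-column matrix/data frame of unordered
#'   pairs, or character vector like `"a ~~ b"`.
#' @return A list of class `path_model_spec`.
#' @export
path_model_spec <- function(variables, paths = NULL, covariances = NULL) {
  parse_pairs <- function(x, sep) {
    if (is.null(x) || (is.matrix(x) && nrow(x) == 0)) {
      return(matrix(character(0), 0, 2))
    }
    if (is.matrix(x) || is.data.frame(x)) return(as.matrix(x))
    if (is.character(x)) {
      parts <- strsplit(gsub("\\s+", "", x), sep)
      bad <- lengths(parts) != 2
      if (any(bad)) stop("cannot parse: ", paste(x[bad], collapse = ", "))
      return(do.call(rbind, parts))
    }
    as.matrix(x)
  }
  paths <- parse_pairs(paths, "->")
  covariances <- parse_pairs(covariances, "~~")
  all_named <- unique(c(paths, covariances))
  if (!all(all_named %in% variables)) {
    stop("unknown variables in paths/covariances: ",
         paste(setdiff(all_named, variables), collapse = ", "))
  }
  if (anyDuplicated(variables)) stop("duplicated variable names")
  # acyclicity via repeated leaf removal
  if (nrow(paths)) {
    g <- paths
    repeat {
      sinks <- setdiff(unique(c(g)), g[, 1])
      if (!length(sinks)) {
        if (nrow(g)) stop("directed paths contain a cycle")
        break
      }
      g <- g[!(g[, 2] %in% sinks), , drop = FALSE]
      if (!nrow(g)) break
    }
  }
  structure(list(variables = variables,
                 paths = paths, covariances = covariances),
            class = "path_model_spec")
}

#' Read a path model specification from a plain-text file
#'
#' Format: a `variables:` line (comma- or space-separated), then lines
#' `path: a -> b` and `cov: a ~~ b` (the prefixes are optional; bare
#' `a -> b` / `a ~~ b` lines work). Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A [path_model_spec()].
#' @export
read_path_spec <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[ln != "" & !startsWith(ln, "#")]
  vars <- character(0); paths <- character(0); covs <- character(0)
  for (l in ln) {
    l <- sub("^(variables|path|cov|covariance)s?:\\s*", "", l)
    if (grepl("->", l, fixed = TRUE)) paths <- c(paths, l)
    else if (grepl("~~", l, fixed = TRUE)) covs <- c(covs, l)
    else vars <- c(vars, strsplit(l, "[,[:space:]]+")[[1]])
  }
  path_model_spec(vars[vars != ""], paths = if (length(paths)) paths,
                  covariances = if (length(covs)) covs)
}

#' Degrees of freedom of a path model
#'
#' Non-redundant covariance moments `p(p+1)/2` minus free parameters (paths +
#' free covariances + one variance per variable).
#'
#' @param spec A [path_model_spec()].
#' @return Integer degrees of freedom.
#' @export
path_model_df <- function(spec) {
  p <- length(spec$variables)
  n_free <- nrow(spec$paths) + nrow(spec$covariances) + p
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model has more free parameters (", n_free,
                   ") than covariance moments (", p * (p + 1) / 2, ")")
  as.integer(df)
}

# model-implied covariance: Sigma = (I - A)^-1 S_res (I - A)^-T
implied_sigma <- function(A, Sres) {
  p <- nrow(A)
  IA <- diag(p) - A
  Binv <- solve(IA)
  Binv %*% Sres %*% t(Binv)
}

# pack/unpack parameter vector <-> (A, Sres)
path_par_index <- function(spec) {
  v <- spec$variables
  p <- length(v)
  idx <- list()
  k <- 0L
  for (i in seq_len(nrow(spec$paths))) {
    k <- k + 1L
    idx[[k]] <- list(type = "path", from = match(spec$paths[i, 1], v),
                     to = match(spec$paths[i, 2], v),
                     label = paste(spec$paths[i, 1], "->", spec$paths[i, 2]))
  }
  for (i in seq_len(nrow(spec$covariances))) {
    k <- k + 1L
    idx[[k]] <- list(type = "cov", a = match(spec$covariances[i, 1], v),
                     b = match(spec$covariances[i, 2], v),
                     label = paste(spec$covariances[i, 1], "~~", spec$covariances[i, 2]))
  }
  for (i in seq_len(p)) {
    k <- k + 1L
    idx[[k]] <- list(type = "var", a = i, label = paste(v[i], "~~", v[i]))
  }
  idx
}

path_theta_to_matrices <- function(theta, spec, idx) {
  p <- length(spec$variables)
  A <- matrix(0, p, p)
  Sres <- matrix(0, p, p)
  for (k in seq_along(idx)) {
    e <- idx[[k]]
    if (e$type == "path") A[e$to, e$from] <- theta[k]
    else if (e$type == "cov") { Sres[e$a, e$b] <- theta[k]; Sres[e$b, e$a] <- theta[k] }
    else Sres[e$a, e$a] <- theta[k]
  }
  list(A = A, Sres = Sres)
}

# ML discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p
path_discrepancy <- function(theta, spec, idx, S, logdetS) {
  m <- path_theta_to_matrices(theta, spec, idx)
  Sigma <- try(implied_sigma(m$A, m$Sres), silent = TRUE)
  if (inherits(Sigma, "try-error")) return(1e10)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 1e-10)) return(1e10)
  ld <- sum(log(ev))
  tr <- sum(diag(solve(Sigma, S)))
  ld + tr - logdetS - nrow(S)
}

#' Fit a path model by maximum likelihood on a covariance matrix
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p` over the free paths,
#' covariances and variances, with `Sigma(theta)` the covariance implied by
#' the acyclic path structure. The lack-of-fit statistic is
#' `chi^2 = (n - 1) F` at the optimum, with `df = p(p+1)/2 - n_free`;
#' standard errors come from the inverse observed information. Quasi-Newton
#' optimization starts from sample moments and identity-scaled residuals,
#' with seeded jittered restarts as a guard against local minima.
#'
#' @param spec A [path_model_spec()].
#' @param S Sample covariance (or correlation) matrix with dimnames matching
#'   the spec's variables.
#' @param n Number of observations behind `S` (complete cases).
#' @param restarts Number of jittered restarts (default 10).
#' @param seed Seed for the restart jitter (default 1).
#' @return A list of class `path_fit`: `estimates` (data frame with label,
#'   estimate, se), `chi_square`, `df`, `p_value`, `rmsea`, `aicc`,
#'   `converged`, `n`, plus internals (`theta`, `spec`, `S`).
#' @export
fit_path_model <- function(spec, S, n, restarts = 10L, seed = 1L) {
  stopifnot(inherits(spec, "path_model_spec"))
  v <- spec$variables
  if (is.null(dimnames(S)) || !all(v %in% rownames(S))) {
    stop("S must have dimnames covering the model variables")
  }
  S <- S[v, v]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("S is not positive definite")
  df <- path_model_df(spec)
  idx <- path_par_index(spec)
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  # start values: regression coefficients from S, sample covariances, full
  # variances scaled down for endogenous variables
  start <- vapply(idx, function(e) {
    if (e$type == "path") S[e$to, e$from] / S[e$from, e$from]
    else if (e$type == "cov") S[e$a, e$b]
    else S[e$a, e$a] * 0.8
  }, numeric(1))
  obj <- function(th) path_discrepancy(th, spec, idx, S, logdetS)
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (r in seq_len(max(1L, restarts))) {
    th0 <- if (r == 1) start else start * stats::runif(length(start), 0.6, 1.4) +
      stats::rnorm(length(start), 0, 0.05)
    opt <- try(stats::optim(th0, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, spec = spec, n = n), class = "path_fit"))
  }
  # polish with a finer finite-difference step: the default ndeps leaves
  # gradient truncation error ~1e-6 in the parameters near flat optima
  for (pol in 1:4) {
    opt <- try(stats::optim(best$par, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-16,
                                           ndeps = rep(1e-6, length(best$par)))),
               silent = TRUE)
    if (inherits(opt, "try-error")) break
    if (opt$value <= best$value) best <- opt
    if (pol > 1 && opt$value >= best$value - 1e-15) break
  }
  theta <- best$par
  Fmin <- max(0, best$value)
  chi2 <- (n - 1) * Fmin
  # observed information: (n-1)/2 x Hessian of F
  H <- stats::optimHess(theta, obj)
  info <- (n - 1) / 2 * H
  se <- rep(NA_real_, length(theta))
  eg <- eigen(info, symmetric = TRUE)
  if (all(eg$values > max(abs(eg$values)) * 1e-10)) {
    cv <- eg$vectors %*% (t(eg$vectors) / eg$values)
    se <- sqrt(pmax(diag(cv), 0))
  }  # singular information: SEs stay NA rather than silently wrong
  k <- length(theta)
  est <- data.frame(label = vapply(idx, `[[`, character(1), "label"),
                    type = vapply(idx, `[[`, character(1), "type"),
                    estimate = theta, se = se)
  structure(list(
    estimates = est, chi_square = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    rmsea = if (df > 0) rmsea(chi2, df, n) else NA_real_,
    aic = chi2 + 2 * k,
    aicc = if (n - k - 1 > 0) chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1) else Inf,
    converged = best$convergence == 0, n = n, theta = theta, spec = spec,
    S = S, idx = idx, Fmin = Fmin), class = "path_fit")
}

#' Root mean square error of approximation
#'
#' `RMSEA = sqrt(max(chi^2 - df, 0) / (df (n - 1)))`; zero indicates
#' perfect-or-better fit per degree of freedom.
#'
#' @param chi_square Lack-of-fit chi-square statistic.
#' @param df Model degrees of freedom (>= 1).
#' @param n Sample size (>= 2).
#' @return RMSEA value.
#' @export
rmsea <- function(chi_square, df, n) {
  if (df < 1) stop("RMSEA undefined for df < 1")
  if (n < 2) stop("RMSEA requires n >= 2")
  sqrt(max(chi_square - df, 0) / (df * (n - 1)))
}

#' Likelihood ratio test for a single path
#'
#' Refits the model with one directed path fixed to zero and compares fits:
#' `chi^2_diff = chi^2_restricted - chi^2_full` on 1 df.
#'
#' @param fit A converged [fit_path_model()] result.
#' @param path Path label, e.g. `"frequency -> speed"` (spacing flexible).
#' @param restarts,seed Passed to the restricted refit.
#' @return List with `chi_square_diff`, `p_value`, and the restricted fit.
#' @export
lrt_path <- function(fit, path, restarts = 10L, seed = 1L) {
  stopifnot(inherits(fit, "path_fit"), isTRUE(fit$converged))
  spec <- fit$spec
  key <- gsub("\\s+", "", path)
  have <- paste0(spec$paths[, 1], "->", spec$paths[, 2])
  i <- match(key, have)
  if (is.na(i)) stop("path '", path, "' is not in the model")
  rspec <- path_model_spec(spec$variables, paths = spec$paths[-i, , drop = FALSE],
                           covariances = spec$covariances)
  rfit <- fit_path_model(rspec, fit$S, fit$n, restarts = restarts, seed = seed)
  if (!isTRUE(rfit$converged)) {
    return(list(chi_square_diff = NA_real_, p_value = NA_real_,
                restricted = rfit, converged = FALSE))
  }
  d <- max(0, rfit$chi_square - fit$chi_square)
  list(chi_square_diff = d, p_value = stats::pchisq(d, 1, lower.tail = FALSE),
       restricted = rfit, converged = TRUE)
}

#' Compare a menu of candidate path models
#'
#' Fits every candidate, rejects models with significant lack of fit
#' (chi-square p < `alpha`), ranks survivors by RMSEA (ascending) with ties
#' broken by AICc, and returns the ranked table plus the selected model.
#'
#' @param menu Named list of [path_model_spec()]s.
#' @param S Covariance/correlation matrix (or named list of matrices, one per
#'   model, when the models use different complete-case sets).
#' @param n Sample size (or named/positional vector, one per model).
#' @param alpha Lack-of-fit rejection level (default 0.05).
#' @param restarts,seed Passed to [fit_path_model()].
#' @return List of class `path_menu`: `table` (model, df, chi_square, p,
#'   rmsea, aicc, rejected), `selected` (name or `NA`), `fits`.
#' @export
model_menu_search <- function(menu, S, n, alpha = 0.05, restarts = 10L,
                              seed = 1L) {
  stopifnot(length(menu) >= 1)
  if (is.null(names(menu))) names(menu) <- paste0("model", seq_along(menu))
  Slist <- if (is.matrix(S)) rep(list(S), length(menu)) else S
  nvec <- if (length(n) == 1) rep(n, length(menu)) else n
  fits <- list(); rows <- list()
  for (i in seq_along(menu)) {
    f <- fit_path_model(menu[[i]], Slist[[i]], nvec[i], restarts = restarts,
                        seed = seed)
    fits[[names(menu)[i]]] <- f
    rows[[i]] <- data.frame(
      model = names(menu)[i],
      df = if (isTRUE(f$converged)) f$df else NA_integer_,
      chi_square = if (isTRUE(f$converged)) f$chi_square else NA_real_,
      p_value = if (isTRUE(f$converged)) f$p_value else NA_real_,
      rmsea = if (isTRUE(f$converged)) f$rmsea else NA_real_,
      aic = if (isTRUE(f$converged)) f$aic else NA_real_,
      aicc = if (isTRUE(f$converged)) f$aicc else NA_real_,
      converged = isTRUE(f$converged))
  }
  tab <- do.call(rbind, rows)
  tab$rejected <- !tab$converged | (!is.na(tab$p_value) & tab$p_value < alpha)
  surv <- tab[!tab$rejected, , drop = FALSE]
  selected <- NA_character_
  if (nrow(surv)) {
    # the small-sample AICc correction is undefined when n <= k + 1; fall
    # back to AIC for the tie-break if any survivor is affected
    crit <- if (any(!is.finite(surv$aicc))) surv$aic else surv$aicc
    surv <- surv[order(surv$rmsea, crit), ]
    selected <- surv$model[1]
  }
  structure(list(table = tab, selected = selected, fits = fits),
            class = "path_menu")
}

#' Residualize variables on log SVL (and sex/age where indicated)
#'
#' For each variable: optionally log10-transform (skew angle stays signed and
#' untransformed), then regress on log10 SVL plus any of sex/age the
#' variable's best ANCOVA model retained, and return the residuals aligned by
#' individual. Rows with missing values yield `NA` residuals for that
#' variable; previously flagged outliers should be removed beforehand.
#'
#' @param data Data frame with `svl_cm`, `sex`, `age_class` and the variables.
#' @param variables Character vector of variable column names.
#' @param log_transform Logical vector (recycled) — log10 the variable?
#' @param covariates Named list: for each variable, a character subset of
#'   `c("sex", "age")` to include alongside log SVL (default none).
#' @return Data frame of residuals, same rows as `data`.
#' @export
residualize <- function(data, variables, log_transform = TRUE,
                        covariates = list()) {
  log_transform <- rep_len(log_transform, length(variables))
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (i in seq_along(variables)) {
    v <- variables[i]
    y <- data[[v]]
    if (is.null(y)) stop("variable '", v, "' not found")
    if (log_transform[i]) y <- log10(y)
    df <- data.frame(y = y, svl = log10(data$svl_cm))
    co <- covariates[[v]]
    if (!is.null(co) && "sex" %in% co) df$sex <- factor(data$sex)
    if (!is.null(co) && "age" %in% co) df$age <- factor(data$age_class)
    ok <- stats::complete.cases(df)
    if (stats::var(df$y[ok]) == 0) stop("variable '", v, "' is constant")
    fit <- stats::lm(y ~ ., data = df[ok, , drop = FALSE])
    res <- rep(NA_real_, nrow(data))
    res[ok] <- stats::residuals(fit)
    out[[v]] <- res
  }
  out
}

#' Pairwise Pearson correlations with tests
#'
#' @param data Data frame of numeric variables (typically residuals).
#' @return List with matrices `r`, `p` and `n` (pairwise complete).
#' @export
pearson_matrix <- function(data) {
  v <- names(data)
  p <- length(v)
  r <- pv <- nn <- matrix(NA_real_, p, p, dimnames = list(v, v))
  diag(r) <- 1; diag(pv) <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(data[[i]], data[[j]])
    nn[i, j] <- nn[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    if (stats::sd(data[[i]][ok]) == 0 || stats::sd(data[[j]][ok]) == 0) next
    ct <- stats::cor.test(data[[i]][ok], data[[j]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  diag(nn) <- vapply(data, function(x) sum(!is.na(x)), numeric(1))
  list(r = r, p = pv, n = nn)
}
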