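#' Flag outliers from standardized residuals of log-log regressions
#'
#' Within each age group, log10(trait) is regressed on log10(SVL) plus sex;
#' an individual is flagged when its standardized residual exceeds
#' `threshold` in magnitude and (default rule) is separated from the
#' next-most-extreme standardized residual by more than `gap` standard
#' deviations. Flagged individuals should be excluded from all later analyses
#' of that trait; the screen is applied once (a second pass on the cleaned
#' data is not part of the procedure).
#'
#' @param data Data frame with the trait, `svl_cm`, `sex` and `age_class`.
#' @param trait Name of the trait column.
#' @param threshold Standardized-residual magnitude cutoff (default 3).
#' @param gap Required separation (in SD units) from the next value
#'   (default 1).
#' @param rule `"and"` (both conditions, default) or `"or"` (either).
#' @return Character vector of flagged `id`s (possibly empty).
#' @export
detect_outliers <- function(data, trait, threshold = 3, gap = 1,
                            rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(all(c(trait, "id", "svl_cm", "sex", "age_class") %in% names(data)))
  flagged <- character(0)
  for (ag in unique(data$age_class)) {
    sub <- data[data$age_class == ag & !is.na(data[[trait]]), ]
    if (nrow(sub) < 4) stop("need at least 4 individuals per age group, got ",
                            nrow(sub), " for ", ag)
    y <- log10(sub[[trait]])
    x <- log10(sub$svl_cm)
    fml <- if (length(unique(sub$sex)) > 1) y ~ x + sex else y ~ x
    fit <- stats::lm(fml, data = data.frame(y = y, x = x, sex = sub$sex))
    if (any(!is.finite(stats::coef(fit)))) stop("singular design in outlier screen")
    if (stats::sigma(fit) < 1e-10 * max(abs(y), 1)) next  # exact fit: no outliers
    z <- stats::rstandard(fit)
    o <- order(abs(z), decreasing = TRUE)
    for (r in seq_along(o)) {
      i <- o[r]
      extreme <- abs(z[i]) > threshold
      nxt <- if (r < length(o)) abs(z[o[r + 1]]) else 0
      separated <- (abs(z[i]) - nxt) > gap
      hit <- if (rule == "and") extreme && separated else extreme || separated
      if (hit) flagged <- c(flagged, sub$id[i]) else break
    }
  }
  unique(flagged)
}

# all marginality-respecting submodels of a factorial term set: a term may be
# included only if all lower-order terms it contains are included
marginality_lattice <- function(terms) {
  contains <- function(t1, t2) all(strsplit(t2, ":")[[1]] %in% strsplit(t1, ":")[[1]])
  n <- length(terms)
  keep <- list()
  for (mask in 0:(2^n - 1)) {
    inc <- terms[bitwAnd(bitwShiftR(mask, seq_len(n) - 1), 1L) == 1L]
    ok <- TRUE
    for (t1 in inc) {
      lower <- terms[vapply(terms, function(t2) t2 != t1 && contains(t1, t2), logical(1))]
      if (!all(lower %in% inc)) { ok <- FALSE; break }
    }
    if (ok) keep[[length(keep) + 1]] <- inc
  }
  keep
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `k` the number of estimated
#' parameters including the residual variance.
#'
#' @param fit A fitted model with `logLik` method.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' ANCOVA model search ranked by AICc
#'
#' Fits the full factorial ANCOVA (e.g. `SVL + sex + age + SVL:sex + SVL:age +
#' sex:age + SVL:sex:age`) and every marginality-respecting submodel
#' (interactions are dropped before the main effects they contain), ranks them
#' by AICc, and reports Type III F tests (sum-to-zero contrasts) for the
#' selected model. Body temperature can be added as a covariate, without
#' interactions. With `tie_rule = "best"` (default) the lowest-AICc model is
#' selected; `tie_rule = "richer_within_2"` instead selects, among models
#' within 2 AICc units of the best, the one with the most predictors (useful
#' for a more granular view of group-specific scaling, at the cost of
#' admitting weakly supported terms).
#'
#' @param data Data frame.
#' @param trait Response column name (log10-transformed unless `log = FALSE`).
#' @param predictors Character vector among `"svl"`, `"sex"`, `"age"`
#'   (factorial part; default all three).
#' @param temperature Name of an optional temperature column to include as an
#'   additive covariate (`NULL` to omit).
#' @param log Log10-transform the response (default `TRUE`).
#' @param tie_rule `"best"` or `"richer_within_2"`.
#' @return A list of class `ancova_search`: `table` (one row per model:
#'   formula, k, AICc, delta), `best` (the selected fitted model), `terms`
#'   (its predictor terms), and `type3` (car Type III ANOVA of the selected
#'   model, `NULL` for the intercept-only model).
#' @export
ancova_search <- function(data, trait, predictors = c("svl", "sex", "age"),
                          temperature = NULL, log = TRUE,
                          tie_rule = c("best", "richer_within_2")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(trait %in% names(data))
  df <- data.frame(y = if (log) log10(data[[trait]]) else data[[trait]])
  vars <- character(0)
  if ("svl" %in% predictors) { df$svl <- log10(data$svl_cm); vars <- c(vars, "svl") }
  if ("sex" %in% predictors) { df$sex <- factor(data$sex); vars <- c(vars, "sex") }
  if ("age" %in% predictors) { df$age <- factor(data$age_class); vars <- c(vars, "age") }
  if (!is.null(temperature)) df$temp <- data[[temperature]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  full_terms <- unlist(lapply(seq_along(vars), function(k) {
    utils::combn(vars, k, paste, collapse = ":")
  }))
  models <- marginality_lattice(full_terms)
  if (!is.null(temperature)) {
    # temperature enters additively (no interactions considered)
    models <- c(models, lapply(models, function(m) c(m, "temp")))
  }
  rows <- list(); fits <- list()
  for (i in seq_along(models)) {
    trm <- models[[i]]
    fml <- stats::as.formula(paste("y ~", if (length(trm)) paste(trm, collapse = " + ") else "1"))
    k <- length(trm) + 2  # rough parameter count guard before fitting
    if (nrow(df) <= k + 1) {
      warning("skipping model with ", length(trm), " terms: too few observations")
      next
    }
    fit <- stats::lm(fml, data = df,
                     contrasts = sex_age_contrasts(df, trm))
    a <- aicc(fit)
    rows[[length(rows) + 1]] <- data.frame(
      model = paste(if (length(trm)) trm else "1", collapse = " + "),
      n_terms = length(trm), k = attr(stats::logLik(fit), "df"), aicc = a)
    fits[[length(fits) + 1]] <- list(fit = fit, terms = trm)
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$aicc - min(tab$aicc)
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  pick <- 1L
  if (tie_rule == "richer_within_2") {
    within <- which(tab$delta <= 2)
    pick <- within[which.max(tab$n_terms[within])]
  }
  best <- fits[[pick]]
  type3 <- NULL
  if (length(best$terms)) {
    type3 <- car::Anova(best$fit, type = "III")
  }
  structure(list(table = tab, best = best$fit, terms = best$terms,
                 type3 = type3, n = nrow(df)),
            class = "ancova_search")
}

# sum-to-zero contrasts for any factor among the model terms (required for
# meaningful Type III sums of squares)
sex_age_contrasts <- function(df, trm) {
  fac <- intersect(c("sex", "age"), unlist(strsplit(trm, ":")))
  fac <- fac[vapply(fac, function(v) is.factor(df[[v]]), logical(1))]
  if (!length(fac)) return(NULL)
  stats::setNames(lapply(fac, function(v) "contr.sum"), fac)
}

#' Reduced major axis (RMA) regression with confidence intervals
#'
#' RMA (standardized major axis) slope `sign(r) * sd(y) / sd(x)` with
#' intercept through the means and the standard 95% CI: with
#' `B = t^2 (1 - r^2) / (n - 2)`, the CI is `slope * (sqrt(B + 1) +/- sqrt(B))`.
#' Appropriate when both variables carry error, as in allometric scaling.
#'
#' @param x,y Numeric vectors (typically log10 SVL and log10 trait).
#' @param conf Confidence level (default 0.95).
#' @return List of class `rma_fit`: `slope`, `intercept`, `ci` (length 2),
#'   `ols_slope`, `ols_ci`, `r`, `n`.
#' @export
rma_fit <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: a variable has zero variance")
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 2)
  B <- tq^2 * (1 - r^2) / (n - 2)
  ci <- slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
  if (slope < 0) ci <- rev(ci)
  ols <- stats::lm(y ~ x)
  ols_ci <- stats::confint(ols, "x", level = conf)
  structure(list(slope = slope, intercept = intercept, ci = ci,
                 ols_slope = unname(stats::coef(ols)[2]),
                 ols_ci = as.numeric(ols_ci), r = r, n = n),
            class = "rma_fit")
}

#' Isometry verdict for a scaling fit
#'
#' Under geometric similarity the expected log-log slope is 1 for linear
#' measurements and 3 for mass. A trait is isometric when the expected value
#' lies inside the slope's confidence interval, otherwise positively or
#' negatively allometric according to the side.
#'
#' @param fit An [rma_fit()] (or any list with `slope` and `ci`).
#' @param expected Expected slope under isometry (1 or 3).
#' @return `"isometric"`, `"positive allometry"` or `"negative allometry"`.
#' @export
isometry_test <- function(fit, expected = 1) {
  if (expected >= fit$ci[1] && expected <= fit$ci[2]) return("isometric")
  if (fit$slope > expected) "positive allometry" else "negative allometry"
}

#' Scaling analysis of one trait
#'
#' Runs the AICc ANCOVA search, splits the sample into the groups suggested
#' by the selected model (by sex and/or age when those factors are retained),
#' and fits RMA and OLS slopes with isometry verdicts per group.
#'
#' @param data Morphometrics or kinematics data frame (`svl_cm`, `sex`,
#'   `age_class`, trait column; outliers already removed).
#' @param trait Trait column name.
#' @param expected Expected isometric slope (1 linear, 3 mass).
#' @param ... Passed to [ancova_search()].
#' @return List of class `scaling_fit`: the search result, the grouping used
#'   and a data frame `groups` with per-group slopes, CIs and verdicts.
#' @export
scaling_fit <- function(data, trait, expected = 1, ...) {
  search <- ancova_search(data, trait, ...)
  split_vars <- character(0)
  flat <- unlist(strsplit(search$terms, ":"))
  if ("sex" %in% flat) split_vars <- c(split_vars, "sex")
  if ("age" %in% flat) split_vars <- c(split_vars, "age_class")
  groups <- if (length(split_vars)) {
    interaction(data[split_vars], drop = TRUE, sep = "/")
  } else {
    factor(rep("all", nrow(data)))
  }
  rows <- list()
  for (g in levels(groups)) {
    sub <- data[groups == g & !is.na(data[[trait]]), ]
    if (nrow(sub) < 3) next
    fit <- rma_fit(log10(sub$svl_cm), log10(sub[[trait]]))
    rows[[length(rows) + 1]] <- data.frame(
      trait = trait, group = g, n = fit$n,
      rma_slope = fit$slope, rma_lo = fit$ci[1], rma_hi = fit$ci[2],
      ols_slope = fit$ols_slope, ols_lo = fit$ols_ci[1], ols_hi = fit$ols_ci[2],
      expected = expected,
      verdict = isometry_test(fit, expected))
  }
  structure(list(search = search, split_vars = split_vars,
                 groups = do.call(rbind, rows)),
            class = "scaling_fit")
}

#' Group-comparison tests used alongside the scaling analysis
#'
#' One-way ANOVA, Levene's test for homogeneity of variance (centered on the
#' group means) and Welch's t-test with Satterthwaite degrees of freedom for
#' a numeric response across groups.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (2+ levels; Welch's t only for 2).
#' @return List with `anova` (F, df, p), `levene` (F, df, p) and, for two
#'   groups, `welch` (t, df, p).
#' @export
aux_tests <- function(values, group) {
  group <- factor(group)
  if (any(table(group) < 2)) stop("every group needs at least 2 observations")
  a <- stats::anova(stats::lm(values ~ group))
  lv <- car::leveneTest(values, group, center = mean)
  out <- list(
    anova = list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1]),
    levene = list(F = lv$`F value`[1], df = c(lv$Df[1], lv$Df[2]),
                  p = lv$`Pr(>F)`[1]))
  if (nlevels(group) == 2) {
    tw <- stats::t.test(values ~ group)
    out$welch <- list(t = unname(tw$statistic), df = unname(tw$parameter),
                      p = tw$p.value)
  }
  out
}

#' Handedness summary of scored sidewinding trials
#'
#' Counts trials by handedness, and for individuals with exactly `k_trials`
#' scored left/right trials reports how many used the same handedness
#' throughout, with the analytic expectation under independent fair-coin
#' handedness, `2 * (1/2)^k` (25% for three trials).
#'
#' @param trials Data frame with columns `individual` and `handedness`
#'   (`"left"`, `"right"`, or `"switched"`).
#' @param k_trials Number of scored trials defining the consistency cohort
#'   (default 3).
#' @return List: `counts` (table over handedness categories), `n_individuals`
#'   (with exactly `k_trials` scored trials), `n_consistent`,
#'   `prop_consistent_pct`, `expected_pct`.
#' @export
handedness_summary <- function(trials, k_trials = 3L) {
  stopifnot(all(c("individual", "handedness") %in% names(trials)))
  counts <- table(factor(trials$handedness,
                         levels = c("left", "right", "switched")))
  scored <- trials[trials$handedness %in% c("left", "right"), ]
  per <- table(scored$individual)
  cohort <- names(per)[per == k_trials]
  consistent <- vapply(cohort, function(id) {
    h <- scored$handedness[scored$individual == id]
    length(unique(h)) == 1
  }, logical(1))
  list(counts = counts,
       n_individuals = length(cohort),
       n_consistent = sum(consistent),
       prop_consistent_pct = if (length(cohort)) 100 * sum(consistent) / length(cohort) else NA_real_,
       expected_pct = 100 * 2 * 0.5^k_trials)
}
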