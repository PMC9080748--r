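#' Configuration for the synthetic morphometrics generator
#'
#' Morphometric traits are generated from a power-law (allometric) model,
#' `trait = a * SVL^b * 10^(sex + age + e)`, with log10-scale sex/age offsets
#' and residual noise. Exponents default to isometry (b = 1 for linear
#' measurements, b = 3 for mass). Meristic traits (scale counts) are drawn
#' from discrete distributions independent of SVL, with a female-biased
#' ventral count and male-biased subcaudal count and tail length.
#'
#' @param n_individuals Number of individuals.
#' @param svl_log10_mean,svl_log10_sd Mean and SD of log10 SVL (cm); defaults
#'   give an SVL range of roughly 18-80 cm spanning juveniles to adults.
#' @param traits Data frame with columns `trait`, `a`, `b`, `sex_m`,
#'   `age_adult` (log10 offsets applied to males / adults) and `resid_sd`
#'   (log10 residual SD). Defaults cover mass and seven linear traits.
#' @param adult_svl_cm SVL threshold separating juveniles from adults
#'   (default 40 cm).
#' @param seed Integer seed.
#' @return A list of class `morpho_gen_config`.
#' @export
morpho_gen_config <- function(n_individuals = 74L, svl_log10_mean = 1.57,
                              svl_log10_sd = 0.16, traits = NULL,
                              adult_svl_cm = 40, seed = 1L) {
  if (is.null(traits)) traits <- default_morpho_traits()
  req <- c("trait", "a", "b", "sex_m", "age_adult", "resid_sd")
  if (!all(req %in% names(traits))) {
    stop("traits table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(traits$resid_sd < 0)) stop("resid_sd must be >= 0")
  if (svl_log10_sd < 0) stop("svl_log10_sd must be >= 0")
  structure(list(n_individuals = as.integer(n_individuals),
                 svl_log10_mean = svl_log10_mean, svl_log10_sd = svl_log10_sd,
                 traits = traits, adult_svl_cm = adult_svl_cm,
                 seed = as.integer(seed)),
            class = "morpho_gen_config")
}

#' @rdname morpho_gen_config
#' @export
default_morpho_traits <- function() {
  data.frame(
    trait = c("mass_g", "tail_cm", "width25_cm", "width50_cm", "width75_cm",
              "neck_width_cm", "head_width_cm", "head_length_cm"),
    a = c(8e-4, 0.12, 0.050, 0.055, 0.045, 0.025, 0.035, 0.050),
    b = c(3, 1, 1, 1, 1, 1, 1, 1),
    sex_m = c(0, 0.05, 0, 0, 0, 0, 0, 0.02),
    age_adult = c(0, 0, 0, 0, 0, 0, 0, 0),
    resid_sd = c(0.05, 0.03, 0.04, 0.04, 0.04, 0.04, 0.03, 0.03)
  )
}

#' Generate a synthetic morphometrics table
#'
#' @param cfg A [morpho_gen_config()].
#' @return Data frame with one row per individual: `id`, `sex` ("F"/"M"),
#'   `age_class` ("juvenile"/"adult"), `svl_cm`, the configured power-law
#'   traits, and meristic counts (`ventral_count`, `subcaudal_count`,
#'   `dorsal_rows`).
#' @export
generate_morphometrics <- function(cfg) {
  stopifnot(inherits(cfg, "morpho_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  sex <- sample(rep(c("F", "M"), length.out = n))
  svl <- 10^stats::rnorm(n, cfg$svl_log10_mean, cfg$svl_log10_sd)
  age <- ifelse(svl >= cfg$adult_svl_cm, "adult", "juvenile")
  out <- data.frame(id = sprintf("ind%02d", seq_len(n)), sex = sex,
                    age_class = age, svl_cm = svl)
  for (j in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[j, ]
    lg <- log10(tr$a) + tr$b * log10(svl) +
      tr$sex_m * (sex == "M") + tr$age_adult * (age == "adult") +
      stats::rnorm(n, 0, tr$resid_sd)
    out[[tr$trait]] <- 10^lg
  }
  out$ventral_count <- as.integer(round(stats::rnorm(n, 141 + 3 * (sex == "F"), 3)))
  out$subcaudal_count <- as.integer(round(stats::rnorm(n, 16 + 4 * (sex == "M"), 1.5)))
  out$dorsal_rows <- as.integer(sample(c(21L, 23L), n, replace = TRUE, prob = c(0.85, 0.15)))
  out
}
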