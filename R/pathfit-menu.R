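#' Default free-covariance structure for a speed path model
#'
#' Exogenous variables (no incoming path) covary freely in all pairs.
#' Mediators (endogenous variables that predict another variable) get free
#' residual covariances with every exogenous variable that is not one of
#' their parents. The residual of the final outcome covaries with nothing.
#'
#' @param variables Variable names.
#' @param paths Two-column matrix of directed paths (from, to).
#' @return Two-column matrix of unordered covariance pairs.
#' @export
default_path_covariances <- function(variables, paths) {
  to <- unique(paths[, 2])
  from <- unique(paths[, 1])
  exo <- setdiff(variables, to)
  mediators <- intersect(to, from)
  covs <- list()
  if (length(exo) >= 2) {
    cmb <- utils::combn(exo, 2)
    for (i in seq_len(ncol(cmb))) covs[[length(covs) + 1]] <- cmb[, i]
  }
  for (m in mediators) {
    parents <- paths[paths[, 2] == m, 1]
    for (e in setdiff(exo, parents)) covs[[length(covs) + 1]] <- c(m, e)
  }
  if (!length(covs)) return(matrix(character(0), 0, 2))
  do.call(rbind, covs)
}

#' The default seven-variable sidewinding speed model
#'
#' Mean centroid speed is predicted by cycle frequency, wavelength,
#' peak-to-peak amplitude and skew angle; body width at 50% SVL predicts
#' wavelength; height lifted enters as a correlate only. All variables are
#' size-corrected residuals. With the default covariance structure the model
#' has 26 free parameters against 28 covariance moments: 2 degrees of
#' freedom.
#'
#' @return A [path_model_spec()].
#' @export
sidewinding_path_spec <- function() {
  vars <- c("frequency", "wavelength", "amplitude", "skew", "height",
            "width50", "speed")
  paths <- rbind(c("frequency", "speed"), c("wavelength", "speed"),
                 c("amplitude", "speed"), c("skew", "speed"),
                 c("width50", "wavelength"))
  path_model_spec(vars, paths = paths,
                  covariances = default_path_covariances(vars, paths))
}

#' Sixteen-model menu of candidate speed path models
#'
#' Every candidate contains the core (frequency, wavelength, amplitude ->
#' speed). Candidates differ in which morphological traits enter with their
#' hypothesized effects on kinematics -- tail length (tail -> frequency),
#' ventral scale count and mass or width at 50% SVL (-> wavelength); mass and
#' width are redundant measures of stoutness and never enter together. Models
#' are filled up to seven variables with skew angle (skew -> speed) and/or
#' height lifted (correlate only): one-trait subsets take both, two-trait
#' subsets take one or the other, and three-trait subsets take neither,
#' giving 4 + 10 + 2 = 16 models. This menu is a reconstruction: the exact
#' candidate list behind the published comparison is not stated.
#'
#' @return Named list of [path_model_spec()]s.
#' @export
sidewinding_path_menu <- function() {
  morph_effect <- list(tail = c("tail", "frequency"),
                       ventral = c("ventral", "wavelength"),
                       mass = c("mass", "wavelength"),
                       width50 = c("width50", "wavelength"))
  base_vars <- c("frequency", "wavelength", "amplitude", "speed")
  base_paths <- rbind(c("frequency", "speed"), c("wavelength", "speed"),
                      c("amplitude", "speed"))
  build <- function(morphs, fillers) {
    vars <- c(base_vars, fillers, morphs)
    paths <- base_paths
    if ("skew" %in% fillers) paths <- rbind(paths, c("skew", "speed"))
    for (m in morphs) paths <- rbind(paths, morph_effect[[m]])
    path_model_spec(vars, paths = paths,
                    covariances = default_path_covariances(vars, paths))
  }
  menu <- list()
  singles <- names(morph_effect)
  for (m in singles) {
    menu[[paste0(m, "+skew+height")]] <- build(m, c("skew", "height"))
  }
  pairs <- utils::combn(singles, 2)
  for (i in seq_len(ncol(pairs))) {
    pr <- pairs[, i]
    if (all(c("mass", "width50") %in% pr)) next
    menu[[paste0(paste(pr, collapse = "+"), "+skew")]] <- build(pr, "skew")
    menu[[paste0(paste(pr, collapse = "+"), "+height")]] <- build(pr, "height")
  }
  triples <- utils::combn(singles, 3)
  for (i in seq_len(ncol(triples))) {
    tr <- triples[, i]
    if (all(c("mass", "width50") %in% tr)) next
    menu[[paste(tr, collapse = "+")]] <- build(tr, character(0))
  }
  menu
}
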