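## S4 class definitions and validity methods.

#' CohortSpec: parameters of the synthetic resting-state cohort
#'
#' Describes the statistical structure of a simulated cohort: a block
#' correlation matrix over nodes grouped into functional networks, an
#' age-dependent between-network coupling, and a planted moderated linear
#' model linking a latent language-production score to age and network
#' segregation.
#'
#' @slot nSubjects number of subjects.
#' @slot ageRange numeric(2), years; subjects are drawn uniformly over it.
#' @slot nTimepoints resting-state volumes per subject.
#' @slot networkSizes named integer vector, nodes per network; the default has
#'   14 networks totalling 231 nodes, with a left-language network and its
#'   right-hemisphere homologue among them.
#' @slot rWithin baseline within-network correlation, in `[0, 1)`.
#' @slot rBetween baseline between-network correlation at the cohort's mean
#'   age, in `[0, rWithin)`.
#' @slot segAgeSlope change in between-network correlation per standardized
#'   age unit; positive values make networks less segregated with age.
#' @slot rBetweenSd subject-level SD of the between-network coupling around
#'   its age-predicted value (gives segregation variance not explained by
#'   age, without which age and segregation would be collinear).
#' @slot behavCoefs named numeric: `b_age`, `b_seg`, `b_int`, `noise_sd` of
#'   the planted model for the latent composite, on the standardized scale.
#' @slot seed master RNG seed; all stage seeds fan out from it.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer",
  ageRange = "numeric",
  nTimepoints = "integer",
  networkSizes = "integer",
  rWithin = "numeric",
  rBetween = "numeric",
  segAgeSlope = "numeric",
  rBetweenSd = "numeric",
  behavCoefs = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@ageRange) != 2 || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be (min, max) with min < max")
  if (object@nTimepoints < 2L)
    msg <- c(msg, "nTimepoints must be >= 2")
  if (any(object@networkSizes < 1L) || is.null(names(object@networkSizes)))
    msg <- c(msg, "networkSizes must be a named vector of positive counts")
  if (!(object@rBetween >= 0 && object@rBetween < object@rWithin &&
        object@rWithin < 1))
    msg <- c(msg, "need 0 <= rBetween < rWithin < 1")
  if (object@rBetweenSd < 0)
    msg <- c(msg, "rBetweenSd must be >= 0")
  needed <- c("b_age", "b_seg", "b_int", "noise_sd")
  if (!all(needed %in% names(object@behavCoefs)))
    msg <- c(msg, sprintf("behavCoefs must name %s",
                          paste(needed, collapse = ", ")))
  else if (object@behavCoefs[["noise_sd"]] < 0)
    msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parcellation: sphere nodes on a reference grid with network labels
#'
#' An ordered set of spherical nodes (MNI mm centers, fixed radii) together
#' with the reference grid on which they are voxelized. Each retained node
#' carries exactly one network label.
#'
#' @slot nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`,
#'   `network` (one row per retained node, order preserved).
#' @slot grid list with `voxdim` (voxel size in mm, length 3) and `origin`
#'   (mm coordinate of the center of voxel index `(0,0,0)`, length 3).
#'   Indexing is 0-based; voxel `(i,j,k)` has its center at
#'   `origin + c(i,j,k) * voxdim`.
#' @slot dropped data.frame of excluded rows (same columns), for the log.
#' @export
setClass("Parcellation", representation(
  nodes = "data.frame",
  grid = "list",
  dropped = "data.frame"
))

setValidity("Parcellation", function(object) {
  msg <- character()
  need <- c("id", "x", "y", "z", "radius", "network")
  if (!all(need %in% names(object@nodes)))
    msg <- c(msg, sprintf("nodes must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@nodes$id))
      msg <- c(msg, "node ids must be unique")
    if (nrow(object@nodes) &&
        (!all(is.finite(as.matrix(object@nodes[, c("x", "y", "z")])))))
      msg <- c(msg, "node centers must be finite")
    if (nrow(object@nodes) && any(object@nodes$radius <= 0))
      msg <- c(msg, "node radii must be > 0")
  }
  g <- object@grid
  if (!all(c("voxdim", "origin") %in% names(g)) ||
      length(g$voxdim) != 3 || length(g$origin) != 3 || any(g$voxdim <= 0))
    msg <- c(msg, "grid must have voxdim (>0) and origin, each length 3")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: thresholded Fisher-z matrix for one subject
#'
#' Symmetric node-by-node matrix of Fisher-z connectivity values with the
#' diagonal and all negative entries set to exactly zero. Zeros created by
#' thresholding are genuine entries: by default they stay in every
#' within-/between-network mean.
#'
#' @slot values numeric n x n matrix, Fisher-z units, dimnames = node ids.
#' @slot nodeIds character vector of node ids in matrix order.
#' @export
setClass("ConnectivityMatrix", representation(
  values = "matrix",
  nodeIds = "character"
))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else {
    if (length(object@nodeIds) != nrow(v))
      msg <- c(msg, "nodeIds length must equal matrix dimension")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-10)))
      msg <- c(msg, "matrix must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be exactly zero")
    if (any(v < 0)) msg <- c(msg, "entries must be nonnegative (thresholded)")
  }
  if (length(msg)) msg else TRUE
})

#' SegregationProfile: within/between connectivity and segregation
#'
#' Per-network mean within- and between-network Fisher-z connectivity and the
#' segregation index `(within - between) / within`, plus the whole-brain
#' value, the unweighted mean of the per-network segregation values.
#'
#' @slot perNetwork data.frame: `network`, `within`, `between`, `segregation`.
#' @slot wholeBrain numeric(1), mean segregation across networks.
#' @export
setClass("SegregationProfile", representation(
  perNetwork = "data.frame",
  wholeBrain = "numeric"
))

setValidity("SegregationProfile", function(object) {
  pn <- object@perNetwork
  need <- c("network", "within", "between", "segregation")
  if (!all(need %in% names(pn)))
    return(sprintf("perNetwork must have columns %s",
                   paste(need, collapse = ", ")))
  ok <- pn$within > 0
  if (any(abs(pn$segregation[ok] -
              (pn$within[ok] - pn$between[ok]) / pn$within[ok]) > 1e-8))
    return("segregation must equal (within - between)/within")
  TRUE
})

#' ModerationFit: a moderated OLS regression on standardized predictors
#'
#' Holds the least-squares fit of an outcome on a focal predictor, a
#' moderator, their product, and optional covariates, all predictors
#' standardized (sample SD) before fitting. Stores everything the
#' Johnson-Neyman computation needs: coefficients, their covariance, the
#' residual df, and the (mean, SD) used to standardize each predictor.
#'
#' @slot coefficients named numeric vector.
#' @slot se named numeric vector of standard errors.
#' @slot vcovMat coefficient covariance matrix `sigma2 * (X'X)^-1`.
#' @slot df residual degrees of freedom, `n - p`.
#' @slot sigma2 residual variance.
#' @slot scaling data.frame: `variable`, `mean`, `sd` per standardized column.
#' @slot terms named list with elements `focal`, `moderator`, `interaction`,
#'   `covariates` giving coefficient names.
#' @slot lmFit the underlying `lm` object.
#' @export
setClass("ModerationFit", representation(
  coefficients = "numeric",
  se = "numeric",
  vcovMat = "matrix",
  df = "numeric",
  sigma2 = "numeric",
  scaling = "data.frame",
  terms = "list",
  lmFit = "ANY"
))

setValidity("ModerationFit", function(object) {
  msg <- character()
  V <- object@vcovMat
  if (!isTRUE(all.equal(V, t(V), tolerance = 1e-8)))
    msg <- c(msg, "coefficient covariance must be symmetric")
  else if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    msg <- c(msg, "coefficient covariance must be PSD")
  if (object@df < 1) msg <- c(msg, "residual df must be >= 1")
  if (length(msg)) msg else TRUE
})

#' JNRegion: Johnson-Neyman region of significance
#'
#' The moderator values (raw units, e.g. years) at which the conditional
#' slope of the focal predictor crosses the two-sided critical t, with the
#' significant side(s) and the observed moderator range.
#'
#' @slot boundaries numeric, 0-2 sorted moderator values in raw units.
#' @slot side character: `"below"`, `"above"`, `"between"`, `"outside"`,
#'   `"everywhere"` or `"nowhere"`.
#' @slot alpha significance level.
#' @slot observedRange numeric(2), raw-unit moderator range in the data.
#' @slot boundariesZ the same boundaries in standardized moderator units.
#' @export
setClass("JNRegion", representation(
  boundaries = "numeric",
  side = "character",
  alpha = "numeric",
  observedRange = "numeric",
  boundariesZ = "numeric"
))

setValidity("JNRegion", function(object) {
  msg <- character()
  if (is.unsorted(object@boundaries))
    msg <- c(msg, "boundaries must be sorted")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' InfluenceReport: Cook's-distance screening result
#'
#' @slot distances named numeric vector of per-subject Cook's distances.
#' @slot threshold numeric(1), `4 / n`.
#' @slot removed character vector of removed subject ids.
#' @export
setClass("InfluenceReport", representation(
  distances = "numeric",
  threshold = "numeric",
  removed = "character"
))

setValidity("InfluenceReport", function(object) {
  if (any(object@distances < 0)) "Cook's distances must be >= 0" else TRUE
})
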