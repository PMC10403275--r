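## Generics and simple accessors / show methods.

#' Node table of a Parcellation
#' @param x a [Parcellation-class] object.
#' @return data.frame of retained nodes.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname nodes
#' @export
setMethod("nodes", "Parcellation", function(x) x@nodes)

#' Network labels of an object
#' @param x a [Parcellation-class] object.
#' @return character vector of network labels.
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname networks
#' @export
setMethod("networks", "Parcellation",
          function(x) sort(unique(x@nodes$network)))

#' Number of nodes
#' @param x a [Parcellation-class] or [ConnectivityMatrix-class] object.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "Parcellation", function(x) nrow(x@nodes))

#' @rdname nNodes
#' @export
setMethod("nNodes", "ConnectivityMatrix", function(x) length(x@nodeIds))

#' Matrix values of a ConnectivityMatrix
#' @param x a [ConnectivityMatrix-class] object.
#' @return numeric matrix (Fisher-z units, thresholded).
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname connValues
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' Per-network table of a SegregationProfile
#' @param x a [SegregationProfile-class] object.
#' @return data.frame with within, between and segregation per network.
#' @export
setGeneric("perNetwork", function(x) standardGeneric("perNetwork"))

#' @rdname perNetwork
#' @export
setMethod("perNetwork", "SegregationProfile", function(x) x@perNetwork)

#' Whole-brain segregation
#' @param x a [SegregationProfile-class] object.
#' @return numeric(1), unweighted mean of per-network segregation.
#' @export
setGeneric("wholeBrainSegregation",
           function(x) standardGeneric("wholeBrainSegregation"))

#' @rdname wholeBrainSegregation
#' @export
setMethod("wholeBrainSegregation", "SegregationProfile",
          function(x) x@wholeBrain)

#' @describeIn ModerationFit-class coefficient vector
#' @param object a `ModerationFit`.
#' @export
setMethod("coef", "ModerationFit", function(object) object@coefficients)

#' @describeIn ModerationFit-class coefficient covariance matrix
#' @export
setMethod("vcov", "ModerationFit", function(object) object@vcovMat)

#' JN region boundaries in raw moderator units
#' @param x a [JNRegion-class] object.
#' @return numeric vector of length 0-2.
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname boundaries
#' @export
setMethod("boundaries", "JNRegion", function(x) x@boundaries)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects, ages %g-%g yr, %d timepoints\n",
    object@nSubjects, object@ageRange[1], object@ageRange[2],
    object@nTimepoints))
  cat(sprintf("  %d networks / %d nodes; r_within=%.2f r_between=%.2f (slope %.3f/SD age)\n",
              length(object@networkSizes), sum(object@networkSizes),
              object@rWithin, object@rBetween, object@segAgeSlope))
  b <- object@behavCoefs
  cat(sprintf("  planted model: b_age=%.2f b_seg=%.2f b_int=%.2f noise_sd=%.2f (seed %d)\n",
              b[["b_age"]], b[["b_seg"]], b[["b_int"]], b[["noise_sd"]],
              object@seed))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d nodes in %d networks (%d dropped)\n",
              nrow(object@nodes), length(unique(object@nodes$network)),
              nrow(object@dropped)))
  cat(sprintf("  grid: voxdim %s mm, origin (%s) mm\n",
              paste(object@grid$voxdim, collapse = "x"),
              paste(object@grid$origin, collapse = ", ")))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  cat(sprintf("ConnectivityMatrix: %d x %d, mean off-diagonal z = %.4f, %.1f%% zero\n",
              nrow(v), ncol(v), mean(v[upper.tri(v)]),
              100 * mean(v[upper.tri(v)] == 0)))
})

setMethod("show", "SegregationProfile", function(object) {
  cat(sprintf("SegregationProfile: %d networks, whole-brain segregation %.4f\n",
              nrow(object@perNetwork), object@wholeBrain))
  print(object@perNetwork, digits = 4, row.names = FALSE)
})

setMethod("show", "ModerationFit", function(object) {
  cat("ModerationFit (standardized predictors)\n")
  tab <- data.frame(
    estimate = object@coefficients,
    se = object@se,
    t = object@coefficients / object@se,
    p = 2 * pt(abs(object@coefficients / object@se), object@df,
               lower.tail = FALSE))
  print(round(tab, 4))
  cat(sprintf("residual df = %d, sigma2 = %.4f\n",
              as.integer(object@df), object@sigma2))
})

setMethod("show", "JNRegion", function(object) {
  if (length(object@boundaries) == 0) {
    cat(sprintf("JNRegion: slope %s over observed range [%g, %g] (alpha=%g)\n",
                object@side, object@observedRange[1], object@observedRange[2],
                object@alpha))
  } else {
    cat(sprintf("JNRegion: significant %s %s (alpha=%g, observed [%g, %g])\n",
                object@side,
                paste(round(object@boundaries, 2), collapse = " and "),
                object@alpha, object@observedRange[1],
                object@observedRange[2]))
  }
})

setMethod("show", "InfluenceReport", function(object) {
  cat(sprintf("InfluenceReport: n=%d, threshold 4/n=%.4f, removed %d: %s\n",
              length(object@distances), object@threshold,
              length(object@removed),
              if (length(object@removed)) paste(object@removed, collapse = ", ")
              else "none"))
})
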