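## Subject-level weighted z-matrix and network segregation measures.

#' Pearson correlation matrix of node time series
#'
#' Cross-correlates each node's time course with every other node's.
#'
#' @param ts numeric matrix, nodes x time (rows are nodes). Row names, if
#'   present, are carried through as node ids.
#' @return symmetric correlation matrix with unit diagonal.
#' @details A constant row has undefined correlations and is an error (it
#'   indicates degenerate input, e.g. a node with no in-brain voxels).
#' @export
correlationMatrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2) stopf("need >= 2 time points, got %d", ncol(ts))
  sds <- apply(ts, 1, sd)
  if (any(sds == 0)) {
    bad <- if (!is.null(rownames(ts))) rownames(ts)[sds == 0]
           else as.character(which(sds == 0))
    stopf("constant time series for node(s): %s",
          paste(bad, collapse = ", "))
  }
  r <- cor(t(ts))
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform applied elementwise to off-diagonal correlations.
#'
#' @param r correlations, strictly inside (-1, 1).
#' @return z values, same shape as `r`.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1 & !is.na(r)))
    stopf("|r| >= 1 is degenerate input to the Fisher transform")
  atanh(r)
}

#' Threshold a z-matrix into a ConnectivityMatrix
#'
#' Sets the diagonal and all negative values to exactly zero. Zeros are
#' retained as matrix entries and participate in all subsequent means.
#'
#' @param z symmetric numeric matrix of Fisher-z values (diagonal ignored).
#' @param nodeIds optional node ids; defaults to rownames or `n1..nn`.
#' @return a [ConnectivityMatrix-class].
#' @export
thresholdMatrix <- function(z, nodeIds = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stopf("matrix must be square")
  if (max(abs(z - t(z))) > 1e-8) stopf("matrix must be symmetric")
  z <- (z + t(z)) / 2 # kill rounding asymmetry
  z[z < 0] <- 0
  diag(z) <- 0
  if (is.null(nodeIds))
    nodeIds <- if (!is.null(rownames(z))) rownames(z)
               else paste0("n", seq_len(nrow(z)))
  dimnames(z) <- list(nodeIds, nodeIds)
  new("ConnectivityMatrix", values = z, nodeIds = as.character(nodeIds))
}

#' Subject connectivity matrix from node time series
#'
#' Convenience wrapper: Pearson correlation, Fisher z, then thresholding of
#' negatives and the diagonal to zero.
#'
#' @param ts nodes x time matrix.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityFromTimeseries <- function(ts) {
  r <- correlationMatrix(ts)
  z <- r
  off <- row(r) != col(r)
  z[off] <- fisherZ(r[off])
  diag(z) <- 0
  thresholdMatrix(z, nodeIds = rownames(ts))
}

## resolve a partition argument into a factor aligned with the matrix
resolvePartition <- function(M, partition) {
  ids <- M@nodeIds
  if (is(partition, "Parcellation")) {
    nd <- partition@nodes
    if (!all(ids %in% nd$id))
      stopf("matrix node ids missing from parcellation")
    part <- setNames(nd$network, nd$id)[ids]
  } else {
    part <- partition
    if (!is.null(names(part))) part <- part[ids]
    if (length(part) != length(ids))
      stopf("partition length (%d) != number of nodes (%d)",
            length(part), length(ids))
  }
  as.character(part)
}

#' Mean within-network connectivity
#'
#' Mean Fisher-z value over the unordered off-diagonal node pairs inside one
#' network (the diagonal block of the matrix, diagonal excluded). Zeros
#' created by negative-edge thresholding stay in the mean.
#'
#' @param M a [ConnectivityMatrix-class].
#' @param network network label.
#' @param partition network label per node (vector aligned with the matrix,
#'   named by node id, or a [Parcellation-class]).
#' @param zeroPolicy `"include"` (default) keeps zeros created by
#'   thresholding in the mean; `"exclude"` drops them, treating a removed
#'   negative edge as missing rather than zero-weight.
#' @return numeric(1), mean z.
#' @export
withinNetwork <- function(M, network, partition,
                          zeroPolicy = c("include", "exclude")) {
  zeroPolicy <- match.arg(zeroPolicy)
  part <- resolvePartition(M, partition)
  idx <- which(part == network)
  if (length(idx) < 2)
    stopf("network '%s' has %d node(s); within-network connectivity needs >= 2",
          network, length(idx))
  block <- M@values[idx, idx, drop = FALSE]
  meanEdges(block[upper.tri(block)], zeroPolicy, network, "within")
}

## mean over edge values under the chosen zero policy
meanEdges <- function(vals, zeroPolicy, network, kind) {
  if (zeroPolicy == "exclude") {
    vals <- vals[vals != 0]
    if (length(vals) == 0)
      stopf("network '%s': every %s-network edge is zero; mean undefined under zeroPolicy = 'exclude'",
            network, kind)
  }
  mean(vals)
}

#' Mean between-network connectivity
#'
#' Mean Fisher-z value over all pairs linking a network's nodes to every node
#' outside it (the off-diagonal blocks of the matrix).
#'
#' @inheritParams withinNetwork
#' @return numeric(1), mean z.
#' @export
betweenNetwork <- function(M, network, partition,
                           zeroPolicy = c("include", "exclude")) {
  zeroPolicy <- match.arg(zeroPolicy)
  part <- resolvePartition(M, partition)
  idx <- which(part == network)
  if (length(idx) == 0) stopf("network '%s' has no nodes", network)
  out <- which(part != network)
  if (length(out) == 0)
    stopf("network '%s' spans all nodes; between-network undefined", network)
  meanEdges(as.vector(M@values[idx, out, drop = FALSE]), zeroPolicy,
            network, "between")
}

#' Network segregation index
#'
#' `(within - between) / within`: 1 when a network shares no connectivity
#' with the rest of the brain, 0 when within- and between-network
#' connectivity are equal.
#'
#' @param within mean within-network z, must be > 0.
#' @param between mean between-network z.
#' @return numeric segregation value.
#' @export
networkSegregation <- function(within, between) {
  if (any(within <= 0))
    stopf("segregation undefined for within-network connectivity <= 0")
  (within - between) / within
}

#' Segregation profile of a subject
#'
#' Per-network within/between connectivity and segregation, plus the
#' whole-brain value: the unweighted mean of the per-network segregation
#' values (networks count equally regardless of size).
#'
#' @param M a [ConnectivityMatrix-class].
#' @param partition network label per node (see [withinNetwork()]).
#' @param zeroPolicy zero-edge handling, see [withinNetwork()].
#' @return a [SegregationProfile-class].
#' @export
segregationProfile <- function(M, partition,
                               zeroPolicy = c("include", "exclude")) {
  zeroPolicy <- match.arg(zeroPolicy)
  part <- resolvePartition(M, partition)
  nets <- unique(part) # first-appearance order
  rows <- lapply(nets, function(nw) {
    w <- tryCatch(withinNetwork(M, nw, part, zeroPolicy),
                  error = function(e) stopf("network '%s': %s", nw,
                                            conditionMessage(e)))
    b <- betweenNetwork(M, nw, part, zeroPolicy)
    data.frame(network = nw, within = w, between = b,
               segregation = networkSegregation(w, b),
               stringsAsFactors = FALSE)
  })
  pn <- do.call(rbind, rows)
  new("SegregationProfile", perNetwork = pn,
      wholeBrain = mean(pn$segregation))
}

#' Segregation profiles for a directory of time-series files
#'
#' Reads per-subject node-by-time TSV files (nodes x time, row names = node
#' ids written as a leading column), computes each subject's thresholded
#' z-matrix and segregation profile, and returns a long table.
#'
#' @param files named character vector of TSV paths (names = subject ids).
#' @param partition network label per node id (named vector or
#'   [Parcellation-class]).
#' @param zeroPolicy zero-edge handling, see [withinNetwork()].
#' @return long data.frame: subject_id, network, within, between,
#'   segregation, and the subject's whole_brain segregation repeated on each
#'   row (use [profilesWide()] for one row per subject).
#' @export
cohortProfiles <- function(files, partition,
                           zeroPolicy = c("include", "exclude")) {
  zeroPolicy <- match.arg(zeroPolicy)
  res <- NULL
  if (is.null(names(files))) names(files) <- basename(files)
  res <- lapply(names(files), function(sid) {
    ts <- readTimeseriesTSV(files[[sid]])
    prof <- segregationProfile(connectivityFromTimeseries(ts), partition,
                               zeroPolicy)
    cbind(subject_id = sid, perNetwork(prof),
          whole_brain = wholeBrainSegregation(prof))
  })
  do.call(rbind, res)
}

#' Widen a long profile table to one row per subject
#'
#' @param long output of [cohortProfiles()].
#' @param languageNetwork label of the left-language network.
#' @return data.frame: subject_id, language_segregation,
#'   wholebrain_segregation.
#' @export
profilesWide <- function(long, languageNetwork = "left_language") {
  sids <- unique(long$subject_id)
  lang <- long[long$network == languageNetwork, ]
  wb <- long[!duplicated(long$subject_id), c("subject_id", "whole_brain")]
  out <- data.frame(subject_id = sids, stringsAsFactors = FALSE)
  out$language_segregation <-
    lang$segregation[match(sids, lang$subject_id)]
  out$wholebrain_segregation <- wb$whole_brain[match(sids, wb$subject_id)]
  out
}

#' Read / write a node-by-time TSV
#'
#' Format: tab-separated, one row per node, first column `node_id`, remaining
#' columns the time points in order.
#'
#' @param path file path.
#' @return numeric matrix with node ids as row names.
#' @export
readTimeseriesTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "node_id")
    stopf("%s: first column must be node_id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node_id
  storage.mode(m) <- "double"
  m
}

#' @rdname readTimeseriesTSV
#' @param ts nodes x time matrix with row names.
#' @export
writeTimeseriesTSV <- function(ts, path) {
  df <- data.frame(node_id = rownames(ts), ts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
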