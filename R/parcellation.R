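## Sphere-node parcellations on an MNI reference grid: loading, voxelization,
## non-overlap checking, localizer-based network assignment, and ROI
## time-series extraction from 4D volumes.

#' Reference grids
#'
#' Helper constructors for common grids. `mniGrid2mm()` is the MNI152 2 mm
#' grid convention used for node voxelization; `functionalGrid()` matches a
#' typical EPI acquisition grid (3 x 3 x 4 mm). Origins give the mm
#' coordinate of the center of voxel (0,0,0); voxel (i,j,k) is centered at
#' `origin + c(i,j,k) * voxdim`.
#'
#' @param origin mm coordinate of voxel (0,0,0).
#' @return list with `voxdim` and `origin`.
#' @export
mniGrid2mm <- function(origin = c(-90, -126, -72)) {
  list(voxdim = c(2, 2, 2), origin = origin)
}

#' @rdname mniGrid2mm
#' @export
functionalGrid <- function(origin = c(-90, -126, -72)) {
  list(voxdim = c(3, 3, 4), origin = origin)
}

#' Load a node table into a Parcellation
#'
#' Reads a TSV/CSV with columns `id, x, y, z, radius, network` (radius
#' optional, default 5 mm). Rows whose network is flagged `excluded` are
#' dropped (and kept in the `dropped` slot for the log); this is how a
#' 264-node table with 33 poorly classified nodes reduces to the 231
#' retained nodes.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param grid reference grid (default [mniGrid2mm()]).
#' @param defaultRadius radius in mm for rows lacking one.
#' @return a [Parcellation-class].
#' @export
loadNodeTable <- function(path, grid = mniGrid2mm(), defaultRadius = 5) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("%s: empty node table", path)
  need <- c("id", "x", "y", "z", "network")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (!("radius" %in% names(df))) df$radius <- defaultRadius
  for (cc in c("x", "y", "z", "radius")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stopf("%s: non-numeric values in column %s", path, cc)
    df[[cc]] <- v
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stopf("%s: duplicate node id(s): %s", path,
          paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  excl <- tolower(df$network) == "excluded"
  if (any(excl))
    message(sprintf("dropping %d node(s) flagged excluded (%d retained)",
                    sum(excl), sum(!excl)))
  parcellation(df[!excl, , drop = FALSE], grid = grid,
               dropped = df[excl, , drop = FALSE])
}

#' Construct a Parcellation from a data.frame
#'
#' @param nodes data.frame with columns `id, x, y, z, radius, network`.
#' @param grid reference grid list (`voxdim`, `origin`).
#' @param dropped optional data.frame of excluded rows.
#' @return a [Parcellation-class].
#' @export
parcellation <- function(nodes, grid = mniGrid2mm(), dropped = NULL) {
  if (is.null(dropped)) dropped <- nodes[0, , drop = FALSE]
  rownames(nodes) <- NULL
  new("Parcellation", nodes = nodes, grid = grid, dropped = dropped)
}

#' Voxelize a sphere node on the reference grid
#'
#' Returns the set of voxels whose centers lie within `radius` mm (Euclidean,
#' inclusive) of the node center. Distances are evaluated in mm space so
#' anisotropic grids are handled directly. Deterministic and invariant to
#' shifting the grid origin by whole voxels.
#'
#' @param center numeric(3) mm coordinates of the node center.
#' @param radius sphere radius in mm.
#' @param grid reference grid (`voxdim`, `origin`).
#' @return integer matrix, one row per voxel, columns `i, j, k` (0-based
#'   voxel indices).
#' @export
voxelizeSphere <- function(center, radius, grid) {
  stopifnot(length(center) == 3, radius > 0)
  vox <- grid$voxdim
  # candidate index ranges covering the bounding box
  rng <- lapply(1:3, function(d) {
    lo <- ceiling((center[d] - radius - grid$origin[d]) / vox[d])
    hi <- floor((center[d] + radius - grid$origin[d]) / vox[d])
    if (hi < lo) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  ctr <- sweep(sweep(g, 2, vox, `*`), 2, grid$origin, `+`)
  d2 <- rowSums(sweep(ctr, 2, center, `-`)^2)
  out <- g[d2 <= radius^2 + 1e-9, , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  out
}

## voxel key strings for set operations
voxelKeys <- function(vox) paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")

## voxelize every node of a parcellation; returns named list of index matrices
voxelizeAll <- function(parc) {
  nd <- parc@nodes
  out <- lapply(seq_len(nrow(nd)), function(i)
    voxelizeSphere(c(nd$x[i], nd$y[i], nd$z[i]), nd$radius[i], parc@grid))
  names(out) <- nd$id
  out
}

#' Check a parcellation for overlapping nodes
#'
#' Lists every pair of nodes sharing at least one voxel on the reference
#' grid. A valid parcellation yields an empty report.
#'
#' @param parc a [Parcellation-class].
#' @return data.frame with columns `id1, id2, shared_voxels` (zero rows when
#'   the parcellation is non-overlapping).
#' @export
checkNonoverlap <- function(parc) {
  vox <- voxelizeAll(parc)
  keys <- lapply(vox, voxelKeys)
  ids <- names(keys)
  out <- list()
  if (length(ids) >= 2) {
    # only compare nodes whose bounding spheres can touch
    nd <- parc@nodes
    ctr <- as.matrix(nd[, c("x", "y", "z")])
    for (a in seq_len(length(ids) - 1)) {
      for (b in seq.int(a + 1, length(ids))) {
        maxd <- nd$radius[a] + nd$radius[b] + max(parc@grid$voxdim)
        if (sum((ctr[a, ] - ctr[b, ])^2) > maxd^2) next
        shared <- length(intersect(keys[[a]], keys[[b]]))
        if (shared > 0)
          out[[length(out) + 1]] <-
            data.frame(id1 = ids[a], id2 = ids[b], shared_voxels = shared,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id1 = character(), id2 = character(),
                  shared_voxels = integer(), stringsAsFactors = FALSE)
}

#' Relabel nodes overlapping language localizer masks
#'
#' Any node whose voxel set shares at least one voxel with a localizer mask
#' is reassigned to that localizer's network (applied before network
#' measures); all other nodes keep their prior label. A node overlapping both
#' masks is ambiguous and raises an error rather than being tie-broken.
#'
#' @param parc a [Parcellation-class].
#' @param masks named list of binary 3D arrays on the same reference grid
#'   (array index 1 = voxel index 0); names are the target network labels,
#'   e.g. `left_language`, `right_homologue`.
#' @return the relabeled [Parcellation-class].
#' @export
assignLanguageNetworks <- function(parc, masks) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  for (m in masks) {
    if (!any(m != 0)) stopf("localizer mask has no nonzero voxel")
  }
  vox <- voxelizeAll(parc)
  nd <- parc@nodes
  for (i in seq_len(nrow(nd))) {
    v <- vox[[i]]
    hits <- vapply(masks, function(mask) {
      idx <- v + 1L # 0-based voxel index -> 1-based array index
      inb <- idx[, 1] >= 1 & idx[, 1] <= dim(mask)[1] &
             idx[, 2] >= 1 & idx[, 2] <= dim(mask)[2] &
             idx[, 3] >= 1 & idx[, 3] <= dim(mask)[3]
      idx <- idx[inb, , drop = FALSE]
      nrow(idx) > 0 && any(mask[idx] != 0)
    }, logical(1))
    if (sum(hits) > 1)
      stopf("node %s overlaps multiple localizer masks (%s); ambiguous",
            nd$id[i], paste(names(masks)[hits], collapse = ", "))
    if (sum(hits) == 1) {
      newLab <- names(masks)[hits]
      if (nd$network[i] != newLab)
        message(sprintf("node %s: %s -> %s (localizer overlap)",
                        nd$id[i], nd$network[i], newLab))
      nd$network[i] <- newLab
    }
  }
  parcellation(nd, grid = parc@grid, dropped = parc@dropped)
}

#' Extract node time series from a 4D volume
#'
#' Row per node: the mean over the node's voxel set of the voxel time
#' series, time order preserved. Voxels falling outside the volume are
#' ignored; a node with no in-volume voxel yields an all-NA row and a
#' warning.
#'
#' @param volume4d a 4D numeric array (x, y, z, t) or a NIfTI file path
#'   (read with RNifti), assumed to live on the parcellation's grid with
#'   array index 1 at voxel index 0.
#' @param parc a [Parcellation-class].
#' @return nodes x time numeric matrix, row names = node ids.
#' @export
extractTimeseries <- function(volume4d, parc) {
  if (is.character(volume4d)) volume4d <- RNifti::readNifti(volume4d)
  vol <- as.array(volume4d)
  if (length(dim(vol)) != 4) stopf("expected a 4D volume")
  dims <- dim(vol)
  nT <- dims[4]
  vox <- voxelizeAll(parc)
  nd <- parc@nodes
  out <- matrix(NA_real_, nrow(nd), nT,
                dimnames = list(nd$id, paste0("t", seq_len(nT))))
  flat <- matrix(vol, prod(dims[1:3]), nT)
  for (i in seq_len(nrow(nd))) {
    v <- vox[[i]] + 1L
    inb <- v[, 1] >= 1 & v[, 1] <= dims[1] &
           v[, 2] >= 1 & v[, 2] <= dims[2] &
           v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- v[inb, , drop = FALSE]
    if (nrow(v) == 0) {
      warnf("node %s has no in-volume voxel; row set to NA", nd$id[i])
      next
    }
    lin <- v[, 1] + dims[1] * (v[, 2] - 1L) + dims[1] * dims[2] * (v[, 3] - 1L)
    out[i, ] <- colMeans(flat[lin, , drop = FALSE])
  }
  out
}
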