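writeNodeTable <- function(df, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  sep <- if (ext == ".csv") "," else "\t"
  write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

test_that("a 264-row table with 33 excluded nodes loads as 231 retained", {
  set.seed(2)
  nets <- c("default", "visual", "salience")
  df <- data.frame(id = sprintf("node%03d", 1:264),
                   x = seq(-90, 88, length.out = 264),
                   y = 0, z = 0, radius = 5,
                   network = sample(nets, 264, replace = TRUE))
  df$network[sample(264, 33)] <- "excluded"
  f <- writeNodeTable(df)
  expect_message(parc <- loadNodeTable(f), "33")
  expect_equal(nNodes(parc), 231)
  expect_equal(nrow(parc@dropped), 33)
  expect_false("excluded" %in% networks(parc))
})

test_that("node table parsing preserves order and rejects bad input", {
  df <- data.frame(id = c("a", "b"), x = c(10, -10), y = 0, z = 0,
                   radius = 5, network = "default")
  parc <- loadNodeTable(writeNodeTable(df, ".csv"))
  expect_equal(nodes(parc)$id, c("a", "b"))

  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tx\ty\tz\tradius\tnetwork", empty)
  expect_error(loadNodeTable(empty), "empty")

  dup <- df; dup$id <- c("a", "a")
  expect_error(loadNodeTable(writeNodeTable(dup)), "duplicate")

  bad <- df; bad$x <- c("10", "oops")
  expect_error(loadNodeTable(writeNodeTable(bad)), "non-numeric")

  nocol <- df[, setdiff(names(df), "network")]
  expect_error(loadNodeTable(writeNodeTable(nocol)), "network")
})

test_that("5 mm sphere on the 2 mm grid holds exactly the enumerated voxels", {
  grid <- mniGrid2mm()
  center <- grid$origin + c(20, 30, 10) * grid$voxdim # on a voxel center
  vox <- voxelizeSphere(center, 5, grid)
  expect_equal(nrow(vox),
               bruteSphereCount(center, 5, grid$voxdim, grid$origin +
                                  c(20, 30, 10) * grid$voxdim, reach = 4))
  expect_equal(nrow(vox), 81)

  tiny <- voxelizeSphere(center, 0.9, grid)
  expect_equal(nrow(tiny), 1)
})

test_that("voxelization is invariant to whole-voxel origin shifts and anisotropy", {
  g1 <- mniGrid2mm()
  g2 <- mniGrid2mm(origin = g1$origin + c(4, -6, 2)) # whole-voxel shift
  center <- c(10, 12, -8)
  expect_equal(nrow(voxelizeSphere(center, 5, g1)),
               nrow(voxelizeSphere(center, 5, g2)))
  # anisotropic grid evaluates distance in mm space
  gf <- functionalGrid()
  ctr <- gf$origin + c(10, 10, 10) * gf$voxdim
  vox <- voxelizeSphere(ctr, 5, gf)
  expect_equal(nrow(vox), bruteSphereCount(ctr, 5, gf$voxdim, ctr, reach = 3))
})

test_that("overlap reporting follows sphere geometry", {
  mk <- function(centers) {
    parcellation(data.frame(id = paste0("n", seq_len(nrow(centers))),
                            x = centers[, 1], y = centers[, 2],
                            z = centers[, 3], radius = 5,
                            network = "default"))
  }
  far <- mk(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(nrow(checkNonoverlap(far)), 0)
  near <- mk(rbind(c(0, 0, 0), c(4, 0, 0)))
  rep <- checkNonoverlap(near)
  expect_equal(nrow(rep), 1)
  expect_gt(rep$shared_voxels, 0)
  solo <- mk(rbind(c(0, 0, 0)))
  expect_equal(nrow(checkNonoverlap(solo)), 0)
})

test_that("localizer overlap relabels nodes; ambiguity is an error", {
  grid <- list(voxdim = c(2, 2, 2), origin = c(0, 0, 0))
  parc <- parcellation(data.frame(
    id = c("inside", "outside", "edge"),
    x = c(10, 40, 20), y = 10, z = 10, radius = 3,
    network = "default"), grid = grid)
  dims <- c(30, 12, 12)
  left <- array(0, dims)
  left[3:9, 3:9, 3:9] <- 1 # fully contains "inside" (voxel idx 5,5,5 +- 2)
  left[11, 6, 6] <- 1      # exactly one voxel of "edge" (center 20,10,10 -> idx 10,5,5; 11 is 2mm off)
  right <- array(0, dims)
  right[dims[1], dims[2], dims[3]] <- 1 # far corner, away from every node
  expect_message(
    out <- assignLanguageNetworks(parc, list(left_language = left,
                                             right_homologue = right)),
    "localizer overlap")
  labs <- setNames(nodes(out)$network, nodes(out)$id)
  expect_equal(labs[["inside"]], "left_language")
  expect_equal(labs[["edge"]], "left_language")  # >= 1 shared voxel suffices
  expect_equal(labs[["outside"]], "default")     # no overlap: unchanged
  # each node still carries exactly one label
  expect_equal(anyDuplicated(nodes(out)$id), 0)

  both <- right; both[3:9, 3:9, 3:9] <- 1
  expect_error(
    assignLanguageNetworks(parc, list(left_language = left,
                                      right_homologue = both)),
    "ambiguous")
  expect_error(
    assignLanguageNetworks(parc, list(left_language = array(0, dims))),
    "nonzero")
})

test_that("ROI extraction averages voxel time series exactly", {
  grid <- list(voxdim = c(2, 2, 2), origin = c(0, 0, 0))
  parc <- parcellation(data.frame(id = "roi", x = 20, y = 20, z = 20,
                                  radius = 5, network = "default"),
                       grid = grid)
  dims <- c(22, 22, 22, 6)
  vol <- array(7, dims)
  ts <- extractTimeseries(vol, parc)
  expect_equal(unname(ts["roi", ]), rep(7, 6))

  # one voxel carries s(t), the other 80 are zero -> node series = s(t)/81
  vol2 <- array(0, dims)
  s <- sin(1:6)
  vol2[11, 11, 11, ] <- s # voxel index (10,10,10) = node center
  ts2 <- extractTimeseries(vol2, parc)
  expect_equal(unname(ts2["roi", ]), s / 81, tolerance = 1e-12)

  # scaling the volume scales the series (commutes with extraction)
  ts3 <- extractTimeseries(vol2 * 3.5, parc)
  expect_equal(ts3, ts2 * 3.5, tolerance = 1e-12)

  # disjoint nodes over disjoint regions stay independent
  parc2 <- parcellation(data.frame(
    id = c("a", "b"), x = c(10, 34), y = 20, z = 20, radius = 3,
    network = "default"), grid = grid)
  vol3 <- array(0, dims); vol3[6, 11, 11, ] <- 1:6
  ts4 <- extractTimeseries(vol3, parc2)
  expect_true(all(ts4["b", ] == 0))
  expect_false(all(ts4["a", ] == 0))
})

test_that("voxelization is independent of node-table row order", {
  df <- data.frame(id = c("p", "q"), x = c(0, 10), y = 0, z = 0,
                   radius = 5, network = "default")
  v1 <- segconn:::voxelizeAll(parcellation(df))
  v2 <- segconn:::voxelizeAll(parcellation(df[2:1, ]))
  expect_equal(v1[["p"]], v2[["p"]])
  expect_equal(v1[["q"]], v2[["q"]])
})
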