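fresh_ws <- function(size = 16, seed = 1) {
  ph <- make_multiregion(size = size, seed = seed)
  new_workspace(ph$volume)
}

test_that("levels and labels get unique ids; parents must be earlier", {
  ws <- fresh_ws()
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  b <- add_label(ws, l1, "b")
  expect_false(a == b)
  expect_error(add_label(ws, l1, "c", parent = c(l1, a)), "previous level")
  l2 <- add_level(ws)
  expect_silent(child <- add_label(ws, l2, "child", parent = c(l1, a)))
  expect_error(add_label(ws, l2, "bad", parent = c(l1, 99)), "not found")
})

test_that("child annotation outside the parent extent is rejected", {
  ws <- fresh_ws()
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "parent")
  lv <- ws$levels[[as.character(l1)]]
  lv$voxel_labels[1:8, , ] <- a
  ws$levels[[as.character(l1)]] <- lv
  l2 <- add_level(ws)
  ch <- add_label(ws, l2, "child", parent = c(l1, a))
  n <- annotate(ws, l2, ch, rbind(c(4, 8, 8), c(12, 8, 8)), mode = "voxel",
                pen_width = 1)
  expect_gt(attr(n, "rejected"), 0) # the z = 12 disk is outside the parent
  lab2 <- ws$levels[[as.character(l2)]]$voxel_labels
  expect_true(all(which(lab2 == ch) %in%
                    which(ws$levels[[as.character(l1)]]$voxel_labels == a)))
})

test_that("voxel-mode pen labels a small in-plane disk", {
  ws <- fresh_ws()
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  n <- annotate(ws, l1, a, matrix(c(8, 8, 8), 1), mode = "voxel",
                pen_width = 1)
  expect_lte(as.integer(n), 7) # within the 6-ball bound
  expect_equal(as.integer(n), 5) # in-plane disk of radius 1
})

test_that("supervoxel mode labels whole supervoxels and is idempotent", {
  ws <- fresh_ws(24)
  compute_supervoxels(ws, shape = c(6, 6, 6), compactness = 30)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  seed <- matrix(c(3, 3, 3), 1)
  n1 <- annotate(ws, l1, a, seed, mode = "supervoxel", pen_width = 1)
  svl <- supervoxel_labels(ws)
  touched <- unique(svl[ws$levels[[as.character(l1)]]$voxel_labels == a])
  expect_equal(as.integer(n1), sum(svl %in% touched))
  state1 <- ws$levels[[as.character(l1)]]$voxel_labels
  annotate(ws, l1, a, seed, mode = "supervoxel", pen_width = 1)
  expect_identical(ws$levels[[as.character(l1)]]$voxel_labels, state1)
  # labeling never splits a supervoxel
  lab <- ws$levels[[as.character(l1)]]$voxel_labels
  per_sv <- tapply(lab, svl, function(v) length(unique(v)))
  expect_true(all(per_sv == 1))
})

test_that("megavoxel mode labels whole megavoxels", {
  ws <- fresh_ws(24)
  compute_supervoxels(ws, shape = c(6, 6, 6), compactness = 30)
  compute_megavoxels(ws, lambda_mv = 0.3)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  n <- annotate(ws, l1, a, matrix(c(12, 12, 12), 1), mode = "megavoxel")
  mvl <- megavoxel_labels(ws)
  expect_equal(as.integer(n), sum(mvl == mvl[12, 12, 12]))
})

test_that("later strokes overwrite earlier ones (last stroke wins)", {
  ws <- fresh_ws()
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  b <- add_label(ws, l1, "b")
  annotate(ws, l1, a, matrix(c(8, 8, 8), 1), mode = "voxel", pen_width = 2)
  annotate(ws, l1, b, matrix(c(8, 8, 8), 1), mode = "voxel", pen_width = 1)
  lab <- ws$levels[[as.character(l1)]]$voxel_labels
  expect_equal(lab[8, 8, 8], b)
  expect_equal(lab[8, 8, 10], a) # outer ring keeps the first label
})

test_that("strokes out of the ROI or to unknown labels error", {
  ws <- fresh_ws()
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  expect_error(annotate(ws, l1, a, matrix(c(99, 1, 1), 1)), "outside")
  expect_error(annotate(ws, l1, 42, matrix(c(2, 2, 2), 1)), "unknown label")
  expect_error(annotate(ws, l1, a, matrix(c(2, 2, 2), 1),
                        mode = "supervoxel"), "partition")
})

test_that("stroke sidecars round-trip through JSON and CSV", {
  strokes <- list(
    list(level = 1, label = 1, mode = "voxel", pen_width = 2,
         seeds = rbind(c(2, 3, 4), c(5, 6, 7))),
    list(level = 1, label = 2, mode = "voxel", pen_width = 1,
         seeds = rbind(c(8, 8, 8))))
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(strokes, jf, auto_unbox = TRUE, digits = NA)
  back <- read_strokes(jf)
  expect_length(back, 2)
  expect_equal(back[[1]]$seeds, strokes[[1]]$seeds)

  cf <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(strokes, function(s)
    data.frame(level = s$level, label = s$label, mode = s$mode,
               pen_width = s$pen_width, z = s$seeds[, 1], y = s$seeds[, 2],
               x = s$seeds[, 3])))
  write.csv(df, cf, row.names = FALSE)
  back2 <- read_strokes(cf)
  expect_length(back2, 2)
  ws <- fresh_ws()
  l1 <- add_level(ws)
  add_label(ws, l1, "a"); add_label(ws, l1, "b")
  expect_silent(apply_strokes(ws, back2))
  expect_gt(sum(ws$levels[[as.character(l1)]]$voxel_labels >= 0), 0)
})

test_that("dilation grows, erosion shrinks, opening is idempotent", {
  ws <- fresh_ws(20)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  lv <- ws$levels[[as.character(l1)]]
  lv$voxel_labels[8:13, 8:13, 8:13] <- a
  lv$voxel_labels[10, 10, 2] <- a # isolated speck, removed by opening
  ws$levels[[as.character(l1)]] <- lv
  before <- ws$levels[[as.character(l1)]]$voxel_labels == a

  refine_label(ws, l1, a, "dilation", radius = 2,
               scope = "whole_volume_3d")
  after_d <- ws$levels[[as.character(l1)]]$voxel_labels == a
  expect_true(all(before[before])) # dilation is a superset
  expect_true(all(after_d[before]))
  expect_gt(sum(after_d), sum(before))
  # matches the brute-force ball dilation
  expect_identical(after_d, brute_dilate(before, 2))

  refine_label(ws, l1, a, "erosion", radius = 2,
               scope = "whole_volume_3d")
  after_e <- ws$levels[[as.character(l1)]]$voxel_labels == a
  expect_true(all(which(after_e) %in% which(after_d)))

  refine_label(ws, l1, a, "opening", radius = 1,
               scope = "whole_volume_3d")
  once <- ws$levels[[as.character(l1)]]$voxel_labels == a
  refine_label(ws, l1, a, "opening", radius = 1,
               scope = "whole_volume_3d")
  twice <- ws$levels[[as.character(l1)]]$voxel_labels == a
  expect_identical(once, twice)
})

test_that("fill_holes solidifies a hollow shell in 3D", {
  ws <- fresh_ws(21)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "shell")
  ctr <- array(FALSE, c(21, 21, 21)); ctr[11, 11, 11] <- TRUE
  d2 <- srvox:::edt_sq_cpp(as.logical(ctr), as.integer(dim(ctr)))
  lv <- ws$levels[[as.character(l1)]]
  lv$voxel_labels[d2 >= 25 & d2 <= 49] <- a
  ws$levels[[as.character(l1)]] <- lv
  refine_label(ws, l1, a, "fill_holes", scope = "whole_volume_3d")
  filled <- ws$levels[[as.character(l1)]]$voxel_labels == a
  expect_identical(unname(which(filled)), unname(which(d2 <= 49)))
})

test_that("dilation never overwrites other labels", {
  ws <- fresh_ws(16)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  b <- add_label(ws, l1, "b")
  lv <- ws$levels[[as.character(l1)]]
  lv$voxel_labels[, 1:8, ] <- a
  lv$voxel_labels[, 9:10, ] <- b
  ws$levels[[as.character(l1)]] <- lv
  refine_label(ws, l1, a, "dilation", radius = 3,
               scope = "whole_volume_3d")
  lab <- ws$levels[[as.character(l1)]]$voxel_labels
  expect_true(all(lab[, 9:10, ] == b))
  expect_true(all(lab[, 11, ] == a))  # grew into unlabeled space only
  expect_true(all(lab[, 12:16, ] == -1L)) # beyond the ball radius
  expect_error(refine_label(ws, l1, a, "dilation", radius = 50), "radius")
  expect_error(refine_label(ws, l1, a, "dilation", scope = "this_slice"),
               "slice")
})

test_that("2D scope operates slice by slice", {
  ws <- fresh_ws(12)
  l1 <- add_level(ws)
  a <- add_label(ws, l1, "a")
  lv <- ws$levels[[as.character(l1)]]
  # a ring in one slice only (hole not enclosed in 3D)
  lv$voxel_labels[6, 4:8, 4:8] <- a
  lv$voxel_labels[6, 5:7, 5:7] <- -1L
  ws$levels[[as.character(l1)]] <- lv
  refine_label(ws, l1, a, "fill_holes", scope = "all_slices_2d")
  lab <- ws$levels[[as.character(l1)]]$voxel_labels
  expect_true(all(lab[6, 4:8, 4:8] == a)) # 2D fill closes the ring
  expect_true(all(lab[-6, , ] == -1L))
})
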