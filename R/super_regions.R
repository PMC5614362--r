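# Two-tier super-region hierarchy: SLIC-style supervoxels over a source
# channel, then megavoxels by greedy graph agglomeration of similar adjacent
# supervoxels.

rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else x * 0
}

#' Compute supervoxels
#'
#' SLIC-style clustering: seeds start on a regular grid of cell size `shape`
#' (perturbed to the lowest-gradient voxel in a 3x3x3 neighborhood), then a
#' fixed number of assignment/update iterations minimize
#' `|I - c_I| + compactness/100 * d_spatial`, where the spatial distance is
#' normalized by the cell size and weighted per axis by `spacing`. A final
#' connectivity pass merges orphaned fragments (smaller than a quarter cell)
#' into the adjacent region discovered just before them, so every region is
#' 6-connected and ids are dense. Lower compactness lets supervoxels deform
#' more; `spacing` emphasizes boundary adherence per axis. The whole
#' procedure is deterministic.
#'
#' @param ws a workspace.
#' @param source `"raw"` or a channel name; intensities are rescaled to
#'   `[0, 1]` internally so compactness behaves comparably across datasets.
#' @param shape target cell size `(sz, sy, sx)`; the product must be <= 1024.
#' @param spacing per-axis spatial weights `(z, y, x)`.
#' @param compactness deformation penalty, usual range `[1, 200]`.
#' @param n_iter number of assignment/update iterations.
#' @return a `supervoxel_partition`: `labels` (3D integer grid over the ROI,
#'   ids `1..n_regions`), `n_regions`, and the parameters used. Also stored
#'   in the workspace (invalidates any megavoxel partition).
#' @export
compute_supervoxels <- function(ws, source = "raw", shape = c(10, 10, 10),
                                spacing = c(1, 1, 1), compactness = 20,
                                n_iter = 10) {
  stopifnot(inherits(ws, "srvox_workspace"), length(shape) == 3,
            length(spacing) == 3)
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("shape components must be >= 1")
  if (prod(shape) > 1024)
    stop("supervoxel shape parameters must equal 1024 or less when ",
         "multiplied together (got ", prod(shape), ")")
  if (compactness <= 0) stop("compactness must be > 0")
  check_range(compactness, "compactness")
  check_range(spacing, "sv_spacing", "spacing")
  x <- source_data(ws, source)
  d <- dim(x)
  if (any(shape > d))
    stop("shape exceeds the ROI extent on at least one axis")
  res <- slic_cpp(rescale01(x), as.integer(d), shape, as.numeric(spacing),
                  compactness, as.integer(n_iter))
  res <- enforce_connectivity_cpp(res$labels, as.integer(d),
                                  as.integer(max(1, prod(shape) %/% 4)))
  svp <- structure(list(labels = res$labels, n_regions = res$k,
                        params = list(source = source, shape = shape,
                                      spacing = spacing,
                                      compactness = compactness,
                                      n_iter = n_iter)),
                   class = "supervoxel_partition")
  ws$supervoxels <- svp
  ws$megavoxels <- NULL
  svp
}

#' @export
print.supervoxel_partition <- function(x, ...) {
  cat("supervoxel partition: ", x$n_regions, " regions over ",
      paste(dim(x$labels), collapse = "x"), " (source '",
      x$params$source, "')\n", sep = "")
  invisible(x)
}

chi2_hist_dist <- function(H) {
  # pairwise worker is not needed: distances are evaluated per edge
  function(i, j) {
    a <- H[i, ]; b <- H[j, ]
    s <- a + b
    ok <- s > 0
    0.5 * sum((a[ok] - b[ok])^2 / s[ok])
  }
}

#' Compute megavoxels
#'
#' Merges adjacent, similar supervoxels into megavoxels by greedy
#' agglomeration on the region adjacency graph (Felzenszwalb-style scale
#' test). Each supervoxel gets a `num_bins`-bin normalized intensity
#' histogram of the source channel; edge dissimilarity is the chi-squared
#' histogram distance (in `[0, 1]`). Edges are processed in increasing
#' dissimilarity and two clusters merge when the edge weight does not exceed
#' `min(Int(A) + lambda/|A|, Int(B) + lambda/|B|)`, with `Int` the largest
#' dissimilarity already absorbed: larger `lambda` therefore yields larger,
#' fewer megavoxels. The optional `gamma` sharpens similarity before merging
#' via `w' = 1 - exp(-w * gamma / median(w))`: small gamma makes neighbors
#' look more alike and so produces fewer megavoxels; `"auto"` uses the median
#' edge weight as gamma.
#'
#' @param ws a workspace (supervoxels must exist).
#' @param source `"raw"` or a channel name for the histograms.
#' @param lambda_mv merge scale in `(0, 1]`.
#' @param num_bins histogram bins (>= 2).
#' @param gamma `NULL` (off), `"auto"`, or a value in `[0, 1]`.
#' @return a `megavoxel_partition`: `sv_to_mv` (map supervoxel id ->
#'   megavoxel id, dense 1..n_regions), `n_regions`, parameters. Stored in
#'   the workspace.
#' @export
compute_megavoxels <- function(ws, source = "raw", lambda_mv = 0.1,
                               num_bins = 20, gamma = NULL) {
  stopifnot(inherits(ws, "srvox_workspace"))
  svp <- ws$supervoxels
  if (is.null(svp)) stop("compute supervoxels before megavoxels")
  if (lambda_mv <= 0 || lambda_mv > 1) stop("lambda_mv must be in (0, 1]")
  if (num_bins < 2) stop("num_bins must be >= 2")
  if (!is.null(gamma) && !identical(gamma, "auto") &&
      (gamma < 0 || gamma > 1))
    stop("gamma must be NULL, 'auto', or in [0, 1]")
  check_range(lambda_mv, "lambda_mv", "lambda")
  check_range(num_bins, "num_bins")

  x <- rescale01(source_data(ws, source))
  lab <- as.integer(svp$labels)
  K <- svp$n_regions
  bin <- pmin(num_bins, 1L + as.integer(floor(x * num_bins)))
  H <- matrix(0, K, num_bins)
  cnt <- tabulate(lab, K)
  idx <- (lab - 1L) * num_bins + bin
  tab <- tabulate(idx, K * num_bins)
  H <- matrix(tab, K, num_bins, byrow = TRUE)
  H <- H / pmax(cnt, 1)

  adj <- region_adjacency_cpp(svp$labels, as.integer(dim(svp$labels)))
  i <- adj[, 1]; j <- adj[, 2]
  s <- H[i, , drop = FALSE] + H[j, , drop = FALSE]
  dlt <- H[i, , drop = FALSE] - H[j, , drop = FALSE]
  w <- 0.5 * rowSums(ifelse(s > 0, dlt^2 / pmax(s, 1e-300), 0))

  if (!is.null(gamma)) {
    med <- median(w[w > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    g <- if (identical(gamma, "auto")) med else gamma
    w <- 1 - exp(-w * g / med)
  }

  ord <- order(w, i, j) # deterministic tie-break
  parent <- seq_len(K)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  int_w <- numeric(K)
  size <- rep(1L, K)
  for (e in ord) {
    ra <- find(i[e]); rb <- find(j[e])
    if (ra == rb) next
    we <- w[e]
    if (we <= min(int_w[ra] + lambda_mv / size[ra],
                  int_w[rb] + lambda_mv / size[rb])) {
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
      int_w[ra] <- max(int_w[ra], int_w[rb], we)
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))
  sv_to_mv <- match(roots, unique(roots))
  mvp <- structure(list(sv_to_mv = as.integer(sv_to_mv),
                        n_regions = length(unique(roots)),
                        params = list(source = source, lambda_mv = lambda_mv,
                                      num_bins = num_bins, gamma = gamma)),
                   class = "megavoxel_partition")
  ws$megavoxels <- mvp
  mvp
}

#' @export
print.megavoxel_partition <- function(x, ...) {
  cat("megavoxel partition: ", x$n_regions, " regions from ",
      length(x$sv_to_mv), " supervoxels\n", sep = "")
  invisible(x)
}

#' Supervoxel / megavoxel label grids
#'
#' @param ws a workspace with computed partitions.
#' @return integer 3D grid of region ids over the ROI.
#' @export
supervoxel_labels <- function(ws) {
  if (is.null(ws$supervoxels)) stop("no supervoxel partition")
  ws$supervoxels$labels
}

#' @rdname supervoxel_labels
#' @export
megavoxel_labels <- function(ws) {
  if (is.null(ws$megavoxels)) stop("no megavoxel partition")
  out <- ws$megavoxels$sv_to_mv[ws$supervoxels$labels]
  dim(out) <- dim(ws$supervoxels$labels)
  out
}

#' Per-region means of a channel
#'
#' @param labels integer 3D grid of region ids `1..K`.
#' @param data numeric array of the same extent.
#' @return numeric vector of length `K` with the mean of `data` over each
#'   region.
#' @export
region_means <- function(labels, data) {
  stopifnot(identical(dim(labels), dim(data)))
  k <- max(labels)
  sums <- rowsum(as.numeric(data), as.integer(labels))
  cnt <- tabulate(as.integer(labels), k)
  out <- as.numeric(sums[, 1]) / cnt
  out
}

#' Inter-region boundary map
#'
#' Marks every voxel having at least one 6-neighbor with a different region
#' id (both sides of each boundary face are marked).
#'
#' @param labels integer 3D grid of region ids.
#' @return logical array of the same extent.
#' @export
boundary_map <- function(labels) {
  d <- dim(labels)
  out <- array(FALSE, d)
  for (a in 1:3) {
    if (d[a] < 2) next
    nb <- shift_axis(labels, a, -1)
    diff_fwd <- labels != nb & slice.index(labels, a) != d[a]
    nb2 <- shift_axis(labels, a, 1)
    diff_bwd <- labels != nb2 & slice.index(labels, a) != 1
    out <- out | diff_fwd | diff_bwd
  }
  out
}
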