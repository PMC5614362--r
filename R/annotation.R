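# Hierarchical annotation levels, scribble strokes at voxel / supervoxel /
# megavoxel granularity, and morphological label refinement.

#' Add an annotation level
#'
#' A level holds a set of labels and a per-voxel integer grid over the ROI
#' (`-1` = unlabeled). Labels in later levels may declare a parent label from
#' an earlier level to express part-of hierarchies.
#'
#' @param ws a workspace.
#' @return the new level id (integer).
#' @export
add_level <- function(ws) {
  stopifnot(inherits(ws, "srvox_workspace"))
  id <- ws$next_level_id
  ws$next_level_id <- id + 1L
  lv <- list(id = id, labels = list(),
             voxel_labels = array(-1L, roi_dim(ws)), next_label_id = 1L)
  ws$levels[[as.character(id)]] <- lv
  id
}

get_level <- function(ws, level) {
  lv <- ws$levels[[as.character(level)]]
  if (is.null(lv)) stop("unknown annotation level: ", level)
  lv
}

set_level <- function(ws, lv) {
  ws$levels[[as.character(lv$id)]] <- lv
  invisible(lv)
}

#' Add a label to a level
#'
#' @param ws a workspace.
#' @param level level id.
#' @param name,color display metadata (mutable, not semantic).
#' @param parent optional `c(level, label)` reference to a label in an
#'   *earlier* level; child annotations must stay inside the parent's voxels.
#' @return the new label id (integer).
#' @export
add_label <- function(ws, level, name = NULL, color = NULL, parent = NULL) {
  lv <- get_level(ws, level)
  if (!is.null(parent)) {
    stopifnot(length(parent) == 2)
    if (parent[1] >= lv$id)
      stop("parent label must come from a previous level")
    plv <- get_level(ws, parent[1])
    if (!any(vapply(plv$labels, function(l) l$id == parent[2], logical(1))))
      stop("parent label ", parent[2], " not found in level ", parent[1])
  }
  id <- lv$next_label_id
  lv$next_label_id <- id + 1L
  lv$labels[[as.character(id)]] <-
    list(id = id, name = name %||% paste0("label", id),
         color = color %||% "#808080", parent = parent)
  set_level(ws, lv)
  id
}

pen_footprint <- function(seeds, pen_width, d) {
  # in-plane disk of radius pen_width around each seed (z, y, x), 1-based
  r <- pen_width
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
  out <- matrix(0L, 0, 3)
  for (s in seq_len(nrow(seeds))) {
    z <- seeds[s, 1]; y <- seeds[s, 2] + off$dy; x <- seeds[s, 3] + off$dx
    ok <- y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    out <- rbind(out, cbind(z, y[ok], x[ok]))
  }
  unique(out)
}

#' Apply a scribble stroke
#'
#' Labels voxels around the stroke seeds. In `voxel` mode the pen footprint
#' (an in-plane disk of radius `pen_width`) is labeled directly; in
#' `supervoxel` / `megavoxel` mode every voxel of each super-region touched
#' by the footprint is labeled, so a single click can claim thousands of
#' similar voxels. Later strokes overwrite earlier labels (last stroke
#' wins). If the target label has a parent, voxels outside the parent's
#' region are rejected and their count reported as attribute `"rejected"`.
#'
#' @param ws a workspace.
#' @param level level id.
#' @param label label id within the level.
#' @param seeds integer matrix of seed coordinates, one `(z, y, x)` row per
#'   seed, 1-based, relative to the ROI.
#' @param mode `"voxel"`, `"supervoxel"` or `"megavoxel"`.
#' @param pen_width pen radius in voxels (>= 1).
#' @return number of voxels labeled, invisibly (attribute `"rejected"`
#'   counts voxels refused by the parent constraint).
#' @export
annotate <- function(ws, level, label, seeds, mode = "supervoxel",
                     pen_width = 1) {
  mode <- match.arg(mode, c("voxel", "supervoxel", "megavoxel"))
  stopifnot(pen_width >= 1)
  lv <- get_level(ws, level)
  lab <- lv$labels[[as.character(label)]]
  if (is.null(lab)) stop("unknown label ", label, " in level ", level)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- roi_dim(ws)
  if (any(seeds < 1) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("stroke seeds outside the ROI")
  fp <- pen_footprint(seeds, pen_width, d)
  sel <- array(FALSE, d)
  sel[fp] <- TRUE
  if (mode != "voxel") {
    if (is.null(ws$supervoxels)) stop("no supervoxel partition for ", mode,
                                      " annotation")
    rl <- if (mode == "supervoxel") supervoxel_labels(ws)
          else megavoxel_labels(ws)
    hit <- unique(rl[sel])
    sel <- array(rl %in% hit, d)
  }
  rejected <- 0L
  if (!is.null(lab$parent)) {
    plv <- get_level(ws, lab$parent[1])
    inside <- plv$voxel_labels == lab$parent[2]
    rejected <- sum(sel & !inside)
    sel <- sel & inside
  }
  lv$voxel_labels[sel] <- lab$id
  set_level(ws, lv)
  invisible(structure(sum(sel), rejected = rejected))
}

#' Read strokes from a JSON/CSV sidecar
#'
#' JSON: an array of objects with fields `level`, `label`, `mode`,
#' `pen_width` and `seeds` (an n x 3 matrix of `(z, y, x)` rows).
#' CSV: columns `level, label, mode, pen_width, z, y, x`, one seed per row;
#' consecutive rows sharing all stroke fields form one stroke.
#'
#' @param path file path (`.json` or `.csv`).
#' @return list of stroke records suitable for [apply_strokes()].
#' @export
read_strokes <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lapply(raw, function(s) {
      s$seeds <- if (is.matrix(s$seeds)) s$seeds else
        matrix(as.integer(unlist(s$seeds)), ncol = 3, byrow = TRUE)
      storage.mode(s$seeds) <- "integer"
      s
    })
  } else {
    df <- read.csv(path)
    key <- interaction(df$level, df$label, df$mode, df$pen_width,
                       drop = TRUE)
    lapply(split(df, key), function(g) {
      list(level = g$level[1], label = g$label[1], mode = as.character(g$mode[1]),
           pen_width = g$pen_width[1],
           seeds = as.matrix(g[, c("z", "y", "x")]))
    })
  }
}

#' Apply a list of strokes in order
#' @param ws a workspace.
#' @param strokes list of stroke records (see [read_strokes()]).
#' @return invisibly, total voxels labeled.
#' @export
apply_strokes <- function(ws, strokes) {
  n <- 0L
  for (s in strokes)
    n <- n + annotate(ws, s$level, s$label, s$seeds,
                      s$mode %||% "supervoxel", s$pen_width %||% 1)
  invisible(n)
}

#' Morphological refinement of one label
#'
#' Applies a binary morphological operator to the voxel set of one label
#' using a discrete Euclidean ball of the given radius. `dilation` grows the
#' label but only claims voxels that are unlabeled (it never overwrites
#' other labels, and never escapes the parent label when one is set);
#' `erosion` shrinks it; `opening`/`closing` compose the two; `fill_holes`
#' fills enclosed background cavities. Scope `all_slices_2d` applies the 2D
#' operator slice by slice, `whole_volume_3d` in 3D, `this_slice` to the
#' single slice given by `slice`.
#'
#' @param ws a workspace.
#' @param level level id.
#' @param label label id.
#' @param method one of `"dilation"`, `"erosion"`, `"opening"`, `"closing"`,
#'   `"fill_holes"`.
#' @param radius structuring-element radius in voxels, in `[1, 20]`.
#' @param scope `"all_slices_2d"` (default, recommended), `"whole_volume_3d"`
#'   or `"this_slice"`.
#' @param slice z index for `this_slice`.
#' @return invisibly, the updated voxel count of the label.
#' @export
refine_label <- function(ws, level, label, method, radius = 1,
                         scope = "all_slices_2d", slice = NULL) {
  method <- match.arg(method, c("dilation", "erosion", "opening", "closing",
                                "fill_holes"))
  scope <- match.arg(scope, c("all_slices_2d", "whole_volume_3d",
                              "this_slice"))
  if (radius < 1 || radius > 20) stop("radius must be in [1, 20]")
  lv <- get_level(ws, level)
  lab <- lv$labels[[as.character(label)]]
  if (is.null(lab)) stop("unknown label ", label)
  vl <- lv$voxel_labels
  mask <- vl == label

  op3 <- function(m) morph_op(m, method, radius)
  new_mask <-
    if (scope == "whole_volume_3d") {
      op3(mask)
    } else if (scope == "all_slices_2d") {
      out <- mask
      for (z in seq_len(dim(mask)[1]))
        out[z, , ] <- morph_op_slice(mask[z, , , drop = TRUE], method, radius)
      out
    } else {
      if (is.null(slice)) stop("scope 'this_slice' requires `slice`")
      out <- mask
      out[slice, , ] <- morph_op_slice(mask[slice, , , drop = TRUE], method,
                                       radius)
      out
    }

  grown <- new_mask & !mask
  # growth never overwrites other labels
  grown <- grown & (vl == -1L)
  if (!is.null(lab$parent)) {
    plv <- get_level(ws, lab$parent[1])
    grown <- grown & (plv$voxel_labels == lab$parent[2])
  }
  removed <- mask & !new_mask
  vl[removed] <- -1L
  vl[grown] <- lab$id
  lv$voxel_labels <- vl
  set_level(ws, lv)
  invisible(sum(vl == lab$id))
}

# 3D ball morphology via the squared Euclidean distance transform
dilate_mask <- function(mask, radius) {
  if (!any(mask)) return(mask)
  d2 <- edt_sq_cpp(as.logical(mask), as.integer(dim(mask)))
  out <- d2 <= radius^2 + 1e-9
  dim(out) <- dim(mask)
  out
}

erode_mask <- function(mask, radius) !dilate_mask(!mask, radius)

fill_holes_mask <- function(mask, connectivity = 6) {
  bg <- cc_label_cpp(as.logical(!mask), as.integer(dim(mask)),
                     as.integer(connectivity))
  d <- dim(mask)
  border_ids <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                         bg[, , 1], bg[, , d[3]]))
  border_ids <- setdiff(border_ids, 0L)
  holes <- bg != 0 & !(bg %in% border_ids)
  dim(holes) <- d
  mask | holes
}

morph_op <- function(mask, method, radius) {
  switch(method,
    dilation = dilate_mask(mask, radius),
    erosion = erode_mask(mask, radius),
    opening = dilate_mask(erode_mask(mask, radius), radius),
    closing = erode_mask(dilate_mask(mask, radius), radius),
    fill_holes = fill_holes_mask(mask)
  )
}

# 2D variants reuse the 3D code on a 1-slice array
morph_op_slice <- function(mask2d, method, radius) {
  m <- array(mask2d, dim = c(1, dim(mask2d)))
  out <- morph_op_2d(m, method, radius)
  out[1, , ]
}

morph_op_2d <- function(m1, method, radius) {
  switch(method,
    fill_holes = {
      # border = slice border only (the z faces are the slice itself)
      d <- dim(m1)
      bg <- cc_label_cpp(as.logical(!m1), as.integer(d), 6L)
      border_ids <- setdiff(unique(c(bg[, 1, ], bg[, d[2], ], bg[, , 1],
                                     bg[, , d[3]])), 0L)
      holes <- bg != 0 & !(bg %in% border_ids)
      dim(holes) <- d
      m1 | holes
    },
    morph_op(m1, method, radius) # EDT on 1-slice array == 2D ops
  )
}
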