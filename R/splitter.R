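# Rule-based splitting of a segmentation into connected objects with
# per-object measures (intensity, variance, volume, position), plus
# statistics export.

#' Extract connected objects from annotation labels
#'
#' Connected components (26-neighborhood by default) are computed per
#' selected label and pooled; touching objects carrying different labels
#' stay separate. Intensity measures are taken over `query_channel`.
#' Measures per object: `average_intensity`, `intensity_sd`,
#' `intensity_var`, `volume_voxels`, `volume_calibrated`, centroid
#' (`centroid_z/y/x`), bounding box (`bbox_*`), and per-axis extent.
#'
#' @param ws a workspace.
#' @param level level id.
#' @param labels label ids to include (default: all labels of the level).
#' @param query_channel `"raw"` or a channel name for intensity measures.
#' @param connectivity 26 (default) or 6.
#' @param voxel_size physical size of a voxel per axis `(z, y, x)` for
#'   `volume_calibrated`.
#' @return a `seg_objects` record: `$table` (one row per object) and the
#'   object-id grid used by [save_split()].
#' @export
extract_objects <- function(ws, level, labels = NULL, query_channel = "raw",
                            connectivity = 26, voxel_size = c(1, 1, 1)) {
  lv <- get_level(ws, level)
  sel <- labels %||% vapply(lv$labels, function(l) l$id, integer(1))
  if (length(sel) == 0) stop("no labels selected")
  x <- source_data(ws, query_channel)
  d <- dim(lv$voxel_labels)
  obj_grid <- array(0L, d)
  rows <- list()
  next_id <- 0L
  for (lab in sort(as.integer(sel))) {
    mask <- lv$voxel_labels == lab
    if (!any(mask)) next
    cc <- cc_label_cpp(as.logical(mask), as.integer(d),
                       as.integer(connectivity))
    for (k in seq_len(max(cc))) {
      next_id <- next_id + 1L
      vox <- which(cc == k)
      obj_grid[vox] <- next_id
      coord <- arrayInd(vox, d)
      vals <- x[vox]
      n <- length(vox)
      rows[[next_id]] <- data.frame(
        object_id = next_id, source_label = lab,
        average_intensity = mean(vals),
        intensity_sd = if (n > 1) sd(vals) else 0,
        intensity_var = if (n > 1) var(vals) else 0,
        volume_voxels = n,
        volume_calibrated = n * prod(voxel_size),
        centroid_z = mean(coord[, 1]), centroid_y = mean(coord[, 2]),
        centroid_x = mean(coord[, 3]),
        bbox_z0 = min(coord[, 1]), bbox_z1 = max(coord[, 1]),
        bbox_y0 = min(coord[, 2]), bbox_y1 = max(coord[, 2]),
        bbox_x0 = min(coord[, 3]), bbox_x1 = max(coord[, 3]),
        extent_z = diff(range(coord[, 1])) + 1L,
        extent_y = diff(range(coord[, 2])) + 1L,
        extent_x = diff(range(coord[, 3])) + 1L)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = integer(0))
  structure(list(table = tab, object_grid = obj_grid, level = level,
                 labels = sel, query_channel = query_channel),
            class = "seg_objects")
}

#' @export
print.seg_objects <- function(x, ...) {
  cat("seg_objects: ", nrow(x$table), " objects from level ", x$level,
      " (labels ", paste(x$labels, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Build a rule label for object splitting
#'
#' @param name class name.
#' @param rules list of rules, each `list(measure=, comparator=, value=)`
#'   with comparator one of `"<"`, `"<="`, `">"`, `">="`, `"between"`
#'   (value = `c(lo, hi)`, inclusive). Rules within a label are conjunctive.
#' @param color display color.
#' @param is_others flag: collects every object matched by no rule label
#'   (at most one per split; such a label carries no rules).
#' @return a `rule_label` record.
#' @export
rule_label <- function(name, rules = list(), color = "#808080",
                       is_others = FALSE) {
  for (r in rules)
    if (!r$comparator %in% c("<", "<=", ">", ">=", "between"))
      stop("unknown comparator: ", r$comparator)
  structure(list(name = name, rules = rules, color = color,
                 is_others = is_others), class = "rule_label")
}

rule_holds <- function(rule, tab) {
  if (!rule$measure %in% names(tab))
    stop("rule references unknown measure: ", rule$measure)
  v <- tab[[rule$measure]]
  switch(rule$comparator,
    "<" = v < rule$value, "<=" = v <= rule$value,
    ">" = v > rule$value, ">=" = v >= rule$value,
    between = v >= rule$value[1] & v <= rule$value[2])
}

#' Assign objects to rule labels
#'
#' Each object goes to the first rule label (in list order) whose rules all
#' hold; unmatched objects fall to the `is_others` label when present,
#' otherwise they stay unclassified (`NA`).
#'
#' @param objects a `seg_objects` record.
#' @param rule_labels ordered list of [rule_label()] records; at most one
#'   may have `is_others = TRUE`.
#' @return `objects` with a `class` column added to `$table`.
#' @export
apply_split <- function(objects, rule_labels) {
  stopifnot(inherits(objects, "seg_objects"))
  if (sum(vapply(rule_labels, function(l) isTRUE(l$is_others),
                 logical(1))) > 1)
    stop("at most one 'others' label is allowed")
  tab <- objects$table
  cls <- rep(NA_character_, nrow(tab))
  others <- NULL
  for (rl in rule_labels) {
    if (isTRUE(rl$is_others)) { others <- rl$name; next }
    ok <- rep(TRUE, nrow(tab))
    for (r in rl$rules) ok <- ok & rule_holds(r, tab)
    cls[is.na(cls) & ok] <- rl$name
  }
  if (!is.null(others)) cls[is.na(cls)] <- others
  objects$table$class <- cls
  objects$rule_labels <- rule_labels
  objects
}

#' Read rule labels from a JSON config
#'
#' JSON: an array of objects `{name, color, is_others, rules: [{measure,
#' comparator, value}]}`.
#' @param path JSON file path.
#' @return list of `rule_label` records.
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(s)
    rule_label(s$name, lapply(s$rules %||% list(), function(r) {
      r$value <- unlist(r$value)
      r
    }), s$color %||% "#808080", isTRUE(s$is_others)))
}

#' Save a split into an empty annotation level
#'
#' Writes each object's voxels into the target level under an integer id
#' per class (in first-appearance order of the class names); a label record
#' is added per class. Voxel count is conserved from the classified objects.
#'
#' @param ws a workspace.
#' @param objects a classified `seg_objects` (after [apply_split()]).
#' @param target_level id of an *empty* level.
#' @return invisibly, named vector mapping class name -> label id.
#' @export
save_split <- function(ws, objects, target_level) {
  lv <- get_level(ws, target_level)
  if (any(lv$voxel_labels >= 0) || length(lv$labels) > 0)
    stop("target level must be empty")
  tab <- objects$table
  if (is.null(tab$class)) stop("objects have not been classified; run ",
                               "apply_split() first")
  classes <- unique(tab$class[!is.na(tab$class)])
  ids <- integer(0)
  for (cn in classes) ids[cn] <- add_label(ws, target_level, name = cn)
  lv <- get_level(ws, target_level)
  lut <- rep(NA_integer_, max(c(0L, tab$object_id)))
  for (i in seq_len(nrow(tab)))
    if (!is.na(tab$class[i])) lut[tab$object_id[i]] <- ids[[tab$class[i]]]
  sel <- objects$object_grid > 0
  assigned <- sel
  assigned[sel] <- !is.na(lut[objects$object_grid[sel]])
  lv$voxel_labels[assigned] <- lut[objects$object_grid[assigned]]
  set_level(ws, lv)
  invisible(ids)
}

#' Long-format measure table and pairwise plots
#'
#' Builds the long table (object id, class, measure, value) over the
#' selected measures, writes it as CSV when `csv` is given, and emits one
#' scatter plot per measure pair when `plot_dir` is given (PNG when the
#' device is available, PDF otherwise).
#'
#' @param objects a `seg_objects` record (classified or not).
#' @param measures measure column names (default: the numeric measures).
#' @param csv optional CSV output path.
#' @param plot_dir optional directory for pairwise plots.
#' @return list with `long` (the long table) and `pairs` (a k(k-1)/2 x 2
#'   matrix of measure pairs).
#' @export
label_statistics <- function(objects, measures = NULL, csv = NULL,
                             plot_dir = NULL) {
  tab <- objects$table
  default <- c("average_intensity", "intensity_sd", "volume_voxels",
               "centroid_z", "centroid_y", "centroid_x")
  measures <- measures %||% intersect(default, names(tab))
  missing <- setdiff(measures, names(tab))
  if (length(missing)) stop("unknown measure(s): ",
                            paste(missing, collapse = ", "))
  cls <- if ("class" %in% names(tab)) tab$class else NA_character_
  long <- do.call(rbind, lapply(measures, function(m)
    data.frame(object_id = tab$object_id, class = cls, measure = m,
               value = tab[[m]])))
  pairs <- if (length(measures) >= 2) t(utils::combn(measures, 2)) else
    matrix(character(0), 0, 2)
  if (!is.null(csv)) {
    out <- long
    out$value <- sprintf("%.17g", out$value) # lossless double round-trip
    write.csv(out, csv, row.names = FALSE)
  }
  if (!is.null(plot_dir) && nrow(pairs) > 0) {
    if (!dir.exists(plot_dir)) dir.create(plot_dir, recursive = TRUE)
    use_png <- capabilities("png")
    colv <- as.integer(factor(cls))
    colv[is.na(colv)] <- 1L
    for (p in seq_len(nrow(pairs))) {
      base <- file.path(plot_dir, paste0(pairs[p, 1], "_vs_", pairs[p, 2]))
      if (use_png) grDevices::png(paste0(base, ".png"), 640, 640)
      else grDevices::pdf(paste0(base, ".pdf"))
      graphics::plot(tab[[pairs[p, 1]]], tab[[pairs[p, 2]]],
                     col = colv, pch = 19,
                     xlab = pairs[p, 1], ylab = pairs[p, 2])
      grDevices::dev.off()
    }
  }
  list(long = long, pairs = pairs)
}
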