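# End-to-end reproducible runs from a single configuration, the scripted
# equivalent of the interactive protocol (load -> ROI -> channels ->
# super-regions -> annotate -> train -> refine -> split -> stats -> export).
# Any stage may be omitted.

#' Run a full segmentation pipeline from a config
#'
#' The config is a nested list (or a YAML/JSON file path) with optional
#' stages executed in protocol order:
#' \describe{
#'   \item{seed}{integer; seeds phantom generation and training.}
#'   \item{input}{either `list(path=, orientation=, dataset=)` or
#'     `list(phantom = list(type = "multiregion"|"organelle", <args>))`.}
#'   \item{roi}{bounds `(z0, z1, y0, y1, x0, x1)`.}
#'   \item{channels}{list of channel specs for [compute_queue()].}
#'   \item{supervoxels}{args of [compute_supervoxels()].}
#'   \item{megavoxels}{args of [compute_megavoxels()].}
#'   \item{annotations}{`list(labels = list(list(name=, color=)), strokes =
#'     <path or list of stroke records>)`; a level is created for them.}
#'   \item{train}{args of [train_config()] minus `predict_level`, plus
#'     `rounds`; runs [iterate_training()] on the annotation level.}
#'   \item{refine}{list of morphology steps `list(label=, method=, radius=,
#'     scope=)` applied to the annotation level in order.}
#'   \item{split}{`list(labels=, query_channel=, rules = <path or list>,
#'     measures=, csv=, plot_dir=)`; objects are extracted, classified and
#'     saved to a fresh level.}
#'   \item{export}{list of export specs, args of [export_workspace()].}
#'   \item{log_path}{optional JSON run-log output.}
#' }
#'
#' @param config nested list, or path to a `.yaml`/`.json` config.
#' @return invisibly, `list(workspace, level, history, objects, stats,
#'   exports, log)`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- switch(tolower(tools::file_ext(config)),
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::fromJSON(config, simplifyDataFrame = FALSE),
      stop("config must be YAML or JSON"))
  }
  seed <- config$seed %||% 1
  log <- list()
  tick <- function(stage, params, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log[[length(log) + 1]] <<- list(stage = stage, params = params,
                                    elapsed_s = round(proc.time()[["elapsed"]]
                                                      - t0, 3))
    val
  }
  res <- list()

  # 1. load
  ws <- tick("load", config$input, {
    inp <- config$input %||% stop("config$input is required")
    if (!is.null(inp$phantom)) {
      ph <- inp$phantom
      ph$seed <- ph$seed %||% seed
      type <- ph$type %||% "multiregion"
      ph$type <- NULL
      gen <- switch(type, multiregion = make_multiregion,
                    organelle = make_organelle_cell,
                    stop("unknown phantom type: ", type))
      phantom <- do.call(gen, ph)
      res$phantom <- phantom
      new_workspace(phantom$volume)
    } else {
      load_volume(inp$path, inp$orientation %||% "zyx", inp$dataset)
    }
  })

  # 2. ROI
  if (!is.null(config$roi))
    tick("roi", config$roi, set_roi(ws, unlist(config$roi)))

  # 3. feature channels
  if (!is.null(config$channels))
    tick("channels", config$channels, compute_queue(ws, config$channels))

  # 4. super-regions
  if (!is.null(config$supervoxels))
    tick("supervoxels", config$supervoxels,
         do.call(compute_supervoxels, c(list(ws), config$supervoxels)))
  if (!is.null(config$megavoxels))
    tick("megavoxels", config$megavoxels,
         do.call(compute_megavoxels, c(list(ws), config$megavoxels)))

  # 5. annotations
  level <- NULL
  if (!is.null(config$annotations)) {
    level <- tick("annotations", config$annotations, {
      lvl <- add_level(ws)
      for (lb in config$annotations$labels %||% list())
        add_label(ws, lvl, lb$name, lb$color)
      st <- config$annotations$strokes
      if (is.character(st)) st <- read_strokes(st)
      if (!is.null(st)) {
        st <- lapply(st, function(s) {
          s$level <- lvl
          s$seeds <- matrix(as.integer(unlist(s$seeds)), ncol = 3,
                            byrow = !is.matrix(s$seeds))
          s
        })
        apply_strokes(ws, st)
      }
      lvl
    })
    res$level <- level
  }

  # 6. model training
  if (!is.null(config$train)) {
    tr <- config$train
    rounds <- tr$rounds %||% 5
    tr$rounds <- NULL
    tr$predict_level <- tr$predict_level %||% level
    tr$sources <- unlist(tr$sources)
    tr$seed <- tr$seed %||% seed
    cfg <- do.call(train_config, tr)
    res$history <- tick("train", tr, iterate_training(ws, cfg, rounds))
  }

  # morphology refinement
  if (!is.null(config$refine)) {
    tick("refine", config$refine, {
      for (st in config$refine)
        refine_label(ws, st$level %||% level, st$label, st$method,
                     st$radius %||% 1, st$scope %||% "all_slices_2d")
      NULL
    })
  }

  # 7. label splitting + statistics
  if (!is.null(config$split)) {
    sp <- config$split
    res$objects <- tick("split", sp, {
      obj <- extract_objects(ws, sp$level %||% level, sp$labels,
                             sp$query_channel %||% "raw")
      rules <- sp$rules
      if (is.character(rules)) rules <- read_rules(rules)
      else if (!is.null(rules))
        rules <- lapply(rules, function(r)
          rule_label(r$name, lapply(r$rules %||% list(), function(x) {
            x$value <- unlist(x$value)
            x
          }), r$color %||% "#808080", isTRUE(r$is_others)))
      if (!is.null(rules)) {
        obj <- apply_split(obj, rules)
        tgt <- add_level(ws)
        save_split(ws, obj, tgt)
        res$split_level <- tgt
      }
      obj
    })
    if (!is.null(sp$measures) || !is.null(sp$csv))
      res$stats <- tick("stats", sp,
                        label_statistics(res$objects, sp$measures, sp$csv,
                                         sp$plot_dir))
  }

  # 8. export
  if (!is.null(config$export)) {
    res$exports <- tick("export", config$export,
                        unlist(lapply(config$export, function(e)
                          do.call(export_workspace, c(list(ws), e)))))
  }

  if (!is.null(config$log_path))
    jsonlite::write_json(log, config$log_path, auto_unbox = TRUE,
                         digits = NA)
  res$workspace <- ws
  res$log <- log
  invisible(res)
}
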