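# Classifier-driven segmentation over super-regions: per-region descriptors
# from feature channels, a probabilistic classifier trained on scribbled
# regions, MRF refinement on the region adjacency graph, and
# confidence-gated commitment of predictions back into annotation labels.

#' Training configuration
#'
#' @param predict_level level id holding the training annotations.
#' @param sources channel names (or `"raw"`) used as descriptors; non-empty.
#' @param region `"supervoxel"` (default) or `"voxel"`.
#' @param classifier `"ensemble_rf"` (random forest, default), `"svm"`, or
#'   `"online_linear"` (penalized multinomial logistic regression).
#' @param n_trees random-forest size, usual range `[10, 100]`.
#' @param refinement `"appearance"` (default), `"potts"`, or `"none"`.
#' @param refine_lambda pairwise coupling strength, usual range `[1, 500]`.
#' @param confidence commitment threshold in `[0, 100]`.
#' @param seed RNG seed controlling classifier fitting.
#' @return a `train_config` list.
#' @export
train_config <- function(predict_level, sources, region = "supervoxel",
                         classifier = "ensemble_rf", n_trees = 100,
                         refinement = "appearance", refine_lambda = 10,
                         confidence = 50, seed = 1) {
  if (length(sources) == 0) stop("sources must be non-empty")
  region <- match.arg(region, c("supervoxel", "voxel"))
  classifier <- match.arg(classifier, c("ensemble_rf", "svm",
                                        "online_linear"))
  refinement <- match.arg(refinement, c("appearance", "potts", "none"))
  check_range(n_trees, "n_trees")
  check_range(refine_lambda, "refine_lambda")
  if (confidence < 0 || confidence > 100)
    stop("confidence must be in [0, 100]")
  structure(list(predict_level = predict_level, sources = sources,
                 region = region, classifier = classifier,
                 n_trees = n_trees, refinement = refinement,
                 refine_lambda = refine_lambda, confidence = confidence,
                 seed = seed),
            class = "train_config")
}

#' Per-region descriptor matrix
#'
#' For every region and every source channel: mean, standard deviation and
#' the 25/50/75th percentiles of the channel values inside the region
#' (5 columns per channel).
#'
#' @param ws a workspace with supervoxels.
#' @param sources channel names or `"raw"`.
#' @param labels optional region label grid (defaults to the supervoxel
#'   partition).
#' @return numeric matrix, rows = regions (id order), named columns.
#' @export
build_descriptors <- function(ws, sources, labels = NULL) {
  if (length(sources) == 0) stop("sources must be non-empty")
  labels <- labels %||% supervoxel_labels(ws)
  lab <- as.integer(labels)
  k <- max(lab)
  ord <- order(lab)
  cnt <- tabulate(lab, k)
  ends <- cumsum(cnt)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- matrix(NA_real_, k, 5 * length(sources))
  cn <- character(0)
  for (ci in seq_along(sources)) {
    v <- as.numeric(source_data(ws, sources[ci]))[ord]
    for (r in seq_len(k)) {
      seg <- v[starts[r]:ends[r]]
      q <- quantile(seg, c(0.25, 0.5, 0.75), names = FALSE)
      out[r, (ci - 1) * 5 + 1:5] <- c(mean(seg),
                                      if (length(seg) > 1) sd(seg) else 0,
                                      q)
    }
    cn <- c(cn, paste0(sources[ci], c("_mean", "_sd", "_q25", "_q50",
                                      "_q75")))
  }
  colnames(out) <- cn
  out
}

region_training_labels <- function(voxel_labels, region_labels) {
  # majority vote of annotated voxels within each region; NA if none
  k <- max(region_labels)
  ann <- voxel_labels >= 0
  if (!any(ann)) return(rep(NA_integer_, k))
  tab <- table(factor(region_labels[ann], levels = seq_len(k)),
               voxel_labels[ann])
  out <- rep(NA_integer_, k)
  has <- rowSums(tab) > 0
  cls <- as.integer(colnames(tab))
  out[has] <- cls[max.col(tab[has, , drop = FALSE], ties.method = "first")]
  out
}

fit_probs <- function(X, y, Xall, classifier, n_trees, seed) {
  set.seed(seed)
  yf <- factor(y)
  if (nlevels(yf) < 2) stop("training set contains a single class")
  keep <- apply(X, 2, function(v) sd(v) > 0) # drop constant columns
  if (!any(keep)) keep[] <- TRUE
  X <- X[, keep, drop = FALSE]; Xall <- Xall[, keep, drop = FALSE]
  prob <- switch(classifier,
    ensemble_rf = {
      fit <- randomForest::randomForest(X, yf, ntree = n_trees)
      predict(fit, Xall, type = "prob")
    },
    svm = {
      fit <- e1071::svm(X, yf, probability = TRUE, kernel = "radial")
      p <- attr(predict(fit, Xall, probability = TRUE), "probabilities")
      p[, levels(yf), drop = FALSE]
    },
    online_linear = {
      fit <- glmnet::glmnet(X, yf, family = "multinomial", alpha = 0,
                            lambda = 0.01)
      p <- predict(fit, Xall, type = "response")[, , 1]
      if (is.null(dim(p))) p <- matrix(p, ncol = nlevels(yf))
      colnames(p) <- levels(yf)
      p
    })
  prob <- prob / rowSums(prob)
  colnames(prob) <- levels(yf)
  prob
}

#' Train a classifier on annotated regions and predict all regions
#'
#' Regions containing scribbled voxels (majority label) form the training
#' set; descriptors are region statistics of the configured source channels.
#' The fitted classifier emits a class-probability row for every region.
#' Training regions keep their user-assigned label (probability 1)
#' regardless of the classifier output. Deterministic given `cfg$seed`.
#'
#' @param ws a workspace with supervoxels and an annotated level.
#' @param cfg a [train_config()].
#' @return a `prediction_result`: `prob` (regions x classes), `labels_hat`
#'   (argmax ids), `train_mask`, `level`, `region_labels` grid reference.
#' @export
train_predict <- function(ws, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  lv <- get_level(ws, cfg$predict_level)
  region_labels <- if (cfg$region == "supervoxel") supervoxel_labels(ws)
    else array(seq_along(lv$voxel_labels), roi_dim(ws))
  ytrain <- region_training_labels(lv$voxel_labels, region_labels)
  classes <- sort(unique(ytrain[!is.na(ytrain)]))
  if (length(classes) < 2)
    stop("need at least 2 annotated classes to train")
  X <- build_descriptors(ws, cfg$sources, labels = region_labels)
  tr <- !is.na(ytrain)
  prob <- fit_probs(X[tr, , drop = FALSE], ytrain[tr], X, cfg$classifier,
                    cfg$n_trees, cfg$seed)
  # training regions keep their label
  cls_ids <- as.integer(colnames(prob))
  prob[tr, ] <- 0
  prob[cbind(which(tr), match(ytrain[tr], cls_ids))] <- 1
  structure(list(prob = prob, classes = cls_ids,
                 labels_hat = cls_ids[max.col(prob, ties.method = "first")],
                 train_mask = tr, train_labels = ytrain,
                 level = cfg$predict_level, region = cfg$region,
                 refined = FALSE, energy_trace = NULL),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction over ", nrow(x$prob), " regions, ", length(x$classes),
      " classes (", sum(x$train_mask), " training regions)",
      if (x$refined) ", refined", "\n", sep = "")
  invisible(x)
}

#' MRF refinement of region predictions
#'
#' MAP relabeling over the supervoxel adjacency graph with unary cost
#' `-log p(region, class)` and pairwise cost `refine_lambda * w_e` on
#' disagreeing neighbors, where `w_e = 1` for Potts and
#' `w_e = exp(-(dmean)^2 / (2 s^2))` (s = median absolute neighbor mean
#' difference) for appearance coupling, so similar-looking neighbors are
#' penalized more for disagreeing. Solved by iterated conditional modes in a
#' fixed region-id sweep order until no label changes (at most 50 sweeps);
#' the energy after each sweep is recorded and never increases. Training
#' regions are held fixed.
#'
#' @param ws a workspace.
#' @param pred a `prediction_result` from [train_predict()].
#' @param refinement `"potts"` or `"appearance"`.
#' @param refine_lambda coupling strength (>= 0).
#' @param source channel used for appearance similarity.
#' @return the refined `prediction_result` (adds `energy_trace`).
#' @export
refine_predictions <- function(ws, pred, refinement = "appearance",
                               refine_lambda = 10, source = "raw") {
  stopifnot(inherits(pred, "prediction_result"))
  refinement <- match.arg(refinement, c("potts", "appearance", "none"))
  if (refinement == "none") return(pred)
  if (pred$region != "supervoxel")
    stop("refinement operates on supervoxel predictions")
  svl <- supervoxel_labels(ws)
  adj <- region_adjacency_cpp(svl, as.integer(dim(svl)))
  wts <- if (refinement == "potts") rep(1, nrow(adj)) else {
    mu <- region_means(svl, source_data(ws, source))
    dm <- abs(mu[adj[, 1]] - mu[adj[, 2]])
    s <- median(dm)
    if (!is.finite(s) || s <= 0) s <- 1
    exp(-dm^2 / (2 * s^2))
  }
  unary <- -log(pmax(pred$prob, 1e-12))
  K <- nrow(unary)
  nbrs <- vector("list", K)
  nbw <- vector("list", K)
  for (e in seq_len(nrow(adj))) {
    a <- adj[e, 1]; b <- adj[e, 2]
    nbrs[[a]] <- c(nbrs[[a]], b); nbw[[a]] <- c(nbw[[a]], wts[e])
    nbrs[[b]] <- c(nbrs[[b]], a); nbw[[b]] <- c(nbw[[b]], wts[e])
  }
  lab <- match(pred$labels_hat, pred$classes)
  nclass <- length(pred$classes)
  energy <- function() {
    u <- sum(unary[cbind(seq_len(K), lab)])
    p <- sum(wts * (lab[adj[, 1]] != lab[adj[, 2]]))
    u + refine_lambda * p
  }
  trace <- energy()
  for (sweep in seq_len(50)) {
    changed <- FALSE
    for (r in seq_len(K)) {
      if (pred$train_mask[r]) next
      cost <- unary[r, ]
      if (length(nbrs[[r]])) {
        nl <- lab[nbrs[[r]]]
        for (cl in seq_len(nclass))
          cost[cl] <- cost[cl] + refine_lambda * sum(nbw[[r]][nl != cl])
      }
      best <- which.min(cost)
      if (best != lab[r]) {
        lab[r] <- best
        changed <- TRUE
      }
    }
    trace <- c(trace, energy())
    if (!changed) break
  }
  pred$labels_hat <- pred$classes[lab]
  pred$refined <- TRUE
  pred$energy_trace <- trace
  pred
}

#' Commit confident predictions to annotation labels
#'
#' A region is assigned its predicted label iff its top-two probability
#' margin, scaled to `[0, 100]`, is at least `confidence`: confidence 0
#' assigns every unlabeled region to its closest match, confidence 100 only
#' assigns regions where a single class holds all probability mass.
#' Training annotations are never overwritten. An optional `subregion`
#' (`(z0, z1, y0, y1, x0, x1)` within the ROI) and a label selection
#' restrict which voxels are committed.
#'
#' @param ws a workspace.
#' @param pred a `prediction_result`.
#' @param confidence threshold in `[0, 100]`.
#' @param subregion optional bounds restricting commitment.
#' @param labels optional subset of class ids to commit.
#' @return invisibly, the number of regions committed.
#' @export
commit_predictions <- function(ws, pred, confidence = 50, subregion = NULL,
                               labels = NULL) {
  if (confidence < 0 || confidence > 100)
    stop("confidence must be in [0, 100]")
  lv <- get_level(ws, pred$level)
  svl <- if (pred$region == "supervoxel") supervoxel_labels(ws)
    else array(seq_along(lv$voxel_labels), roi_dim(ws))
  ps <- apply(pred$prob, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    c(s[1], if (length(s) > 1) s[2] else 0)
  })
  margin <- (ps[1, ] - ps[2, ]) * 100
  commit <- !pred$train_mask & margin >= confidence
  if (!is.null(labels)) commit <- commit & pred$labels_hat %in% labels
  sel_regions <- which(commit)
  vox <- array(svl %in% sel_regions, dim(svl))
  if (!is.null(subregion)) {
    b <- as.integer(subregion)
    inside <- array(FALSE, dim(svl))
    inside[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- TRUE
    vox <- vox & inside
  }
  # map each committed voxel to its region's predicted label
  lut <- rep(NA_integer_, nrow(pred$prob))
  lut[sel_regions] <- pred$labels_hat[sel_regions]
  lv$voxel_labels[vox] <- lut[svl[vox]]
  set_level(ws, lv)
  invisible(length(sel_regions))
}

#' Iterate train / refine / commit until no region is unlabeled
#'
#' Runs the full loop: each round trains on all currently labeled regions,
#' refines, commits predictions above `cfg$confidence`, and stops when no
#' unlabeled supervoxel remains. If a round commits nothing new, the
#' remainder is committed at confidence 0 (every region to its closest
#' match) and the loop terminates.
#'
#' @param ws a workspace.
#' @param cfg a [train_config()].
#' @param rounds maximum number of rounds.
#' @param refine_source channel for appearance refinement.
#' @return invisibly, a data.frame history (round, unlabeled_before,
#'   committed).
#' @export
iterate_training <- function(ws, cfg, rounds = 5, refine_source = NULL) {
  refine_source <- refine_source %||% cfg$sources[1]
  hist <- data.frame(round = integer(0), unlabeled_before = integer(0),
                     committed = integer(0))
  for (r in seq_len(rounds)) {
    lv <- get_level(ws, cfg$predict_level)
    svl <- supervoxel_labels(ws)
    ann <- region_training_labels(lv$voxel_labels, svl)
    unlabeled <- sum(is.na(ann))
    if (unlabeled == 0) break
    pred <- train_predict(ws, cfg)
    if (cfg$refinement != "none")
      pred <- refine_predictions(ws, pred, cfg$refinement,
                                 cfg$refine_lambda, refine_source)
    n <- commit_predictions(ws, pred, cfg$confidence)
    hist <- rbind(hist, data.frame(round = r, unlabeled_before = unlabeled,
                                   committed = n))
    left <- sum(is.na(region_training_labels(
      get_level(ws, cfg$predict_level)$voxel_labels, svl)))
    if (left == 0) break
    if (left >= unlabeled) {
      # no progress this round: commit the remainder at confidence 0
      commit_predictions(ws, pred, 0)
      break
    }
  }
  # safety: any remaining unlabeled regions go in at confidence 0
  lv <- get_level(ws, cfg$predict_level)
  if (any(lv$voxel_labels < 0)) {
    pred <- train_predict(ws, cfg)
    if (cfg$refinement != "none")
      pred <- refine_predictions(ws, pred, cfg$refinement,
                                 cfg$refine_lambda, refine_source)
    commit_predictions(ws, pred, 0)
  }
  invisible(hist)
}
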