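# Per-user stress classification of SCR samples with a gain-ratio decision
# tree (C4.5-style binary splits on continuous features). Each subject gets
# their own model: skin-response levels are not comparable across people, so
# no pooling across users ever happens.

#' Extract classifier features from an SCR record
#'
#' `voltage` is the instantaneous divider output (V); `slope` is the first
#' difference times the sampling rate (V/s, 0 for the first sample).
#'
#' @param scr an [scr_record()].
#' @param features subset of `c("voltage", "slope")`.
#' @return numeric matrix, one column per feature.
#' @export
scr_features <- function(scr, features = "voltage") {
  stopifnot(inherits(scr, "scr_record"))
  features <- match.arg(features, c("voltage", "slope"), several.ok = TRUE)
  cols <- lapply(features, function(f) switch(f,
    voltage = scr$samples,
    slope = c(0, diff(scr$samples)) * scr$fs))
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Best gain-ratio split of y (factor) on one numeric feature.
# Candidate thresholds are midpoints between sorted distinct values; both
# children must hold at least min_leaf samples. Ties break to the lower
# threshold. Returns NULL when no split has positive gain.
best_split_1d <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  lev <- levels(y)
  # cumulative class counts after each sorted sample
  cum <- apply(sapply(lev, function(l) cumsum(ys == l)), 2, as.numeric)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  h_root <- entropy_bits(total)
  # split after position i (left = 1..i) only where the value changes
  cand <- which(diff(xs) > 0)
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (!length(cand)) return(NULL)
  best <- NULL
  for (i in cand) {
    left <- cum[i, ]; right <- total - left
    gain <- h_root - (i / n) * entropy_bits(left) -
      ((n - i) / n) * entropy_bits(right)
    if (gain <= 1e-12) next
    split_info <- entropy_bits(c(i, n - i))
    gr <- gain / split_info
    if (is.null(best) || gr > best$gain_ratio + 1e-12) {
      best <- list(threshold = (xs[i] + xs[i + 1L]) / 2,
                   gain = gain, gain_ratio = gr)
    }
  }
  best
}

grow_node <- function(X, y, min_leaf) {
  counts <- table(y)
  if (length(unique(y)) == 1L || length(y) < 2L * min_leaf) {
    return(leaf_node(counts))
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    s <- best_split_1d(X[, j], y, min_leaf)
    if (!is.null(s) &&
        (is.null(best) || s$gain_ratio > best$gain_ratio + 1e-12)) {
      best <- c(s, list(feature = colnames(X)[j], j = j))
    }
  }
  if (is.null(best)) return(leaf_node(counts))
  go_left <- X[, best$j] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_node(X[go_left, , drop = FALSE], factor(y[go_left], levels(y)), min_leaf),
       right = grow_node(X[!go_left, , drop = FALSE], factor(y[!go_left], levels(y)), min_leaf))
}

leaf_node <- function(counts) {
  counts <- as.integer(counts[c("stress", "relax")])
  names(counts) <- c("stress", "relax")
  counts[is.na(counts)] <- 0L
  # majority class; tie breaks to "relax" (the negative class)
  cls <- if (counts[["stress"]] > counts[["relax"]]) "stress" else "relax"
  list(leaf = TRUE, class = cls, counts = as.list(counts))
}

#' Train a per-user gain-ratio stress tree on labeled SCR samples
#'
#' Grows an unpruned binary decision tree by maximizing the information gain
#' ratio over candidate thresholds (midpoints between sorted distinct feature
#' values); growth stops at class purity, at `min_leaf`, or when no split
#' yields positive gain. Training is deterministic given the data; threshold
#' ties break to the lower threshold. Unlabeled samples are ignored.
#'
#' @param scr a labeled [scr_record()] with both classes present.
#' @param features subset of `c("voltage", "slope")` (default voltage only).
#' @param min_leaf minimum samples per leaf (default 2).
#' @return object of class `stress_tree`.
#' @export
train_stress_tree <- function(scr, features = "voltage", min_leaf = 2L) {
  stopifnot(inherits(scr, "scr_record"))
  keep <- scr$labels %in% c("stress", "relax")
  if (!any(keep)) stop("no labeled samples to train on")
  X <- scr_features(scr, features)[keep, , drop = FALSE]
  y <- factor(scr$labels[keep], levels = c("stress", "relax"))
  if (length(unique(y)) < 2L)
    stop("training requires both classes; got only '", unique(y), "'")
  if (length(y) < 2L * min_leaf)
    stop("need at least 2 * min_leaf = ", 2L * min_leaf, " labeled samples")
  structure(list(root = grow_node(X, y, as.integer(min_leaf)),
                 features = colnames(X), min_leaf = as.integer(min_leaf),
                 subject_id = scr$subject_id, n_train = length(y)),
            class = "stress_tree")
}

#' @export
print.stress_tree <- function(x, ...) {
  depth <- function(nd) if (nd$leaf) 0L else 1L + max(depth(nd$left), depth(nd$right))
  nleaf <- function(nd) if (nd$leaf) 1L else nleaf(nd$left) + nleaf(nd$right)
  cat(sprintf("<stress_tree> features [%s], %d leaves, depth %d, trained on %d samples%s\n",
              paste(x$features, collapse = ", "), nleaf(x$root), depth(x$root),
              x$n_train,
              if (is.na(x$subject_id)) "" else paste0(" (subject ", x$subject_id, ")")))
  invisible(x)
}

#' Predict stress/relax labels for SCR samples
#'
#' @param object a [train_stress_tree()] model.
#' @param scr an [scr_record()].
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.stress_tree <- function(object, scr, ...) {
  X <- scr_features(scr, object$features)
  apply(X, 1L, function(row) {
    nd <- object$root
    while (!nd$leaf) {
      nd <- if (row[[nd$feature]] <= nd$threshold) nd$left else nd$right
    }
    nd$class
  })
}

#' Evaluate a stress tree against labeled SCR samples
#'
#' Per-sample confusion counts with stress as the positive class: TP = stress
#' predicted stress, FN = stress predicted relax, FP = relax predicted stress,
#' TN = relax predicted relax. Unlabeled samples are skipped.
#'
#' @param tree a [train_stress_tree()] model.
#' @param scr a labeled [scr_record()].
#' @return a [confusion_matrix()].
#' @export
evaluate_tree <- function(tree, scr) {
  stopifnot(inherits(tree, "stress_tree"), inherits(scr, "scr_record"))
  keep <- scr$labels %in% c("stress", "relax")
  if (!any(keep)) stop("record has no labeled samples to evaluate on")
  pred <- predict(tree, scr)[keep]
  truth <- scr$labels[keep]
  confusion_matrix(TP = sum(truth == "stress" & pred == "stress"),
                   FN = sum(truth == "stress" & pred == "relax"),
                   FP = sum(truth == "relax" & pred == "stress"),
                   TN = sum(truth == "relax" & pred == "relax"))
}

#' Reduced-error pruning against a validation record
#'
#' Bottom-up: any subtree whose replacement by its majority leaf does not
#' increase the error count on the validation samples is collapsed.
#'
#' @param tree a [train_stress_tree()] model.
#' @param scr a labeled validation [scr_record()].
#' @return the pruned `stress_tree`.
#' @export
prune_stress_tree <- function(tree, scr) {
  stopifnot(inherits(tree, "stress_tree"), inherits(scr, "scr_record"))
  keep <- scr$labels %in% c("stress", "relax")
  X <- scr_features(scr, tree$features)[keep, , drop = FALSE]
  y <- scr$labels[keep]
  prune <- function(nd, idx) {
    if (nd$leaf || !length(idx)) return(nd)
    go_left <- X[idx, nd$feature] <= nd$threshold
    nd$left <- prune(nd$left, idx[go_left])
    nd$right <- prune(nd$right, idx[!go_left])
    counts <- merge_counts(nd)
    cls <- if (counts[["stress"]] > counts[["relax"]]) "stress" else "relax"
    err_sub <- sum(predict_node(nd, X[idx, , drop = FALSE]) != y[idx])
    err_leaf <- sum(y[idx] != cls)
    if (err_leaf <= err_sub)
      list(leaf = TRUE, class = cls, counts = as.list(counts))
    else nd
  }
  tree$root <- prune(tree$root, seq_len(nrow(X)))
  tree
}

merge_counts <- function(nd) {
  if (nd$leaf) return(unlist(nd$counts))
  merge_counts(nd$left) + merge_counts(nd$right)
}

predict_node <- function(nd, X) {
  apply(X, 1L, function(row) {
    cur <- nd
    while (!cur$leaf) cur <- if (row[[cur$feature]] <= cur$threshold) cur$left else cur$right
    cur$class
  })
}

#' Serialize / restore a stress tree as JSON
#'
#' @param tree a `stress_tree`.
#' @param path file path.
#' @export
write_stress_tree <- function(tree, path) {
  stopifnot(inherits(tree, "stress_tree"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stress_tree
#' @export
read_stress_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(nd) {
    if (isTRUE(nd$leaf)) {
      list(leaf = TRUE, class = nd$class,
           counts = list(stress = as.integer(nd$counts$stress),
                         relax = as.integer(nd$counts$relax)))
    } else {
      list(leaf = FALSE, feature = nd$feature,
           threshold = as.numeric(nd$threshold),
           left = fix(nd$left), right = fix(nd$right))
    }
  }
  structure(list(root = fix(obj$root), features = unlist(obj$features),
                 min_leaf = as.integer(obj$min_leaf),
                 subject_id = obj$subject_id %||% NA_character_,
                 n_train = as.integer(obj$n_train)),
            class = "stress_tree")
}
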