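# Compact bagged-CART Gini-importance estimator.
#
# Only the quantity the scoring model needs is implemented: the normalized
# total impurity decrease attributed to each feature over an ensemble of
# depth-limited classification trees grown on bootstrap samples with
# random feature subsampling (mtry = sqrt(p)). No prediction path is kept;
# the trees exist solely to measure importance.

# best binary split of y (0/1) on numeric x by weighted Gini impurity;
# returns c(gain, threshold) or NULL when no split improves
best_split <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  if (n < 2L) return(NULL)
  pos_left <- cumsum(ys)
  npos <- pos_left[n]
  parent <- gini_node(npos, n)
  # split between distinct consecutive values only
  cut_ok <- which(diff(xs) > 0)
  if (!length(cut_ok)) return(NULL)
  nl <- cut_ok
  nr <- n - nl
  pl <- pos_left[cut_ok]
  pr <- npos - pl
  child <- (nl * gini_node(pl, nl) + nr * gini_node(pr, nr)) / n
  gain <- parent - child
  b <- which.max(gain)
  if (gain[b] <= 1e-12) return(NULL)
  c(gain = gain[b] * n, threshold = (xs[cut_ok[b]] + xs[cut_ok[b] + 1L]) / 2)
}

gini_node <- function(npos, n) {
  p <- npos / n
  2 * p * (1 - p)
}

# recursively grow one tree on rows `idx`, accumulating per-feature
# impurity decrease (weighted by node size) into environment `acc`
grow_tree <- function(X, y, idx, depth, max_depth, min_node, mtry, acc) {
  if (depth >= max_depth || length(idx) < 2L * min_node) return(invisible())
  ysub <- y[idx]
  if (all(ysub == ysub[1])) return(invisible())
  feats <- sample.int(ncol(X), mtry)
  best <- NULL; best_f <- NA_integer_
  for (f in feats) {
    sp <- best_split(X[idx, f], ysub)
    if (!is.null(sp) && (is.null(best) || sp["gain"] > best["gain"])) {
      best <- sp; best_f <- f
    }
  }
  if (is.null(best)) return(invisible())
  acc$imp[best_f] <- acc$imp[best_f] + best[["gain"]]
  go_left <- X[idx, best_f] <= best[["threshold"]]
  left <- idx[go_left]
  right <- idx[!go_left]
  if (length(left) >= min_node) {
    grow_tree(X, y, left, depth + 1L, max_depth, min_node, mtry, acc)
  }
  if (length(right) >= min_node) {
    grow_tree(X, y, right, depth + 1L, max_depth, min_node, mtry, acc)
  }
  invisible()
}

#' Gini feature importance from a bagged-tree ensemble
#'
#' @param X Numeric matrix (rows = cases, columns = features).
#' @param y 0/1 integer class labels.
#' @param n_trees Number of bootstrap trees.
#' @param max_depth Maximum tree depth (root = depth 0 splits allowed up to
#'   `max_depth` levels).
#' @param min_node Minimum cases per leaf.
#' @param mtry Features sampled per split; default `ceiling(sqrt(p))`.
#' @param seed Integer seed.
#' @return Named numeric vector of raw (unnormalized) importances, one per
#'   column of `X`.
#' @export
gini_forest_importance <- function(X, y, n_trees = 60L, max_depth = 3L,
                                   min_node = 5L, mtry = NULL, seed = 0L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(ncol(X))))
  acc <- new.env()
  acc$imp <- numeric(ncol(X))
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    grow_tree(X, y, boot, 0L, max_depth, min_node, mtry, acc)
  }
  names(acc$imp) <- colnames(X)
  acc$imp
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(list = ".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
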