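#' Gini impurity of a two-class node
#'
#' `1 - sum(p_c^2)`; 0 for a pure node, 0.5 at a 50/50 split.
#'
#' @param class_counts Non-negative counts, one per class, total > 0.
#' @return Impurity in `[0, 0.5]` for two classes.
#' @examples
#' gini_impurity(c(3, 1))
#' @export
gini_impurity <- function(class_counts) {
  total <- sum(class_counts)
  if (total <= 0) stop("empty node: total count must be > 0", call. = FALSE)
  1 - sum((class_counts / total)^2)
}

#' Fit a Gini decision tree with size-based stopping
#'
#' Greedy binary CART-style tree on component scores. Candidate splits are
#' the midpoints between adjacent distinct values of each column; the
#' split maximizing the weighted Gini impurity decrease wins, with ties
#' broken by lowest column index, then lowest threshold. A node becomes a
#' leaf when it is pure, when it holds fewer than
#' `ceil(min_node_fraction * N_total)` samples (by default 20% of all
#' observations), or when no split yields a positive impurity decrease.
#' Leaf labels are the majority class (ties go to condition I).
#'
#' @param X Numeric matrix of predictors (component scores).
#' @param y Class labels (`"I"` / `"II"`).
#' @param min_node_fraction Minimum splittable node size as a fraction of
#'   the total sample count. Default 0.2.
#' @return An object of class `gini_tree` (nested node list; each node
#'   has `n_samples`, `gini`, `counts`, and either `split`/`left`/`right`
#'   or `label`).
#' @export
fit_tree <- function(X, y, min_node_fraction = 0.2) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  classes <- c("I", "II")
  if (!all(y %in% classes)) {
    stop("labels must be 'I' or 'II'", call. = FALSE)
  }
  n_total <- nrow(X)
  min_n <- ceiling(min_node_fraction * n_total)

  grow <- function(idx) {
    yy <- y[idx]
    counts <- c(I = sum(yy == "I"), II = sum(yy == "II"))
    node <- list(n_samples = length(idx),
                 gini = gini_impurity(counts),
                 counts = counts)
    majority <- if (counts[["II"]] > counts[["I"]]) "II" else "I"
    make_leaf <- function() { node$label <- majority; node }
    if (node$gini == 0 || length(idx) < min_n) return(make_leaf())

    best <- NULL
    for (j in seq_len(ncol(X))) {
      v <- X[idx, j]
      uq <- sort(unique(v))
      if (length(uq) < 2) next
      mids <- (uq[-1] + uq[-length(uq)]) / 2
      for (th in mids) {
        left <- v <= th
        nl <- sum(left); nr <- length(idx) - nl
        gl <- gini_impurity(c(sum(yy[left] == "I"), sum(yy[left] == "II")))
        gr <- gini_impurity(c(sum(yy[!left] == "I"), sum(yy[!left] == "II")))
        decrease <- node$gini - (nl * gl + nr * gr) / length(idx)
        if (decrease > 1e-12 &&
            (is.null(best) || decrease > best$decrease + 1e-12)) {
          best <- list(j = j, threshold = th, decrease = decrease,
                       left = idx[left], right = idx[!left])
        }
      }
    }
    if (is.null(best)) return(make_leaf())
    node$split <- list(column = best$j, threshold = best$threshold,
                       decrease = best$decrease)
    node$left <- grow(best$left)
    node$right <- grow(best$right)
    node
  }

  structure(
    list(root = grow(seq_len(n_total)), n_total = n_total,
         min_node_fraction = min_node_fraction, min_n = min_n,
         n_columns = ncol(X)),
    class = "gini_tree"
  )
}

#' @export
print.gini_tree <- function(x, ...) {
  depth <- function(node) {
    if (!is.null(node$label)) return(0L)
    1L + max(depth(node$left), depth(node$right))
  }
  n_leaves <- function(node) {
    if (!is.null(node$label)) return(1L)
    n_leaves(node$left) + n_leaves(node$right)
  }
  cat(sprintf(
    "<gini_tree> %d samples, %d leaves, depth %d (min splittable node %d)\n",
    x$n_total, n_leaves(x$root), depth(x$root), x$min_n))
  invisible(x)
}

#' Predict classes from a fitted Gini tree
#'
#' @param object A `gini_tree`.
#' @param newdata Numeric matrix with the columns the tree was fit on.
#' @param ... Unused.
#' @return Character vector of `"I"` / `"II"` labels.
#' @export
predict.gini_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  classify_one <- function(node, row) {
    while (is.null(node$label)) {
      node <- if (row[node$split$column] <= node$split$threshold)
        node$left else node$right
    }
    node$label
  }
  apply(newdata, 1, function(row) classify_one(object$root, row))
}

#' Walk a tree and collect every node
#'
#' Utility for structural checks: returns a tibble with one row per node
#' (internal and leaf), its sample count, impurity and leaf status.
#'
#' @param tree A `gini_tree`.
#' @return A tibble with columns `n_samples`, `gini`, `is_leaf`, `depth`.
#' @export
tree_nodes <- function(tree) {
  acc <- list()
  walk <- function(node, depth) {
    acc[[length(acc) + 1]] <<- tibble::tibble(
      n_samples = node$n_samples, gini = node$gini,
      is_leaf = !is.null(node$label), depth = depth)
    if (is.null(node$label)) {
      walk(node$left, depth + 1L)
      walk(node$right, depth + 1L)
    }
  }
  walk(tree$root, 0L)
  dplyr::bind_rows(acc)
}
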