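#' Standardized PCA with a cumulative-variance retention rule
#'
#' Standardizes each feature column (zero mean, unit variance — band powers
#' differ by orders of magnitude, so unstandardized PCA would be dominated
#' by the low-frequency bands), then computes principal components via
#' [stats::prcomp] and retains the smallest number of components whose
#' cumulative explained-variance fraction reaches `variance_target`
#' (default 95%).
#'
#' @param X Numeric matrix or data frame (rows = samples, columns =
#'   features); no column may be constant.
#' @param variance_target Cumulative explained-variance fraction in
#'   (0, 1]. Default 0.95.
#' @return An object of class `pca_model`: `means`, `scales`, `components`
#'   (orthonormal loadings, columns ordered by explained variance),
#'   `explained_fraction`, `n_retained`.
#' @export
fit_pca <- function(X, variance_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  stopifnot(variance_target > 0, variance_target <= 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  # Drop numerically null components so the loadings stay well-defined.
  keep <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  n_retained <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  n_retained <- min(n_retained, sum(keep))
  structure(
    list(means = pc$center, scales = pc$scale,
         components = pc$rotation[, keep, drop = FALSE],
         explained_fraction = frac[keep],
         n_retained = n_retained,
         variance_target = variance_target),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d features -> %d retained components (>= %.0f%% variance)\n",
    length(x$means), x$n_retained, 100 * x$variance_target))
  invisible(x)
}

#' Project data onto retained principal components
#'
#' @param model A `pca_model`.
#' @param X New data with the model's feature columns.
#' @return Score matrix, one column per retained component.
#' @export
project_pca <- function(model, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, model$means, `-`), 2, model$scales, `/`)
  Z %*% model$components[, seq_len(model$n_retained), drop = FALSE]
}
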