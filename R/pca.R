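#' Fit standardized PCA to an 8-feature matrix
#'
#' Columns are standardized by their mean and standard deviation (stored in
#' the model), the covariance of the standardized data is eigendecomposed,
#' eigenpairs are sorted by descending eigenvalue, and each eigenvector's
#' sign is fixed so that its largest-magnitude entry is positive (the
#' loadings are otherwise sign-ambiguous). On standardized 8-feature data
#' the eigenvalues sum to 8.
#'
#' @param ff Numeric matrix, n x 8, one cycle per row.
#' @param m Number of components retained for projection (default 3).
#' @return Object of class `pcg_pca`: `mu`, `sigma` (8-vectors), `vectors`
#'   (8 x 8, columns = eigenvectors), `values` (descending eigenvalues), `m`.
#' @export
fit_pca <- function(ff, m = 3) {
  ff <- as.matrix(ff)
  if (nrow(ff) < 9) stop("need at least 9 cycles to fit the 8-feature PCA")
  mu <- colMeans(ff)
  sdv <- apply(ff, 2, stats::sd)
  if (any(sdv == 0)) stop("degenerate data: a feature column is constant")
  z <- scale(ff, center = mu, scale = sdv)
  e <- eigen(stats::cov(z), symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- colnames(ff)
  structure(list(mu = mu, sigma = sdv, vectors = vec,
                 values = pmax(e$values, 0), m = m),
            class = "pcg_pca")
}

#' Project feature vectors onto the leading principal components
#'
#' Each row is standardized by the model's feature means and SDs and dotted
#' with the first `m` eigenvectors, yielding the diagnostic features
#' `[gamma_1, ..., gamma_m]`.
#'
#' @param ff Numeric vector (length 8) or matrix (n x 8).
#' @param model A `pcg_pca` model ([fit_pca()] or [bundled_pca_model()]).
#' @param m Number of components (default `model$m`).
#' @return Numeric matrix n x m with columns `gamma1..gammam`.
#' @export
project_features <- function(ff, model, m = model$m) {
  stopifnot(inherits(model, "pcg_pca"))
  if (m > ncol(model$vectors)) stop("m exceeds the number of components")
  if (is.null(dim(ff))) ff <- matrix(ff, nrow = 1)
  z <- sweep(sweep(ff, 2, model$mu), 2, model$sigma, "/")
  g <- z %*% model$vectors[, seq_len(m), drop = FALSE]
  colnames(g) <- paste0("gamma", seq_len(m))
  g
}

#' Cumulative explained variance of the leading components
#'
#' @param model A `pcg_pca` model (or a numeric vector of eigenvalues).
#' @param m Number of leading components.
#' @return Percentage in `[0, 100]`.
#' @export
explained_variance <- function(model, m) {
  values <- if (inherits(model, "pcg_pca")) model$values else as.numeric(model)
  if (m < 1 || m > length(values)) stop("m out of range")
  100 * sum(values[seq_len(m)]) / sum(values)
}

#' PCA model published with the method
#'
#' Loads the packaged feature means/SDs, eigenvectors and eigenvalues of the
#' reference clinical feature matrix, for scoring new recordings without
#' refitting. The first three components carry 86.73% of the variance.
#'
#' @return A `pcg_pca` model with `m = 3`.
#' @export
bundled_pca_model <- function() {
  path <- system.file("extdata", "ff_pca_constants.json", package = "pcgmdc",
                      mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vec <- t(as.matrix(j$eigenvectors))  # stored one eigenvector per row
  rownames(vec) <- j$feature_names
  colnames(vec) <- NULL
  mu <- stats::setNames(j$mu_ff, j$feature_names)
  sdv <- stats::setNames(j$sigma_ff, j$feature_names)
  structure(list(mu = mu, sigma = sdv, vectors = vec,
                 values = j$eigenvalues, m = 3L),
            class = "pcg_pca")
}
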