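#' Squared Mahalanobis distance to a Gaussian component
#'
#' `(x - mu)' Sigma^{-1} (x - mu)`. For draws from `N(mu, Sigma)` in d
#' dimensions this statistic follows a chi-square distribution with d
#' degrees of freedom, which is what turns a confidence level into an
#' ellipsoidal decision region.
#'
#' @param x Numeric vector, or matrix with one point per row.
#' @param mu Component mean.
#' @param sigma Component covariance (symmetric positive-definite).
#' @return Nonnegative squared distance(s).
#' @export
mahalanobis_sq <- function(x, mu, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ch <- tryCatch(chol(sigma), error = function(e) stop("singular covariance"))
  centered <- sweep(x, 2, mu)
  y <- backsolve(ch, t(centered), transpose = TRUE)
  colSums(y^2)
}

#' Chi-square quantile threshold for a confidence level
#'
#' The Mahalanobis-distance criterion `MDC = qchisq(beta, dof)`: a point
#' belongs to a component's confidence ellipsoid when its squared
#' Mahalanobis distance does not exceed this threshold.
#'
#' @param beta Confidence level in `[0, 1)`.
#' @param dof Degrees of freedom (default 3, the projected feature space).
#' @return The chi-square quantile.
#' @export
chi2_inverse <- function(beta, dof = 3) {
  if (any(beta < 0 | beta >= 1)) stop("beta must lie in [0, 1)")
  stats::qchisq(beta, df = dof)
}

# log density of N(mu, sigma) for rows of x
gauss_logdens <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (d * log(2 * pi) + logdet + mahalanobis_sq(x, mu, sigma))
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' Expectation-maximization with a fixed regularization added to every
#' covariance diagonal in each M-step to avoid ill-conditioned estimates.
#' Iteration stops at `max_iter` or when the log-likelihood improves by
#' less than `tol`.
#'
#' With `labels` supplied (the usual case - training recordings come with a
#' diagnosis) the component memberships are known, so the responsibilities
#' are held at the one-hot labels and EM converges in a single M-step to
#' the class-conditional moments: the complete-data maximum-likelihood fit.
#' Running free EM from a labelled start instead lets diffuse components
#' absorb or swap with compact neighbouring classes whenever clusters
#' overlap, silently corrupting the component-class correspondence.
#' Without labels, ordinary EM runs from a seeded k-means start and the
#' components stay unlabelled until matched externally (see
#' [match_components()]).
#'
#' @param x Numeric matrix, n x d feature rows.
#' @param K Number of mixture components (default 7, one per class).
#' @param regularization Value added to each covariance diagonal per M-step.
#' @param max_iter Maximum EM iterations.
#' @param tol Log-likelihood convergence tolerance.
#' @param seed Integer seed for the initialization.
#' @param labels Optional character vector of true class labels (length n).
#' @return Object of class `pcg_gmm`: `pi`, `mu` (K x d), `sigma` (list of
#'   d x d), `labels` (length K, NA when unlabelled), `loglik` (trace),
#'   `meta` (regularization, iterations, seed).
#' @export
fit_gmm <- function(x, K = 7, regularization = 0.01, max_iter = 1000,
                    tol = 1e-8, seed = 1, labels = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (any(!is.finite(x))) stop("features contain non-finite values")
  if (n < 10 * K) stop("too few points: need at least 10 observations per component")

  set.seed(seed)
  supervised <- !is.null(labels)
  if (supervised && length(unique(labels)) != K)
    stop("number of distinct labels must equal K")
  cluster0 <- if (supervised) as.integer(factor(labels))
              else stats::kmeans(x, centers = K, nstart = 25,
                                 iter.max = 100)$cluster

  m_step_hard <- function(cl) {
    pi_k <<- as.numeric(table(factor(cl, levels = seq_len(K)))) / n
    mu_k <<- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(x[cl == k, , drop = FALSE])))
    sigma_k <<- lapply(seq_len(K), function(k) {
      pts <- x[cl == k, , drop = FALSE]
      s <- if (nrow(pts) > d) stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
           else diag(d)
      s + regularization * diag(d)
    })
  }
  pi_k <- NULL; mu_k <- NULL; sigma_k <- NULL
  m_step_hard(cluster0)

  mixture_loglik <- function() {
    logp <- vapply(seq_len(K), function(k)
      log(pi_k[k]) + gauss_logdens(x, mu_k[k, ], sigma_k[[k]]), numeric(n))
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    list(loglik = sum(lse), resp = exp(logp - lse))
  }

  if (supervised) {
    # responsibilities fixed at the one-hot labels: already converged
    loglik <- mixture_loglik()$loglik
  } else {
    loglik <- numeric(0)
    for (iter in seq_len(max_iter)) {
      e <- mixture_loglik()
      loglik <- c(loglik, e$loglik)
      resp <- e$resp
      nk <- colSums(resp)
      pi_k <- nk / n
      for (k in seq_len(K)) {
        mu_k[k, ] <- colSums(resp[, k] * x) / nk[k]
        centered <- sweep(x, 2, mu_k[k, ])
        sigma_k[[k]] <- crossprod(centered * sqrt(resp[, k])) / nk[k] +
          regularization * diag(d)
      }
      if (iter > 1 && abs(loglik[iter] - loglik[iter - 1]) < tol) break
    }
  }

  comp_labels <- if (supervised) levels(factor(labels))
                 else rep(NA_character_, K)
  structure(list(pi = pi_k, mu = mu_k, sigma = sigma_k, labels = comp_labels,
                 loglik = loglik,
                 meta = list(regularization = regularization,
                             iterations = length(loglik), seed = seed,
                             supervised = supervised)),
            class = "pcg_gmm")
}

#' Match unlabelled mixture components to class labels
#'
#' Assigns each fitted component a class label so that the total number of
#' points whose maximum-posterior component carries their own label is
#' maximized, searching all one-to-one assignments (K = 7 means 5040
#' permutations). A plain per-component majority vote can hand the same
#' label to two components and leave classes unnamed when components
#' overlap.
#'
#' @param gmm An unlabelled `pcg_gmm`.
#' @param x Feature matrix the mixture was fitted to.
#' @param labels True class labels for the rows of `x`.
#' @return The `pcg_gmm` with `labels` filled in.
#' @export
match_components <- function(gmm, x, labels) {
  x <- as.matrix(x)
  K <- length(gmm$pi)
  classes <- sort(unique(labels))
  if (length(classes) != K) stop("need exactly K distinct labels")
  logp <- vapply(seq_len(K), function(k)
    log(gmm$pi[k]) + gauss_logdens(x, gmm$mu[k, ], gmm$sigma[[k]]),
    numeric(nrow(x)))
  comp <- max.col(logp)
  counts <- table(factor(comp, levels = seq_len(K)),
                  factor(labels, levels = classes))
  perms <- perm_all(K)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(counts[cbind(seq_len(K), perms[i, ])]), numeric(1))
  gmm$labels <- classes[perms[which.max(scores), ]]
  gmm
}

# all permutations of 1..k (k small)
perm_all <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(j) {
    rest <- setdiff(seq_len(k), j)
    cbind(j, matrix(rest[sub], nrow(sub)))
  }))
}

#' Assemble a Mahalanobis-distance classifier from mixture components
#'
#' @param gmm A `pcg_gmm` (or compatible list with `pi`, `mu`, `sigma`,
#'   `labels`).
#' @param beta Per-class confidence levels (recycled to K).
#' @param dof Degrees of freedom of the chi-square thresholds.
#' @return Object of class `pcg_classifier`: the components plus `beta` and
#'   `mdc = qchisq(beta, dof)`.
#' @export
classifier_model <- function(gmm, beta, dof = 3) {
  K <- length(gmm$pi)
  beta <- rep_len(beta, K)
  structure(list(pi = gmm$pi, mu = gmm$mu, sigma = gmm$sigma,
                 labels = gmm$labels, beta = beta,
                 mdc = chi2_inverse(beta, dof), dof = dof,
                 meta = gmm$meta),
            class = "pcg_classifier")
}

#' Classify diagnostic feature vectors
#'
#' A point is eligible for class k when its squared Mahalanobis distance to
#' component k is within that class's chi-square threshold `mdc[k]`. Points
#' inside no ellipsoid are labelled `"unknown"`; points inside several take
#' the class minimizing the normalized ratio `d2 / mdc` (the class
#' ellipsoids are designed to barely overlap, so ties are rare and the
#' normalized ratio respects differing per-class confidence levels).
#'
#' @param x Numeric vector (length d) or n x d matrix.
#' @param model A `pcg_classifier`.
#' @return Character vector of class labels (`"unknown"` possible).
#' @export
classify_features <- function(x, model) {
  stopifnot(inherits(model, "pcg_classifier"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  K <- length(model$pi)
  d2 <- vapply(seq_len(K), function(k)
    mahalanobis_sq(x, model$mu[k, ], model$sigma[[k]]), numeric(nrow(x)))
  if (nrow(x) == 1) d2 <- matrix(d2, nrow = 1)
  ratio <- sweep(d2, 2, model$mdc, "/")
  apply(ratio, 1, function(r) {
    if (all(r > 1)) "unknown" else model$labels[which.min(r)]
  })
}

#' Sweep the confidence level and pick per-class optima
#'
#' Evaluates, for each confidence level on the grid, the one-vs-rest
#' classification accuracy of every class when all thresholds are set to
#' that level, and selects per class the largest level whose accuracy is
#' within `1e-9` of the class's maximum (largest admissible ellipsoid at
#' highest accuracy).
#'
#' @param gmm A labelled `pcg_gmm` (or `pcg_classifier`).
#' @param x Labelled feature matrix (n x d).
#' @param labels True class labels (length n).
#' @param grid Candidate confidence levels.
#' @return List with `beta` (named per-class selection), `sweep` (long
#'   data.frame `beta` x `class` x `ca`).
#' @export
select_beta <- function(gmm, x, labels, grid = seq(0.63, 0.97, by = 0.02)) {
  classes <- gmm$labels
  if (anyNA(classes)) stop("components must be labelled before selecting beta")
  if (!all(classes %in% labels)) stop("labelled features must span all classes")
  rows <- lapply(grid, function(b) {
    mod <- classifier_model(gmm, beta = b)
    pred <- classify_features(x, mod)
    data.frame(beta = b, class = classes,
               ca = vapply(classes, function(cl)
                 evaluate_classification(pred, labels, cl)$ca, numeric(1)))
  })
  sweep_tab <- do.call(rbind, rows)
  beta_sel <- vapply(classes, function(cl) {
    tab <- sweep_tab[sweep_tab$class == cl, ]
    best <- max(tab$ca)
    max(tab$beta[tab$ca >= best - 1e-9])
  }, numeric(1))
  names(beta_sel) <- classes
  list(beta = beta_sel, sweep = sweep_tab)
}

#' Majority-vote label over the cycles of one recording
#'
#' A recording receives the most frequent non-unknown per-cycle label;
#' `"unknown"` only when every cycle is unknown. Ties break to the first
#' label in sort order.
#'
#' @param labels Character vector of per-cycle labels.
#' @return A single label.
#' @export
majority_vote <- function(labels) {
  known <- labels[labels != "unknown"]
  if (length(known) == 0) return("unknown")
  tab <- sort(table(known), decreasing = TRUE)
  names(tab)[1]
}

#' One-vs-rest classification metrics
#'
#' Counts true/false positives and negatives of `positive_class` against
#' the rest (an `"unknown"` prediction is a negative for every class) and
#' derives classification accuracy, sensitivity and specificity as
#' percentages.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_class The class evaluated one-vs-rest.
#' @return List with `tp`, `fp`, `tn`, `fn`, `ca`, `se`, `sp`.
#' @export
evaluate_classification <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  pp <- predicted == positive_class
  tp <- sum(pp & truth == positive_class)
  fp <- sum(pp & truth != positive_class)
  fn <- sum(!pp & truth == positive_class)
  tn <- sum(!pp & truth != positive_class)
  if (tp + fn == 0) stop("sensitivity undefined: no positives in truth")
  if (fp + tn == 0) stop("specificity undefined: no negatives in truth")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ca = 100 * (tp + tn) / (tp + fp + fn + tn),
       se = 100 * tp / (tp + fn),
       sp = 100 * tn / (fp + tn))
}

#' Per-class evaluation report
#'
#' @param predicted,truth Equal-length label vectors.
#' @param classes Classes to report (default: unique truth labels).
#' @return Data.frame with one row per class: counts and CA/Se/Sp.
#' @export
evaluation_report <- function(predicted, truth, classes = sort(unique(truth))) {
  do.call(rbind, lapply(classes, function(cl) {
    m <- evaluate_classification(predicted, truth, cl)
    data.frame(class = cl, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               ca = m$ca, se = m$se, sp = m$sp)
  }))
}

#' The published seven-class classifier
#'
#' Loads the packaged Gaussian-mixture parameter estimates (mixing weights,
#' means and covariances of the MR, MS, ASD, NM, AS, AR and VSD components)
#' together with the published per-class confidence levels
#' `beta = (0.87, 0.65, 0.67, 0.65, 0.67, 0.79, 0.87)`. The chi-square(3)
#' thresholds are recomputed from `beta` and checked against the published
#' values at four decimals.
#'
#' @return A `pcg_classifier` with K = 7 labelled components.
#' @export
bundled_paper_model <- function() {
  path <- system.file("extdata", "gmm_paper_model.json", package = "pcgmdc",
                      mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- j$components
  K <- nrow(comps)
  gmm <- list(pi = comps$pi,
              mu = do.call(rbind, comps$mu),
              sigma = lapply(comps$sigma, function(s) as.matrix(s)),
              labels = comps$label,
              meta = list(source = "published parameter table"))
  model <- classifier_model(gmm, beta = j$beta)
  if (any(abs(round(model$mdc, 4) - j$mdc_printed) > 5e-5))
    stop("packaged model is corrupt: thresholds disagree with stored values")
  model
}

#' Serialize a classifier to JSON
#'
#' Full-precision JSON round trip: numbers are written with enough digits
#' to reproduce the doubles exactly.
#'
#' @param model A `pcg_classifier`.
#' @param path Output file.
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "pcg_classifier"))
  # doubles are emitted with 17 significant digits, which R re-parses to
  # the identical bit pattern (jsonlite caps at 15 and loses ulps)
  num <- function(v) sprintf("%.17g", v)
  arr <- function(v) paste0("[", paste(num(v), collapse = ", "), "]")
  mat <- function(m) paste0("[", paste(apply(m, 1, arr), collapse = ", "), "]")
  comp <- vapply(seq_along(model$pi), function(k) paste0(
    '{"label": "', model$labels[k], '", "pi": ', num(model$pi[k]),
    ', "mu": ', arr(model$mu[k, ]),
    ', "sigma": ', mat(as.matrix(model$sigma[[k]])), "}"), character(1))
  meta <- jsonlite::toJSON(model$meta, auto_unbox = TRUE, digits = NA,
                           null = "null")
  txt <- paste0(
    '{\n"components": [\n', paste(comp, collapse = ",\n"), "\n],\n",
    '"beta": ', arr(model$beta), ",\n",
    '"mdc": ', arr(model$mdc), ",\n",
    '"dof": ', model$dof, ",\n",
    '"metadata": ', meta, "\n}\n")
  writeLines(txt, path)
  invisible(path)
}

#' Read a classifier serialized by [write_classifier_json()]
#'
#' @param path JSON file.
#' @return A `pcg_classifier`.
#' @export
read_classifier_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- j$components
  gmm <- list(pi = comps$pi,
              mu = do.call(rbind, comps$mu),
              sigma = lapply(comps$sigma, function(s) as.matrix(s)),
              labels = comps$label,
              meta = j$metadata)
  model <- classifier_model(gmm, beta = j$beta, dof = j$dof)
  model$mdc <- j$mdc  # preserve bit-exact thresholds
  model
}
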