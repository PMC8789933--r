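test_that("squared Mahalanobis distance equals the explicit quadratic form", {
  model <- bundled_paper_model()
  expect_equal(mahalanobis_sq(model$mu[1, ], model$mu[1, ], model$sigma[[1]]), 0)
  # identity metric reduces to squared Euclidean distance
  expect_equal(mahalanobis_sq(c(1, 2, 2), c(0, 0, 0), diag(3)), 9)
  # explicit 3x3 inversion oracle on the first bundled component
  x <- model$mu[1, ] + c(1, 0, 0)
  d2 <- mahalanobis_sq(x, model$mu[1, ], model$sigma[[1]])
  expect_equal(d2, drop(t(c(1, 0, 0)) %*% solve(model$sigma[[1]]) %*% c(1, 0, 0)),
               tolerance = 1e-10)
  # agrees with stats::mahalanobis on random inputs
  set.seed(41)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  xs <- matrix(rnorm(30), 10, 3)
  expect_equal(mahalanobis_sq(xs, c(1, -1, 0), S),
               stats::mahalanobis(xs, c(1, -1, 0), S), tolerance = 1e-10)
  expect_error(mahalanobis_sq(c(0, 0, 0), c(0, 0, 0),
                              matrix(0, 3, 3)), "singular")
})

test_that("chi-square thresholds reproduce the published criterion values", {
  expect_equal(round(chi2_inverse(0.87), 4), 5.6489)
  expect_equal(round(chi2_inverse(0.65), 4), 3.2831)
  expect_equal(round(chi2_inverse(0.67), 4), 3.4297)
  expect_equal(round(chi2_inverse(0.79), 4), 4.5258)
  expect_equal(chi2_inverse(0), 0)
  expect_error(chi2_inverse(1), "beta")
  # strictly increasing in beta; inverse of the CDF on the grid
  grid <- seq(0.63, 0.97, by = 0.02)
  q <- chi2_inverse(grid)
  expect_true(all(diff(q) > 0))
  expect_equal(pchisq(q, df = 3), grid, tolerance = 1e-9)
})

test_that("classification follows the confidence-ellipsoid rule", {
  model <- bundled_paper_model()
  for (k in seq_along(model$labels)) {
    expect_equal(classify_features(model$mu[k, ], model), model$labels[k])
  }
  expect_equal(classify_features(c(100, 100, 100), model), "unknown")
  # a point far along component 1's first axis leaves its ellipsoid
  x <- model$mu[1, ] + c(10 * sqrt(model$sigma[[1]][1, 1]), 0, 0)
  expect_false(classify_features(x, model) == "MR")
})

test_that("coverage of each bundled ellipsoid approximates its beta", {
  model <- bundled_paper_model()
  set.seed(42)
  for (k in c(1, 4, 7)) {   # spot-check; the full sweep runs in acceptance
    draws <- pcgmdc:::rmvnorm_chol(20000, model$mu[k, ], model$sigma[[k]])
    inside <- mean(mahalanobis_sq(draws, model$mu[k, ], model$sigma[[k]]) <=
                   model$mdc[k])
    expect_equal(inside, model$beta[k], tolerance = 0.01)
  }
})

test_that("supervised fit recovers class-conditional moments", {
  model <- bundled_paper_model()
  data <- generate_feature_dataset(model, 2000, seed = 5)
  gmm <- fit_gmm(data$features, K = 7, seed = 1, labels = data$labels)
  expect_equal(sum(gmm$pi), 1, tolerance = 1e-12)
  expect_equal(sort(gmm$labels), sort(model$labels))
  for (k in seq_len(7)) {
    truth_k <- which(model$labels == gmm$labels[k])
    expect_lt(max(abs(gmm$mu[k, ] - model$mu[truth_k, ])), 0.1)
  }
})

test_that("unsupervised EM is monotone and recovers a single Gaussian", {
  set.seed(43)
  x <- pcgmdc:::rmvnorm_chol(10000, c(0, 0, 0), diag(3))
  gmm <- fit_gmm(x, K = 1, seed = 2)
  expect_lt(max(abs(gmm$mu)), 0.05)
  expect_lt(max(abs(gmm$sigma[[1]] - 1.01 * diag(3))), 0.1)
  expect_true(all(diff(gmm$loglik) > -1e-8))
  expect_error(fit_gmm(matrix(rnorm(15), 5, 3), K = 7), "too few")
})

test_that("unsupervised EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  model <- bundled_paper_model()
  data <- generate_feature_dataset(model, 400, seed = 9)
  gmm <- fit_gmm(data$features, K = 7, seed = 3)
  gmm <- match_components(gmm, data$features, data$labels)
  mc <- mclust::Mclust(data$features, G = 7, modelNames = "VVV",
                       verbose = FALSE)
  # both fitters must place component centers on the same clusters
  mc_mu <- t(mc$parameters$mean)
  for (k in seq_len(7)) {
    nearest <- min(sqrt(rowSums(sweep(mc_mu, 2, gmm$mu[k, ])^2)))
    expect_lt(nearest, 0.2)
  }
})

test_that("component matching assigns each class exactly once", {
  model <- bundled_paper_model()
  data <- generate_feature_dataset(model, 500, seed = 11)
  gmm <- fit_gmm(data$features, K = 7, seed = 4)
  gmm <- match_components(gmm, data$features, data$labels)
  expect_setequal(gmm$labels, model$labels)
  for (k in seq_len(7)) {
    truth_k <- which(model$labels == gmm$labels[k])
    expect_lt(max(abs(gmm$mu[k, ] - model$mu[truth_k, ])), 0.3)
  }
})

test_that("beta selection honors the largest-ellipsoid-at-best-accuracy rule", {
  set.seed(44)
  # two well-separated classes: accuracy is perfect on the whole grid,
  # so the largest level must be chosen
  x <- rbind(pcgmdc:::rmvnorm_chol(150, c(0, 0, 0), 0.01 * diag(3)),
             pcgmdc:::rmvnorm_chol(150, c(10, 0, 0), 0.01 * diag(3)))
  labels <- rep(c("A", "B"), each = 150)
  gmm <- fit_gmm(x, K = 2, seed = 5, labels = labels)
  sel <- select_beta(gmm, x, labels)
  expect_equal(unname(sel$beta), c(0.97, 0.97))
  grid <- seq(0.63, 0.97, by = 0.02)
  expect_true(all(sel$beta %in% grid))
  # the sweep table covers every grid point and class
  expect_equal(nrow(sel$sweep), length(grid) * 2)
  # selected level attains the class maximum of the sweep
  for (cl in c("A", "B")) {
    tab <- sel$sweep[sel$sweep$class == cl, ]
    expect_equal(tab$ca[tab$beta == sel$beta[cl]], max(tab$ca))
  }
})

test_that("evaluation counts and rates follow the one-vs-rest definitions", {
  pred <- c(rep("A", 9), "B", rep("B", 90))
  truth <- c(rep("A", 10), rep("B", 90))
  m <- evaluate_classification(pred, truth, "A")
  expect_equal(m[c("tp", "fn", "tn", "fp")], list(tp = 9, fn = 1, tn = 90, fp = 0))
  expect_equal(m$se, 90)
  expect_equal(m$sp, 100)
  expect_equal(m$ca, 99)
  perfect <- evaluate_classification(truth, truth, "A")
  expect_equal(c(perfect$ca, perfect$se, perfect$sp), c(100, 100, 100))
  # counting oracle on random labels
  set.seed(45)
  p <- sample(c("A", "B", "C"), 200, replace = TRUE)
  t2 <- sample(c("A", "B", "C"), 200, replace = TRUE)
  m2 <- evaluate_classification(p, t2, "B")
  expect_equal(m2$tp, sum(p == "B" & t2 == "B"))
  expect_equal(m2$fp, sum(p == "B" & t2 != "B"))
  expect_equal(m2$fn, sum(p != "B" & t2 == "B"))
  expect_equal(m2$tn, sum(p != "B" & t2 != "B"))
  expect_error(evaluate_classification(c("A", "A"), c("B", "B"), "A"),
               "sensitivity undefined")
  expect_error(evaluate_classification(c("A"), c("A", "B"), "A"),
               "equal length")
})

test_that("majority vote aggregates cycle labels sensibly", {
  expect_equal(majority_vote(c("MR", "MR", "unknown", "AS")), "MR")
  expect_equal(majority_vote(c("unknown", "unknown")), "unknown")
  expect_equal(majority_vote("VSD"), "VSD")
})

test_that("the bundled model satisfies its published constraints", {
  model <- bundled_paper_model()
  expect_equal(round(sum(model$pi), 4), 1)
  expect_equal(round(model$mdc, 4),
               c(5.6489, 3.2831, 3.4297, 3.2831, 3.4297, 4.5258, 5.6489))
  expect_equal(model$labels,
               c("MR", "MS", "ASD", "NM", "AS", "AR", "VSD"))
  for (S in model$sigma) {
    expect_equal(S, t(S))
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("classifier JSON serialization round-trips exactly", {
  model <- bundled_paper_model()
  p <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(model, p)
  back <- read_classifier_json(p)
  expect_identical(back$pi, unname(model$pi))
  expect_identical(back$mu, unname(model$mu))
  for (k in 1:7) expect_identical(back$sigma[[k]], unname(model$sigma[[k]]))
  expect_identical(back$beta, unname(model$beta))
  expect_identical(back$mdc, unname(model$mdc))
  expect_identical(back$labels, model$labels)
})
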