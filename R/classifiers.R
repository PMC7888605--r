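# The four supervised area classifiers behind one fit/predict contract.
#
# Generative models (unimodal Gaussian, Gaussian mixture) are authored
# here: maximum-likelihood estimates with 1/n covariances, eigenvalue
# flooring for near-singular estimates, and expectation-maximization with
# k-means initialization and a monotone log-likelihood guarantee. The
# discriminative models wrap the established libraries: e1071 (libsvm,
# whose native multiclass scheme is the one-against-one vote) and nnet
# (single hidden layer + softmax + cross-entropy). Every argmax tie breaks
# to the lowest area code.

# ---- Gaussian utilities ----------------------------------------------------

# raise eigenvalues of a symmetric covariance estimate to at least
# tau = 1e-6 * mean eigenvalue. `scale` (typically the mean per-dimension
# variance of the whole training set) supplies a floor shared by all
# components of a model, so that density comparisons between degenerate
# (noise-free) components are decided by mixture weights rather than by
# whichever component collapsed further.
floor_cov <- function(S, scale = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tau <- max(1e-6 * mean(pmax(e, 0)), 1e-8 * scale, 1e-12)
  if (min(e) < tau) S <- S + diag(tau - min(e, 0), nrow(S))
  S
}

# log N(x | mu, S) for each row of x, via Cholesky
mvn_logdens <- function(x, mu, S) {
  L <- chol(S)
  d <- ncol(x)
  z <- forwardsolve(t(L), t(sweep(x, 2, mu)))
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# diagonal-covariance variant: vars is a d-vector
mvn_logdens_diag <- function(x, mu, vars) {
  d <- length(mu)
  z2 <- sweep(sweep(x, 2, mu)^2, 2, vars, "/")
  -0.5 * d * log(2 * pi) - 0.5 * sum(log(vars)) - 0.5 * rowSums(z2)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

resolve_xy <- function(x, labels) {
  if (inherits(x, "vc_features")) list(x = x$features, y = x$labels)
  else list(x = as.matrix(x), y = as.integer(labels))
}

check_dims <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != d)
    stop_visparc("feature dimension %d does not match model dimension %d",
                 ncol(x), d, class = "visparc_input_error")
  x
}

# ---- unimodal Bayes --------------------------------------------------------

#' Fit the unimodal Gaussian (Bayes) area classifier
#'
#' Maximum-likelihood Gaussian per area (sample mean and 1/n covariance,
#' floored to positive definiteness); classification is the equal-priors
#' Bayes rule, i.e. the maximum-likelihood class.
#'
#' @param x A feature matrix (units x dims) or a `vc_features` object.
#' @param labels Area codes (ignored when `x` is a `vc_features`).
#' @return An object of class `vc_bayes`.
#' @export
fit_bayes <- function(x, labels = NULL) {
  d <- resolve_xy(x, labels)
  classes <- sort(unique(d$y))
  if (length(classes) < 2)
    stop_visparc("need >= 2 areas in training labels",
                 class = "visparc_missing_class_error")
  scale <- mean(apply(d$x, 2, var))
  models <- lapply(classes, function(cl) {
    xi <- d$x[d$y == cl, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2, mu)
    list(mean = mu, cov = floor_cov(crossprod(xc) / nrow(xi), scale),
         n = nrow(xi))
  })
  structure(list(classes = classes, models = models, d = ncol(d$x)),
            class = "vc_bayes")
}

#' @export
predict.vc_bayes <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- check_dims(newdata, object$d)
  scores <- vapply(object$models,
                   function(m) mvn_logdens(x, m$mean, m$cov),
                   numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

# ---- GMM (EM) --------------------------------------------------------------

# EM for one mixture; cov_type "full" or "diag". Deterministic given seed
# (k-means initialization). Returns weights, means, covariances and the
# per-iteration training log-likelihood trace (non-decreasing).
gmm_em <- function(x, M, seed = 1, cov_type = c("full", "diag"),
                   max_iter = 200, tol = 1e-6) {
  cov_type <- match.arg(cov_type)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (M < 1) stop_visparc("M must be >= 1", class = "visparc_param_error")
  if (M > n)
    stop_visparc("M = %d mixture components exceed the %d samples", M, n,
                 class = "visparc_capacity_error")
  n_distinct <- nrow(unique(x))
  if (M > n_distinct) {
    warning(sprintf("reducing mixture count %d to %d distinct samples",
                    M, n_distinct))
    M <- n_distinct
  }
  scale <- mean(apply(x, 2, var))
  dfloor <- function(v) pmax(v, max(1e-6 * mean(v), 1e-8 * scale, 1e-12))
  withr::with_seed(as.integer(seed), {
    if (M == 1) {
      centers <- matrix(colMeans(x), 1)
      assign <- rep(1L, n)
    } else {
      km <- suppressWarnings(kmeans(x, centers = M, nstart = 1,
                                    iter.max = 50))
      centers <- km$centers
      assign <- km$cluster
    }
    w <- tabulate(assign, M) / n
    means <- centers
    covs <- lapply(seq_len(M), function(k) {
      xi <- x[assign == k, , drop = FALSE]
      mu <- means[k, ]
      S <- if (nrow(xi) > 0) crossprod(sweep(xi, 2, mu)) / nrow(xi)
           else diag(1, d)
      if (cov_type == "diag") dfloor(diag(S)) else floor_cov(S, scale)
    })
    ll_trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      logcomp <- vapply(seq_len(M), function(k) {
        ld <- if (cov_type == "diag")
                mvn_logdens_diag(x, means[k, ], covs[[k]])
              else mvn_logdens(x, means[k, ], covs[[k]])
        ld + log(w[k])
      }, numeric(n))
      logcomp <- matrix(logcomp, nrow = n)
      ll_row <- logsumexp_rows(logcomp)
      ll <- sum(ll_row)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(prev) && ll - prev < tol * abs(prev)) break
      prev <- ll
      gamma <- exp(logcomp - ll_row)
      nk <- colSums(gamma)
      nk <- pmax(nk, 1e-12)
      w <- nk / n
      means <- crossprod(gamma, x) / nk
      covs <- lapply(seq_len(M), function(k) {
        xc <- sweep(x, 2, means[k, ])
        if (cov_type == "diag") {
          dfloor(colSums(gamma[, k] * xc^2) / nk[k])
        } else {
          floor_cov(crossprod(xc * sqrt(gamma[, k])) / nk[k], scale)
        }
      })
    }
    list(weights = w, means = means, covs = covs, cov_type = cov_type,
         loglik = ll_trace, M = M, d = d)
  })
}

gmm_logdens <- function(gmm, x) {
  n <- nrow(x)
  logcomp <- vapply(seq_len(gmm$M), function(k) {
    ld <- if (gmm$cov_type == "diag")
            mvn_logdens_diag(x, gmm$means[k, ], gmm$covs[[k]])
          else mvn_logdens(x, gmm$means[k, ], gmm$covs[[k]])
    ld + log(gmm$weights[k])
  }, numeric(n))
  logsumexp_rows(matrix(logcomp, nrow = n))
}

#' Fit the Gaussian-mixture area classifier
#'
#' One M-component full-covariance mixture per area, fitted by
#' expectation-maximization from a k-means start. The per-iteration
#' training log-likelihood is non-decreasing; EM stops at a relative
#' tolerance of 1e-6 or 200 iterations. Classification is the
#' equal-priors maximum-likelihood rule.
#'
#' @param x Feature matrix or `vc_features`.
#' @param labels Area codes (ignored for `vc_features`).
#' @param M Components per area mixture (default 4).
#' @param seed Seed for the k-means initializations.
#' @return An object of class `vc_gmm`; element `mixtures` holds the
#'   per-area fits including their log-likelihood traces.
#' @export
fit_gmm <- function(x, labels = NULL, M = 4, seed = 1) {
  d <- resolve_xy(x, labels)
  classes <- sort(unique(d$y))
  if (length(classes) < 2)
    stop_visparc("need >= 2 areas in training labels",
                 class = "visparc_missing_class_error")
  mixtures <- lapply(seq_along(classes), function(i) {
    gmm_em(d$x[d$y == classes[i], , drop = FALSE], M,
           seed = derive_seed(seed, i))
  })
  structure(list(classes = classes, mixtures = mixtures, d = ncol(d$x),
                 M = M), class = "vc_gmm")
}

#' @export
predict.vc_gmm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- check_dims(newdata, object$d)
  scores <- vapply(object$mixtures, function(g) gmm_logdens(g, x),
                   numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

# ---- SVM (libsvm, one-against-one) ----------------------------------------

#' Fit the support-vector-machine area classifier
#'
#' Soft-margin SVMs via libsvm (package e1071), using libsvm's native
#' one-against-one decomposition: one machine per class pair (15 machines
#' for 6 areas) with a majority vote over pairwise decisions.
#'
#' @param x Feature matrix or `vc_features`.
#' @param labels Area codes.
#' @param C Soft-margin cost (> 0).
#' @param kernel `"radial"` (default, gamma = 1/(d * var(x))) or
#'   `"linear"`.
#' @param gamma RBF width; default scales with the feature variance.
#' @return An object of class `vc_svm` wrapping the e1071 fit.
#' @export
fit_svm <- function(x, labels = NULL, C = 1,
                    kernel = c("radial", "linear"), gamma = NULL) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop_visparc("C must be > 0", class = "visparc_param_error")
  d <- resolve_xy(x, labels)
  classes <- sort(unique(d$y))
  if (length(classes) < 2)
    stop_visparc("need >= 2 areas in training labels",
                 class = "visparc_missing_class_error")
  v <- var(as.vector(d$x))
  gamma <- gamma %||% (1 / (ncol(d$x) * if (v > 0) v else 1))
  fit <- e1071::svm(x = d$x, y = factor(d$y, levels = classes),
                    type = "C-classification", kernel = kernel,
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, classes = classes, d = ncol(d$x)),
            class = "vc_svm")
}

#' @export
predict.vc_svm <- function(object, newdata, ...) {
  x <- check_dims(newdata, object$d)
  as.integer(as.character(predict(object$fit, x)))
}

# ---- ANN (nnet) ------------------------------------------------------------

#' Fit the neural-network area classifier
#'
#' A single-hidden-layer network with 30 hidden units, softmax output and
#' cross-entropy loss (package nnet). Training is deterministic given the
#' seed. nnet optimizes by quasi-Newton (BFGS) rather than stochastic
#' gradient descent; with one hidden layer the two reach the same loss
#' surface minima and BFGS needs no learning-rate tuning.
#'
#' @param x Feature matrix or `vc_features`.
#' @param labels Area codes.
#' @param epochs Maximum optimizer iterations (default 500).
#' @param seed Seed for the weight initialization.
#' @param hidden Hidden-layer width (default 30).
#' @param decay L2 weight decay (default 1e-4, stabilizes separable data).
#' @return An object of class `vc_ann`.
#' @export
fit_ann <- function(x, labels = NULL, epochs = 500, seed = 1, hidden = 30,
                    decay = 1e-4) {
  d <- resolve_xy(x, labels)
  classes <- sort(unique(d$y))
  if (length(classes) < 2)
    stop_visparc("need >= 2 areas in training labels",
                 class = "visparc_missing_class_error")
  y_ind <- nnet::class.ind(factor(d$y, levels = classes))
  fit <- withr::with_seed(as.integer(seed),
    nnet::nnet(x = d$x, y = y_ind, size = hidden, softmax = TRUE,
               maxit = epochs, decay = decay, trace = FALSE,
               MaxNWts = 100000))
  if (!is.finite(fit$value))
    stop_visparc("training diverged (non-finite loss); lower `decay` or rescale features",
                 class = "visparc_divergence_error")
  structure(list(fit = fit, classes = classes, d = ncol(d$x)),
            class = "vc_ann")
}

#' @export
predict.vc_ann <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- check_dims(newdata, object$d)
  probs <- predict(object$fit, x, type = "raw")
  probs <- matrix(probs, nrow = nrow(x),
                  dimnames = list(NULL, object$classes))
  if (type == "score") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

# dispatch by classifier name, shared by evaluation and the CLI
fit_area_classifier <- function(name, x, labels, seed = 1, gmm_M = 4,
                                svm_C = 1, ann_epochs = 500) {
  switch(name,
         bayes = fit_bayes(x, labels),
         gmm   = fit_gmm(x, labels, M = gmm_M, seed = seed),
         svm   = fit_svm(x, labels, C = svm_C),
         ann   = fit_ann(x, labels, epochs = ann_epochs, seed = seed),
         stop_visparc("unknown classifier '%s'", name,
                      class = "visparc_input_error"))
}
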