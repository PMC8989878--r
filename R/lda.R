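#' Pooled-covariance linear discriminant analysis
#'
#' Gaussian discriminant with equal covariances across classes: class
#' means and the pooled within-class covariance are estimated from the
#' training data and a new observation is assigned to the class maximizing
#' \deqn{\delta_k(x) = x^\top \Sigma^{-1} \mu_k - \tfrac{1}{2}
#'   \mu_k^\top \Sigma^{-1} \mu_k + \log \pi_k.}
#' Priors default to equal across classes (group sizes in this study are
#' by design, not prevalence). A singular pooled covariance is
#' ridge-regularized by adding an escalating epsilon to the diagonal; the
#' epsilon used is recorded on the returned object. Ties in discriminant
#' scores break toward the class with the larger prior, then toward the
#' lexicographically smaller label.
#'
#' @param x numeric matrix (observations x features) or vector for a
#'   single feature
#' @param y class labels
#' @param priors named or ordered numeric vector of priors (defaults to
#'   equal)
#' @return list of class `sfdi_lda`
#' @export
lda_train <- function(x, y, priors = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes")
  n <- nrow(x); p <- ncol(x)
  if (any(table(y) < 2)) stop("each class needs n >= 2")
  if (p >= n) stop("feature count must be below observation count")
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (!is.null(names(priors))) priors <- priors[classes]
  priors <- priors / sum(priors)
  mu <- t(sapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE])))
  mu <- matrix(mu, nrow = k, dimnames = list(classes, colnames(x)))
  S <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2, mu[cl, ])
    S <- S + crossprod(xc)
  }
  S <- S / (n - k)
  eps_used <- 0
  Sinv <- NULL
  eps <- 0
  repeat {
    Si <- S + diag(eps, p)
    ok <- tryCatch({
      rc <- rcond(Si)
      if (!is.finite(rc) || rc < 1e-12) stop("ill-conditioned")
      Sinv <- solve(Si)
      TRUE
    }, error = function(e) FALSE)
    if (ok) { eps_used <- eps; break }
    eps <- if (eps == 0) 1e-8 * mean(diag(S) + 1e-12) else eps * 10
    if (eps > 1e6 * (mean(diag(S)) + 1)) stop("pooled covariance unusable")
  }
  structure(list(classes = classes, priors = priors, means = mu,
                 cov = S, cov_inv = Sinv, ridge_eps = eps_used),
            class = "sfdi_lda")
}

#' @rdname lda_train
#' @param model an `sfdi_lda`
#' @param newx matrix/vector of observations to classify
#' @return character vector of predicted labels
#' @export
lda_predict <- function(model, newx) {
  newx <- matrix(as.matrix(newx), ncol = ncol(model$means))
  k <- length(model$classes)
  scores <- sapply(seq_len(k), function(j) {
    m <- model$means[j, ]
    as.vector(newx %*% (model$cov_inv %*% m)) -
      0.5 * sum(m * (model$cov_inv %*% m)) + log(model$priors[j])
  })
  scores <- matrix(scores, ncol = k)
  ## tie-break: larger prior first, then lexicographic label
  ord <- order(-model$priors, model$classes)
  apply(scores, 1, function(s) {
    best <- ord[which(s[ord] >= max(s) - 0)[1]]
    model$classes[best]
  })
}

#' Leave-one-out cross-validated LDA accuracy
#'
#' For every observation, trains the pooled-covariance discriminant on the
#' remaining observations and classifies the held-out one; the figure of
#' merit is (correctly classified cases) / (all cases). Deterministic for
#' fixed input.
#'
#' @param x feature matrix (observations x features) or vector
#' @param y class labels
#' @param priors class priors (default equal)
#' @return list with `accuracy`, `predictions`, `truth`
#' @export
lda_loocv <- function(x, y, priors = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- lda_train(x[-i, , drop = FALSE], y[-i], priors = priors)
    pred[i] <- lda_predict(model, x[i, , drop = FALSE])
  }
  list(accuracy = mean(pred == y), predictions = pred, truth = y)
}

.default_feature_sets <- function() {
  list(volume    = "pct_change_volume",
       a         = "pct_change_a",
       ctHHb     = "pct_change_ctHHb",
       b         = "pct_change_b",
       StO2      = "pct_change_StO2",
       `ctHHb+a` = c("pct_change_ctHHb", "pct_change_a"))
}

#' LOOCV accuracy grid over feature sets and days
#'
#' One leave-one-out LDA per (feature set, day) using that day's
#' percent-change features. The short-term scope classifies all three
#' arms on Days 1-6; the long-term scope classifies CPA vs CPA+Ab on
#' every post-baseline measurement day through Day 30. A cell is NA
#' unless every group in scope has at least 2 subjects with complete
#' features on that day.
#'
#' @param table a `cohort_table`
#' @param feature_sets named list of column-name vectors; defaults to
#'   volume, a, ctHHb, b, StO2 and ctHHb+a
#' @param scope `"short"` or `"long"`
#' @param priors passed to [lda_loocv()] (default equal)
#' @return matrix (feature sets x days) of accuracies with attributes
#'   `scope` and `groups`; class `accuracy_grid`
#' @export
accuracy_grid <- function(table, feature_sets = .default_feature_sets(),
                          scope = c("short", "long"), priors = NULL) {
  scope <- match.arg(scope)
  if (scope == "short") {
    groups <- sort(unique(table$group))
    days <- sort(unique(table$day[table$day >= 1 & table$day <= 6]))
  } else {
    groups <- intersect(c("CPA", "CPA+Ab"), unique(table$group))
    days <- sort(unique(table$day[table$day >= 1]))
  }
  if (length(groups) < 2) stop("scope '", scope, "' requires >= 2 groups")
  grid <- matrix(NA_real_, length(feature_sets), length(days),
                 dimnames = list(names(feature_sets), as.character(days)))
  for (d in seq_along(days)) {
    sub <- table[table$day == days[d] & table$group %in% groups, , drop = FALSE]
    for (f in seq_along(feature_sets)) {
      cols <- feature_sets[[f]]
      if (!all(cols %in% names(sub))) next
      X <- as.matrix(sub[, cols, drop = FALSE])
      ok <- stats::complete.cases(X)
      Xo <- X[ok, , drop = FALSE]; yo <- sub$group[ok]
      tab <- table(factor(yo, levels = groups))
      if (any(tab < 2)) next
      grid[f, d] <- lda_loocv(Xo, yo, priors = priors)$accuracy
    }
  }
  attr(grid, "scope") <- scope
  attr(grid, "groups") <- groups
  class(grid) <- c("accuracy_grid", class(grid))
  grid
}
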