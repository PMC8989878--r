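#' Generalized estimating equations for clustered longitudinal data
#'
#' Population-averaged linear model (normal family, identity link) with a
#' working correlation structure over repeated measurements within
#' clusters, and a cluster-robust (sandwich) covariance for the
#' coefficients. Estimation iterates generalized least squares with
#' moment estimates of the dispersion and, for the AR(1) structure, of the
#' lag-1 autocorrelation of the within-cluster Pearson residuals (by
#' observation order within cluster). With the independence structure the
#' estimator reduces exactly to ordinary least squares.
#'
#' @param formula model formula
#' @param data data.frame, ordered within cluster by time
#' @param id cluster identifier (vector, length nrow(data))
#' @param corstr working correlation: `"ar1"`, `"independence"` or
#'   `"exchangeable"`
#' @param maxit,tol iteration control
#' @return object of class `sfdi_gee` with `coefficients`, robust `vcov`,
#'   `alpha` (working-correlation parameter), `phi` (dispersion),
#'   `n_clusters`, and the model frame metadata needed for prediction
#' @export
gee_fit <- function(formula, data, id, corstr = c("ar1", "independence",
                                                  "exchangeable"),
                    maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- as.character(id)
  if (length(id) != length(y)) stop("id length mismatch")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  clusters <- split(seq_along(y), id)
  n_clus <- length(clusters)
  p <- ncol(X)

  beta <- stats::coef(stats::lm.fit(X, y))
  alpha <- 0
  phi <- 1
  for (it in seq_len(maxit)) {
    e <- y - as.vector(X %*% beta)
    phi <- sum(e^2) / (length(y) - p)
    if (phi < 1e-300) phi <- 1e-300  # degenerate exact fit
    if (corstr == "ar1") {
      num <- 0; nn <- 0
      for (ix in clusters) {
        ni <- length(ix)
        if (ni >= 2) {
          num <- num + sum(e[ix[-ni]] * e[ix[-1]])
          nn <- nn + (ni - 1)
        }
      }
      alpha <- if (nn > p) num / ((nn - p) * phi) else 0
      if (!is.finite(alpha)) alpha <- 0
      alpha <- max(min(alpha, 0.95), -0.95)
    } else if (corstr == "exchangeable") {
      num <- 0; nn <- 0
      for (ix in clusters) {
        ni <- length(ix)
        if (ni >= 2) {
          num <- num + (sum(e[ix])^2 - sum(e[ix]^2)) / 2
          nn <- nn + ni * (ni - 1) / 2
        }
      }
      alpha <- if (nn > p) num / ((nn - p) * phi) else 0
      if (!is.finite(alpha)) alpha <- 0
      alpha <- max(min(alpha, 0.95), -1 / (max(lengths(clusters)) - 1) + 0.01)
    }
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (ix in clusters) {
      ni <- length(ix)
      Ri <- switch(corstr,
        independence = diag(ni),
        ar1 = alpha^abs(outer(seq_len(ni), seq_len(ni), "-")),
        exchangeable = matrix(alpha, ni, ni) + diag(1 - alpha, ni))
      Wi <- solve(Ri)
      Xi <- X[ix, , drop = FALSE]
      A <- A + crossprod(Xi, Wi %*% Xi)
      bvec <- bvec + crossprod(Xi, Wi %*% y[ix])
    }
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) break
  }

  ## sandwich covariance: B^-1 M B^-1 with V_i = phi * R_i
  e <- y - as.vector(X %*% beta)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in clusters) {
    ni <- length(ix)
    Ri <- switch(corstr,
      independence = diag(ni),
      ar1 = alpha^abs(outer(seq_len(ni), seq_len(ni), "-")),
      exchangeable = matrix(alpha, ni, ni) + diag(1 - alpha, ni))
    Vinv <- solve(Ri) / phi
    Xi <- X[ix, , drop = FALSE]
    XtV <- crossprod(Xi, Vinv)
    B <- B + XtV %*% Xi
    u <- XtV %*% e[ix]
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vc <- Binv %*% M %*% Binv
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vc, alpha = alpha, phi = phi,
                 corstr = corstr, n_clusters = n_clus,
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 contrasts = attr(X, "contrasts"),
                 formula = formula, n_obs = length(y)),
            class = "sfdi_gee")
}

## Linear-combination rows (model matrix) for new data
.gee_lincomb <- function(fit, newdata) {
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
}

#' Adjusted means and linear contrasts from a GEE fit
#'
#' `gee_adjusted_means` evaluates the fitted population-average outcome at
#' given covariate combinations with delta-method robust standard errors;
#' `gee_contrast` tests an arbitrary linear combination of coefficients
#' with a Wald z test on the sandwich covariance.
#'
#' @param fit an `sfdi_gee`
#' @param newdata data.frame of covariate combinations
#' @return data.frame with `estimate` and `se`
#' @export
gee_adjusted_means <- function(fit, newdata) {
  L <- .gee_lincomb(fit, newdata)
  est <- as.vector(L %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((L %*% fit$vcov) * L)))
  data.frame(newdata, estimate = est, se = se)
}

#' @rdname gee_adjusted_means
#' @param L numeric contrast vector (length = number of coefficients)
#' @export
gee_contrast <- function(fit, L) {
  est <- sum(L * fit$coefficients)
  se <- sqrt(max(0, as.vector(t(L) %*% fit$vcov %*% L)))
  z <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  list(estimate = est, se = se, z = z, p = p)
}

#' Fit the longitudinal GEE model for one outcome and scope
#'
#' Models the percent-change outcome with categorical day, treatment
#' group, and their interaction (per-day group effects), AR(1) working
#' correlation, subjects as clusters, and robust standard errors. The
#' short-term scope keeps all three arms through Day 12 (while every arm
#' still has subjects); the long-term scope keeps the CPA and CPA+Ab arms
#' through Day 30.
#'
#' @param table a `cohort_table`
#' @param outcome one of `"a"`, `"b"`, `"ctHbO2"`, `"ctHHb"`, `"ctTHb"`,
#'   `"StO2"`, `"volume"`
#' @param scope `"short"` or `"long"`
#' @param corstr working correlation (default AR(1))
#' @return `sfdi_gee` with `scope`, `outcome` and `days` attached
#' @export
fit_gee <- function(table, outcome, scope = c("short", "long"),
                    corstr = "ar1") {
  scope <- match.arg(scope)
  col <- paste0("pct_change_", outcome)
  if (!col %in% names(table)) stop("outcome column ", col, " not present")
  dat <- if (scope == "short") {
    table[table$day <= 12, , drop = FALSE]
  } else {
    table[table$group %in% c("CPA", "CPA+Ab"), , drop = FALSE]
  }
  dat <- dat[is.finite(dat[[col]]), , drop = FALSE]
  if (length(unique(dat$group)) < 2) stop("scope '", scope,
                                          "' requires at least two groups")
  counts <- table(unique(dat[, c("subject", "group")])$group)
  if (any(counts < 2)) stop("each group in scope needs >= 2 clusters")
  dat$day_f <- factor(dat$day)
  dat$group_f <- factor(dat$group)
  dat$.y <- dat[[col]]
  dat <- dat[order(dat$subject, dat$day), , drop = FALSE]
  fit <- gee_fit(.y ~ day_f * group_f, dat, id = dat$subject, corstr = corstr)
  fit$scope <- scope
  fit$outcome <- outcome
  fit$days <- sort(unique(dat$day))
  fit$groups <- levels(dat$group_f)
  fit
}

#' Per-day post-hoc group contrasts from a longitudinal GEE fit
#'
#' Differences of adjusted group means at each measurement day for each
#' group pair, with robust Wald p-values and significance flags at the
#' nominal level and at the multiplicity-adjusted level (0.007 for the
#' short-term analysis, 0.003 for the long-term analysis).
#'
#' @param fit an `sfdi_gee` from [fit_gee()]
#' @param days days at which to contrast (default: all modeled days > 0)
#' @param alpha nominal significance level
#' @param alpha_adjusted multiplicity-adjusted level; defaults by scope
#' @return data.frame of class `contrast_result`
#' @export
posthoc_contrasts <- function(fit, days = NULL, alpha = 0.05,
                              alpha_adjusted = NULL) {
  stopifnot(inherits(fit, "sfdi_gee"))
  if (is.null(days)) days <- setdiff(fit$days, 0)
  if (is.null(alpha_adjusted)) {
    alpha_adjusted <- if (identical(fit$scope, "long")) 0.003 else 0.007
  }
  groups <- fit$groups
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- list()
  for (d in days) {
    for (pr in pairs) {
      nd <- data.frame(day_f = factor(d, levels = fit$xlevels$day_f),
                       group_f = factor(pr, levels = fit$xlevels$group_f))
      L <- .gee_lincomb(fit, nd)
      ct <- gee_contrast(fit, L[1, ] - L[2, ])
      out[[length(out) + 1]] <- data.frame(
        day = d, group1 = pr[1], group2 = pr[2],
        estimate = ct$estimate, se = ct$se, p = ct$p,
        sig = ct$p < alpha, sig_adjusted = ct$p < alpha_adjusted)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "alpha_adjusted") <- alpha_adjusted
  class(res) <- c("contrast_result", "data.frame")
  res
}
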