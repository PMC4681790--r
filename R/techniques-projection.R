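#' Cross-validated R-squared of principal component regression
#'
#' Projects samples onto the top-k variance-ordered principal components of
#' the column-standardized abundance matrix and regresses the 0/1 group
#' indicator on the scores by least squares. The statistic is
#' `1 - PRESS/TSS` over stratified cross-validation folds, with
#' standardization, component extraction and the regression all refit
#' inside each training fold, so no information leaks from held-out
#' samples. The value can be negative when the model predicts worse than
#' the grand mean.
#'
#' @param table An [abundance_table()] (normalized internally).
#' @param labels Group labels (see [group_labels()]).
#' @param k Number of components, or `"all"` (capped at the training-fold
#'   rank; a `k` above the rank is capped with a warning).
#' @param cv_folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @return Cross-validated R-squared.
#' @export
pcr_cv_r2 <- function(table, labels, k = 5, cv_folds = 10, seed = 1L) {
  cv_projection_r2(table, labels, k, cv_folds, seed, method = "pcr")
}

#' Cross-validated R-squared of partial least squares regression
#'
#' Identical protocol to [pcr_cv_r2()] but components are extracted by
#' NIPALS-style deflation, each maximizing covariance with the response
#' rather than variance alone. This is the defining contrast with PCR:
#' a response-aligned direction carrying little variance is found by the
#' first PLS component but may be invisible to the first principal
#' component.
#'
#' @inheritParams pcr_cv_r2
#' @return Cross-validated R-squared.
#' @export
plsr_cv_r2 <- function(table, labels, k = 5, cv_folds = 10, seed = 1L) {
  cv_projection_r2(table, labels, k, cv_folds, seed, method = "plsr")
}

cv_projection_r2 <- function(table, labels, k, cv_folds, seed, method) {
  stopifnot(inherits(table, "abundance_table"))
  case <- case_indicator(labels, table$sample_ids)
  x <- t(normalize_relative(table)$values)
  projection_cv_engine(x, case, k, cv_folds, seed, method)
}

projection_cv_engine <- function(x, case, k, cv_folds, seed, method) {
  y <- as.numeric(case)
  n <- nrow(x)
  if (!(identical(k, "all") || is_count(k))) {
    abort("k must be a positive integer or 'all'")
  }
  fold <- make_folds(case, cv_folds, seed)
  press <- 0
  warned <- FALSE
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- projection_fit(x[tr, , drop = FALSE], y[tr], k, method)
    if (fit$capped && !warned && is_count(k)) {
      warn(paste0("k = ", k, " exceeds the training rank; capped at ", fit$k))
      warned <- TRUE
    }
    pred <- projection_predict(fit, x[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - pred)^2)
  }
  tss <- sum((y - mean(y))^2)
  1 - press / tss
}

# Fit on a training block: column-standardize (zero-variance columns get
# unit scale), then extract k components by SVD (pcr) or NIPALS (plsr) and
# regress y on the scores.
projection_fit <- function(x, y, k, method) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  n <- nrow(xs)
  max_k <- min(n - 1L, ncol(xs))
  k_req <- if (identical(k, "all")) max_k else as.integer(k)
  if (method == "pcr") {
    sv <- svd(xs, nu = 0)
    rank <- sum(sv$d > sv$d[1L] * 1e-10)
    k_use <- min(k_req, rank, max_k)
    rot <- sv$v[, seq_len(k_use), drop = FALSE]
    scores <- xs %*% rot
    beta <- qr.solve(cbind(1, scores), y)
    list(method = "pcr", ctr = ctr, scl = scl, rot = rot, beta = beta,
         k = k_use, capped = k_use < k_req)
  } else {
    k_use <- min(k_req, max_k)
    pls <- nipals_pls(xs, y, k_use)
    list(method = "plsr", ctr = ctr, scl = scl, coef = pls$coef,
         intercept = pls$intercept, k = pls$k, capped = pls$k < k_req)
  }
}

projection_predict <- function(fit, x_new) {
  xs <- sweep(sweep(x_new, 2L, fit$ctr, "-"), 2L, fit$scl, "/")
  if (fit$method == "pcr") {
    drop(cbind(1, xs %*% fit$rot) %*% fit$beta)
  } else {
    drop(fit$intercept + xs %*% fit$coef)
  }
}

# PLS1 via NIPALS deflation: each weight vector maximizes covariance of the
# score with the (current residual of the) response. Stops early if the
# residual covariance vanishes.
nipals_pls <- function(xs, y, k) {
  y0 <- y - mean(y)
  e <- xs
  f <- y0
  p_dim <- ncol(xs)
  w_mat <- matrix(0, p_dim, 0)
  p_mat <- matrix(0, p_dim, 0)
  q_vec <- numeric(0)
  for (a in seq_len(k)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(e, t_sc) / tt
    q_load <- sum(f * t_sc) / tt
    e <- e - t_sc %*% t(p_load)
    f <- f - q_load * t_sc
    w_mat <- cbind(w_mat, w)
    p_mat <- cbind(p_mat, p_load)
    q_vec <- c(q_vec, q_load)
  }
  k_use <- length(q_vec)
  if (k_use == 0L) {
    return(list(coef = numeric(p_dim), intercept = mean(y), k = 0L))
  }
  coef <- w_mat %*% solve(crossprod(p_mat, w_mat), q_vec)
  list(coef = drop(coef), intercept = mean(y), k = k_use)
}
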