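#' Univariate partial least squares regression (PLS1)
#'
#' Fits a NIPALS PLS1 model of a single response on a complete indicator
#' matrix. Predictors are centred and scaled, the response is centred, and
#' components are extracted with deflation. Variable importance in
#' projection (VIP) scores are computed from the component weights and the
#' per-component explained response variance.
#'
#' @param X complete numeric matrix or data frame (environments x
#'   indicators); no missing cells.
#' @param y numeric response (mean probe-genotype yield per environment).
#' @param n_components number of latent components (0 gives the null model
#'   predicting `mean(y)`).
#' @return an object of class `pls1` with elements `n_components`, `x_mean`,
#'   `x_scale`, `y_mean`, `weights`, `x_scores`, `x_loadings`, `y_loadings`,
#'   `coef_std` (standardized-scale), `coefficients` and `intercept`
#'   (original scale), `vip`, `fitted`, `r2`, `rmse`.
#' @export
fit_pls1 <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_field("X", "must be numeric")
  if (anyNA(X) || anyNA(y)) stop_field("X", "missing cells are not allowed; impute first")
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop_field("X", "needs at least 3 rows")
  if (length(y) != n) stop_field("y", "length must equal nrow(X)")
  n_components <- check_count(n_components, "n_components", min = 0L)
  if (n_components > min(n - 1L, p))
    stop_field("n_components", "cannot exceed min(nrow(X) - 1, ncol(X))")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  x_mean <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0))
    stop_field("X", paste("zero-variance column(s):",
                          paste(colnames(X)[x_scale == 0], collapse = ", ")))
  Z <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  u <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  ss_y <- numeric(n_components)      # response variance captured per component
  Zd <- Z; ud <- u
  a <- 0L
  while (a < n_components) {
    wv <- drop(crossprod(Zd, ud))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break            # response variance exhausted
    a <- a + 1L
    wv <- wv / nw
    tv <- drop(Zd %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(Zd, tv)) / tt
    qa <- sum(ud * tv) / tt
    Zd <- Zd - tcrossprod(tv, pv)
    ud <- ud - tv * qa
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv
    q[a] <- qa; ss_y[a] <- qa^2 * tt
  }
  A <- a
  if (A > 0) {
    W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
    Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
    ss_y <- ss_y[seq_len(A)]
    Wstar <- W %*% solve(crossprod(P, W))
    coef_std <- drop(Wstar %*% q)
    vip <- sqrt(p * drop((W^2) %*% ss_y) / sum(ss_y))
  } else {
    W <- P <- matrix(0, p, 0); Tm <- matrix(0, n, 0); q <- numeric(0)
    coef_std <- numeric(p)
    vip <- rep(0, p)
  }
  names(coef_std) <- names(vip) <- colnames(X)
  coefficients <- coef_std / x_scale
  intercept <- y_mean - sum(coefficients * x_mean)
  fitted <- drop(Z %*% coef_std) + y_mean
  ss_tot <- sum((y - y_mean)^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - fitted)^2) / ss_tot else 0
  structure(list(
    n_components = A, x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    weights = W, x_scores = Tm, x_loadings = P, y_loadings = q,
    coef_std = coef_std, coefficients = coefficients, intercept = intercept,
    vip = vip, fitted = fitted, r2 = max(0, r2),
    rmse = sqrt(mean((y - fitted)^2))), class = "pls1")
}

#' Predict from a PLS1 model and score against observations
#'
#' @param model a [fit_pls1()] object.
#' @param X new indicator matrix with the model's columns.
#' @param y observed response.
#' @return list with `predictions`, `r2` (`1 - SS_res/SS_tot`) and `rmse`.
#' @export
predict_and_score <- function(model, X, y) {
  stopifnot(inherits(model, "pls1"))
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(model$x_mean))
    colnames(X) <- names(model$x_mean)
  if (!identical(colnames(X), names(model$x_mean)))
    stop_field("X", "columns do not match the fitted model")
  Z <- sweep(sweep(X, 2, model$x_mean), 2, model$x_scale, "/")
  pred <- drop(Z %*% model$coef_std) + model$y_mean
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - pred)^2)
  list(predictions = pred,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
       rmse = sqrt(mean((y - pred)^2)))
}

# K-fold cross-validated RMSE of a PLS1 fit, deterministic in `seed`.
cv_rmse_pls1 <- function(X, y, n_components, folds = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- min(folds, n)
  assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  press <- 0
  for (f in seq_len(folds)) {
    tr <- assign_fold != f
    if (sum(tr) < 3) return(NA_real_)
    nc <- min(n_components, sum(tr) - 1L, ncol(X))
    fit <- fit_pls1(X[tr, , drop = FALSE], y[tr], nc)
    Z <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$x_mean), 2, fit$x_scale, "/")
    pred <- drop(Z %*% fit$coef_std) + fit$y_mean
    press <- press + sum((y[!tr] - pred)^2)
  }
  sqrt(press / n)
}

# Pick the number of components (1..max_comp) minimizing CV-RMSE.
choose_ncomp_pls1 <- function(X, y, max_comp = 5, folds = 5, seed = 1) {
  max_comp <- min(max_comp, ncol(X), nrow(X) - 2L)
  rmses <- vapply(seq_len(max_comp), function(a)
    cv_rmse_pls1(X, y, a, folds = folds, seed = seed), 0)
  which.min(rmses)
}

#' Select seed-yield limiting factors by VIP-guided backward elimination
#'
#' Starting from the full indicator set, the variable with the lowest VIP
#' score is dropped and the model refitted, tracking the cross-validated
#' RMSE of every visited set. The returned set is the one minimizing
#' CV-RMSE (ties broken toward the smaller set); elimination never goes
#' below one variable. The number of PLS components is chosen by
#' cross-validation on the full set before selection begins.
#'
#' @param X complete indicator matrix (environments x indicators).
#' @param y mean probe-genotype yield per environment.
#' @param vip_floor VIP value regarded as "important"; recorded in the trace
#'   (variables at or above it are flagged) but elimination explores the full
#'   path.
#' @param cv_folds folds for the CV-RMSE criterion.
#' @param max_components upper bound on the CV-chosen component count.
#' @param seed seed for the (deterministic) fold assignment.
#' @return list with `selected` (retained indicator names, original column
#'   order), `trace` (data frame: step, n_vars, removed, cv_rmse),
#'   `n_components`.
#' @export
select_limiting_factors <- function(X, y, vip_floor = 1.0, cv_folds = 5,
                                    max_components = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  ncomp <- choose_ncomp_pls1(X, y, max_comp = max_components,
                             folds = cv_folds, seed = seed)
  vars <- colnames(X)
  sets <- list(vars)
  removed <- NA_character_
  cvr <- cv_rmse_pls1(X[, vars, drop = FALSE], y, min(ncomp, length(vars)),
                      folds = cv_folds, seed = seed)
  cur <- vars
  while (length(cur) > 1) {
    fit <- fit_pls1(X[, cur, drop = FALSE], y, min(ncomp, length(cur)))
    drop_var <- cur[which.min(fit$vip)]
    cur <- setdiff(cur, drop_var)
    sets[[length(sets) + 1L]] <- cur
    removed <- c(removed, drop_var)
    cvr <- c(cvr, cv_rmse_pls1(X[, cur, drop = FALSE], y,
                               min(ncomp, length(cur)),
                               folds = cv_folds, seed = seed))
  }
  # argmin with ties (to numerical tolerance) resolved toward the smaller set
  best <- min(cvr, na.rm = TRUE)
  candidates <- which(cvr <= best + 1e-10)
  pick <- candidates[length(candidates)]
  trace <- data.frame(step = seq_along(sets) - 1L,
                      n_vars = lengths(sets),
                      removed = removed,
                      cv_rmse = cvr,
                      stringsAsFactors = FALSE)
  list(selected = colnames(X)[colnames(X) %in% sets[[pick]]],
       trace = trace, n_components = ncomp)
}
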