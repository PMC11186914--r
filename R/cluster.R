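#' Cluster environments into envirotypes
#'
#' Environments are clustered on their (column-standardized) limiting-factor
#' profiles with Ward linkage on Euclidean distances. When `k` is not given,
#' the number of envirotypes is chosen at the elbow of the inertia-gain
#' curve: the candidate `k` in `[2, min(10, rows - 1)]` with the largest
#' relative drop between the inertia gained by allowing `k` clusters and the
#' gain from allowing `k + 1`. Degenerate inputs with zero total inertia
#' fall back to `k = 2`.
#'
#' @param Z environments x limiting-factors data (data frame with an
#'   `environment_id` first column, or matrix with rownames).
#' @param k optional number of envirotypes.
#' @return list with `assignment` (data frame `environment_id`,
#'   `envirotype`), `k`, `hclust` (the dendrogram), `inertia_gain` (data
#'   frame `k`, `gain`), `within_inertia`, `total_inertia`.
#' @export
cluster_envirotypes <- function(Z, k = NULL) {
  ids <- NULL
  if (is.data.frame(Z) && names(Z)[1] == "environment_id") {
    ids <- Z[[1]]
    Z <- Z[, -1, drop = FALSE]
  }
  M <- as.matrix(Z)
  if (is.null(ids)) ids <- if (!is.null(rownames(M))) rownames(M) else as.character(seq_len(nrow(M)))
  n <- nrow(M)
  if (n < 2) stop_field("Z", "needs at least 2 rows")
  if (!is.null(k)) {
    k <- check_count(k, "k", min = 1L)
    if (k > n) stop_field("k", "cannot exceed the number of environments")
  }
  sdv <- apply(M, 2, stats::sd)
  S <- sweep(M, 2, colMeans(M))
  S <- sweep(S, 2, ifelse(sdv > 0, sdv, 1), "/")
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")

  within_ss <- function(groups) {
    sum(vapply(split(seq_len(n), groups), function(ix) {
      sum(sweep(S[ix, , drop = FALSE], 2,
                colMeans(S[ix, , drop = FALSE]))^2)
    }, 0))
  }
  kmax <- min(10L, n - 1L)
  ks <- seq_len(min(kmax + 1L, n))
  W <- vapply(ks, function(kk) within_ss(stats::cutree(hc, k = kk)), 0)
  total <- W[1]
  gain <- c(NA_real_, -diff(W))   # gain[k] = inertia explained by k vs k-1 clusters
  if (is.null(k)) {
    if (total < 1e-12 || kmax < 2L) {
      k <- min(2L, n)
    } else {
      cand <- 2:kmax
      rel_drop <- vapply(cand, function(kk) {
        g1 <- gain[kk]
        g2 <- if (kk + 1L <= length(gain)) gain[kk + 1L] else 0
        if (!is.finite(g1) || g1 <= 1e-12) return(-Inf)
        (g1 - g2) / g1
      }, 0)
      k <- cand[which.max(rel_drop)]
    }
  }
  cl <- stats::cutree(hc, k = k)
  # contiguous labels in order of first appearance
  lab <- match(cl, unique(cl))
  assignment <- data.frame(environment_id = ids,
                           envirotype = paste0("E", lab),
                           stringsAsFactors = FALSE)
  list(assignment = assignment, k = as.integer(k), hclust = hc,
       inertia_gain = data.frame(k = ks, gain = gain),
       within_inertia = data.frame(k = ks, within = W),
       total_inertia = total)
}

#' Limiting-factor profiles of the envirotypes on a 0-10 scale
#'
#' For each indicator, the per-envirotype means plus the overall (MET) mean
#' are min-max scaled to `[0, 10]` across that set of means. An indicator
#' constant across envirotypes maps all profiles to 5.
#'
#' @param Z environments x limiting-factors data (same layout as
#'   [cluster_envirotypes()]).
#' @param assignment data frame `environment_id`, `envirotype` covering all
#'   rows of `Z`.
#' @return matrix of profiles, one row per envirotype plus a final `"MET"`
#'   row, one column per indicator.
#' @export
envirotype_profiles <- function(Z, assignment) {
  ids <- NULL
  if (is.data.frame(Z) && names(Z)[1] == "environment_id") {
    ids <- Z[[1]]
    Z <- Z[, -1, drop = FALSE]
  }
  M <- as.matrix(Z)
  if (is.null(ids)) ids <- if (!is.null(rownames(M))) rownames(M) else as.character(seq_len(nrow(M)))
  env_of <- assignment$envirotype[match(ids, assignment$environment_id)]
  if (anyNA(env_of)) stop_field("assignment", "must cover every row of Z")
  groups <- sort(unique(assignment$envirotype))
  if (any(!groups %in% env_of))
    stop_field("assignment", "empty envirotype (no rows of Z assigned to it)")
  means <- rbind(
    do.call(rbind, lapply(groups, function(g)
      colMeans(M[env_of == g, , drop = FALSE]))),
    colMeans(M))
  rownames(means) <- c(groups, "MET")
  prof <- apply(means, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng < 1e-12) rep(5, length(v)) else (v - min(v)) / rng * 10
  })
  rownames(prof) <- rownames(means)
  prof
}
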