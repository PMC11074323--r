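# upper-triangle vectorisation (diagonal excluded) and its inverse
vec_upper <- function(M) M[upper.tri(M)]

unvec_upper <- function(v, n, dimnames_ = NULL) {
  M <- matrix(0, n, n, dimnames = dimnames_)
  M[upper.tri(M)] <- v
  M <- M + t(M)
  M
}

# city-block k-means with component-wise median centroids: the L1-consistent
# centroid, so the within-cluster city-block cost is non-increasing over
# iterations. Empty clusters are re-seeded at the point farthest from its
# assigned centroid.
kmeans_cityblock <- function(V, k, replicates = 10, max_iter = 100) {
  n <- nrow(V)
  if (k > n) stop("kmeans_cityblock: k exceeds number of observations")
  run_once <- function() {
    centroids <- V[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      D <- vapply(seq_len(k), function(j) {
        rowSums(abs(sweep(V, 2, centroids[j, ])))
      }, numeric(n))
      D <- matrix(D, nrow = n)
      assign_cur <- max.col(-D, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(assign_cur == j)) { # re-seed empty cluster at farthest point
          far <- which.max(D[cbind(seq_len(n), assign_cur)])
          assign_cur[far] <- j
          centroids[j, ] <- V[far, ]
        }
      }
      if (all(assign_cur == assign_prev)) break
      assign_prev <- assign_cur
      for (j in seq_len(k)) {
        centroids[j, ] <- apply(V[assign_cur == j, , drop = FALSE], 2,
                                stats::median)
      }
    }
    D <- vapply(seq_len(k), function(j) {
      rowSums(abs(sweep(V, 2, centroids[j, ])))
    }, numeric(n))
    D <- matrix(D, nrow = n)
    assign_cur <- max.col(-D, ties.method = "first")
    cost <- sum(D[cbind(seq_len(n), assign_cur)])
    list(assignment = assign_cur, centroids = centroids, cost = cost)
  }
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- run_once()
    if (is.null(best) || fit$cost < best$cost - 1e-12) best <- fit
  }
  best
}

#' Cluster windowed connectivity matrices into recurring brain states
#'
#' Pools the windowed Fisher-z matrices of all subjects, vectorises each as
#' its upper triangle (diagonal excluded), and applies k-means with
#' city-block distance (component-wise median centroids), repeated
#' `replicates` times with random initialisation; the lowest-cost solution
#' is kept (ties to the earliest replicate).
#'
#' @param fcs list of `windowed_fc` objects (one per subject), or a plain
#'   list of symmetric matrices.
#' @param k number of states (default 2).
#' @param replicates random restarts (default 10).
#' @return a `state_model`: list with `k`, `centroids` (list of
#'   nodes-by-nodes matrices), `assignment` (data frame `subject`, `window`,
#'   `state`), `cost`, `distance`.
#' @export
cluster_states <- function(fcs, k = 2, replicates = 10) {
  if (inherits(fcs, "windowed_fc")) fcs <- list(fcs)
  if (is.list(fcs) && all(vapply(fcs, inherits, logical(1), "windowed_fc"))) {
    mats <- unlist(lapply(fcs, `[[`, "z"), recursive = FALSE)
    subject <- rep(vapply(fcs, function(f) as.character(f$subject_id),
                          character(1)),
                   vapply(fcs, function(f) length(f$z), integer(1)))
    window <- unlist(lapply(fcs, function(f) seq_along(f$z)))
  } else {
    mats <- fcs
    subject <- rep("s1", length(mats))
    window <- seq_along(mats)
  }
  if (length(mats) < k) stop("cluster_states: fewer matrices than k")
  n_nodes <- nrow(mats[[1]])
  V <- t(vapply(mats, vec_upper, numeric(n_nodes * (n_nodes - 1) / 2)))
  fit <- kmeans_cityblock(V, k, replicates)
  centroids <- lapply(seq_len(k), function(j) {
    unvec_upper(fit$centroids[j, ], n_nodes, dimnames(mats[[1]]))
  })
  structure(
    list(k = k, centroids = centroids,
         assignment = data.frame(subject = subject, window = window,
                                 state = fit$assignment),
         cost = fit$cost, distance = "cityblock"),
    class = "state_model"
  )
}

#' System segregation of a connectivity matrix
#'
#' \deqn{1 - \bar z_b / \bar z_w}: one minus the ratio of the mean
#' between-network edge to the mean within-network edge (diagonal excluded),
#' over an a-priori network atlas. Returns `NA` with a warning when the mean
#' within-network edge is zero.
#'
#' @param W symmetric nodes-by-nodes matrix.
#' @param atlas a `network_atlas` covering all nodes.
#' @return scalar segregation value.
#' @export
system_segregation <- function(W, atlas) {
  stopifnot(inherits(atlas, "network_atlas"),
            nrow(W) == length(atlas$node_id))
  same <- outer(atlas$network_of_node, atlas$network_of_node, "==")
  ut <- upper.tri(W)
  zw <- mean(W[ut & same])
  zb <- mean(W[ut & !same])
  if (zw == 0) {
    warning("system_segregation: zero mean within-network edge")
    return(NA_real_)
  }
  1 - zb / zw
}

#' Label brain states and compute prevalence time courses
#'
#' The state whose centroid has higher [system_segregation()] is labelled
#' `"segregated"`, the other `"integrated"` (k = 2; for k > 2 states are
#' ranked by segregation). Per-window prevalence of a state is the fraction
#' of subjects assigned to it; frequencies sum to 1 in every window.
#'
#' @param model a `state_model` from [cluster_states()].
#' @param atlas a `network_atlas`.
#' @return a `state_prevalence`: list with `labels` (state id -> label),
#'   `segregation` (per-state centroid segregation), and `prevalence`
#'   (data frame `window`, one column per label).
#' @export
label_and_prevalence <- function(model, atlas) {
  stopifnot(inherits(model, "state_model"))
  seg <- vapply(model$centroids, system_segregation, numeric(1),
                atlas = atlas)
  if (anyDuplicated(seg)) {
    stop("label_and_prevalence: exact centroid segregation tie; ",
         "label states manually")
  }
  labels <- rep("intermediate", model$k)
  labels[which.max(seg)] <- "segregated"
  labels[which.min(seg)] <- "integrated"
  asg <- model$assignment
  windows <- sort(unique(asg$window))
  prev <- vapply(windows, function(w) {
    sub <- asg$state[asg$window == w]
    vapply(seq_len(model$k), function(s) mean(sub == s), numeric(1))
  }, numeric(model$k))
  prev <- t(matrix(prev, nrow = model$k))
  colnames(prev) <- labels
  structure(
    list(labels = labels, segregation = seg,
         prevalence = data.frame(window = windows, prev,
                                 check.names = FALSE)),
    class = "state_prevalence"
  )
}

#' Silhouette diagnostic for the number of states
#'
#' Mean city-block silhouette width of a fitted state model: for each
#' windowed matrix, \eqn{s = (b - a)/\max(a, b)} with `a` the mean distance
#' to its own state's members and `b` the smallest mean distance to another
#' state's members. Provided as a diagnostic for alternative `k`; the main
#' analysis path fixes `k = 2`.
#'
#' @param fcs the same input handed to [cluster_states()].
#' @param model the fitted `state_model`.
#' @return list with `mean_width` and per-observation `widths`.
#' @export
state_silhouette <- function(fcs, model) {
  if (inherits(fcs, "windowed_fc")) fcs <- list(fcs)
  if (is.list(fcs) && all(vapply(fcs, inherits, logical(1), "windowed_fc"))) {
    mats <- unlist(lapply(fcs, `[[`, "z"), recursive = FALSE)
  } else {
    mats <- fcs
  }
  n_nodes <- nrow(mats[[1]])
  V <- t(vapply(mats, vec_upper, numeric(n_nodes * (n_nodes - 1) / 2)))
  lab <- model$assignment$state
  stopifnot(nrow(V) == length(lab))
  n <- nrow(V)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(V, 2, V[i, ])))
    own <- lab == lab[i]
    a <- if (sum(own) > 1) sum(d[own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d[lab == g]), numeric(1)))
    widths[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean_width = mean(widths), widths = widths)
}
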