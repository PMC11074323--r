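#' Signed asymmetric modularity matrix
#'
#' Builds the matrix `B` whose block sums give the signed asymmetric quality
#' function
#' \deqn{Q = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij} -
#'   \gamma\frac{s^+_i s^+_j}{v^+}\right)\delta_{c_i c_j}
#'   - \frac{1}{v^+ + v^-}\sum_{ij}\left(w^-_{ij} -
#'   \gamma\frac{s^-_i s^-_j}{v^-}\right)\delta_{c_i c_j}}
#' where \eqn{w^\pm} are the positive/negative parts of `W`, \eqn{s^\pm}
#' node strengths and \eqn{v^\pm} total weights. The positive term carries
#' full weight while the negative null term is tempered by
#' \eqn{1/(v^+ + v^-)}, the convention recommended for signed weighted
#' connectivity matrices. For a purely positive `W` this reduces to the
#' standard Newman-Girvan weighted modularity.
#'
#' @param W symmetric numeric matrix, zero diagonal.
#' @param gamma resolution parameter (default 1).
#' @return symmetric matrix `B` with `Q(partition) = sum of within-module
#'   entries of B` (diagonal included).
#' @keywords internal
signed_modularity_matrix <- function(W, gamma = 1) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  diag(Wp) <- 0
  diag(Wn) <- 0
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  vp <- sum(sp)
  vn <- sum(sn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) B <- (Wp - gamma * outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (Wn - gamma * outer(sn, sn) / vn) / (vp + vn)
  B
}

#' Modularity of a given partition on a signed weighted matrix
#'
#' @param W symmetric matrix, zero diagonal.
#' @param membership integer module assignment per node.
#' @param gamma resolution parameter.
#' @return the signed asymmetric Q value.
#' @export
modularity_signed <- function(W, membership, gamma = 1) {
  B <- signed_modularity_matrix(W, gamma)
  .partition_quality_B(B, as.integer(membership))
}

#' Signed weighted Louvain community detection
#'
#' Greedy two-phase Louvain optimisation of the signed asymmetric quality
#' function (see [modularity_signed()]); node sweep order is randomised via
#' R's RNG, so results are reproducible under `set.seed()`. With
#' `n_restarts > 1` the best-Q solution is returned (ties to the earliest
#' restart).
#'
#' @param W symmetric numeric matrix with zero diagonal; may contain
#'   negative weights.
#' @param gamma resolution parameter (default 1).
#' @param n_restarts number of random restarts (default 1).
#' @return A `partition`: list with `membership` (contiguous ids from 1),
#'   `Q`, `gamma`, `n_runs`.
#' @export
louvain_signed <- function(W, gamma = 1, n_restarts = 1) {
  stopifnot(nrow(W) == ncol(W))
  if (any(diag(W) != 0)) stop("louvain_signed: W must have zero diagonal")
  n <- nrow(W)
  if (all(W == 0)) {
    return(structure(list(membership = rep(1L, n), Q = 0, gamma = gamma,
                          n_runs = 0L), class = "partition"))
  }
  B <- signed_modularity_matrix(W, gamma)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .louvain_B(B)
    if (is.null(best) || fit$Q > best$Q + 1e-12) best <- fit
  }
  structure(
    list(membership = as.integer(best$membership), Q = best$Q,
         gamma = gamma, n_runs = as.integer(n_restarts)),
    class = "partition"
  )
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs [louvain_signed()] `n_runs` times, forms the node-by-node agreement
#' matrix (fraction of runs co-assigning each pair), zeroes entries below
#' `tau`, and re-clusters the thresholded agreement matrix repeatedly until
#' all runs agree. The final Q is computed on `W` with the consensus
#' assignment. If consensus does not converge within 100 iterations the
#' best-Q single run is returned with a warning.
#'
#' @param W symmetric matrix, zero diagonal.
#' @param n_runs number of Louvain runs (default 500).
#' @param tau agreement threshold in \[0, 1\] (default 0.5).
#' @param gamma resolution parameter.
#' @return a `partition` as in [louvain_signed()], with `n_runs` recorded.
#' @export
consensus_partition <- function(W, n_runs = 500, tau = 0.5, gamma = 1) {
  runs <- lapply(seq_len(n_runs), function(i) louvain_signed(W, gamma))
  memb <- vapply(runs, `[[`, integer(nrow(W)), "membership")
  memb <- matrix(memb, nrow = nrow(W))
  identical_runs <- function(m) {
    refco <- outer(m[, 1], m[, 1], "==")
    all(vapply(seq_len(ncol(m)), function(j) {
      identical(outer(m[, j], m[, j], "=="), refco)
    }, logical(1)))
  }
  agree <- function(m) {
    A <- matrix(0, nrow(m), nrow(m))
    for (j in seq_len(ncol(m))) A <- A + outer(m[, j], m[, j], "==")
    A <- A / ncol(m)
    diag(A) <- 0
    A
  }
  final <- NULL
  for (iter in seq_len(100)) {
    if (identical_runs(memb)) {
      final <- memb[, 1]
      break
    }
    A <- agree(memb)
    A[A < tau] <- 0
    if (all(A == 0)) { # no stable agreement: every node its own module
      final <- seq_len(nrow(memb))
      break
    }
    memb <- vapply(seq_len(n_runs),
                   function(i) louvain_signed(A, gamma)$membership,
                   integer(nrow(memb)))
    memb <- matrix(memb, nrow = nrow(W))
  }
  if (is.null(final)) {
    warning("consensus_partition: no convergence in 100 iterations; ",
            "returning best single run")
    qs <- vapply(runs, `[[`, numeric(1), "Q")
    return(runs[[which.max(qs)]])
  }
  final <- match(final, unique(final))
  structure(
    list(membership = as.integer(final),
         Q = modularity_signed(W, final, gamma),
         gamma = gamma, n_runs = as.integer(n_runs)),
    class = "partition"
  )
}

#' Node cartography: participation coefficient and module-degree z-score
#'
#' On the positive weights of `W`: the participation coefficient
#' \eqn{PC_i = 1 - \sum_s (k_{is}/k_i)^2} measures how evenly a node's
#' strength spreads across modules (0 = all within its own module), and the
#' module-degree z-score \eqn{MDZ_i = (k_i^{within} - \mu_{m(i)})/\sigma_{m(i)}}
#' standardises within-module strength inside each module. Modules with zero
#' strength s.d. yield MDZ 0; isolated nodes get PC 0 with a warning.
#'
#' @param W symmetric matrix, zero diagonal.
#' @param partition a `partition` or integer membership vector.
#' @return data frame with `node`, `module`, `pc`, `mdz`.
#' @export
node_cartography <- function(W, partition) {
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  stopifnot(length(memb) == nrow(W))
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  k <- rowSums(Wp)
  mods <- sort(unique(memb))
  kis <- vapply(mods, function(m) rowSums(Wp[, memb == m, drop = FALSE]),
                numeric(nrow(W)))
  kis <- matrix(kis, nrow = nrow(W))
  pc <- numeric(nrow(W))
  pos <- k > 0
  pc[pos] <- 1 - rowSums((kis[pos, , drop = FALSE] / k[pos])^2)
  if (any(!pos)) warning("node_cartography: isolated node(s); PC set to 0")
  kwithin <- kis[cbind(seq_along(memb), match(memb, mods))]
  mdz <- numeric(length(memb))
  for (m in mods) {
    idx <- memb == m
    mu <- mean(kwithin[idx])
    sdv <- stats::sd(kwithin[idx])
    mdz[idx] <- if (is.na(sdv) || sdv == 0) 0 else (kwithin[idx] - mu) / sdv
  }
  data.frame(node = seq_along(memb), module = memb, pc = pc, mdz = mdz)
}

#' Summarise cartography within a-priori networks
#'
#' Arithmetic mean of a per-node metric within each atlas network. Empty
#' networks are flagged `NA`.
#'
#' @param cartography data frame from [node_cartography()] (order = atlas
#'   node order).
#' @param atlas a `network_atlas` (see [network_atlas()]).
#' @return data frame with `network`, `mean_pc`, `mean_mdz`.
#' @export
network_summarize <- function(cartography, atlas) {
  stopifnot(inherits(atlas, "network_atlas"))
  nets <- atlas$networks
  out <- data.frame(network = nets,
                    mean_pc = NA_real_, mean_mdz = NA_real_)
  for (i in seq_along(nets)) {
    idx <- atlas$network_of_node == nets[i]
    if (!any(idx)) next
    out$mean_pc[i] <- mean(cartography$pc[idx])
    out$mean_mdz[i] <- mean(cartography$mdz[idx])
  }
  out
}
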