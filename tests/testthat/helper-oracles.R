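# Independent oracles used across tests. These re-derive quantities from
# first principles (direct formula evaluation, exhaustive enumeration) and
# never call the implementation paths they check.

# direct evaluation of the signed asymmetric quality function
oracle_signed_q <- function(W, memb, gamma = 1) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  diag(Wp) <- 0; diag(Wn) <- 0
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  same <- outer(memb, memb, "==")
  qp <- if (vp > 0) sum((Wp - gamma * outer(sp, sp) / vp)[same]) / vp else 0
  qn <- if (vn > 0) {
    sum((Wn - gamma * outer(sn, sn) / vn)[same]) / (vp + vn)
  } else 0
  qp - qn
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximum of the signed quality function over all partitions
oracle_max_q <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  max(vapply(parts, function(p) oracle_signed_q(W, p, gamma), numeric(1)))
}

# random symmetric signed graph with zero diagonal
random_signed_graph <- function(n, p_neg = 0.3) {
  W <- matrix(stats::runif(n * n), n, n)
  sgn <- matrix(ifelse(stats::runif(n * n) < p_neg, -1, 1), n, n)
  W <- W * sgn
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

# block correlation matrix helper for segregation closed forms
block_corr <- function(n_per_block, n_blocks, within, between) {
  net <- rep(seq_len(n_blocks), each = n_per_block)
  S <- ifelse(outer(net, net, "=="), within, between)
  diag(S) <- 1
  list(W = S,
       atlas = network_atlas(seq_len(n_per_block * n_blocks),
                             paste0("B", net)))
}

# direct weighted-Pearson evaluation (scalar loops, no matrix shortcuts)
oracle_weighted_r <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  num <- sum(w * (x - xb) * (y - yb))
  num / (sqrt(sum(w * (x - xb)^2)) * sqrt(sum(w * (y - yb)^2)))
}
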