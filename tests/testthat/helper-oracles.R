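# Independent oracles used across the suite. These deliberately avoid the
# package's own pruning/exponential code paths: transition probabilities come
# from Matrix::expm and likelihoods from exhaustive enumeration over all
# internal-node state combinations.

# transition matrix by scaling-and-squaring, independent of .expm_eig
oracle_P <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# exhaustive-enumeration log-likelihood of tip states on a rooted tree
# states: named character vector (names = tips); NA or "?" = missing
oracle_loglik <- function(tree, states, Q, pi, labels = rownames(Q)) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  k <- nrow(Q)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) oracle_P(Q, tree$edge.length[e]))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
  tip_idx <- match(states[tree$tip.label], labels)  # NA = missing
  miss <- which(is.na(tip_idx))
  tip_combos <- if (length(miss) == 0) matrix(0L, 1, 0) else
    as.matrix(expand.grid(rep(list(seq_len(k)), length(miss))))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    for (tr in seq_len(nrow(tip_combos))) {
      full <- c(tip_idx, combos[r, ])
      if (length(miss) > 0) full[miss] <- tip_combos[tr, ]
      p <- pi[full[n_tip + 1]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * P[[e]][full[tree$edge[e, 1]], full[tree$edge[e, 2]]]
      }
      total <- total + p
    }
  }
  log(total)
}

# brute-force marginal posterior of each state at one internal node
oracle_marginal <- function(tree, states, Q, pi, node, labels = rownames(Q)) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  joint <- vapply(seq_len(k), function(s) {
    # condition the node on state s by enumerating with that node fixed
    n_node <- tree$Nnode
    P <- lapply(seq_len(nrow(tree$edge)),
                function(e) oracle_P(Q, tree$edge.length[e]))
    combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
    combos <- combos[combos[, node - n_tip] == s, , drop = FALSE]
    tip_idx <- match(states[tree$tip.label], labels)
    miss <- which(is.na(tip_idx))
    tip_combos <- if (length(miss) == 0) matrix(0L, 1, 0) else
      as.matrix(expand.grid(rep(list(seq_len(k)), length(miss))))
    total <- 0
    for (r in seq_len(nrow(combos))) {
      for (tr in seq_len(nrow(tip_combos))) {
        full <- c(tip_idx, combos[r, ])
        if (length(miss) > 0) full[miss] <- tip_combos[tr, ]
        p <- pi[full[n_tip + 1]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- p * P[[e]][full[tree$edge[e, 1]], full[tree$edge[e, 2]]]
        }
        total <- total + p
      }
    }
    total
  }, numeric(1))
  joint / sum(joint)
}

# a fully parameterised random k-state model (every ordered pair its own class)
random_rate_model <- function(k, seed, rate_range = c(0.005, 0.2),
                              root = "uniform") {
  cl <- matrix(0L, k, k)
  cl[row(cl) != col(cl)] <- seq_len(k * (k - 1))
  vals <- odontotrace:::.with_seed(seed,
    exp(stats::runif(k * (k - 1), log(rate_range[1]), log(rate_range[2]))))
  rate_model(cl, values = vals, labels = as.character(seq_len(k) - 1), root = root)
}

# numerical-quadrature oracle for mean-of-bin gamma category rates
quadrature_gamma_rates <- function(alpha, K) {
  bounds <- stats::qgamma(seq(0, 1, length.out = K + 1), alpha, rate = alpha)
  vapply(seq_len(K), function(i) {
    num <- stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                            bounds[i], bounds[i + 1], rel.tol = 1e-10)$value
    num * K
  }, numeric(1))
}

# random tip states for a model's alphabet
random_states <- function(tree, labels, seed, missing_prob = 0) {
  odontotrace:::.with_seed(seed, {
    s <- sample(labels, length(tree$tip.label), replace = TRUE)
    if (missing_prob > 0) s[stats::runif(length(s)) < missing_prob] <- NA
    stats::setNames(s, tree$tip.label)
  })
}
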