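#' Felsenstein pruning likelihood for a discrete character
#'
#' Computes the log-probability of the tip states on a chronogram under a
#' [rate_model], by the post-order partial-likelihood recursion. The root is
#' weighted by the model's root rule. Tips listed with the missing marker, or
#' absent from the character matrix, contribute a vector of ones. Polytomies
#' are handled naturally (product over all children).
#'
#' @param tree A [chronogram] (any rooted `phylo` with branch lengths in Myr
#'   is accepted).
#' @param char A [char_matrix], or a named character vector of states. Every
#'   taxon in the matrix must be a tip of the tree.
#' @param model A [rate_model] whose labels cover the observed states.
#' @param multiplier Scalar rate multiplier applied to the generator.
#' @return The log-likelihood (a scalar).
#' @examples
#' tr <- as_chronogram("((A:5,B:5):5,C:10);")
#' m <- rate_model(matrix(c(0, 2, 1, 0), 2, 2), values = c(0.05, 0.02),
#'                 labels = c("0", "1"))
#' prune_loglik(tr, c(A = "1", B = "1", C = "0"), m)
#' @export
prune_loglik <- function(tree, char, model, multiplier = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "rate_model"))
  tipL <- .tip_partials(tree, char, model)
  idx <- .tree_index(tree)
  Q <- generator(model) * multiplier
  Plist <- .edge_transitions(Q, idx$elen)
  up <- .up_pass(idx, Plist, tipL)
  pi <- root_distribution(model)
  lik <- sum(pi * up$partial[, idx$root])
  if (lik <= 0) return(-Inf)
  log(lik) + up$logscale[idx$root]
}

# --- internal machinery shared by the likelihood, the ML fit and the ASR ---

# postorder edge list and bookkeeping, computed once per tree
.tree_index <- function(tree) {
  pt <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  list(n_tip = n_tip, n_node = tree$Nnode,
       root = n_tip + 1L,
       edge = pt$edge, elen = pt$edge.length,
       tip_label = tree$tip.label)
}

# k x (n_tip + n_node) partial-likelihood start matrix from observed states
.tip_partials <- function(tree, char, model) {
  states <- if (inherits(char, "char_matrix")) char_states(char) else char
  missing_marker <- if (inherits(char, "char_matrix")) char$missing else "?"
  absent <- setdiff(names(states), tree$tip.label)
  if (length(absent) > 0) {
    stop(sprintf("taxon '%s' in the character matrix is not a tip of the tree",
                 absent[1]), call. = FALSE)
  }
  k <- model$k
  n_tip <- length(tree$tip.label)
  L <- matrix(1, k, n_tip + tree$Nnode)
  rownames(L) <- model$labels
  for (i in seq_len(n_tip)) {
    s <- states[tree$tip.label[i]]
    if (is.na(s) || s == missing_marker) next
    if (!(s %in% model$labels)) {
      stop(sprintf("state '%s' of taxon '%s' is outside the model alphabet",
                   s, tree$tip.label[i]), call. = FALSE)
    }
    L[, i] <- as.numeric(model$labels == s)
  }
  L
}

# transition matrices for every edge, one eigendecomposition per generator
.edge_transitions <- function(Q, elen) {
  k <- nrow(Q)
  if (max(abs(Q)) == 0) {
    I <- diag(k)
    return(lapply(elen, function(t) I))
  }
  eig <- .eig_Q(Q)
  if (is.null(eig)) return(lapply(elen, function(t) .expm_Q(Q, t)))
  lapply(elen, function(t) .expm_eig(eig, t))
}

# upward (post-order) pass; returns partials and per-node log scale factors
.up_pass <- function(idx, Plist, tipL) {
  L <- tipL
  logscale <- numeric(ncol(L))
  edge <- idx$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    v <- Plist[[e]] %*% L[, child]
    L[, parent] <- L[, parent] * v
    logscale[parent] <- logscale[parent] + logscale[child]
    m <- max(L[, parent])
    if (m <= 0) {
      # impossible data under this model: signal through a -Inf likelihood
      logscale[parent] <- -Inf
      m <- 1
    }
    L[, parent] <- L[, parent] / m
    logscale[parent] <- logscale[parent] + log(m)
  }
  list(partial = L, logscale = logscale)
}

# downward (pre-order) pass: "outside" partials O[, v] so that the marginal
# posterior at node v is proportional to O[, v] * up$partial[, v]
.down_pass <- function(idx, Plist, up, pi) {
  edge <- idx$edge
  n <- ncol(up$partial)
  O <- matrix(NA_real_, nrow(up$partial), n)
  O[, idx$root] <- pi
  # edge contributions arriving at each parent: P_e %*% L_child
  contrib <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    contrib[[e]] <- as.vector(Plist[[e]] %*% up$partial[, edge[e, 2]])
  }
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  # pre-order = reverse of postorder edge order
  for (e in rev(seq_len(nrow(edge)))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    sib <- setdiff(kids[[as.character(parent)]], e)
    w <- O[, parent]
    for (s in sib) w <- w * contrib[[s]]
    O[, child] <- as.vector(crossprod(Plist[[e]], w))
    m <- max(O[, child])
    if (m > 0) O[, child] <- O[, child] / m
  }
  O
}

# marginal posterior state probabilities for every node (tips included)
.node_marginals <- function(tree, char, model, multiplier = 1) {
  tipL <- .tip_partials(tree, char, model)
  idx <- .tree_index(tree)
  Q <- generator(model) * multiplier
  Plist <- .edge_transitions(Q, idx$elen)
  up <- .up_pass(idx, Plist, tipL)
  pi <- root_distribution(model)
  O <- .down_pass(idx, Plist, up, pi)
  O[, idx$root] <- pi
  post <- O * up$partial
  post <- sweep(post, 2, colSums(post), "/")
  rownames(post) <- model$labels
  post
}
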