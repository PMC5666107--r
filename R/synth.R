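#' Simulate a pure-birth chronogram
#'
#' Yule tree conditioned on the number of tips, rescaled so the root age is
#' exactly `root_age`. Reproducible: the same seed always returns the same
#' tree, and the caller's RNG stream is left untouched.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in Ma (> 0); the study-scale default matches the
#'   fixture root.
#' @param seed Integer seed.
#' @return A [chronogram] with tips `t1..tn`.
#' @examples
#' simulate_chronogram(23, seed = 7)
#' @export
simulate_chronogram <- function(n_tips, root_age = 146.7, seed = 1) {
  stopifnot(n_tips >= 2, root_age > 0)
  phy <- .with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (root_age / depth)
  as_chronogram(phy)
}

#' Simulate a discrete character along a chronogram
#'
#' Exact endpoint sampling: the root state is drawn from the model's root
#' rule (or a supplied rule), then each edge draws the child state from the
#' transition matrix over the edge's duration. All internal-node states are
#' retained, so reconstruction accuracy can be scored against the truth.
#'
#' @param tree A [chronogram].
#' @param model A [rate_model].
#' @param root_rule Optional override of the model's root rule ("uniform",
#'   "stationary", or a probability vector).
#' @param seed Integer seed.
#' @return A `simulated_character` list: `tip_states` (named vector),
#'   `node_states` (all nodes, ape numbering), `root_state`, `model`, `seed`.
#' @export
simulate_discrete_character <- function(tree, model, root_rule = NULL, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "rate_model"))
  if (!is.null(root_rule)) model$root <- root_rule
  Q <- generator(model)
  idx <- .tree_index(tree)
  n_all <- idx$n_tip + idx$n_node
  edge <- idx$edge
  Plist <- .edge_transitions(Q, idx$elen)
  states <- .with_seed(seed, {
    s <- integer(n_all)
    s[idx$root] <- sample.int(model$k, 1, prob = root_distribution(model))
    for (e in rev(seq_len(nrow(edge)))) {   # pre-order
      s[edge[e, 2]] <- sample.int(model$k, 1, prob = Plist[[e]][s[edge[e, 1]], ])
    }
    s
  })
  lab <- model$labels[states]
  list(tip_states = stats::setNames(lab[seq_len(idx$n_tip)], tree$tip.label),
       node_states = lab,
       root_state = lab[idx$root],
       model = model, seed = seed)
}

#' Simulate alignment columns under GTR+Gamma with known rate categories
#'
#' Each site draws its category uniformly from 1..K (the equal-weight
#' discrete-gamma design), its root base from the stationary frequencies,
#' and then evolves down the tree with the GTR generator scaled by
#' `scale * category rate`. True labels are retained.
#'
#' @param tree A [chronogram].
#' @param params A [gtr_params].
#' @param n_sites Number of columns.
#' @param K Number of gamma categories.
#' @param seed Integer seed.
#' @param mask_rate Optional missing-data rate: each cell is independently
#'   replaced by `?` with this probability (default 0, off).
#' @return A `simulated_sites` list: `seq` (taxa x sites character matrix),
#'   `true_category` (integer vector), `params`, `K`, `seed`.
#' @export
simulate_sites <- function(tree, params, n_sites, K = 10, seed = 1, mask_rate = 0) {
  stopifnot(inherits(params, "gtr_params"), n_sites >= 1)
  sys <- .gtr_system(params)
  gm <- discretize_gamma(params$alpha, K)
  idx <- .tree_index(tree)
  n_all <- idx$n_tip + idx$n_node
  edge <- idx$edge
  bases <- c("A", "C", "G", "T")
  out <- .with_seed(seed, {
    cat_of <- sample.int(K, n_sites, replace = TRUE)
    states <- matrix(0L, n_all, n_sites)
    states[idx$root, ] <- sample.int(4, n_sites, replace = TRUE, prob = sys$pi)
    for (e in rev(seq_len(nrow(edge)))) {
      parent <- edge[e, 1]; child <- edge[e, 2]
      for (k in seq_len(K)) {
        sel <- which(cat_of == k)
        if (length(sel) == 0) next
        P <- .gtr_P(sys, idx$elen[e] * params$scale * gm$rate[k])
        ps <- states[parent, sel]
        cs <- integer(length(sel))
        for (b in 1:4) {
          ib <- which(ps == b)
          if (length(ib) > 0) {
            cs[ib] <- sample.int(4, length(ib), replace = TRUE, prob = P[b, ])
          }
        }
        states[child, sel] <- cs
      }
    }
    seqmat <- matrix(bases[states[seq_len(idx$n_tip), ]], idx$n_tip, n_sites,
                     dimnames = list(tree$tip.label, NULL))
    if (mask_rate > 0) {
      mask <- matrix(stats::runif(length(seqmat)) < mask_rate, nrow(seqmat))
      seqmat[mask] <- "?"
    }
    list(seq = seqmat, true_category = cat_of)
  })
  structure(c(out, list(params = params, K = K, seed = seed)),
            class = "simulated_sites")
}

#' Simulate a partitioned multi-gene alignment
#'
#' Builds the 10-gene study layout by default: coding genes (stop-free
#' in-frame nucleotides) followed by rRNA genes, all evolved under GTR+Gamma
#' on the supplied chronogram with per-site categories retained for the rRNA
#' partitions. Stop codons arising in coding genes are neutralized by
#' setting the third codon position to C, so the partitions always translate
#' cleanly.
#'
#' @param tree A [chronogram].
#' @param n_coding,n_rrna Gene counts.
#' @param coding_codons Codons per coding gene.
#' @param rrna_sites Sites per rRNA gene.
#' @param params A [gtr_params] shared by all genes (per-gene heterogeneity
#'   is out of scope for the generator).
#' @param K Gamma categories.
#' @param seed Integer seed.
#' @return A list with `alignment` (a [partitioned_alignment]),
#'   `true_category` (per-column; `NA` for coding columns), `params`, `seed`.
#' @export
simulate_gene_set <- function(tree, n_coding = 6, n_rrna = 4,
                              coding_codons = 30, rrna_sites = 120,
                              params = gtr_params(c(1, 2, 1, 1, 2, 1),
                                                  c(0.3, 0.2, 0.2, 0.3),
                                                  alpha = 0.4, scale = 0.002),
                              K = 10, seed = 1) {
  blocks <- list(); truth <- list(); parts <- list()
  pos <- 1L
  for (g in seq_len(n_coding + n_rrna)) {
    coding <- g <= n_coding
    n_sites <- if (coding) coding_codons * 3 else rrna_sites
    sim <- simulate_sites(tree, params, n_sites, K = K, seed = seed * 1000L + g)
    seqmat <- sim$seq
    if (coding) {
      # kill stop codons: third position -> C wherever TAA/TAG/TGA appears
      for (j in seq_len(coding_codons)) {
        codon <- apply(seqmat[, (3 * j - 2):(3 * j), drop = FALSE], 1, paste, collapse = "")
        hit <- codon %in% c("TAA", "TAG", "TGA")
        if (any(hit)) seqmat[hit, 3 * j] <- "C"
      }
    }
    blocks[[g]] <- seqmat
    truth[[g]] <- if (coding) rep(NA_integer_, n_sites) else sim$true_category
    parts[[g]] <- tibble::tibble(
      gene = sprintf("%s%d", if (coding) "cds" else "rrna", if (coding) g else g - n_coding),
      kind = if (coding) "coding" else "rRNA",
      start = pos, end = pos + n_sites - 1L, frame = 0L)
    pos <- pos + n_sites
  }
  aln <- partitioned_alignment(do.call(cbind, blocks), purrr::list_rbind(parts))
  list(alignment = aln, true_category = unlist(truth), params = params, seed = seed)
}
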