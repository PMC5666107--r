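#' GTR+Gamma parameters
#'
#' Container for the general time-reversible nucleotide model with discrete
#' gamma rate variation used to classify ribosomal RNA sites into rate
#' categories.
#'
#' @param exchangeabilities Six relative exchange rates in the order
#'   AC, AG, AT, CG, CT, GT; scaled internally so the GT rate is 1.
#' @param freqs Base frequencies (A, C, G, T), strictly positive, sum 1.
#' @param alpha Gamma shape (> 0) of among-site rate variation.
#' @param scale Global branch-scale multiplier in expected substitutions per
#'   site per Myr (the chronogram supplies time in Myr; the product
#'   `scale * branch length * category rate` is in substitutions per site).
#' @return A `gtr_params` object.
#' @examples
#' gtr_params(rep(1, 6), rep(0.25, 4), alpha = 0.5, scale = 0.002)
#' @export
gtr_params <- function(exchangeabilities, freqs, alpha, scale) {
  stopifnot(length(exchangeabilities) == 6, all(exchangeabilities > 0),
            length(freqs) == 4, all(freqs > 0),
            alpha > 0, scale >= 0)
  if (abs(sum(freqs) - 1) > 1e-12) stop("base frequencies must sum to 1", call. = FALSE)
  ex <- exchangeabilities / exchangeabilities[6]
  structure(list(exchangeabilities = stats::setNames(ex, c("AC","AG","AT","CG","CT","GT")),
                 freqs = stats::setNames(freqs, c("A","C","G","T")),
                 alpha = alpha, scale = scale),
            class = "gtr_params")
}

#' @export
print.gtr_params <- function(x, ...) {
  cat("GTR+Gamma parameters\n")
  cat("  exchangeabilities:", paste(sprintf("%s=%.4g", names(x$exchangeabilities),
                                            x$exchangeabilities), collapse = " "), "\n")
  cat("  base freqs:", paste(sprintf("%s=%.4g", names(x$freqs), x$freqs),
                             collapse = " "), "\n")
  cat(sprintf("  alpha = %.4g, branch scale = %.4g subs/site/Myr\n", x$alpha, x$scale))
  invisible(x)
}

# normalized GTR generator (mean rate 1 at stationarity) and its reversible
# eigendecomposition; P(t) = A %*% (exp(lambda t) * B)
.gtr_system <- function(params) {
  s <- params$exchangeabilities
  pi <- params$freqs
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  Q["A","C"] <- s["AC"]*pi["C"]; Q["A","G"] <- s["AG"]*pi["G"]; Q["A","T"] <- s["AT"]*pi["T"]
  Q["C","A"] <- s["AC"]*pi["A"]; Q["C","G"] <- s["CG"]*pi["G"]; Q["C","T"] <- s["CT"]*pi["T"]
  Q["G","A"] <- s["AG"]*pi["A"]; Q["G","C"] <- s["CG"]*pi["C"]; Q["G","T"] <- s["GT"]*pi["T"]
  Q["T","A"] <- s["AT"]*pi["A"]; Q["T","C"] <- s["CT"]*pi["C"]; Q["T","G"] <- s["GT"]*pi["G"]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  d <- sqrt(pi)
  Ssym <- (d %o% (1/d)) * Q        # D^{1/2} Q D^{-1/2}, symmetric
  eg <- eigen((Ssym + t(Ssym)) / 2, symmetric = TRUE)
  A <- (1/d) * eg$vectors          # D^{-1/2} U
  B <- t(eg$vectors) * rep(d, each = 4)  # U' D^{1/2}
  list(Q = Q, lambda = eg$values, A = A, B = B, pi = pi)
}

.gtr_P <- function(sys, t_subs) {
  P <- sys$A %*% (exp(sys$lambda * t_subs) * sys$B)
  P[P < 0] <- 0
  P / rowSums(P)
}

# IUPAC partial-observation vectors; gaps and '?' are fully missing
.iupac_partials <- local({
  tab <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A","G"), Y = c("C","T"), S = c("C","G"), W = c("A","T"),
              K = c("G","T"), M = c("A","C"), B = c("C","G","T"),
              D = c("A","G","T"), H = c("A","C","T"), V = c("A","C","G"),
              N = c("A","C","G","T"), `-` = c("A","C","G","T"),
              `?` = c("A","C","G","T"))
  bases <- c("A","C","G","T")
  m <- vapply(tab, function(b) as.numeric(bases %in% b), numeric(4))
  colnames(m) <- names(tab)
  m
})

# tip partial matrices (4 x S) for a character sequence matrix (taxa x sites)
.nt_tip_partials <- function(seqmat) {
  sym <- toupper(seqmat)
  unknown <- setdiff(unique(as.vector(sym)), colnames(.iupac_partials))
  if (length(unknown) > 0) {
    stop(sprintf("unknown nucleotide symbol '%s'", unknown[1]), call. = FALSE)
  }
  lapply(seq_len(nrow(seqmat)), function(i) .iupac_partials[, sym[i, ], drop = FALSE])
}

# per-site likelihood under one fixed substitution amount per edge set
# returns list(lik = S vector (scaled), logscale = S vector)
.nt_up_pass <- function(idx, Plist, tipL) {
  n_all <- idx$n_tip + idx$n_node
  S <- ncol(tipL[[1]])
  partial <- vector("list", n_all)
  for (i in seq_len(idx$n_tip)) partial[[i]] <- tipL[[i]]
  logscale <- matrix(0, 1, 0)
  sc <- vector("list", n_all)
  edge <- idx$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    v <- Plist[[e]] %*% partial[[ch]]
    if (is.null(partial[[p]])) {
      partial[[p]] <- v
      sc[[p]] <- if (is.null(sc[[ch]])) numeric(S) else sc[[ch]]
    } else {
      partial[[p]] <- partial[[p]] * v
      if (!is.null(sc[[ch]])) sc[[p]] <- sc[[p]] + sc[[ch]]
      m <- pmax(partial[[p]][1, ], partial[[p]][2, ], partial[[p]][3, ], partial[[p]][4, ])
      m[m <= 0] <- 1
      partial[[p]] <- partial[[p]] / rep(m, each = 4)
      sc[[p]] <- sc[[p]] + log(m)
    }
  }
  root <- idx$root
  list(partial = partial[[root]],
       logscale = if (is.null(sc[[root]])) numeric(S) else sc[[root]])
}

# S x K matrix of per-site log-likelihoods, one column per gamma category
.site_cat_logliks <- function(tree, seqmat, params, K) {
  idx <- .tree_index(tree)
  ord <- match(tree$tip.label, rownames(seqmat))
  if (anyNA(ord)) {
    stop(sprintf("tree tip '%s' is missing from the alignment",
                 tree$tip.label[which(is.na(ord))[1]]), call. = FALSE)
  }
  tipL <- .nt_tip_partials(seqmat[ord, , drop = FALSE])
  sys <- .gtr_system(params)
  gm <- discretize_gamma(params$alpha, K)
  S <- ncol(seqmat)
  out <- matrix(NA_real_, S, K)
  for (k in seq_len(K)) {
    Plist <- lapply(idx$elen, function(t) .gtr_P(sys, t * params$scale * gm$rate[k]))
    up <- .nt_up_pass(idx, Plist, tipL)
    out[, k] <- log(colSums(sys$pi * up$partial)) + up$logscale
  }
  out
}

#' Fit GTR+Gamma on a fixed chronogram topology
#'
#' Maximum-likelihood estimation of the five free exchangeabilities, the
#' gamma shape, and a single global branch-scale multiplier, with branch
#' lengths proportional to the chronogram (strict-clock-like). Base
#' frequencies are empirical. Alignment columns that are entirely gaps are
#' dropped with a warning. Site patterns are compressed before optimization.
#'
#' @param seqmat Character matrix of aligned sequences (taxa x sites,
#'   rownames = taxon labels), or a [partitioned_alignment] (all columns are
#'   used; subset first to fit per gene).
#' @param tree A [chronogram] sharing >= 4 taxa with the alignment.
#' @param K Number of gamma rate categories (>= 2).
#' @param init Optional `gtr_params` starting point.
#' @param control Passed to [stats::optim()] (Nelder--Mead).
#' @return A `gtr_fit` object with elements `params` ([gtr_params]),
#'   `loglik`, `n_sites`, `n_patterns`, `convergence`.
#' @export
fit_gtr_gamma <- function(seqmat, tree, K = 10, init = NULL,
                          control = list(maxit = 1500, reltol = 1e-9)) {
  if (inherits(seqmat, "partitioned_alignment")) seqmat <- seqmat$seq
  stopifnot(is.matrix(seqmat), K >= 2)
  common <- intersect(tree$tip.label, rownames(seqmat))
  if (length(common) < 4) stop("need >= 4 taxa shared between tree and alignment", call. = FALSE)
  if (length(common) < length(tree$tip.label)) {
    tree <- as_chronogram(ape::drop.tip(tree, setdiff(tree$tip.label, common)))
  }
  seqmat <- seqmat[common, , drop = FALSE]
  all_gap <- apply(seqmat, 2, function(col) all(toupper(col) %in% c("-", "?", "N")))
  if (any(all_gap)) {
    warning(sprintf("dropping %d all-gap/unknown column(s)", sum(all_gap)))
    seqmat <- seqmat[, !all_gap, drop = FALSE]
  }
  if (nrow(unique(as.data.frame(seqmat))) < 2) {
    stop("fewer than 2 distinct sequences; nothing to fit", call. = FALSE)
  }
  # empirical base frequencies with a pseudocount
  sym <- toupper(as.vector(seqmat))
  counts <- vapply(c("A","C","G","T"), function(b) sum(sym == b), numeric(1)) + 1
  freqs <- counts / sum(counts)
  # pattern compression
  pat <- apply(seqmat, 2, paste, collapse = "")
  uniq <- !duplicated(pat)
  w <- as.vector(table(factor(pat, levels = pat[uniq])))
  pmat <- seqmat[, uniq, drop = FALSE]

  if (is.null(init)) {
    # crude scale from mean pairwise mismatch over tree depth
    probe_cols <- unique(round(seq(1, ncol(pmat), length.out = min(200, ncol(pmat)))))
    d <- mean(apply(pmat[, probe_cols, drop = FALSE], 2,
                    function(col) {
                      b <- toupper(col); b <- b[b %in% c("A","C","G","T")]
                      if (length(b) < 2) 0 else 1 - max(table(b)) / length(b)
                    }))
    depth <- max(ape::node.depth.edgelength(tree))
    init <- gtr_params(rep(1, 6), freqs, alpha = 1,
                       scale = max(d, 0.01) / (2 * depth))
  }
  par0 <- c(log(init$exchangeabilities[1:5]), log(init$alpha), log(init$scale))
  nll <- function(p) {
    pr <- tryCatch(
      gtr_params(c(exp(p[1:5]), 1), freqs, alpha = exp(p[6]), scale = exp(p[7])),
      error = function(e) NULL)
    if (is.null(pr) || any(!is.finite(exp(p)))) return(1e10)
    lm <- .site_cat_logliks(tree, pmat, pr, K)
    mx <- apply(lm, 1, max)
    ll <- sum(w * (mx + log(rowMeans(exp(lm - mx)))))
    if (!is.finite(ll)) 1e10 else -ll
  }
  o <- stats::optim(par0, nll, method = "Nelder-Mead", control = control)
  if (o$convergence != 0) {
    o2 <- stats::optim(o$par, nll, method = "Nelder-Mead", control = control)
    if (o2$value < o$value) o <- o2
  }
  params <- gtr_params(c(exp(o$par[1:5]), 1), freqs,
                       alpha = exp(o$par[6]), scale = exp(o$par[7]))
  structure(list(params = params, loglik = -o$value,
                 n_sites = length(pat), n_patterns = sum(uniq),
                 convergence = o$convergence == 0),
            class = "gtr_fit")
}

#' @export
print.gtr_fit <- function(x, ...) {
  cat(sprintf("GTR+Gamma fit: logL = %.3f over %d sites (%d patterns)\n",
              x$loglik, x$n_sites, x$n_patterns))
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gtr_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$params$exchangeabilities), names(x$params$freqs), "alpha", "scale"),
    estimate = c(unname(x$params$exchangeabilities), unname(x$params$freqs),
                 x$params$alpha, x$params$scale))
}

#' @exportS3Method generics::glance
glance.gtr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_sites = x$n_sites,
                 n_patterns = x$n_patterns, converged = x$convergence)
}

#' Assign alignment sites to discrete gamma rate categories
#'
#' Empirical-Bayes classification: with equal category weights 1/K, the
#' posterior probability that site s belongs to category k is proportional
#' to its likelihood under that category's rate; the assigned category is the
#' posterior argmax, ties broken toward the slower category. Category K is
#' the fastest; constant gap-free columns always land in category 1.
#'
#' @param seqmat Character matrix (taxa x sites) or [partitioned_alignment]
#'   (then `genes` selects which partitions to classify, default all
#'   rRNA-nucleotide ones).
#' @param tree A [chronogram].
#' @param params A [gtr_params] (typically from [fit_gtr_gamma()]).
#' @param K Number of categories.
#' @param genes For partitioned input: gene names to classify.
#' @return A `site_rate_assignment` tibble with columns `site` (column index
#'   in the full alignment), `gene`, `category`, `max_posterior`, and one
#'   `p_cat<k>` column per category (each row sums to 1).
#' @export
assign_site_categories <- function(seqmat, tree, params, K = 10, genes = NULL) {
  stopifnot(inherits(params, "gtr_params"))
  gene_col <- NULL
  if (inherits(seqmat, "partitioned_alignment")) {
    aln <- seqmat
    if (is.null(genes)) genes <- aln$partitions$gene[aln$partitions$kind == "rRNA"]
    parts <- aln$partitions[aln$partitions$gene %in% genes, , drop = FALSE]
    cols <- unlist(purrr::map2(parts$start, parts$end, seq))
    gene_col <- unlist(purrr::pmap(parts, function(gene, start, end, ...)
      rep(gene, end - start + 1)))
    seqmat <- aln$seq[, cols, drop = FALSE]
  } else {
    cols <- seq_len(ncol(seqmat))
    gene_col <- rep(NA_character_, length(cols))
  }
  common <- intersect(tree$tip.label, rownames(seqmat))
  if (length(common) < length(tree$tip.label)) {
    tree <- as_chronogram(ape::drop.tip(tree, setdiff(tree$tip.label, common)))
  }
  lm <- .site_cat_logliks(tree, seqmat[common, , drop = FALSE], params, K)
  mx <- apply(lm, 1, max)
  post <- exp(lm - mx)
  post <- post / rowSums(post)
  # argmax with ties toward the lower category (max.col breaks ties at random)
  assigned <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])
  out <- tibble::tibble(site = cols, gene = gene_col,
                        category = as.integer(assigned),
                        max_posterior = post[cbind(seq_len(nrow(post)), assigned)])
  post_df <- tibble::as_tibble(post, .name_repair = ~ paste0("p_cat", seq_len(K)))
  out <- dplyr::bind_cols(out, post_df)
  class(out) <- c("site_rate_assignment", class(out))
  out
}

#' Log-likelihood of an alignment under fixed GTR+Gamma parameters
#'
#' The mixture likelihood summed over the K equal-weight gamma categories,
#' at fixed parameters on the fixed chronogram — the quantity maximized by
#' [fit_gtr_gamma()].
#'
#' @inheritParams fit_gtr_gamma
#' @param params A [gtr_params].
#' @return Scalar log-likelihood.
#' @export
gtr_loglik <- function(seqmat, tree, params, K = 10) {
  if (inherits(seqmat, "partitioned_alignment")) seqmat <- seqmat$seq
  common <- intersect(tree$tip.label, rownames(seqmat))
  if (length(common) < length(tree$tip.label)) {
    tree <- as_chronogram(ape::drop.tip(tree, setdiff(tree$tip.label, common)))
  }
  lm <- .site_cat_logliks(tree, seqmat[common, , drop = FALSE], params, K)
  mx <- apply(lm, 1, max)
  sum(mx + log(rowMeans(exp(lm - mx))))
}
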