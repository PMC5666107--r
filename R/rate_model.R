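#' Rate models with equality constraints
#'
#' A `rate_model` is a continuous-time Markov (Mk-type) model over k discrete
#' states in which every ordered state pair (i, j), i != j, is either a
#' structural zero or assigned to a rate class; all pairs in a class share one
#' rate value (per Myr). The diagonal of the generator is minus the row sum
#' of the off-diagonals. The root-state weighting rule is `"uniform"`
#' (default), `"stationary"`, or a custom probability vector.
#'
#' @param classes k x k integer matrix; off-diagonal entries are 0 (structural
#'   zero) or a class id; class ids must be contiguous starting at 1 and each
#'   class must be referenced by at least one pair. The diagonal is ignored.
#' @param values Numeric vector of per-class rates (per Myr, >= 0), one per
#'   class.
#' @param labels Ordered state labels; defaults to the dimnames of `classes`
#'   or `"1"..."k"`.
#' @param root Root weighting rule: `"uniform"`, `"stationary"`, or a
#'   probability vector of length k.
#' @return A `rate_model` object.
#' @examples
#' # 2-state model with independent gain and loss rates
#' cl <- matrix(c(0, 2, 1, 0), 2, 2, dimnames = list(c("0","1"), c("0","1")))
#' rate_model(cl, values = c(gain = 0.01, loss = 0.005))
#' @export
rate_model <- function(classes, values, labels = NULL, root = "uniform") {
  stopifnot(is.matrix(classes), nrow(classes) == ncol(classes))
  k <- nrow(classes)
  diag(classes) <- 0L
  ids <- sort(unique(classes[classes > 0]))
  n_class <- length(ids)
  if (n_class == 0) stop("model has no free rate classes", call. = FALSE)
  if (!identical(as.integer(ids), seq_len(n_class))) {
    stop("class ids must be contiguous starting at 1", call. = FALSE)
  }
  if (length(values) != n_class) {
    stop(sprintf("model has %d rate classes but %d values were given",
                 n_class, length(values)), call. = FALSE)
  }
  if (any(values < 0)) stop("rate values must be >= 0", call. = FALSE)
  if (is.null(labels)) labels <- rownames(classes)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  stopifnot(length(labels) == k)
  if (is.numeric(root)) {
    stopifnot(length(root) == k, all(root >= 0), abs(sum(root) - 1) < 1e-9)
  } else {
    root <- match.arg(root, c("uniform", "stationary"))
  }
  dimnames(classes) <- list(labels, labels)
  if (is.null(names(values))) names(values) <- paste0("class", seq_len(n_class))
  structure(list(k = k, labels = labels, classes = classes,
                 values = values, root = root),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Rate model: %d states (%s), %d rate class(es), root rule: %s\n",
              x$k, paste(x$labels, collapse = ","), length(x$values),
              if (is.numeric(x$root)) "custom" else x$root))
  print(x$classes)
  print(x$values)
  invisible(x)
}

#' Replace the rate values of a model
#' @param model A [rate_model].
#' @param values New per-class rates.
#' @return The updated model.
#' @export
set_rates <- function(model, values) {
  stopifnot(inherits(model, "rate_model"))
  nm <- names(model$values)
  model$values <- stats::setNames(as.numeric(values), nm)
  if (any(model$values < 0)) stop("rate values must be >= 0", call. = FALSE)
  model
}

#' Generator matrix of a rate model
#'
#' @param model A [rate_model].
#' @return k x k generator Q (rows sum to zero) in units of events per Myr.
#' @export
generator <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  Q <- matrix(0, model$k, model$k, dimnames = list(model$labels, model$labels))
  off <- model$classes > 0
  Q[off] <- model$values[model$classes[off]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a generator or model
#'
#' Solves pi Q = 0 with sum(pi) = 1. Falls back to the uniform distribution
#' when the chain is degenerate (all rates zero).
#'
#' @param x A [rate_model] or a generator matrix.
#' @return Probability vector of length k.
#' @export
stationary_dist <- function(x) {
  Q <- if (inherits(x, "rate_model")) generator(x) else x
  k <- nrow(Q)
  if (max(abs(Q)) == 0) return(rep(1 / k, k))
  # left null space: solve t(Q) v = 0 augmented with the normalisation row
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- as.vector(qr.solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Root-state weighting of a model
#' @param model A [rate_model].
#' @return Probability vector over the model's states.
#' @export
root_distribution <- function(model) {
  if (is.numeric(model$root)) return(model$root)
  switch(model$root,
         uniform = rep(1 / model$k, model$k),
         stationary = stationary_dist(model))
}

#' Transition probability matrix over an elapsed time
#'
#' Computes `expm(multiplier * Q * t)` by eigendecomposition of the
#' generator, falling back to `Matrix::expm()` when the generator is
#' defective or the reconstruction is inaccurate. Rows sum to one within
#' 1e-12.
#'
#' @param model A [rate_model] or a generator matrix.
#' @param t Elapsed time in Myr (>= 0).
#' @param multiplier Scalar rate multiplier (>= 0).
#' @return k x k stochastic matrix.
#' @examples
#' cl <- matrix(c(0, 1, 1, 0), 2, 2)
#' m <- rate_model(cl, values = 0.1)
#' transition_matrix(m, 5)
#' @export
transition_matrix <- function(model, t, multiplier = 1) {
  stopifnot(t >= 0, multiplier >= 0)
  Q <- if (inherits(model, "rate_model")) generator(model) else model
  P <- .expm_Q(Q * multiplier, t)
  dimnames(P) <- dimnames(Q)
  P
}

# eigendecomposition cache for repeated exponentials of one generator
.eig_Q <- function(Q) {
  ev <- eigen(Q)
  Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  # reject near-defective systems where inversion is unstable
  if (max(Mod(Vi)) * max(Mod(ev$vectors)) > 1e8) return(NULL)
  list(values = ev$values, V = ev$vectors, Vi = Vi)
}

.expm_eig <- function(eig, t) {
  P <- Re(eig$V %*% (exp(eig$values * t) * eig$Vi))
  P[P < 0] <- 0
  P / rowSums(P)
}

.expm_Q <- function(Q, t) {
  if (t == 0 || max(abs(Q)) == 0) return(diag(nrow(Q)))
  eig <- .eig_Q(Q)
  if (!is.null(eig)) {
    P <- .expm_eig(eig, t)
    if (max(abs(rowSums(P) - 1)) < 1e-9 && min(P) >= 0) return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discretize a gamma distribution into equal-probability rate categories
#'
#' Mean-of-bin discretization of the unit-mean gamma distribution of relative
#' site rates: the (0,1) interval is cut into K equal-probability bins at
#' gamma quantiles and each category rate is the conditional mean of its bin,
#' so category rates are strictly increasing and their average is exactly 1.
#' Category K is the fastest.
#'
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories (>= 1).
#' @return A tibble with columns `category`, `rate`, `weight` (all `1/K`),
#'   carrying `alpha` and `K` as attributes; class `gamma_mixture`.
#' @examples
#' discretize_gamma(0.4, 10)
#' @export
discretize_gamma <- function(alpha, K) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(K) || K < 1 || K != round(K)) stop("K must be an integer >= 1", call. = FALSE)
  K <- as.integer(K)
  bounds <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  # conditional bin means: integral of x f(x) over a bin is a gamma(alpha+1) cdf difference
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(K + 1)], shape = alpha + 1, rate = alpha)
  rates <- K * (upper - lower)
  rates <- rates / (sum(rates) / K)   # exact unit mean
  out <- tibble::tibble(category = seq_len(K), rate = rates, weight = 1 / K)
  attr(out, "alpha") <- alpha
  attr(out, "K") <- K
  class(out) <- c("gamma_mixture", class(out))
  out
}

#' Serialize a rate model to plain text (JSON) and back
#'
#' @param model A [rate_model].
#' @param path Output path.
#' @return `write_rate_model()`: `path` invisibly; `read_rate_model()`: a
#'   [rate_model].
#' @export
write_rate_model <- function(model, path) {
  stopifnot(inherits(model, "rate_model"))
  jsonlite::write_json(list(
    labels = model$labels,
    classes = apply(model$classes, 1, as.integer, simplify = FALSE),
    values = as.list(model$values),
    root = model$root), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_model
#' @export
read_rate_model <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- do.call(rbind, lapply(seq_along(spec$labels), function(i) {
    as.integer(if (is.list(spec$classes)) spec$classes[[i]] else spec$classes[i, ])
  }))
  root <- if (is.numeric(spec$root)) as.numeric(spec$root) else spec$root
  rate_model(classes, values = unlist(spec$values), labels = spec$labels, root = root)
}
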