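#' Preset constrained transition models
#'
#' The three transition models used for the armour characters:
#'
#' * `odontode_model1` (4 states): one rate for gaining odontodes regardless
#'   of where they appear (p01 = p02 = p03), one for losing them entirely
#'   (p10 = p20 = p30), and one for shifts between partial and fuller cover
#'   (p23 = p31 = p32 = p13). The head-only/trunk-only exchanges p12 and p21
#'   are not pinned down by the three stated equalities; by default they join
#'   the shift class, and `own_class_12 = TRUE` gives them a class of their
#'   own (4 classes).
#' * `odontode_model2` (4 states): one rate for gaining trunk odontodes
#'   whatever the initial state (p02 = p03 = p12 = p13) and one for losing
#'   them whatever the final state (p20 = p30 = p21 = p31). The remaining
#'   head-only moves default to head-gain {p01, p23} and head-loss
#'   {p10, p32} classes (4 classes); `six_classes = TRUE` frees all four
#'   (6 classes).
#' * `plates_independent` (2 states): independent gain and loss rates for
#'   trunk dermal bony plates.
#'
#' @param name One of `"odontode_model1"`, `"odontode_model2"`,
#'   `"plates_independent"`.
#' @param own_class_12 Model 1 only: give p12/p21 their own class.
#' @param six_classes Model 2 only: free p01, p10, p23, p32 individually.
#' @param root Root weighting rule, see [rate_model()].
#' @param init Initial per-class rate (per Myr) stored in the returned model.
#' @return A [rate_model].
#' @examples
#' preset_model("plates_independent")
#' preset_model("odontode_model2", six_classes = TRUE)
#' @export
preset_model <- function(name, own_class_12 = FALSE, six_classes = FALSE,
                         root = "uniform", init = 0.01) {
  presets <- c("odontode_model1", "odontode_model2", "plates_independent")
  if (!name %in% presets) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(presets, collapse = ", ")), call. = FALSE)
  }
  if (name == "plates_independent") {
    cl <- matrix(0L, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    cl["0", "1"] <- 1L; cl["1", "0"] <- 2L
    m <- rate_model(cl, values = stats::setNames(rep(init, 2), c("gain", "loss")),
                    root = root)
  } else if (name == "odontode_model1") {
    cl <- matrix(0L, 4, 4, dimnames = list(0:3, 0:3))
    cl["0", "1"] <- cl["0", "2"] <- cl["0", "3"] <- 1L
    cl["1", "0"] <- cl["2", "0"] <- cl["3", "0"] <- 2L
    cl["2", "3"] <- cl["3", "1"] <- cl["3", "2"] <- cl["1", "3"] <- 3L
    cls <- c("gain", "loss", "shift")
    if (own_class_12) {
      cl["1", "2"] <- cl["2", "1"] <- 4L
      cls <- c(cls, "headtrunk_exchange")
    } else {
      cl["1", "2"] <- cl["2", "1"] <- 3L
    }
    m <- rate_model(cl, values = stats::setNames(rep(init, length(cls)), cls),
                    root = root)
  } else {
    cl <- matrix(0L, 4, 4, dimnames = list(0:3, 0:3))
    cl["0", "2"] <- cl["0", "3"] <- cl["1", "2"] <- cl["1", "3"] <- 1L
    cl["2", "0"] <- cl["3", "0"] <- cl["2", "1"] <- cl["3", "1"] <- 2L
    if (six_classes) {
      cl["0", "1"] <- 3L; cl["1", "0"] <- 4L; cl["2", "3"] <- 5L; cl["3", "2"] <- 6L
      cls <- c("trunk_gain", "trunk_loss", "head_gain_naked", "head_loss_naked",
               "head_gain_armoured", "head_loss_armoured")
    } else {
      cl["0", "1"] <- cl["2", "3"] <- 3L
      cl["1", "0"] <- cl["3", "2"] <- 4L
      cls <- c("trunk_gain", "trunk_loss", "head_gain", "head_loss")
    }
    m <- rate_model(cl, values = stats::setNames(rep(init, length(cls)), cls),
                    root = root)
  }
  attr(m, "preset") <- name
  m
}

# run code under a fixed RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a constrained Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's rate-class values by
#' multi-restart box-constrained quasi-Newton search on the log-rate scale,
#' followed by a Nelder--Mead polish from the best restart. Restart starting
#' points are log-uniform over the bounds and are drawn from a seeded stream,
#' so a given seed always reproduces the same fit.
#'
#' @param tree A [chronogram].
#' @param char A [char_matrix] (or named state vector); its taxa must all be
#'   tips of `tree`.
#' @param model A [rate_model] defining the constraint classes and root rule.
#' @param restarts Number of random restarts (the published analyses used
#'   10,000; 100 is the desk-scale default).
#' @param seed Integer seed for the restart stream.
#' @param bounds Lower/upper bounds on every rate, per Myr.
#' @return An object of class `mk_fit`: a list with the fitted `model`,
#'   `loglik`, `estimates` (tibble of per-class rates), `restarts` (tibble of
#'   per-restart best values), `seed`, and `convergence`.
#' @examples
#' fx <- loricarioid_fixture()
#' fit <- fit_mk(fx$tree, fx$plates, preset_model("plates_independent"),
#'               restarts = 10, seed = 1)
#' glance(fit)
#' @export
fit_mk <- function(tree, char, model, restarts = 100, seed = 1,
                   bounds = c(1e-8, 10)) {
  stopifnot(inherits(model, "rate_model"), restarts >= 1,
            length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  tipL <- .tip_partials(tree, char, model)
  idx <- .tree_index(tree)
  off <- model$classes > 0
  class_vec <- model$classes[off]
  k <- model$k
  n_par <- length(model$values)
  Q0 <- matrix(0, k, k)
  uniform_root <- !is.numeric(model$root) && model$root == "uniform"
  pi_fixed <- if (is.numeric(model$root)) model$root else rep(1 / k, k)

  nll <- function(logv) {
    v <- exp(logv)
    Q <- Q0
    Q[off] <- v[class_vec]
    diag(Q) <- -rowSums(Q)
    Plist <- .edge_transitions(Q, idx$elen)
    up <- .up_pass(idx, Plist, tipL)
    pi <- if (uniform_root || is.numeric(model$root)) pi_fixed else stationary_dist(Q)
    lik <- sum(pi * up$partial[, idx$root])
    if (!is.finite(lik) || lik <= 0) return(1e10)
    ll <- log(lik) + up$logscale[idx$root]
    if (!is.finite(ll)) return(1e10) else -ll
  }

  lb <- log(bounds[1]); ub <- log(bounds[2])
  starts <- .with_seed(seed, {
    s <- matrix(stats::runif(restarts * n_par, lb, ub), restarts, n_par)
    s[1, ] <- pmin(pmax(log(unname(model$values)), lb), ub)
    s
  })
  runs <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    o <- tryCatch(
      stats::optim(starts[r, ], nll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(o)) o <- list(par = starts[r, ], value = nll(starts[r, ]), convergence = 1L)
    runs[[r]] <- tibble::tibble(restart = r, loglik = -o$value,
                                start_loglik = -nll(starts[r, ]))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(-best$value) || best$value >= 1e10) {
    stop("optimization failed: non-finite likelihood at every restart", call. = FALSE)
  }
  polish <- if (n_par >= 2) {
    stats::optim(best$par, nll, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
  } else {
    stats::optim(best$par, nll, method = "Brent", lower = lb, upper = ub)
  }
  if (polish$value <= best$value) best <- polish
  par <- pmin(pmax(best$par, lb), ub)
  fitted <- set_rates(model, exp(par))
  attr(fitted, "preset") <- attr(model, "preset")
  structure(list(
    model = fitted,
    loglik = -best$value,
    estimates = tibble::tibble(class = names(model$values), rate = exp(par)),
    restarts = dplyr::bind_rows(runs),
    seed = seed,
    bounds = bounds,
    convergence = best$convergence == 0,
    n_tip = idx$n_tip,
    char_name = if (inherits(char, "char_matrix")) char$name else "character"),
    class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit of '%s' on %d tips: logL = %.4f (%d restarts, seed %d)\n",
              x$char_name, x$n_tip, x$loglik, nrow(x$restarts), x$seed))
  print(x$estimates)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mk_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.mk_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_par = nrow(x$estimates),
                 AIC = 2 * nrow(x$estimates) - 2 * x$loglik,
                 restarts = nrow(x$restarts), converged = x$convergence,
                 seed = x$seed)
}

#' Marginal ancestral-state reconstruction
#'
#' Computes, for every node, the posterior probability of each state given
#' all tip data and fixed rates (usually the MLE), by combining the upward
#' partial likelihoods with a downward "outside" pass and normalizing per
#' node.
#'
#' @param tree A [chronogram].
#' @param char A [char_matrix] or named state vector.
#' @param fit An [fit_mk()] result, or a [rate_model] with fixed rates.
#' @param multiplier Scalar rate multiplier (rarely needed).
#' @return An `asr` object: a tibble with columns `node`, `label`, `is_tip`,
#'   `age_ma`, `state`, `probability` (long format; probabilities sum to one
#'   within each node). The tree, model and character are kept as attributes.
#' @examples
#' fx <- loricarioid_fixture()
#' fit <- fit_mk(fx$tree, fx$plates, preset_model("plates_independent"),
#'               restarts = 5, seed = 1)
#' rec <- marginal_asr(fx$tree, fx$plates, fit)
#' head(as.data.frame(rec))
#' @export
marginal_asr <- function(tree, char, fit, multiplier = 1) {
  model <- if (inherits(fit, "mk_fit")) fit$model else fit
  stopifnot(inherits(model, "rate_model"))
  post <- .node_marginals(tree, char, model, multiplier)
  n_tip <- length(tree$tip.label)
  n_all <- ncol(post)
  age <- if (inherits(tree, "chronogram")) attr(tree, "node_age") else
    rep(NA_real_, n_all)
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(node = seq_len(n_all),
                     label = c(tree$tip.label, rep(NA_character_, n_all - n_tip)),
                     is_tip = seq_len(n_all) <= n_tip,
                     age_ma = age),
      tibble::as_tibble(t(post), .name_repair = ~ paste0("p_", model$labels))),
    cols = dplyr::starts_with("p_"), names_to = "state", names_prefix = "p_",
    values_to = "probability")
  attr(out, "tree") <- tree
  attr(out, "model") <- model
  attr(out, "char_name") <- if (inherits(char, "char_matrix")) char$name else "character"
  class(out) <- c("asr", class(out))
  out
}

#' Summarize reconstructions at named clades
#'
#' Builds the per-node report: one row per named clade per reconstruction,
#' with the state probabilities (wide), the node age, and for four-state
#' odontode characters the derived trunk-odontode total P(2) + P(3).
#'
#' @param recons A named list of [marginal_asr()] results sharing a tree (the
#'   names identify the models).
#' @param clades Named list of tip-label sets defining the nodes of interest;
#'   defaults to [named_clades()] filtered to the tips present.
#' @param digits Rounding applied to the echoed probabilities (full-precision
#'   values are in the returned tibble; rounding only affects `format`ted
#'   output columns not kept here).
#' @return A tibble with columns `model`, `clade`, `node`, `age_ma`, one
#'   `p_<state>` column per state, and `p_trunk_total` for 4-state models.
#' @export
asr_report <- function(recons, clades = NULL, digits = NA) {
  stopifnot(is.list(recons), length(recons) >= 1)
  if (is.null(names(recons))) names(recons) <- paste0("model", seq_along(recons))
  tree <- attr(recons[[1]], "tree")
  if (is.null(clades)) {
    clades <- Filter(function(tips) all(tips %in% tree$tip.label), named_clades())
  }
  rows <- purrr::imap(recons, function(rec, model_name) {
    wide <- tidyr::pivot_wider(rec, names_from = "state", values_from = "probability",
                               names_prefix = "p_")
    purrr::imap(clades, function(tips, clade_name) {
      node <- if (length(tips) == 1) match(tips, tree$tip.label) else
        ape::getMRCA(tree, tips)
      row <- wide[wide$node == node, , drop = FALSE]
      row$model <- model_name
      row$clade <- clade_name
      row
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  pcols <- grep("^p_", names(rows), value = TRUE)
  out <- rows[, c("model", "clade", "node", "age_ma", pcols)]
  if (all(c("p_2", "p_3") %in% pcols)) {
    out$p_trunk_total <- dplyr::coalesce(out$p_2, 0) + dplyr::coalesce(out$p_3, 0)
    out$p_trunk_total[is.na(out$p_2) & is.na(out$p_3)] <- NA_real_
  }
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::starts_with("p_"),
                                            ~ round(.x, digits)))
  }
  out
}

#' Write/read a reconstruction as TSV
#'
#' Fixed-format serialization so that regenerating a report from a round-
#' tripped reconstruction is byte-identical.
#'
#' @param x An `asr` tibble.
#' @param path Output path.
#' @return `write_asr()`: `path` invisibly; `read_asr()` a plain tibble (tree
#'   attributes are not round-tripped).
#' @export
write_asr <- function(x, path) {
  df <- as.data.frame(x)
  df$probability <- sprintf("%.12g", df$probability)
  df$age_ma <- sprintf("%.6f", df$age_ma)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_asr
#' @export
read_asr <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             colClasses = c(state = "character")))
  out$label <- as.character(out$label)
  out
}
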