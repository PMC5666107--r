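test_that("preset models encode the published rate equalities", {
  m1 <- preset_model("odontode_model1")
  cl <- m1$classes
  expect_equal(length(unique(c(cl["0", "1"], cl["0", "2"], cl["0", "3"]))), 1)
  expect_equal(length(unique(c(cl["1", "0"], cl["2", "0"], cl["3", "0"]))), 1)
  expect_equal(length(unique(c(cl["2", "3"], cl["3", "1"], cl["3", "2"],
                               cl["1", "3"], cl["1", "2"], cl["2", "1"]))), 1)
  expect_equal(length(m1$values), 3)
  expect_equal(length(preset_model("odontode_model1", own_class_12 = TRUE)$values), 4)

  m2 <- preset_model("odontode_model2")
  cl2 <- m2$classes
  expect_equal(length(unique(c(cl2["0", "2"], cl2["0", "3"],
                               cl2["1", "2"], cl2["1", "3"]))), 1)
  expect_equal(length(unique(c(cl2["2", "0"], cl2["3", "0"],
                               cl2["2", "1"], cl2["3", "1"]))), 1)
  expect_equal(length(m2$values), 4)
  expect_equal(length(preset_model("odontode_model2", six_classes = TRUE)$values), 6)

  mp <- preset_model("plates_independent")
  expect_equal(mp$k, 2)
  expect_equal(length(mp$values), 2)

  expect_error(preset_model("no_such_model"), "plates_independent")
})

test_that("fit_mk is deterministic given a seed and honours restart bookkeeping", {
  fx <- loricarioid_fixture()
  f1 <- fit_mk(fx$tree, fx$plates, preset_model("plates_independent"),
               restarts = 6, seed = 42)
  f2 <- fit_mk(fx$tree, fx$plates, preset_model("plates_independent"),
               restarts = 6, seed = 42)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$restarts, f2$restarts)
  # the kept optimum dominates every restart's starting point
  expect_true(all(f1$loglik >= f1$restarts$start_loglik - 1e-9))
  expect_true(all(f1$estimates$rate >= f1$bounds[1] &
                    f1$estimates$rate <= f1$bounds[2]))
  expect_equal(glance(f1)$logLik, f1$loglik)
})

test_that("the fitted optimum beats random probe parameter vectors", {
  fx <- loricarioid_fixture()
  model <- preset_model("plates_independent")
  fit <- fit_mk(fx$tree, fx$plates, model, restarts = 8, seed = 1)
  probes <- odontotrace:::.with_seed(7,
    matrix(exp(stats::runif(50 * 2, log(1e-6), log(1))), 50, 2))
  for (i in seq_len(nrow(probes))) {
    ll <- prune_loglik(fx$tree, fx$plates, set_rates(model, probes[i, ]))
    expect_lte(ll, fit$loglik + 1e-6)
  }
})

test_that("marginal reconstruction matches the brute-force posterior", {
  for (seed in 1:8) {
    n <- 3 + (seed %% 3)   # 3..5 tips
    tr <- simulate_chronogram(n, root_age = 80, seed = seed)
    k <- if (seed %% 2 == 0) 2 else 4
    root <- if (seed %% 3 == 0) "stationary" else "uniform"
    m <- random_rate_model(k, seed + 50, root = root)
    states <- random_states(tr, m$labels, seed + 99)
    rec <- marginal_asr(tr, states, m)
    wide <- tidyr::pivot_wider(rec, names_from = "state", values_from = "probability", names_prefix = "p_")
    for (node in (n + 1):(n + tr$Nnode)) {
      mine <- as.numeric(wide[wide$node == node, paste0("p_", m$labels)])
      oracle <- oracle_marginal(tr, states, generator(m), root_distribution(m),
                                node, labels = m$labels)
      expect_equal(mine, unname(oracle), tolerance = 1e-8)
    }
  }
})

test_that("presets agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  fx <- loricarioid_fixture()
  fit <- fit_mk(fx$tree, fx$plates, preset_model("plates_independent"),
                restarts = 10, seed = 1)
  x <- char_states(fx$plates)
  ref <- phytools::fitMk(fx$tree, x[fx$tree$tip.label], model = "ARD", pi = "equal")
  # same surface: our multi-restart optimum must not fall below phytools'
  expect_gte(fit$loglik, as.numeric(stats::logLik(ref)) - 1e-4)
  # and our likelihood evaluated at phytools' rates matches phytools' logLik
  i0 <- match("0", ref$states); i1 <- match("1", ref$states)
  q01 <- ref$rates[ref$index.matrix[i0, i1]]
  q10 <- ref$rates[ref$index.matrix[i1, i0]]
  ll <- prune_loglik(fx$tree, fx$plates,
                     set_rates(preset_model("plates_independent"), c(q01, q10)))
  expect_equal(ll, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("node posteriors sum to one and relabeling leaves the likelihood unchanged", {
  fx <- loricarioid_fixture()
  fit <- fit_mk(fx$tree, fx$odontodes, preset_model("odontode_model2"),
                restarts = 5, seed = 2)
  rec <- marginal_asr(fx$tree, fx$odontodes, fit)
  sums <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(rec), node),
                           s = sum(probability))
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # consistent relabeling of states in model and data
  perm <- c("0" = "3", "1" = "2", "2" = "1", "3" = "0")
  m <- fit$model
  relab <- m
  relab$labels <- rev(m$labels)  # label i now names old state perm
  relab$classes <- m$classes[4:1, 4:1]
  dimnames(relab$classes) <- list(m$labels, m$labels)
  states <- char_states(fx$odontodes)
  states_perm <- stats::setNames(unname(perm[states]), names(states))
  ll1 <- prune_loglik(fx$tree, fx$odontodes, m)
  relab$labels <- m$labels
  ll2 <- prune_loglik(fx$tree, states_perm, relab)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("reports expose trunk totals and serialize byte-identically", {
  fx <- loricarioid_fixture()
  fit <- fit_mk(fx$tree, fx$odontodes, preset_model("odontode_model1"),
                restarts = 4, seed = 3)
  rec <- marginal_asr(fx$tree, fx$odontodes, fit)
  rep <- asr_report(list(odontode_model1 = rec))
  expect_equal(rep$p_trunk_total, rep$p_2 + rep$p_3)
  lori <- rep[rep$clade == "Loricarioidei", ]
  expect_equal(nrow(lori), 1)
  # echoing to 2 decimals equals rounding the full-precision values
  rounded <- asr_report(list(odontode_model1 = rec), digits = 2)
  expect_equal(rounded$p_3, round(rep$p_3, 2))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_asr(rec, path)
  again <- withr::local_tempfile(fileext = ".tsv")
  write_asr(rec, again)
  expect_identical(readLines(path), readLines(again))
})

test_that("root-state recovery is calibrated against the reported posterior", {
  # simulate odontode histories at known rates on the fixture tree and check
  # that argmax-at-root accuracy tracks the average root posterior
  fx <- loricarioid_fixture()
  model <- set_rates(preset_model("odontode_model2"),
                     c(0.008, 0.004, 0.006, 0.003))
  n_rep <- 300
  hits <- 0; conf <- 0
  root_node <- length(fx$tree$tip.label) + 1
  for (i in seq_len(n_rep)) {
    sim <- simulate_discrete_character(fx$tree, model, seed = 5000 + i)
    rec <- marginal_asr(fx$tree, sim$tip_states, model)
    wide <- tidyr::pivot_wider(rec, names_from = "state", values_from = "probability", names_prefix = "p_")
    p <- as.numeric(wide[wide$node == root_node, paste0("p_", model$labels)])
    hits <- hits + (model$labels[which.max(p)] == sim$root_state)
    conf <- conf + max(p)
  }
  expect_gt(hits / n_rep, conf / n_rep - 0.05)
})
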