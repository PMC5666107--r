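test_that("chronogram simulation is reproducible and hits the requested root age", {
  two <- simulate_chronogram(2, root_age = 33, seed = 5)
  expect_equal(length(two$tip.label), 2)
  expect_equal(unname(two$edge.length), c(33, 33))

  big <- simulate_chronogram(23, root_age = 146.7, seed = 9)
  expect_equal(length(big$tip.label), 23)
  expect_equal(max(attr(big, "node_age")), 146.7, tolerance = 1e-12)

  expect_identical(write_chronogram(simulate_chronogram(10, seed = 3)),
                   write_chronogram(simulate_chronogram(10, seed = 3)))
  expect_false(identical(write_chronogram(simulate_chronogram(10, seed = 3)),
                         write_chronogram(simulate_chronogram(10, seed = 4))))
  # caller RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_chronogram(5, seed = 99)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("character simulation matches the closed-form change probability", {
  m <- rate_model(matrix(c(0L, 1L, 1L, 0L), 2, 2), values = 0.05,
                  labels = c("0", "1"))
  tr <- as_chronogram("(A:10,B:10);")
  # zero rates: every node inherits the root state
  m0 <- set_rates(m, 0)
  s0 <- simulate_discrete_character(tr, m0, seed = 1)
  expect_true(all(s0$node_states == s0$root_state))
  # same seed, same draw
  expect_identical(simulate_discrete_character(tr, m, seed = 7)$node_states,
                   simulate_discrete_character(tr, m, seed = 7)$node_states)

  # P(change along one edge of length t) = (1 - exp(-2 r t)) / 2
  n_rep <- 10000
  changes <- 0
  for (i in seq_len(n_rep)) {
    sim <- simulate_discrete_character(tr, m, seed = i)
    changes <- changes + (sim$tip_states[["A"]] != sim$root_state)
  }
  expect_equal(changes / n_rep, (1 - exp(-2 * 0.05 * 10)) / 2, tolerance = 0.01)
})

test_that("site simulation respects the stationary and mixture design", {
  params <- gtr_params(c(1, 2, 1, 1, 2, 1), c(0.35, 0.15, 0.2, 0.3),
                       alpha = 0.5, scale = 0.002)
  tr <- simulate_chronogram(5, root_age = 146.7, seed = 61)
  # zero branch-scale: all columns constant
  sim0 <- simulate_sites(tr, gtr_params(rep(1, 6), rep(0.25, 4), 1, 0),
                         n_sites = 50, seed = 2)
  expect_true(all(apply(sim0$seq, 2, function(x) length(unique(x))) == 1))

  sim <- simulate_sites(tr, params, n_sites = 50000, seed = 3)
  # empirical base frequencies near the stationary frequencies
  freq <- table(factor(sim$seq, levels = c("A", "C", "G", "T"))) / length(sim$seq)
  expect_true(all(abs(as.numeric(freq) - params$freqs) < 0.01))
  # uniform true-category histogram within binomial noise
  h <- table(factor(sim$true_category, levels = 1:10))
  expect_true(all(abs(h / 50000 - 0.1) < 4 * sqrt(0.1 * 0.9 / 50000)))
})

test_that("generating parameters are near-optimal for their own simulations", {
  tr <- simulate_chronogram(23, root_age = 146.7, seed = 71)
  model <- set_rates(preset_model("plates_independent"), c(0.01, 0.005))
  ll_true <- 0; ll_up <- 0; ll_dn <- 0
  up <- set_rates(model, c(0.02, 0.01)); dn <- set_rates(model, c(0.005, 0.0025))
  for (i in 1:300) {
    sim <- simulate_discrete_character(tr, model, seed = 900 + i)
    ll_true <- ll_true + prune_loglik(tr, sim$tip_states, model)
    ll_up <- ll_up + prune_loglik(tr, sim$tip_states, up)
    ll_dn <- ll_dn + prune_loglik(tr, sim$tip_states, dn)
  }
  expect_gt(ll_true, ll_up)
  expect_gt(ll_true, ll_dn)
})

test_that("simulated gene sets translate cleanly and carry rRNA truth only", {
  tr <- simulate_chronogram(8, root_age = 146.7, seed = 81)
  gs <- simulate_gene_set(tr, n_coding = 3, n_rrna = 2, coding_codons = 10,
                          rrna_sites = 40, seed = 4)
  aln <- gs$alignment
  expect_equal(nrow(aln$partitions), 5)
  for (g in aln$partitions$gene[aln$partitions$kind == "coding"]) {
    expect_no_error(translate_cds(gene_columns(aln, g)))
  }
  p <- aln$partitions
  coding_cols <- unlist(purrr::map2(p$start[p$kind == "coding"],
                                    p$end[p$kind == "coding"], seq))
  expect_true(all(is.na(gs$true_category[coding_cols])))
  expect_true(all(!is.na(gs$true_category[-coding_cols])))
})
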