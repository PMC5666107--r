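ds_params <- gtr_params(c(1, 2, 1, 1, 2, 1), c(0.3, 0.2, 0.2, 0.3),
                        alpha = 0.4, scale = 0.002)

make_series <- function(seed, n_coding = 3, n_rrna = 2, tree_seed = 77) {
  tr <- simulate_chronogram(8, root_age = 146.7, seed = tree_seed)
  gs <- simulate_gene_set(tr, n_coding = n_coding, n_rrna = n_rrna,
                          coding_codons = 12, rrna_sites = 60,
                          params = ds_params, seed = seed)
  list(tree = tr, gs = gs,
       series = build_ds_series(gs$alignment, tr, K = 10, params = ds_params))
}

test_that("the dataset series has the published structure", {
  x <- make_series(1, n_coding = 6, n_rrna = 4)
  s <- x$series
  # DS1 passthrough
  expect_identical(s$DS1$seq, x$gs$alignment$seq)
  # DS2: coding columns reduced 3:1, rRNA unchanged
  n_coding_nt <- sum(x$gs$alignment$partitions$kind == "coding") * 12 * 3
  n_rrna_nt <- 4 * 60
  expect_equal(ncol(s$DS2$seq), n_coding_nt / 3 + n_rrna_nt)
  expect_true(all(s$DS2$partitions$kind %in% c("aa", "rRNA")))
  # removal counts match the assignment
  expect_equal(s$removal$n_removed[s$removal$step == "DS3"],
               sum(s$assignment$category == 10))
  expect_equal(s$removal$n_removed[s$removal$step == "DS4"],
               sum(s$assignment$category >= 9))
})

test_that("rRNA column sets are nested DS4 within DS3 within DS2 and fractions recount", {
  for (seed in c(2, 3, 4)) {
    s <- make_series(seed)$series
    rrna_ds2 <- s$manifest$ds2_column[s$manifest$kind == "rRNA"]
    kept3 <- setdiff(rrna_ds2, s$removed$DS3$removed_sites)
    kept4 <- setdiff(rrna_ds2, s$removed$DS4$removed_sites)
    expect_true(all(kept4 %in% kept3))
    expect_true(all(kept3 %in% rrna_ds2))
    # independent recount oracle for the removal fractions
    n_rrna <- length(rrna_ds2)
    expect_equal(s$removal$fraction[1],
                 sum(s$assignment$category == 10) / n_rrna)
    expect_equal(s$removal$fraction[2],
                 sum(s$assignment$category %in% c(9, 10)) / n_rrna)
  }
})

test_that("manifests allow lossless reconstruction of DS2", {
  s <- make_series(5)$series
  expect_identical(unname(reconstruct_ds2(s, "DS3")), unname(s$DS2$seq))
  expect_identical(unname(reconstruct_ds2(s, "DS4")), unname(s$DS2$seq))
})

test_that("category removal is exact bookkeeping", {
  x <- make_series(6)
  aln <- x$series$DS2
  asg <- tibble::tibble(
    site = x$series$manifest$ds2_column[x$series$manifest$kind == "rRNA"],
    gene = x$series$manifest$gene[x$series$manifest$kind == "rRNA"],
    category = x$series$manifest$category[x$series$manifest$kind == "rRNA"])
  for (k in 1:10) asg[[paste0("p_cat", k)]] <- NA_real_

  # empty drop set leaves the alignment unchanged
  r0 <- remove_categories(aln, asg, drop = integer(0))
  expect_identical(r0$alignment$seq, aln$seq)
  expect_equal(r0$fraction, 0)

  # dropping one category removes exactly the matching columns
  k_use <- asg$category[1]
  rk <- remove_categories(aln, asg, drop = k_use)
  expect_equal(ncol(rk$alignment$seq), ncol(aln$seq) - sum(asg$category == k_use))
  expect_error(remove_categories(aln, asg, drop = 11), "1..10")
})

test_that("series invariants hold across many randomized 10-gene inputs", {
  for (seed in 1:10) {
    x <- make_series(seed + 100, n_coding = 6, n_rrna = 4, tree_seed = seed)
    s <- x$series
    expect_true(ncol(s$DS4$seq) <= ncol(s$DS3$seq))
    expect_true(ncol(s$DS3$seq) <= ncol(s$DS2$seq))
    expect_identical(unname(reconstruct_ds2(s, "DS3")), unname(s$DS2$seq))
    expect_identical(unname(reconstruct_ds2(s, "DS4")), unname(s$DS2$seq))
    fr <- s$removal$fraction
    expect_true(all(fr >= 0 & fr <= 1))
  }
})
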