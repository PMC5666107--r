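test_that("branch-length newick yields a validated chronogram", {
  tr <- read_chronogram(text = "(A:10,B:10):0;")
  expect_s3_class(tr, "chronogram")
  expect_equal(max(attr(tr, "node_age")), 10)
  expect_equal(mrca_age(tr, c("A", "B")), 10)

  expect_error(read_chronogram(text = "(A:5,B:10):0;"), "not ultrametric.*A")
  expect_error(read_chronogram(text = "(A:5,B:10"), "malformed newick")
})

test_that("newick with node-age labels is supported", {
  tr <- read_chronogram(text = "((A,B)5,C)10;", age_mode = "node-ages")
  expect_equal(mrca_age(tr, c("A", "B")), 5)
  expect_equal(mrca_age(tr, c("A", "C")), 10)
  expect_error(read_chronogram(text = "((A,B)x,C)10;", age_mode = "node-ages"),
               "not a numeric age")
})

test_that("write/read round-trips topology, labels and ages to 1e-9", {
  for (seed in 1:5) {
    tr <- simulate_chronogram(9, root_age = 146.7, seed = seed)
    tr2 <- read_chronogram(text = write_chronogram(tr))
    expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
    a1 <- node_ages(tr); a2 <- node_ages(tr2)
    common <- intersect(a1$label[a1$is_tip], a2$label[a2$is_tip])
    for (pair in list(common[1:2], common[c(1, length(common))])) {
      expect_equal(mrca_age(tr2, pair), mrca_age(tr, pair), tolerance = 1e-9)
    }
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  }
})

test_that("build_chronogram reproduces the clade-age table exactly", {
  topo <- "((Nematogenyidae,Trichomycteridae),(Callichthyidae,(Loricariidae,(Scoloplacidae,Astroblepidae))));"
  ages <- tibble::tibble(
    clade_tips = c("Nematogenyidae;Loricariidae", "Nematogenyidae;Trichomycteridae",
                   "Callichthyidae;Loricariidae", "Loricariidae;Astroblepidae",
                   "Scoloplacidae;Astroblepidae"),
    age_ma = c(123.8, 114.0, 117.2, 97.4, 92.1))
  tr <- build_chronogram(topo, ages)
  # root-to-tip distance equals the crown age
  expect_equal(max(ape::node.depth.edgelength(tr)), 123.8)
  for (i in seq_len(nrow(ages))) {
    tips <- strsplit(ages$clade_tips[i], ";")[[1]]
    expect_identical(mrca_age(tr, tips), ages$age_ma[i])
  }
})

test_that("build_chronogram catches missing and inconsistent ages", {
  tr2 <- build_chronogram("(A,B);", tibble::tibble(clade_tips = "A;B", age_ma = 10))
  expect_equal(tr2$edge.length, c(10, 10))

  expect_error(
    build_chronogram("((A,B),C);",
                     tibble::tibble(clade_tips = "A;B;C", age_ma = 50)),
    "no age supplied.*A, B")
  expect_error(
    build_chronogram("((A,B),C);",
                     tibble::tibble(clade_tips = c("A;B;C", "A;B"),
                                    age_ma = c(50, 60))),
    "not younger")
})

test_that("clade-age tables round-trip through CSV with their source flags", {
  ages <- tibble::tibble(clade_tips = c("A;B", "A;C"), age_ma = c(4.25, 10),
                         source = c("reported", "interpolated_synthetic"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clade_ages(ages, path)
  expect_equal(as.data.frame(read_clade_ages(path)), as.data.frame(ages))
})

test_that("collapsing to representatives keeps surviving node ages", {
  # identity mapping leaves the tree unchanged
  tr <- simulate_chronogram(8, root_age = 100, seed = 3)
  same <- collapse_to_representatives(
    tr, stats::setNames(tr$tip.label, tr$tip.label))
  expect_equal(attr(same, "node_age"), attr(tr, "node_age"))

  # property: collapse random clades on random trees; retained MRCA ages equal
  for (seed in 1:6) {
    tr <- simulate_chronogram(12, root_age = 146.7, seed = seed)
    node <- length(tr$tip.label) + 3  # some internal node
    clade_tips <- tr$tip.label[odontotrace:::.descendant_tips(tr, node)]
    mapping <- tibble::tibble(
      tip = tr$tip.label,
      group = ifelse(tr$tip.label %in% clade_tips, "G", tr$tip.label))
    col <- collapse_to_representatives(tr, mapping)
    expect_equal(length(col$tip.label), 12 - length(clade_tips) + 1)
    others <- setdiff(tr$tip.label, clade_tips)
    if (length(others) >= 2) {
      expect_equal(mrca_age(col, others[1:2]), mrca_age(tr, others[1:2]),
                   tolerance = 1e-9)
    }
    # the group tip hangs from the group's stem: its age from any outside tip
    # equals the original MRCA age of (clade, that tip)
    expect_equal(mrca_age(col, c("G", others[1])),
                 mrca_age(tr, c(clade_tips[1], others[1])), tolerance = 1e-9)
  }
})

test_that("non-monophyletic groups are rejected with the intruding tip named", {
  tr <- as_chronogram("((A:1,B:1):1,(C:1,D:1):1);")
  mapping <- tibble::tibble(tip = c("A", "B", "C", "D"),
                            group = c("G1", "G2", "G1", "G2"))
  expect_error(collapse_to_representatives(tr, mapping), "not monophyletic")
  expect_error(collapse_to_representatives(tr, mapping[1:3, ]), "does not cover")
})

test_that("simulator output always satisfies the chronogram invariants", {
  for (seed in 1:8) {
    n <- 2 + (seed %% 7)
    tr <- simulate_chronogram(n, root_age = 50 + seed, seed = seed)
    age <- attr(tr, "node_age")
    expect_true(all(age[seq_len(n)] == 0))
    expect_true(all(tr$edge.length > 0))
    depth <- ape::node.depth.edgelength(tr)
    expect_lt(max(abs(max(depth) - depth[seq_len(n)])), 1e-9 * max(age))
    expect_equal(max(age), 50 + seed, tolerance = 1e-12)
  }
})
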