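write_tree_file <- function(text) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(text, tf)
  tf
}

test_that("read_newick parses valid dated trees and validates them", {
  tr <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[match("A", tr$tip.label)], 2)  # root-to-A path

  tr4 <- read_newick(write_tree_file("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(length(tr4$tip.label), 4L)
})

test_that("read_newick rejects invalid input rather than repairing it", {
  expect_error(read_newick(write_tree_file("((A:1,B):1,C:2);")),
               "missing branch length")
  expect_error(read_newick(write_tree_file("((A:1,A:1):1,C:2);")),
               "duplicate tip")
  expect_error(read_newick(write_tree_file("((A:1,B:1:1,C:2);")),
               "malformed|Newick")
  expect_error(read_newick(tempfile()), "not found")
})

test_that("newick round-trip preserves topology and branch lengths", {
  for (seed in 1:5) {
    tr <- simulate_tree(sample(4:12, 1), "yule", seed = seed)
    tf <- tempfile(fileext = ".nwk")
    write_newick(tr, tf)
    back <- read_newick(tf)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }
})

test_that("patristic distances equal hand path summation", {
  d3 <- patristic_matrix(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(d3["A", "B"], 2)
  expect_equal(d3["A", "C"], 4)
  expect_equal(diag(d3), setNames(rep(0, 3), rownames(d3)))
  expect_true(isSymmetric(d3))

  d4 <- patristic_matrix(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
  expect_equal(d4["A", "D"], 6)
  expect_equal(d4["C", "D"], 6)
  expect_equal(d4["A", "C"], 4)
})

test_that("patristic_matrix matches a naive path-walking oracle on random trees", {
  for (seed in 1:8) {
    tr <- simulate_tree(sample(4:8, 1), "yule", seed = 100 + seed)
    expect_equal(patristic_matrix(tr), patristic_oracle(tr), tolerance = 1e-9)
  }
})

test_that("patristic_matrix refuses degenerate trees", {
  one_tip <- ape::read.tree(text = "(A:1);")
  expect_error(patristic_matrix(one_tip), "2 tips")
})

occ_csv <- function(rows) {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("site,species,genus,growth_form,endemic", rows), tf)
  tf
}

test_that("read_occurrence builds a binary incidence matrix from long CSV", {
  occ <- read_occurrence(occ_csv(c(
    "s1,Gentiana_algida,Gentiana,perennial herb,yes",
    "s1,Saussurea_ovata,Saussurea,perennial herb,no",
    "s2,Gentiana_algida,Gentiana,perennial herb,yes")))
  expect_equal(dim(occ$incidence), c(2L, 2L))
  expect_equal(sum(occ$incidence), 3L)
  expect_equal(occ$incidence["s2", "Saussurea_ovata"], 0L)
  expect_equal(occ$species_meta$endemic[occ$species_meta$species ==
                                          "Gentiana_algida"], TRUE)
})

test_that("duplicate rows collapse with a warning, idempotently", {
  rows <- c("s1,X_a,X,shrub,no", "s1,X_a,X,shrub,no", "s2,X_a,X,shrub,no")
  expect_warning(dup <- read_occurrence(occ_csv(rows)), "duplicate")
  clean <- read_occurrence(occ_csv(rows[-2]))
  expect_identical(dup$incidence, clean$incidence)
})

test_that("a species mapped to two genera is rejected with the offender named", {
  expect_error(
    read_occurrence(occ_csv(c("s1,X_a,G1,shrub,no", "s2,X_a,G2,shrub,no"))),
    "X_a")
})

test_that("read_occurrence is invariant to row order", {
  rows <- c("s1,A_a,A,tree,yes", "s2,B_b,B,shrub,no", "s1,B_b,B,shrub,no",
            "s3,C_c,C,liana,no")
  a <- read_occurrence(occ_csv(rows))
  b <- read_occurrence(occ_csv(rev(rows)))
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$species_meta[order(a$species_meta$species), ],
                   b$species_meta[order(b$species_meta$species), ])
})

test_that("occurrence round-trips through write_occurrence", {
  fx <- make_fixture()
  tf <- tempfile(fileext = ".csv")
  write_occurrence(fx$occurrence, tf)
  back <- read_occurrence(tf)
  orig <- fx$occurrence$incidence
  expect_identical(back$incidence[rownames(orig), colnames(orig)[order(colnames(orig))]],
                   orig[, order(colnames(orig))])
})
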