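test_that("simulated trees are reproducible, rooted and ultrametric", {
  cherry <- simulate_tree(2, "yule", seed = 1)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])           # single cherry, equal depths

  a <- simulate_tree(25, "yule", seed = 99)
  b <- simulate_tree(25, "yule", seed = 99)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(ape::is.ultrametric(a, tol = 1e-8))
  expect_true(ape::is.rooted(a))

  bd <- simulate_tree(15, "birth-death", birth = 1, death = 0.4, seed = 3)
  expect_equal(length(bd$tip.label), 15L)
  expect_true(ape::is.ultrametric(bd, tol = 1e-8))
})

test_that("invalid diversification rates are rejected", {
  expect_error(simulate_tree(10, "birth-death", birth = 0.5, death = 0.5))
  expect_error(simulate_tree(10, "birth-death", birth = 1, death = -0.1))
  expect_error(simulate_tree(1, "yule"))
})

test_that("Yule tree depth matches the analytic expectation", {
  # crown-start pure birth stopped just before the (n+1)th speciation:
  # E[depth] = sum_{k=2..n} 1/(lambda k), Var = sum 1/(lambda k)^2
  n <- 50; lambda <- 1; reps <- 400
  withr::with_seed(51, {
    depths <- vapply(seq_len(reps), function(i) {
      max(ape::node.depth.edgelength(simulate_tree(n, "yule", birth = lambda)))
    }, 0)
  })
  expected <- sum(1 / (lambda * 2:n))
  se <- sqrt(sum(1 / (lambda * 2:n)^2) / reps)
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("clade-table simulation honours its distribution specs", {
  const <- simulate_clade_table(30, age_dist = dist_spec("constant", value = 19.4),
                                seed = 61)
  expect_true(all(const$age_ma == 19.4))
  expect_equal(mdt(const[sample(30, 10), ])$mdt, 19.4)  # any subsample

  unif <- simulate_clade_table(10000,
                               age_dist = dist_spec("uniform", min = 0.01, max = 40),
                               seed = 62)
  se <- (40 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(unif$age_ma) - 20), 3 * se)

  ea <- simulate_clade_table(50, origin_probs = c("Eastern Asia" = 1),
                             seed = 63)
  expect_true(all(ea$origin == "Eastern Asia"))
  expect_true(all(simulate_clade_table(200, seed = 64)$species_count >= 1L))
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulate_clade_table(10, age_dist = dist_spec("cauchy")),
               "unknown distribution")
  expect_error(simulate_clade_table(10, origin_probs = c(a = 0.4, b = 0.4)),
               "sum to 1")
  expect_error(simulate_clade_table(0))
})

test_that("communities are reproducible and respect richness bounds", {
  tr <- simulate_tree(30, "yule", seed = 71)
  sc <- assembly_scenario("neutral", n_sites = 6, richness = c(5, 10), seed = 72)
  a <- simulate_communities(tr, sc)
  b <- simulate_communities(tr, sc)
  expect_identical(a$incidence, b$incidence)
  expect_true(all(rowSums(a$incidence) >= 5 & rowSums(a$incidence) <= 10))
  expect_error(simulate_communities(
    tr, assembly_scenario("neutral", richness = 31)), "richness")
})

test_that("zero strength reduces filtering and repulsion to neutral", {
  tr <- simulate_tree(32, "yule", seed = 81)
  d <- patristic_matrix(tr)
  nti_dist <- function(regime) {
    occ <- simulate_communities(
      tr, assembly_scenario(regime, strength = 0, n_sites = 150, richness = 8,
                            seed = 82))
    vapply(rownames(occ$incidence), function(s) {
      sp <- colnames(occ$incidence)[occ$incidence[s, ] == 1L]
      nti(sp, d, pool = tr$tip.label, n_reps = 199, seed = 83)$nti
    }, 0)
  }
  neutral <- nti_dist("neutral")
  for (regime in c("filtering", "repulsion")) {
    ks <- suppressWarnings(stats::ks.test(nti_dist(regime), neutral))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("mean NTI rises with filtering strength across a grid", {
  tr <- simulate_tree(48, "yule", seed = 91)
  d <- patristic_matrix(tr)
  grid <- c(0, 0.5, 1, 2, 4)
  mean_nti <- vapply(seq_along(grid), function(i) {
    occ <- simulate_communities(
      tr, assembly_scenario("filtering", strength = grid[i], n_sites = 100,
                            richness = 10, seed = 92 + i))
    mean(vapply(rownames(occ$incidence), function(s) {
      sp <- colnames(occ$incidence)[occ$incidence[s, ] == 1L]
      nti(sp, d, pool = tr$tip.label, n_reps = 199, seed = 93)$nti
    }, 0))
  }, 0)
  expect_gt(stats::cor(grid, mean_nti, method = "spearman"), 0)
  expect_gt(mean_nti[5], mean_nti[1])
})

test_that("the kunlun-mini fixture is deterministic and well-formed", {
  fx1 <- make_fixture("kunlun-mini")
  fx2 <- make_fixture("kunlun-mini")
  expect_identical(ape::write.tree(fx1$tree), ape::write.tree(fx2$tree))
  expect_identical(fx1$occurrence$incidence, fx2$occurrence$incidence)
  expect_identical(fx1$clades, fx2$clades)

  validate_phylogeny(fx1$tree)
  expect_s3_class(fx1$clades, "clade_age_table")
  expect_s3_class(fx1$occurrence, "occurrence_matrix")
  expect_setequal(fx1$regions$site, rownames(fx1$occurrence$incidence))

  endemic_frac <- mean(fx1$occurrence$species_meta$endemic)
  expect_lt(abs(endemic_frac - 0.30), 0.05)  # set by construction

  expect_error(make_fixture("atlantis"), "unknown fixture")
})
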