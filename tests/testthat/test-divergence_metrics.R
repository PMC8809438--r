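test_that("mdt is the species-count-weighted mean of crown ages", {
  one <- clade_age_table("A", 10, 3)
  expect_equal(mdt(one)$mdt, 10)

  two <- clade_age_table(c("A", "B"), c(20, 10), c(2, 6))
  r <- mdt(two)
  expect_equal(r$mdt, 12.5)
  expect_equal(r$median_age, 15)   # unweighted median of {20, 10}
  expect_equal(r$n_clades, 2L)
  expect_equal(r$n_species, 8L)
})

test_that("mdt input validation rejects empty and malformed tables", {
  tab <- clade_age_table(c("A", "B"), c(20, 10), c(2, 6))
  expect_error(mdt(tab[0, ]), "empty")
  expect_error(clade_age_table("A", 10, 0), "species_count")
  expect_error(clade_age_table("A", -1, 2), "positive")
  expect_error(clade_age_table(c("A", "A"), c(1, 2), c(1, 1)), "duplicate")
})

test_that("mdt is bounded by the age range and scale-invariant in counts", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(2:30, 1)
      tab <- clade_age_table(paste0("g", 1:n), runif(n, 1, 60),
                             sample(1:20, n, replace = TRUE))
      m <- mdt(tab)$mdt
      expect_gte(m, min(tab$age_ma))
      expect_lte(m, max(tab$age_ma))
      scaled <- tab
      scaled$species_count <- tab$species_count * 7L
      expect_equal(mdt(scaled)$mdt, m)
    }
  })
})

test_that("mdt reduces to the plain mean under equal species counts", {
  withr::with_seed(12, {
    ages <- runif(15, 1, 50)
    tab <- clade_age_table(paste0("g", 1:15), ages, rep(4L, 15))
    expect_equal(mdt(tab)$mdt, mean(ages))
  })
})

test_that("the species-weighted median variant weights by counts", {
  tab <- clade_age_table(c("A", "B"), c(10, 30), c(9, 1))
  expect_equal(mdt(tab)$median_age, 20)                          # unweighted
  expect_equal(mdt(tab, weighted_median = TRUE)$median_age, 10)  # mass at 10
})

test_that("exhaustive SES-MDT matches full enumeration of the null", {
  pool <- clade_age_table(paste0("g", 1:4), c(10, 10, 10, 30), rep(1L, 4))
  r <- ses_mdt(pool[4, ], pool, mode = "exhaustive")
  expect_equal(r$observed, 30)
  expect_equal(r$null_mean, 15)
  expect_equal(r$null_sd, sqrt(75))          # population SD of {10,10,10,30}
  expect_equal(r$ses, 15 / sqrt(75), tolerance = 1e-12)
  expect_equal(r$n_reps, 4L)
})

test_that("sample equal to the pool gives a degenerate null", {
  pool <- clade_age_table(paste0("g", 1:5), runif(5, 5, 40), rep(2L, 5))
  r <- ses_mdt(pool, pool, mode = "exhaustive")
  expect_equal(r$null_sd, 0)
  expect_equal(r$ses, 0)
  expect_equal(r$classification, "degenerate")
})

test_that("a sample larger than the pool is rejected", {
  pool <- clade_age_table(paste0("g", 1:3), c(5, 10, 15), c(1, 1, 1))
  big <- clade_age_table(paste0("x", 1:4), c(5, 10, 15, 20), rep(1L, 4))
  expect_error(ses_mdt(big, pool), "more genera")
})

test_that("Monte-Carlo SES-MDT converges on the exhaustive value", {
  withr::with_seed(21, {
    for (i in 1:4) {
      np <- sample(6:8, 1)
      k <- sample(2:4, 1)
      pool <- clade_age_table(paste0("g", 1:np), runif(np, 2, 50),
                              sample(1:8, np, replace = TRUE))
      samp <- pool[sample(np, k), ]
      ex <- ses_mdt(samp, pool, mode = "exhaustive")
      mc <- ses_mdt(samp, pool, n_reps = 9999, seed = 500 + i)
      expect_lt(abs(mc$ses - ex$ses), 3 * ses_mc_se(ex$ses, 9999) + 1e-9)
    }
  })
})

test_that("flora classification follows the strict +/-1.96 rule", {
  expect_equal(classify_flora(2.10), "ancient")
  expect_equal(classify_flora(-1.95), "nonsignificant")
  expect_equal(classify_flora(1.96), "nonsignificant")  # strict inequality
  expect_equal(classify_flora(-2.2), "young")
  expect_equal(classify_flora(c(2, -2, 0)),
               c("ancient", "young", "nonsignificant"))
})

test_that("degenerate classification passes through classify_flora", {
  pool <- clade_age_table(paste0("g", 1:3), c(5, 10, 15), rep(1L, 3))
  r <- ses_mdt(pool, pool, mode = "exhaustive")
  expect_equal(classify_flora(r), "degenerate")
})

test_that("mean SES-MDT rises monotonically with an old-age shift", {
  withr::with_seed(31, {
    np <- 40
    pool <- clade_age_table(paste0("g", 1:np), runif(np, 5, 30),
                            sample(1:6, np, replace = TRUE))
    mean_ses <- vapply(c(0, 3, 6, 9), function(delta) {
      mean(vapply(1:40, function(i) {
        idx <- sample(np, 10)
        samp <- pool[idx, ]
        samp$age_ma <- samp$age_ma + delta
        ses_mdt(samp, pool, n_reps = 199)$ses
      }, 0))
    }, 0)
    expect_true(all(diff(mean_ses) > 0))
  })
})
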