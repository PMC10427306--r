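test_that("identical groups give a null difference and p of 1", {
  v <- setNames(rep(5, 8), letters[1:8])
  lab <- rep(c("A", "B"), 4)
  pt <- permutation_test(v, lab, n_permutations = 500, seed = 1)
  expect_equal(pt$observed_difference, 0)
  expect_equal(pt$p_two_tailed, 1)
})

test_that("sampled permutation p matches the exhaustive oracle at small n", {
  v <- c(10, 10, 10, 0, 0, 0)
  lab <- rep(c("A", "B"), each = 3)
  exact <- oracle_exhaustive_perm(v, lab)
  expect_equal(exact, 2 / 20)   # only the two extreme assignments qualify
  pt <- permutation_test(setNames(v, letters[1:6]), lab,
                         n_permutations = 9999, seed = 5)
  se <- sqrt(exact * (1 - exact) / 9999)
  expect_lt(abs(pt$p_two_tailed - exact), 4 * se + 2e-4)

  # a second, non-degenerate fixture
  set.seed(7)
  v2 <- round(rnorm(9), 2)
  lab2 <- rep(c("A", "B"), c(4, 5))
  exact2 <- oracle_exhaustive_perm(v2, lab2)
  pt2 <- permutation_test(setNames(v2, letters[1:9]), lab2,
                          n_permutations = 9999, seed = 6)
  expect_lt(abs(pt2$p_two_tailed - exact2),
            4 * sqrt(exact2 * (1 - exact2) / 9999) + 2e-4)
})

test_that("permutation p-values are calibrated on exchangeable data", {
  set.seed(3)
  ps <- replicate(300, {
    v <- rnorm(30)
    permutation_test(setNames(v, paste0("i", 1:30)),
                     rep(c("A", "B"), 15), n_permutations = 199,
                     seed = sample.int(1e6, 1))$p_two_tailed
  })
  rej <- mean(ps <= 0.05)
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(rej - 0.05), 3.5 * se + 1 / 200)
})

test_that("permutation test is seed-reproducible and validates inputs", {
  v <- setNames(rnorm(12), paste0("i", 1:12))
  lab <- rep(c("A", "B"), 6)
  p1 <- permutation_test(v, lab, 200, seed = 9)
  p2 <- permutation_test(v, lab, 200, seed = 9)
  expect_identical(p1$p_two_tailed, p2$p_two_tailed)
  expect_error(permutation_test(v, rep("A", 12), 10, 1), "two label groups")
})

test_that("couple-swap scheme preserves group sizes and flags bad pairs", {
  v <- setNames(c(1, 5, 2, 6, 3, 4), paste0("i", 1:6))
  lab <- c("A", "B", "A", "B", "A", "B")
  pairs <- setNames(c("i2", "i1", "i4", "i3", NA, NA), names(v))
  pt <- permutation_test(v, lab, 500, seed = 2, pairs = pairs)
  expect_match(pt$scheme, "couple-swap")
  expect_equal(unname(pt$groups), c(3L, 3L))
  bad <- setNames(c("i3", NA, "i1", NA, NA, NA), names(v))
  expect_error(permutation_test(v, lab, 10, 1, pairs = bad),
               "opposite labels")
})

test_that("correlations match cor.test and reject degenerate input", {
  x <- 1:10
  expect_equal(correlation(x, 2 * x + 1)$estimate, 1)
  mono <- correlation(x, x^3, method = "spearman")
  expect_equal(mono$estimate, 1)
  expect_lt(correlation(x, x^3)$estimate, 1)
  ct <- cor.test(x, c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  ours <- correlation(x, c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  expect_equal(ours$estimate, unname(ct$estimate))
  expect_equal(ours$p_value, ct$p.value)
  expect_error(correlation(x, rep(1, 10)), "zero variance")
  expect_error(correlation(1:2, 1:2), "at least 3")
})

test_that("partial correlation equals the residual-residual construction", {
  set.seed(21)
  for (k in 1:5) {
    z <- rnorm(25)
    x <- 0.5 * z + rnorm(25)
    y <- -0.3 * z + rnorm(25)
    pc <- partial_correlation(x, y, z)
    rr <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc$estimate, rr, tolerance = 1e-10)
    n <- 25
    tt <- rr * sqrt((n - 3) / (1 - rr^2))
    expect_equal(pc$p_value, 2 * pt(-abs(tt), n - 3), tolerance = 1e-10)
  }
  expect_error(partial_correlation(1:10, 1:10 + 0, 1:10), "degenerate")
})

test_that("partial correlation approaches the raw one when z is irrelevant", {
  set.seed(8)
  n <- 4000
  z <- rnorm(n)
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  expect_equal(partial_correlation(x, y, z)$estimate,
               correlation(x, y)$estimate, tolerance = 0.02)
})

test_that("haversine reproduces analytic distances and metric properties", {
  expect_equal(haversine_km(c(10, 20), c(10, 20)), 0)
  expect_equal(haversine_km(c(0, 0), c(0, 180)), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(haversine_km(c(0, 0), c(0, 1)), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  expect_error(haversine_km(c(95, 0), c(0, 0)), "out of range")
  set.seed(4)
  for (k in 1:10) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    cc <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
    expect_lte(haversine_km(a, b),
               haversine_km(a, cc) + haversine_km(cc, b) + 1e-9)
  }
})

test_that("camp pairs enumerate C(k,2) rows and detect planted decay", {
  pop <- generate_population(generator_config(), seed = 2)
  rec <- pop$pedigree$records
  r <- relatedness_matrix(kinship_matrix(pop$pedigree))
  cpa <- camp_pair_analysis(r, pop$panel$memberships, pop$panel$coordinates,
                            setNames(rec$adult, rec$id))
  expect_equal(nrow(cpa$pairs), choose(15, 2))
  expect_true(all(cpa$pairs$distance_km >= 0))

  # distance-weighted marriage market produces relatedness decaying with
  # distance (sign check over several seeds)
  sgn <- vapply(1:6, function(sd) {
    p2 <- generate_population(
      generator_config(n_camps = 8, mean_adults_per_camp = 10,
                       marriage_distance_decay_km = 10), seed = sd)
    rc <- p2$pedigree$records
    r2 <- relatedness_matrix(kinship_matrix(p2$pedigree))
    camp_pair_analysis(r2, p2$panel$memberships, p2$panel$coordinates,
                       setNames(rc$adult, rc$id))$spearman$estimate
  }, numeric(1))
  expect_gte(sum(sgn < 0), 5)
})

test_that("camps without coordinates are excluded with a warning", {
  ids <- sprintf("i%d", 1:9)
  set.seed(1)
  r <- matrix(0, 9, 9, dimnames = list(ids, ids))
  r[upper.tri(r)] <- runif(36, 0, 0.2)
  r <- r + t(r)
  diag(r) <- NA
  mem <- setNames(rep(c("A", "B", "C", "D"), c(3, 2, 2, 2)), ids)
  coords <- data.frame(camp = c("A", "B", "C"),
                       lat = c(0, 0.1, 0.2), lon = c(0, 0, 0))
  expect_warning(cpa <- camp_pair_analysis(r, mem, coords), "without coordinates")
  expect_equal(nrow(cpa$pairs), choose(3, 2))
})
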