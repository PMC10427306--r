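make_r <- function(ids, fill = 0) {
  r <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(r) <- NA_real_
  r
}

test_that("s equals r exactly when nobody is married", {
  pop <- small_population()
  r <- relatedness_matrix(kinship_matrix(pop$pedigree))
  empty <- setNames(rep(NA_character_, nrow(r)), rownames(r))
  s <- shared_interest_matrix(r, empty)
  expect_equal(unclass(s), unclass(r), ignore_attr = TRUE)
})

test_that("s credits the affinal tie through a sibling's marriage", {
  # ego unmarried; alter married to ego's full sibling: r_D = 0.5, r_C = 0
  ped <- pedigree(
    data.frame(id = c("F", "M", "ego", "sib", "alter"),
               father = c(NA, NA, "F", "F", NA),
               mother = c(NA, NA, "M", "M", NA),
               sex = c("male", "female", "male", "female", "male"),
               stringsAsFactors = FALSE))
  r <- relatedness_matrix(kinship_matrix(ped))
  sm <- setNames(c(NA, NA, NA, "alter", "sib"), ped$records$id)
  s <- shared_interest_matrix(r, sm)
  expect_equal(s["ego", "alter"], r["ego", "alter"] + 0.5)
  # and between spouses r_D is self-relatedness: s(sib, alter) = (0 + 1)/1
  expect_equal(s["sib", "alter"], 1)
})

test_that("consanguineous ego marriage deflates s; strangers give s = 0", {
  fx <- named_pedigree_fixtures()$first_cousin_spouses
  ped <- fx$pedigree
  rec <- ped$records[, c("id", "father", "mother", "sex")]
  rec <- rbind(rec,
               data.frame(id = c("J", "Jsp"), father = NA_character_,
                          mother = NA_character_, sex = c("male", "female")))
  ped2 <- pedigree(rec)
  r <- relatedness_matrix(kinship_matrix(ped2))
  sm <- setNames(rep(NA_character_, nrow(rec)), rec$id)
  sm[c("H", "W", "J", "Jsp")] <- c("W", "H", "Jsp", "J")
  s <- shared_interest_matrix(r, sm)
  # i married to first cousin (r_C = 0.125); j a stranger married to a
  # stranger: numerator r_B + r_D = 0
  expect_identical(s["H", "J"], 0)
  # the affinal term can only add when ego's marriage is non-consanguineous
  nc <- setdiff(rec$id, c("H", "W"))
  expect_true(all(s[nc, ] >= unclass(r)[nc, ] - 1e-15, na.rm = TRUE))
})

test_that("shared interest rejects non-mutual spouse maps", {
  r <- make_r(c("a", "b"))
  expect_error(shared_interest_matrix(r, c(a = "b", b = NA)), "not mutual")
})

test_that("worked two-community example yields 0.06 / 0.033 / 0.023", {
  wf <- worked_example_fixture()
  agg <- aggregate_relatedness(wf$r, wf$memberships, "everyone")
  expect_equal(agg$r_group, 0.06)
  expect_equal(agg$r_individual, 1 / 30)
  expect_equal(agg$r_dyads, 118 / 5140)
  expect_equal(agg$n_dyads, choose(20, 2) + choose(100, 2))
  expect_equal(round(c(agg$r_group, agg$r_individual, agg$r_dyads), 3),
               c(0.06, 0.033, 0.023))
})

test_that("equal camps with constant relatedness collapse all three levels", {
  ids <- sprintf("i%02d", 1:30)
  r <- make_r(ids, fill = 0.07)
  mem <- setNames(rep(c("A", "B", "C"), each = 10), ids)
  agg <- aggregate_relatedness(r, mem, "everyone")
  expect_equal(agg$r_group, 0.07)
  expect_equal(agg$r_individual, 0.07)
  expect_equal(agg$r_dyads, 0.07)
})

test_that("aggregations equal the brute-force double-loop oracle", {
  for (seed in c(11, 12, 13)) {
    pop <- small_population(seed)
    rec <- pop$pedigree$records
    r <- relatedness_matrix(kinship_matrix(pop$pedigree))
    mem <- pop$panel$memberships
    adult <- setNames(rec$adult, rec$id)

    agg <- aggregate_relatedness(r, mem, "everyone", adult)
    ora <- oracle_aggregate(unclass(r), mem, rec$id)
    expect_equal(agg$r_group, ora$r_group, tolerance = 1e-12)
    expect_equal(agg$r_individual, ora$r_individual, tolerance = 1e-12)
    expect_equal(agg$r_dyads, ora$r_dyads, tolerance = 1e-12)
    expect_equal(agg$n_dyads, ora$n_dyads)

    agg_a <- aggregate_relatedness(r, mem, "adults_only", adult)
    ora_a <- oracle_aggregate(unclass(r), mem, rec$id[rec$adult])
    expect_equal(agg_a$r_dyads, ora_a$r_dyads, tolerance = 1e-12)
    expect_equal(agg_a$r_group, ora_a$r_group, tolerance = 1e-12)
  }
})

test_that("adult-to-child aggregation averages the cross dyads", {
  ids <- c("a1", "a2", "c1", "c2")
  r <- make_r(ids)
  r["a1", c("c1", "c2")] <- r[c("c1", "c2"), "a1"] <- c(0.5, 0.25)
  r["a2", c("c1", "c2")] <- r[c("c1", "c2"), "a2"] <- c(0, 0.5)
  mem <- setNames(rep("A", 4), ids)
  adult <- setNames(c(TRUE, TRUE, FALSE, FALSE), ids)
  agg <- aggregate_relatedness(r, mem, "adult_to_child", adult)
  expect_equal(unname(agg$per_individual[c("a1", "a2")]), c(0.375, 0.25))
  expect_equal(agg$r_dyads, mean(c(0.5, 0.25, 0, 0.5)))
  all_adult <- setNames(rep(TRUE, 4), ids)
  expect_error(aggregate_relatedness(r, mem, "child_to_child", all_adult),
               "empty subset")
})

test_that("population mean relatedness matches hand enumeration", {
  ids <- c("s1", "s2", "x")
  r <- make_r(ids)
  r["s1", "s2"] <- r["s2", "s1"] <- 0.5
  pm <- population_mean_relatedness(r)
  expect_equal(unname(pm$per_individual), c(0.25, 0.25, 0))
  expect_equal(pm$mean, 1 / 6)
  r3 <- make_r(ids, 0.5)
  pm3 <- population_mean_relatedness(r3)
  expect_equal(pm3$mean, 0.5)
  expect_equal(pm3$sd, 0)
  expect_error(population_mean_relatedness(r, ids = "s1"), "at least 2")
})

test_that("kin camp counts scan all camps and honour the inclusivity flag", {
  ids <- c("ego", "sib", "cuz", "far")
  r <- make_r(ids)
  r["ego", "sib"] <- r["sib", "ego"] <- 0.5
  r["ego", "cuz"] <- r["cuz", "ego"] <- 0.125
  mem <- setNames(c("A", "A", "B", "C"), ids)
  expect_equal(kin_camp_count(r, mem, "ego"), 2)
  expect_equal(kin_camp_count(r, mem, "ego", include_own_camp = FALSE), 1)
  expect_equal(kin_camp_count(r, mem, "ego", threshold = 0.25), 1)
  expect_equal(kin_camp_count(r, mem, "far"), 0)   # no kin anywhere
  expect_error(kin_camp_count(r, mem, "nobody"), "unknown ego")
})

test_that("kin camp count equals a brute-force scan on synthetic data", {
  pop <- small_population()
  rec <- pop$pedigree$records
  r <- relatedness_matrix(kinship_matrix(pop$pedigree))
  mem <- pop$panel$memberships
  adults <- rec$id[rec$adult]
  for (ego in adults[1:12]) {
    brute <- sum(vapply(unique(mem), function(cp) {
      any(vapply(setdiff(names(mem)[mem == cp], ego), function(j)
        !is.na(r[ego, j]) && r[ego, j] >= 0.0625, logical(1)))
    }, logical(1)))
    expect_equal(kin_camp_count(r, mem, ego), brute)
  }
})

test_that("household residence options are the union of both kin networks", {
  ids <- c("h", "w", "hk", "wk1", "wk2")
  r <- make_r(ids)
  r["h", "hk"] <- r["hk", "h"] <- 0.5
  r["w", c("wk1", "wk2")] <- r[c("wk1", "wk2"), "w"] <- 0.25
  mem <- setNames(c("A", "A", "B", "B", "C"), ids)
  expect_equal(household_residence_options(r, mem, c("h", "w")), 3)
  # kinless co-resident couple: only their own camp
  r0 <- make_r(c("h", "w"))
  expect_equal(household_residence_options(
    r0, setNames(c("A", "A"), c("h", "w")), c("h", "w")), 1)
})

test_that("camp stability spans its endpoints and matches hand Jaccard", {
  expect_equal(camp_stability(list(c("a", "b"), c("a", "b"), c("b", "a"))), 1)
  expect_equal(camp_stability(list(c("a", "b"), c("c", "d"))), 0)
  expect_equal(camp_stability(list(c("a", "b", "c", "d"),
                                   c("a", "b", "e", "f"))), 2 / 6)
  # invariant to within-visit ordering and duplicated listings
  expect_equal(camp_stability(list(c("d", "c", "b", "a", "a"),
                                   c("f", "e", "b", "a"))), 2 / 6)
  expect_error(camp_stability(list(c("a"))), "fewer than 2")
})

test_that("spouse summary reports consanguinity and signed age gaps", {
  fx <- named_pedigree_fixtures()$first_cousin_spouses
  rec <- fx$pedigree$records[, c("id", "father", "mother", "sex")]
  attrs <- data.frame(id = rec$id, age = NA_real_, spouse = NA_character_,
                      stringsAsFactors = FALSE)
  attrs$spouse[match(c("H", "W"), attrs$id)] <- c("W", "H")
  attrs$age[match(c("H", "W"), attrs$id)] <- c(30, 25)
  ped <- pedigree(rec, attrs)
  r <- relatedness_matrix(kinship_matrix(ped))
  ss <- spouse_summary(ped, r)
  expect_equal(nrow(ss$couples), 1)
  expect_equal(ss$couples$r, 0.125)
  expect_equal(ss$couples$age_gap, 5)
  expect_equal(ss$stats$prop_husband_older, 1)
  expect_equal(ss$stats$n_consanguineous, 1)
})

test_that("synthetic spouse gaps average to the arithmetic-mean oracle", {
  pop <- small_population()
  rec <- pop$pedigree$records
  r <- relatedness_matrix(kinship_matrix(pop$pedigree))
  ss <- spouse_summary(pop$pedigree, r)
  hus <- rec$id[rec$sex == "male" & !is.na(rec$spouse)]
  gaps <- rec$age[match(hus, rec$id)] -
    rec$age[match(rec$spouse[match(hus, rec$id)], rec$id)]
  expect_equal(ss$stats$mean_gap, mean(gaps))
  expect_equal(ss$stats$n_marriages, length(hus))
})
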