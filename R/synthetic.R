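#' Configuration for the synthetic population generator
#'
#' Defaults emulate the descriptive scales of a bilocal immediate-return
#' forager population organised into residential camps: ~15 camps averaging
#' ~18 adults, a genealogy of 4 generations, monogamous marriages mostly
#' between genealogically unrelated partners from different camps, a
#' husband-older spousal age gap of about 4.3 +/- 5.3 years, and repeated
#' camp visits with partial household turnover.
#'
#' @param n_camps number of camps (>= 2, so cross-camp marriage is feasible).
#' @param mean_adults_per_camp target expected number of adults per camp.
#' @param n_generations genealogy depth; the last generation are children.
#' @param dispersal post-marital residence rule: `"bilocal"` (couple settles
#'   in the husband's camp with probability 0.5), `"patrilocal"` (always
#'   husband's), `"matrilocal"` (always wife's), or `"custom"` with
#'   `dispersal_p` = probability of settling on the husband's side.
#' @param dispersal_p probability of husband-side residence when
#'   `dispersal = "custom"`.
#' @param marriage_kin_threshold maximum permitted relatedness between
#'   spouses; the default 0 prohibits any known shared ancestry.
#' @param consanguineous_exception_rate probability that a marriage ignores
#'   the kin prohibition (default 2/80, i.e. rare).
#' @param husband_age_gap_mean,husband_age_gap_sd normal model for husband
#'   age minus wife age, in years.
#' @param mean_offspring Poisson mean number of (surviving) children per
#'   couple; the default 4 gives a generation growth factor of 2, a mean
#'   genealogical depth near 3.3 over four generations, and roughly the
#'   observed adult/child split of a high-fertility forager population.
#' @param generation_interval mean age difference between consecutive
#'   generations, years.
#' @param camp_extent_km side of the square bounding box camps are scattered
#'   in, km.
#' @param centre (lat, lon) of the bounding box centre, decimal degrees.
#' @param n_visits number of repeated visits per camp for the rosters.
#' @param turnover_per_visit probability that a household relocates to a
#'   random other camp between consecutive visits.
#' @param marriage_distance_decay_km `Inf` for a uniform cross-camp marriage
#'   market; a finite value makes partner camps weighted by
#'   exp(-distance / decay), producing kin networks that decay with
#'   distance.
#' @param foraging_range range of the per-camp foraging-proportion
#'   covariate (drawn uniformly).
#' @param seed default integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_camps = 15,
                             mean_adults_per_camp = 18.1,
                             n_generations = 4,
                             dispersal = c("bilocal", "patrilocal",
                                           "matrilocal", "custom"),
                             dispersal_p = 0.5,
                             marriage_kin_threshold = 0,
                             consanguineous_exception_rate = 2 / 80,
                             husband_age_gap_mean = 4.29,
                             husband_age_gap_sd = 5.31,
                             mean_offspring = 4,
                             generation_interval = 25,
                             camp_extent_km = 40,
                             centre = c(lat = 17.06, lon = 122.43),
                             n_visits = 4,
                             turnover_per_visit = 0.25,
                             marriage_distance_decay_km = Inf,
                             foraging_range = c(0.195, 1),
                             seed = 1L) {
  dispersal <- match.arg(dispersal)
  p_husband <- switch(dispersal, bilocal = 0.5, patrilocal = 1,
                      matrilocal = 0, custom = dispersal_p)
  cfg <- list(n_camps = n_camps, mean_adults_per_camp = mean_adults_per_camp,
              n_generations = n_generations, dispersal = dispersal,
              p_husband = p_husband,
              marriage_kin_threshold = marriage_kin_threshold,
              consanguineous_exception_rate = consanguineous_exception_rate,
              husband_age_gap_mean = husband_age_gap_mean,
              husband_age_gap_sd = husband_age_gap_sd,
              mean_offspring = mean_offspring,
              generation_interval = generation_interval,
              camp_extent_km = camp_extent_km, centre = centre,
              n_visits = n_visits, turnover_per_visit = turnover_per_visit,
              marriage_distance_decay_km = marriage_distance_decay_km,
              foraging_range = foraging_range, seed = as.integer(seed))
  probs <- c(cfg$p_husband, cfg$consanguineous_exception_rate,
             cfg$turnover_per_visit)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_camps < 2) stop("cross-camp marriage requires at least 2 camps")
  if (n_generations < 2 || mean_adults_per_camp <= 0 || mean_offspring <= 0) {
    stop("infeasible generator configuration")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic population
#'
#' Forward-simulates a multi-generation genealogy with camp structure.
#' Founder couples are seeded across camps; in each subsequent generation
#' individuals marry partners from other camps subject to the kin-marriage
#' prohibition (with a configurable exception rate), the couple settles on
#' the husband's or wife's side according to the dispersal rule, and
#' offspring counts are Poisson. Ages are assigned top-down by generation
#' with the configured inter-generation interval, the spousal age gap
#' applied to husbands. Visit rosters move whole households (couple plus
#' dependent children) between camps at the turnover rate; camp coordinates
#' are uniform in the bounding box. Fully reproducible given the seed.
#'
#' The founder count is solved from the geometric growth factor
#' (mean_offspring / 2 per generation) so that the expected number of
#' adults per camp matches the configured target.
#'
#' @param cfg a [generator_config].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return List with elements `pedigree` (a [pedigree] with ages, camps,
#'   spouses and adult flags) and `panel` (a [camp_panel] with coordinates,
#'   rosters and covariates).
#' @export
generate_population <- function(cfg = generator_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  G <- cfg$n_generations
  nc <- cfg$n_camps
  camps <- sprintf("C%02d", seq_len(nc))

  # coordinates first: the marriage market may be distance-weighted
  half <- cfg$camp_extent_km / 2
  dlat <- half / 111.1949
  dlon <- half / (111.1949 * cos(cfg$centre[["lat"]] * pi / 180))
  coords <- data.frame(
    camp = camps,
    lat = stats::runif(nc, cfg$centre[["lat"]] - dlat, cfg$centre[["lat"]] + dlat),
    lon = stats::runif(nc, cfg$centre[["lon"]] - dlon, cfg$centre[["lon"]] + dlon),
    stringsAsFactors = FALSE)
  camp_dist <- matrix(0, nc, nc, dimnames = list(camps, camps))
  for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
    d <- haversine_km(c(coords$lat[i], coords$lon[i]),
                      c(coords$lat[j], coords$lon[j]))
    camp_dist[i, j] <- camp_dist[j, i] <- d
  }

  # founder couples: solve expected adults per camp from the growth factor
  growth <- sum((cfg$mean_offspring / 2)^(0:(G - 2)))
  k_couples <- max(nc, round(nc * cfg$mean_adults_per_camp / (2 * growth)))
  founder_camp <- sample(rep_len(camps, k_couples))

  # columnar population tables, grown generation by generation
  sex <- character(0); father <- integer(0); mother <- integer(0)
  gen <- integer(0); camp <- character(0); spouse <- integer(0)
  anc <- list()   # ancestor index sets (self included): kin-prohibition check

  add <- function(s, f, m, g, cp) {
    sex <<- c(sex, s); father <<- c(father, f); mother <<- c(mother, m)
    gen <<- c(gen, g); camp <<- c(camp, cp); spouse <<- c(spouse, NA_integer_)
    i <- length(sex)
    anc[[i]] <<- c(i, if (!is.na(f)) anc[[f]], if (!is.na(m)) anc[[m]])
    i
  }

  for (k in seq_len(k_couples)) {
    h <- add("male", NA_integer_, NA_integer_, 1L, founder_camp[k])
    w <- add("female", NA_integer_, NA_integer_, 1L, founder_camp[k])
    spouse[h] <- w; spouse[w] <- h
  }

  related <- function(i, j) {
    if (cfg$marriage_kin_threshold <= 0) {
      length(intersect(anc[[i]], anc[[j]])) > 0L
    } else {
      # shared-ancestry pairs are screened by actual relatedness
      .pair_relatedness(father, mother, i, j) > cfg$marriage_kin_threshold
    }
  }

  for (g in seq(2L, G)) {
    # reproduction: each couple of generation g-1 has Poisson offspring;
    # cohort sexes are balanced so the marriage market stays symmetric
    parents <- which(gen == g - 1L & sex == "male" & !is.na(spouse))
    born <- integer(0)
    for (h in parents) {
      w <- spouse[h]
      for (b in seq_len(stats::rpois(1L, cfg$mean_offspring))) {
        born <- c(born, add("male", h, w, g, camp[h]))
      }
    }
    nb <- length(born)
    if (nb) {
      half <- c(rep("male", nb %/% 2), rep("female", nb %/% 2),
                if (nb %% 2) sample(c("male", "female"), 1L))
      sex[born] <- sample(half)
    }
    if (g == G) break  # last generation are unmarried children

    # marriage market for generation g
    singles <- which(gen == g)
    for (i in sample(singles)) {
      if (!is.na(spouse[i])) next
      pool <- which(gen == g & is.na(spouse) & sex != sex[i] & camp != camp[i])
      if (!length(pool)) next
      rel <- vapply(pool, function(j) related(i, j), logical(1))
      use_rel <- stats::runif(1) < cfg$consanguineous_exception_rate &&
        any(rel)
      cand <- if (use_rel) pool[rel] else pool[!rel]
      if (!length(cand)) next
      wts <- if (is.finite(cfg$marriage_distance_decay_km)) {
        exp(-camp_dist[cbind(camp[i], camp[cand])] /
              cfg$marriage_distance_decay_km)
      } else rep(1, length(cand))
      j <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = wts)
      spouse[i] <- j; spouse[j] <- i
      h <- if (sex[i] == "male") i else j
      w <- spouse[h]
      newcamp <- if (stats::runif(1) < cfg$p_husband) camp[h] else camp[w]
      camp[h] <- newcamp; camp[w] <- newcamp
    }
  }

  n <- length(sex)
  ids <- sprintf("I%04d", seq_len(n))

  # ages: top-down by generation, spousal gap applied to husbands
  age <- (G - gen) * cfg$generation_interval + stats::rnorm(n, 10, 3)
  hus <- which(sex == "male" & !is.na(spouse))
  age[hus] <- age[spouse[hus]] +
    stats::rnorm(length(hus), cfg$husband_age_gap_mean, cfg$husband_age_gap_sd)
  age <- pmax(age, 0.5)
  adult <- gen < G

  records <- data.frame(id = ids, father = ids[father], mother = ids[mother],
                        sex = sex, stringsAsFactors = FALSE)
  attributes <- data.frame(id = ids, age = age, camp = camp,
                           spouse = ids[spouse], adult = adult,
                           stringsAsFactors = FALSE)
  ped <- pedigree(records, attributes)

  # visit rosters: households (couple + dependent children) move as units
  house <- ifelse(!is.na(spouse), pmin(seq_len(n), spouse), seq_len(n))
  kidp <- which(gen == G)                 # children follow the father's household
  house[kidp] <- house[father[kidp]]
  cur <- camp
  rosters <- stats::setNames(lapply(camps, function(cp) {
    list(ids[cur == cp])
  }), camps)
  for (v in seq_len(cfg$n_visits - 1L)) {
    for (hh in unique(house)) {
      if (stats::runif(1) < cfg$turnover_per_visit) {
        members <- which(house == hh)
        cur[members] <- sample(setdiff(camps, cur[members][1L]), 1L)
      }
    }
    for (cp in camps) {
      rosters[[cp]] <- c(rosters[[cp]], list(ids[cur == cp]))
    }
  }

  covariates <- data.frame(
    camp = camps,
    size = as.integer(table(factor(camp[adult], levels = camps))),
    stability = vapply(rosters, camp_stability, numeric(1)),
    foraging_proportion = stats::runif(nc, cfg$foraging_range[1],
                                       cfg$foraging_range[2]),
    stringsAsFactors = FALSE)

  panel <- camp_panel(stats::setNames(camp, ids), coords, rosters,
                      covariates, ids = ids)
  list(pedigree = ped, panel = panel)
}

# kinship between a single pair by upward recursion on parent indices;
# only used when the marriage rule needs a numeric threshold
.pair_relatedness <- function(father, mother, i, j) {
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (a == b) {
      return(0.5 * (1 + phi(father[a], mother[a])))
    }
    if (a < b) { tmp <- a; a <- b; b <- tmp }  # recurse on the later (younger) index
    0.5 * (phi(father[a], b) + phi(mother[a], b))
  }
  2 * phi(i, j)
}

#' Two-community worked example
#'
#' The canonical illustration of why the three aggregation levels differ:
#' one community of 20 members all pairwise related at r = 0.1 and one of
#' 100 members at r = 0.02 (communities mutually unrelated). Yields
#' r_group = 0.06, r_individual = 1/30 (0.033) and r_dyads = 118/5140
#' (0.023).
#'
#' @return List with `r` (a 120 x 120 [relatedness_matrix]-like matrix with
#'   `NA` diagonal) and `memberships`.
#' @export
worked_example_fixture <- function() {
  ids <- c(sprintf("A%02d", 1:20), sprintf("B%03d", 1:100))
  r <- matrix(0, 120, 120, dimnames = list(ids, ids))
  r[1:20, 1:20] <- 0.1
  r[21:120, 21:120] <- 0.02
  diag(r) <- NA_real_
  class(r) <- c("relatedness_matrix", "matrix", "array")
  list(r = r,
       memberships = stats::setNames(rep(c("A", "B"), c(20, 100)), ids))
}

#' Catalogue of hand-built pedigree fixtures
#'
#' Small pedigrees with textbook relatedness values, each tagged with the
#' focal pair and its expected r (or expected self-kinship phi for the
#' inbred case). Used throughout the test-suite and as worked examples.
#'
#' @return Named list; each element has `pedigree`, `pair`, and either
#'   `expected_r` or `expected_phi`.
#' @export
named_pedigree_fixtures <- function() {
  ped_df <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(id = m[, 1], father = m[, 2], mother = m[, 3], sex = m[, 4],
               stringsAsFactors = FALSE)
  }
  fx <- list()

  fx$trio <- list(
    pedigree = pedigree(ped_df("F", NA, NA, "male",
                               "M", NA, NA, "female",
                               "C", "F", "M", "female")),
    pair = c("F", "C"), expected_r = 0.5)

  fx$full_siblings <- list(
    pedigree = pedigree(ped_df("F", NA, NA, "male",
                               "M", NA, NA, "female",
                               "S1", "F", "M", "male",
                               "S2", "F", "M", "female")),
    pair = c("S1", "S2"), expected_r = 0.5)

  fx$half_siblings <- list(
    pedigree = pedigree(ped_df("F", NA, NA, "male",
                               "M1", NA, NA, "female",
                               "M2", NA, NA, "female",
                               "A", "F", "M1", "male",
                               "B", "F", "M2", "female")),
    pair = c("A", "B"), expected_r = 0.25)

  # grandparental founder couple; their children S1/S2 are full siblings;
  # S1's and S2's children (by unrelated spouses) are first cousins
  cousin_df <- ped_df("GF", NA, NA, "male",
                      "GM", NA, NA, "female",
                      "S1", "GF", "GM", "female",
                      "S2", "GF", "GM", "male",
                      "S1sp", NA, NA, "male",
                      "S2sp", NA, NA, "female",
                      "E", "S1sp", "S1", "male",
                      "C", "S2", "S2sp", "female")
  fx$first_cousins <- list(
    pedigree = pedigree(cousin_df),
    pair = c("E", "C"), expected_r = 0.125)

  # husband's mother and wife's father are full siblings -> spouses are
  # first cousins
  fx$first_cousin_spouses <- list(
    pedigree = pedigree(ped_df("GF", NA, NA, "male",
                               "GM", NA, NA, "female",
                               "HM", "GF", "GM", "female",
                               "WF", "GF", "GM", "male",
                               "HF", NA, NA, "male",
                               "WM", NA, NA, "female",
                               "H", "HF", "HM", "male",
                               "W", "WF", "WM", "female")),
    pair = c("H", "W"), expected_r = 0.125)

  # extend the first-cousin pedigree one generation on each side
  fx$second_cousins <- list(
    pedigree = pedigree(rbind(cousin_df,
                              ped_df("Esp", NA, NA, "female",
                                     "Csp", NA, NA, "male",
                                     "G1", "E", "Esp", "male",
                                     "G2", "Csp", "C", "female"))),
    pair = c("G1", "G2"), expected_r = 0.03125)

  # ego and ego's first cousin's child
  fx$cousins_child <- list(
    pedigree = pedigree(rbind(cousin_df,
                              ped_df("Csp", NA, NA, "male",
                                     "X", "Csp", "C", "female"))),
    pair = c("E", "X"), expected_r = 0.0625)

  # child of a full-sibling mating: F = 0.25, phi(self, self) = 0.625
  fx$inbred_child_self_kinship <- list(
    pedigree = pedigree(ped_df("F", NA, NA, "male",
                               "M", NA, NA, "female",
                               "S1", "F", "M", "male",
                               "S2", "F", "M", "female",
                               "I", "S1", "S2", "male")),
    pair = c("I", "I"), expected_phi = 0.625)

  fx
}

#' Random pedigree for property testing
#'
#' Builds a random overlapping-generation pedigree: the first `n_founders`
#' individuals are founders of alternating sex; each later individual draws
#' its father uniformly from earlier males and its mother from earlier
#' females (so the structure is acyclic by construction and inbred pairs
#' arise naturally).
#'
#' @param n total individuals.
#' @param n_founders number of founders (>= 2, at least one of each sex).
#' @param seed integer seed.
#' @return A [pedigree].
#' @export
random_pedigree <- function(n, n_founders = max(4L, ceiling(n / 4)), seed = 1L) {
  stopifnot(n_founders >= 2L, n >= n_founders)
  set.seed(seed)
  sex <- c(rep_len(c("male", "female"), n_founders),
           sample(c("male", "female"), n - n_founders, replace = TRUE))
  father <- mother <- rep(NA_character_, n)
  ids <- sprintf("R%03d", seq_len(n))
  for (i in seq(n_founders + 1L, length.out = n - n_founders)) {
    males <- which(sex[seq_len(i - 1L)] == "male")
    females <- which(sex[seq_len(i - 1L)] == "female")
    father[i] <- ids[if (length(males) == 1L) males else sample(males, 1L)]
    mother[i] <- ids[if (length(females) == 1L) females else sample(females, 1L)]
  }
  pedigree(data.frame(id = ids, father = father, mother = mother, sex = sex,
                      stringsAsFactors = FALSE))
}
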