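#' Run the full camp-kinship analysis
#'
#' End-to-end pipeline over a genealogy and camp panel: kinship and
#' relatedness matrices, shared reproductive interest, population-wide and
#' campmate means (adults and everyone, with SDs), per-camp summaries with
#' stability and covariates, camp-size and covariate correlations (with
#' partial correlations controlling for camp size), sex permutation tests
#' for mean campmate r and s, age-binned profiles by sex, kin-camp count
#' distributions with a sex permutation test, household residence options,
#' camp-pair relatedness versus distance, and the spouse consanguinity and
#' age-gap summary. Stages whose inputs are missing (e.g. no rosters, no
#' coordinates) are skipped with a notice recorded in the result.
#'
#' @param ped a [pedigree] with attributes (age, camp, spouse, adult).
#' @param panel a [camp_panel] (defaults to one built from the pedigree's
#'   camp column, without coordinates or rosters).
#' @param kin_threshold relatedness threshold for kin-network dispersion
#'   (default 0.0625).
#' @param n_permutations permutations for the sex tests.
#' @param seed integer seed for the permutation tests.
#' @param age_bin_width width of the age bins (years) for the age profiles.
#' @param include_own_camp passed to [kin_camp_count].
#' @param permutation_strata `NULL` for a global label shuffle (default) or
#'   `"camp"` to shuffle within camps.
#' @return List of class `camp_kinship_report`; see Details in the package
#'   vignette. Includes a `manifest` recording seeds, decision flags and
#'   package version.
#' @export
run_full_analysis <- function(ped, panel = NULL, kin_threshold = 0.0625,
                              n_permutations = 10000L, seed = 1L,
                              age_bin_width = 5,
                              include_own_camp = TRUE,
                              permutation_strata = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  rec <- ped$records
  if (is.null(panel)) {
    panel <- camp_panel(stats::setNames(rec$camp, rec$id), ids = rec$id)
  }
  notices <- character(0)
  mem <- panel$memberships[rec$id]
  names(mem) <- rec$id
  adult <- stats::setNames(ifelse(is.na(rec$adult), TRUE, rec$adult), rec$id)
  sexv <- stats::setNames(rec$sex, rec$id)

  kin <- kinship_matrix(ped)
  r <- relatedness_matrix(kin)
  s <- shared_interest_matrix(r, spouse_map(ped))

  adults <- rec$id[adult]
  res <- list()

  # population-wide and campmate means
  res$population <- list(
    adults_r = population_mean_relatedness(r, adults),
    everyone_r = population_mean_relatedness(r, rec$id),
    adults_s = population_mean_relatedness(s, adults))
  agg <- list(
    adults_r = aggregate_relatedness(r, mem, "adults_only", adult),
    everyone_r = aggregate_relatedness(r, mem, "everyone", adult),
    adults_s = aggregate_relatedness(s, mem, "adults_only", adult))
  agg$adult_to_child_r <- tryCatch(
    aggregate_relatedness(r, mem, "adult_to_child", adult),
    error = function(e) NULL)
  agg$child_to_child_r <- tryCatch(
    aggregate_relatedness(r, mem, "child_to_child", adult),
    error = function(e) NULL)
  res$campmates <- agg

  # per-camp table
  pc <- agg$adults_r$per_camp
  names(pc)[names(pc) == "mean_r"] <- "mean_adult_r"
  if (!is.null(panel$covariates)) {
    pc <- merge(pc, panel$covariates[, setdiff(names(panel$covariates), "size"),
                                     drop = FALSE],
                by = "camp", all.x = TRUE)
  }
  res$per_camp <- pc

  # camp-size correlation and covariate (partial) correlations
  res$correlations <- list(
    size_vs_r = correlation(pc$size, pc$mean_adult_r))
  for (v in intersect(c("stability", "foraging_proportion"), names(pc))) {
    ok <- !is.na(pc[[v]])
    if (sum(ok) >= 4) {
      res$correlations[[paste0(v, "_vs_r")]] <-
        correlation(pc[[v]][ok], pc$mean_adult_r[ok])
      res$correlations[[paste0(v, "_vs_r_partial_size")]] <-
        partial_correlation(pc[[v]][ok], pc$mean_adult_r[ok], pc$size[ok])
    } else {
      notices <- c(notices, paste0("too few camps with '", v,
                                   "' for correlation; skipped"))
    }
  }

  # sex differences in mean campmate r and s (adults)
  pi_r <- agg$adults_r$per_individual
  pi_s <- agg$adults_s$per_individual
  strata <- if (identical(permutation_strata, "camp")) mem[names(pi_r)]
  sp_map <- spouse_map(ped)
  res$sex_tests <- list(
    r = permutation_test(pi_r, sexv[names(pi_r)], n_permutations,
                         seed = seed, strata = strata, pairs = sp_map),
    s = permutation_test(pi_s, sexv[names(pi_s)], n_permutations,
                         seed = seed + 1L,
                         strata = if (is.null(strata)) NULL else mem[names(pi_s)],
                         pairs = sp_map))

  # age profiles in 5-year bins by sex
  agev <- stats::setNames(rec$age, rec$id)
  prof <- data.frame(id = names(pi_r), mean_r = unname(pi_r),
                     mean_s = unname(pi_s[names(pi_r)]),
                     sex = unname(sexv[names(pi_r)]),
                     age = unname(agev[names(pi_r)]),
                     stringsAsFactors = FALSE)
  prof <- prof[!is.na(prof$age), ]
  if (nrow(prof)) {
    prof$age_bin <- age_bin_width * (prof$age %/% age_bin_width)
    res$age_profile <- do.call(rbind, lapply(
      split(prof, list(prof$sex, prof$age_bin), drop = TRUE),
      function(d) data.frame(sex = d$sex[1], age_bin = d$age_bin[1],
                             n = nrow(d), mean_r = mean(d$mean_r),
                             mean_s = mean(d$mean_s),
                             stringsAsFactors = FALSE)))
    rownames(res$age_profile) <- NULL
  } else {
    notices <- c(notices, "no ages available; age profile skipped")
  }

  # kin-network dispersion across camps
  kc <- vapply(adults, function(e)
    kin_camp_count(r, mem, e, kin_threshold, include_own_camp), numeric(1))
  res$kin_camps <- list(
    per_adult = kc, mean = mean(kc), sd = stats::sd(kc), range = range(kc),
    threshold = kin_threshold,
    by_sex = tapply(kc, sexv[adults], function(x)
      c(mean = mean(x), sd = stats::sd(x), n = length(x))),
    sex_test = permutation_test(kc, sexv[adults], n_permutations,
                                seed = seed + 2L, pairs = sp_map))

  # household residence options
  hus <- rec$id[rec$sex == "male" & !is.na(rec$spouse)]
  if (length(hus)) {
    ho <- vapply(hus, function(h)
      household_residence_options(r, mem, c(h, rec$spouse[match(h, rec$id)]),
                                  kin_threshold), numeric(1))
    res$household_options <- list(per_household = ho, mean = mean(ho),
                                  sd = stats::sd(ho), range = range(ho))
  } else {
    notices <- c(notices, "no marriages; household residence options skipped")
  }

  # camp-pair relatedness vs distance
  if (!is.null(panel$coordinates)) {
    res$camp_pairs <- camp_pair_analysis(r, mem, panel$coordinates, adult)
  } else {
    notices <- c(notices, "no coordinates; camp-pair distance analysis skipped")
  }

  # spouse consanguinity and age gaps
  res$spouses <- spouse_summary(ped, r)

  res$matrices <- list(kinship = kin, relatedness = r, shared_interest = s)
  res$notices <- notices
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("campkin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    n_permutations = n_permutations,
    kin_threshold = kin_threshold,
    decision_flags = list(
      relatedness = "r = 2*phi (no inbreeding normalisation)",
      aggregation_subsets = "adults_only/everyone/adult_to_child/child_to_child",
      stability = "mean consecutive-visit Jaccard similarity",
      kin_camp_count = if (include_own_camp) "own camp included" else
        "own camp excluded",
      permutation_scheme = paste0(
        "couple-exchangeable (within-couple swap); unmarried shuffled ",
        if (is.null(permutation_strata)) "globally" else "within camps"),
      distance = "haversine great-circle, R = 6371.0088 km"))
  class(res) <- "camp_kinship_report"
  res
}

#' @export
print.camp_kinship_report <- function(x, digits = 3, ...) {
  f <- function(v) format(round(v, digits), nsmall = digits)
  cat("== Camp kinship analysis ==\n")
  cat(sprintf("Population: %d adults of %d individuals, %d camps\n",
              x$population$adults_r$n, x$population$everyone_r$n,
              x$campmates$adults_r$n_groups))
  cat(sprintf("Mean r to all other adults: %s (SD %s)\n",
              f(x$population$adults_r$mean), f(x$population$adults_r$sd)))
  cat(sprintf("Mean r to adult campmates:  %s (SD %s)\n",
              f(x$campmates$adults_r$r_individual),
              f(stats::sd(x$campmates$adults_r$per_individual))))
  cat(sprintf("Mean s to adult campmates:  %s (SD %s)\n",
              f(x$campmates$adults_s$r_individual),
              f(stats::sd(x$campmates$adults_s$per_individual))))
  cat(sprintf("Camp size vs adult relatedness: r = %s, p = %s\n",
              f(x$correlations$size_vs_r$estimate),
              format.pval(x$correlations$size_vs_r$p_value, digits = 3)))
  cat(sprintf("Sex difference in campmate r: diff = %s, p = %s\n",
              f(x$sex_tests$r$observed_difference),
              f(x$sex_tests$r$p_two_tailed)))
  cat(sprintf("Kin (r >= %s) found in %s camps on average (SD %s, range %d-%d)\n",
              format(x$kin_camps$threshold), f(x$kin_camps$mean),
              f(x$kin_camps$sd), x$kin_camps$range[1], x$kin_camps$range[2]))
  if (!is.null(x$household_options)) {
    cat(sprintf("Average household can reside in %s camps (range %d-%d)\n",
                f(x$household_options$mean), x$household_options$range[1],
                x$household_options$range[2]))
  }
  if (!is.null(x$camp_pairs)) {
    cat(sprintf("Camp-pair relatedness vs distance: Spearman r = %s, p = %s (N = %d pairs)\n",
                f(x$camp_pairs$spearman$estimate),
                format.pval(x$camp_pairs$spearman$p_value, digits = 3),
                nrow(x$camp_pairs$pairs)))
  }
  sp <- x$spouses$stats
  if (sp$n_marriages > 0) {
    cat(sprintf("Marriages: %d (%d consanguineous); husband - wife age gap mean %s (SD %s)\n",
                sp$n_marriages, sp$n_consanguineous,
                f(sp$mean_gap), f(sp$sd_gap)))
  }
  for (nt in x$notices) cat("note: ", nt, "\n", sep = "")
  invisible(x)
}

#' @export
summary.camp_kinship_report <- function(object, ...) {
  print(object, ...)
}

#' Write a report bundle to disk
#'
#' Emits the per-camp table, camp-pair table, spouse table, per-adult
#' kin-camp counts, the relatedness matrix (long format) and a JSON run
#' manifest into a directory. All CSV output uses '.' decimals, UTF-8 and
#' Unix newlines.
#'
#' @param report a `camp_kinship_report`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "camp_kinship_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE, eol = "\n")
  wcsv(report$per_camp, "per_camp.csv")
  wcsv(report$spouses$couples, "spouses.csv")
  wcsv(data.frame(id = names(report$kin_camps$per_adult),
                  kin_camps = unname(report$kin_camps$per_adult)),
       "kin_camp_counts.csv")
  if (!is.null(report$camp_pairs)) wcsv(report$camp_pairs$pairs, "camp_pairs.csv")
  if (!is.null(report$age_profile)) wcsv(report$age_profile, "age_profile.csv")
  write_matrix_csv(unclass(report$matrices$relatedness),
                   file.path(dir, "relatedness_long.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
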