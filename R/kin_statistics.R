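#' Shared reproductive interest matrix
#'
#' The shared reproductive interest of ego i in alter j measures how related
#' ego expects to be to alter's future offspring, relative to ego's own:
#' \deqn{s(i,j) = \frac{r_B + r_D}{1 + r_C}}
#' where \eqn{r_B = r(i,j)} is ego's relatedness to the alter,
#' \eqn{r_D = r(i, \mathrm{spouse}(j))} ego's relatedness to the alter's
#' spouse (0 when the alter is unmarried), and
#' \eqn{r_C = r(i, \mathrm{spouse}(i))} ego's relatedness to their own
#' spouse (0 when ego is unmarried). When no one marries a consanguineal
#' relative, s equals r for consanguineal kin but additionally credits
#' affinal ties. The matrix is generally asymmetric. When the alter is
#' married to ego, \eqn{r_D} is ego's self-relatedness, taken as 1.
#'
#' @param r a [relatedness_matrix] (or plain symmetric matrix with id
#'   dimnames and `NA` diagonal).
#' @param spouse_map named character vector id -> spouse id, `NA` for
#'   unmarried; must be mutual.
#' @return Matrix of s values with `NA` diagonal, class
#'   `shared_interest_matrix`.
#' @export
shared_interest_matrix <- function(r, spouse_map) {
  ids <- rownames(r)
  stopifnot(!is.null(ids), identical(ids, colnames(r)))
  spouse_map <- spouse_map[ids]
  names(spouse_map) <- ids
  .check_spouse_map(spouse_map)
  sp_idx <- match(spouse_map, ids)

  rb <- unclass(r)
  diag(rb) <- 0
  rself <- rb
  diag(rself) <- 1            # self-relatedness for the spouse-of-ego cell
  rd <- matrix(0, nrow(r), ncol(r))
  married <- which(!is.na(sp_idx))
  rd[, married] <- rself[, sp_idx[married]]
  rc <- rep(0, length(ids))
  rc[married] <- rb[cbind(married, sp_idx[married])]

  s <- (rb + rd) / (1 + rc)   # (1 + rc) indexed by ego = row
  diag(s) <- NA_real_
  dimnames(s) <- dimnames(r)
  structure(s, class = c("shared_interest_matrix", "matrix", "array"))
}

#' @export
print.shared_interest_matrix <- function(x, ...) {
  v <- c(unclass(x))
  cat("<shared_interest_matrix> ", nrow(x), " individuals; mean s ",
      format(round(mean(v, na.rm = TRUE), 4)), "\n", sep = "")
  invisible(x)
}

.subset_sets <- function(ids, adult, subset) {
  adult <- ifelse(is.na(adult), TRUE, adult)  # unspecified: treat as adult
  switch(subset,
    everyone       = list(a = ids, b = ids, cross = FALSE),
    adults_only    = list(a = ids[adult], b = ids[adult], cross = FALSE),
    child_to_child = list(a = ids[!adult], b = ids[!adult], cross = FALSE),
    adult_to_child = list(a = ids[adult], b = ids[!adult], cross = TRUE),
    stop("unknown subset: ", subset))
}

#' Aggregate within-camp relatedness at three levels
#'
#' Within-group relatedness can be summarised three ways, and they differ
#' whenever group sizes differ: `r_group` averages the mean pairwise
#' relatedness of each camp across camps; `r_individual` averages each
#' individual's mean relatedness to their campmates across individuals;
#' `r_dyads` averages over all co-resident dyads. When larger camps are less
#' closely related (the typical case) `r_dyads < r_individual < r_group`.
#'
#' The `subset` argument selects which dyads count: all members, adults
#' only, children only, or the adult-to-child cross dyads (for which
#' `r_individual` is each adult's mean relatedness to co-resident children).
#' Singleton camps (no valid dyad/alter in the subset) are dropped from
#' `r_group` and their members from `r_individual`.
#'
#' @param r relatedness (or shared-interest) matrix with id dimnames, `NA`
#'   diagonal.
#' @param memberships named character vector id -> camp id.
#' @param subset one of `"adults_only"`, `"everyone"`, `"adult_to_child"`,
#'   `"child_to_child"`.
#' @param adult named logical vector id -> is adult (required for subsets
#'   other than `"everyone"`).
#' @return List of class `aggregation_report`: `r_group`, `r_individual`,
#'   `r_dyads`, counts `n_groups`/`n_individuals`/`n_dyads`, a `per_camp`
#'   data frame (camp, size, mean pairwise value) and `per_individual`
#'   named vector.
#' @export
aggregate_relatedness <- function(r, memberships,
                                  subset = c("adults_only", "everyone",
                                             "adult_to_child", "child_to_child"),
                                  adult = NULL) {
  subset <- match.arg(subset)
  ids <- rownames(r)
  memberships <- memberships[ids]
  names(memberships) <- ids
  if (is.null(adult)) {
    if (subset != "everyone") stop("'adult' flags required for subset ", subset)
    adult <- stats::setNames(rep(TRUE, length(ids)), ids)
  }
  adult <- adult[ids]
  ss <- .subset_sets(ids, adult, subset)
  keep <- !is.na(memberships)
  a <- intersect(ss$a, ids[keep])
  b <- intersect(ss$b, ids[keep])
  if (!length(a) || !length(b)) stop("empty subset '", subset, "'")
  rm_ <- unclass(r)

  camps <- sort(unique(memberships[c(a, b)]))
  per_camp <- data.frame(camp = character(0), size = integer(0),
                         mean_r = numeric(0), stringsAsFactors = FALSE)
  indiv_means <- c()
  dyad_sum <- 0; dyad_n <- 0L
  for (cp in camps) {
    ca <- a[memberships[a] == cp]
    cb <- b[memberships[b] == cp]
    if (ss$cross) {
      if (!length(ca) || !length(cb)) next
      block <- rm_[ca, cb, drop = FALSE]
      m <- rowMeans(block)
      indiv_means <- c(indiv_means, stats::setNames(m, ca))
      per_camp <- rbind(per_camp, data.frame(
        camp = cp, size = length(ca) + length(cb),
        mean_r = mean(block), stringsAsFactors = FALSE))
      dyad_sum <- dyad_sum + sum(block); dyad_n <- dyad_n + length(block)
    } else {
      if (length(ca) < 2L) next
      block <- rm_[ca, ca, drop = FALSE]
      m <- rowMeans(block, na.rm = TRUE)     # NA diagonal excluded
      indiv_means <- c(indiv_means, stats::setNames(m, ca))
      ut <- block[upper.tri(block)]
      per_camp <- rbind(per_camp, data.frame(
        camp = cp, size = length(ca), mean_r = mean(ut),
        stringsAsFactors = FALSE))
      dyad_sum <- dyad_sum + sum(ut); dyad_n <- dyad_n + length(ut)
    }
  }
  if (!nrow(per_camp)) stop("no camp has a valid dyad in subset '", subset, "'")
  structure(list(
    r_group = mean(per_camp$mean_r),
    r_individual = mean(indiv_means),
    r_dyads = dyad_sum / dyad_n,
    n_groups = nrow(per_camp),
    n_individuals = length(indiv_means),
    n_dyads = dyad_n,
    per_camp = per_camp,
    per_individual = indiv_means,
    subset = subset
  ), class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, digits = 3, ...) {
  cat("<aggregation_report> subset: ", x$subset, "\n", sep = "")
  cat(sprintf("  r_group      = %.*f  (N = %d camps)\n", digits, x$r_group, x$n_groups))
  cat(sprintf("  r_individual = %.*f  (N = %d individuals)\n", digits,
              x$r_individual, x$n_individuals))
  cat(sprintf("  r_dyads      = %.*f  (N = %d dyads)\n", digits, x$r_dyads, x$n_dyads))
  invisible(x)
}

#' Population-wide mean relatedness
#'
#' Each individual's mean relatedness to all other members of the subset,
#' then averaged across individuals; the SD is across individuals.
#'
#' @param r relatedness matrix with id dimnames, `NA` diagonal.
#' @param ids subset of ids (default all).
#' @return List with `mean`, `sd`, `per_individual`, `n`.
#' @export
population_mean_relatedness <- function(r, ids = rownames(r)) {
  if (length(ids) < 2L) stop("need at least 2 individuals")
  block <- unclass(r)[ids, ids, drop = FALSE]
  m <- rowMeans(block, na.rm = TRUE)
  list(mean = mean(m), sd = stats::sd(m),
       per_individual = stats::setNames(m, ids), n = length(ids))
}

#' Number of camps in which an ego has consanguineal kin
#'
#' Counts the distinct camps containing at least one individual (other than
#' ego) related to ego at or above the threshold. Ego's own camp is eligible
#' to be counted (it counts when it contains such kin); set
#' `include_own_camp = FALSE` to count only other camps.
#'
#' @param r relatedness matrix.
#' @param memberships named character vector id -> camp id.
#' @param ego id.
#' @param threshold relatedness threshold in (0, 1\]; default 0.0625, the
#'   relatedness of a cousin's child.
#' @param include_own_camp whether ego's own camp may be counted.
#' @return Integer count of camps.
#' @export
kin_camp_count <- function(r, memberships, ego, threshold = 0.0625,
                           include_own_camp = TRUE) {
  ids <- rownames(r)
  if (!ego %in% ids) stop("unknown ego id: ", ego)
  stopifnot(threshold > 0, threshold <= 1)
  memberships <- memberships[ids]
  names(memberships) <- ids
  kin <- ids[!is.na(unclass(r)[ego, ]) & unclass(r)[ego, ] >= threshold]
  camps <- unique(memberships[kin])
  camps <- camps[!is.na(camps)]
  if (!include_own_camp) camps <- setdiff(camps, memberships[ego])
  length(camps)
}

#' Residence options of a household
#'
#' A couple can in principle reside in any camp where either spouse has
#' consanguineal kin at or above the threshold; each spouse's current camp
#' is always available. Returns the size of that union of camps.
#'
#' @param r relatedness matrix.
#' @param memberships named character vector id -> camp id.
#' @param couple character vector of two spouse ids.
#' @param threshold relatedness threshold, default 0.0625.
#' @return Integer count of camps.
#' @export
household_residence_options <- function(r, memberships, couple,
                                        threshold = 0.0625) {
  ids <- rownames(r)
  if (!all(couple %in% ids)) {
    stop("unknown id(s): ", paste(setdiff(couple, ids), collapse = ", "))
  }
  memberships <- memberships[ids]
  names(memberships) <- ids
  rm_ <- unclass(r)
  camps <- character(0)
  for (sp in couple) {
    kin <- ids[!is.na(rm_[sp, ]) & rm_[sp, ] >= threshold]
    camps <- union(camps, memberships[kin])
    camps <- union(camps, memberships[sp])
  }
  length(camps[!is.na(camps)])
}

#' Camp stability index from repeated visit rosters
#'
#' Membership persistence across repeated visits, summarised as the mean
#' Jaccard similarity of consecutive rosters: 1 means identical composition
#' throughout, 0 means complete turnover between every pair of consecutive
#' visits. The index is invariant to roster ordering and member relabeling.
#'
#' @param rosters list of character vectors (member ids), one per visit, in
#'   visit order; at least two visits.
#' @return Stability in \[0, 1\].
#' @export
camp_stability <- function(rosters) {
  if (length(rosters) < 2L) {
    stop("camp stability is undefined with fewer than 2 visits")
  }
  jac <- vapply(seq_len(length(rosters) - 1L), function(k) {
    a <- unique(as.character(rosters[[k]]))
    b <- unique(as.character(rosters[[k + 1L]]))
    u <- length(union(a, b))
    if (u == 0L) return(1)   # two empty rosters: nothing changed
    length(intersect(a, b)) / u
  }, numeric(1))
  mean(jac)
}

#' Spouse consanguinity and age-gap table
#'
#' One row per marriage: the relatedness between the spouses and the signed
#' age gap (husband age minus wife age, positive when the husband is older).
#' Couples with a missing age keep their row (for the consanguinity column)
#' with a missing gap.
#'
#' @param ped a [pedigree] with spouse links (and sexes/ages).
#' @param r relatedness matrix over the pedigree ids.
#' @return List of class `spouse_summary`: `couples` data frame (husband,
#'   wife, r, age_gap) and `stats` (mean/sd/min/max gap, proportion
#'   husband-older, n marriages, n consanguineous).
#' @export
spouse_summary <- function(ped, r) {
  stopifnot(inherits(ped, "pedigree"))
  rec <- ped$records
  rm_ <- unclass(r)
  hus <- rec$id[rec$sex == "male" & !is.na(rec$spouse)]
  couples <- data.frame(husband = hus, wife = rec$spouse[match(hus, rec$id)],
                        stringsAsFactors = FALSE)
  couples$r <- if (nrow(couples)) {
    rm_[cbind(couples$husband, couples$wife)]
  } else numeric(0)
  ha <- rec$age[match(couples$husband, rec$id)]
  wa <- rec$age[match(couples$wife, rec$id)]
  couples$age_gap <- ha - wa
  g <- couples$age_gap[!is.na(couples$age_gap)]
  stats <- list(
    mean_gap = if (length(g)) mean(g) else NA_real_,
    sd_gap = if (length(g) > 1) stats::sd(g) else NA_real_,
    min_gap = if (length(g)) min(g) else NA_real_,
    max_gap = if (length(g)) max(g) else NA_real_,
    prop_husband_older = if (length(g)) mean(g > 0) else NA_real_,
    n_marriages = nrow(couples),
    n_with_ages = length(g),
    n_consanguineous = sum(couples$r > 0, na.rm = TRUE)
  )
  structure(list(couples = couples, stats = stats), class = "spouse_summary")
}

#' @export
print.spouse_summary <- function(x, ...) {
  s <- x$stats
  cat("<spouse_summary> ", s$n_marriages, " marriages, ",
      s$n_consanguineous, " consanguineous\n", sep = "")
  if (!is.na(s$mean_gap)) {
    cat(sprintf("  husband - wife age gap: mean %.2f (SD %.2f), range %.1f to %.1f\n",
                s$mean_gap, s$sd_gap, s$min_gap, s$max_gap))
    cat(sprintf("  husband older in %.0f%% of %d marriages with ages\n",
                100 * s$prop_husband_older, s$n_with_ages))
  }
  invisible(x)
}
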