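#' Two-tailed permutation test for a difference in group means
#'
#' Tests whether the mean of `values` differs between the two label groups.
#' The observed statistic is mean(A) - mean(B); the null distribution is
#' built by randomly reassigning labels, and the two-tailed p-value uses
#' the add-one correction \eqn{p = (b + 1)/(m + 1)} where b counts permuted
#' statistics at least as extreme in absolute value as the observed one.
#'
#' Three randomization schemes are available. The default global shuffle
#' reassigns all labels freely. When `pairs` is supplied (a spouse map),
#' labels are instead swapped within each couple with probability 1/2 and
#' shuffled freely among the unpaired: when the groups are the two sexes
#' and the data contain married couples, each couple contributes exactly
#' one label of each sex while the paired values are typically correlated
#' (often negatively, e.g. one spouse resides natally and one does not), so
#' a free shuffle misstates the null variance; the within-couple swap is
#' the exchangeable randomization for that structure. `strata` restricts
#' the shuffle of unpaired labels to strata such as camps.
#'
#' @param values named numeric vector (one value per individual).
#' @param labels factor/character vector of two levels, aligned with
#'   `values`.
#' @param n_permutations number of label permutations (default 10000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param strata optional vector aligned with `values`; labels are shuffled
#'   within each stratum instead of globally.
#' @param pairs optional named character vector (id -> partner id, `NA` for
#'   unpaired), e.g. [spouse_map()]; pair members must carry opposite
#'   labels.
#' @return List of class `permutation_result`: `observed_difference`,
#'   `p_two_tailed`, `n_permutations`, `seed`, `groups` (labels with sizes),
#'   `scheme`.
#' @export
permutation_test <- function(values, labels, n_permutations = 10000L,
                             seed = 1L, strata = NULL, pairs = NULL) {
  nm <- names(values)
  keep <- !is.na(values) & !is.na(labels)
  values <- as.numeric(values[keep])
  labels <- as.character(labels[keep])
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("need exactly two label groups, got ", length(lev))
  if (!all(table(labels) > 0L)) stop("one label group is empty")
  stopifnot(n_permutations >= 1)
  ia <- labels == lev[1L]
  obs <- mean(values[ia]) - mean(values[!ia])
  if (!is.null(strata)) strata <- as.character(strata[keep])

  # resolve couples: index pairs with both members present, each kept once
  cp <- NULL
  free <- seq_along(values)
  if (!is.null(pairs)) {
    if (is.null(nm)) stop("'pairs' requires named values")
    nm <- nm[keep]
    partner <- match(pairs[nm], nm)
    i <- which(!is.na(partner) & seq_along(partner) < partner)
    if (length(i)) {
      cp <- cbind(i, partner[i])
      if (any(labels[cp[, 1]] == labels[cp[, 2]])) {
        stop("pair members must carry opposite labels")
      }
      free <- setdiff(free, c(cp))
    }
  }

  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(k) {
    lab <- labels
    if (!is.null(cp)) {
      flip <- stats::runif(nrow(cp)) < 0.5
      lab[cp[flip, 1]] <- labels[cp[flip, 2]]
      lab[cp[flip, 2]] <- labels[cp[flip, 1]]
    }
    if (length(free) > 1L) {
      if (is.null(strata)) {
        lab[free] <- sample(lab[free])
      } else {
        for (st in unique(strata[free])) {
          idx <- free[strata[free] == st]
          lab[idx] <- sample(lab[idx])
        }
      }
    }
    pa <- lab == lev[1L]
    mean(values[pa]) - mean(values[!pa])
  }, numeric(1))
  p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_permutations + 1)
  structure(list(
    observed_difference = obs,
    p_two_tailed = p,
    n_permutations = n_permutations,
    seed = seed,
    groups = stats::setNames(as.integer(table(labels)[lev]), lev),
    scheme = paste0(if (!is.null(cp)) "couple-swap + " else "",
                    if (is.null(strata)) "global" else "camp-stratified")
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s vs %s (n = %d, %d)\n",
              names(x$groups)[1], names(x$groups)[2], x$groups[1], x$groups[2]))
  cat(sprintf("  observed difference in means: %.4f\n", x$observed_difference))
  cat(sprintf("  two-tailed p = %.4f (%d permutations, %s shuffle)\n",
              x$p_two_tailed, x$n_permutations, x$scheme))
  invisible(x)
}

#' Pearson or Spearman correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test] with pairwise deletion of missing
#' values and an explicit error on zero variance.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method)
}

#' First-order partial correlation
#'
#' Correlation between x and y with the linear effect of z removed:
#' \deqn{r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' with a two-sided p-value from the t distribution on n - 3 degrees of
#' freedom. Equivalent to correlating the residuals of x on z with the
#' residuals of y on z.
#'
#' @param x,y,z numeric vectors of equal length (>= 4 complete triples).
#' @return List with `estimate`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete triples")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("degenerate: a variable is collinear with the control z")
  }
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tstat <- pr * sqrt((n - 3) / (1 - pr^2))
  list(estimate = pr, p_value = 2 * stats::pt(-abs(tstat), df = n - 3), n = n)
}

#' Great-circle distance between two coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km. At the tens-of-km
#' scale of a municipality the difference from an ellipsoidal geodesic is
#' negligible.
#'
#' @param a,b numeric length-2 vectors `(latitude, longitude)` in decimal
#'   degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(a, b) {
  .check_coord(a); .check_coord(b)
  # geosphere expects (lon, lat); radius in metres
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371008.8) / 1000
}

.check_coord <- function(p) {
  if (length(p) != 2L || anyNA(p)) stop("coordinate must be (lat, lon)")
  if (abs(p[1]) > 90 || abs(p[2]) > 180) {
    stop("coordinate out of range: lat in [-90, 90], lon in [-180, 180]")
  }
  invisible(TRUE)
}

#' Camp-pair relatedness versus distance
#'
#' For every unordered pair of camps, the mean relatedness over all
#' cross-camp adult dyads and the great-circle distance between the camps,
#' plus the Spearman correlation of the two. With k camps the table has
#' choose(k, 2) rows. Camps without coordinates are excluded with a warning.
#'
#' @param r relatedness matrix with id dimnames.
#' @param memberships named character vector id -> camp id.
#' @param coordinates data frame with columns `camp`, `lat`, `lon`.
#' @param adult optional named logical vector; when supplied only adults
#'   enter the cross-camp dyads.
#' @return List of class `camp_pair_analysis`: `pairs` data frame (camp_a,
#'   camp_b, mean_r, distance_km) and `spearman` (from [correlation]).
#' @export
camp_pair_analysis <- function(r, memberships, coordinates, adult = NULL) {
  ids <- rownames(r)
  memberships <- memberships[ids]
  names(memberships) <- ids
  if (!is.null(adult)) {
    adult <- adult[ids]
    ids <- ids[!is.na(adult) & adult]
  }
  camps <- sort(unique(memberships[ids]))
  camps <- camps[!is.na(camps)]
  have_xy <- camps %in% as.character(coordinates$camp)
  if (any(!have_xy)) {
    warning("camp(s) without coordinates excluded: ",
            paste(camps[!have_xy], collapse = ", "))
    camps <- camps[have_xy]
  }
  if (length(camps) < 3L) stop("need at least 3 camps with coordinates")
  ci <- match(camps, as.character(coordinates$camp))
  rm_ <- unclass(r)
  members <- lapply(camps, function(cp) ids[memberships[ids] == cp])
  out <- list(); k <- 0L
  for (i in seq_along(camps)[-length(camps)]) {
    for (j in seq((i + 1L), length(camps))) {
      k <- k + 1L
      out[[k]] <- data.frame(
        camp_a = camps[i], camp_b = camps[j],
        mean_r = mean(rm_[members[[i]], members[[j]], drop = FALSE]),
        distance_km = haversine_km(
          c(coordinates$lat[ci[i]], coordinates$lon[ci[i]]),
          c(coordinates$lat[ci[j]], coordinates$lon[ci[j]])),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  sp <- correlation(pairs$mean_r, pairs$distance_km, method = "spearman")
  structure(list(pairs = pairs, spearman = sp), class = "camp_pair_analysis")
}

#' @export
print.camp_pair_analysis <- function(x, ...) {
  cat("<camp_pair_analysis> ", nrow(x$pairs), " camp pairs\n", sep = "")
  cat(sprintf("  Spearman r = %.3f, p = %.4g\n",
              x$spearman$estimate, x$spearman$p_value))
  invisible(x)
}
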