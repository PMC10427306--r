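#' Camp panel: memberships, coordinates, visit rosters, covariates
#'
#' Grouping structure for all within-camp statistics: a census membership
#' map, camp coordinates, optional repeated visit rosters and optional camp
#' covariates.
#'
#' @param memberships named character vector id -> camp id (`NA` allowed).
#' @param coordinates data frame with columns `camp`, `lat`, `lon`, or NULL.
#' @param rosters named list camp -> list of character vectors (member ids
#'   per visit, in visit order), or NULL.
#' @param covariates data frame with column `camp` and any of
#'   `foraging_proportion`, `stability`, `size`, or NULL.
#' @param ids optional vector of known individual ids; every member id in
#'   memberships or rosters must resolve to it.
#' @return Object of class `camp_panel`.
#' @export
camp_panel <- function(memberships, coordinates = NULL, rosters = NULL,
                       covariates = NULL, ids = NULL) {
  memberships <- stats::setNames(as.character(memberships), names(memberships))
  if (is.null(names(memberships))) stop("memberships must be a named vector")
  if (!is.null(ids)) {
    orphan <- setdiff(names(memberships), ids)
    if (!is.null(rosters)) {
      orphan <- union(orphan, setdiff(unlist(rosters), ids))
    }
    if (length(orphan)) {
      stop("member id(s) not in the population: ",
           paste(utils::head(orphan, 10), collapse = ", "))
    }
  }
  if (!is.null(coordinates)) {
    stopifnot(all(c("camp", "lat", "lon") %in% names(coordinates)))
    apply(coordinates[, c("lat", "lon")], 1, .check_coord)
  }
  if (!is.null(covariates)) {
    stopifnot("camp" %in% names(covariates))
    for (v in intersect(c("foraging_proportion", "stability"), names(covariates))) {
      x <- covariates[[v]]
      if (any(!is.na(x) & (x < 0 | x > 1))) stop(v, " must lie in [0, 1]")
    }
  }
  structure(list(memberships = memberships, coordinates = coordinates,
                 rosters = rosters, covariates = covariates),
            class = "camp_panel")
}

#' @export
print.camp_panel <- function(x, ...) {
  camps <- unique(x$memberships[!is.na(x$memberships)])
  cat("<camp_panel> ", length(camps), " camps, ",
      sum(!is.na(x$memberships)), " resident individuals\n", sep = "")
  if (!is.null(x$rosters)) {
    cat("  visit rosters: ", length(x$rosters[[1]]), " visits\n", sep = "")
  }
  invisible(x)
}

#' Read camp panel files
#'
#' @param attributes_path attribute CSV (id, camp, ...) giving memberships.
#' @param coordinates_path camp coordinate CSV (camp, lat, lon), optional.
#' @param rosters_path visit roster CSV (camp, visit_index, member_id),
#'   optional.
#' @param covariates_path camp covariate CSV (camp, foraging_proportion,
#'   ...), optional.
#' @param ids optional known individual ids for cross-validation.
#' @return A [camp_panel].
#' @export
read_camp_panel <- function(attributes_path, coordinates_path = NULL,
                            rosters_path = NULL, covariates_path = NULL,
                            ids = NULL) {
  at <- utils::read.csv(attributes_path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "camp") %in% names(at)))
  mem <- stats::setNames(.norm_parent(at$camp), as.character(at$id))
  coords <- if (!is.null(coordinates_path)) {
    utils::read.csv(coordinates_path, stringsAsFactors = FALSE)
  }
  rosters <- NULL
  if (!is.null(rosters_path)) {
    rr <- utils::read.csv(rosters_path, stringsAsFactors = FALSE)
    stopifnot(all(c("camp", "visit_index", "member_id") %in% names(rr)))
    rosters <- lapply(split(rr, rr$camp), function(d) {
      lapply(split(as.character(d$member_id), d$visit_index), identity)
    })
  }
  covar <- if (!is.null(covariates_path)) {
    utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  }
  camp_panel(mem, coords, rosters, covar, ids = ids)
}
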