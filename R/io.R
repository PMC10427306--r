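#' Write a (synthetic) population to disk
#'
#' Writes the four delimited-text files consumed by [read_pedigree] and
#' [read_camp_panel]: genealogy CSV (id, father, mother, sex), attribute
#' CSV (id, age, camp, spouse, adult), visit-roster CSV (camp, visit_index,
#' member_id), coordinate CSV (camp, lat, lon) and camp covariate CSV.
#'
#' @param pop list with `pedigree` and `panel`, as returned by
#'   [generate_population].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- pop$pedigree$records
  gen <- rec[, c("id", "father", "mother", "sex")]
  gen$father[is.na(gen$father)] <- "0"
  gen$mother[is.na(gen$mother)] <- "0"
  utils::write.csv(gen, file.path(dir, "genealogy.csv"),
                   row.names = FALSE, eol = "\n")
  utils::write.csv(rec[, c("id", "age", "camp", "spouse", "adult")],
                   file.path(dir, "attributes.csv"),
                   row.names = FALSE, eol = "\n")
  panel <- pop$panel
  if (!is.null(panel$coordinates)) {
    utils::write.csv(panel$coordinates, file.path(dir, "coordinates.csv"),
                     row.names = FALSE, eol = "\n")
  }
  if (!is.null(panel$rosters)) {
    rows <- do.call(rbind, lapply(names(panel$rosters), function(cp) {
      do.call(rbind, lapply(seq_along(panel$rosters[[cp]]), function(v) {
        ms <- panel$rosters[[cp]][[v]]
        if (!length(ms)) return(NULL)
        data.frame(camp = cp, visit_index = v, member_id = ms,
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(rows, file.path(dir, "rosters.csv"),
                     row.names = FALSE, eol = "\n")
  }
  if (!is.null(panel$covariates)) {
    utils::write.csv(panel$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE, eol = "\n")
  }
  invisible(dir)
}

#' Load a population directory written by [write_population]
#'
#' @param dir directory containing `genealogy.csv` and `attributes.csv`
#'   (and optionally `coordinates.csv`, `rosters.csv`, `covariates.csv`).
#' @return List with `pedigree` and `panel`.
#' @export
read_population <- function(dir) {
  opt <- function(f) { p <- file.path(dir, f); if (file.exists(p)) p }
  ped <- read_pedigree(file.path(dir, "genealogy.csv"),
                       file.path(dir, "attributes.csv"))
  panel <- read_camp_panel(file.path(dir, "attributes.csv"),
                           opt("coordinates.csv"), opt("rosters.csv"),
                           opt("covariates.csv"), ids = ped$records$id)
  list(pedigree = ped, panel = panel)
}
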