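#' Construct a validated pedigree
#'
#' Builds a `pedigree` object from a genealogy table, checking structural
#' integrity: every referenced parent resolves to a record of the right sex,
#' the parent relation is acyclic, and spouse links (when supplied) are
#' mutual. Individuals are topologically ordered so that ancestors always
#' precede descendants; this ordering drives the kinship recursion.
#'
#' @param records data frame with columns `id`, `father`, `mother`, `sex`
#'   (`"male"`/`"female"`, abbreviations `m`/`f` and `1`/`2` PED codes are
#'   accepted). Missing parents are encoded `NA`, `""` or `"0"`.
#' @param attributes optional data frame with column `id` and any of `age`,
#'   `camp`, `spouse`, `adult`; merged onto the records.
#' @return An object of class `pedigree`: a list with `records` (normalised
#'   data frame), `father_idx`/`mother_idx` (integer indices, `NA` for
#'   founders on that side), `order` (topological ordering of row indices),
#'   `founders` (ids with both parents missing) and `depth` (per-individual
#'   generation depth, founders = 1).
#' @examples
#' ped <- pedigree(data.frame(id = c("f", "m", "c"),
#'                            father = c(NA, NA, "f"),
#'                            mother = c(NA, NA, "m"),
#'                            sex = c("male", "female", "female")))
#' ped$founders
#' @export
pedigree <- function(records, attributes = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother", "sex")
  if (!all(need %in% names(records))) {
    stop("genealogy table must have columns: ", paste(need, collapse = ", "))
  }
  rec <- data.frame(
    id     = as.character(records$id),
    father = .norm_parent(records$father),
    mother = .norm_parent(records$mother),
    sex    = .norm_sex(records$sex),
    stringsAsFactors = FALSE
  )
  if (anyNA(rec$id) || any(rec$id == "")) stop("missing individual id")
  if (anyDuplicated(rec$id)) {
    stop("duplicate individual ids: ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  }

  fa <- match(rec$father, rec$id)
  mo <- match(rec$mother, rec$id)
  dangling <- c(rec$father[!is.na(rec$father) & is.na(fa)],
                rec$mother[!is.na(rec$mother) & is.na(mo)])
  if (length(dangling)) {
    stop("parent id(s) not found in genealogy: ",
         paste(unique(dangling), collapse = ", "))
  }
  bad_fa <- which(!is.na(fa) & rec$sex[fa] != "male")
  bad_mo <- which(!is.na(mo) & rec$sex[mo] != "female")
  if (length(bad_fa) || length(bad_mo)) {
    stop("parent sex inconsistency for individual(s): ",
         paste(rec$id[union(bad_fa, bad_mo)], collapse = ", "))
  }

  ord <- .topological_order(fa, mo, rec$id)

  depth <- integer(nrow(rec))
  for (i in ord) {
    dp <- c(if (!is.na(fa[i])) depth[fa[i]], if (!is.na(mo[i])) depth[mo[i]])
    depth[i] <- if (length(dp)) max(dp) + 1L else 1L
  }

  rec$age <- NA_real_
  rec$camp <- NA_character_
  rec$spouse <- NA_character_
  rec$adult <- NA
  if (!is.null(attributes)) {
    attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
    if (!"id" %in% names(attributes)) stop("attribute table must have an 'id' column")
    j <- match(rec$id, as.character(attributes$id))
    if ("age" %in% names(attributes))  rec$age  <- as.numeric(attributes$age)[j]
    if ("camp" %in% names(attributes)) rec$camp <- .norm_parent(attributes$camp)[j]
    if ("spouse" %in% names(attributes)) rec$spouse <- .norm_parent(attributes$spouse)[j]
    if ("adult" %in% names(attributes)) rec$adult <- as.logical(attributes$adult)[j]
    .check_spouse_map(stats::setNames(rec$spouse, rec$id))
    sp <- rec$spouse[!is.na(rec$spouse)]
    if (any(is.na(match(sp, rec$id)))) {
      stop("spouse id(s) not found in genealogy: ",
           paste(setdiff(sp, rec$id), collapse = ", "))
    }
    if (any(!is.na(rec$age) & rec$age < 0)) stop("negative age")
  }

  structure(list(records = rec, father_idx = fa, mother_idx = mo,
                 order = ord, founders = rec$id[is.na(fa) & is.na(mo)],
                 depth = depth),
            class = "pedigree")
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

.norm_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  if (anyNA(out)) stop("unrecognised sex code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

.check_spouse_map <- function(spouse_map) {
  sp <- spouse_map[!is.na(spouse_map)]
  back <- spouse_map[sp]
  bad <- names(sp)[is.na(back) | back != names(sp)]
  if (length(bad)) {
    stop("spouse links are not mutual for: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Kahn's algorithm on the parent -> child relation; reports a cycle member
# on failure (self-parenthood is the degenerate cycle of length 1).
.topological_order <- function(fa, mo, ids) {
  n <- length(ids)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving individual '",
         ids[setdiff(seq_len(n), ord)[1L]], "'")
  }
  ord
}

#' Read a genealogy file into a pedigree
#'
#' Reads a PED-like delimited text file (comma or whitespace separated, with
#' header) with columns `id`, `father`, `mother`, `sex`; missing parents are
#' `"0"` or empty. An optional attribute CSV (columns `id`, `age`, `camp`,
#' `spouse`, `adult`) is merged.
#'
#' @param path genealogy file path.
#' @param attributes_path optional attribute CSV path.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, attributes_path = NULL) {
  if (!file.exists(path)) stop("genealogy file not found: ", path)
  first <- readLines(path, n = 1L)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  attrs <- NULL
  if (!is.null(attributes_path)) {
    if (!file.exists(attributes_path)) {
      stop("attribute file not found: ", attributes_path)
    }
    attrs <- utils::read.csv(attributes_path, stringsAsFactors = FALSE)
  }
  pedigree(df, attrs)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x$records), " individuals, ",
      length(x$founders), " founders\n", sep = "")
  cat("  generational depth: mean ", round(mean(x$depth), 2),
      ", max ", max(x$depth), "\n", sep = "")
  nm <- sum(!is.na(x$records$spouse)) / 2
  if (nm > 0) cat("  marriages: ", nm, "\n", sep = "")
  invisible(x)
}

#' Spouse map of a pedigree
#'
#' @param ped a [pedigree].
#' @return Named character vector mapping each id to its spouse id (`NA` when
#'   unmarried).
#' @export
spouse_map <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$records$spouse, ped$records$id)
}

#' Kinship matrix by the recursive (tabular) method
#'
#' Computes the kinship coefficient phi(i, j) — the probability that a random
#' allele drawn from i and one drawn from j at the same locus are identical
#' by descent — for every pair in the pedigree, by dynamic programming over
#' the topological order: for non-founder i and any j that is not a
#' descendant of i,
#' \deqn{\phi(i,j) = \tfrac12[\phi(f_i, j) + \phi(m_i, j)]}
#' with missing parents contributing 0, and
#' \deqn{\phi(i,i) = \tfrac12 (1 + F_i), \quad F_i = \phi(f_i, m_i).}
#' Each entry is computed exactly once.
#'
#' @param ped a [pedigree].
#' @return An object of class `kinship_matrix`: list with `ids`, symmetric
#'   matrix `phi`, and per-individual inbreeding coefficients `F`.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped$records)
  fa <- ped$father_idx
  mo <- ped$mother_idx
  phi <- matrix(0, n, n, dimnames = list(ped$records$id, ped$records$id))
  Fcoef <- numeric(n)
  done <- integer(0)
  for (i in ped$order) {
    if (length(done)) {
      pf <- if (is.na(fa[i])) 0 else phi[fa[i], done]
      pm <- if (is.na(mo[i])) 0 else phi[mo[i], done]
      v <- (pf + pm) / 2
      phi[i, done] <- v
      phi[done, i] <- v
    }
    Fcoef[i] <- if (is.na(fa[i]) || is.na(mo[i])) 0 else phi[fa[i], mo[i]]
    phi[i, i] <- (1 + Fcoef[i]) / 2
    done <- c(done, i)
  }
  structure(list(ids = ped$records$id, phi = phi,
                 F = stats::setNames(Fcoef, ped$records$id)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", length(x$ids), " individuals; ",
      sum(x$F > 0), " inbred\n", sep = "")
  invisible(x)
}

#' Wright's coefficient of relatedness from a kinship matrix
#'
#' Returns the pairwise relatedness matrix r(i, j) = 2 phi(i, j). The
#' population this toolkit targets is essentially outbred, so the plain
#' doubling is the default; set `inbreeding_adjust = TRUE` for the normalised
#' form \eqn{2\phi_{ij} / \sqrt{(1+F_i)(1+F_j)}}. The diagonal is set to
#' `NA` — self-relatedness is never a co-residence dyad, and a sentinel that
#' poisons any accidental inclusion is safer than a silently absorbed 1.
#'
#' @param k a [kinship_matrix].
#' @param inbreeding_adjust normalise by parental inbreeding (default FALSE).
#' @return A symmetric numeric matrix with id dimnames, class
#'   `relatedness_matrix`, diagonal `NA`.
#' @export
relatedness_matrix <- function(k, inbreeding_adjust = FALSE) {
  stopifnot(inherits(k, "kinship_matrix"))
  r <- 2 * k$phi
  if (inbreeding_adjust) {
    w <- sqrt(1 + k$F)
    r <- r / outer(w, w)
  }
  diag(r) <- NA_real_
  class(r) <- c("relatedness_matrix", class(r))
  r
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat("<relatedness_matrix> ", nrow(x), " individuals; mean pairwise r ",
      format(round(mean(v), 4)), "\n", sep = "")
  invisible(x)
}

#' Gene-dropping Monte Carlo estimate of a kinship coefficient
#'
#' Independent oracle for the kinship recursion: founders receive unique
#' allele pairs, every non-founder inherits one uniformly random allele from
#' each parent per replicate (a missing parent contributes a private allele
#' that can never be identical by descent with anything else), and the
#' estimate is the frequency across replicates with which one allele drawn
#' at random from each member of the pair is identical by descent. This is
#' an unbiased binomial estimator of phi with standard error
#' sqrt(phi (1 - phi) / n_reps).
#'
#' @param ped a [pedigree].
#' @param pair character vector of two ids.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed.
#' @return Estimated kinship coefficient in \[0, 1\].
#' @export
gene_drop_ibd <- function(ped, pair, n_reps = 100000L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), n_reps >= 1)
  est <- gene_drop_kinship(ped, matrix(pair, nrow = 1), n_reps, seed)
  unname(est[1L])
}

#' Gene-dropping estimates for several pairs from shared replicates
#'
#' Same simulation as [gene_drop_ibd] but all pairs are evaluated against one
#' set of dropped genomes, so the per-replicate cost is paid once.
#'
#' @param ped a [pedigree].
#' @param pairs 2-column matrix (or data frame) of ids.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return Numeric vector of estimated kinship coefficients, one per row.
#' @export
gene_drop_kinship <- function(ped, pairs, n_reps = 100000L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  pairs <- as.matrix(pairs)
  ia <- match(as.character(pairs[, 1]), ped$records$id)
  ib <- match(as.character(pairs[, 2]), ped$records$id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("unknown id(s): ",
         paste(unique(c(pairs[, 1][is.na(ia)], pairs[, 2][is.na(ib)])),
               collapse = ", "))
  }
  n <- nrow(ped$records)
  fa <- ped$father_idx
  mo <- ped$mother_idx
  set.seed(seed)
  # allele codes: founders 2i-1 / 2i; phantom parents of i get 2n+i / 3n+i
  a1 <- matrix(0L, n, n_reps)
  a2 <- matrix(0L, n, n_reps)
  for (i in ped$order) {
    a1[i, ] <- if (is.na(fa[i])) {
      if (is.na(mo[i])) rep.int(2L * i - 1L, n_reps) else rep.int(2L * n + i, n_reps)
    } else {
      pick <- stats::runif(n_reps) < 0.5
      x <- a2[fa[i], ]; x[pick] <- a1[fa[i], pick]; x
    }
    a2[i, ] <- if (is.na(mo[i])) {
      if (is.na(fa[i])) rep.int(2L * i, n_reps) else rep.int(3L * n + i, n_reps)
    } else {
      pick <- stats::runif(n_reps) < 0.5
      x <- a2[mo[i], ]; x[pick] <- a1[mo[i], pick]; x
    }
  }
  est <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pa <- stats::runif(n_reps) < 0.5
    pb <- stats::runif(n_reps) < 0.5
    xa <- a2[ia[k], ]; xa[pa] <- a1[ia[k], pa]
    xb <- a2[ib[k], ]; xb[pb] <- a1[ib[k], pb]
    est[k] <- mean(xa == xb)
  }
  est
}

#' Export a pairwise matrix to CSV
#'
#' @param m square matrix with id dimnames (kinship phi or relatedness r).
#' @param path output file.
#' @param format `"long"` (columns id_a, id_b, value; upper triangle) or
#'   `"square"` (id header row and column).
#' @export
write_matrix_csv <- function(m, path, format = c("long", "square")) {
  format <- match.arg(format)
  if (inherits(m, "kinship_matrix")) m <- m$phi
  if (format == "square") {
    utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  } else {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(id_a = rownames(m)[ut[, 1]],
                     id_b = colnames(m)[ut[, 2]],
                     value = m[ut])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
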