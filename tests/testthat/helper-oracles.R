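# Independent oracles, deliberately naive: plain double loops and
# recursions that share no code with the package internals.

# longest ancestor path, by direct recursion on the raw table
oracle_depth <- function(records) {
  ids <- records$id
  fa <- match(records$father, ids)
  mo <- match(records$mother, ids)
  depth1 <- function(i) {
    d <- 1L
    for (p in c(fa[i], mo[i])) if (!is.na(p)) d <- max(d, 1L + depth1(p))
    d
  }
  vapply(seq_along(ids), depth1, integer(1))
}

# all three aggregation levels by explicit double loops
oracle_aggregate <- function(r, mem, ids) {
  camps <- unique(mem[ids])
  camp_means <- c()
  indiv_means <- c()
  dyad_vals <- c()
  for (cp in camps) {
    members <- ids[mem[ids] == cp]
    if (length(members) < 2) next
    vals <- c()
    for (i in seq_along(members)) {
      row <- c()
      for (j in seq_along(members)) {
        if (i == j) next
        row <- c(row, r[members[i], members[j]])
        if (i < j) vals <- c(vals, r[members[i], members[j]])
      }
      indiv_means <- c(indiv_means, mean(row))
    }
    camp_means <- c(camp_means, mean(vals))
    dyad_vals <- c(dyad_vals, vals)
  }
  list(r_group = mean(camp_means), r_individual = mean(indiv_means),
       r_dyads = mean(dyad_vals), n_dyads = length(dyad_vals))
}

# exhaustive two-group permutation p-value (feasible for n <= 10)
oracle_exhaustive_perm <- function(values, labels) {
  lev <- sort(unique(labels))
  na <- sum(labels == lev[1])
  obs <- mean(values[labels == lev[1]]) - mean(values[labels != lev[1]])
  idx <- utils::combn(length(values), na)
  diffs <- apply(idx, 2, function(a)
    mean(values[a]) - mean(values[-a]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# standard small synthetic population shared across tests
small_population <- function(seed = 11) {
  generate_population(
    generator_config(n_camps = 5, mean_adults_per_camp = 8,
                     n_generations = 3, n_visits = 3),
    seed = seed)
}
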