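# Independent oracles used across tests. These deliberately use different
# algorithms/data structures than the package implementation.

# Brute-force single-shortcut distance matrix: direct evaluation of
# min(|i-j|, |i-a|+1+|b-j|, |i-b|+1+|a-j|) over all contacts.
oracle_shortcut_distances <- function(n, contacts) {
  idx <- seq_len(n)
  D <- abs(outer(idx, idx, "-"))
  if (nrow(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      a <- contacts[r, 1]; b <- contacts[r, 2]
      ia <- abs(idx - a); ib <- abs(idx - b)
      f <- pmin(outer(ia, ib, "+"), outer(ib, ia, "+")) + 1
      D <- pmin(D, f)
    }
  }
  diag(D) <- 0L
  storage.mode(D) <- "integer"
  D
}

# Union-find component sizes of the bound-site contact subgraph.
oracle_component_sizes <- function(bound, contacts) {
  ids <- which(bound)
  if (!length(ids)) return(integer())
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  pos <- integer(max(c(ids, 1L))); pos[ids] <- seq_along(ids)
  if (nrow(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      a <- contacts[r, 1]; b <- contacts[r, 2]
      if (bound[a] && bound[b]) {
        ra <- find(pos[a]); rb <- find(pos[b])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  as.integer(table(roots))
}

# Random valid lattice_state with contacts respecting the valence cap.
random_state <- function(n, n_try_contacts = 8, n_val = 5) {
  st <- lattice_state(n, sample(c(TRUE, FALSE), n, replace = TRUE),
                      methylated = sample(c(TRUE, FALSE), n, replace = TRUE),
                      hp1_bound = sample(c(TRUE, FALSE), n, replace = TRUE),
                      n_val = n_val)
  for (k in seq_len(n_try_contacts)) {
    ij <- sample(n, 2)
    st2 <- try(add_contact(st, ij[1], ij[2], n_val = n_val), silent = TRUE)
    if (!inherits(st2, "try-error")) st <- st2
  }
  st
}

# Hand-constructed trajectory object (bypasses the engine) for exact
# observable tests.
fake_trajectory <- function(times, methylated, bound, contacts = NULL,
                            replicate = 1L, condition = "control") {
  if (is.null(contacts))
    contacts <- rep(list(matrix(integer(), ncol = 2)), length(times))
  structure(list(times = times, methylated = methylated, bound = bound,
                 contacts = contacts, replicate = replicate,
                 condition = condition),
            class = "hp1_trajectory")
}

# Engine-side propensity totals recomputed from scratch (exposed C++ path).
engine_breakdown <- function(state, params, spread_fiber = FALSE) {
  plist <- unclass(params)
  plist$spread_fiber <- spread_fiber
  hp1sim:::propensity_breakdown_cpp(
    state$n_sites, as.integer(state$binding_site),
    as.integer(state$methylated), as.integer(state$hp1_bound),
    state$contacts - 1L, plist)
}
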