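#' Effective distance between two lattice units
#'
#' The contact-formation rate between units i and j is
#' `k_c / L_ij^alpha`, where `L_ij` is the minimum number of links — along
#' the chromatin fibre or through space — connecting the two units. For
#' speed the model approximates `L_ij` by allowing at most a *single*
#' spatial contact to shortcut the genomic distance:
#'
#' `L_ij = min(|i - j|, min over contacts (a,b) of
#'             |i - a| + 1 + |b - j|, |i - b| + 1 + |a - j|)`
#'
#' This deliberately differs from a full shortest-path (BFS) distance on
#' the link graph, which could chain several contacts.
#'
#' @param i,j 1-based site indices, `i != j` (vectorised over pairs of
#'   equal length).
#' @param contacts two-column matrix of 1-based contact pairs (or a
#'   [lattice_state()], whose contact set is used).
#' @return Integer vector of effective distances (>= 1).
#' @examples
#' effective_distance(4, 18, matrix(integer(), ncol = 2))  # 14
#' effective_distance(3, 10, rbind(c(1, 11)))              # 4
#' @export
effective_distance <- function(i, j, contacts) {
  if (inherits(contacts, "lattice_state")) contacts <- contacts$contacts
  contacts <- matrix(as.integer(contacts), ncol = 2)
  if (length(i) != length(j)) stop("'i' and 'j' must have equal length")
  if (any(i == j)) stop("effective distance undefined for i == j")
  vapply(seq_along(i), function(k) {
    d <- abs(i[k] - j[k])
    if (nrow(contacts)) {
      a <- contacts[, 1]; b <- contacts[, 2]
      d <- min(d,
               abs(i[k] - a) + 1L + abs(b - j[k]),
               abs(i[k] - b) + 1L + abs(a - j[k]))
    }
    as.integer(d)
  }, integer(1))
}

#' Enumerate all eligible stochastic events and their propensities
#'
#' The reference enumeration of the model's nine event classes on a given
#' state. It defines the contract the simulation engine implements:
#'
#' 1. methylation of each unmethylated site at `k_m`;
#' 2. demethylation of each methylated, HP1-free site at `k_d`;
#' 3. HP1 binding at each unbound site at `k_b`;
#' 4. HP1 unbinding at `k_u` from each bound binding site with no contact;
#' 5. HP1 unbinding at `k_y` from each bound non-binding site with no contact;
#' 6. methylation spreading at `k_n` from each methylated+bound site to each
#'    unmethylated site in contact with it;
#' 7. contact formation for each non-contacting pair with both endpoints
#'    below the valence cap, at `k_c / L_ij^alpha`, where `L_ij` is the
#'    [effective_distance()] (or the plain genomic distance when
#'    `params$formation_distance == "genomic"`);
#' 8. breaking of each contact whose endpoints are both methylated and
#'    bound, at `k_w`;
#' 9. breaking of every other contact at `k_z`.
#'
#' Under `coupling_mode = "binding_only"` rules 4-5 use `k_u` on methylated
#' and `k_y` on unmethylated sites (ignoring binding-site status) and every
#' contact breaks at `k_z` (rule 8 never fires).
#'
#' Events with zero propensity are omitted. This function is O(n^2) per
#' call and intended for small systems, oracles and tests; production runs
#' use the compiled engine in [hp1_simulate()].
#'
#' @param state a [lattice_state()].
#' @param params a [rate_params()].
#' @param spread_fiber if `TRUE`, rule 6 additionally spreads to the fibre
#'   neighbours i-1 and i+1 (off by default; spreading is across spatial
#'   contacts only).
#' @return A data frame with columns `kind` (event class), `i`, `j` (site
#'   indices; `j` is `NA` for single-site events) and `propensity`.
#' @export
enumerate_propensities <- function(state, params, spread_fiber = FALSE) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "rate_params"))
  n <- state$n_sites
  meth <- state$methylated; bound <- state$hp1_bound
  bsite <- state$binding_site
  con <- state$contacts
  deg <- tabulate(c(con[, 1], con[, 2]), nbins = n)
  binding_only <- params$coupling_mode == "binding_only"

  ev <- list()
  emit <- function(kind, i, j, rate) {
    if (length(i))
      ev[[length(ev) + 1L]] <<- data.frame(
        kind = kind, i = as.integer(i), j = as.integer(j),
        propensity = rate)
  }

  if (params$k_m > 0) emit("methylate", which(!meth), NA, params$k_m)
  if (params$k_d > 0) emit("demethylate", which(meth & !bound), NA, params$k_d)
  if (params$k_b > 0) emit("bind", which(!bound), NA, params$k_b)
  free <- deg == 0L
  if (binding_only) {
    if (params$k_u > 0)
      emit("unbind_site", which(bound & meth & free), NA, params$k_u)
    if (params$k_y > 0)
      emit("unbind_nonsite", which(bound & !meth & free), NA, params$k_y)
  } else {
    if (params$k_u > 0)
      emit("unbind_site", which(bound & bsite & free), NA, params$k_u)
    if (params$k_y > 0)
      emit("unbind_nonsite", which(bound & !bsite & free), NA, params$k_y)
  }

  # rule 6: spreading from methylated+bound donors to unmethylated acceptors
  if (params$k_n > 0) {
    donors <- meth & bound
    if (nrow(con)) {
      for (r in seq_len(nrow(con))) {
        a <- con[r, 1]; b <- con[r, 2]
        if (donors[a] && !meth[b]) emit("spread", a, b, params$k_n)
        if (donors[b] && !meth[a]) emit("spread", b, a, params$k_n)
      }
    }
    if (spread_fiber) {
      for (a in which(donors)) {
        for (b in c(a - 1L, a + 1L)) {
          if (b >= 1L && b <= n && !meth[b]) emit("spread", a, b, params$k_n)
        }
      }
    }
  }

  # rule 7: contact formation over non-contacting, valence-free pairs
  if (params$k_c > 0 && n >= 2L) {
    has_con <- matrix(FALSE, n, n)
    if (nrow(con)) has_con[con] <- TRUE
    for (a in seq_len(n - 1L)) {
      if (deg[a] >= params$n_val) next
      for (b in seq.int(a + 1L, n)) {
        if (deg[b] >= params$n_val || has_con[a, b]) next
        L <- if (params$formation_distance == "genomic") b - a
             else effective_distance(a, b, con)
        emit("form_contact", a, b, params$k_c / L^params$alpha)
      }
    }
  }

  # rules 8-9: contact breaking
  if (nrow(con)) {
    both_mb <- meth[con[, 1]] & bound[con[, 1]] &
               meth[con[, 2]] & bound[con[, 2]]
    if (binding_only) both_mb <- rep(FALSE, nrow(con))
    if (params$k_w > 0)
      emit("break_contact_slow", con[both_mb, 1], con[both_mb, 2], params$k_w)
    if (params$k_z > 0)
      emit("break_contact_fast", con[!both_mb, 1], con[!both_mb, 2],
           params$k_z)
  }

  if (!length(ev))
    return(data.frame(kind = character(), i = integer(), j = integer(),
                      propensity = numeric()))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}
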