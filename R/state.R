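#' Lattice simulation state
#'
#' The discrete state of the model: per-site H3K9-methylation and
#' HP1-occupancy flags, the fixed binding-site annotation, and the set of
#' spatial contacts. Contacts are unordered site pairs stored once in
#' canonical `i < j` order; no self-contacts are allowed and each site may
#' hold at most `n_val` contacts.
#'
#' @param n_sites number of lattice units.
#' @param binding_site logical mask of HP1 binding sites (length `n_sites`).
#' @param methylated,hp1_bound logical per-site flags (default all `FALSE`).
#' @param contacts two-column integer matrix of 1-based site pairs
#'   (zero rows allowed).
#' @param n_val valence cap used to validate `contacts`.
#' @return An object of class `"lattice_state"`.
#' @export
lattice_state <- function(n_sites, binding_site,
                          methylated = logical(n_sites),
                          hp1_bound = logical(n_sites),
                          contacts = matrix(integer(), ncol = 2),
                          n_val = 5L) {
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 0L) stop("'n_sites' must be >= 0")
  for (nm in c("binding_site", "methylated", "hp1_bound")) {
    v <- get(nm)
    if (!is.logical(v) || length(v) != n_sites || anyNA(v))
      stop("'", nm, "' must be a logical vector of length ", n_sites)
  }
  contacts <- canonical_contacts(contacts, n_sites, n_val)
  structure(list(n_sites = n_sites, methylated = methylated,
                 hp1_bound = hp1_bound, binding_site = binding_site,
                 contacts = contacts),
            class = "lattice_state")
}

# Canonicalise and validate a contact matrix: i < j per row, unique rows,
# indices in range, per-site degree <= n_val.
canonical_contacts <- function(contacts, n_sites, n_val) {
  contacts <- matrix(as.integer(contacts), ncol = 2)
  if (nrow(contacts) == 0L) {
    dimnames(contacts) <- list(NULL, c("i", "j"))
    return(contacts)
  }
  if (anyNA(contacts) || any(contacts < 1L) || any(contacts > n_sites))
    stop("contact indices must lie in [1, n_sites]")
  if (any(contacts[, 1] == contacts[, 2]))
    stop("self-contacts (i,i) are not allowed")
  contacts <- cbind(i = pmin(contacts[, 1], contacts[, 2]),
                    j = pmax(contacts[, 1], contacts[, 2]))
  if (anyDuplicated(paste(contacts[, 1], contacts[, 2])))
    stop("duplicate contacts")
  deg <- tabulate(c(contacts[, 1], contacts[, 2]), nbins = n_sites)
  if (any(deg > n_val))
    stop("valence cap exceeded: a site holds more than ", n_val, " contacts")
  contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
}

#' Initial condition of a simulation
#'
#' At time zero all sites are free of HP1 and there are no contacts. In the
#' control condition the HP1 binding sites start methylated; in the TM
#' (triple-mutant, no H3K9 methyltransferase) condition no site is
#' methylated initially.
#'
#' @param n_sites number of lattice units.
#' @param binding_sites logical binding-site mask of length `n_sites`.
#' @param condition `"control"` or `"TM"`.
#' @return A [lattice_state()] with no HP1 bound and no contacts.
#' @export
init_state <- function(n_sites, binding_sites,
                       condition = c("control", "TM")) {
  condition <- match.arg(condition)
  n_sites <- as.integer(n_sites)
  if (length(binding_sites) != n_sites)
    stop("'binding_sites' must have length n_sites (", n_sites, ")")
  meth <- if (condition == "control") as.logical(binding_sites)
          else logical(n_sites)
  lattice_state(n_sites, as.logical(binding_sites), methylated = meth)
}

#' Add or remove a contact, preserving state invariants
#'
#' @param state a [lattice_state()].
#' @param i,j 1-based site indices (order irrelevant).
#' @param n_val valence cap enforced on addition.
#' @return The mutated state.
#' @export
add_contact <- function(state, i, j, n_val = 5L) {
  stopifnot(inherits(state, "lattice_state"))
  state$contacts <- canonical_contacts(rbind(state$contacts, c(i, j)),
                                       state$n_sites, n_val)
  state
}

#' @rdname add_contact
#' @export
remove_contact <- function(state, i, j) {
  stopifnot(inherits(state, "lattice_state"))
  a <- min(i, j); b <- max(i, j)
  hit <- state$contacts[, 1] == a & state$contacts[, 2] == b
  if (!any(hit)) stop("contact (", a, ",", b, ") not present")
  state$contacts <- state$contacts[!hit, , drop = FALSE]
  state
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(
    "<lattice_state> %d sites: %d methylated, %d HP1-bound, %d binding sites, %d contacts\n",
    x$n_sites, sum(x$methylated), sum(x$hp1_bound), sum(x$binding_site),
    nrow(x$contacts)))
  invisible(x)
}
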