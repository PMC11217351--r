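#' Kinetic rate parameters of the HP1/H3K9me lattice model
#'
#' Constructs the full parameter set of the stochastic model. The defaults
#' are the fitted values of the published model, already rescaled to
#' min^-1 (the rescaling factor 0.34 min^-1 is carried as metadata in
#' `time_rescale`). Rates:
#'
#' \describe{
#'   \item{k_m}{random (noisy) H3K9 methylation of any unmethylated site.}
#'   \item{k_d}{demethylation of a methylated site not bound by HP1.}
#'   \item{k_b}{HP1 binding to any unbound site.}
#'   \item{k_u}{HP1 unbinding from a *binding site* with no spatial contact.}
#'   \item{k_y}{HP1 unbinding from a non-binding site with no spatial contact.}
#'   \item{k_n}{methylation spreading from a methylated+HP1-bound site to each
#'     unmethylated site it contacts.}
#'   \item{k_c}{contact-formation prefactor; a pair (i,j) forms a contact at
#'     rate `k_c / L_ij^alpha`, where `L_ij` is the effective distance (see
#'     [effective_distance()]).}
#'   \item{k_w}{breaking of a contact whose two endpoints are both methylated
#'     and HP1-bound (the stabilised, "bridged" state).}
#'   \item{k_z}{breaking of any other contact.}
#' }
#'
#' `coupling_mode` selects the main model (`"bridging"`: methylation
#' stabilises HP1-HP1 contacts via k_w) or the rejected alternative
#' (`"binding_only"`: methylation gates only HP1 residence — unbinding uses
#' `k_u` on methylated and `k_y` on unmethylated sites irrespective of
#' binding-site status, and every contact breaks at `k_z`). No refitted
#' rates are published for the alternative, so the defaults are reused and
#' can be overridden.
#'
#' @param k_m,k_d,k_b,k_u,k_y,k_n,k_c,k_w,k_z event rates in min^-1.
#' @param alpha contact-probability exponent (polymer contact scaling).
#' @param n_val maximum number of simultaneous contacts per unit.
#' @param time_rescale metadata: the factor (min^-1) used to convert the
#'   fitted arbitrary-unit rates to minutes.
#' @param coupling_mode `"bridging"` or `"binding_only"`.
#' @param formation_distance distance entering the contact-formation rate
#'   `k_c / L^alpha`. `"shortcut"` (default): the current effective
#'   distance, i.e. the genomic distance dynamically shortcut by at most
#'   one existing spatial contact (see [effective_distance()]).
#'   `"genomic"`: the plain genomic distance `|i - j|`, i.e. the polymer
#'   contact-probability kernel without network feedback. At the default
#'   rates the `"shortcut"` kernel drives the network into a condensed
#'   phase (see the package vignette); `"genomic"` keeps contacts local.
#' @return An object of class `"rate_params"`.
#' @examples
#' rate_params()
#' rate_params(k_m = 0)  # methylation switched off (triple-mutant condition)
#' @export
rate_params <- function(k_m = 3.4e-6, k_d = 0.34, k_b = 0.27, k_u = 0.034,
                        k_y = 3.4, k_n = 0.51, k_c = 0.1, k_w = 0.034,
                        k_z = 0.69, alpha = 1.5, n_val = 5L,
                        time_rescale = 0.34,
                        coupling_mode = c("bridging", "binding_only"),
                        formation_distance = c("shortcut", "genomic")) {
  coupling_mode <- match.arg(coupling_mode)
  formation_distance <- match.arg(formation_distance)
  rates <- c(k_m = k_m, k_d = k_d, k_b = k_b, k_u = k_u, k_y = k_y,
             k_n = k_n, k_c = k_c, k_w = k_w, k_z = k_z)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  n_val <- as.integer(n_val)
  if (is.na(n_val) || n_val < 1L) stop("'n_val' must be >= 1")
  structure(c(as.list(rates),
              list(alpha = alpha, n_val = n_val,
                   time_rescale = time_rescale,
                   coupling_mode = coupling_mode,
                   formation_distance = formation_distance)),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params> (min^-1)\n")
  r <- unlist(x[c("k_m", "k_d", "k_b", "k_u", "k_y", "k_n", "k_c",
                  "k_w", "k_z")])
  print(r)
  cat(sprintf("alpha = %g, n_val = %d, coupling_mode = %s, formation_distance = %s\n",
              x$alpha, x$n_val, x$coupling_mode, x$formation_distance))
  invisible(x)
}
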