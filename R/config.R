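# Model configuration: semiflexible DNA chain and multivalent bridge particles.
#
# Internal units are reduced: bead diameter sigma = 1, k_B T = 1, bead mass 1.
# The chain maps to DNA through sigma_nm (default 10 nm = 29.4 bp per bead),
# so a persistence length of 50 nm is 5 beads.

#' Bending stiffness for a target persistence length
#'
#' Inverts the discrete Kratky-Porod relation
#' \eqn{l_P = -\sigma / \ln\langle\cos\theta\rangle} with
#' \eqn{\langle\cos\theta\rangle = \coth\kappa - 1/\kappa}
#' to find the bending modulus \eqn{\kappa} (in units of \eqn{k_BT}) that gives
#' a chain of unit-diameter beads the requested persistence length.
#'
#' @param lp_sigma target persistence length in units of the bead diameter.
#' @return bending stiffness \eqn{\kappa} in \eqn{k_BT}.
#' @examples
#' kappa_for_persistence_length(5)  # l_P = 50 nm at sigma = 10 nm
#' @export
kappa_for_persistence_length <- function(lp_sigma) {
  stopifnot(is.numeric(lp_sigma), lp_sigma > 0.2)
  lp_of_kappa <- function(k) {
    costh <- 1 / tanh(k) - 1 / k
    -1 / log(costh)
  }
  uniroot(function(k) lp_of_kappa(k) - lp_sigma,
          lower = 0.3, upper = 1000, tol = 1e-10)$root
}

#' Configure the DNA chain
#'
#' Defines a semiflexible bead-spring chain. Each bead represents
#' \code{bead_diameter_nm / 0.34} bp of double-stranded DNA; the bending
#' stiffness is chosen so that the discrete-chain persistence length matches
#' \code{persistence_length_nm}.
#'
#' @param n_beads number of beads.
#' @param bead_diameter_nm bead diameter \eqn{\sigma} in nm (default 10).
#' @param persistence_length_nm target persistence length in nm (default 50,
#'   double-stranded DNA). Use 0 for a freely jointed chain.
#' @param bindable logical vector of length \code{n_beads} (or a single value)
#'   marking beads that bridge particles may bind. Block patterns, e.g.
#'   alternating sticky/neutral stretches, are how compartment experiments are
#'   set up.
#' @return object of class \code{chain_config}.
#' @examples
#' ch <- chain_config(100)
#' ch$length_bp
#' @export
chain_config <- function(n_beads, bead_diameter_nm = 10,
                         persistence_length_nm = 50, bindable = TRUE) {
  stopifnot(n_beads >= 2, bead_diameter_nm > 0, persistence_length_nm >= 0)
  bindable <- rep_len(as.logical(bindable), n_beads)
  lp_sigma <- persistence_length_nm / bead_diameter_nm
  kappa <- if (lp_sigma > 0.5) kappa_for_persistence_length(lp_sigma) else 0
  # verify the discrete-chain relation round-trips (within 5%)
  if (kappa > 0) {
    costh <- 1 / tanh(kappa) - 1 / kappa
    lp_check <- -1 / log(costh)
    stopifnot(abs(lp_check - lp_sigma) / lp_sigma < 0.05)
  }
  bp_per_bead <- bead_diameter_nm / 0.34
  structure(list(
    n_beads = as.integer(n_beads),
    sigma_nm = bead_diameter_nm,
    bp_per_bead = bp_per_bead,
    length_bp = n_beads * bp_per_bead,
    contour_nm = n_beads * bead_diameter_nm,
    persistence_length_nm = persistence_length_nm,
    kappa = kappa,
    bindable = bindable
  ), class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf(
    "Semiflexible chain: %d beads (sigma = %g nm, %.1f bp/bead, %.1f kbp)\n",
    x$n_beads, x$sigma_nm, x$bp_per_bead, x$length_bp / 1000))
  cat(sprintf("  l_P = %g nm  (kappa = %.3f kT); %d of %d beads bindable\n",
              x$persistence_length_nm, x$kappa, sum(x$bindable), x$n_beads))
  invisible(x)
}

#' Configure bridge particles
#'
#' Bridge particles are diffusing spheres (one bead diameter wide) that can
#' hold up to \code{valence} simultaneous bonds to chain beads, gaining
#' \code{binding_energy} \eqn{k_BT} per bond. Valence 2 is the minimal
#' DNA-bridging unit; valence ~10 is the classic multivalent bridge that
#' collapses the chain into a globule.
#'
#' @param valence maximum simultaneous bonds per bridge (>= 2).
#' @param binding_energy bond energy \eqn{\epsilon} in \eqn{k_BT}
#'   (default 4, in the 3-5 \eqn{k_BT} range where bridging-induced clustering
#'   operates).
#' @param capture_radius_nm maximum bead-bridge distance for bond creation.
#' @param density bridge particles per chain bead (default 0.2); keeping this
#'   ratio fixed makes bulk bridge concentration the controlled variable as
#'   chain length varies.
#' @return object of class \code{bridge_config}.
#' @export
bridge_config <- function(valence = 2, binding_energy = 4,
                          capture_radius_nm = 15, density = 0.2) {
  stopifnot(valence >= 2, binding_energy > 0, capture_radius_nm > 0,
            density >= 0)
  structure(list(
    valence = as.integer(valence),
    binding_energy = binding_energy,
    capture_radius_nm = capture_radius_nm,
    density = density
  ), class = "bridge_config")
}

#' @export
print.bridge_config <- function(x, ...) {
  cat(sprintf(
    "Bridge particles: valence %d, epsilon = %g kT, capture %g nm, %.2g per bead\n",
    x$valence, x$binding_energy, x$capture_radius_nm, x$density))
  invisible(x)
}

#' Simulation parameters
#'
#' @param timestep integration step in reduced time units (default 0.01).
#' @param friction Langevin friction (default 0.3; diffusion constant
#'   \eqn{D = k_BT/\gamma}. A lightly damped thermostat samples the same
#'   ensemble while exploring conformations faster per step).
#' @param n_steps number of integration steps.
#' @param binding_every Metropolis binding sweep interval, in steps.
#' @param bead_density chain beads per \eqn{\sigma^3}; sets the periodic box
#'   volume \code{n_beads / bead_density} so that bead and bridge bulk
#'   concentrations stay constant across chain lengths.
#' @param snapshot_every snapshot recording stride in steps (0 = none).
#' @param seed integer seed controlling every random draw of a run.
#' @return object of class \code{sim_params}.
#' @export
sim_params <- function(timestep = 0.01, friction = 0.3, n_steps = 2e5,
                       binding_every = 10, bead_density = 0.02,
                       snapshot_every = 5000, seed = 1) {
  stopifnot(timestep > 0, friction > 0, n_steps >= 0, bead_density > 0)
  structure(list(
    timestep = timestep, friction = friction,
    n_steps = as.integer(n_steps),
    binding_every = as.integer(binding_every),
    bead_density = bead_density,
    snapshot_every = as.integer(snapshot_every),
    seed = as.integer(seed)
  ), class = "sim_params")
}

# force-field constants shared by all runs (Kremer-Grest backbone)
ff_list <- function(chain, bridges, excluded_volume = TRUE) {
  list(
    fene_k = 30, fene_r0 = 1.5,
    kappa = chain$kappa,
    wca = isTRUE(excluded_volume), wca_eps = 1,
    eps_bind = if (is.null(bridges)) 0 else bridges$binding_energy,
    r_capture = if (is.null(bridges)) 1.5 else
      bridges$capture_radius_nm / chain$sigma_nm,
    k_bond = 40, r0_bond = 2^(1 / 6),
    valence = if (is.null(bridges)) 2L else bridges$valence,
    # binding sites engage distinct DNA segments: no two bonds of one bridge
    # within this many beads along the chain
    seg_excl = 2L
  )
}
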