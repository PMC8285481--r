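#' Energy model parameters
#'
#' The posterior over bead coordinates, written as a potential energy in
#' units where the bead diameter \code{a} is the unit length:
#' \itemize{
#'   \item backbone bonds: harmonic, force constant \code{k = 100/a^2},
#'     rest length \code{a};
#'   \item contacted pairs (\code{c != 0}):
#'     \code{-2 ln r - (c/2) ln((r0 - r)/(r0 + r))} for
#'     \code{r < 0.995 r0}, continued linearly (first-order Taylor
#'     extension anchored at \code{0.995 r0}) beyond it, with the contact
#'     distance threshold \code{r0 = 2a};
#'   \item non-contacted pairs (\code{c == 0}):
#'     \code{-2 ln r + 0.075 ln(1 + exp(-4 (r - r0)))} up to \code{r = 3a},
#'     constant beyond (so far pairs exert no force).
#' }
#'
#' @param a bead diameter (the unit length; default 1).
#' @param r0 contact distance threshold (default \code{2 a}).
#' @param k backbone force constant (default \code{100 / a^2}).
#' @param s_exponent power coefficient of the no-contact sigmoid
#'   (default 0.075).
#' @param sigmoid_rate rate of the sigmoid, per unit \code{a} (default 4).
#' @param taylor_fraction fraction of \code{r0} where the Taylor extension
#'   of the contact term is anchored (default 0.995).
#' @param plateau_radius plateau onset for the no-contact term, in units of
#'   \code{a} (default 3).
#' @return list of class \code{energy_params}.
#' @export
energy_params <- function(a = 1, r0 = 2 * a, k = 100 / a^2,
                          s_exponent = 0.075, sigmoid_rate = 4,
                          taylor_fraction = 0.995, plateau_radius = 3) {
  stopifnot(a > 0, r0 > a, k > 0, s_exponent > 0, sigmoid_rate > 0,
            taylor_fraction > 0, taylor_fraction < 1, plateau_radius > 0)
  structure(list(a = a, r0 = r0, k = k, s_exponent = s_exponent,
                 sigmoid_rate = sigmoid_rate,
                 taylor_fraction = taylor_fraction,
                 plateau_radius = plateau_radius),
            class = "energy_params")
}

#' Backbone bond energy
#'
#' Harmonic potential \code{(k/2) (r - a)^2} between adjacent beads of the
#' same chromosome.
#'
#' @param r distance(s) in units of \code{a}.
#' @param params an \code{\link{energy_params}} list.
#' @return energy value(s).
#' @export
epsilon_phys <- function(r, params = energy_params()) {
  stopifnot(all(r >= 0))
  0.5 * params$k * (r - params$a)^2
}

#' Contact-restraint energy of one bead pair
#'
#' Negative log posterior of the pair distance given its contact count; see
#' \code{\link{energy_params}} for the functional form, Taylor tail and
#' plateau.
#'
#' @param r distance(s), > 0.
#' @param c contact count(s) (non-negative integers), recycled against
#'   \code{r}.
#' @param params an \code{\link{energy_params}} list.
#' @return energy value(s).
#' @export
epsilon_cont <- function(r, c, params = energy_params()) {
  .eps_cont_cpp(as.numeric(r), as.numeric(c), unclass(params))
}

#' Derivative of the contact-restraint energy in the distance
#' @inheritParams epsilon_cont
#' @return d epsilon / d r value(s).
#' @export
epsilon_cont_deriv <- function(r, c, params = energy_params()) {
  .deps_cont_cpp(as.numeric(r), as.numeric(c), unclass(params))
}

#' Distance minimising the contact energy for a given count
#'
#' Closed form root of the derivative of the contacted-pair energy:
#' \code{r0 (-c + sqrt(c^2 + 16)) / 4}.
#'
#' @param c contact count(s), > 0.
#' @param params an \code{\link{energy_params}} list.
#' @return optimal distance(s) in units of \code{a}.
#' @export
contact_optimum <- function(c, params = energy_params()) {
  stopifnot(all(c > 0))
  params$r0 * (-c + sqrt(c^2 + 16)) / 4
}

# Backbone bonds (0-based index pairs) of a lattice: adjacent beads within
# each chromosome only -- beads of different chromosomes are never bonded.
backbone_bonds <- function(lattice) {
  n <- lattice$n_per_chrom
  b1 <- integer(0)
  for (ci in seq_along(n)) {
    if (n[ci] > 1L)
      b1 <- c(b1, lattice$offsets[ci] + seq_len(n[ci] - 1L) - 1L)
  }
  list(b1 = as.integer(b1), b2 = as.integer(b1 + 1L))
}

check_same_lattice <- function(conf, contacts) {
  la <- conf$lattice; lb <- contacts$lattice
  if (la$n_beads != lb$n_beads || la$resolution != lb$resolution ||
      !identical(la$assembly$name, lb$assembly$name))
    stop("conformation and contacts are on different lattices")
}

#' Total potential energy of a conformation
#'
#' Backbone bonds plus the contact term summed over all bead pairs
#' (non-contacted pairs beyond the 3a plateau contribute their constant
#' plateau value, counted analytically).
#'
#' @param conf a \code{\link{conformation}}.
#' @param contacts \code{binned_contacts} on the same lattice.
#' @param params an \code{\link{energy_params}} list.
#' @param use_grid use the 3a cell-list neighbour search (default) rather
#'   than the dense O(N^2) loop; the two are interchangeable.
#' @return total energy (double).
#' @export
total_energy <- function(conf, contacts, params = energy_params(),
                         use_grid = TRUE) {
  check_same_lattice(conf, contacts)
  b <- backbone_bonds(conf$lattice)
  .total_energy_cpp(conf$coords, b$b1, b$b2, contacts$i, contacts$j,
                    contacts$c, unclass(params), use_grid)
}

#' Forces on every bead
#'
#' Negative gradient of \code{\link{total_energy}} with respect to the bead
#' coordinates, computed analytically. Non-contacted pairs beyond the 3a
#' plateau exert no force.
#'
#' @inheritParams total_energy
#' @return numeric \code{n_beads x 3} matrix.
#' @export
forces <- function(conf, contacts, params = energy_params(),
                   use_grid = TRUE) {
  check_same_lattice(conf, contacts)
  b <- backbone_bonds(conf$lattice)
  .forces_cpp(conf$coords, b$b1, b$b2, contacts$i, contacts$j, contacts$c,
              unclass(params), use_grid)
}
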