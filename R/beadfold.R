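#' Fit 3D genome structures to single-cell Hi-C contacts
#'
#' The package's main entry point. Filters the contact list (optional),
#' bins it at 1 kb, and runs the full hierarchical Bayesian optimisation
#' for an ensemble of replicas at the requested resolution: random initial
#' conformation, 2000 steepest-descent steps with periodic shrinking plus
#' 8000 without at the coarsest ladder level, then bead splitting and
#' 10,000 refinement steps per halving of the resolution down to the
#' target.
#'
#' @param records \code{contact_records} (see \code{\link{read_contacts}}).
#' @param assembly a \code{\link{genome_assembly}}.
#' @param resolution target resolution in bp.
#' @param replicas ensemble size (default from \code{config}).
#' @param filter apply the 2-Mb isolated-contact filter first
#'   (default TRUE).
#' @param config an \code{\link{optimizer_config}}.
#' @param seed base random seed (overrides \code{config$seed}).
#' @return Object of class \code{beadfold}: a fitted ensemble with
#'   components \code{ensemble} (\code{structure_ensemble}),
#'   \code{records}, \code{removed} (filtered-out records),
#'   \code{assembly}, \code{resolution}, \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{plot}, \code{fitted},
#'   \code{coef}, \code{residuals}, \code{simulate}.
#' @examples
#' \donttest{
#' spec <- toy_two_domain_spec(chrom_length = 4e5, resolution = 2e4)
#' truth <- simulate_truth(spec)
#' set.seed(1)
#' rec <- sample_contacts(truth, spec)
#' cfg <- optimizer_config(stage1_steps = 200, stage2_steps = 300,
#'                         refine_steps = 300, replicas = 2,
#'                         ladder_floor = 4e4)
#' fit <- beadfold(rec, spec$assembly, resolution = 2e4, config = cfg)
#' summary(fit)
#' }
#' @export
beadfold <- function(records, assembly, resolution,
                     replicas = NULL, filter = TRUE,
                     config = optimizer_config(), seed = NULL) {
  cl <- match.call()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(replicas)) config$replicas <- as.integer(replicas)
  removed <- NULL
  if (filter) {
    fl <- filter_isolated_contacts(records)
    records <- fl$kept
    removed <- fl$removed
  }
  if (nrow(records) == 0L) stop("no contact records left to fit")
  ens <- run_ensemble(records, assembly, resolution, config)
  structure(list(ensemble = ens, records = records, removed = removed,
                 assembly = assembly, resolution = resolution,
                 config = config, call = cl),
            class = "beadfold")
}

contact_distances <- function(conf, contacts) {
  D <- conf$coords[contacts$i + 1L, , drop = FALSE] -
       conf$coords[contacts$j + 1L, , drop = FALSE]
  sqrt(rowSums(D^2))
}

# replica with the lowest total energy: the ensemble's representative
best_replica <- function(object) {
  ens <- object$ensemble
  e <- vapply(ens$conformations, total_energy, numeric(1),
              contacts = ens$contacts,
              params = object$config$energy_params)
  which.min(e)
}

#' @export
print.beadfold <- function(x, ...) {
  ens <- x$ensemble
  cat("Bayesian single-cell Hi-C structure fit\n")
  cat(sprintf("  resolution: %s bp, %d beads, %d chromosome(s)\n",
              format(x$resolution, big.mark = ","),
              ens$contacts$lattice$n_beads, nrow(x$assembly)))
  cat(sprintf("  restraints: %d bead pair(s) from %d read(s)\n",
              length(ens$contacts$i), sum(ens$contacts$c)))
  cat(sprintf("  replicas:   %d (seeds %d..%d)\n",
              length(ens$conformations), min(ens$seeds), max(ens$seeds)))
  invisible(x)
}

#' Summarise a fitted structure ensemble
#'
#' Reports, per replica, the total energy and restraint-violation
#' percentage, plus contacts per bead, the median pairwise RMSD across
#' replicas and the 4-bead-diameter reliability flag.
#'
#' @param object a \code{\link{beadfold}} fit.
#' @param ... unused.
#' @return list of class \code{summary.beadfold}.
#' @export
summary.beadfold <- function(object, ...) {
  ens <- object$ensemble
  pars <- object$config$energy_params
  viol <- vapply(ens$conformations, violation_percentage, numeric(1),
                 contacts = ens$contacts)
  en <- vapply(ens$conformations, total_energy, numeric(1),
               contacts = ens$contacts, params = pars)
  rm_ <- if (length(ens$conformations) >= 2L) ensemble_rmsd(ens)
         else list(median = NA_real_, reliable = NA)
  out <- list(resolution = object$resolution,
              n_beads = ens$contacts$lattice$n_beads,
              n_restraints = length(ens$contacts$i),
              n_reads = sum(ens$contacts$c),
              contacts_per_bead = contacts_per_bead(ens$contacts),
              violation_percent = viol,
              energy = en,
              median_rmsd = rm_$median,
              reliable = rm_$reliable,
              n_removed = if (is.null(object$removed)) NA_integer_
                          else nrow(object$removed))
  class(out) <- "summary.beadfold"
  out
}

#' @export
print.summary.beadfold <- function(x, ...) {
  cat("Bayesian single-cell Hi-C structure fit\n")
  cat(sprintf("  %d beads at %s bp; %d restraints from %d reads\n",
              x$n_beads, format(x$resolution, big.mark = ","),
              x$n_restraints, x$n_reads))
  if (!is.na(x$n_removed))
    cat(sprintf("  isolated-contact filter removed %d record(s)\n",
                x$n_removed))
  cat(sprintf("  contacts per bead: %.3f %s\n", x$contacts_per_bead,
              if (x$contacts_per_bead > 0.2) "(> 0.2: resolution supported)"
              else "(< 0.2: consider a coarser resolution)"))
  cat(sprintf("  violation %%: mean %.3f (range %.3f..%.3f)\n",
              mean(x$violation_percent), min(x$violation_percent),
              max(x$violation_percent)))
  if (!is.na(x$median_rmsd))
    cat(sprintf("  median pairwise RMSD: %.2f bd -> %s\n", x$median_rmsd,
                if (isTRUE(x$reliable)) "reliable (< 4 bd)"
                else "not reliable (>= 4 bd)"))
  invisible(x)
}

#' @export
fitted.beadfold <- function(object, ...) {
  object$ensemble$conformations[[best_replica(object)]]
}

#' @export
coef.beadfold <- function(object, ...) {
  fitted(object)$coords
}

#' Restraint residuals of a fitted ensemble
#'
#' For every contact restraint, the model distance minus the contact
#' threshold \code{r0} in the best-energy replica; positive values exceed
#' the restraint, values above \code{threshold - r0} (i.e. distance > 2 bd)
#' are violations.
#'
#' @param object a \code{\link{beadfold}} fit.
#' @param ... unused.
#' @return numeric vector, one value per restrained bead pair.
#' @export
residuals.beadfold <- function(object, ...) {
  conf <- fitted(object)
  contact_distances(conf, object$ensemble$contacts) -
    object$config$energy_params$r0
}

#' Plot the distance matrix of a fitted structure
#'
#' Heat map of the pairwise distance matrix of one chromosome window of
#' the best-energy replica (near = dark).
#'
#' @param x a \code{\link{beadfold}} fit.
#' @param chrom chromosome (default: first).
#' @param from,to 0-based local bead window (default: whole chromosome).
#' @param ... passed to \code{image}.
#' @return the \code{distance_matrix}, invisibly.
#' @export
plot.beadfold <- function(x, chrom = x$assembly$name[1], from = 0L,
                          to = NULL, ...) {
  dm <- distance_matrix(fitted(x), chrom = chrom, from = from, to = to)
  n <- nrow(dm)
  graphics::image(seq_len(n), seq_len(n), unclass(dm)[, n:1],
                  col = grDevices::hcl.colors(64, "YlOrRd"),
                  xlab = "bead", ylab = "bead",
                  main = sprintf("%s pairwise distances (bd)", chrom), ...)
  invisible(dm)
}

#' Simulate contact records from a fitted structure
#'
#' Draws new sparse contact lists from the best-energy replica with the
#' same detection model used by the synthetic generator (capture radius
#' 2a unless overridden), enabling parametric-bootstrap style checks.
#'
#' @param object a \code{\link{beadfold}} fit.
#' @param nsim number of contact lists (default 1).
#' @param seed optional seed.
#' @param detection_prob per-pair detection probability (default 0.5).
#' @param capture_radius capture radius in units of \code{a} (default 2).
#' @param ... unused.
#' @return list of \code{contact_records} of length \code{nsim}.
#' @export
simulate.beadfold <- function(object, nsim = 1, seed = NULL,
                              detection_prob = 0.5, capture_radius = 2,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  conf <- fitted(object)
  spec <- simulation_spec(object$assembly, object$resolution,
                          capture_radius = capture_radius,
                          detection_prob = detection_prob,
                          seed = if (is.null(seed)) 1L else seed)
  lapply(seq_len(nsim), function(k) sample_contacts(conf, spec))
}
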