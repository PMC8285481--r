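#' Specification of a synthetic single-cell experiment
#'
#' Describes a ground-truth polymer conformation with optionally planted
#' domains, and the sparse contact-detection process applied to it: every
#' bead pair closer than \code{capture_radius} is detected independently
#' with probability \code{detection_prob}, emulating the sparsity of
#' single-cell Hi-C (of order 0.2 usable reads per bead at working
#' resolutions).
#'
#' @param assembly a \code{\link{genome_assembly}}.
#' @param truth_resolution bead size of the ground truth in bp.
#' @param capture_radius detection radius in units of \code{a}
#'   (default 2, the contact distance threshold).
#' @param detection_prob per-pair detection probability in [0, 1]
#'   (default 0.5, a mid-sparsity single-cell regime).
#' @param domains optional data.frame with columns \code{chrom},
#'   \code{start_bead}, \code{end_bead} (0-based local, end exclusive),
#'   \code{compactness} (>= 0) describing planted collapsed domains.
#' @param reads_per_pair if > 0, each detected pair emits
#'   \code{1 + rpois(1, reads_per_pair - 1)} records (default 0 = one
#'   record per detected pair).
#' @param seed integer random seed.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(assembly, truth_resolution,
                            capture_radius = 2, detection_prob = 0.5,
                            domains = NULL, reads_per_pair = 0,
                            seed = 1L) {
  stopifnot(inherits(assembly, "genome_assembly"),
            capture_radius > 0,
            detection_prob >= 0, detection_prob <= 1)
  structure(list(assembly = assembly,
                 truth_resolution = truth_resolution,
                 capture_radius = capture_radius,
                 detection_prob = detection_prob,
                 domains = domains,
                 reads_per_pair = reads_per_pair,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a ground-truth conformation
#'
#' Per chromosome, a confined random walk with step length \code{a}.
#' Inside a planted domain the walk is biased toward the running centroid
#' of the domain (weight = \code{compactness}), producing a collapsed
#' globule; outside domains the walk is persistent (correlated step
#' directions), producing extended linkers. Deterministic per seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param a bead diameter (default 1).
#' @return a \code{\link{conformation}} on the truth lattice.
#' @export
simulate_truth <- function(spec, a = 1) {
  set.seed(spec$seed)
  lat <- make_lattice(spec$assembly, spec$truth_resolution)
  X <- matrix(0, lat$n_beads, 3)
  confine <- a * max(3, 1.25 * lat$n_beads^(1 / 3))
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (ci in seq_along(lat$n_per_chrom)) {
    n <- lat$n_per_chrom[ci]
    o <- lat$offsets[ci]
    dom <- if (!is.null(spec$domains))
      spec$domains[spec$domains$chrom == lat$assembly$name[ci], ,
                   drop = FALSE]
    else NULL
    in_domain <- function(b) {
      if (is.null(dom) || nrow(dom) == 0L) return(0)
      hit <- dom$start_bead <= b & b < dom$end_bead
      if (any(hit)) dom$compactness[which(hit)[1]] else 0
    }
    X[o + 1L, ] <- stats::rnorm(3, 0, a / 4)
    prev_dir <- rand_dir()
    dom_anchor <- NULL
    for (b in 2:n) {
      comp <- in_domain(b - 1L)  # 0-based local index of the new bead
      if (comp > 0) {
        if (is.null(dom_anchor)) dom_anchor <- X[o + b - 1L, ]
        pull <- dom_anchor - X[o + b - 1L, ]
        np <- sqrt(sum(pull^2))
        if (np > 0) pull <- pull / np else pull <- c(0, 0, 0)
        d <- rand_dir() + comp * pull
      } else {
        dom_anchor <- NULL
        # persistent linker: correlate with the previous direction
        d <- rand_dir() + 1.5 * prev_dir
      }
      d <- d / sqrt(sum(d^2))
      cand <- X[o + b - 1L, ] + a * d
      if (sum(cand^2) > confine^2) {
        # reflect back toward the origin
        d <- -cand / sqrt(sum(cand^2))
        cand <- X[o + b - 1L, ] + a * d
      }
      X[o + b, ] <- cand
      prev_dir <- d
    }
  }
  X <- X + matrix(stats::runif(length(X), -0.5e-6, 0.5e-6) * a,
                  nrow(X), 3)
  conformation(lat, X)
}

#' Sample sparse contact records from a ground truth
#'
#' Every bead pair separated by at most \code{capture_radius} is emitted
#' independently with probability \code{detection_prob}; the two record
#' positions are drawn uniformly within the genomic bins of the two beads,
#' so binning at the truth resolution recovers the pair.
#'
#' @param truth a \code{\link{conformation}}.
#' @param spec a \code{\link{simulation_spec}}.
#' @param seed optional seed for the detection draw (default: continue the
#'   current RNG stream).
#' @return \code{contact_records}; the attribute
#'   \code{"contacts_per_bead"} holds emitted records / bead count.
#' @export
sample_contacts <- function(truth, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lat <- truth$lattice
  D <- as.matrix(stats::dist(truth$coords))
  within <- which(upper.tri(D) & D <= spec$capture_radius, arr.ind = TRUE)
  if (nrow(within)) {
    take <- stats::runif(nrow(within)) < spec$detection_prob
    within <- within[take, , drop = FALSE]
  }
  if (nrow(within) == 0L) {
    warning("no contacts detected")
    rec <- contact_records(character(0), numeric(0), character(0),
                           numeric(0), integer(0))
    attr(rec, "contacts_per_bead") <- 0
    return(rec)
  }
  mult <- if (spec$reads_per_pair > 0)
    1L + stats::rpois(nrow(within), spec$reads_per_pair - 1)
  else rep.int(1L, nrow(within))
  i <- rep.int(within[, 1] - 1L, mult)   # 0-based global bead indices
  j <- rep.int(within[, 2] - 1L, mult)
  ri <- bead_ranges(lat, i)
  rj <- bead_ranges(lat, j)
  posA <- floor(stats::runif(length(i), ri$start, ri$end)) + 1
  posB <- floor(stats::runif(length(j), rj$start, rj$end)) + 1
  rec <- contact_records(ri$chrom, posA, rj$chrom, posB, 1L)
  attr(rec, "contacts_per_bead") <- nrow(rec) / lat$n_beads
  rec
}

#' Two-domain toy system
#'
#' Convenience generator used throughout the tests and examples: one
#' chromosome split into two planted domains joined by an extended linker.
#'
#' @param chrom_length chromosome length in bp (default 2e6).
#' @param resolution truth resolution in bp (default 2e4).
#' @param detection_prob per-pair detection probability (default 0.5).
#' @param compactness domain collapse strength (default 0.8).
#' @param seed random seed.
#' @return a \code{\link{simulation_spec}}.
#' @export
toy_two_domain_spec <- function(chrom_length = 2e6, resolution = 2e4,
                                detection_prob = 0.5, compactness = 0.8,
                                seed = 1L) {
  asm <- genome_assembly("chrS", chrom_length)
  n <- ceiling(chrom_length / resolution)
  linker <- max(2L, round(0.06 * n))
  half <- (n - linker) %/% 2L
  domains <- data.frame(
    chrom = "chrS",
    start_bead = c(0L, half + linker),
    end_bead = c(half, n),
    compactness = compactness)
  simulation_spec(asm, resolution, detection_prob = detection_prob,
                  domains = domains, seed = seed)
}
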