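#' Optimiser configuration
#'
#' Defaults follow the published protocol: at the coarsest resolution,
#' 2000 steepest-descent steps with the structure shrunk once per ten steps,
#' then 8000 steps without shrinking; after each bead-splitting refinement,
#' 10,000 steps without shrinking; each displacement is
#' \code{(0.1 a / f_max) f_i}; 20 replicas per ensemble; the resolution
#' ladder starts at the smallest power-of-two multiple of the target that
#' reaches 1000 kb.
#'
#' @param step_factor maximum per-step displacement in units of \code{a}
#'   (default 0.1).
#' @param stage1_steps shrink-stage step count at the coarsest resolution
#'   (default 2000).
#' @param shrink_every shrink period in steps during stage 1 (default 10).
#' @param shrink_exponent exponent of the shrink factor
#'   \code{(sum a / sum r)^0.05} (default 0.05).
#' @param stage2_steps no-shrink step count at the coarsest resolution
#'   (default 8000).
#' @param refine_steps no-shrink step count after each bead split
#'   (default 10000).
#' @param replicas ensemble size (default 20).
#' @param ladder_floor ladder starting floor in bp (default 1e6).
#' @param seed base random seed; replica \code{r} uses \code{seed + r - 1}.
#' @param energy_params an \code{\link{energy_params}} list.
#' @param use_grid use the cell-list neighbour search (default TRUE).
#' @param trace_every record the total energy every this many steps
#'   (0 = never; default 0).
#' @return list of class \code{optimizer_config}.
#' @export
optimizer_config <- function(step_factor = 0.1, stage1_steps = 2000L,
                             shrink_every = 10L, shrink_exponent = 0.05,
                             stage2_steps = 8000L, refine_steps = 10000L,
                             replicas = 20L, ladder_floor = 1e6,
                             seed = 1L, energy_params = beadfold::energy_params(),
                             use_grid = TRUE, trace_every = 0L) {
  stopifnot(step_factor > 0, stage1_steps >= 0, stage2_steps >= 0,
            refine_steps >= 0, replicas >= 1, shrink_every >= 1,
            ladder_floor >= 1)
  structure(list(step_factor = step_factor,
                 stage1_steps = as.integer(stage1_steps),
                 shrink_every = as.integer(shrink_every),
                 shrink_exponent = shrink_exponent,
                 stage2_steps = as.integer(stage2_steps),
                 refine_steps = as.integer(refine_steps),
                 replicas = as.integer(replicas),
                 ladder_floor = ladder_floor,
                 seed = as.integer(seed),
                 energy_params = energy_params,
                 use_grid = isTRUE(use_grid),
                 trace_every = as.integer(trace_every)),
            class = "optimizer_config")
}

#' Random initial conformation
#'
#' Each chromosome is laid down as a 3D random walk with step length
#' \code{a}; chromosome starting points are i.i.d. uniform in a sphere of
#' radius \code{a n_beads^(1/3)}. A uniform jitter of \code{1e-6 a} breaks
#' exact coincidences. Reproducible for a given seed.
#'
#' @param lattice a \code{\link{make_lattice}} result.
#' @param seed integer random seed.
#' @param a bead diameter (default 1).
#' @return a \code{\link{conformation}}.
#' @export
random_initial_conformation <- function(lattice, seed, a = 1) {
  set.seed(as.integer(seed))
  n <- lattice$n_beads
  radius <- a * n^(1 / 3)
  X <- matrix(0, n, 3)
  for (ci in seq_along(lattice$n_per_chrom)) {
    nc <- lattice$n_per_chrom[ci]
    o <- lattice$offsets[ci]
    # uniform point in the sphere by rejection
    repeat {
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) <= radius^2) break
    }
    X[o + 1L, ] <- p
    if (nc > 1L) {
      steps <- matrix(stats::rnorm(3L * (nc - 1L)), ncol = 3)
      steps <- a * steps / sqrt(rowSums(steps^2))
      X[(o + 2L):(o + nc), ] <-
        rep(p, each = nc - 1L) + apply(steps, 2, cumsum)
    }
  }
  X <- X + matrix(stats::runif(3L * n, -0.5e-6, 0.5e-6) * a, n, 3)
  conformation(lattice, X)
}

#' One steepest-descent step
#'
#' Displaces every bead by \code{(step_factor a / f_max) f_i}, where
#' \code{f_max} is the largest per-bead force magnitude; the largest
#' displacement is therefore exactly \code{step_factor a}. A zero-force
#' state is returned unchanged.
#'
#' @param conf a \code{\link{conformation}}.
#' @param contacts \code{binned_contacts} on the same lattice.
#' @param config an \code{\link{optimizer_config}}.
#' @return the displaced \code{conformation}.
#' @export
descend_step <- function(conf, contacts, config = optimizer_config()) {
  st <- optimize_stage(conf, contacts, n_steps = 1L, shrink_every = 0L,
                       config = config)
  st
}

#' Shrink a structure toward unit contact distances
#'
#' Multiplies all coordinates by \code{(sum a / sum r)^shrink_exponent},
#' sums running over contacted bead pairs. The factor is 1 exactly when the
#' mean contacted-pair distance equals \code{a}.
#'
#' @inheritParams descend_step
#' @return the rescaled \code{conformation}.
#' @export
shrink <- function(conf, contacts, config = optimizer_config()) {
  check_same_lattice(conf, contacts)
  if (length(contacts$i) == 0L) {
    warning("no contact pairs: shrink is the identity")
    return(conf)
  }
  D <- conf$coords[contacts$i + 1L, , drop = FALSE] -
       conf$coords[contacts$j + 1L, , drop = FALSE]
  r <- sqrt(rowSums(D^2))
  a <- config$energy_params$a
  fac <- (length(r) * a / sum(r))^config$shrink_exponent
  conformation(conf$lattice, conf$coords * fac)
}

#' Run one optimisation stage
#'
#' \code{n_steps} steepest-descent steps, with the structure shrunk after
#' every \code{shrink_every}-th step when \code{shrink_every > 0}.
#' Deterministic given its inputs.
#'
#' @inheritParams descend_step
#' @param n_steps number of descent steps (>= 0).
#' @param shrink_every shrink period (0 disables shrinking).
#' @return the optimised \code{conformation}; the energy trace (if
#'   \code{config$trace_every > 0}) is attached as attribute
#'   \code{"energy_trace"}.
#' @export
optimize_stage <- function(conf, contacts, n_steps,
                           shrink_every = 0L,
                           config = optimizer_config()) {
  check_same_lattice(conf, contacts)
  stopifnot(n_steps >= 0)
  if (n_steps == 0L) return(conf)
  b <- backbone_bonds(conf$lattice)
  res <- .descent_cpp(conf$coords, b$b1, b$b2, contacts$i, contacts$j,
                      contacts$c, unclass(config$energy_params),
                      as.integer(n_steps), as.integer(shrink_every),
                      config$step_factor, config$shrink_exponent,
                      config$use_grid, config$trace_every)
  out <- conformation(conf$lattice, res$coords)
  if (config$trace_every > 0L) attr(out, "energy_trace") <- res$trace
  out
}

#' Split every bead in two for the next ladder level
#'
#' Each bead of an optimised low-resolution structure is divided into two
#' beads of half the size: the first child sits at the parent position and
#' the second at the midpoint of the parent and its successor. The terminal
#' parent of each chromosome has no successor; its second child is placed at
#' the parent position (the harmonic backbone relaxes it within a few
#' steps). Children beyond the fine lattice's bead count (odd terminal
#' bins) are discarded. Use \code{\link{resolve_coincident}} before
#' evaluating energies: the terminal children coincide exactly.
#'
#' @param conf_low optimised \code{\link{conformation}} at resolution r.
#' @return initial \code{conformation} on the lattice at resolution r/2.
#' @export
split_beads <- function(conf_low) {
  lat_lo <- conf_low$lattice
  lat_hi <- make_lattice(lat_lo$assembly, lat_lo$resolution / 2)
  X_lo <- conf_low$coords
  X_hi <- matrix(NA_real_, lat_hi$n_beads, 3)
  for (ci in seq_along(lat_lo$n_per_chrom)) {
    n_lo <- lat_lo$n_per_chrom[ci]
    n_hi <- lat_hi$n_per_chrom[ci]
    lo <- lat_lo$offsets[ci] + seq_len(n_lo)
    child1 <- X_lo[lo, , drop = FALSE]
    succ <- X_lo[c(lo[-1L], lo[n_lo]), , drop = FALSE]
    child2 <- (child1 + succ) / 2
    inter <- matrix(rbind(t(child1), t(child2)), ncol = 3, byrow = TRUE)
    X_hi[lat_hi$offsets[ci] + seq_len(n_hi), ] <-
      inter[seq_len(n_hi), , drop = FALSE]
  }
  conformation(lat_hi, X_hi)
}

#' Separate exactly coincident beads
#'
#' Displaces the later bead of every coincident pair of adjacent beads by
#' \code{eps} along a deterministic direction (the incoming backbone
#' direction where defined, the x axis otherwise), so that energies and
#' forces are finite. Deterministic: no random numbers are drawn.
#'
#' @param conf a \code{\link{conformation}}.
#' @param eps displacement amplitude in units of \code{a} (default 1e-6).
#' @return the adjusted \code{conformation}.
#' @export
resolve_coincident <- function(conf, eps = 1e-6) {
  X <- conf$coords
  b <- backbone_bonds(conf$lattice)
  for (q in seq_along(b$b1)) {
    i <- b$b1[q] + 1L; j <- b$b2[q] + 1L
    if (sum((X[i, ] - X[j, ])^2) == 0) {
      dirv <- if (i > 1L) X[i, ] - X[i - 1L, ] else c(1, 0, 0)
      nv <- sqrt(sum(dirv^2))
      if (nv == 0) dirv <- c(1, 0, 0) else dirv <- dirv / nv
      X[j, ] <- X[j, ] + eps * dirv
    }
  }
  conformation(conf$lattice, X)
}

#' Resolution ladder for hierarchical optimisation
#'
#' Successive halvings from the coarsest start down to the target. The
#' start is \code{target * 2^J} with the smallest J such that the start
#' reaches \code{floor_} (so a 10-kb target starts at 1280 kb, 100 kb at
#' 1600 kb and 1 kb at 1024 kb with the default 1000-kb floor).
#'
#' @param target_resolution target resolution in bp.
#' @param floor_ ladder starting floor in bp (default 1e6).
#' @return numeric vector of resolutions in bp, coarsest first.
#' @examples
#' resolution_ladder(1e4) / 1000  # 1280 640 320 160 80 40 20 10
#' @export
resolution_ladder <- function(target_resolution, floor_ = 1e6) {
  stopifnot(target_resolution >= 1, floor_ >= 1)
  J <- 0L
  while (target_resolution * 2^J < floor_) J <- J + 1L
  target_resolution * 2^(J:0)
}

#' Infer a 3D structure from contact records
#'
#' The full hierarchical protocol: contacts are binned once at 1 kb and
#' merged to every ladder resolution; at the coarsest level a random
#' conformation is optimised with the shrink stage then the plain stage;
#' each subsequent level starts from the bead-split previous structure and
#' runs \code{refine_steps} no-shrink steps.
#'
#' @param records \code{contact_records} (already filtered as desired).
#' @param assembly a \code{\link{genome_assembly}}.
#' @param target_resolution target resolution in bp.
#' @param config an \code{\link{optimizer_config}}.
#' @param seed random seed for the initial conformation (default
#'   \code{config$seed}).
#' @param base_resolution base-map resolution in bp (default 1000).
#' @param checkpoint_dir if non-NULL, the optimised structure at every
#'   ladder level is written there as TSV.
#' @return final \code{conformation}, with attribute \code{"ladder"}.
#' @export
infer_structure <- function(records, assembly, target_resolution,
                            config = optimizer_config(),
                            seed = config$seed,
                            base_resolution = 1000,
                            checkpoint_dir = NULL) {
  ladder <- resolution_ladder(target_resolution, config$ladder_floor)
  base_lat <- make_lattice(assembly, base_resolution)
  base_map <- bin_contacts(records, base_lat)
  if (length(base_map$i) == 0L)
    stop("no usable contacts after binning at the base resolution")
  log_stage <- function(conf, contacts, res, stage) {
    if (config$trace_every <= 0L) return(invisible())
    tr <- attr(conf, "energy_trace")
    if (!is.null(tr) && length(tr))
      message(sprintf("[%7.0f bp] %-7s E every %d steps: %s", res, stage,
                      config$trace_every,
                      paste(sprintf("%.4g", tr), collapse = " ")))
    if (length(contacts$i))
      message(sprintf("[%7.0f bp] %-7s E = %.6g, violation %.2f%%", res,
                      stage, total_energy(conf, contacts,
                                          params = config$energy_params),
                      violation_percentage(conf, contacts)))
  }
  conf <- NULL
  for (lev in seq_along(ladder)) {
    res <- ladder[lev]
    contacts <- merge_bins(base_map, res)
    if (lev == 1L) {
      conf <- random_initial_conformation(make_lattice(assembly, res), seed,
                                          a = config$energy_params$a)
      conf <- optimize_stage(conf, contacts, config$stage1_steps,
                             shrink_every = config$shrink_every,
                             config = config)
      log_stage(conf, contacts, res, "shrink")
      conf <- optimize_stage(conf, contacts, config$stage2_steps,
                             shrink_every = 0L, config = config)
      log_stage(conf, contacts, res, "plain")
    } else {
      conf <- resolve_coincident(split_beads(conf))
      conf <- optimize_stage(conf, contacts, config$refine_steps,
                             shrink_every = 0L, config = config)
      log_stage(conf, contacts, res, "refine")
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      write_structure_tsv(conf, file.path(
        checkpoint_dir, sprintf("level_%06.0fbp.tsv", res)))
    }
  }
  attr(conf, "ladder") <- ladder
  conf
}

#' Optimise an ensemble of replicas
#'
#' Repeats the whole calculation \code{config$replicas} times from
#' different random initial structures under the same restraints; replica
#' \code{r} uses seed \code{config$seed + r - 1}, so replicas are
#' independent of execution order.
#'
#' @inheritParams infer_structure
#' @return object of class \code{structure_ensemble}: list with
#'   \code{conformations}, \code{seeds}, \code{config}, \code{contacts}
#'   (the binned map at the target resolution).
#' @export
run_ensemble <- function(records, assembly, target_resolution,
                         config = optimizer_config(),
                         base_resolution = 1000) {
  seeds <- config$seed + seq_len(config$replicas) - 1L
  confs <- lapply(seeds, function(s)
    infer_structure(records, assembly, target_resolution, config, seed = s,
                    base_resolution = base_resolution))
  base_map <- bin_contacts(records, make_lattice(assembly, base_resolution))
  contacts <- merge_bins(base_map, target_resolution)
  structure(list(conformations = confs, seeds = seeds, config = config,
                 contacts = contacts),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d replica(s), %d beads at %s bp\n",
              length(x$conformations), x$contacts$lattice$n_beads,
              format(x$contacts$lattice$resolution, big.mark = ",")))
  invisible(x)
}
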