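test_that("a descent step displaces the most-forced bead by exactly 0.1a", {
  conf <- random_conformation(15, seed = 2, spread = 2)
  bc <- make_contacts(conf$lattice, c(0L, 5L), c(9L, 14L), 2L)
  cfg <- optimizer_config()
  out <- descend_step(conf, bc, cfg)
  disp <- sqrt(rowSums((out$coords - conf$coords)^2))
  expect_equal(max(disp), 0.1, tolerance = 1e-12)
  # displacement is parallel to the force
  F <- forces(conf, bc)
  fmax <- max(sqrt(rowSums(F^2)))
  expect_equal(out$coords - conf$coords, 0.1 * F / fmax,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a zero-force state is a fixed point of the descent", {
  # two lone beads on different chromosomes beyond the 3a plateau
  asm <- genome_assembly(c("p", "q"), c(1e4, 1e4))
  lat <- make_lattice(asm, 1e4)
  conf <- conformation(lat, rbind(c(0, 0, 0), c(5, 0, 0)))
  bc <- make_contacts(lat, integer(0), integer(0), integer(0))
  out <- descend_step(conf, bc)
  expect_equal(out$coords, conf$coords)
})

test_that("shrinking rescales by (sum a / sum r)^0.05 over contact pairs", {
  conf <- line_conformation(6)  # beads at spacing 1 along x
  # contacts (0,2) and (2,4): both at distance 2a
  bc <- make_contacts(conf$lattice, c(0L, 2L), c(2L, 4L))
  out <- shrink(conf, bc)
  expect_equal(out$coords, conf$coords * 0.5^0.05, tolerance = 1e-12)
  expect_equal(0.5^0.05, 0.9659, tolerance = 1e-4)

  # all contact distances at a: identity (fixed point)
  bc1 <- make_contacts(conf$lattice, c(0L, 3L), c(1L, 4L))
  expect_equal(shrink(conf, bc1)$coords, conf$coords, tolerance = 1e-12)

  # mean contact distance below a: expansion
  confc <- conformation(conf$lattice, conf$coords * 0.5)
  expect_gt(shrink(confc, bc1)$coords[2, 1] / confc$coords[2, 1], 1)

  # no contacts: identity with a warning
  bce <- make_contacts(conf$lattice, integer(0), integer(0), integer(0))
  expect_warning(out0 <- shrink(conf, bce), "identity")
  expect_equal(out0$coords, conf$coords)
})

test_that("optimize_stage is deterministic, lowers the energy, and
          n_steps = 0 is the identity", {
  set.seed(1)
  conf <- random_initial_conformation(make_lattice(
    genome_assembly("c", 5e5), 1e4), seed = 4)  # 50 beads
  set.seed(21)
  i <- sample(0:48, 25, TRUE)
  j <- pmin(i + sample(1:15, 25, TRUE), 49L)
  ok <- i != j
  bc <- make_contacts(conf$lattice, i[ok], j[ok])
  cfg <- optimizer_config()
  expect_equal(optimize_stage(conf, bc, 0L)$coords, conf$coords)
  o1 <- optimize_stage(conf, bc, 150L, shrink_every = 10L, config = cfg)
  o2 <- optimize_stage(conf, bc, 150L, shrink_every = 10L, config = cfg)
  expect_identical(o1$coords, o2$coords)
  expect_lt(total_energy(o1, bc), total_energy(conf, bc))
})

test_that("random initial conformations are reproducible walks with unit
          steps", {
  lat <- make_lattice(genome_assembly(c("c1", "c2"), c(3e5, 2e5)), 1e4)
  c1 <- random_initial_conformation(lat, seed = 33)
  c2 <- random_initial_conformation(lat, seed = 33)
  expect_identical(c1$coords, c2$coords)
  c3 <- random_initial_conformation(lat, seed = 34)
  expect_gt(max(abs(c1$coords - c3$coords)), 0)
  # adjacent intra-chromosome beads at distance a (up to the 1e-6 jitter)
  b <- beadfold:::backbone_bonds(lat)
  d <- sqrt(rowSums((c1$coords[b$b1 + 1, ] - c1$coords[b$b2 + 1, ])^2))
  expect_equal(d, rep(1, length(d)), tolerance = 1e-5)
})

test_that("bead splitting follows the parent/midpoint rule with the
          terminal child at the parent", {
  conf <- conformation(make_lattice(genome_assembly("c", 4e4), 2e4),
                       rbind(c(0, 0, 0), c(2, 0, 0)))
  hi <- split_beads(conf)
  expect_equal(hi$lattice$resolution, 1e4)
  expect_equal(hi$coords,
               rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 0, 0)),
               ignore_attr = TRUE)
  # energy is finite once coincident children are separated
  sep <- resolve_coincident(hi)
  bc <- make_contacts(hi$lattice, 0L, 2L)
  expect_true(is.finite(total_energy(sep, bc)))
})

test_that("bead counts double per chromosome on splitting, respecting odd
          terminal bins", {
  asm <- genome_assembly(c("c1", "c2"), c(5e4, 4e4))
  lo <- make_lattice(asm, 2e4)       # 3 + 2 beads
  hi <- make_lattice(asm, 1e4)       # 5 + 4 beads
  conf <- random_initial_conformation(lo, seed = 3)
  sp <- split_beads(conf)
  expect_equal(sp$lattice$n_beads, hi$n_beads)
  # child 1 of each parent sits at the parent position
  expect_equal(sp$coords[1, ], conf$coords[1, ], ignore_attr = TRUE)
  expect_equal(sp$coords[3, ], conf$coords[2, ], ignore_attr = TRUE)
})

test_that("the resolution ladder reproduces the published sequences", {
  expect_equal(resolution_ladder(1e4) / 1e3,
               c(1280, 640, 320, 160, 80, 40, 20, 10))
  expect_equal(resolution_ladder(1e5)[1] / 1e3, 1600)
  expect_equal(resolution_ladder(1e3)[1] / 1e3, 1024)
  expect_equal(resolution_ladder(2e6), 2e6)  # already at the floor
})

test_that("infer_structure returns the requested lattice and run_ensemble
          is replica-deterministic", {
  spec <- toy_two_domain_spec(chrom_length = 6e5, resolution = 2e4,
                              seed = 2)
  truth <- simulate_truth(spec)
  rec <- sample_contacts(truth, spec, seed = 12)
  cfg <- optimizer_config(stage1_steps = 100L, stage2_steps = 150L,
                          refine_steps = 150L, replicas = 2L,
                          ladder_floor = 4e4, seed = 9L)
  conf <- infer_structure(rec, spec$assembly, 2e4, cfg)
  expect_equal(conf$lattice$n_beads, 30L)
  expect_equal(attr(conf, "ladder"), c(4e4, 2e4))
  ensA <- run_ensemble(rec, spec$assembly, 2e4, cfg)
  ensB <- run_ensemble(rec, spec$assembly, 2e4, cfg)
  expect_identical(ensA$conformations[[1]]$coords,
                   ensB$conformations[[1]]$coords)
  expect_identical(ensA$conformations[[2]]$coords,
                   ensB$conformations[[2]]$coords)
  expect_equal(ensA$seeds, c(9L, 10L))
  # replicas differ from each other (different random starts)
  expect_gt(max(abs(ensA$conformations[[1]]$coords -
                    ensA$conformations[[2]]$coords)), 0)
  expect_error(infer_structure(rec[0, ], spec$assembly, 2e4, cfg),
               "no usable contacts|no contact")
})

test_that("checkpoints are written per ladder level and resumable as TSV", {
  spec <- toy_two_domain_spec(chrom_length = 4e5, resolution = 2e4,
                              seed = 5)
  truth <- simulate_truth(spec)
  rec <- sample_contacts(truth, spec, seed = 6)
  cfg <- optimizer_config(stage1_steps = 50L, stage2_steps = 50L,
                          refine_steps = 50L, ladder_floor = 4e4)
  dir <- tempfile("ckpt")
  conf <- infer_structure(rec, spec$assembly, 2e4, cfg,
                          checkpoint_dir = dir)
  files <- list.files(dir)
  expect_length(files, 2L)
  final <- read_structure_tsv(file.path(dir, "level_020000bp.tsv"))
  expect_equal(final$coords, conf$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
})
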