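test_that("violation percentage counts restraints beyond a strict 2 bd", {
  conf <- line_conformation(10)
  # distances: (0,1)=1, (1,4)=3, (2,4)=2, (5,9)=4
  bc <- make_contacts(conf$lattice, c(0L, 1L, 2L, 5L), c(1L, 4L, 4L, 9L))
  expect_equal(violation_percentage(conf, bc), 50)
  # r exactly 2a is not a violation
  bc2 <- make_contacts(conf$lattice, 2L, 4L)
  expect_equal(violation_percentage(conf, bc2), 0)
  # all satisfied
  bc3 <- make_contacts(conf$lattice, c(0L, 3L), c(1L, 4L), c(5L, 1L))
  expect_equal(violation_percentage(conf, bc3), 0)
  # multiplicity does not change the count: pairs are single restraints
  bc4 <- make_contacts(conf$lattice, c(0L, 1L), c(1L, 4L), c(9L, 1L))
  expect_equal(violation_percentage(conf, bc4), 50)
  bce <- make_contacts(conf$lattice, integer(0), integer(0), integer(0))
  expect_error(violation_percentage(conf, bce), "no contact")
})

test_that("violation percentage does not increase when violated pairs
          close in", {
  conf <- line_conformation(10)
  bc <- make_contacts(conf$lattice, c(0L, 1L), c(5L, 9L))
  v0 <- violation_percentage(conf, bc)
  squeezed <- conformation(conf$lattice, conf$coords * 0.5)
  expect_lte(violation_percentage(squeezed, bc), v0)
})

test_that("pairwise RMSD is blind to rotation, translation and chirality", {
  conf <- random_conformation(10, seed = 8)
  expect_equal(pairwise_rmsd(conf, conf), 0, tolerance = 1e-8)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- conformation(conf$lattice,
                        conf$coords %*% R + rep(c(3, -1, 2), each = 10))
  expect_equal(pairwise_rmsd(conf, moved), 0, tolerance = 1e-8)
  mirrored <- conformation(conf$lattice,
                           conf$coords %*% diag(c(-1, 1, 1)))
  expect_equal(pairwise_rmsd(conf, mirrored), 0, tolerance = 1e-8)
})

test_that("pairwise RMSD matches an orthogonal-Procrustes oracle", {
  skip_if_not_installed("vegan")
  for (seed in 1:4) {
    a <- random_conformation(10, seed = seed)
    b <- random_conformation(10, seed = seed + 50)
    ours <- pairwise_rmsd(a, b)
    # vegan::procrustes solves min ||Y R - X|| over orthogonal R (incl.
    # reflections) with symmetric = FALSE, scale = FALSE
    pr <- vegan::procrustes(a$coords, b$coords, scale = FALSE,
                            symmetric = FALSE)
    oracle <- sqrt(sum(stats::residuals(pr)^2) / 10)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("pairwise RMSD behaves as a pseudometric on random triples", {
  for (seed in 1:3) {
    a <- random_conformation(12, seed = seed)
    b <- random_conformation(12, seed = seed + 10)
    c_ <- random_conformation(12, seed = seed + 20)
    dab <- pairwise_rmsd(a, b)
    dba <- pairwise_rmsd(b, a)
    expect_equal(dab, dba, tolerance = 1e-8)
    expect_lte(pairwise_rmsd(a, c_), dab + pairwise_rmsd(b, c_) + 1e-8)
  }
})

test_that("nuclear-radius normalisation divides by the bounding radius", {
  a <- random_conformation(15, seed = 4)
  b <- random_conformation(15, seed = 5)
  expect_equal(pairwise_rmsd(a, b, normalize = "nuclear_radius"),
               pairwise_rmsd(a, b) / nuclear_radius(a), tolerance = 1e-12)
  X <- scale(a$coords, scale = FALSE)
  expect_equal(nuclear_radius(a), sqrt(max(rowSums(X^2))))
})

test_that("distance matrices are exact Euclidean distances in bd", {
  conf <- line_conformation(8)
  dm <- distance_matrix(conf)
  expect_equal(unclass(dm), abs(outer(0:7, 0:7, "-")) * 1,
               ignore_attr = TRUE)
  conf2 <- random_conformation(9, seed = 6)
  dm2 <- distance_matrix(conf2)
  expect_equal(diag(dm2), rep(0, 9))
  expect_equal(unclass(dm2), t(unclass(dm2)), ignore_attr = TRUE)
  # dense oracle
  oracle <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9)
    oracle[i, j] <- sqrt(sum((conf2$coords[i, ] - conf2$coords[j, ])^2))
  expect_equal(unclass(dm2), oracle, ignore_attr = TRUE)
  expect_error(distance_matrix(conf, from = 2, to = 20), "within")
})

test_that("separation score peaks at a planted gap between two clusters", {
  # two tight clusters far apart: 12 + 12 beads
  set.seed(2)
  X <- rbind(matrix(rnorm(36, 0, 0.3), 12, 3),
             matrix(rnorm(36, 0, 0.3), 12, 3) +
               rep(c(30, 0, 0), each = 12))
  conf <- conformation(make_lattice(genome_assembly("c", 24e4), 1e4), X)
  s <- separation_score(distance_matrix(conf), w = 6)
  expect_true(all(is.na(s[1:6])))
  expect_true(all(is.na(s[20:24])))
  expect_equal(which.max(s), 13L)  # boundary: first bead of cluster 2
  # rigid motion invariance
  R <- diag(3)[c(2, 3, 1), ]
  conf2 <- conformation(conf$lattice, X %*% R + 5)
  expect_equal(separation_score(distance_matrix(conf2), w = 6), s,
               tolerance = 1e-9)
})

test_that("a uniform random coil has no dominant separation peak", {
  set.seed(14)
  X <- apply(matrix(rnorm(3 * 60), 60, 3), 2, cumsum)
  conf <- conformation(make_lattice(genome_assembly("c", 6e5), 1e4), X)
  s <- separation_score(distance_matrix(conf), w = 10)
  s <- s[!is.na(s)]
  expect_lt(max(s), 2 * stats::median(s))
})

test_that("boundary calls pick prominent local maxima, ties to the lower
          index", {
  expect_equal(nrow(call_boundaries(c(NA, 1:8, NA), 0.1)), 0L)
  one <- call_boundaries(c(1, 1, 5, 1, 1), 0.5)
  expect_equal(one$bead, 3L)
  expect_equal(one$prominence, 4)
  # plateau peak resolves to its first index
  plat <- call_boundaries(c(0, 3, 3, 0), 0.5)
  expect_equal(plat$bead, 2L)
  # prominence threshold suppresses minor wiggles
  two <- call_boundaries(c(0, 5, 4.8, 4.9, 0.5, 6, 0), min_prominence = 1)
  expect_equal(two$bead, c(2L, 6L))
  expect_equal(call_boundaries(c(0, 5, 4.8, 4.9, 0.5, 6, 0), 5)$bead, 6L)
})

test_that("gyration radius profile matches closed forms and flags edges", {
  # coincident beads: zero
  lat <- make_lattice(genome_assembly("c", 3e5), 1e4)
  conf0 <- conformation(lat, matrix(1, 30, 3))
  rg0 <- rg_profile(conf0, fragment_size = 1e5)
  expect_equal(rg0[!is.na(rg0)], rep(0, sum(!is.na(rg0))))
  # collinear beads at spacing a, window of n beads: a sqrt((n^2-1)/12)
  confl <- line_conformation(30)
  for (frag in c(1e5, 2e5)) {
    n_w <- frag / 1e4
    rgl <- rg_profile(confl, fragment_size = frag)
    expect_equal(unique(round(rgl[!is.na(rgl)], 9)),
                 round(sqrt((n_w^2 - 1) / 12), 9))
  }
  # edge windows are missing
  expect_true(is.na(rg_profile(confl, 2e5)[1]))
  # an extended linker between two globules peaks at the linker
  set.seed(3)
  X <- rbind(matrix(rnorm(30, 0, 0.4), 10, 3),
             cbind(seq(2, 20, length.out = 10), 0, 0),
             matrix(rnorm(30, 0, 0.4), 10, 3) + rep(c(22, 0, 0), each = 10))
  confg <- conformation(make_lattice(genome_assembly("c", 3e5), 1e4), X)
  rgg <- rg_profile(confg, fragment_size = 6e4)
  expect_true(which.max(rgg) %in% 11:20)
})

test_that("ensemble reliability is judged by the median pairwise RMSD", {
  lat <- make_lattice(genome_assembly("c", 1e5), 1e4)
  confs <- lapply(1:4, function(s) {
    set.seed(s)
    conformation(lat, matrix(rnorm(30, sd = 0.1), 10, 3))
  })
  bc <- make_contacts(lat, 0L, 5L)
  ens <- structure(list(conformations = confs, seeds = 1:4,
                        config = optimizer_config(), contacts = bc),
                   class = "structure_ensemble")
  er <- ensemble_rmsd(ens)
  expect_equal(dim(er$rmsd), c(4L, 4L))
  expect_true(er$reliable)  # near-identical tight clouds
  expect_equal(er$median, stats::median(er$rmsd[upper.tri(er$rmsd)]))
})
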