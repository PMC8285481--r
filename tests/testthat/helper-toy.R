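# Small fixtures built in code; everything is deterministic per seed.

toy_assembly <- function() genome_assembly(c("chrA", "chrB"), c(2e4, 2e4))

toy_lattice <- function(resolution = 1e4) make_lattice(toy_assembly(),
                                                       resolution)

# a straight chain along x at spacing `a`, one chromosome
line_conformation <- function(n = 10, a = 1, resolution = 1e4) {
  asm <- genome_assembly("chrL", n * resolution)
  lat <- make_lattice(asm, resolution)
  conformation(lat, cbind(a * (seq_len(n) - 1), 0, 0))
}

# binned contacts straight from 0-based index vectors
make_contacts <- function(lattice, i, j, c = 1L) {
  beadfold:::binned_contacts(lattice, as.integer(pmin(i, j)),
                             as.integer(pmax(i, j)),
                             as.integer(rep_len(c, length(i))))
}

# write a minimal 4/5-column TSV contact file; returns the path
write_toy_contacts <- function(lines, dir = tempdir()) {
  path <- tempfile("contacts", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_conformation <- function(n = 20, seed = 1, spread = 3,
                                resolution = 1e4) {
  set.seed(seed)
  asm <- genome_assembly("chrR", n * resolution)
  lat <- make_lattice(asm, resolution)
  conformation(lat, matrix(stats::rnorm(3 * n, sd = spread), n, 3))
}

# brute-force O(N^2) total energy in plain R, independent of the C++ path
reference_energy <- function(conf, contacts, params = energy_params()) {
  X <- conf$coords
  n <- nrow(X)
  cmat <- matrix(0L, n, n)
  if (length(contacts$i))
    cmat[cbind(contacts$i + 1L, contacts$j + 1L)] <- contacts$c
  e <- 0
  eps0 <- function(r) {
    rr <- min(r, params$plateau_radius * params$a)
    -2 * log(rr) + params$s_exponent *
      log(1 + exp(-params$sigmoid_rate * (rr - params$r0)))
  }
  epsc <- function(r, cc) {
    rt <- params$taylor_fraction * params$r0
    f <- function(x) -2 * log(x) -
      (cc / 2) * log((params$r0 - x) / (params$r0 + x))
    g <- function(x) -2 / x + cc * params$r0 / (params$r0^2 - x^2)
    if (r < rt) f(r) else f(rt) + g(rt) * (r - rt)
  }
  cid <- beadfold:::bead_chrom_id(conf$lattice)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (j == i + 1 && cid[i] == cid[j])
      e <- e + params$k / 2 * (r - params$a)^2
    e <- e + if (cmat[i, j] > 0) epsc(r, cmat[i, j]) else eps0(r)
  }
  e
}
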