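#' Write a conformation as TSV
#'
#' One row per bead: chrom, start, end (0-based half-open), x, y, z in
#' units of \code{a}.
#'
#' @param conf a \code{\link{conformation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_tsv <- function(conf, path) {
  rng <- bead_ranges(conf$lattice)
  out <- cbind(rng[, c("chrom", "start", "end")],
               as.data.frame(conf$coords))
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a conformation written by \code{\link{write_structure_tsv}}
#'
#' The lattice is reconstructed from the intervals in the file; chromosome
#' order follows first appearance.
#'
#' @param path input path.
#' @return a \code{\link{conformation}}.
#' @export
read_structure_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  chroms <- unique(tab$chrom)
  lens <- vapply(chroms, function(ch) max(tab$end[tab$chrom == ch]),
                 numeric(1))
  res <- max(tab$end - tab$start)
  lat <- make_lattice(genome_assembly(chroms, lens), res)
  if (lat$n_beads != nrow(tab))
    stop("file does not describe a complete lattice")
  conformation(lat, as.matrix(tab[, c("x", "y", "z")]))
}

#' Write a conformation as a PDB-like file for molecular viewers
#'
#' One pseudo-atom per bead, one chain per chromosome (chain IDs cycle
#' through A-Z, a-z, 0-9), coordinates multiplied by \code{scale}
#' (interpretable as Angstroms per bead diameter). Multiple conformations
#' are written as successive MODEL records.
#'
#' @param confs a \code{\link{conformation}} or list of conformations on
#'   one lattice.
#' @param path output path.
#' @param scale multiplier applied to the coordinates (default 10).
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(confs, path, scale = 10) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  lat <- confs[[1]]$lattice
  chain_ids <- c(LETTERS, letters, 0:9)
  cid <- chain_ids[(bead_chrom_id(lat) - 1L) %% length(chain_ids) + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    X <- confs[[m]]$coords * scale
    serial <- (seq_len(lat$n_beads) - 1L) %% 99999L + 1L
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial, cid, (seq_len(lat$n_beads) - 1L) %% 9999L + 1L,
      X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a distance matrix as dense TSV
#' @param dm a \code{\link{distance_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(unclass(dm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of inputs, parameters and seeds sufficient to reproduce a
#' run bit-exactly.
#'
#' @param path output path.
#' @param inputs named list of input file paths.
#' @param config an \code{\link{optimizer_config}}.
#' @param extra optional named list merged into the manifest.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, inputs, config, extra = list()) {
  manifest <- c(list(
    package = "beadfold",
    version = as.character(utils::packageVersion("beadfold")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = unclass(config)[setdiff(names(config), "energy_params")],
    energy_params = unclass(config$energy_params)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
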