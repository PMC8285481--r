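#' Genome assembly: ordered chromosome names and lengths
#'
#' An assembly is the ordered list of chromosomes (name, length in bp) that
#' defines the global bead indexing at any resolution. Order is fixed: bead
#' indices are assigned chromosome by chromosome in the order given here.
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in base pairs (> 0).
#' @return An object of class \code{genome_assembly}: a data.frame with
#'   columns \code{name} and \code{length}.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_assembly <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) == 0L)
    stop("assembly must contain at least one chromosome")
  if (length(chromosomes) != length(lengths))
    stop("'chromosomes' and 'lengths' must have equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(name = chromosomes, length = lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_assembly", "data.frame")
  out
}

#' Read a UCSC chrom.sizes table
#'
#' Two-column TSV (name, length). Chromosome order in the file is preserved.
#'
#' @param path path to a chrom.sizes file.
#' @return A \code{\link{genome_assembly}}.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  genome_assembly(tab$name, tab$length)
}

#' Write a chrom.sizes table
#' @param assembly a \code{\link{genome_assembly}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  utils::write.table(assembly[, c("name", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bead lattice: the assembly divided into equally sized beads
#'
#' Divides every chromosome into consecutive, equally sized beads of
#' \code{resolution} bp; the last bead of a chromosome may cover less than a
#' full bead. Global bead indices are 0-based and contiguous across
#' chromosomes in assembly order.
#'
#' @param assembly a \code{\link{genome_assembly}}.
#' @param resolution bead size in base pairs (>= 1).
#' @return An object of class \code{bead_lattice} with fields
#'   \code{assembly}, \code{resolution}, \code{n_per_chrom}, \code{offsets}
#'   (0-based starting global index per chromosome) and \code{n_beads}.
#' @examples
#' asm <- genome_assembly("chrA", 25000)
#' make_lattice(asm, 10000)$n_beads  # 3 beads
#' @export
make_lattice <- function(assembly, resolution) {
  stopifnot(inherits(assembly, "genome_assembly"))
  resolution <- as.numeric(resolution)
  if (!is.finite(resolution) || resolution < 1)
    stop("resolution must be >= 1 bp")
  n_per_chrom <- as.integer(ceiling(assembly$length / resolution))
  offsets <- c(0L, cumsum(n_per_chrom))[seq_along(n_per_chrom)]
  structure(list(assembly = assembly,
                 resolution = resolution,
                 n_per_chrom = n_per_chrom,
                 offsets = offsets,
                 n_beads = sum(n_per_chrom)),
            class = "bead_lattice")
}

#' @export
print.bead_lattice <- function(x, ...) {
  cat(sprintf("bead_lattice: %d chromosome(s), resolution %s bp, %d beads\n",
              nrow(x$assembly), format(x$resolution, big.mark = ","),
              x$n_beads))
  invisible(x)
}

chrom_index <- function(lattice, chrom) {
  idx <- match(chrom, lattice$assembly$name)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  idx
}

#' Map genomic loci to global bead indices
#'
#' Input positions are 1-based base pairs; bins are half-open
#' \code{[start, end)} after conversion to 0 based, so position
#' \code{resolution} falls in bead 0 and \code{resolution + 1} in bead 1.
#'
#' @param lattice a \code{\link{make_lattice}} result.
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s) in bp; recycled against \code{chrom}.
#' @return Integer vector of 0-based global bead indices.
#' @examples
#' lat <- make_lattice(genome_assembly(c("chrA", "chrB"), c(2e4, 2e4)), 1e4)
#' locus_to_bead(lat, "chrB", 1)  # 2
#' @export
locus_to_bead <- function(lattice, chrom, pos) {
  stopifnot(inherits(lattice, "bead_lattice"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  ci <- chrom_index(lattice, chrom)
  len <- lattice$assembly$length[ci]
  bad <- which(!is.finite(pos) | pos < 1 | pos > len)
  if (length(bad))
    stop(sprintf("position out of range: %s:%s (chromosome length %s)",
                 chrom[bad[1]], format(pos[bad[1]]), format(len[bad[1]])))
  as.integer(lattice$offsets[ci] + floor((pos - 1) / lattice$resolution))
}

#' Genomic intervals covered by each bead
#'
#' Inverse of \code{\link{locus_to_bead}}: returns, for each global bead
#' index, its chromosome and 0-based half-open genomic interval.
#'
#' @param lattice a bead lattice.
#' @param beads 0-based global bead indices (default: all beads).
#' @return data.frame with columns \code{bead}, \code{chrom}, \code{start},
#'   \code{end} (end clipped to the chromosome length).
#' @export
bead_ranges <- function(lattice, beads = seq_len(lattice$n_beads) - 1L) {
  stopifnot(inherits(lattice, "bead_lattice"))
  beads <- as.integer(beads)
  if (any(beads < 0L | beads >= lattice$n_beads))
    stop("bead index out of range")
  ends <- cumsum(lattice$n_per_chrom)
  ci <- findInterval(beads, ends) + 1L
  local_bin <- beads - lattice$offsets[ci]
  start <- local_bin * lattice$resolution
  end <- pmin(start + lattice$resolution, lattice$assembly$length[ci])
  data.frame(bead = beads, chrom = lattice$assembly$name[ci],
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Per-bead chromosome index (1-based into the assembly)
#' @keywords internal
bead_chrom_id <- function(lattice) {
  rep.int(seq_along(lattice$n_per_chrom), lattice$n_per_chrom)
}

#' A conformation: bead coordinates on a lattice
#'
#' Coordinates are in units of the bead diameter \code{a} (\code{a = 1}
#' internally).
#'
#' @param lattice a bead lattice.
#' @param coords numeric matrix \code{n_beads x 3}.
#' @return Object of class \code{conformation}.
#' @export
conformation <- function(lattice, coords) {
  stopifnot(inherits(lattice, "bead_lattice"))
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != lattice$n_beads)
    stop("coords must be a numeric n_beads x 3 matrix")
  if (any(!is.finite(coords))) stop("coords must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(lattice = lattice, coords = coords),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: %d beads at %s bp resolution\n",
              x$lattice$n_beads, format(x$lattice$resolution, big.mark = ",")))
  invisible(x)
}
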