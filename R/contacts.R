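#' Read single-cell Hi-C contact records
#'
#' Parses tab-separated contact lists into a data.frame of records with
#' columns \code{chromA}, \code{posA}, \code{chromB}, \code{posB},
#' \code{count}. Positions are 1-based base pairs. Lines starting with
#' \code{#} (and the \code{.pairs} \code{columns:} header) are skipped.
#'
#' Dialects:
#' \describe{
#'   \item{\code{tsv4}}{minimal 4/5-column TSV: chromA posA chromB posB
#'     [count].}
#'   \item{\code{pairs}}{4DN-style .pairs: readID chr1 pos1 chr2 pos2
#'     [strand1 strand2]; strands ignored, count 1 per line.}
#'   \item{\code{ncc}}{column-index mapped dialect; give the 1-based indices
#'     of chromA/posA/chromB/posB in \code{columns}. The default matches NCC
#'     files, where each of the two read ends carries chromosome, start and
#'     end fields and the contact position is the leading coordinate.}
#' }
#'
#' @param path input file.
#' @param dialect one of \code{"tsv4"}, \code{"pairs"}, \code{"ncc"}.
#' @param columns for \code{dialect = "ncc"}: integer vector of length 4
#'   (or 5, with a count column) giving the source columns of chromA, posA,
#'   chromB, posB (, count).
#' @param assembly optional \code{\link{genome_assembly}} used to validate
#'   chromosome names and positions.
#' @param on_unknown what to do with records on chromosomes absent from
#'   \code{assembly}: \code{"error"} (default) or \code{"skip"} with a
#'   warning.
#' @return data.frame of contact records (class \code{contact_records}).
#' @export
read_contacts <- function(path,
                          dialect = c("tsv4", "pairs", "ncc"),
                          columns = NULL,
                          assembly = NULL,
                          on_unknown = c("error", "skip")) {
  dialect <- match.arg(dialect)
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop("contact file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no contact records in ", path)
    return(contact_records(character(0), numeric(0), character(0),
                           numeric(0), integer(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  idx <- switch(dialect,
                tsv4 = c(1L, 2L, 3L, 4L, 5L),
                pairs = c(2L, 3L, 4L, 5L, NA_integer_),
                ncc = {
                  if (is.null(columns))
                    columns <- c(1L, 2L, 7L, 8L)
                  if (!length(columns) %in% 4:5)
                    stop("'columns' must give 4 or 5 column indices")
                  c(as.integer(columns),
                    if (length(columns) == 4L) NA_integer_)
                })
  need <- max(idx, na.rm = TRUE)
  nf <- lengths(fields)
  if (any(nf < max(idx[1:4]))) {
    bad <- lineno[which(nf < max(idx[1:4]))[1]]
    stop(sprintf("line %d of %s: expected at least %d fields", bad, path,
                 max(idx[1:4])))
  }
  pick <- function(j) vapply(fields, `[`, character(1), j)
  chromA <- pick(idx[1]); chromB <- pick(idx[3])
  posA <- suppressWarnings(as.numeric(pick(idx[2])))
  posB <- suppressWarnings(as.numeric(pick(idx[4])))
  if (anyNA(posA) || anyNA(posB)) {
    bad <- lineno[which(is.na(posA) | is.na(posB))[1]]
    stop(sprintf("line %d of %s: non-numeric position", bad, path))
  }
  count <- rep.int(1L, length(lines))
  if (!is.na(idx[5])) {
    raw <- vapply(fields, function(f)
      if (length(f) >= idx[5]) f[[idx[5]]] else NA_character_, character(1))
    cnt <- suppressWarnings(as.integer(raw))
    count <- ifelse(is.na(cnt), 1L, cnt)
    if (any(count < 1L)) {
      bad <- lineno[which(count < 1L)[1]]
      stop(sprintf("line %d of %s: count must be >= 1", bad, path))
    }
  }
  rec <- contact_records(chromA, posA, chromB, posB, count)
  if (!is.null(assembly)) {
    known <- rec$chromA %in% assembly$name & rec$chromB %in% assembly$name
    if (!all(known)) {
      if (on_unknown == "error") {
        bad <- lineno[which(!known)[1]]
        stop(sprintf("line %d of %s: chromosome not in assembly", bad, path))
      }
      warning(sum(!known), " record(s) on chromosomes absent from the ",
              "assembly were skipped")
      rec <- rec[known, , drop = FALSE]
      class(rec) <- c("contact_records", "data.frame")
    }
  }
  rec
}

#' Construct a contact-record table
#' @param chromA,posA,chromB,posB loci of the two read ends (1-based bp).
#' @param count read multiplicity per record (>= 1, default 1).
#' @return data.frame of class \code{contact_records}.
#' @export
contact_records <- function(chromA, posA, chromB, posB, count = 1L) {
  n <- length(chromA)
  count <- rep_len(as.integer(count), n)
  if (any(count < 1L)) stop("count must be >= 1")
  out <- data.frame(chromA = as.character(chromA), posA = as.numeric(posA),
                    chromB = as.character(chromB), posB = as.numeric(posB),
                    count = count, stringsAsFactors = FALSE)
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Write contact records as minimal 4/5-column TSV
#' @param records a \code{contact_records} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts <- function(records, path) {
  cols <- c("chromA", "posA", "chromB", "posB")
  if (any(records$count != 1L)) cols <- c(cols, "count")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove isolated contacts unsupported within 2-Mb windows
#'
#' Bins both loci of every record into fixed 2-Mb windows (grid anchored at
#' coordinate 0) and keeps a record only if at least \code{min_support}
#' OTHER read observations fall in the same unordered window pair. A record
#' with count k contributes k observations, so duplicates support each
#' other.
#'
#' @param records a \code{contact_records} data.frame.
#' @param window window size in bp (default 2,000,000).
#' @param min_support minimum number of other supporting observations
#'   (default 1).
#' @return list with elements \code{kept} and \code{removed}, both
#'   \code{contact_records}.
#' @export
filter_isolated_contacts <- function(records, window = 2e6,
                                     min_support = 1L) {
  stopifnot(window >= 1)
  if (nrow(records) == 0L)
    return(list(kept = records, removed = records))
  wA <- floor((records$posA - 1) / window)
  wB <- floor((records$posB - 1) / window)
  keyA <- paste0(records$chromA, ":", wA)
  keyB <- paste0(records$chromB, ":", wB)
  swap <- keyA > keyB
  key <- paste(ifelse(swap, keyB, keyA), ifelse(swap, keyA, keyB),
               sep = "|")
  tot <- tapply(records$count, key, sum)
  # each read observation is supported by the tot - 1 others in its window
  # pair; duplicates within one record support each other
  support <- as.numeric(tot[key]) - 1
  keep <- support >= min_support
  kept <- records[keep, , drop = FALSE]
  removed <- records[!keep, , drop = FALSE]
  class(kept) <- class(removed) <- c("contact_records", "data.frame")
  list(kept = kept, removed = removed)
}

#' Bin contact records onto a bead lattice
#'
#' Maps each record's two loci to beads and accumulates integer counts per
#' unordered bead pair. Records whose two ends fall in the same bead are
#' dropped (they carry no structural information) and tallied.
#'
#' Intended use is a 1-kb base map (\code{lattice} at 1000 bp) that is then
#' coarsened with \code{\link{merge_bins}}, but any resolution is accepted
#' and direct binning equals binning at 1 kb followed by merging.
#'
#' @param records a \code{contact_records} data.frame.
#' @param lattice target \code{\link{make_lattice}}.
#' @return Object of class \code{binned_contacts}: list with \code{lattice},
#'   \code{i}, \code{j} (0-based bead indices, i < j), \code{c} (counts),
#'   \code{dropped_self} (reads dropped as self-bead).
#' @export
bin_contacts <- function(records, lattice) {
  stopifnot(inherits(lattice, "bead_lattice"))
  if (nrow(records) == 0L)
    return(binned_contacts(lattice, integer(0), integer(0), integer(0), 0L))
  bA <- locus_to_bead(lattice, records$chromA, records$posA)
  bB <- locus_to_bead(lattice, records$chromB, records$posB)
  self <- bA == bB
  dropped <- sum(records$count[self])
  i <- pmin(bA, bB)[!self]
  j <- pmax(bA, bB)[!self]
  cnt <- records$count[!self]
  if (length(i)) {
    key <- paste(i, j)
    agg <- rowsum(as.numeric(cnt), key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    i <- as.integer(vapply(parts, `[`, character(1), 1L))
    j <- as.integer(vapply(parts, `[`, character(1), 2L))
    cnt <- as.integer(agg[, 1])
    o <- order(i, j)
    i <- i[o]; j <- j[o]; cnt <- cnt[o]
  }
  binned_contacts(lattice, i, j, cnt, dropped)
}

binned_contacts <- function(lattice, i, j, c, dropped_self = 0L) {
  stopifnot(all(i < j | length(i) == 0L))
  structure(list(lattice = lattice, i = as.integer(i), j = as.integer(j),
                 c = as.integer(c), dropped_self = as.integer(dropped_self)),
            class = "binned_contacts")
}

#' @export
print.binned_contacts <- function(x, ...) {
  cat(sprintf(paste0("binned_contacts: %d bead pair(s), %d read(s) at %s bp",
                     " resolution (%d self-bead read(s) dropped)\n"),
              length(x$i), sum(x$c),
              format(x$lattice$resolution, big.mark = ","), x$dropped_self))
  invisible(x)
}

#' Total reads kept in a binned contact map
#' @param contacts a \code{binned_contacts} object.
#' @return integer total of all pair counts.
#' @export
total_reads <- function(contacts) sum(contacts$c)

#' Merge a binned contact map to a coarser resolution
#'
#' Merges consecutive base beads into beads of \code{target_resolution}
#' (an integer multiple of the base resolution). Counts are summed per
#' coarse pair; pairs whose beads merge into one coarse bead become
#' self-bead contacts and are dropped and tallied, so
#' \code{kept + dropped = base total}.
#'
#' @param base a \code{binned_contacts} map (e.g. the 1-kb base map).
#' @param target_resolution coarse resolution in bp.
#' @return \code{binned_contacts} at the target resolution; its
#'   \code{dropped_self} includes the base map's tally.
#' @export
merge_bins <- function(base, target_resolution) {
  stopifnot(inherits(base, "binned_contacts"))
  r0 <- base$lattice$resolution
  k <- target_resolution / r0
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("target resolution must be an integer multiple of the base ",
         "resolution")
  lat <- make_lattice(base$lattice$assembly, target_resolution)
  if (length(base$i) == 0L)
    return(binned_contacts(lat, integer(0), integer(0), integer(0),
                           base$dropped_self))
  # Convert global base index -> (chrom, local bin) -> coarse global index.
  ends <- cumsum(base$lattice$n_per_chrom)
  coarse_of <- function(b) {
    ci <- findInterval(b, ends) + 1L
    local <- b - base$lattice$offsets[ci]
    as.integer(lat$offsets[ci] + floor(local / k))
  }
  bi <- coarse_of(base$i)
  bj <- coarse_of(base$j)
  self <- bi == bj
  dropped <- base$dropped_self + sum(base$c[self])
  i <- pmin(bi, bj)[!self]
  j <- pmax(bi, bj)[!self]
  cnt <- base$c[!self]
  if (length(i)) {
    key <- paste(i, j)
    agg <- rowsum(as.numeric(cnt), key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    i <- as.integer(vapply(parts, `[`, character(1), 1L))
    j <- as.integer(vapply(parts, `[`, character(1), 2L))
    cnt <- as.integer(agg[, 1])
    o <- order(i, j)
    i <- i[o]; j <- j[o]; cnt <- cnt[o]
  }
  binned_contacts(lat, i, j, cnt, dropped)
}

#' Contact reads per bead
#'
#' Reads usable at the working resolution (kept after binning, i.e. after
#' self-bead contacts are discarded) divided by the number of beads. The
#' reliability rule of thumb for choosing a resolution is that this ratio
#' should exceed 0.2.
#'
#' @param contacts a \code{binned_contacts} object, or a plain read total.
#' @param n_beads bead count; defaults to the contact map's lattice size.
#' @return the ratio (double).
#' @examples
#' contacts_per_bead(110623, 658453)  # 0.168
#' @export
contacts_per_bead <- function(contacts, n_beads = NULL) {
  if (inherits(contacts, "binned_contacts")) {
    if (is.null(n_beads)) n_beads <- contacts$lattice$n_beads
    reads <- sum(contacts$c)
  } else {
    reads <- as.numeric(contacts)
    if (is.null(n_beads)) stop("n_beads required with a plain read total")
  }
  if (n_beads <= 0) stop("n_beads must be positive")
  reads / n_beads
}
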