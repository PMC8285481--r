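#' Percentage of violated contact restraints
#'
#' A contact restraint (one bead pair with c != 0, counted once regardless
#' of its read multiplicity) is violated when the model distance between
#' the two beads exceeds the threshold, by default 2 bead diameters.
#' Distances exactly at the threshold are not violations (strict >).
#'
#' @param conf a \code{\link{conformation}}.
#' @param contacts \code{binned_contacts} on the same lattice.
#' @param threshold violation distance in units of \code{a} (default 2).
#' @return percentage in [0, 100].
#' @export
violation_percentage <- function(conf, contacts, threshold = 2) {
  check_same_lattice(conf, contacts)
  if (length(contacts$i) == 0L) stop("no contact restraints to check")
  D <- conf$coords[contacts$i + 1L, , drop = FALSE] -
       conf$coords[contacts$j + 1L, , drop = FALSE]
  r <- sqrt(rowSums(D^2))
  100 * sum(r > threshold) / length(r)
}

#' Pairwise RMSD after optimal superposition
#'
#' Root-mean-square deviation between two conformations on the same
#' lattice after the rigid superposition (rotation + translation)
#' minimising it; the reflected superposition is also evaluated and the
#' smaller RMSD returned, because contact data cannot constrain chirality.
#' With \code{normalize = "nuclear_radius"} the RMSD is divided by the
#' nuclear radius of \code{confA} (the radius of the smallest
#' centroid-centred sphere containing all its beads).
#'
#' @param confA,confB conformations on the same lattice.
#' @param normalize \code{"none"} (units of \code{a}) or
#'   \code{"nuclear_radius"}.
#' @return the RMSD (double).
#' @export
pairwise_rmsd <- function(confA, confB,
                          normalize = c("none", "nuclear_radius")) {
  normalize <- match.arg(normalize)
  if (confA$lattice$n_beads != confB$lattice$n_beads ||
      confA$lattice$resolution != confB$lattice$resolution)
    stop("conformations are on different lattices")
  A <- scale(confA$coords, scale = FALSE)
  B <- scale(confB$coords, scale = FALSE)
  n <- nrow(A)
  # min RMSD over the full orthogonal group (rotations + reflections):
  # R = U t(V) from the SVD of t(B) A maximises tr(t(R) t(B) A); the RMSD
  # is evaluated from the explicit residuals for numerical accuracy
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% t(sv$v)
  out <- sqrt(mean(rowSums((A - B %*% R)^2)))
  if (normalize == "nuclear_radius") out <- out / nuclear_radius(confA)
  out
}

#' Nuclear radius of a conformation
#'
#' Radius of the smallest sphere centred at the coordinate centroid that
#' contains every bead, in units of \code{a}.
#'
#' @param conf a \code{\link{conformation}}.
#' @return the radius (double).
#' @export
nuclear_radius <- function(conf) {
  X <- scale(conf$coords, scale = FALSE)
  sqrt(max(rowSums(X^2)))
}

#' Median pairwise RMSD within an ensemble
#'
#' All-pairs RMSD across the replicas of a \code{structure_ensemble}; the
#' ensemble is flagged reliable when the median is below 4 bead diameters
#' (a contacted bead can move within a sphere of diameter twice the 2-bd
#' contact threshold relative to its partner).
#'
#' @param ensemble a \code{structure_ensemble}.
#' @param normalize passed to \code{\link{pairwise_rmsd}}.
#' @param reliability_threshold threshold on the median, in the chosen
#'   units (default 4 bead diameters).
#' @return list with \code{rmsd} (matrix), \code{median}, \code{reliable}.
#' @export
ensemble_rmsd <- function(ensemble, normalize = "none",
                          reliability_threshold = 4) {
  k <- length(ensemble$conformations)
  if (k < 2L) stop("need at least two replicas")
  M <- matrix(0, k, k)
  for (p in seq_len(k - 1L))
    for (q in (p + 1L):k)
      M[p, q] <- M[q, p] <- pairwise_rmsd(ensemble$conformations[[p]],
                                          ensemble$conformations[[q]],
                                          normalize = normalize)
  med <- stats::median(M[upper.tri(M)])
  list(rmsd = M, median = med,
       reliable = med < reliability_threshold)
}

#' Pairwise distance matrix of a lattice window
#'
#' Euclidean distances, in units of \code{a}, between all beads of a
#' window within one chromosome.
#'
#' @param conf a \code{\link{conformation}}.
#' @param chrom chromosome name (default: first of the assembly).
#' @param from,to 0-based local bead range within the chromosome
#'   (defaults: whole chromosome); \code{to} exclusive.
#' @return object of class \code{distance_matrix}: the symmetric matrix
#'   with attributes \code{chrom}, \code{from}, \code{to},
#'   \code{resolution}.
#' @export
distance_matrix <- function(conf, chrom = conf$lattice$assembly$name[1],
                            from = 0L, to = NULL) {
  lat <- conf$lattice
  ci <- chrom_index(lat, chrom)
  n_chrom <- lat$n_per_chrom[ci]
  if (is.null(to)) to <- n_chrom
  if (from < 0L || to > n_chrom || to <= from)
    stop("window must lie within chromosome ", chrom)
  idx <- lat$offsets[ci] + (from + 1L):to
  M <- as.matrix(stats::dist(conf$coords[idx, , drop = FALSE]))
  dimnames(M) <- NULL
  structure(M, class = c("distance_matrix", "matrix"),
            chrom = chrom, from = from, to = to,
            resolution = lat$resolution)
}

#' Separation score along a distance matrix
#'
#' For each position i, the mean distance between the w beads upstream and
#' the w beads downstream of i; peaks mark boundaries between spatially
#' segregated domains. Positions within w beads of the window edge are NA.
#'
#' @param dm a \code{\link{distance_matrix}} (or plain symmetric matrix).
#' @param w flank width in beads (default 20, the 200-kb scale at 10-kb
#'   resolution).
#' @return numeric vector of scores, one per matrix row, in units of
#'   \code{a}.
#' @export
separation_score <- function(dm, w = 20L) {
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  n <- nrow(dm)
  if (n < 2L * w) stop("window must span at least 2w beads")
  s <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w + 1L)) {
    up <- (i - w):(i - 1L)
    down <- i:(i + w - 1L)
    s[i] <- mean(dm[up, down])
  }
  s
}

#' Call domain boundaries from separation scores
#'
#' Local maxima of the score with topographic prominence at least
#' \code{min_prominence}; ties broken to the lower index. The prominence
#' of a peak is its height minus the higher of the two valley floors
#' separating it from higher terrain on either side.
#'
#' @param scores vector from \code{\link{separation_score}} (NAs allowed
#'   at the edges).
#' @param min_prominence minimum prominence in units of \code{a}
#'   (default 0.5).
#' @return data.frame with columns \code{bead} (1-based index into
#'   \code{scores}), \code{score}, \code{prominence}.
#' @export
call_boundaries <- function(scores, min_prominence = 0.5) {
  ok <- which(!is.na(scores))
  if (length(ok) < 3L)
    return(data.frame(bead = integer(0), score = numeric(0),
                      prominence = numeric(0)))
  s <- scores[ok]
  n <- length(s)
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    # strictly above the previous point, not below the next: plateaus
    # resolve to their first (lower-index) point
    if (s[i] > s[i - 1L] && s[i] >= s[i + 1L]) peaks <- c(peaks, i)
  }
  if (length(peaks) == 0L)
    return(data.frame(bead = integer(0), score = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(peaks, function(i) {
    left <- if (any(s[seq_len(i - 1L)] > s[i])) {
      j <- max(which(s[seq_len(i - 1L)] > s[i]))
      min(s[j:i])
    } else min(s[1:i])
    right <- if (any(s[(i + 1L):n] > s[i]) && i < n) {
      j <- i + min(which(s[(i + 1L):n] > s[i]))
      min(s[i:j])
    } else min(s[i:n])
    s[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(bead = ok[peaks[keep]], score = s[peaks][keep],
             prominence = prom[keep])
}

#' Gyration-radius profile along a chromosome
#'
#' For every bead taken as the midpoint of a genomic fragment of
#' \code{fragment_size} bp, the root-mean-square distance of the fragment's
#' bead positions from their centroid, in units of \code{a}. Windows
#' truncated by a chromosome end are reported NA.
#'
#' @param conf a \code{\link{conformation}}.
#' @param fragment_size fragment size in bp (default 200,000).
#' @param chrom chromosome name (default: first of the assembly).
#' @return numeric vector, one value per bead of the chromosome.
#' @export
rg_profile <- function(conf, fragment_size = 2e5,
                       chrom = conf$lattice$assembly$name[1]) {
  lat <- conf$lattice
  ci <- chrom_index(lat, chrom)
  n <- lat$n_per_chrom[ci]
  nw <- as.integer(round(fragment_size / lat$resolution))
  if (nw < 1L) stop("fragment smaller than one bead")
  if (n < nw) stop("chromosome shorter than the fragment")
  X <- conf$coords[lat$offsets[ci] + seq_len(n), , drop = FALSE]
  half <- (nw - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - half
    hi <- lo + nw - 1L
    if (lo < 1L || hi > n) next
    W <- X[lo:hi, , drop = FALSE]
    ctr <- colMeans(W)
    out[i] <- sqrt(mean(rowSums((W - rep(ctr, each = nw))^2)))
  }
  out
}

#' Write boundary calls as BED
#'
#' 0-based half-open records; score column carries the separation score.
#'
#' @param calls data.frame from \code{\link{call_boundaries}}.
#' @param lattice the lattice of the scored window.
#' @param chrom chromosome name of the window.
#' @param from 0-based local bead offset of the window start.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_boundaries_bed <- function(calls, lattice, chrom, from = 0L, path) {
  res <- lattice$resolution
  start <- (from + calls$bead - 1L) * res
  bed <- data.frame(chrom = chrom, start = start, end = start + res,
                    name = sprintf("boundary_%d", seq_len(nrow(calls))),
                    score = calls$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
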