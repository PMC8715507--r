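#' Wrap angles to the half-open interval (-180, 180]
#'
#' All dihedral angles in the package use degrees wrapped to `(-180, 180]`.
#'
#' @param theta Numeric vector of angles in degrees (any real values).
#' @return Numeric vector of the same length, each value in `(-180, 180]`.
#' @examples
#' wrap_angle(c(360, -180, 181, 540))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  w <- theta %% 360
  ifelse(w > 180, w - 360, w)
}

#' Circular distance between two angles
#'
#' The minor arc between two directions, computed on the unit circle:
#' equivalent to `acos(cos a cos b + sin a sin b)` but evaluated without
#' trigonometry round-trip. Symmetric, zero iff the angles coincide modulo
#' 360 degrees, and bounded by 180 degrees.
#'
#' @param a,b Angles in degrees (vectors recycle).
#' @return Distance(s) in degrees, in `[0, 180]`.
#' @examples
#' circ_distance(170, -170)  # 20
#' @export
circ_distance <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("angles must be finite", call. = FALSE)
  }
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Circular mean of a set of angles
#'
#' Each angle is represented by its unit vector `(cos x, sin x)`; the mean is
#' `atan2(sum sin, sum cos)` in degrees. A vanishing resultant (e.g. an exact
#' antipodal pair) has no defined mean direction and is an error.
#'
#' @param x Angles in degrees.
#' @param tol Resultant-length tolerance below which the mean is declared
#'   degenerate (relative to `length(x)`).
#' @return Mean direction in degrees, in `(-180, 180]`.
#' @examples
#' circ_mean(c(170, -170))  # 180
#' @export
circ_mean <- function(x, tol = 1e-9) {
  if (length(x) == 0L) stop("cannot average an empty angle set", call. = FALSE)
  if (any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  r <- x * pi / 180
  s <- sum(sin(r)); cc <- sum(cos(r))
  if (sqrt(s^2 + cc^2) < tol * length(x)) {
    stop("degenerate circular mean: resultant vector has zero length",
         call. = FALSE)
  }
  wrap_angle(atan2(s, cc) * 180 / pi)
}

#' Circular rms deviation between two chi1 angle sets
#'
#' Compares two sets of dihedral angles over their shared residues using the
#' circular distance, excluding pairs that disagree by more than `exclusion`
#' degrees (strictly greater; a deviation equal to the cutoff is kept). The
#' statistic is `sqrt(mean(d^2))` over the retained pairs.
#'
#' @param set1,set2 Named numeric vectors (names are residue ids) or plain
#'   numeric vectors of equal length (positional pairing).
#' @param exclusion Exclusion cutoff in degrees (default 40).
#' @return A list with `rmsd` (degrees), `n_used`, `max_deviation` (degrees,
#'   over retained pairs), and `excluded` (character vector of residue ids or
#'   indices dropped by the cutoff).
#' @examples
#' rmsd_chi1(c(a = 60, b = 180), c(a = 65, b = 175))
#' @export
rmsd_chi1 <- function(set1, set2, exclusion = 40) {
  if (!is.null(names(set1)) && !is.null(names(set2))) {
    shared <- intersect(names(set1), names(set2))
    if (length(shared) == 0L) stop("no shared residues between the two sets",
                                   call. = FALSE)
    a <- set1[shared]; b <- set2[shared]; ids <- shared
  } else {
    if (length(set1) != length(set2)) {
      stop("unnamed angle sets must have equal length", call. = FALSE)
    }
    a <- set1; b <- set2; ids <- as.character(seq_along(a))
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]; ids <- ids[keep]
  if (length(a) == 0L) stop("no complete residue pairs to compare", call. = FALSE)
  d <- circ_distance(a, b)
  use <- d <= exclusion
  if (!any(use)) stop("no residue pairs survive the exclusion cutoff",
                      call. = FALSE)
  list(rmsd = sqrt(mean(d[use]^2)),
       n_used = sum(use),
       max_deviation = max(d[use]),
       excluded = ids[!use])
}

#' Robust circular average of X-ray torsion angles
#'
#' Averages a set of crystallographic chi1 angles, iteratively removing
#' outliers: compute the circular mean of the retained values, drop every
#' value whose circular distance from that mean exceeds `threshold` (strictly
#' greater), and repeat until the retained set is stable. With
#' `iterate = FALSE` a single exclude-then-average pass is performed.
#'
#' @param x Angles in degrees.
#' @param threshold Outlier cutoff in degrees (default 30).
#' @param sources Optional character vector of per-angle source labels (e.g.
#'   PDB entry ids), recycled into the exclusion report.
#' @param iterate Iterate removal to a fixed point (default) or stop after
#'   one pass.
#' @return A list with `mean` (degrees), `spread` (rms circular deviation of
#'   the retained values from the mean, degrees), `n_used`, and `excluded`
#'   (data.frame of dropped values and their sources).
#' @examples
#' robust_xray_average(c(-60, -58, -62, 100))
#' @export
robust_xray_average <- function(x, threshold = 30, sources = NULL,
                                iterate = TRUE) {
  if (length(x) == 0L) stop("empty angle set", call. = FALSE)
  if (is.null(sources)) sources <- rep(NA_character_, length(x))
  if (length(sources) != length(x)) stop("one source label per angle",
                                         call. = FALSE)
  keep <- rep(TRUE, length(x))
  for (i in seq_len(length(x) + 1L)) {
    if (!any(keep)) stop("all values excluded as outliers", call. = FALSE)
    m <- circ_mean(x[keep])
    new_keep <- circ_distance(x, m) <= threshold
    # never resurrect a value once dropped: the retained set must shrink
    new_keep <- new_keep & keep
    if (identical(new_keep, keep) || !iterate) { keep <- new_keep; break }
    keep <- new_keep
  }
  if (!any(keep)) stop("all values excluded as outliers", call. = FALSE)
  m <- circ_mean(x[keep])
  list(mean = m,
       spread = sqrt(mean(circ_distance(x[keep], m)^2)),
       n_used = sum(keep),
       excluded = data.frame(value = x[!keep], source = sources[!keep],
                             stringsAsFactors = FALSE))
}
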