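#' Extended Karplus (Fourier) coefficients for one coupling type
#'
#' Container for the six coefficients of the truncated Fourier series
#' `J(theta) = C0 + C1 cos(theta) + C2 cos(2 theta) + C3 cos(3 theta) +
#' S1 sin(theta) + S2 sin(2 theta)` (Hz), plus provenance metadata.
#'
#' @param c0,c1,c2,c3,s1,s2 Coefficients in Hz; all must be finite.
#' @param method,basis,residue_type,backbone,chi2 Optional provenance labels.
#'   `backbone` must be one of `"alpha"`, `"beta"`, `"unspecified"`.
#' @return An object of class `karplus_coefficients`.
#' @examples
#' k <- karplus_coefficients(7.1, -1.3, 3.9, 0.2, 0.1, -0.1)
#' evaluate_karplus(k, -60)
#' @export
karplus_coefficients <- function(c0 = 0, c1 = 0, c2 = 0, c3 = 0,
                                 s1 = 0, s2 = 0,
                                 method = "unspecified",
                                 basis = "unspecified",
                                 residue_type = NA_character_,
                                 backbone = "unspecified",
                                 chi2 = "unspecified") {
  co <- c(c0 = unname(c0)[1], c1 = unname(c1)[1], c2 = unname(c2)[1],
          c3 = unname(c3)[1], s1 = unname(s1)[1], s2 = unname(s2)[1])
  if (!is.numeric(co) || any(!is.finite(co))) {
    stop("all six Karplus coefficients must be finite numbers", call. = FALSE)
  }
  backbone <- match.arg(backbone, c("alpha", "beta", "unspecified"))
  structure(list(coef = co,
                 meta = list(method = method, basis = basis,
                             residue_type = residue_type,
                             backbone = backbone, chi2 = chi2)),
            class = "karplus_coefficients")
}

#' @export
print.karplus_coefficients <- function(x, ...) {
  cat("Karplus coefficients (Hz):\n")
  print(round(x$coef, 4))
  if (!identical(x$meta$method, "unspecified")) {
    cat("method:", x$meta$method, " basis:", x$meta$basis,
        " backbone:", x$meta$backbone, "\n")
  }
  invisible(x)
}

.karplus_design <- function(theta_deg) {
  t <- theta_deg * pi / 180
  cbind(c0 = rep(1, length(t)), c1 = cos(t), c2 = cos(2 * t),
        c3 = cos(3 * t), s1 = sin(t), s2 = sin(2 * t))
}

#' Evaluate an extended Karplus equation
#'
#' @param coeffs A [karplus_coefficients()] object (or bare numeric vector of
#'   the six coefficients in the order c0, c1, c2, c3, s1, s2).
#' @param theta Dihedral angle(s) between the coupled nuclei, degrees. Any
#'   real value; the series is 360-degree periodic.
#' @return Coupling value(s) in Hz.
#' @examples
#' evaluate_karplus(karplus_coefficients(c0 = 1), 137)  # 1
#' @export
evaluate_karplus <- function(coeffs, theta) {
  co <- if (inherits(coeffs, "karplus_coefficients")) coeffs$coef else coeffs
  if (length(co) != 6L || any(!is.finite(co))) {
    stop("need six finite Karplus coefficients", call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  drop(.karplus_design(theta) %*% co)
}

#' Karplus-equation set for a residue type
#'
#' Associates each coupling path in a residue type's topology table with one
#' set of Fourier coefficients, so that all (up to nine) couplings can be
#' evaluated at a given chi1.
#'
#' @param residue_type Residue type name (registered in the topology table).
#' @param entries Named list of [karplus_coefficients()] objects; names are
#'   coupling ids from [residue_topology()]. Couplings may be omitted, but
#'   evaluation requests for a missing coupling error.
#' @param delta_theta_override Optional per-coupling phase-shift overrides,
#'   passed to [residue_topology()].
#' @return An object of class `karplus_set`.
#' @export
karplus_set <- function(residue_type, entries, delta_theta_override = NULL) {
  topo <- residue_topology(residue_type, delta_theta_override)
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("entries must be a uniquely named list of coefficient sets",
         call. = FALSE)
  }
  unknown <- setdiff(names(entries), topo$coupling_id)
  if (length(unknown)) {
    stop("coupling id(s) not in the ", toupper(residue_type),
         " topology: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok <- vapply(entries, inherits, logical(1), "karplus_coefficients")
  if (!all(ok)) stop("every entry must be a karplus_coefficients object",
                     call. = FALSE)
  structure(list(residue_type = toupper(residue_type), topology = topo,
                 entries = entries),
            class = "karplus_set")
}

#' @export
print.karplus_set <- function(x, ...) {
  cat("Karplus set for", x$residue_type, "-", length(x$entries),
      "of", nrow(x$topology), "couplings parameterized\n")
  invisible(x)
}

#' Evaluate a Karplus set at a chi1 angle
#'
#' For each requested coupling, evaluates its Karplus equation at
#' `theta = chi1 + delta_theta` using the phase shift from the set's
#' topology table.
#'
#' @param kset A [karplus_set()].
#' @param chi1 Side-chain torsion angle chi1, degrees (scalar).
#' @param coupling_ids Couplings to evaluate; default all parameterized ones.
#' @return Named numeric vector of couplings in Hz.
#' @export
evaluate_at_chi1 <- function(kset, chi1, coupling_ids = NULL) {
  stopifnot(inherits(kset, "karplus_set"), length(chi1) == 1L)
  if (is.null(coupling_ids)) coupling_ids <- names(kset$entries)
  missing_ids <- setdiff(coupling_ids, names(kset$entries))
  if (length(missing_ids)) {
    stop("no Karplus coefficients for coupling(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  dth <- kset$topology$delta_theta[match(coupling_ids,
                                         kset$topology$coupling_id)]
  vapply(seq_along(coupling_ids), function(i) {
    evaluate_karplus(kset$entries[[coupling_ids[i]]], chi1 + dth[i])
  }, numeric(1), USE.NAMES = FALSE) |> setNames(coupling_ids)
}

# n_grid x n_coupling matrix of J values over a chi1 grid; the workhorse
# behind the UMS/TMST scans.
.evaluate_grid <- function(kset, chi1_grid, coupling_ids) {
  dth <- kset$topology$delta_theta[match(coupling_ids,
                                         kset$topology$coupling_id)]
  out <- matrix(0, length(chi1_grid), length(coupling_ids),
                dimnames = list(NULL, coupling_ids))
  for (i in seq_along(coupling_ids)) {
    out[, i] <- evaluate_karplus(kset$entries[[coupling_ids[i]]],
                                 chi1_grid + dth[i])
  }
  out
}

#' Canonical six-angle chi1/theta grid
#'
#' The six staggered/eclipsed angles `0, 60, 120, 180, -120, -60` degrees at
#' which dihedral scans are computed and on which the coefficient-space rmsd
#' is defined.
#'
#' @return Numeric vector of six angles in degrees.
#' @export
canonical_angles <- function() c(0, 60, 120, 180, -120, -60)

#' Fit extended Karplus coefficients to a dihedral scan
#'
#' Ordinary least squares of coupling values on the Fourier design
#' `{1, cos, cos2, cos3, sin, sin2}` evaluated at
#' `theta = chi1 + delta_theta`, restricted to the requested terms. With the
#' six canonical 60-degree-spaced angles and all six terms the design is
#' square and orthogonal (up to column scaling), so the fit interpolates the
#' data exactly. Unrequested terms are fixed at zero.
#'
#' An optional empirical-style sign constraint forces `c1 <= 0` (or `>= 0`
#' when the coupling involves 15N, whose magnetogyric ratio is negative) by
#' clamping c1 and refitting the remaining terms.
#'
#' @param scan A scan table data.frame with columns `chi1_deg`,
#'   `coupling_id`, `j_hz` (see [read_scan_table()]).
#' @param coupling_id Which coupling to fit.
#' @param terms Character subset of `c("c0","c1","c2","c3","s1","s2")`.
#' @param topology Topology table supplying `delta_theta` (default: derived
#'   from `residue_type`).
#' @param residue_type Residue type used when `topology` is not given.
#' @param sign_constrain_c1 Apply the empirical sign convention on c1.
#' @return A list with `coefficients` (a [karplus_coefficients()] with
#'   unrequested terms zero), `residual_rmsd` (Hz), and `n_points`.
#' @export
fit_coefficients <- function(scan, coupling_id,
                             terms = c("c0", "c1", "c2", "c3", "s1", "s2"),
                             topology = NULL, residue_type = NULL,
                             sign_constrain_c1 = FALSE) {
  terms <- match.arg(terms, c("c0", "c1", "c2", "c3", "s1", "s2"),
                     several.ok = TRUE)
  rows <- scan[scan$coupling_id == coupling_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("scan table has no rows for coupling '", coupling_id, "'",
         call. = FALSE)
  }
  if (is.null(topology)) {
    if (is.null(residue_type)) {
      dth <- 0
    } else {
      topology <- residue_topology(residue_type)
    }
  }
  if (!is.null(topology)) {
    i <- match(coupling_id, topology$coupling_id)
    if (is.na(i)) stop("coupling '", coupling_id,
                       "' absent from topology table", call. = FALSE)
    dth <- topology$delta_theta[i]
  }
  chi1 <- wrap_angle(rows$chi1_deg)
  n_distinct <- length(unique(chi1))
  if (n_distinct < length(terms)) {
    stop("need at least ", length(terms), " distinct angles to fit ",
         length(terms), " terms; scan has ", n_distinct, call. = FALSE)
  }
  theta <- chi1 + dth
  X <- .karplus_design(theta)[, terms, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient Fourier design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, rows$j_hz)
  if (sign_constrain_c1 && "c1" %in% terms) {
    want_nonneg <- grepl("^N", coupling_id)
    viol <- if (want_nonneg) beta["c1"] < 0 else beta["c1"] > 0
    if (viol) {
      rest <- setdiff(terms, "c1")
      beta[] <- 0
      if (length(rest)) {
        Xr <- .karplus_design(theta)[, rest, drop = FALSE]
        beta[rest] <- qr.coef(qr(Xr), rows$j_hz)
      }
    }
  }
  full <- setNames(numeric(6), c("c0", "c1", "c2", "c3", "s1", "s2"))
  full[terms] <- beta
  fitted <- drop(.karplus_design(theta) %*% full)
  list(coefficients = karplus_coefficients(full["c0"], full["c1"],
                                           full["c2"], full["c3"],
                                           full["s1"], full["s2"],
                                           method = "ols-fit",
                                           residue_type =
                                             if (is.null(residue_type))
                                               NA_character_
                                             else toupper(residue_type)),
       residual_rmsd = sqrt(mean((rows$j_hz - fitted)^2)),
       n_points = nrow(rows))
}

#' rmsd between two sets of coupling values
#'
#' `sqrt(mean((J1 - J2)^2))` over the shared coupling keys of two named
#' vectors (or positionally for unnamed vectors of equal length).
#'
#' @param set1,set2 Named (or equal-length unnamed) numeric vectors, Hz.
#' @return rmsd in Hz.
#' @export
rmsd_couplings <- function(set1, set2) {
  if (!is.null(names(set1)) && !is.null(names(set2))) {
    shared <- intersect(names(set1), names(set2))
    if (length(shared) == 0L) stop("no shared couplings", call. = FALSE)
    a <- set1[shared]; b <- set2[shared]
  } else {
    if (length(set1) != length(set2) || length(set1) == 0L) {
      stop("unnamed coupling sets must be non-empty and of equal length",
           call. = FALSE)
    }
    a <- set1; b <- set2
  }
  sqrt(mean((a - b)^2))
}

#' rmsd between two Karplus coefficient sets
#'
#' Defined as the coupling-space rmsd of the two curves sampled on the
#' canonical six-angle grid. Discrete orthogonality on the 60-degree grid
#' gives the closed form
#' `sqrt(dC0^2 + (dC1^2 + dC2^2 + dS1^2 + dS2^2)/2 + dC3^2)`: on six points
#' the third cosine harmonic aliases to a full-weight alternating column.
#' `mode = "continuous"` instead integrates over the full circle (Parseval),
#' where every harmonic including c3 carries weight 1/2.
#'
#' @param k1,k2 [karplus_coefficients()] objects (or bare 6-vectors).
#' @param mode `"grid6"` (default, consistent with [rmsd_couplings()] on the
#'   canonical angles) or `"continuous"`.
#' @return rmsd in Hz.
#' @export
rmsd_coefficients <- function(k1, k2, mode = c("grid6", "continuous")) {
  mode <- match.arg(mode)
  a <- if (inherits(k1, "karplus_coefficients")) k1$coef else k1
  b <- if (inherits(k2, "karplus_coefficients")) k2$coef else k2
  if (length(a) != 6L || length(b) != 6L || any(!is.finite(c(a, b)))) {
    stop("need two finite six-coefficient sets", call. = FALSE)
  }
  d <- unname(a - b)
  w_c3 <- if (mode == "grid6") 1 else 0.5
  sqrt(d[1]^2 + 0.5 * (d[2]^2 + d[3]^2 + d[5]^2 + d[6]^2) + w_c3 * d[4]^2)
}

#' Average weighted relative rmsd across coupling types (percent)
#'
#' Combines per-coupling-type rmsd values into one relative figure: each
#' rmsd is normalized by the reference average coupling `|C0|` of its type,
#' and the relative values are averaged with weights proportional to the
#' same `|C0|` values,
#' `100 * sum(w_i * rmsd_i / |C0_i|) / sum(w_i)` with `w_i = |C0_i|`,
#' which collapses to `100 * sum(rmsd_i) / sum(|C0_i|)`. Because only the
#' weight ratios matter, the statistic is invariant under a common
#' rescaling of the weights (supply `weights` separately to use a different
#' weighting than the normalizers).
#'
#' @param rmsds Named numeric vector of rmsd values (Hz) per coupling type.
#' @param c0_weights Named numeric vector of reference `|C0|` values (Hz);
#'   must cover every name in `rmsds` and be non-zero (absolute values are
#'   taken first).
#' @param weights Averaging weights; defaults to `c0_weights`.
#' @return awrmsd in percent.
#' @examples
#' awrmsd(c(A = 0.2, B = 0.02), c(A = 6, B = 2))  # 2.75
#' @export
awrmsd <- function(rmsds, c0_weights, weights = c0_weights) {
  if (length(rmsds) == 0L) stop("empty rmsd set", call. = FALSE)
  align <- function(v, what) {
    v <- abs(v)
    if (!is.null(names(rmsds)) && !is.null(names(v))) {
      missing_v <- setdiff(names(rmsds), names(v))
      if (length(missing_v)) {
        stop("no ", what, " for: ", paste(missing_v, collapse = ", "),
             call. = FALSE)
      }
      v <- v[names(rmsds)]
    } else if (length(v) != length(rmsds)) {
      stop("need one ", what, " per rmsd", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("all ", what, " values must be finite and non-zero", call. = FALSE)
    }
    v
  }
  c0 <- align(c0_weights, "|C0| weight")
  w <- align(weights, "averaging weight")
  100 * sum(w * rmsds / c0) / sum(w)
}
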