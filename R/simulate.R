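#' @importFrom stats rnorm runif
NULL

# run code under a fixed RNG state (Mersenne-Twister + inversion, so seeded
# output is identical across platforms), restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Demonstration Karplus set (synthetic coefficients)
#'
#' Builds a Karplus set with synthetic six-term Fourier coefficients of
#' realistic magnitude for each of the six coupling types (large positive
#' cos/cos2 structure for proton-proton couplings, smaller magnitudes for
#' carbon and nitrogen partners, with the nitrogen sign flipped for the
#' negative 15N magnetogyric ratio). These coefficients are invented for
#' demonstration and testing; they are not a published parameterization.
#'
#' @param residue_type Residue type (default `"VAL"`).
#' @return A [karplus_set()] covering all nine couplings.
#' @export
demo_karplus_set <- function(residue_type = "VAL") {
  base <- list(
    "HA-HB" = c(7.20, -1.40, 3.90, 0.20, 0.15, -0.10),
    "HA-CG" = c(3.80, -1.00, 2.30, 0.10, 0.10, 0.05),
    "C-HB"  = c(3.90, -0.90, 2.60, 0.10, -0.10, 0.10),
    "C-CG"  = c(1.90, -0.60, 1.30, 0.05, 0.05, 0.05),
    "N-HB"  = c(-1.60, 0.50, -1.20, -0.05, 0.05, -0.05),
    "N-CG"  = c(1.20, 0.40, 0.90, 0.05, 0.00, 0.05)
  )
  topo <- residue_topology(residue_type)
  entries <- lapply(seq_len(nrow(topo)), function(i) {
    co <- base[[topo$coupling_type[i]]]
    karplus_coefficients(co[1], co[2], co[3], co[4], co[5], co[6],
                         method = "synthetic-demo",
                         residue_type = toupper(residue_type))
  })
  names(entries) <- topo$coupling_id
  karplus_set(residue_type, entries)
}

#' Simulate a dihedral scan table
#'
#' Samples each coupling's Karplus curve at the given chi1 angles
#' (evaluated at `theta = chi1 + delta_theta`) and adds independent
#' Gaussian noise of standard deviation `sigma`. With `sigma = 0` the table
#' contains exact curve values, so refitting recovers the generating
#' coefficients.
#'
#' @param kset A [karplus_set()].
#' @param angles chi1 angles in degrees (default the canonical six).
#' @param sigma Noise standard deviation in Hz (default 0).
#' @param seed Optional integer seed (fixed seed gives identical output).
#' @param coupling_ids Couplings to include (default all parameterized).
#' @return A scan table data.frame (`chi1_deg`, `coupling_id`, `j_hz`) with
#'   the generating parameters attached as attribute `ground_truth`.
#' @export
generate_scan <- function(kset, angles = canonical_angles(), sigma = 0,
                          seed = NULL, coupling_ids = NULL) {
  stopifnot(inherits(kset, "karplus_set"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(coupling_ids)) coupling_ids <- names(kset$entries)
  angles <- wrap_angle(angles)
  J <- .evaluate_grid(kset, angles, coupling_ids)
  df <- data.frame(chi1_deg = rep(angles, times = length(coupling_ids)),
                   coupling_id = rep(coupling_ids, each = length(angles)),
                   j_hz = as.vector(J))
  if (sigma > 0) {
    df$j_hz <- df$j_hz + .with_seed(seed, rnorm(nrow(df), 0, sigma))
  }
  attr(df, "ground_truth") <- list(sigma = sigma, seed = seed,
                                   residue_type = kset$residue_type)
  df
}

#' Simulate one residue's experimental couplings with known ground truth
#'
#' Generates a coupling set as a population-weighted mixture of conformer
#' evaluations plus Gaussian noise, in one of three modes:
#' \describe{
#'   \item{pure}{a single conformer at `chi1` (populations ignored);}
#'   \item{staggered}{a mixture of the staggered conformers 60/180/-60 with
#'     the given populations;}
#'   \item{trigonal}{a mixture of `chi1`, `chi1 + 120`, `chi1 - 120` with
#'     the given populations.}
#' }
#'
#' @param kset A [karplus_set()].
#' @param mode `"pure"`, `"staggered"` or `"trigonal"`.
#' @param chi1 Generating chi1 in degrees (pure and trigonal modes).
#' @param populations Length-3 simplex vector, order (60, 180, -60) for
#'   staggered mode or (chi1, chi1+120, chi1-120) for trigonal mode.
#' @param sigma Noise standard deviation in Hz (common to all couplings).
#' @param mask Coupling ids to drop (simulating unavailable measurements),
#'   or a character vector of ids to keep prefixed by none. Must leave at
#'   least one coupling.
#' @param seed Optional integer seed.
#' @param residue_id Identifier for the generated residue.
#' @return A [residue_couplings()] object with the generating parameters
#'   attached as attribute `ground_truth`.
#' @export
generate_residue <- function(kset, mode = c("pure", "staggered", "trigonal"),
                             chi1 = NULL, populations = NULL, sigma = 0,
                             mask = character(0), seed = NULL,
                             residue_id = "sim1") {
  stopifnot(inherits(kset, "karplus_set"))
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (mode == "pure") {
    if (is.null(chi1)) stop("pure mode needs chi1", call. = FALSE)
    angles <- chi1; pops <- 1
  } else {
    if (is.null(populations) || length(populations) != 3L ||
        any(populations < 0) || abs(sum(populations) - 1) > 1e-9) {
      stop(mode, " mode needs three nonnegative populations summing to 1",
           call. = FALSE)
    }
    if (mode == "staggered") {
      angles <- c(60, 180, -60)
    } else {
      if (is.null(chi1)) stop("trigonal mode needs chi1", call. = FALSE)
      angles <- chi1 + c(0, 120, -120)
    }
    pops <- populations
  }
  ids <- setdiff(names(kset$entries), mask)
  if (length(ids) == 0L) stop("mask removes every coupling", call. = FALSE)
  j <- numeric(length(ids))
  for (k in seq_along(angles)) {
    j <- j + pops[k] * evaluate_at_chi1(kset, angles[k], ids)
  }
  if (sigma > 0) j <- j + .with_seed(seed, rnorm(length(j), 0, sigma))
  res <- residue_couplings(residue_id, kset$residue_type, setNames(j, ids))
  attr(res, "ground_truth") <- list(mode = mode, chi1 = chi1,
                                    populations = pops, sigma = sigma,
                                    mask = mask, seed = seed)
  res
}
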