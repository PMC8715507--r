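#' Experimental couplings for one residue
#'
#' Bundle of one residue's measured vicinal couplings (Hz), keyed by coupling
#' id from the residue type's topology table. Any subset of the nine paths is
#' accepted; fewer than three measurements triggers a warning because rotamer
#' populations are then under-determined.
#'
#' @param residue_id Identifier such as `"Val7"`.
#' @param residue_type Residue type with a registered topology.
#' @param measurements Named numeric vector, coupling id -> value in Hz.
#' @return An object of class `residue_couplings`.
#' @export
residue_couplings <- function(residue_id, residue_type, measurements) {
  topo <- residue_topology(residue_type)
  if (length(measurements) < 1L || is.null(names(measurements))) {
    stop("measurements must be a non-empty named vector", call. = FALSE)
  }
  if (any(!is.finite(measurements))) {
    stop("all coupling values must be finite", call. = FALSE)
  }
  unknown <- setdiff(names(measurements), topo$coupling_id)
  if (length(unknown)) {
    stop("coupling id(s) not in the ", toupper(residue_type), " topology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(measurements))) {
    stop("duplicate coupling ids in measurements", call. = FALSE)
  }
  if (length(measurements) < 3L) {
    warning("only ", length(measurements), " coupling(s) for ", residue_id,
            ": rotamer populations are under-determined", call. = FALSE)
  }
  structure(list(residue_id = residue_id,
                 residue_type = toupper(residue_type),
                 measurements = measurements,
                 n = length(measurements)),
            class = "residue_couplings")
}

#' @export
print.residue_couplings <- function(x, ...) {
  cat(x$residue_id, "(", x$residue_type, "):", x$n, "couplings\n")
  print(round(x$measurements, 3))
  invisible(x)
}

.check_res_kset <- function(res, kset) {
  stopifnot(inherits(res, "residue_couplings"), inherits(kset, "karplus_set"))
  missing_ids <- setdiff(names(res$measurements), names(kset$entries))
  if (length(missing_ids)) {
    stop("no Karplus coefficients for measured coupling(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
}

#' Unimodal rmsd profile over chi1
#'
#' For each chi1 on a regular grid covering `(-180, 180]`, computes the
#' single-conformer residual
#' `rmsd_J(chi1) = sqrt(mean((J_exp - J_calc(chi1))^2))` over the residue's
#' measured couplings.
#'
#' @param res A [residue_couplings()] object.
#' @param kset A [karplus_set()] covering every measured coupling.
#' @param step Grid step in degrees (default 0.1).
#' @return data.frame with columns `chi1` and `rmsd`, of class `ums_profile`.
#' @export
ums_profile <- function(res, kset, step = 0.1) {
  .check_res_kset(res, kset)
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  ids <- names(res$measurements)
  grid <- seq(-180 + step, 180, by = step)
  J <- .evaluate_grid(kset, grid, ids)
  resid2 <- sweep(J, 2, res$measurements)^2
  out <- data.frame(chi1 = grid, rmsd = sqrt(rowMeans(resid2)))
  attr(out, "step") <- step
  attr(out, "residue_id") <- res$residue_id
  class(out) <- c("ums_profile", "data.frame")
  out
}

# indices of local minima of a cyclic discrete curve, plateau-aware
.cyclic_minima <- function(v, tol = 0) {
  n <- length(v)
  if (diff(range(v)) <= tol) {
    stop("degenerate rmsd profile: curve is flat", call. = FALSE)
  }
  prev <- v[c(n, seq_len(n - 1L))]
  nxt <- v[c(seq(2L, n), 1L)]
  cand <- which(v <= prev & v <= nxt)
  if (length(cand) == 0L) return(integer(0))
  # collapse cyclically-contiguous candidate runs (plateaus) to their centre
  gap <- which(diff(cand) > 1L)
  runs <- if (length(gap)) {
    split(cand, rep(seq_len(length(gap) + 1L),
                    diff(c(0L, gap, length(cand)))))
  } else list(cand)
  if (length(runs) > 1L && cand[1L] == 1L && cand[length(cand)] == n) {
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs[[length(runs)]] <- NULL
  }
  vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1))
}

#' Locate and select minima of a unimodal rmsd profile
#'
#' Karplus-equation degeneracy typically produces two local minima roughly
#' 180 degrees apart. All local minima of the periodic profile are returned
#' sorted by ascending rmsd. The selected minimum is, by default, the
#' lowest-rmsd minimum among those lying within `staggered_tolerance` of a
#' staggered angle (60, 180, -60); when no minimum qualifies — or with
#' `force_global = TRUE` — the global minimum is selected. This rule lets a
#' second minimum near a staggered angle override a slightly deeper
#' non-staggered one.
#'
#' The chi1 uncertainty of the selected minimum is the distance from the
#' minimum to either edge of the contiguous region where
#' `rmsd <= rmsd_min + window`.
#'
#' @param profile A [ums_profile()] result (step must be <= 0.5 degrees).
#' @param window Uncertainty window height in Hz (default 0.2).
#' @param staggered_tolerance Degrees around a staggered angle within which a
#'   minimum counts as staggered (default 30, inclusive).
#' @param force_global Always select the global minimum.
#' @return A list of class `ums_result`: `minima` (data.frame of `chi1`,
#'   `rmsd`, `rank`), `chi1`, `rmsd`, `selected_index`, `selected_rank`, and
#'   `uncertainty` (`c(minus, plus)` degrees, below-/above-minimum).
#' @export
ums_minima <- function(profile, window = 0.2, staggered_tolerance = 30,
                       force_global = FALSE) {
  stopifnot(inherits(profile, "ums_profile"))
  step <- attr(profile, "step")
  if (step > 0.5) {
    stop("profile step ", step, " too coarse for minima analysis (need <= 0.5)",
         call. = FALSE)
  }
  v <- profile$rmsd
  idx <- .cyclic_minima(v)
  ord <- order(v[idx], circ_distance(profile$chi1[idx],
                                     .nearest_staggered(profile$chi1[idx])))
  idx <- idx[ord]
  minima <- data.frame(chi1 = profile$chi1[idx], rmsd = v[idx],
                       rank = seq_along(idx))
  sel <- 1L
  if (!force_global) {
    dev <- circ_distance(minima$chi1, .nearest_staggered(minima$chi1))
    ok <- which(dev <= staggered_tolerance)
    if (length(ok)) sel <- ok[1L]  # minima already sorted by rmsd
  }
  n <- length(v)
  i0 <- idx[sel]
  lim <- v[i0] + window
  left <- 0L
  while (left < n - 1L && v[((i0 - left - 2L) %% n) + 1L] <= lim) {
    left <- left + 1L
  }
  right <- 0L
  while (right < n - 1L && v[(i0 + right) %% n + 1L] <= lim) {
    right <- right + 1L
  }
  structure(list(minima = minima,
                 chi1 = minima$chi1[sel],
                 rmsd = minima$rmsd[sel],
                 selected_index = sel,
                 selected_rank = minima$rank[sel],
                 uncertainty = c(minus = left * step, plus = right * step),
                 window = window),
            class = "ums_result")
}

#' @export
print.ums_result <- function(x, ...) {
  cat(sprintf("UMS: chi1 = %.1f (-%d/+%d) deg, rmsd = %.2f Hz (minimum %d of %d)\n",
              x$chi1, round(x$uncertainty[1]), round(x$uncertainty[2]),
              x$rmsd, x$selected_rank, nrow(x$minima)))
  invisible(x)
}

#' Fit the unimodal-static (UMS) model
#'
#' Convenience wrapper: [ums_profile()] followed by [ums_minima()].
#'
#' @inheritParams ums_profile
#' @inheritParams ums_minima
#' @return A `ums_result` (the profile is attached as attribute `profile`).
#' @export
fit_ums <- function(res, kset, step = 0.1, window = 0.2,
                    staggered_tolerance = 30, force_global = FALSE) {
  prof <- ums_profile(res, kset, step)
  out <- ums_minima(prof, window, staggered_tolerance, force_global)
  attr(out, "profile") <- prof
  out
}

.nearest_staggered <- function(chi1) {
  s <- c(60, 180, -60)
  d <- sapply(s, function(a) circ_distance(chi1, a))
  d <- matrix(d, nrow = length(chi1))
  s[max.col(-d, ties.method = "first")]
}

# Exact minimizer of ||b - A p||^2 over the probability simplex (3 vars) by
# enumeration of the seven support sets. Small and provably optimal: any
# optimum has some support S; on S the equality-constrained LS solution is
# either the optimum (if feasible) or the objective is flat toward the
# boundary, which a smaller support then captures.
.simplex_ls <- function(A, b) {
  best <- list(obj = Inf, p = c(1, 0, 0))
  consider <- function(p) {
    if (any(p < -1e-10)) return()
    p <- pmax(p, 0); p <- p / sum(p)
    obj <- sum((b - drop(A %*% p))^2)
    if (obj < best$obj - 1e-15) best <<- list(obj = obj, p = p)
  }
  # vertices
  for (i in 1:3) consider(replace(numeric(3), i, 1))
  # edges: p_i = t, p_j = 1 - t
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    d <- A[, i] - A[, j]
    den <- sum(d^2)
    if (den > 0) {
      t <- sum((b - A[, j]) * d) / den
      if (t > 0 && t < 1) {
        p <- numeric(3); p[i] <- t; p[j] <- 1 - t
        consider(p)
      }
    }
  }
  # interior: equality-constrained least squares via KKT
  K <- rbind(cbind(crossprod(A), rep(1, 3)), c(1, 1, 1, 0))
  sol <- tryCatch(solve(K, c(crossprod(A, b), 1)), error = function(e) NULL)
  if (!is.null(sol)) consider(sol[1:3])
  best
}

#' Fit the trimodal-static-staggered (TMSS) model
#'
#' Models the residue as a population mixture of the three staggered
#' conformers chi1 = 60, 180, -60 degrees and minimizes
#' `sqrt(mean((J_exp - sum_j P_j J_calc(chi_j))^2))` subject to
#' `P_60 + P_180 + P_-60 = 1`, `P_j >= 0`. The constrained least-squares
#' problem is solved exactly by enumerating the seven support sets of the
#' 2-simplex (equivalent to an active-set quadratic program at this size).
#'
#' @inheritParams ums_profile
#' @return A list of class `tmss_result`: `populations` (named `p60`,
#'   `p180`, `pm60`), `rmsd` (Hz), `chi1` (the staggered angle of the most
#'   populated conformer), `n`.
#' @export
tmss_populations <- function(res, kset) {
  .check_res_kset(res, kset)
  ids <- names(res$measurements)
  A <- t(.evaluate_grid(kset, c(60, 180, -60), ids))  # n x 3
  fit <- .simplex_ls(A, res$measurements)
  p <- setNames(fit$p, c("p60", "p180", "pm60"))
  structure(list(populations = p,
                 rmsd = sqrt(fit$obj / res$n),
                 chi1 = c(60, 180, -60)[which.max(p)],
                 n = res$n,
                 residue_id = res$residue_id),
            class = "tmss_result")
}

#' @export
print.tmss_result <- function(x, ...) {
  cat(sprintf("TMSS: P60 = %.0f%%, P180 = %.0f%%, P-60 = %.0f%%, rmsd = %.2f Hz\n",
              100 * x$populations[1], 100 * x$populations[2],
              100 * x$populations[3], x$rmsd))
  invisible(x)
}

# cyclic assignment of three conformer angles (120 apart) to the staggered
# bins 60/180/-60 minimizing total circular distance
.staggered_bins <- function(conf_angles) {
  s <- c(60, 180, -60)
  shifts <- vapply(0:2, function(k) {
    sum(circ_distance(conf_angles, s[((0:2 + k) %% 3) + 1]))
  }, numeric(1))
  k <- which.min(shifts) - 1L
  s[((0:2 + k) %% 3) + 1]
}

#' Fit the trimodal-static-trigonal (TMST) model
#'
#' Three conformers constrained to trigonal symmetry — chi1, chi1 + 120,
#' chi1 - 120 — with three free parameters: the angle and two independent
#' populations. The joint minimum is found by an outer grid over a
#' 120-degree fundamental domain of chi1 (the conformer triple is invariant
#' under 120-degree rotation with permuted populations) with the exact
#' simplex population solve of [tmss_populations()] at each angle. The
#' result is canonicalized so that `chi1` is the most populated conformer's
#' angle and each population is tagged with its nearest staggered bin.
#'
#' @inheritParams ums_profile
#' @param step Outer chi1 grid step in degrees (default 0.1).
#' @return A list of class `tmst_result`: `chi1` (most populated conformer),
#'   `conformers` (data.frame of `chi1`, `population`, `bin`), `populations`
#'   (named by bin, `p60`/`p180`/`pm60` order), `rmsd` (Hz), `n`.
#' @export
tmst_fit <- function(res, kset, step = 0.1) {
  .check_res_kset(res, kset)
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  ids <- names(res$measurements)
  grid <- seq(-60 + step, 60, by = step)
  # J values for all three conformer branches over the whole grid
  Jc <- .evaluate_grid(kset, grid, ids)
  Jp <- .evaluate_grid(kset, grid + 120, ids)
  Jm <- .evaluate_grid(kset, grid - 120, ids)
  b <- res$measurements
  best <- list(obj = Inf, i = 1L, p = c(1, 0, 0))
  for (i in seq_along(grid)) {
    A <- cbind(Jc[i, ], Jp[i, ], Jm[i, ])
    fit <- .simplex_ls(A, b)
    if (fit$obj < best$obj - 1e-15) best <- list(obj = fit$obj, i = i,
                                                 p = fit$p)
  }
  chi0 <- grid[best$i]
  conf <- wrap_angle(chi0 + c(0, 120, -120))
  pops <- best$p
  bins <- .staggered_bins(conf)
  top <- which.max(pops)
  conformers <- data.frame(chi1 = conf, population = pops, bin = bins)
  conformers <- conformers[order(match(conformers$bin, c(60, 180, -60))), ]
  rownames(conformers) <- NULL
  p_named <- setNames(conformers$population,
                      c("p60", "p180", "pm60")[match(conformers$bin,
                                                     c(60, 180, -60))])
  p_named <- p_named[c("p60", "p180", "pm60")]
  structure(list(chi1 = conf[top],
                 conformers = conformers,
                 populations = p_named,
                 rmsd = sqrt(best$obj / res$n),
                 n = res$n,
                 residue_id = res$residue_id),
            class = "tmst_result")
}

#' @export
print.tmst_result <- function(x, ...) {
  cat(sprintf("TMST: chi1 = %.1f deg, rmsd = %.2f Hz\n", x$chi1, x$rmsd))
  print(transform(x$conformers, population = round(population, 3)))
  invisible(x)
}

#' Classify a residue as unimodal or trimodal
#'
#' A residue is unimodal when both criteria hold: (a) the UMS chi1 lies
#' within `staggered_tolerance` (inclusive) of a staggered angle, and (b)
#' the largest conformer population exceeds `population_threshold`
#' (strictly). The population is taken from the TMST fit by default; the
#' TMSS populations can be used instead via `population_from`.
#'
#' @param ums A `ums_result` (or a single UMS chi1 value in degrees).
#' @param tmst A `tmst_result` (or a numeric vector of populations).
#' @param tmss Optional `tmss_result`, used when
#'   `population_from = "tmss"`.
#' @param population_threshold Population criterion threshold (default 0.60).
#' @param staggered_tolerance Angle criterion half-width in degrees
#'   (default 30).
#' @param population_from `"tmst"` (default) or `"tmss"`.
#' @return A list of class `residue_classification`: `label` (`"unimodal"`
#'   or `"trimodal"`), `dominant_bin` (60, 180, -60, or NA), and `criteria`
#'   (per-criterion pass/fail with the measured values).
#' @export
classify_residue <- function(ums, tmst, tmss = NULL,
                             population_threshold = 0.60,
                             staggered_tolerance = 30,
                             population_from = c("tmst", "tmss")) {
  population_from <- match.arg(population_from)
  chi1 <- if (inherits(ums, "ums_result")) ums$chi1 else as.numeric(ums)
  pops <- if (population_from == "tmss") {
    if (is.null(tmss)) stop("tmss result required when population_from = 'tmss'",
                            call. = FALSE)
    if (inherits(tmss, "tmss_result")) tmss$populations else as.numeric(tmss)
  } else {
    if (inherits(tmst, "tmst_result")) tmst$populations else as.numeric(tmst)
  }
  bin <- .nearest_staggered(chi1)
  dev <- circ_distance(chi1, bin)
  angle_ok <- dev <= staggered_tolerance
  pmax_val <- max(pops)
  pop_ok <- pmax_val > population_threshold
  unimodal <- angle_ok && pop_ok
  structure(list(label = if (unimodal) "unimodal" else "trimodal",
                 dominant_bin = if (unimodal) bin else NA_real_,
                 criteria = list(
                   staggered = list(pass = angle_ok, chi1 = chi1,
                                    nearest = bin, deviation = dev,
                                    tolerance = staggered_tolerance),
                   population = list(pass = pop_ok, max_population = pmax_val,
                                     threshold = population_threshold,
                                     source = population_from))),
            class = "residue_classification")
}

#' @export
print.residue_classification <- function(x, ...) {
  cat(sprintf("%s (staggered criterion: %s, deviation %.1f deg; population criterion: %s, max %.0f%%)\n",
              x$label, ifelse(x$criteria$staggered$pass, "pass", "fail"),
              x$criteria$staggered$deviation,
              ifelse(x$criteria$population$pass, "pass", "fail"),
              100 * x$criteria$population$max_population))
  invisible(x)
}

#' Predict couplings from a fitted conformer model
#'
#' UMS results evaluate the Karplus set at the selected chi1; TMSS and TMST
#' results return the population-weighted sum of the conformer evaluations
#' (the Karplus series is linear in its coefficients, so this equals
#' evaluating the population-weighted coefficient mixture).
#'
#' @param model_result A `ums_result`, `tmss_result` or `tmst_result`.
#' @param kset A [karplus_set()].
#' @param coupling_ids Couplings to predict (default: all parameterized).
#' @return Named numeric vector of predicted couplings, Hz.
#' @export
predict_couplings <- function(model_result, kset, coupling_ids = NULL) {
  if (is.null(coupling_ids)) coupling_ids <- names(kset$entries)
  if (inherits(model_result, "ums_result")) {
    return(evaluate_at_chi1(kset, model_result$chi1, coupling_ids))
  }
  if (inherits(model_result, "tmss_result")) {
    angles <- c(60, 180, -60)
    pops <- model_result$populations
  } else if (inherits(model_result, "tmst_result")) {
    angles <- model_result$conformers$chi1
    pops <- model_result$conformers$population
  } else {
    stop("model_result must be a ums_result, tmss_result or tmst_result",
         call. = FALSE)
  }
  out <- numeric(length(coupling_ids))
  for (j in seq_along(angles)) {
    out <- out + pops[j] * evaluate_at_chi1(kset, angles[j], coupling_ids)
  }
  setNames(out, coupling_ids)
}

#' Global coupling rmsd over a residue collection
#'
#' Pools every (experimental, predicted) coupling pair across residues and
#' returns `sqrt(mean(squared difference))` together with the total number
#' of couplings m.
#'
#' @param residues List of [residue_couplings()] objects.
#' @param results List of fitted model results, parallel to `residues`.
#' @param ksets Either a single [karplus_set()] or a named list keyed by
#'   residue type.
#' @return List with `rmsd` (Hz) and `m` (total coupling count).
#' @export
rmsd_j_total <- function(residues, results, ksets) {
  if (length(residues) == 0L) stop("empty residue collection", call. = FALSE)
  if (length(residues) != length(results)) {
    stop("need one model result per residue", call. = FALSE)
  }
  sq <- 0; m <- 0L
  for (i in seq_along(residues)) {
    res <- residues[[i]]
    kset <- if (inherits(ksets, "karplus_set")) ksets
            else ksets[[res$residue_type]]
    if (is.null(kset)) stop("no Karplus set for residue type ",
                            res$residue_type, call. = FALSE)
    pred <- predict_couplings(results[[i]], kset, names(res$measurements))
    sq <- sq + sum((res$measurements - pred)^2)
    m <- m + res$n
  }
  list(rmsd = sqrt(sq / m), m = m)
}
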