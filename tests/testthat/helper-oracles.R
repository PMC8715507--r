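# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check.

# random six-coefficient set with realistic Hz magnitudes
random_coefficients <- function() {
  karplus_coefficients(runif(1, -2, 8), runif(1, -2, 2), runif(1, -1, 4),
                       runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                       runif(1, -0.5, 0.5))
}

# Karplus set with independently random coefficients on every coupling
# (unlike demo_karplus_set, branch couplings do not share a curve)
random_karplus_set <- function(residue_type = "VAL") {
  topo <- residue_topology(residue_type)
  entries <- lapply(seq_len(nrow(topo)), function(i) random_coefficients())
  names(entries) <- topo$coupling_id
  karplus_set(residue_type, entries)
}

# direct square-solve oracle for the six-point, six-term fit
solve6_oracle <- function(theta_deg, j) {
  t <- theta_deg * pi / 180
  X <- cbind(1, cos(t), cos(2 * t), cos(3 * t), sin(t), sin(2 * t))
  solve(X, j)
}

# vector-form circular distance
circ_distance_oracle <- function(a, b) {
  ar <- a * pi / 180; br <- b * pi / 180
  acos(pmin(1, pmax(-1, cos(ar) * cos(br) + sin(ar) * sin(br)))) * 180 / pi
}

# projection-based dihedral oracle: signed angle between the components of
# (a - b) and (d - c) perpendicular to the central bond
dihedral_oracle <- function(a, b, c, d) {
  axis <- (c - b) / sqrt(sum((c - b)^2))
  u <- (a - b) - sum((a - b) * axis) * axis
  v <- (d - c) - sum((d - c) * axis) * axis
  x <- sum(u * v)
  y <- sum(axis * c(u[2] * v[3] - u[3] * v[2],
                    u[3] * v[1] - u[1] * v[3],
                    u[1] * v[2] - u[2] * v[1]))
  rotamerfit::wrap_angle(atan2(y, x) * 180 / pi)
}

# dense simplex grid search for the staggered-population problem; returns
# the smallest rmsd over the grid
tmss_grid_oracle <- function(A, b, n, resolution = 0.001) {
  p1 <- seq(0, 1, by = resolution)
  reps <- vapply(p1, function(x) length(seq(0, 1 - x, by = resolution)),
                 integer(1))
  P1 <- rep(p1, reps)
  P2 <- unlist(lapply(p1, function(x) seq(0, 1 - x, by = resolution)))
  P <- rbind(P1, P2, 1 - P1 - P2)
  R <- A %*% P - b
  sqrt(min(colSums(R^2)) / n)
}
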