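#' @importFrom stats setNames
NULL

# Phase-shift bookkeeping for the nine vicinal couplings around Calpha-Cbeta.
#
# chi1 is the dihedral N'-CA-CB-CG(1). Every other coupling path
# X-CA-CB-Y is offset from chi1 by a tetrahedral phase shift:
# theta = chi1 + delta(X) + delta(Y), with delta in {0, +120, -120}.
# Viewed along CA->CB, the backbone substituents N', C', HA sit 120 degrees
# apart (delta_X: N' = 0, C' = +120, HA = -120); on the beta carbon the
# reference gamma substituent defining chi1 carries delta_Y = 0 and the other
# two branches +120 / -120. Branch assignment per residue type follows the
# IUPAC atom names (Val/Ile: CG1 reference, CG2 and HB branches; Leu: CG
# reference, HB2 and HB3 branches).
.delta_x <- c(N = 0, C = 120, HA = -120)

.topology_registry <- local({
  make <- function(y_atoms, y_delta) {
    grid <- expand.grid(nucleus_y = y_atoms, nucleus_x = names(.delta_x),
                        stringsAsFactors = FALSE)
    data.frame(
      coupling_id = paste(grid$nucleus_x, grid$nucleus_y, sep = "-"),
      nucleus_x = grid$nucleus_x,
      nucleus_y = grid$nucleus_y,
      coupling_type = paste(grid$nucleus_x,
                            sub("[0-9]+$", "", grid$nucleus_y), sep = "-"),
      delta_theta = wrap_angle(.delta_x[grid$nucleus_x] +
                                 y_delta[grid$nucleus_y]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(
    VAL = make(c("HB", "CG1", "CG2"), c(HB = -120, CG1 = 0, CG2 = 120)),
    ILE = make(c("HB", "CG1", "CG2"), c(HB = -120, CG1 = 0, CG2 = 120)),
    LEU = make(c("HB2", "HB3", "CG"), c(HB2 = 120, HB3 = -120, CG = 0))
  )
})

#' Coupling topology table for a residue type
#'
#' Returns the nine vicinal coupling paths around the Calpha-Cbeta bond for
#' one residue type: coupling id, the two coupled nuclei, the coupling type
#' (one of the six classes 3J(HA,HB), 3J(HA,CG), 3J(C',HB), 3J(C',CG),
#' 3J(N',HB), 3J(N',CG)), and the tetrahedral phase shift `delta_theta`
#' mapping chi1 to the path dihedral, `theta = chi1 + delta_theta`.
#'
#' @param residue_type `"VAL"`, `"LEU"` or `"ILE"` (case-insensitive), or a
#'   type previously added with [register_topology()].
#' @param delta_theta_override Optional named numeric vector of per-coupling
#'   phase shifts (degrees) replacing the tetrahedral defaults, e.g. refined
#'   phases derived from optimized geometries.
#' @return A data.frame with columns `coupling_id`, `nucleus_x`, `nucleus_y`,
#'   `coupling_type`, `delta_theta`.
#' @examples
#' residue_topology("VAL")
#' @export
residue_topology <- function(residue_type, delta_theta_override = NULL) {
  key <- toupper(residue_type)
  topo <- .topology_env$registry[[key]]
  if (is.null(topo)) {
    stop("unknown residue type '", residue_type, "'; known: ",
         paste(names(.topology_env$registry), collapse = ", "), call. = FALSE)
  }
  if (!is.null(delta_theta_override)) {
    unknown <- setdiff(names(delta_theta_override), topo$coupling_id)
    if (length(unknown)) {
      stop("delta_theta override for unknown coupling(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(delta_theta_override <= -180 | delta_theta_override > 180)) {
      stop("delta_theta must lie in (-180, 180]", call. = FALSE)
    }
    idx <- match(names(delta_theta_override), topo$coupling_id)
    topo$delta_theta[idx] <- unname(delta_theta_override)
  }
  topo
}

.topology_env <- new.env(parent = emptyenv())
.topology_env$registry <- .topology_registry

#' Register a custom residue-type topology
#'
#' Adds (or replaces) a residue type in the topology registry. The table must
#' carry one row per coupling path with unique ids and phase shifts in
#' `(-180, 180]`.
#'
#' @param residue_type Name of the residue type (stored upper-case).
#' @param topology data.frame with columns `coupling_id`, `nucleus_x`,
#'   `nucleus_y`, `coupling_type`, `delta_theta`.
#' @return The registered table, invisibly.
#' @export
register_topology <- function(residue_type, topology) {
  need <- c("coupling_id", "nucleus_x", "nucleus_y", "coupling_type",
            "delta_theta")
  if (!all(need %in% names(topology))) {
    stop("topology table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(topology$coupling_id)) {
    stop("duplicate coupling_id in topology table", call. = FALSE)
  }
  if (any(topology$delta_theta <= -180 | topology$delta_theta > 180)) {
    stop("delta_theta must lie in (-180, 180]", call. = FALSE)
  }
  .topology_env$registry[[toupper(residue_type)]] <- topology
  invisible(topology)
}

#' Gamma reference atom used to define chi1
#'
#' chi1 is the dihedral N-CA-CB-CG1 for Val and Ile and N-CA-CB-CG for Leu;
#' the branch choice matters because swapping branches shifts chi1 by
#' +/- 120 degrees.
#'
#' @param residue_type Residue type name (three-letter, case-insensitive).
#' @return Atom name of the gamma reference atom.
#' @export
chi1_gamma_atom <- function(residue_type) {
  key <- toupper(residue_type)
  atom <- .topology_env$gamma[[key]]
  if (is.null(atom)) {
    stop("no chi1 gamma atom configured for residue type '", residue_type,
         "'", call. = FALSE)
  }
  atom
}

.topology_env$gamma <- list(VAL = "CG1", ILE = "CG1", LEU = "CG",
                            THR = "OG1", SER = "OG", CYS = "SG",
                            ASP = "CG", ASN = "CG", GLU = "CG", GLN = "CG",
                            LYS = "CG", ARG = "CG", MET = "CG", PRO = "CG",
                            HIS = "CG", PHE = "CG", TYR = "CG", TRP = "CG")
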