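#' @importFrom utils read.table write.table count.fields
NULL

# Delimited-text conventions shared by every table reader: comma or tab
# autodetected from the header line, mandatory header row, '.' decimal,
# degrees and Hz units. Unknown columns pass through untouched.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

.read_delim_checked <- function(path, required, what) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df
}

.write_delim <- function(df, path, sep = ",") {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a Karplus coefficient table
#'
#' Schema: `residue_type, coupling_id, c0, c1, c2, c3, s1, s2` plus optional
#' provenance columns `backbone, method, basis` (one row per coupling).
#'
#' @param path File path (comma- or tab-delimited, header mandatory).
#' @return `read_coefficient_table()`: a data.frame.
#' @export
read_coefficient_table <- function(path) {
  df <- .read_delim_checked(path, c("residue_type", "coupling_id",
                                    "c0", "c1", "c2", "c3", "s1", "s2"),
                            "coefficient")
  num <- c("c0", "c1", "c2", "c3", "s1", "s2")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (any(!is.finite(as.matrix(df[num])))) {
    stop("non-finite coefficient value in ", path, call. = FALSE)
  }
  key <- paste(df$residue_type, df$coupling_id)
  if (anyDuplicated(key)) {
    stop("duplicate (residue_type, coupling_id) rows in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df
}

#' @rdname read_coefficient_table
#' @param df Table to write.
#' @return `write_coefficient_table()`: the path, invisibly.
#' @export
write_coefficient_table <- function(df, path) .write_delim(df, path)

#' Build Karplus sets from a coefficient table
#'
#' @param df A coefficient table data.frame ([read_coefficient_table()]).
#' @param delta_theta_override Optional per-coupling phase overrides applied
#'   to every residue type.
#' @return Named list of [karplus_set()] objects, one per residue type.
#' @export
karplus_sets_from_table <- function(df, delta_theta_override = NULL) {
  out <- list()
  for (rt in unique(df$residue_type)) {
    rows <- df[df$residue_type == rt, , drop = FALSE]
    entries <- lapply(seq_len(nrow(rows)), function(i) {
      karplus_coefficients(rows$c0[i], rows$c1[i], rows$c2[i], rows$c3[i],
                           rows$s1[i], rows$s2[i],
                           method = if ("method" %in% names(rows))
                             rows$method[i] else "unspecified",
                           basis = if ("basis" %in% names(rows))
                             rows$basis[i] else "unspecified",
                           residue_type = toupper(rt),
                           backbone = if ("backbone" %in% names(rows))
                             rows$backbone[i] else "unspecified")
    })
    names(entries) <- rows$coupling_id
    out[[toupper(rt)]] <- karplus_set(rt, entries, delta_theta_override)
  }
  out
}

#' Read / write a dihedral scan table
#'
#' Schema: `chi1_deg, coupling_id, j_hz`. Duplicate (chi1, coupling) rows
#' are rejected.
#'
#' @param path File path.
#' @return `read_scan_table()`: a data.frame with `chi1_deg` wrapped to
#'   `(-180, 180]`.
#' @export
read_scan_table <- function(path) {
  df <- .read_delim_checked(path, c("chi1_deg", "coupling_id", "j_hz"),
                            "scan")
  df$chi1_deg <- wrap_angle(as.numeric(df$chi1_deg))
  df$j_hz <- as.numeric(df$j_hz)
  key <- paste(df$chi1_deg, df$coupling_id)
  if (anyDuplicated(key)) {
    stop("duplicate (chi1, coupling) rows in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df
}

#' @rdname read_scan_table
#' @param df Table to write.
#' @export
write_scan_table <- function(df, path) .write_delim(df, path)

#' Read / write a residue coupling table
#'
#' Schema: `residue_id, residue_type, coupling_id, j_exp_hz`. Every
#' coupling id is validated against its residue type's topology.
#'
#' @param path File path.
#' @return `read_coupling_table()`: a list of [residue_couplings()] objects.
#' @export
read_coupling_table <- function(path) {
  df <- .read_delim_checked(path, c("residue_id", "residue_type",
                                    "coupling_id", "j_exp_hz"), "coupling")
  df$j_exp_hz <- as.numeric(df$j_exp_hz)
  ids <- unique(df$residue_id)
  lapply(setNames(ids, ids), function(rid) {
    rows <- df[df$residue_id == rid, , drop = FALSE]
    rt <- unique(rows$residue_type)
    if (length(rt) != 1L) {
      stop("residue ", rid, " has inconsistent residue_type values",
           call. = FALSE)
    }
    residue_couplings(rid, rt, setNames(rows$j_exp_hz, rows$coupling_id))
  })
}

#' @rdname read_coupling_table
#' @param residues List of [residue_couplings()] objects to write.
#' @export
write_coupling_table <- function(residues, path) {
  df <- do.call(rbind, lapply(residues, function(r) {
    data.frame(residue_id = r$residue_id, residue_type = r$residue_type,
               coupling_id = names(r$measurements),
               j_exp_hz = unname(r$measurements))
  }))
  .write_delim(df, path)
}

#' Read / write an angle table
#'
#' Schema: `residue_id, chi1_deg` plus optional `source`.
#'
#' @param path File path.
#' @return `read_angle_table()`: a data.frame with `chi1_deg` wrapped to
#'   `(-180, 180]`.
#' @export
read_angle_table <- function(path) {
  df <- .read_delim_checked(path, c("residue_id", "chi1_deg"), "angle")
  df$chi1_deg <- wrap_angle(as.numeric(df$chi1_deg))
  df
}

#' @rdname read_angle_table
#' @param df Table to write.
#' @export
write_angle_table <- function(df, path) .write_delim(df, path)

#' Dihedral angle of four points
#'
#' Standard signed torsion about the b-c axis (IUPAC convention: looking
#' from b to c, the angle from the a-side projection to the d-side
#' projection, positive clockwise), in degrees wrapped to `(-180, 180]`.
#'
#' @param a,b,c,d Numeric xyz coordinate vectors of the four atoms.
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2); y <- -sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Read ATOM/HETATM records from a PDB file
#'
#' Minimal fixed-column PDB coordinate parser (no general-purpose PDB
#' reader is available in this package's dependency set). Only the first
#' MODEL is read; alternate locations are resolved later by occupancy.
#'
#' @param path PDB file path.
#' @return data.frame with `atom`, `altloc`, `resname`, `chain`, `resseq`,
#'   `icode`, `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends)) lines <- lines[seq_len(model_ends[1] - 1L)]
  rec <- lines[grepl("^ATOM  |^HETATM", lines)]
  if (length(rec) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  fld <- function(from, to) trimws(substring(rec, from, to))
  data.frame(atom = fld(13, 16),
             altloc = fld(17, 17),
             resname = fld(18, 20),
             chain = fld(22, 22),
             resseq = as.integer(fld(23, 26)),
             icode = fld(27, 27),
             x = as.numeric(fld(31, 38)),
             y = as.numeric(fld(39, 46)),
             z = as.numeric(fld(47, 54)),
             occupancy = suppressWarnings(as.numeric(fld(55, 60))),
             stringsAsFactors = FALSE)
}

#' Extract chi1 from a PDB structure
#'
#' Computes the side-chain torsion chi1 = N-CA-CB-G where G is the
#' residue-type's gamma reference atom (CG1 for Val/Ile, CG for Leu; see
#' [chi1_gamma_atom()]). Alternate locations are resolved to the highest
#' occupancy (ties by altloc label order); the first model is used.
#'
#' @param path PDB file path (or a data.frame from [read_pdb_atoms()]).
#' @param chain Chain identifier (default: first chain in the file).
#' @param resseq Residue sequence number.
#' @param gamma_atom Override the gamma reference atom name.
#' @return chi1 in degrees, wrapped to `(-180, 180]`.
#' @export
chi1_from_structure <- function(path, chain = NULL, resseq,
                                gamma_atom = NULL) {
  atoms <- if (is.data.frame(path)) path else read_pdb_atoms(path)
  if (is.null(chain)) chain <- atoms$chain[1]
  res <- atoms[atoms$chain == chain & atoms$resseq == resseq, , drop = FALSE]
  if (nrow(res) == 0L) {
    stop("no atoms for chain ", chain, " residue ", resseq, call. = FALSE)
  }
  resname <- res$resname[1]
  if (is.null(gamma_atom)) gamma_atom <- chi1_gamma_atom(resname)
  pick <- function(name) {
    hit <- res[res$atom == name, , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop("missing atom ", name, " in ", resname, " ", resseq, call. = FALSE)
    }
    if (nrow(hit) > 1L) {
      occ <- ifelse(is.na(hit$occupancy), 0, hit$occupancy)
      hit <- hit[order(-occ, hit$altloc), , drop = FALSE]
    }
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  dihedral_angle(pick("N"), pick("CA"), pick("CB"), pick(gamma_atom))
}
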