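#' Reference chi1 tables for D. vulgaris flavodoxin Val/Leu/Ile residues
#'
#' Loads the packaged reference results for the 29 Val, Leu and Ile residues
#' of *Desulfovibrio vulgaris* flavodoxin (strain Hildenborough): 25
#' unimodal residues with UMS/TMSS/TMST fits, coupling counts, two empirical
#' NMR chi1 determinations (labelled Schmidt and Perez after their authors)
#' and robust X-ray averages; and 4 trimodal residues carrying both UMS
#' minima and dual X-ray averages. Angles are degrees, populations percent,
#' rmsd values Hz.
#'
#' File integrity is verified against stored md5 digests at load time.
#'
#' @return A list with data.frames `unimodal` (25 rows) and `trimodal`
#'   (8 rows, two per residue: one per UMS minimum; model-fit and NMR
#'   columns are carried on the first row of each residue).
#' @examples
#' tabs <- load_flavodoxin_tables()
#' sum(tabs$unimodal$n_j)  # 181 couplings
#' @export
load_flavodoxin_tables <- function() {
  files <- c(unimodal = "flavodoxin_unimodal.csv",
             trimodal = "flavodoxin_trimodal.csv")
  out <- lapply(files, function(f) {
    path <- system.file("extdata", f, package = "rotamerfit")
    if (path == "") stop("packaged fixture ", f, " not found", call. = FALSE)
    digest <- unname(tools::md5sum(path))
    if (!identical(digest, .fixture_md5[[f]])) {
      stop("packaged fixture ", f, " is corrupted (md5 mismatch)",
           call. = FALSE)
    }
    read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  })
  if (nrow(out$unimodal) != 25L || sum(out$unimodal$n_j) != 181L) {
    stop("unimodal fixture failed its sanity checks", call. = FALSE)
  }
  expected_tri <- c("Val88", "Val144", "Leu78", "Ile148")
  if (!identical(unique(out$trimodal$residue_id), expected_tri)) {
    stop("trimodal fixture failed its sanity checks", call. = FALSE)
  }
  out
}

.fixture_md5 <- list(
  "flavodoxin_unimodal.csv" = "10e31463df174d359d7a23d9161e0126",
  "flavodoxin_trimodal.csv" = "8dab570cd6434ae331ae6376e0d5302c"
)

#' Cross-method chi1 agreement statistics on the reference tables
#'
#' Recomputes, from the packaged flavodoxin tables, the circular rmsd
#' ([rmsd_chi1()], 40-degree exclusion) between the UMS chi1 column and
#' each comparison column (X-ray average, the two empirical NMR sets, and
#' the dominant TMSS / TMST staggered assignments), the Schmidt-vs-Perez
#' agreement, the pooled coupling count, and the unimodal/trimodal
#' classification of all 29 residues.
#'
#' The TMSS chi1 of a residue is the staggered angle (60/180/-60) of its
#' largest TMSS population. For classification, the trimodal residues use
#' the tabulated first-listed UMS minimum.
#'
#' @param exclusion Exclusion cutoff in degrees for [rmsd_chi1()]
#'   (default 40).
#' @return A list with `comparisons` (data.frame: pair, rmsd, n, max
#'   deviation), `n_couplings`, `n_unimodal`, `n_trimodal`,
#'   `trimodal_residues`, and `classification` (per-residue data.frame).
#' @export
reference_stats <- function(exclusion = 40) {
  tabs <- load_flavodoxin_tables()
  t1 <- tabs$unimodal
  ums <- setNames(t1$ums_chi1, t1$residue_id)
  stag <- c(60, 180, -60)
  tmss_chi1 <- setNames(
    stag[max.col(as.matrix(t1[, c("tmss_p60", "tmss_p180", "tmss_pm60")]),
                 ties.method = "first")], t1$residue_id)
  sets <- list(
    "UMS vs X-ray" = list(ums, setNames(t1$xray_chi1, t1$residue_id)),
    "UMS vs Schmidt" = list(ums, setNames(t1$schmidt_chi1, t1$residue_id)),
    "UMS vs Perez" = list(ums, setNames(t1$perez_chi1, t1$residue_id)),
    "UMS vs TMSS" = list(ums, tmss_chi1),
    "UMS vs TMST" = list(ums, setNames(t1$tmst_chi1, t1$residue_id)),
    "Schmidt vs Perez" = list(setNames(t1$schmidt_chi1, t1$residue_id),
                              setNames(t1$perez_chi1, t1$residue_id))
  )
  comparisons <- do.call(rbind, lapply(names(sets), function(nm) {
    r <- rmsd_chi1(sets[[nm]][[1]], sets[[nm]][[2]], exclusion)
    data.frame(pair = nm, rmsd = r$rmsd, n = r$n_used,
               max_deviation = r$max_deviation)
  }))

  # classification over all 29 residues (trimodal table: first UMS minimum)
  t4 <- tabs$trimodal[tabs$trimodal$minimum == 1, , drop = FALSE]
  all_rows <- rbind(
    t1[, c("residue_id", "ums_chi1", "tmst_p60", "tmst_p180", "tmst_pm60")],
    t4[, c("residue_id", "ums_chi1", "tmst_p60", "tmst_p180", "tmst_pm60")]
  )
  cls <- lapply(seq_len(nrow(all_rows)), function(i) {
    classify_residue(all_rows$ums_chi1[i],
                     c(all_rows$tmst_p60[i], all_rows$tmst_p180[i],
                       all_rows$tmst_pm60[i]) / 100)
  })
  classification <- data.frame(
    residue_id = all_rows$residue_id,
    label = vapply(cls, `[[`, character(1), "label"),
    dominant_bin = vapply(cls, `[[`, numeric(1), "dominant_bin")
  )
  list(comparisons = comparisons,
       n_couplings = sum(t1$n_j),
       n_unimodal = sum(classification$label == "unimodal"),
       n_trimodal = sum(classification$label == "trimodal"),
       trimodal_residues =
         classification$residue_id[classification$label == "trimodal"],
       classification = classification)
}
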