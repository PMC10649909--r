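# Quantum-descriptor tables: HOMO/LUMO energies (eV) computed externally by a
# DFT package are ingested, gaps validated against any printed values, and
# compounds ranked by reactivity (smaller gap = more reactive).

#' HOMO-LUMO energy gap
#'
#' @param e_homo,e_lumo orbital energies in eV; requires `e_homo < e_lumo`.
#' @return the gap `e_lumo - e_homo` in eV (full precision; round to 2
#'   decimals for reporting).
#' @export
homo_lumo_gap <- function(e_homo, e_lumo) {
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo))) {
    stopf("orbital energies must be finite")
  }
  if (any(e_homo >= e_lumo)) stopf("E_HOMO must be strictly below E_LUMO")
  e_lumo - e_homo
}

#' Read a descriptor TSV (compound, homo_ev, lumo_ev[, gap_ev])
#' @param path input file.
#' @return data.frame with a `gap_computed` column appended.
#' @export
read_descriptor_table <- function(path) {
  df <- read_tsv(path)
  need <- c("compound", "homo_ev", "lumo_ev")
  if (!all(need %in% names(df))) {
    stopf("descriptor table needs columns %s", paste(need, collapse = ", "))
  }
  df$gap_computed <- homo_lumo_gap(df$homo_ev, df$lumo_ev)
  df
}

#' Validate printed gaps against recomputed ones
#'
#' Flags rows where `|gap_ev - (lumo_ev - homo_ev)| > tol`. Rows without a
#' printed gap are skipped. The validator reports discrepancies; it never
#' "corrects" the table.
#'
#' @param rows descriptor data.frame (see [read_descriptor_table()]).
#' @param tol tolerance in eV (default 0.005: exact at two printed decimals).
#' @return data.frame (compound, gap_printed, gap_computed, discrepancy,
#'   flagged), one row per validated compound.
#' @export
validate_gaps <- function(rows, tol = 0.005) {
  if (!"gap_computed" %in% names(rows)) {
    rows$gap_computed <- homo_lumo_gap(rows$homo_ev, rows$lumo_ev)
  }
  if (!"gap_ev" %in% names(rows)) {
    return(data.frame(compound = character(0), gap_printed = numeric(0),
                      gap_computed = numeric(0), discrepancy = numeric(0),
                      flagged = logical(0)))
  }
  keep <- !is.na(rows$gap_ev)
  out <- data.frame(compound = rows$compound[keep],
                    gap_printed = rows$gap_ev[keep],
                    gap_computed = rows$gap_computed[keep],
                    stringsAsFactors = FALSE)
  out$discrepancy <- out$gap_printed - out$gap_computed
  out$flagged <- abs(out$discrepancy) > tol
  out
}

#' Rank compounds by reactivity (ascending HOMO-LUMO gap)
#'
#' A smaller gap is read as easier electronic excitation, hence higher
#' chemical reactivity. Ties break lexicographically by compound id.
#'
#' @param rows descriptor data.frame.
#' @return the data.frame reordered, with a `rank` column (1 = most reactive).
#' @export
reactivity_ranking <- function(rows) {
  if (nrow(rows) < 1L) stopf("need at least one descriptor row")
  if (!"gap_computed" %in% names(rows)) {
    rows$gap_computed <- homo_lumo_gap(rows$homo_ev, rows$lumo_ev)
  }
  out <- rows[order(rows$gap_computed, rows$compound), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Packaged descriptor table for the ten licorice flavonoids
#'
#' B3LYP/6-31G* HOMO/LUMO energies (eV) of the seven licochalcones plus
#' Glypallichalcone, Echinatin and
#' 3,4,3'-4'-Tetrahydroxy-2-methoxychalcone, with the published gap values.
#'
#' @return descriptor data.frame (see [read_descriptor_table()]).
#' @export
licorice_descriptors <- function() {
  read_descriptor_table(system.file("extdata", "licorice_homo_lumo.tsv",
                                    package = "csnpharm", mustWork = TRUE))
}

#' Packaged compound table for the ten licorice flavonoids
#'
#' Names, SMILES and published closeness-centrality values of the
#' licochalcone-family cluster.
#'
#' @return data.frame from [parse_smiles_table()] with the published
#'   closeness appended as `closeness_published`.
#' @export
licorice_compounds <- function() {
  path <- system.file("extdata", "licorice_compounds.tsv",
                      package = "csnpharm", mustWork = TRUE)
  out <- parse_smiles_table(path)
  ref <- read_tsv(path)
  out$closeness_published <-
    ref$ClosenessCentrality[match(out$name, ref[["Molecule Name"]])]
  out
}
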