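# Accessors for the packaged reference data: the published candidate and
# control sequences, the published interface-comparison table, and the
# control's functional-annotation odds.

#' Published candidate bacteriocin sequences
#'
#' The 14 gut-microbiome bacteriocin candidates that passed the
#' hydrophobic-percentage window in the published screen, as peptide
#' records (with BAGEL ids and source species), in table order.
#'
#' @return peptide record data frame (14 rows).
#' @export
table1_peptides <- function() {
  read_peptide_fasta(ext_file("table1_peptides.fasta"))
}

#' Azurin and p28-azurin reference sequences
#'
#' The azurin precursor sequence of *Pseudomonas aeruginosa* PAO1 and its
#' p28 fragment (mature residues 50-77, the cancer-cell entry and
#' antiproliferative domain). p18 (mature residues 50-67) is the first 18
#' residues of p28 and can be derived with
#' [extract_reference_subpeptide()].
#'
#' @return peptide record data frame with rows `azurin` and `p28`.
#' @export
azurin_reference <- function() {
  read_peptide_fasta(ext_file("azurin_reference.fasta"))
}

#' Published hydrophobic percentages of the reference and candidate set
#'
#' The integer hydrophobic percentages as printed for azurin, p28-azurin
#' and the 14 candidates; used to cross-check [hydrophobic_percentage()].
#'
#' @return data frame with columns `seq_id`, `hpp`.
#' @export
table1_reported_hpp <- function() {
  read_tsv(ext_file("table1_reported_hpp.tsv"))
}

#' Published binding-interface comparison table
#'
#' Per candidate: peptide size, shared receptor-interface residue counts
#' and percentages against the p28-azurin and azurin references, the
#' polar/nonpolar atom percentages of both interface sides, and whether the
#' row was reported as binding in the same region as the references
#' (`reported_selected`). The reference interface sizes are not printed;
#' [infer_reference_size()] recovers them from the counts and percentages.
#'
#' @return data frame with columns `seq_id`, `size`, `shared_p28`,
#'   `pct_p28`, `shared_azurin`, `pct_azurin`, `polar_pct_ligand`,
#'   `nonpolar_pct_ligand`, `polar_pct_receptor`, `nonpolar_pct_receptor`,
#'   `reported_selected`.
#' @export
table2_interfaces <- function() {
  df <- read_tsv(ext_file("binding_interface_table.tsv"))
  df$reported_selected <- as.logical(df$reported_selected)
  df
}

#' Functional-annotation odds of the azurin control
#'
#' The control's top-category odds: cellular envelope 9.71 (group F),
#' nonenzyme 1.147 (EZ) and immune response 5.877 (GO), as published for
#' azurin. The probability column is a reconstruction (odds multiplied by a
#' typical category prior) supplied only so the table satisfies the
#' annotation dialect; treat it as synthetic.
#'
#' @return an `annotation_set` with the three control rows.
#' @export
azurin_annotation <- function() {
  read_annotation_table(ext_file("azurin_odds.tsv"))
}
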