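# Docked-complex handling: PDB IO, binding-interface extraction at a
# distance cutoff, polar/nonpolar interface composition, and overlap with
# reference interfaces.

#' Construct a two-chain complex model
#'
#' Low-level constructor used by [read_complex_pdb()] and the synthetic
#' generator. `atoms` must hold one row per atom with columns `chain`,
#' `resno`, `insert` (NA when absent), `resid`, `elety` (atom name),
#' `element`, `eleno` (serial), `x`, `y`, `z`.
#'
#' @param atoms atom data frame as described above.
#' @param receptor_chain,ligand_chain chain ids of the two sides.
#' @return object of class `complex_model`.
#' @export
complex_model <- function(atoms, receptor_chain, ligand_chain) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "eleno", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  for (ch in c(receptor_chain, ligand_chain)) {
    if (!any(atoms$chain == ch)) {
      stop("chain '", ch, "' not present in the model")
    }
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  structure(list(atoms = atoms, receptor_chain = receptor_chain,
                 ligand_chain = ligand_chain),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  nres <- function(ch) {
    a <- x$atoms[x$atoms$chain == ch, ]
    length(unique(paste(a$resno, a$insert)))
  }
  cat(sprintf(
    "Docked complex: receptor chain %s (%d residues), ligand chain %s (%d residues), %d atoms\n",
    x$receptor_chain, nres(x$receptor_chain),
    x$ligand_chain, nres(x$ligand_chain), nrow(x$atoms)))
  invisible(x)
}

# element symbol from a PDB atom name when the element column is absent:
# strip leading digits, take the first letter (sufficient for C/N/O/S/H
# protein atoms; docked peptide models carry no metals)
.element_from_name <- function(elety) {
  toupper(substr(sub("^[0-9]*", "", elety), 1, 1))
}

#' Read a docked two-chain complex from a PDB file
#'
#' Loads ATOM/HETATM coordinate records of the receptor and ligand chains.
#' For multi-model files only the first model is used. Alternate locations
#' are resolved per (chain, residue, atom name) by highest occupancy, then
#' altloc `A`. Elements come from the PDB element column when present,
#' otherwise from the atom name.
#'
#' @param path path to a PDB file.
#' @param receptor_chain,ligand_chain chain ids of the receptor (e.g. the
#'   p53 DNA-binding domain) and the docked ligand (bacteriocin).
#' @return a [complex_model()].
#' @export
read_complex_pdb <- function(path, receptor_chain, ligand_chain) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e))
    })
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[at$chain %in% c(receptor_chain, ligand_chain), , drop = FALSE]
  for (ch in c(receptor_chain, ligand_chain)) {
    if (!any(at$chain == ch)) {
      stop("chain '", ch, "' not found in ", path)
    }
  }
  # resolve alternate locations: keep, per atom site, the record with the
  # highest occupancy; ties prefer altloc 'A', then file order
  if (any(!is.na(at$alt))) {
    site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    pref <- ifelse(!is.na(at$alt) & at$alt == "A", 1L, 0L)
    ord <- order(site, -occ, -pref, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(site[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  element <- at$elesy
  miss <- is.na(element) | !nzchar(trimws(element))
  element[miss] <- .element_from_name(at$elety[miss])
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      element = toupper(trimws(element)), eleno = at$eleno,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  complex_model(atoms, receptor_chain, ligand_chain)
}

# residue identifier used for cross-complex matching: chain, residue number
# and insertion code (no sequence alignment; compared complexes share the
# same receptor numbering)
residue_id <- function(atoms) {
  ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  sprintf("%s:%d%s", atoms$chain, atoms$resno, ins)
}

.is_hydrogen <- function(element) element %in% c("H", "D")

#' Extract the binding interface of a docked complex
#'
#' The interface is defined by heavy-atom contacts: every (receptor atom,
#' ligand atom) pair at Euclidean distance less than or equal to the cutoff
#' (inclusive) is a contact pair, and the interface residue sets are the
#' residues owning those atoms. Hydrogens are ignored when
#' `heavy_atoms_only` (docked models typically lack them anyway). The
#' contract is defined by the brute-force all-pairs result; the
#' implementation scans one chain against the other in vectorized blocks.
#'
#' @param model a [complex_model()].
#' @param cutoff contact distance cutoff in Angstrom (default 5.0).
#' @param heavy_atoms_only ignore hydrogen/deuterium atoms (default TRUE).
#' @return object of class `binding_interface` with fields
#'   `receptor_residues`, `ligand_residues` (residue identifier vectors),
#'   `contact_pairs` (data frame of atom serials and distances) and
#'   `params`.
#' @export
compute_interface <- function(model, cutoff = 5.0, heavy_atoms_only = TRUE) {
  stopifnot(inherits(model, "complex_model"), is.numeric(cutoff),
            length(cutoff) == 1, cutoff > 0)
  at <- model$atoms
  if (heavy_atoms_only) {
    at <- at[!.is_hydrogen(at$element), , drop = FALSE]
  }
  rec <- at[at$chain == model$receptor_chain, , drop = FALSE]
  lig <- at[at$chain == model$ligand_chain, , drop = FALSE]
  ri <- integer(0)
  li <- integer(0)
  dist <- numeric(0)
  if (nrow(rec) > 0 && nrow(lig) > 0) {
    R <- t(as.matrix(rec[, c("x", "y", "z")]))  # 3 x nR
    cut2 <- cutoff^2
    for (j in seq_len(nrow(lig))) {
      d2 <- colSums((R - c(lig$x[j], lig$y[j], lig$z[j]))^2)
      hit <- which(d2 <= cut2)
      if (length(hit) > 0) {
        ri <- c(ri, hit)
        li <- c(li, rep.int(j, length(hit)))
        dist <- c(dist, sqrt(d2[hit]))
      }
    }
  }
  structure(list(
    receptor_residues = sort(unique(residue_id(rec[ri, , drop = FALSE]))),
    ligand_residues = sort(unique(residue_id(lig[li, , drop = FALSE]))),
    contact_pairs = data.frame(receptor_atom = rec$eleno[ri],
                               ligand_atom = lig$eleno[li],
                               distance = dist, stringsAsFactors = FALSE),
    params = list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only)
  ), class = "binding_interface")
}

#' @export
print.binding_interface <- function(x, ...) {
  cat(sprintf(
    "Binding interface at %.2f A: %d receptor residues, %d ligand residues, %d contact pairs\n",
    x$params$cutoff, length(x$receptor_residues), length(x$ligand_residues),
    nrow(x$contact_pairs)))
  invisible(x)
}

#' Classify a heavy atom as polar or nonpolar
#'
#' Minimal element-based convention: nitrogen and oxygen are polar; carbon
#' and sulfur are nonpolar; any other heavy element is classed polar with a
#' warning. The rule is isolated here so an alternative convention (e.g.
#' polar sulfur) can be substituted in one place. Hydrogens are an error:
#' callers must pre-filter to heavy atoms.
#'
#' @param element character vector of element symbols.
#' @param atom_name optional atom names, used only in messages.
#' @return character vector of `"polar"` / `"nonpolar"`.
#' @export
atom_polarity <- function(element, atom_name = NULL) {
  element <- toupper(element)
  if (any(.is_hydrogen(element))) {
    stop("atom_polarity() is defined for heavy atoms only; pre-filter hydrogens")
  }
  out <- ifelse(element %in% c("N", "O"), "polar",
                ifelse(element %in% c("C", "S"), "nonpolar", NA))
  other <- is.na(out)
  if (any(other)) {
    warning("unusual heavy element(s) classed polar: ",
            paste(unique(element[other]), collapse = ", "))
    log_msg("WARN", "heavy element(s) ",
            paste(unique(element[other]), collapse = ", "), " classed polar")
    out[other] <- "polar"
  }
  out
}

#' Polar/nonpolar composition of a binding interface
#'
#' Classifies the unique interface atoms of each side (atoms participating
#' in at least one contact pair) with [atom_polarity()] and reports the
#' percentages to two decimals (half-up).
#'
#' @param interface a `binding_interface` from [compute_interface()].
#' @param model the [complex_model()] the interface was computed on.
#' @return data frame with rows `ligand` and `receptor` and columns `side`,
#'   `n_atoms`, `polar_percent`, `nonpolar_percent`.
#' @export
interface_composition <- function(interface, model) {
  stopifnot(inherits(interface, "binding_interface"),
            inherits(model, "complex_model"))
  if (nrow(interface$contact_pairs) == 0) {
    stop("interface is empty; no composition to report")
  }
  one_side <- function(serials) {
    serials <- unique(serials)
    elem <- model$atoms$element[match(serials, model$atoms$eleno)]
    pol <- atom_polarity(elem)
    n <- length(pol)
    data.frame(n_atoms = n,
               polar_percent = round_half_up(100 * sum(pol == "polar") / n, 2),
               nonpolar_percent = round_half_up(100 * sum(pol == "nonpolar") / n, 2))
  }
  lig <- one_side(interface$contact_pairs$ligand_atom)
  rec <- one_side(interface$contact_pairs$receptor_atom)
  cbind(data.frame(side = c("ligand", "receptor"), stringsAsFactors = FALSE),
        rbind(lig, rec))
}

#' Overlap of a candidate interface with a reference interface
#'
#' Intersects receptor-side interface residue sets, matched by chain,
#' residue number and insertion code. The percentage is the shared count
#' over the reference interface size, to two decimals.
#'
#' @param query a `binding_interface`, or a character vector of receptor
#'   residue identifiers.
#' @param reference the reference interface (same forms accepted). The p53
#'   interface of the p28-azurin or azurin pose in typical use.
#' @return object of class `overlap_result` with `shared_count`,
#'   `reference_size`, `overlap_percent`.
#' @export
overlap_with_reference <- function(query, reference) {
  res_set <- function(x) {
    if (inherits(x, "binding_interface")) x$receptor_residues
    else as.character(x)
  }
  q <- unique(res_set(query))
  r <- unique(res_set(reference))
  if (length(r) == 0) {
    stop("reference interface is empty")
  }
  shared <- length(intersect(q, r))
  structure(list(shared_count = shared, reference_size = length(r),
                 overlap_percent = round_half_up(100 * shared / length(r), 2)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Shared interface residues: %d of %d (%.2f%%)\n",
              x$shared_count, x$reference_size, x$overlap_percent))
  invisible(x)
}

#' Azurin-like binding classification
#'
#' A candidate binds "in the same region" of the receptor as the references
#' when it shares at least one receptor interface residue with the
#' p28-azurin reference *and* at least one with the azurin reference.
#' Sharing with only one reference (as p2seq33-type cases do) is not enough.
#'
#' @param overlap_p28,overlap_azurin [overlap_with_reference()] results
#'   against the two references.
#' @return logical scalar.
#' @export
classify_azurin_like <- function(overlap_p28, overlap_azurin) {
  stopifnot(inherits(overlap_p28, "overlap_result"),
            inherits(overlap_azurin, "overlap_result"))
  overlap_p28$shared_count > 0 && overlap_azurin$shared_count > 0
}

#' Recover a reference interface size from shared counts and percentages
#'
#' Published interface-overlap tables often print the shared residue count
#' and the percentage but not the reference interface size. This consistency
#' oracle searches for the unique integer denominator that reproduces every
#' printed percentage (two-decimal, half-up) from its count. Rows with a
#' zero count are uninformative and ignored.
#'
#' @param shared_counts integer shared-residue counts.
#' @param percents printed percentages corresponding to `shared_counts`.
#' @param max_size largest denominator to try.
#' @return the unique consistent reference size (integer).
#' @export
infer_reference_size <- function(shared_counts, percents, max_size = 2000) {
  stopifnot(length(shared_counts) == length(percents))
  keep <- shared_counts > 0
  k <- shared_counts[keep]
  p <- percents[keep]
  if (length(k) == 0) {
    stop("no informative rows (all shared counts are zero)")
  }
  lo <- max(k)
  cand <- integer(0)
  for (n in lo:max_size) {
    if (all(abs(round_half_up(100 * k / n, 2) - p) < 1e-9)) {
      cand <- c(cand, n)
    }
  }
  if (length(cand) == 0) {
    stop("no integer reference size reproduces the printed percentages")
  }
  if (length(cand) > 1) {
    stop("reference size ambiguous: ", paste(cand, collapse = ", "))
  }
  cand
}

#' Build a Table-style interface comparison report
#'
#' One row per candidate, combining overlaps against both references and
#' the interface composition. Candidates whose docked pose has an empty
#' interface get an all-zero row with `selected = FALSE`.
#'
#' @param candidates named list; each element is a list with fields `size`
#'   (candidate length in residues), `overlap_p28`, `overlap_azurin`
#'   ([overlap_with_reference()] results) and `composition`
#'   ([interface_composition()] output, or NULL for an empty interface).
#' @return data frame with columns `seq_id`, `size`, `shared_p28`,
#'   `pct_p28`, `shared_azurin`, `pct_azurin`, `polar_pct_ligand`,
#'   `nonpolar_pct_ligand`, `polar_pct_receptor`, `nonpolar_pct_receptor`,
#'   `selected`.
#' @export
comparison_report <- function(candidates) {
  stopifnot(is.list(candidates), length(names(candidates)) == length(candidates))
  rows <- lapply(names(candidates), function(id) {
    cand <- candidates[[id]]
    if (is.null(cand$composition)) {
      return(data.frame(seq_id = id, size = cand$size, shared_p28 = 0L,
                        pct_p28 = 0, shared_azurin = 0L, pct_azurin = 0,
                        polar_pct_ligand = 0, nonpolar_pct_ligand = 0,
                        polar_pct_receptor = 0, nonpolar_pct_receptor = 0,
                        selected = FALSE, stringsAsFactors = FALSE))
    }
    comp <- cand$composition
    lig <- comp[comp$side == "ligand", ]
    rec <- comp[comp$side == "receptor", ]
    data.frame(
      seq_id = id, size = cand$size,
      shared_p28 = cand$overlap_p28$shared_count,
      pct_p28 = cand$overlap_p28$overlap_percent,
      shared_azurin = cand$overlap_azurin$shared_count,
      pct_azurin = cand$overlap_azurin$overlap_percent,
      polar_pct_ligand = lig$polar_percent,
      nonpolar_pct_ligand = lig$nonpolar_percent,
      polar_pct_receptor = rec$polar_percent,
      nonpolar_pct_receptor = rec$nonpolar_percent,
      selected = classify_azurin_like(cand$overlap_p28, cand$overlap_azurin),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an interface comparison report
#'
#' @param report data frame from [comparison_report()].
#' @param path file path.
#' @return `path` (writer, invisibly) or the report data frame (reader).
#' @export
write_comparison_report <- function(report, path) {
  write_tsv(report, path)
}

#' @rdname write_comparison_report
#' @export
read_comparison_report <- function(path) {
  df <- read_tsv(path)
  df$selected <- as.logical(df$selected)
  df
}

#' Store / load a reference interface as a residue-identifier TSV
#'
#' @param interface a `binding_interface` or character vector of residue
#'   identifiers.
#' @param path file path.
#' @return `path` (writer, invisibly); character vector of residue
#'   identifiers (reader).
#' @export
write_interface_residues <- function(interface, path) {
  res <- if (inherits(interface, "binding_interface")) {
    interface$receptor_residues
  } else {
    as.character(interface)
  }
  write_tsv(data.frame(residue = res, stringsAsFactors = FALSE), path)
}

#' @rdname write_interface_residues
#' @export
read_interface_residues <- function(path) {
  as.character(read_tsv(path)$residue)
}
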