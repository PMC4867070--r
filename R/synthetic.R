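# Seeded synthetic-data generators with planted ground truth for every
# pipeline stage. These stand in for data that real screens obtain from
# function-prediction servers and docking runs; they emulate the *structure*
# of such data (planted azurin-like subsets, planted contact residues), not
# the physics or the predictors' statistics.

#' Specification for the synthetic generators
#'
#' Bundles the knobs of all three generators with their invariants. The
#' defaults mirror the screening study conditions the package emulates:
#' 81 annotated sequences of which 28 are planted azurin-like, planted odds
#' drawn above 1 and background odds below 1 (disjoint around 1 so the
#' planted odds product is guaranteed above 1 and the background product
#' below), and docked pseudo-complexes whose planted contacts sit at
#' `cutoff - 0.5` Angstrom while decoy atoms stay beyond `2 * cutoff`.
#'
#' @param seed integer RNG seed; every generator draw derives from it.
#' @param n_peptides number of peptides to generate.
#' @param length_range inclusive residue-count interval.
#' @param target_hpp target hydrophobic percentage (0-100), or `"random"`
#'   for a uniform draw per sequence.
#' @param n_annotated number of annotated sequences.
#' @param n_planted number of planted azurin-like sequences.
#' @param planted_odds_range per-category odds interval for planted ids;
#'   lower bound must exceed 1.
#' @param background_odds_range per-category odds interval for background
#'   ids; upper bound must be below 1.
#' @param receptor_residues number of single-atom pseudo-residues in the
#'   synthetic receptor chain.
#' @param planted_contacts receptor residue numbers planted as contacts.
#' @param cutoff interface distance cutoff in Angstrom.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_peptides = 20L,
                           length_range = c(30L, 60L),
                           target_hpp = 49,
                           n_annotated = 81L,
                           n_planted = 28L,
                           planted_odds_range = c(1.1, 10),
                           background_odds_range = c(0.05, 0.9),
                           receptor_residues = 30L,
                           planted_contacts = c(3L, 7L, 9L),
                           cutoff = 5.0) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_peptides >= 0, n_annotated >= 0, n_planted >= 0,
            n_planted <= n_annotated,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            length(cutoff) == 1, cutoff > 0, receptor_residues >= 0)
  if (!identical(target_hpp, "random")) {
    stopifnot(is.numeric(target_hpp), length(target_hpp) == 1,
              target_hpp >= 0)
  }
  stopifnot(planted_odds_range[1] > 1,
            planted_odds_range[1] <= planted_odds_range[2],
            background_odds_range[2] < 1,
            background_odds_range[1] >= 0,
            background_odds_range[1] <= background_odds_range[2])
  if (length(planted_contacts) > 0 &&
      (any(planted_contacts < 1) || any(planted_contacts > receptor_residues))) {
    stop("planted_contacts must lie within 1..receptor_residues")
  }
  structure(list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 target_hpp = target_hpp,
                 n_annotated = as.integer(n_annotated),
                 n_planted = as.integer(n_planted),
                 planted_odds_range = planted_odds_range,
                 background_odds_range = background_odds_range,
                 receptor_residues = as.integer(receptor_residues),
                 planted_contacts = as.integer(sort(unique(planted_contacts))),
                 cutoff = cutoff),
            class = "synthetic_spec")
}

#' Generate peptides with controlled hydrophobic percentage
#'
#' Each sequence of length `len` carries exactly
#' `round_half_up(len * target_hpp / 100)` residues drawn uniformly from
#' [HYDROPHOBIC_RESIDUES] and the rest from the 11 non-hydrophobic letters,
#' uniformly shuffled. Output is deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param id_prefix prefix for generated sequence ids.
#' @return list with `records` (peptide record data frame) and `truth`
#'   (planted per-sequence length/count/HPP table).
#' @export
generate_peptides <- function(spec, id_prefix = "syn") {
  stopifnot(inherits(spec, "synthetic_spec"))
  nonhydro <- setdiff(AMINO_ACIDS, HYDROPHOBIC_RESIDUES)
  with_seed(spec$seed, {
    len_pool <- seq(spec$length_range[1], spec$length_range[2])
    lens <- len_pool[sample.int(length(len_pool), spec$n_peptides,
                                replace = TRUE)]
    targets <- if (identical(spec$target_hpp, "random")) {
      stats::runif(spec$n_peptides, 0, 100)
    } else {
      rep(spec$target_hpp, spec$n_peptides)
    }
    n_h <- as.integer(round_half_up(lens * targets / 100))
    if (any(n_h > lens)) {
      stop("target HPP unachievable for generated lengths")
    }
    seqs <- vapply(seq_len(spec$n_peptides), function(i) {
      res <- c(sample(HYDROPHOBIC_RESIDUES, n_h[i], replace = TRUE),
               sample(nonhydro, lens[i] - n_h[i], replace = TRUE))
      paste(sample(res), collapse = "")
    }, character(1))
    ids <- sprintf("%s%03d", id_prefix, seq_len(spec$n_peptides))
    list(
      records = data.frame(seq_id = ids, bagel_id = NA_character_,
                           species = "synthetic", sequence = seqs,
                           stringsAsFactors = FALSE),
      truth = data.frame(seq_id = ids, length = lens,
                         hydrophobic_count = n_h,
                         hpp = as.integer(round_half_up(100 * n_h / lens)),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate an annotation table with a planted azurin-like subset
#'
#' Planted ids draw all three category odds from the planted range (above
#' 1, so the odds product is guaranteed above 1); background ids draw from
#' the background range (below 1, product below 1). Probabilities are the
#' odds scaled by a constant per-group prior, making the probability score
#' exactly collinear with the odds score. Optionally adds control rows with
#' the stated control odds so that [reference_categories()] works on the
#' generated table.
#'
#' @param spec a [synthetic_spec()].
#' @param ids annotated sequence ids; defaults to `seq001..`.
#' @param planted_ids ids to plant; defaults to a seeded random subset of
#'   size `spec$n_planted`.
#' @param control_id optional control id to include (e.g. `"azurin"`).
#' @param control_odds named odds for the control's three reference
#'   categories, in groups F, EZ, GO.
#' @return list with `annotations` (an `annotation_set`) and `planted_ids`.
#' @export
generate_annotation_table <- function(spec, ids = NULL, planted_ids = NULL,
                                      control_id = NULL,
                                      control_odds = c(F = 9.71, EZ = 1.147,
                                                       GO = 5.877)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(ids)) {
    ids <- sprintf("seq%03d", seq_len(spec$n_annotated))
  }
  stopifnot(spec$n_planted <= length(ids))
  categories <- c(F = "Cell_envelope", EZ = "Nonenzyme",
                  GO = "Immune_response")
  max_odds <- max(spec$planted_odds_range[2], control_odds, 1)
  priors <- pmin(c(F = 0.08, EZ = 0.05, GO = 0.03), 0.999 / max_odds)
  with_seed(spec$seed, {
    if (is.null(planted_ids)) {
      planted_ids <- sort(sample(ids, spec$n_planted))
    }
    stopifnot(all(planted_ids %in% ids))
    n <- length(ids)
    planted <- ids %in% planted_ids
    rows <- lapply(names(categories), function(g) {
      odds <- ifelse(planted,
                     stats::runif(n, spec$planted_odds_range[1],
                                  spec$planted_odds_range[2]),
                     stats::runif(n, spec$background_odds_range[1],
                                  spec$background_odds_range[2]))
      data.frame(seq_id = ids, group = g, category = categories[[g]],
                 probability = odds * priors[[g]], odds = odds,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    if (!is.null(control_id)) {
      ctl <- data.frame(seq_id = control_id, group = names(categories),
                        category = unname(categories[names(categories)]),
                        probability = unname(control_odds[names(categories)]) *
                          unname(priors[names(categories)]),
                        odds = unname(control_odds[names(categories)]),
                        stringsAsFactors = FALSE)
      ann <- rbind(ann, ctl)
    }
    ann <- ann[order(match(ann$seq_id, c(control_id, ids)), ann$group), ]
    rownames(ann) <- NULL
    validate_annotations(ann)
    class(ann) <- c("annotation_set", class(ann))
    list(annotations = ann, planted_ids = planted_ids)
  })
}

#' Write an annotation set as TSV
#'
#' @param annotations an annotation set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  validate_annotations(annotations)
  write_tsv(as.data.frame(annotations)[.ANNOTATION_COLUMNS], path)
}

#' Generate a two-chain pseudo-complex with a planted interface
#'
#' The receptor (chain A) is a linear array of single-atom pseudo-residues
#' spaced `2.5 * cutoff` apart, so no two receptor atoms can bridge a
#' contact. For each planted contact residue one ligand (chain B) atom is
#' placed at `cutoff - 0.5` Angstrom from the residue's atom; decoy ligand
#' atoms sit at `3 * cutoff` from every receptor atom. Elements are
#' assigned to realize a requested polar/nonpolar interface composition
#' (polar atoms are nitrogen, nonpolar carbon). With
#' `atoms_per_residue > 1`, extra atoms are clustered within 0.4 Angstrom
#' of each base atom, which stresses the neighbor search without changing
#' the planted residue-level ground truth.
#'
#' @param spec a [synthetic_spec()]; uses `receptor_residues`,
#'   `planted_contacts` and `cutoff`.
#' @param path optional path; when given, the complex is also written as a
#'   PDB file there.
#' @param ligand_polar number of planted ligand contact atoms assigned a
#'   polar element; defaults to half, rounded up.
#' @param receptor_polar number of planted receptor contact atoms assigned
#'   a polar element (default 0: all carbon).
#' @param n_decoys number of far-away decoy ligand atoms.
#' @param atoms_per_residue atoms per pseudo-residue (default 1).
#' @return list with `model` (a [complex_model()]), `truth` (planted
#'   receptor/ligand interface residue ids and the planted ligand
#'   composition) and `path` (NULL unless written).
#' @export
generate_complex <- function(spec, path = NULL, ligand_polar = NULL,
                             receptor_polar = 0L, n_decoys = 5L,
                             atoms_per_residue = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  contacts <- spec$planted_contacts
  if (length(contacts) == 0) {
    stop("planted contact set is empty")
  }
  cutoff <- spec$cutoff
  nres <- spec$receptor_residues
  k <- length(contacts)
  if (is.null(ligand_polar)) {
    ligand_polar <- ceiling(k / 2)
  }
  stopifnot(ligand_polar >= 0, ligand_polar <= k,
            receptor_polar >= 0, receptor_polar <= k,
            atoms_per_residue >= 1)
  spacing <- 2.5 * cutoff
  # receptor: residue r at x = (r - 1) * spacing on the x axis
  rec_elem <- rep("C", nres)
  rec_elem[contacts[seq_len(receptor_polar)]] <- "N"
  rec <- data.frame(chain = "A", resno = seq_len(nres), insert = NA_character_,
                    resid = "GLY", elety = rec_elem, element = rec_elem,
                    x = (seq_len(nres) - 1) * spacing, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  # ligand: one contact atom per planted residue at cutoff - 0.5, then decoys
  lig_elem <- c(rep("N", ligand_polar), rep("C", k - ligand_polar))
  lig <- data.frame(chain = "B", resno = seq_len(k), insert = NA_character_,
                    resid = "GLY", elety = lig_elem, element = lig_elem,
                    x = (contacts - 1) * spacing, y = cutoff - 0.5, z = 0,
                    stringsAsFactors = FALSE)
  if (cutoff <= 0.5) {
    stop("cutoff too small to place planted contacts inside the margin")
  }
  if (n_decoys > 0) {
    dec <- data.frame(chain = "B", resno = k + seq_len(n_decoys),
                      insert = NA_character_, resid = "GLY", elety = "C",
                      element = "C",
                      x = (seq_len(n_decoys) - 1) * spacing, y = 3 * cutoff,
                      z = 0, stringsAsFactors = FALSE)
    lig <- rbind(lig, dec)
  }
  atoms <- rbind(rec, lig)
  if (atoms_per_residue > 1) {
    extra <- do.call(rbind, lapply(seq_len(atoms_per_residue - 1), function(e) {
      a <- atoms
      a$z <- a$z + 0.4 * e / (atoms_per_residue - 1)
      a
    }))
    atoms <- rbind(atoms, extra)
    atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  }
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  model <- complex_model(atoms, receptor_chain = "A", ligand_chain = "B")
  if (!is.null(path)) {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resno, resid = atoms$resid,
                     chain = atoms$chain, eleno = atoms$eleno,
                     elety = atoms$elety, elesy = atoms$element,
                     o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))
  }
  truth <- list(
    receptor_interface = sprintf("A:%d", contacts),
    ligand_interface = sprintf("B:%d", seq_len(k)),
    ligand_polar = as.integer(ligand_polar),
    ligand_nonpolar = as.integer(k - ligand_polar)
  )
  list(model = model, truth = truth, path = path)
}
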