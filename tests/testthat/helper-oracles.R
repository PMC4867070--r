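# Independent oracles and small builders shared across the suite.

# per-residue membership loop, deliberately naive
oracle_hydrophobic_count <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- 0L
  for (ch in chars) {
    if (ch %in% HYDROPHOBIC_RESIDUES) n <- n + 1L
  }
  n
}

# brute-force all-pairs interface: full distance matrix via outer()
oracle_interface <- function(model, cutoff) {
  at <- model$atoms[!(model$atoms$element %in% c("H", "D")), ]
  rec <- at[at$chain == model$receptor_chain, ]
  lig <- at[at$chain == model$ligand_chain, ]
  dx <- outer(rec$x, lig$x, "-")
  dy <- outer(rec$y, lig$y, "-")
  dz <- outer(rec$z, lig$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  rid <- function(a) sprintf("%s:%d%s", a$chain, a$resno,
                             ifelse(is.na(a$insert), "", a$insert))
  list(receptor_residues = sort(unique(rid(rec[hit[, 1], , drop = FALSE]))),
       ligand_residues = sort(unique(rid(lig[hit[, 2], , drop = FALSE]))),
       n_pairs = nrow(hit))
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random two-chain complex with atoms scattered in a cubic box
random_complex_model <- function(n_rec, n_lig, box = 20, seed = 1) {
  set.seed(seed)
  n <- n_rec + n_lig
  atoms <- data.frame(
    chain = rep(c("A", "B"), c(n_rec, n_lig)),
    resno = c(rep(seq_len(ceiling(n_rec / 4)), each = 4)[seq_len(n_rec)],
              rep(seq_len(ceiling(n_lig / 4)), each = 4)[seq_len(n_lig)]),
    insert = NA_character_,
    resid = "GLY",
    elety = "X",
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    eleno = seq_len(n),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    stringsAsFactors = FALSE)
  atoms$elety <- atoms$element
  complex_model(atoms, "A", "B")
}

# random peptide record set over the standard alphabet
random_records <- function(n, len_range = c(5, 80), seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(AMINO_ACIDS, len, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(seq_id = sprintf("r%04d", seq_len(n)), sequence = seqs,
             stringsAsFactors = FALSE)
}

# minimal annotation set built in code: one row per group per id
make_annotations <- function(ids, odds_by_id, prob_by_id = NULL) {
  cats <- c(F = "Cell_envelope", EZ = "Nonenzyme", GO = "Immune_response")
  rows <- lapply(seq_along(ids), function(i) {
    odds <- odds_by_id[[i]]
    prob <- if (is.null(prob_by_id)) pmin(odds * 0.05, 1) else prob_by_id[[i]]
    data.frame(seq_id = ids[i], group = names(cats), category = unname(cats),
               probability = prob, odds = odds, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
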