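test_that("PDB complexes round-trip through write and read", {
  spec <- synthetic_spec(seed = 1, receptor_residues = 10,
                         planted_contacts = c(2, 5), cutoff = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  gen <- generate_complex(spec, path = path, n_decoys = 3)
  m <- read_complex_pdb(path, "A", "B")
  expect_s3_class(m, "complex_model")
  expect_equal(nrow(m$atoms), nrow(gen$model$atoms))
  expect_equal(sum(m$atoms$chain == "A"), 10)
  expect_equal(sum(m$atoms$chain == "B"), 5)   # 2 contacts + 3 decoys
  expect_equal(m$atoms$x, gen$model$atoms$x, tolerance = 1e-3)
  expect_equal(m$atoms$element, gen$model$atoms$element)

  expect_error(read_complex_pdb(path, "A", "Z"), "chain 'Z' not found")
  expect_error(read_complex_pdb(tempfile(), "A", "B"), "not found")
})

test_that("multi-model PDB files contribute first-model atoms only", {
  spec <- synthetic_spec(seed = 1, receptor_residues = 6,
                         planted_contacts = 3, cutoff = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  generate_complex(spec, path = path, n_decoys = 2)
  atom_lines <- grep("^ATOM", readLines(path), value = TRUE)
  mm <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", atom_lines, "ENDMDL",
               "MODEL     2", atom_lines, "ENDMDL", "END"), mm)
  m <- read_complex_pdb(mm, "A", "B")
  expect_equal(nrow(m$atoms), length(atom_lines))
})

test_that("alternate locations resolve to the highest-occupancy record", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  N1  GLY B   1       9.000   4.000   0.000  1.00  0.00           N",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  m <- read_complex_pdb(path, "A", "B")
  expect_equal(sum(m$atoms$chain == "A"), 1)
  expect_equal(m$atoms$x[m$atoms$chain == "A"], 9)  # occupancy 0.60 wins
  iface <- compute_interface(m, cutoff = 5)
  expect_equal(iface$receptor_residues, "A:1")
})

test_that("planted contacts are recovered exactly and margins behave", {
  spec <- synthetic_spec(seed = 2, receptor_residues = 12,
                         planted_contacts = c(3, 7, 9), cutoff = 5)
  gen <- generate_complex(spec, n_decoys = 4)
  iface <- compute_interface(gen$model, cutoff = 5)
  expect_setequal(iface$receptor_residues, c("A:3", "A:7", "A:9"))
  expect_setequal(iface$receptor_residues, gen$truth$receptor_interface)
  expect_setequal(iface$ligand_residues, gen$truth$ligand_interface)

  # contacts sit at cutoff - 0.5: shrinking the cutoff below that excludes
  # them, and decoys at 3x cutoff never enter at slightly larger cutoffs
  expect_equal(length(compute_interface(gen$model, 4.4)$receptor_residues), 0)
  wide <- compute_interface(gen$model, 5.6)
  expect_setequal(wide$receptor_residues, gen$truth$receptor_interface)
})

test_that("interface boundary is inclusive and distant ligands give empty interfaces", {
  atoms <- data.frame(chain = c("A", "B"), resno = 1L, insert = NA_character_,
                      resid = "GLY", elety = "C", element = "C",
                      eleno = 1:2, x = c(0, 5), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  m <- complex_model(atoms, "A", "B")
  at_cutoff <- compute_interface(m, cutoff = 5)
  expect_equal(nrow(at_cutoff$contact_pairs), 1)
  expect_equal(at_cutoff$contact_pairs$distance, 5)

  far <- m
  far$atoms$x[2] <- 105
  expect_equal(nrow(compute_interface(far, 5)$contact_pairs), 0)
  empty <- compute_interface(far, 5)
  expect_length(empty$receptor_residues, 0)
  expect_length(empty$ligand_residues, 0)
})

test_that("interface detection equals the brute-force all-pairs oracle on random complexes", {
  for (i in 1:100) {
    m <- random_complex_model(n_rec = 70, n_lig = 50, box = 18, seed = i)
    got <- compute_interface(m, cutoff = 5)
    want <- oracle_interface(m, cutoff = 5)
    expect_identical(got$receptor_residues, want$receptor_residues)
    expect_identical(got$ligand_residues, want$ligand_residues)
    expect_identical(nrow(got$contact_pairs), want$n_pairs)
  }
})

test_that("interfaces are invariant under rigid motion", {
  m <- random_complex_model(n_rec = 60, n_lig = 40, box = 15, seed = 33)
  before <- compute_interface(m, cutoff = 5)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m$atoms$x <- xyz[, 1] + 100
  m$atoms$y <- xyz[, 2] - 50
  m$atoms$z <- xyz[, 3] + 7
  after <- compute_interface(m, cutoff = 5)
  expect_identical(after$receptor_residues, before$receptor_residues)
  expect_identical(after$ligand_residues, before$ligand_residues)
  expect_equal(after$contact_pairs$distance, before$contact_pairs$distance,
               tolerance = 1e-9)
})

test_that("interface residues are exactly the owners of contact-pair atoms", {
  m <- random_complex_model(n_rec = 80, n_lig = 60, box = 16, seed = 8)
  iface <- compute_interface(m, cutoff = 5)
  rid <- function(serials) {
    a <- m$atoms[match(unique(serials), m$atoms$eleno), ]
    sort(unique(sprintf("%s:%d%s", a$chain, a$resno,
                        ifelse(is.na(a$insert), "", a$insert))))
  }
  expect_identical(iface$receptor_residues,
                   rid(iface$contact_pairs$receptor_atom))
  expect_identical(iface$ligand_residues,
                   rid(iface$contact_pairs$ligand_atom))
})

test_that("atom polarity follows the element rule and refuses hydrogens", {
  expect_equal(atom_polarity(c("O", "N")), c("polar", "polar"))
  expect_equal(atom_polarity(c("C", "S")), c("nonpolar", "nonpolar"))
  expect_error(atom_polarity("H"), "heavy atoms only")
  expect_warning(pol <- atom_polarity("SE"), "classed polar")
  expect_equal(pol, "polar")
})

test_that("interface composition counts unique interface atoms per side", {
  spec <- synthetic_spec(seed = 4, receptor_residues = 8,
                         planted_contacts = c(1, 2, 3, 4), cutoff = 5)
  gen <- generate_complex(spec, ligand_polar = 3)
  iface <- compute_interface(gen$model, 5)
  comp <- interface_composition(iface, gen$model)
  lig <- comp[comp$side == "ligand", ]
  expect_equal(lig$polar_percent, 75)
  expect_equal(lig$nonpolar_percent, 25)
  expect_equal(comp$polar_percent + comp$nonpolar_percent, c(100, 100),
               tolerance = 0.011)

  all_polar <- generate_complex(spec, ligand_polar = 4, receptor_polar = 4)
  cp <- interface_composition(compute_interface(all_polar$model, 5),
                              all_polar$model)
  expect_equal(cp$polar_percent, c(100, 100))
  expect_equal(cp$nonpolar_percent, c(0, 0))

  far <- gen$model
  far$atoms$y[far$atoms$chain == "B"] <- 1000
  expect_error(interface_composition(compute_interface(far, 5), far),
               "empty")
})

test_that("composition equals an independent element recount on random complexes", {
  for (seed in c(3, 14, 25)) {
    m <- random_complex_model(n_rec = 60, n_lig = 50, box = 14, seed = seed)
    iface <- compute_interface(m, 5)
    if (nrow(iface$contact_pairs) == 0) next
    comp <- interface_composition(iface, m)
    recount <- function(serials) {
      elem <- m$atoms$element[match(unique(serials), m$atoms$eleno)]
      100 * sum(elem %in% c("N", "O")) / length(elem)
    }
    expect_equal(comp$polar_percent[comp$side == "ligand"],
                 round_half_up(recount(iface$contact_pairs$ligand_atom), 2))
    expect_equal(comp$polar_percent[comp$side == "receptor"],
                 round_half_up(recount(iface$contact_pairs$receptor_atom), 2))
  }
})

test_that("overlap against a reference interface follows set arithmetic", {
  x <- sprintf("A:%d", 1:12)
  self <- overlap_with_reference(x, x)
  expect_equal(self$overlap_percent, 100)
  expect_equal(overlap_with_reference(sprintf("A:%d", 20:25), x)$shared_count, 0)
  expect_error(overlap_with_reference(x, character(0)), "empty")

  # monotone: adding query residues never decreases the shared count
  ref <- sprintf("A:%d", 1:25)
  q <- character(0)
  last <- 0
  for (r in sample(sprintf("A:%d", 1:40))) {
    q <- c(q, r)
    s <- overlap_with_reference(q, ref)$shared_count
    expect_gte(s, last)
    last <- s
  }
})

test_that("reference interface sizes are recovered by the consistency oracle", {
  tab2 <- table2_interfaces()
  expect_equal(infer_reference_size(tab2$shared_p28, tab2$pct_p28), 30)
  expect_equal(infer_reference_size(tab2$shared_azurin, tab2$pct_azurin), 25)
  expect_error(infer_reference_size(c(0, 0), c(0, 0)), "no informative")
})

test_that("published shared counts classify exactly the reported azurin-like rows", {
  tab2 <- table2_interfaces()
  ref_p28 <- sprintf("R:%d", seq_len(30))
  ref_az <- sprintf("R:%d", 30 + seq_len(25))
  got <- vapply(seq_len(nrow(tab2)), function(i) {
    q <- c(ref_p28[seq_len(tab2$shared_p28[i])],
           ref_az[seq_len(tab2$shared_azurin[i])])
    classify_azurin_like(overlap_with_reference(q, ref_p28),
                         overlap_with_reference(q, ref_az))
  }, logical(1))
  expect_equal(got, tab2$reported_selected)
  expect_equal(sum(got), 8)

  # one-sided sharing (the p2seq33 pattern) is not azurin-like
  q33 <- ref_az[1:4]
  o_p28 <- overlap_with_reference(q33, ref_p28)
  o_az <- overlap_with_reference(q33, ref_az)
  expect_equal(o_az$overlap_percent, 16)
  expect_false(classify_azurin_like(o_p28, o_az))
})

test_that("comparison reports keep the overlap invariants and round-trip as TSV", {
  spec <- function(contacts) synthetic_spec(seed = 6, receptor_residues = 40,
                                            planted_contacts = contacts,
                                            cutoff = 5)
  refs <- list(p28 = sprintf("A:%d", 1:10), azurin = sprintf("A:%d", 11:20))
  build <- function(contacts) {
    gen <- generate_complex(spec(contacts))
    iface <- compute_interface(gen$model, 5)
    if (nrow(iface$contact_pairs) == 0) {
      return(list(size = 30, composition = NULL))
    }
    list(size = 30,
         overlap_p28 = overlap_with_reference(iface, refs$p28),
         overlap_azurin = overlap_with_reference(iface, refs$azurin),
         composition = interface_composition(iface, gen$model))
  }
  cands <- list(both = build(c(1, 2, 12)), p28only = build(c(3, 4)),
                none = build(30))
  report <- comparison_report(cands)
  expect_equal(report$seq_id, c("both", "p28only", "none"))
  expect_equal(report$selected, c(TRUE, FALSE, FALSE))
  expect_equal(report$pct_p28,
               round_half_up(100 * report$shared_p28 / 10, 2))
  expect_equal(report$pct_azurin,
               round_half_up(100 * report$shared_azurin / 10, 2))

  # empty interface rows are all zeros
  far <- list(size = 12, composition = NULL)
  r0 <- comparison_report(list(empty = far))
  expect_equal(r0$shared_p28 + r0$shared_azurin, 0)
  expect_false(r0$selected)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_report(report, path)
  back <- read_comparison_report(path)
  expect_equal(back$seq_id, report$seq_id)
  expect_equal(back$selected, report$selected)
  for (cl in setdiff(names(report), c("seq_id", "selected"))) {
    expect_equal(as.numeric(back[[cl]]), as.numeric(report[[cl]]),
                 tolerance = 1e-9)
  }
})

test_that("reference interfaces round-trip through the residue TSV store", {
  res <- sprintf("A:%d", c(3, 7, 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interface_residues(res, path)
  expect_equal(read_interface_residues(path), res)
})
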