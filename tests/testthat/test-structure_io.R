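test_that("a minimal one-atom PDB record round-trips its coordinates", {
  line <- paste0("ATOM      1  CA  ALA A   1       1.250   2.500  -3.750",
                 "  1.00  0.00")
  conf <- read_conformer(line)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$x, 1.25)
  expect_equal(conf$y, 2.5)
  expect_equal(conf$z, -3.75)
  expect_equal(conf$chain, "A")
  expect_equal(conf$resid, "ALA")
})

test_that("write/read round-trip preserves coordinates at PDB precision", {
  pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "LYS")))
  f <- tempfile(fileext = ".pdb")
  write_conformer(pep$conformer, f)
  back <- read_conformer(f)
  expect_equal(back$x, round(pep$conformer$x, 3))
  expect_equal(back$elety, pep$conformer$elety)
  expect_equal(back$resno, pep$conformer$resno)
})

test_that("malformed and duplicate records are rejected with context", {
  good <- paste0("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
                 "  1.00  0.00")
  bad <- paste0("ATOM      2  CB  ALA A   1       x.yz@   2.000   3.000",
                "  1.00  0.00")
  expect_error(read_conformer(c(good, bad)), "line 2")
  expect_error(read_conformer(c(good, good)), "duplicate atom")
})

test_that("repeated atom serials across chains are accepted", {
  l1 <- paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
               "  1.00  0.00")
  l2 <- paste0("ATOM      1  CA  ALA B   1       5.000   0.000   0.000",
               "  1.00  0.00")
  conf <- read_conformer(c(l1, l2))
  expect_equal(nrow(conf), 2)
})

test_that("the leucine-zipper-like 33-residue chain yields 16 sites", {
  pep <- make_toy_peptide(toy_spec(residues = gcn4_like_residues()))
  sites <- detect_sites(pep$conformer)
  expect_length(sites, 16)
  classes <- table(vapply(sites, `[[`, character(1), "site_class"))
  expect_equal(unname(classes[["carboxyl"]]), 7)  # 6 Glu + 1 Asp
  expect_equal(unname(classes[["amino"]]), 5)
  expect_equal(unname(classes[["imidazole"]]), 1)
  expect_equal(unname(classes[["hydroxyl"]]), 1)
  expect_equal(unname(classes[["n_terminus"]]), 1)
  expect_equal(unname(classes[["c_terminus"]]), 1)
})

test_that("polyalanine has only the two terminal sites", {
  pep <- make_toy_peptide(toy_spec(residues = rep("ALA", 5)))
  sites <- detect_sites(pep$conformer)
  expect_length(sites, 2)
  expect_setequal(vapply(sites, `[[`, character(1), "site_class"),
                  c("n_terminus", "c_terminus"))
  expect_length(detect_sites(pep$conformer, termini_policy = "none"), 0)
})

test_that("model pK values follow the standard per-class table", {
  pep <- make_toy_peptide(toy_spec(residues = c(
    "GLU", "ASP", "LYS", "TYR", "HIS", "ALA")))
  sites <- detect_sites(pep$conformer)
  pk <- null_model(sites)
  expect_equal(unname(pk[grep("GLU1$", names(pk))]), 4.4)
  expect_equal(unname(pk[grep("ASP2$", names(pk))]), 4.0)
  expect_equal(unname(pk[grep("LYS3$", names(pk))]), 10.4)
  expect_equal(unname(pk[grep("TYR4$", names(pk))]), 9.6)
  expect_equal(unname(pk[grep("HIS5$", names(pk))]), 6.4)
  expect_equal(unname(pk[grep(":NT$", names(pk))]), 7.5)
  expect_equal(unname(pk[grep(":CT$", names(pk))]), 3.8)
})

test_that("unknown residue names warn and are skipped, never silent", {
  pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "ALA")))
  conf <- pep$conformer
  conf$resid[conf$resno == 2] <- "XYZ"
  expect_warning(sites <- detect_sites(conf), "unknown residue")
  expect_length(sites, 2)  # termini only
})

test_that("assigned charges give zero net charge per neutral residue", {
  pep <- make_toy_peptide(toy_spec(residues = gcn4_like_residues()))
  net <- residue_net_charge(pep$conformer)
  expect_true(all(abs(net$net_charge) < 1e-6))
})

test_that("microstate charge sets carry the correct formal charges", {
  pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "ALA")))
  sites <- detect_sites(pep$conformer, termini_policy = "none")
  glu <- sites[[1]]
  sums <- vapply(glu$microstates, function(m) sum(m$charges), numeric(1))
  expect_equal(sums[[1]], 0)    # neutral reference
  expect_equal(sums[[2]], -1)   # deprotonated carboxylate
})

test_that("unresolvable atoms raise an error naming residue and atom", {
  pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU")))
  conf <- pep$conformer
  conf$elety[5] <- "QQ1"
  conf$charge <- conf$radius <- NULL
  expect_error(assign_parameters(conf), "QQ1")
})

test_that("parameter table round-trips through write/read identically", {
  pt <- read_parameter_table()
  f <- tempfile(fileext = ".tsv")
  write_parameter_table(pt, f)
  back <- read_parameter_table(f)
  expect_equal(back, pt)
})

test_that("regime overlays give the implied integer total charge", {
  pep <- make_toy_peptide(toy_spec(residues = c("GLU", "ALA", "LYS")))
  sites <- detect_sites(pep$conformer)
  for (reg in c("allC", "glu0", "lys0")) {
    conf <- apply_protonation(pep$conformer, sites, reg)
    expect_equal(sum(conf$charge), attr(conf, "formal_charge"),
                 tolerance = 1e-6)
  }
  ## allC: NT+1, Glu-1, Lys+1, CT-1 -> 0; glu0: +1; lys0: -1
  expect_equal(attr(apply_protonation(pep$conformer, sites, "allC"),
                    "formal_charge"), 0L)
  expect_equal(attr(apply_protonation(pep$conformer, sites, "glu0"),
                    "formal_charge"), 1L)
  expect_equal(attr(apply_protonation(pep$conformer, sites, "lys0"),
                    "formal_charge"), -1L)
})

test_that("site detection is idempotent and stable across an ensemble", {
  spec <- toy_spec(residues = c("GLU", "ALA", "LYS"), n_conformers = 3,
                   jitter_sd = 0.4, seed = 3)
  ens <- make_fixture_ensemble(spec)
  labels <- lapply(ens$conformers, function(cf)
    vapply(detect_sites(cf), `[[`, character(1), "label"))
  expect_equal(labels[[2]], labels[[1]])
  expect_equal(labels[[3]], labels[[1]])
  expect_equal(vapply(detect_sites(ens$conformers[[1]]), `[[`,
                      character(1), "label"), labels[[1]])
})

test_that("multi-model PDB files read as ensembles", {
  spec <- toy_spec(residues = c("ALA", "GLU"), n_conformers = 3,
                   jitter_sd = 0.2, seed = 9)
  ens <- make_fixture_ensemble(spec)
  d <- tempfile()
  dir.create(d)
  paths <- vapply(seq_along(ens$conformers), function(m) {
    f <- file.path(d, sprintf("snap%d.pdb", m))
    write_conformer(ens$conformers[[m]], f)
    f
  }, character(1))
  back <- read_ensemble(paths, regime = "allC")
  expect_equal(back$regime, "allC")
  expect_length(back$conformers, 3)
  expect_equal(back$conformers[[2]]$x,
               round(ens$conformers[[2]]$x, 3))
})
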