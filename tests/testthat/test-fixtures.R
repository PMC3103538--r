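test_that("a Glu/Lys toy system exposes the expected sites", {
  ## one chain carrying Glu and Lys: 2 side-chain sites + both termini
  pep <- make_toy_peptide(toy_spec(residues = c("GLU", "LYS")))
  sites <- detect_sites(pep$conformer)
  expect_length(sites, 4)
  expect_setequal(vapply(sites, `[[`, character(1), "site_class"),
                  c("n_terminus", "carboxyl", "amino", "c_terminus"))
})

test_that("the bridge fixture places donor and acceptor at the set distance", {
  spec <- bridge_spec(d_bridge = 3.0)
  conf <- make_toy_peptide(spec)$conformer
  oe2 <- unlist(conf[conf$elety == "OE2" & conf$chain == "A",
                     c("x", "y", "z")])
  nz <- unlist(conf[conf$elety == "NZ" & conf$chain == "B",
                    c("x", "y", "z")])
  expect_equal(sqrt(sum((oe2 - nz)^2)), 3.0, tolerance = 1e-9)
})

test_that("fixture generation is deterministic given the seed", {
  spec <- toy_spec(residues = c("GLU", "ALA"), n_conformers = 2,
                   jitter_sd = 0.3, seed = 77)
  e1 <- make_regime_ensembles(spec)
  e2 <- make_regime_ensembles(spec)
  f1 <- tempfile(); f2 <- tempfile()
  write_conformer(e1$glu0$conformers[[2]], f1)
  write_conformer(e2$glu0$conformers[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))  # identical PDB bytes
  expect_false(identical(e1$allC$conformers[[1]]$x,
                         e1$allC$conformers[[2]]$x))  # jitter is applied
})

test_that("mirrored dimers are exact symmetry copies", {
  spec <- toy_spec(residues = c("GLU", "ALA"), mirror = TRUE,
                   mirror_plane = 9, n_conformers = 2, jitter_sd = 0.4,
                   seed = 12)
  ens <- make_fixture_ensemble(spec)
  for (cf in ens$conformers) {
    a <- cf[cf$chain == "A", ]
    b <- cf[cf$chain == "B", ]
    expect_equal(b$x, 2 * 9 - a$x, tolerance = 1e-12)
    expect_equal(b$y, a$y, tolerance = 1e-12)
    expect_equal(b$z, a$z, tolerance = 1e-12)
  }
})

test_that("zero jitter collapses the ensemble onto one conformer", {
  spec <- toy_spec(residues = c("ALA", "GLU"), n_conformers = 3,
                   jitter_sd = 0, seed = 1)
  ens <- make_fixture_ensemble(spec)
  expect_equal(ens$conformers[[2]]$x, ens$conformers[[1]]$x)
  expect_equal(ens$conformers[[3]]$z, ens$conformers[[1]]$z)
})

test_that("the default ensemble size mirrors the 50 ps/14 ns cadence", {
  expect_equal(toy_spec()$n_conformers, 280)
})

test_that("the glu0 bias displaces only the flagged chain in glu0", {
  spec <- bridge_spec(d_bridge = 2.9, d_broken = 8, n_conformers = 1,
                      jitter_sd = 0, seed = 1)
  ens <- make_regime_ensembles(spec)
  dist_nz_oe2 <- function(cf) {
    oe2 <- unlist(cf[cf$elety == "OE2", c("x", "y", "z")])
    nz <- unlist(cf[cf$elety == "NZ", c("x", "y", "z")])
    sqrt(sum((oe2 - nz)^2))
  }
  expect_equal(dist_nz_oe2(ens$allC$conformers[[1]]), 2.9,
               tolerance = 1e-9)
  expect_equal(dist_nz_oe2(ens$lys0$conformers[[1]]), 2.9,
               tolerance = 1e-9)
  expect_equal(dist_nz_oe2(ens$glu0$conformers[[1]]), 8, tolerance = 1e-9)
})

test_that("prescribed zero-interaction energy tables return pk_mod", {
  et <- make_energy_table(c("carboxyl", "amino", "imidazole"),
                          c(4.4, 10.4, 6.4), W = 0)
  pops <- populations_exact(et)
  for (i in 1:3) {
    cv <- protonated_fraction(pops, i)
    expect_equal(as.numeric(pk_half(cv)), c(4.4, 10.4, 6.4)[i],
                 tolerance = 0.005)
  }
})

test_that("infeasible fixture geometry (chain clash) is refused", {
  spec <- toy_spec(chains = list(
    list(name = "A", residues = "ALA", translate = c(0, 0, 0)),
    list(name = "B", residues = "ALA", translate = c(0.5, 0, 0))))
  expect_error(make_toy_peptide(spec), "infeasible")
})
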