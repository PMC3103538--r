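test_that("zero charges give an identically zero potential", {
  cfg <- fast_pb()
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  maps <- build_maps(atoms, data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0), q = numeric(0)),
                     cfg)
  phi <- solve_lpb(maps)
  expect_true(all(phi == 0))
})

test_that("trilinear charge spreading conserves charge and is exact", {
  grid <- multipk:::.make_grid(c(0, 0, 0), c(10, 10, 10), 1)
  ## exact node hit
  rho <- multipk:::.spread_charges(grid, matrix(c(0, 0, 0), 1), 1)
  expect_equal(sum(rho), 1)
  expect_equal(max(rho), 1)
  expect_equal(sum(rho > 0), 1)
  ## cell centre: eight nodes carry 0.125 e each
  rho <- multipk:::.spread_charges(grid, matrix(c(0.5, 0.5, 0.5), 1), 1)
  expect_equal(sum(rho), 1)
  expect_equal(sort(unique(round(rho[rho > 0], 12))), 0.125)
  expect_equal(sum(rho > 0), 8)
})

test_that("a single atom defines the protein dielectric region", {
  cfg <- pb_config(grid_spacing_fine = 0.5)
  grid <- multipk:::.make_grid(c(0, 0, 0), c(10, 10, 10), 0.5)
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  maps <- build_maps(atoms, data.frame(x = 0, y = 0, z = 0, q = 1), cfg,
                     grid = grid)
  ex <- array(maps$ex, grid$dims)
  dims <- grid$dims
  ic <- (dims[1] + 1) / 2
  ## links wholly inside the sphere: protein dielectric
  expect_equal(ex[ic, ic, ic], cfg$eps_protein)
  expect_equal(ex[ic - 2, ic, ic], cfg$eps_protein)
  ## links far outside: solvent dielectric
  expect_equal(ex[2, 2, 2], cfg$eps_solvent)
})

test_that("two point charges in uniform solvent match the Coulomb oracle", {
  cfg <- pb_config(ionic_strength = 0, grid_spacing_fine = 0.4,
                   grid_padding = 12, fine_padding = 6)
  ch1 <- data.frame(x = 0, y = 0, z = 0, q = 1)
  sol <- solve_system(data.frame(), ch1, cfg)
  E <- 1 * potential_at(sol, matrix(c(5, 0, 0), 1))
  E_exact <- 332.0637 / (78 * 5)
  expect_lt(abs(E - E_exact) / E_exact, 0.02)
})

test_that("the Born ion matches the closed form and refines monotonically", {
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  chg <- data.frame(x = 0, y = 0, z = 0, q = 1)
  G_exact <- -0.5 * 332.0637 * (1 / 4 - 1 / 78) / 2
  errs <- vapply(c(0.8, 0.6, 0.4), function(hf) {
    cfg <- pb_config(ionic_strength = 0, grid_spacing_fine = hf,
                     grid_padding = 12, fine_padding = 6)
    G <- reaction_field_energy(atoms, chg, cfg)
    abs(G - G_exact) / abs(G_exact)
  }, numeric(1))
  expect_lt(errs[3], 0.03)                 # within 3% at fine spacing
  expect_true(all(diff(errs) < 0))         # monotone refinement
})

test_that("solvation energies are invariant under rigid translation", {
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  chg <- data.frame(x = 0, y = 0, z = 0, q = 1)
  cfg <- pb_config(ionic_strength = 0, grid_spacing_fine = 0.4,
                   grid_padding = 10, fine_padding = 5)
  g1 <- reaction_field_energy(atoms, chg, cfg)
  sh <- c(0.23, -0.11, 0.37)   # off-node displacement
  atoms2 <- data.frame(x = sh[1], y = sh[2], z = sh[3], radius = 2)
  chg2 <- data.frame(x = sh[1], y = sh[2], z = sh[3], q = 1)
  g2 <- reaction_field_energy(atoms2, chg2, cfg)
  expect_lt(abs(g1 - g2) / abs(g1), 0.02)
})

test_that("non-convergence raises an error reporting the residual", {
  cfg <- fast_pb(maxit = 2)
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  maps <- build_maps(atoms, data.frame(x = 0, y = 0, z = 0, q = 1), cfg)
  expect_error(solve_lpb(maps), "did not converge")
})

test_that("a grid too small for the molecule is refused", {
  cfg <- fast_pb()
  grid <- multipk:::.make_grid(c(0, 0, 0), c(2, 2, 2), 1)
  atoms <- data.frame(x = c(0, 5), y = 0, z = 0, radius = 2)
  expect_error(build_maps(atoms, data.frame(x = 0, y = 0, z = 0, q = 1),
                          cfg, grid = grid), "too small")
})

test_that("an isolated model compound has pk_int equal to pk_mod", {
  pep <- make_toy_peptide(toy_spec(residues = "GLU"))
  conf <- pep$conformer
  sites <- detect_sites(conf, termini_policy = "none")
  frag <- conf[conf$elety %in% c("CB", "CG", "CD", "OE1", "OE2"), ]
  et <- site_energy_terms(frag, sites, fast_pb())
  row <- et$ms[!et$ms$reference, ]
  expect_equal(row$dpk_born, 0, tolerance = 1e-8)
  expect_equal(row$dpk_perm, 0, tolerance = 1e-8)
  expect_equal(row$pk_int, 4.4, tolerance = 1e-8)
})

test_that("site-site interaction matches the Coulomb oracle in near-uniform
           dielectric and W is symmetric", {
  ## Glu and Lys on one chain, ~9 A apart, protein dielectric set equal to
  ## solvent so the analytic Coulomb sum over charge differences applies
  spec <- toy_spec(chains = list(
    list(name = "A", residues = "GLU", translate = c(0, 0, 0)),
    list(name = "B", residues = "LYS", translate = c(0, 0, 14),
         zflip = TRUE)))
  conf <- make_toy_peptide(spec)$conformer
  sites <- detect_sites(conf, termini_policy = "none")
  cfg <- pb_config(eps_protein = 77.99, eps_solvent = 78,
                   ionic_strength = 0, grid_spacing_fine = 0.4,
                   grid_padding = 12, fine_padding = 6)
  et <- site_energy_terms(conf, sites, cfg)
  ## analytic Coulomb between the two charge-difference sets
  dq_of <- function(s) {
    ref <- which(vapply(s$microstates, `[[`, logical(1), "reference"))
    oth <- setdiff(seq_along(s$microstates), ref)
    s$microstates[[oth]]$charges - s$microstates[[ref]]$charges
  }
  idx1 <- multipk:::.site_atom_idx(conf, sites[[1]])
  idx2 <- multipk:::.site_atom_idx(conf, sites[[2]])
  dq1 <- dq_of(sites[[1]]); dq2 <- dq_of(sites[[2]])
  Wan <- 0
  for (a in seq_along(idx1)) for (b in seq_along(idx2)) {
    r <- sqrt(sum((unlist(conf[idx1[a], c("x", "y", "z")]) -
                   unlist(conf[idx2[b], c("x", "y", "z")]))^2))
    Wan <- Wan + 332.0637 * dq1[a] * dq2[b] / (78 * r)
  }
  Wnum <- et$W[which(!et$ms$reference & et$ms$site == 1),
               which(!et$ms$reference & et$ms$site == 2)]
  expect_lt(abs(Wnum - Wan) / abs(Wan), 0.05)
  expect_lt(et$W_max_asym, 0.02)
  expect_equal(et$W, t(et$W))           # symmetrised
  expect_true(all(diag(et$W) == 0))
})

test_that("burying a carboxyl site raises dpk_born (destabilised anion)", {
  pep <- make_toy_peptide(toy_spec(residues = "GLU"))
  conf <- pep$conformer
  sites <- detect_sites(conf, termini_policy = "none")
  ## low-dielectric cage: inflate the backbone N (not part of the model
  ## compound fragment) into a sphere engulfing the carboxyl group
  buried <- conf
  buried$radius[buried$elety == "N"] <- 7.5
  et_b <- site_energy_terms(buried, sites, fast_pb())
  expect_gt(et_b$ms$dpk_born[!et_b$ms$reference], 0)
})
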