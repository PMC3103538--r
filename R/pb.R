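## pb_electrostatics: finite-difference linearised Poisson-Boltzmann solver
## and per-conformer assembly of desolvation, permanent-charge and site-site
## interaction energies.

#' Poisson-Boltzmann configuration
#'
#' @param eps_protein relative dielectric of the protein interior (default 4)
#' @param eps_solvent relative dielectric of the solvent (default 78)
#' @param ionic_strength mol/L (default 0.14)
#' @param temperature K (default 298)
#' @param probe_radius solvent probe radius, Angstrom (default 1.4; used by
#'   the optional re-entrant surface correction)
#' @param ion_exclusion thickness of the ion exclusion (Stern) layer,
#'   Angstrom (default 2.0)
#' @param grid_spacing_coarse coarse focusing stage spacing, Angstrom
#' @param grid_spacing_fine fine stage spacing, Angstrom
#' @param grid_padding solvent margin around the molecule on the coarse
#'   grid, Angstrom
#' @param fine_padding margin on the fine (focused) grid, Angstrom
#' @param reentrant logical; apply the probe-rolled re-entrant correction to
#'   the dielectric boundary (default FALSE: the solute volume is the van
#'   der Waals union)
#' @param tol solver convergence threshold on the largest Gauss-Seidel
#'   update, kcal/mol/e
#' @param maxit maximum solver iterations
#' @param omega SOR over-relaxation factor (0 < omega < 2)
#' @return list of class \code{pb_config}
#' @export
pb_config <- function(eps_protein = 4, eps_solvent = 78,
                      ionic_strength = 0.14, temperature = 298,
                      probe_radius = 1.4, ion_exclusion = 2.0,
                      grid_spacing_coarse = 1.0, grid_spacing_fine = 0.4,
                      grid_padding = 10, fine_padding = 3,
                      reentrant = FALSE,
                      tol = 1e-4, maxit = 5000, omega = 1.9) {
  stopifnot(eps_solvent > eps_protein, eps_protein >= 1,
            grid_spacing_coarse > 0, grid_spacing_fine > 0,
            grid_padding > 0, fine_padding > 0, probe_radius > 0,
            ion_exclusion >= 0, temperature > 0, ionic_strength >= 0,
            omega > 0, omega < 2)
  structure(as.list(environment()), class = "pb_config")
}

## grid centred on `center` covering `extent` (full widths); odd node counts
## so the centre is a node -- keeps mirrored systems exactly mirrored on the
## grid.
.make_grid <- function(center, extent, h) {
  half <- ceiling((extent / 2) / h)
  dims <- 2L * as.integer(half) + 1L
  origin <- center - half * h
  list(origin = origin, h = h, dims = dims)
}

.grid_from_atoms <- function(coords, padding, h) {
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  .make_grid((lo + hi) / 2, (hi - lo) + 2 * padding, h)
}

.node_coords_axis <- function(grid, d)
  grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$h

#' Build finite-difference maps for an LPB solve
#'
#' Constructs the link dielectric maps (solute = van der Waals union of the
#' atom spheres, optionally with a probe-rolled re-entrant correction), the
#' ionic screening map (zero inside the solute and within the ion exclusion
#' layer of it) and the trilinearly spread source charge map.
#'
#' @param atoms data.frame/list with numeric \code{x,y,z} and \code{radius}
#'   defining the solute geometry (may be empty for pure solvent)
#' @param charges data.frame with \code{x,y,z,q}: the source charges (need
#'   not coincide with atoms)
#' @param config a [pb_config()]
#' @param grid grid geometry from the internal grid constructor; when NULL a
#'   grid covering the atoms (or charges) plus \code{grid_padding} at the
#'   coarse spacing is used
#' @param uniform_eps when non-NULL, a uniform-dielectric reference system:
#'   this dielectric everywhere and no ionic screening
#' @return list of class \code{grid_maps}
#' @export
build_maps <- function(atoms, charges, config = pb_config(), grid = NULL,
                       uniform_eps = NULL) {
  acoords <- if (length(atoms) && nrow(as.data.frame(atoms)))
    as.matrix(as.data.frame(atoms)[, c("x", "y", "z")]) else
    matrix(numeric(0), 0, 3)
  radii <- if (nrow(acoords)) as.data.frame(atoms)$radius else numeric(0)
  if (is.null(grid)) {
    base <- if (nrow(acoords)) acoords else
      as.matrix(charges[, c("x", "y", "z")])
    grid <- .grid_from_atoms(base, config$grid_padding,
                             config$grid_spacing_coarse)
  }
  h <- grid$h
  dims <- grid$dims
  n <- prod(dims)
  if (nrow(acoords)) {
    lo <- grid$origin
    hi <- grid$origin + (dims - 1) * h
    if (any(sweep(acoords, 2, lo) < 0) || any(sweep(acoords, 2, hi) > 0))
      stop("grid too small to contain the molecule plus padding")
  }
  if (!is.null(uniform_eps)) {
    ex <- ey <- ez <- rep(uniform_eps, n)
    kap2h2 <- rep(0, n)
  } else if (nrow(acoords) == 0) {
    ex <- ey <- ez <- rep(config$eps_solvent, n)
    kap <- debye_kappa(config$ionic_strength, config$eps_solvent,
                       config$temperature)
    kap2h2 <- rep(config$eps_solvent * kap^2 * h^2, n)
  } else {
    eps <- cpp_eps_links(dims, grid$origin, h, acoords, radii,
                         config$eps_protein, config$eps_solvent)
    ex <- eps$ex; ey <- eps$ey; ez <- eps$ez
    if (isTRUE(config$reentrant)) {
      mvdw <- cpp_node_mask(dims, grid$origin, h, acoords, radii, 0)
      macc <- cpp_node_mask(dims, grid$origin, h, acoords, radii,
                            config$probe_radius)
      mses <- cpp_ses_mask(dims, h, mvdw, macc, config$probe_radius)
      ## links with both endpoints in the corrected solute become protein
      solute <- mses == 1L
      sol <- array(solute, dims)
      both_x <- sol[-dims[1], , ] & sol[-1, , ]
      both_y <- sol[, -dims[2], ] & sol[, -1, ]
      both_z <- sol[, , -dims[3]] & sol[, , -1]
      ax <- array(ex, dims); ax[-dims[1], , ][both_x] <- config$eps_protein
      ay <- array(ey, dims); ay[, -dims[2], ][both_y] <- config$eps_protein
      az <- array(ez, dims); az[, , -dims[3]][both_z] <- config$eps_protein
      ex <- as.numeric(ax); ey <- as.numeric(ay); ez <- as.numeric(az)
    }
    ion_excl <- cpp_node_mask(dims, grid$origin, h, acoords, radii,
                              config$ion_exclusion)
    kap <- debye_kappa(config$ionic_strength, config$eps_solvent,
                       config$temperature)
    kap2h2 <- config$eps_solvent * kap^2 * h^2 * as.numeric(ion_excl == 0L)
  }
  src <- rep(0, n)
  if (nrow(charges)) {
    sp <- .spread_charges(grid, as.matrix(charges[, c("x", "y", "z")]),
                          charges$q)
    src <- 4 * pi * .KCAL_COUL * sp / h
  }
  structure(list(grid = grid, ex = ex, ey = ey, ez = ez, kap2h2 = kap2h2,
                 src_h = src, charges = charges, atoms = atoms,
                 uniform_eps = uniform_eps, config = config),
            class = "grid_maps")
}

## trilinear spreading of point charges onto grid nodes; conserves total
## charge exactly
.spread_charges <- function(grid, coords, q) {
  dims <- grid$dims
  rho <- rep(0, prod(dims))
  fx <- (coords[, 1] - grid$origin[1]) / grid$h
  fy <- (coords[, 2] - grid$origin[2]) / grid$h
  fz <- (coords[, 3] - grid$origin[3]) / grid$h
  if (any(fx < 0 | fy < 0 | fz < 0 | fx > dims[1] - 1 | fy > dims[2] - 1 |
          fz > dims[3] - 1))
    stop("charge outside grid")
  i0 <- pmin(floor(fx), dims[1] - 2); wx <- fx - i0
  j0 <- pmin(floor(fy), dims[2] - 2); wy <- fy - j0
  k0 <- pmin(floor(fz), dims[3] - 2); wz <- fz - k0
  for (a in seq_along(q)) {
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      w <- (if (di) wx[a] else 1 - wx[a]) *
           (if (dj) wy[a] else 1 - wy[a]) *
           (if (dk) wz[a] else 1 - wz[a])
      id <- (i0[a] + di) + dims[1] * ((j0[a] + dj) + dims[2] * (k0[a] + dk))
      rho[id + 1] <- rho[id + 1] + w * q[a]
    }
  }
  rho
}

## Debye-Hueckel (or uniform Coulomb) estimate of the potential at arbitrary
## points; used for outer boundary conditions
.analytic_phi <- function(points, charges, config, uniform_eps = NULL) {
  if (!nrow(charges)) return(rep(0, nrow(points)))
  eps <- if (is.null(uniform_eps)) config$eps_solvent else uniform_eps
  kap <- if (is.null(uniform_eps))
    debye_kappa(config$ionic_strength, config$eps_solvent,
                config$temperature) else 0
  phi <- rep(0, nrow(points))
  for (a in seq_len(nrow(charges))) {
    d <- sqrt((points[, 1] - charges$x[a])^2 +
              (points[, 2] - charges$y[a])^2 +
              (points[, 3] - charges$z[a])^2)
    d <- pmax(d, 1e-6)
    phi <- phi + .KCAL_COUL * charges$q[a] * exp(-kap * d) / (eps * d)
  }
  phi
}

## set the six outer faces of phi (3d array) from a function of coordinates
.set_boundary <- function(phi, grid, fun) {
  dims <- grid$dims
  xs <- .node_coords_axis(grid, 1)
  ys <- .node_coords_axis(grid, 2)
  zs <- .node_coords_axis(grid, 3)
  face <- function(ix, iy, iz) {
    g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
    fun(as.matrix(g))
  }
  phi[1, , ] <- face(1, seq_len(dims[2]), seq_len(dims[3]))
  phi[dims[1], , ] <- face(dims[1], seq_len(dims[2]), seq_len(dims[3]))
  phi[, 1, ] <- face(seq_len(dims[1]), 1, seq_len(dims[3]))
  phi[, dims[2], ] <- face(seq_len(dims[1]), dims[2], seq_len(dims[3]))
  phi[, , 1] <- face(seq_len(dims[1]), seq_len(dims[2]), 1)
  phi[, , dims[3]] <- face(seq_len(dims[1]), seq_len(dims[2]), dims[3])
  phi
}

#' Solve the linearised Poisson-Boltzmann equation on a grid
#'
#' Gauss-Seidel successive over-relaxation on the 7-point finite-difference
#' stencil with harmonically coupled link dielectrics.  Outer boundary
#' values are taken from \code{boundary} (a 3d array), or from the
#' Debye-Hueckel analytic estimate of the source charges when NULL.
#'
#' @param maps \code{grid_maps} from [build_maps()]
#' @param boundary optional 3d array holding boundary values (interior
#'   entries are used as the initial guess)
#' @return 3d array of potentials, kcal/mol/e, with attributes
#'   \code{iterations} and \code{max_update}
#' @export
solve_lpb <- function(maps, boundary = NULL) {
  config <- maps$config
  grid <- maps$grid
  if (is.null(boundary)) {
    phi <- array(0, grid$dims)
    phi <- .set_boundary(phi, grid, function(pts)
      .analytic_phi(pts, maps$charges, config, maps$uniform_eps))
  } else phi <- boundary
  res <- cpp_sor(as.numeric(phi), maps$ex, maps$ey, maps$ez, maps$kap2h2,
                 maps$src_h, grid$dims, config$tol, config$maxit,
                 config$omega)
  if (!res$converged)
    stop(sprintf(
      "LPB solver did not converge in %d iterations (max update %.3e)",
      config$maxit, res$max_update))
  structure(array(res$phi, dim = grid$dims),
            iterations = res$iterations, max_update = res$max_update)
}

#' Trilinear interpolation of a grid potential at arbitrary points
#' @param grid grid geometry
#' @param phi 3d potential array on the grid
#' @param points n x 3 matrix of coordinates
#' @return numeric vector of interpolated values
#' @export
interp_phi <- function(grid, phi, points) {
  dims <- grid$dims
  fx <- (points[, 1] - grid$origin[1]) / grid$h
  fy <- (points[, 2] - grid$origin[2]) / grid$h
  fz <- (points[, 3] - grid$origin[3]) / grid$h
  i0 <- pmin(pmax(floor(fx), 0), dims[1] - 2); wx <- fx - i0
  j0 <- pmin(pmax(floor(fy), 0), dims[2] - 2); wy <- fy - j0
  k0 <- pmin(pmax(floor(fz), 0), dims[3] - 2); wz <- fz - k0
  out <- numeric(nrow(points))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
         (if (dk) wz else 1 - wz)
    out <- out + w * phi[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  out
}

## point inside the fine box (with a safety margin of 2h)?
.in_grid <- function(grid, points, margin = 2) {
  lo <- grid$origin + margin * grid$h
  hi <- grid$origin + (grid$dims - 1 - margin) * grid$h
  points[, 1] >= lo[1] & points[, 1] <= hi[1] &
  points[, 2] >= lo[2] & points[, 2] <= hi[2] &
  points[, 3] >= lo[3] & points[, 3] <= hi[3]
}

#' Two-stage focused LPB solve for a molecular system
#'
#' Solves on a coarse grid covering the molecule plus \code{grid_padding}
#' with Debye-Hueckel boundary values, then on a fine grid covering the
#' molecule plus \code{fine_padding} with boundary values interpolated from
#' the coarse solution.
#'
#' @inheritParams build_maps
#' @param grids optional list with \code{coarse} and \code{fine} grid
#'   geometries; pass the same grids to two solves whose energies are to be
#'   subtracted so that grid self-energies cancel exactly.
#' @return list of class \code{pb_solution} with \code{coarse} and
#'   \code{fine} components (each grid + phi); query it with
#'   [potential_at()].
#' @export
solve_system <- function(atoms, charges, config = pb_config(),
                         uniform_eps = NULL, grids = NULL) {
  adf <- as.data.frame(atoms)
  base <- if (nrow(adf)) as.matrix(adf[, c("x", "y", "z")]) else
    as.matrix(charges[, c("x", "y", "z")])
  cgrid <- if (!is.null(grids)) grids$coarse else
    .grid_from_atoms(base, config$grid_padding, config$grid_spacing_coarse)
  cmaps <- build_maps(atoms, charges, config, grid = cgrid,
                      uniform_eps = uniform_eps)
  cphi <- solve_lpb(cmaps)
  fgrid <- if (!is.null(grids)) grids$fine else
    .grid_from_atoms(base, config$fine_padding, config$grid_spacing_fine)
  fmaps <- build_maps(atoms, charges, config, grid = fgrid,
                      uniform_eps = uniform_eps)
  phi0 <- array(0, fgrid$dims)
  phi0 <- .set_boundary(phi0, fgrid, function(pts)
    interp_phi(cgrid, cphi, pts))
  fphi <- solve_lpb(fmaps, boundary = phi0)
  structure(list(coarse = list(grid = cgrid, phi = cphi),
                 fine = list(grid = fgrid, phi = fphi)),
            class = "pb_solution")
}

#' Evaluate a focused PB solution at points
#'
#' Uses the fine grid where the point lies inside it (with a margin), the
#' coarse grid otherwise.
#'
#' @param sol \code{pb_solution} from [solve_system()]
#' @param points n x 3 matrix
#' @return numeric vector, kcal/mol/e
#' @export
potential_at <- function(sol, points) {
  points <- rbind(points)
  infine <- .in_grid(sol$fine$grid, points)
  out <- numeric(nrow(points))
  if (any(infine))
    out[infine] <- interp_phi(sol$fine$grid, sol$fine$phi,
                              points[infine, , drop = FALSE])
  if (any(!infine))
    out[!infine] <- interp_phi(sol$coarse$grid, sol$coarse$phi,
                               points[!infine, , drop = FALSE])
  out
}

#' Reaction-field (solvation) self-energy of a charge set
#'
#' Half the product of the charges with the difference between the potential
#' in the heterogeneous-dielectric system and in a uniform reference medium
#' of the protein dielectric, both computed on identical grids so the
#' singular grid self-energy cancels.
#'
#' @param atoms solute geometry (data.frame with x,y,z,radius)
#' @param charges data.frame x,y,z,q
#' @param config [pb_config()]
#' @return energy in kcal/mol (negative for a charge moved into solvent)
#' @export
reaction_field_energy <- function(atoms, charges, config = pb_config()) {
  pts <- as.matrix(charges[, c("x", "y", "z")])
  s_env <- solve_system(atoms, charges, config)
  s_uni <- solve_system(atoms, charges, config,
                        uniform_eps = config$eps_protein)
  0.5 * sum(charges$q * (potential_at(s_env, pts) - potential_at(s_uni, pts)))
}
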