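## fixtures: deterministic synthetic structures, regime-biased ensembles and
## prescribed energy tables with known ground truth.

## Side-chain/backbone templates: heavy-atom offsets (Angstrom) relative to
## CA, bond-plausible geometry with side chains extended along +z.
.BB_TEMPLATE <- list(N = c(-1.20, 0.77, 0), CA = c(0, 0, 0),
                     C = c(1.25, 0.74, 0), O = c(1.26, 1.97, 0))
.OXT_OFFSET <- c(2.32, 0.11, 0.45)
.SC_TEMPLATES <- list(
  GLY = list(),
  ALA = list(CB = c(0, -0.70, 1.35)),
  SER = list(CB = c(0, -0.70, 1.35), OG = c(0, 0.10, 2.45)),
  THR = list(CB = c(0, -0.70, 1.35), OG1 = c(0, 0.05, 2.45),
             CG2 = c(1.25, -1.35, 1.60)),
  CYS = list(CB = c(0, -0.70, 1.35), SG = c(0, 0.15, 2.90)),
  VAL = list(CB = c(0, -0.70, 1.35), CG1 = c(1.25, -1.35, 1.60),
             CG2 = c(-1.25, -1.35, 1.60)),
  LEU = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD1 = c(1.25, -0.75, 3.30), CD2 = c(-1.25, -0.75, 3.30)),
  ILE = list(CB = c(0, -0.70, 1.35), CG1 = c(1.25, -1.35, 1.60),
             CG2 = c(-1.25, -1.35, 1.60), CD1 = c(1.25, -0.90, 3.05)),
  MET = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             SD = c(0, -0.85, 4.15), CE = c(0, 0.35, 5.35)),
  PRO = list(CB = c(0, -0.70, 1.35), CG = c(-0.70, -0.35, 2.55),
             CD = c(-1.65, 0.35, 1.65)),
  ASN = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             OD1 = c(1.05, -0.20, 3.30), ND2 = c(-1.10, -0.25, 3.25)),
  GLN = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD = c(0, -0.80, 3.90), OE1 = c(1.05, -0.90, 4.60),
             NE2 = c(-1.10, -0.95, 4.55)),
  ASP = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             OD1 = c(1.05, -0.20, 3.30), OD2 = c(-1.10, -0.25, 3.25)),
  GLU = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD = c(0, -0.80, 3.90), OE1 = c(1.05, -0.90, 4.60),
             OE2 = c(-1.10, -0.95, 4.55)),
  LYS = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD = c(0, -0.80, 3.90), CE = c(0, -0.10, 5.25),
             NZ = c(0, -0.75, 6.55)),
  ARG = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD = c(0, -0.80, 3.90), NE = c(0, -0.15, 5.20),
             CZ = c(0, -0.70, 6.40), NH1 = c(1.15, -0.65, 7.15),
             NH2 = c(-1.15, -0.80, 7.10)),
  HIS = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             ND1 = c(1.10, -0.15, 3.45), CD2 = c(-1.05, -0.30, 3.50),
             CE1 = c(0.70, -0.35, 4.70), NE2 = c(-0.65, -0.45, 4.75)),
  PHE = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD1 = c(1.20, -0.20, 3.35), CD2 = c(-1.20, -0.25, 3.35),
             CE1 = c(1.20, -0.35, 4.75), CE2 = c(-1.20, -0.40, 4.75),
             CZ = c(0, -0.45, 5.45)),
  TYR = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD1 = c(1.20, -0.20, 3.35), CD2 = c(-1.20, -0.25, 3.35),
             CE1 = c(1.20, -0.35, 4.75), CE2 = c(-1.20, -0.40, 4.75),
             CZ = c(0, -0.45, 5.45), OH = c(0, -0.60, 6.80)),
  TRP = list(CB = c(0, -0.70, 1.35), CG = c(0, -0.10, 2.60),
             CD1 = c(1.20, -0.20, 3.35), CD2 = c(-1.05, -0.30, 3.50),
             NE1 = c(0.85, -0.35, 4.65), CE2 = c(-0.55, -0.40, 4.75),
             CE3 = c(-2.40, -0.35, 3.05), CZ2 = c(-1.40, -0.55, 5.85),
             CZ3 = c(-3.25, -0.50, 4.15), CH2 = c(-2.75, -0.60, 5.55)))

#' A 33-residue arginine-free leucine-zipper-like sequence
#'
#' Used by the fixture generator to build a chain carrying the same
#' titratable-site content as one chain of the GCN4 leucine-zipper
#' construct (N-terminal amine, 5 Lys, 6 Glu, 1 Asp, 1 Tyr, 1 His,
#' C-terminal carboxyl: 16 sites); arginines are replaced by glutamines so
#' every detected site titrates in the standard pH range.
#'
#' @return character vector of 33 three-letter residue codes
#' @export
gcn4_like_residues <- function() {
  c("GLY", "SER", "MET", "LYS", "GLN", "LEU", "GLU", "ASP", "LYS", "VAL",
    "GLU", "GLU", "LEU", "LEU", "SER", "LYS", "ASN", "TYR", "HIS", "LEU",
    "GLU", "ASN", "GLU", "VAL", "GLN", "GLN", "LEU", "LYS", "LYS", "LEU",
    "VAL", "GLY", "GLU")
}

#' Fixture specification
#'
#' Describes a synthetic system: one or more chains of template residues,
#' optional mirrored second chain, ensemble size, coordinate jitter and
#' regime bias rules.
#'
#' @param residues residue codes of chain A (ignored if \code{chains} given)
#' @param chains list of chain descriptions, each a list with
#'   \code{name}, \code{residues}, optional \code{translate} (length-3),
#'   optional \code{zflip} (point the side chains along -z)
#' @param mirror when TRUE chain "B" is generated as an exact mirror image
#'   of chain A through the plane x = \code{mirror_plane}
#' @param mirror_plane x coordinate of the mirror plane (Angstrom)
#' @param n_conformers ensemble size M per regime (default 280, matching a
#'   50 ps snapshot cadence over 14 ns)
#' @param jitter_sd per-coordinate Gaussian jitter applied to ensemble
#'   conformers, Angstrom (default 0.3)
#' @param seed integer seed; all fixture randomness derives from it
#' @param glu0_bias,lys0_bias optional regime bias: list with \code{chain}
#'   and \code{translate} applied to that chain in the given regime's
#'   conformers (e.g. to break a salt bridge in glu0)
#' @param ca_spacing consecutive CA spacing along x, Angstrom
#' @return list of class \code{fixture_spec}
#' @export
toy_spec <- function(residues = c("ALA", "GLU", "ALA"), chains = NULL,
                     mirror = FALSE, mirror_plane = 8,
                     n_conformers = 280, jitter_sd = 0.3, seed = 1,
                     glu0_bias = NULL, lys0_bias = NULL, ca_spacing = 3.8) {
  if (is.null(chains))
    chains <- list(list(name = "A", residues = residues,
                        translate = c(0, 0, 0), zflip = FALSE))
  for (ch in chains)
    if (!all(ch$residues %in% names(.SC_TEMPLATES)))
      stop("unknown residue code in fixture spec")
  stopifnot(n_conformers >= 1, jitter_sd >= 0, ca_spacing > 2.0)
  structure(list(chains = chains, mirror = mirror,
                 mirror_plane = mirror_plane, n_conformers = n_conformers,
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 glu0_bias = glu0_bias, lys0_bias = lys0_bias,
                 ca_spacing = ca_spacing),
            class = "fixture_spec")
}

.build_chain <- function(name, residues, translate = c(0, 0, 0),
                         zflip = FALSE, ca_spacing = 3.8,
                         eleno_start = 1L) {
  rows <- list()
  eleno <- eleno_start
  for (i in seq_along(residues)) {
    res <- residues[i]
    ca <- c(ca_spacing * (i - 1), 0, 0)
    tpl <- c(.BB_TEMPLATE, .SC_TEMPLATES[[res]])
    if (i == length(residues)) tpl$OXT <- .OXT_OFFSET
    for (an in names(tpl)) {
      off <- tpl[[an]]
      if (zflip) off[3] <- -off[3]
      p <- ca + off + translate
      rows[[length(rows) + 1]] <- data.frame(
        eleno = eleno, elety = an, resid = res, chain = name, resno = i,
        insert = "", x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
      eleno <- eleno + 1L
    }
  }
  do.call(rbind, rows)
}

#' Build a toy peptide conformer from a fixture spec
#'
#' Deterministic, chemically plausible heavy-atom coordinates; every
#' titratable residue (and both termini, via the OXT atom on the last
#' residue) is detectable by [detect_sites()].  Returns the conformer
#' together with the bundled parameter table.
#'
#' @param spec a [toy_spec()]
#' @return list with \code{conformer} (parameterised) and
#'   \code{parameter_table}
#' @export
#' @examples
#' pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "LYS")))
#' print(detect_sites(pep$conformer))
make_toy_peptide <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  parts <- list()
  eleno <- 1L
  for (ch in spec$chains) {
    tr <- if (is.null(ch$translate)) c(0, 0, 0) else ch$translate
    zf <- isTRUE(ch$zflip)
    df <- .build_chain(ch$name, ch$residues, tr, zf, spec$ca_spacing, eleno)
    eleno <- eleno + nrow(df)
    parts[[length(parts) + 1]] <- df
  }
  conf <- do.call(rbind, parts)
  if (isTRUE(spec$mirror)) {
    mb <- conf[conf$chain == spec$chains[[1]]$name, ]
    mb$chain <- "B"
    mb$x <- 2 * spec$mirror_plane - mb$x
    mb$eleno <- seq.int(eleno, length.out = nrow(mb))
    conf <- rbind(conf, mb)
  }
  conf <- structure(conf, class = c("conformer", "data.frame"),
                    source_label = "fixture")
  ## minimum inter-atom contact check across chains
  xyz <- as.matrix(conf[, c("x", "y", "z")])
  if (length(unique(conf$chain)) > 1) {
    d <- as.matrix(stats::dist(xyz))
    inter <- outer(conf$chain, conf$chain, "!=")
    if (min(d[inter]) < 2.0)
      stop("infeasible fixture geometry: inter-chain contact below 2 A")
  }
  pt <- read_parameter_table()
  list(conformer = assign_parameters(conf, pt), parameter_table = pt)
}

## mirror chain B of a conformer from (possibly jittered) chain A
.mirror_into_b <- function(conf, plane) {
  ia <- conf$chain == "A"
  ib <- conf$chain == "B"
  stopifnot(sum(ia) == sum(ib))
  conf$x[ib] <- 2 * plane - conf$x[ia]
  conf$y[ib] <- conf$y[ia]
  conf$z[ib] <- conf$z[ia]
  conf
}

#' Generate the three regime-tagged conformer ensembles
#'
#' Emulates snapshot collection from three trajectories run under different
#' fixed protonation regimes: each ensemble holds M conformers of the toy
#' system with Gaussian coordinate jitter.  Regime bias rules (a rigid
#' displacement of one chain in glu0 and/or lys0 conformers, e.g. to break
#' a carboxyl salt bridge once the acid is neutral) produce the
#' conformational differences the multi-regime combination is designed to
#' exploit.  For mirrored dimers the jitter is applied to chain A and
#' mirrored onto chain B, preserving exact symmetry per conformer.
#' Deterministic given \code{spec$seed}.
#'
#' @param spec a [toy_spec()]
#' @return named list of three \code{ensemble}s: allC, glu0, lys0
#' @export
make_regime_ensembles <- function(spec) {
  base <- make_toy_peptide(spec)$conformer
  regimes <- c("allC", "glu0", "lys0")
  out <- list()
  for (ri in seq_along(regimes)) {
    reg <- regimes[ri]
    set.seed(spec$seed + 1000L * ri)
    bias <- switch(reg, glu0 = spec$glu0_bias, lys0 = spec$lys0_bias, NULL)
    confs <- vector("list", spec$n_conformers)
    for (m in seq_len(spec$n_conformers)) {
      cf <- base
      if (!is.null(bias)) {
        sel <- cf$chain == bias$chain
        cf$x[sel] <- cf$x[sel] + bias$translate[1]
        cf$y[sel] <- cf$y[sel] + bias$translate[2]
        cf$z[sel] <- cf$z[sel] + bias$translate[3]
      }
      if (spec$jitter_sd > 0) {
        n <- nrow(cf)
        cf$x <- cf$x + rnorm(n, 0, spec$jitter_sd)
        cf$y <- cf$y + rnorm(n, 0, spec$jitter_sd)
        cf$z <- cf$z + rnorm(n, 0, spec$jitter_sd)
      }
      if (isTRUE(spec$mirror)) cf <- .mirror_into_b(cf, spec$mirror_plane)
      attr(cf, "source_label") <- sprintf("%s_%03d", reg, m)
      confs[[m]] <- cf
    }
    out[[reg]] <- as_ensemble(confs, reg)
  }
  out
}

#' Single-regime jittered ensemble from a fixture spec
#'
#' @param spec a [toy_spec()]
#' @param regime tag for the resulting ensemble
#' @return an \code{ensemble}
#' @export
make_fixture_ensemble <- function(spec, regime = "single") {
  base <- make_toy_peptide(spec)$conformer
  set.seed(spec$seed)
  confs <- vector("list", spec$n_conformers)
  for (m in seq_len(spec$n_conformers)) {
    cf <- base
    if (spec$jitter_sd > 0) {
      n <- nrow(cf)
      cf$x <- cf$x + rnorm(n, 0, spec$jitter_sd)
      cf$y <- cf$y + rnorm(n, 0, spec$jitter_sd)
      cf$z <- cf$z + rnorm(n, 0, spec$jitter_sd)
    }
    if (isTRUE(spec$mirror)) cf <- .mirror_into_b(cf, spec$mirror_plane)
    attr(cf, "source_label") <- sprintf("snap_%03d", m)
    confs[[m]] <- cf
  }
  as_ensemble(confs, regime)
}

#' Salt-bridge fixture: an acid and a base at a prescribed distance
#'
#' Two single-residue chains placed so the acid's carboxyl oxygen and the
#' base's amine nitrogen sit \code{d_bridge} apart (default 2.9 Angstrom, a
#' typical donor-acceptor distance).  The default glu0 bias displaces the
#' base chain by \code{d_broken - d_bridge} so the bridge is broken in the
#' acidic-regime ensemble.
#'
#' @param d_bridge donor-acceptor distance in allC/lys0 conformers, Angstrom
#' @param d_broken donor-acceptor distance in glu0 conformers, Angstrom
#' @param ... passed to [toy_spec()] (seed, n_conformers, jitter_sd, ...)
#' @return a [toy_spec()]
#' @export
bridge_spec <- function(d_bridge = 2.9, d_broken = 8, ...) {
  ## chain A: GLU with side chain up; chain B: LYS flipped, NZ pointing down
  a <- .build_chain("A", "GLU")
  b0 <- .build_chain("B", "LYS", zflip = TRUE)
  oe2 <- unlist(a[a$elety == "OE2", c("x", "y", "z")])
  nz <- unlist(b0[b0$elety == "NZ", c("x", "y", "z")])
  translate <- oe2 + c(0, 0, d_bridge) - nz
  toy_spec(chains = list(
    list(name = "A", residues = "GLU", translate = c(0, 0, 0),
         zflip = FALSE),
    list(name = "B", residues = "LYS", translate = as.numeric(translate),
         zflip = TRUE)),
    glu0_bias = list(chain = "B",
                     translate = c(0, 0, d_broken - d_bridge)), ...)
}

#' Prescribed synthetic site energy table
#'
#' Builds a \code{site_energy_table} directly from given intrinsic pK
#' values and a site-site interaction matrix, bypassing the PB solver --
#' the ground-truth input for titration-core tests.
#'
#' @param site_class character vector of site classes (\code{"carboxyl"},
#'   \code{"amino"}, ...); acids titrate by losing a proton, bases by
#'   gaining one
#' @param pk_int intrinsic pK per site
#' @param W site-by-site interaction matrix between the charged forms,
#'   kcal/mol (symmetric, zero diagonal); scalar 0 for no interactions
#' @param temperature K
#' @return a \code{site_energy_table}
#' @export
#' @examples
#' et <- make_energy_table(c("carboxyl", "amino"), c(4.4, 10.4), W = 0)
#' pops <- populations_exact(et)
make_energy_table <- function(site_class, pk_int, W = 0,
                              temperature = 298) {
  ns <- length(site_class)
  stopifnot(length(pk_int) == ns)
  if (is.matrix(W)) {
    stopifnot(nrow(W) == ns, ncol(W) == ns,
              isTRUE(all.equal(W, t(W))), all(diag(W) == 0))
  } else {
    W <- matrix(W, ns, ns)
    diag(W) <- 0
  }
  acid <- site_class %in% c("carboxyl", "hydroxyl", "c_terminus")
  ms <- do.call(rbind, lapply(seq_len(ns), function(i) {
    if (acid[i]) {
      pc <- c(1L, 0L)          # reference = protonated (neutral)
    } else {
      pc <- c(0L, 1L)          # reference = deprotonated (neutral)
    }
    data.frame(site = i, site_label = sprintf("S%d_%s", i, site_class[i]),
               site_class = site_class[i], pk_mod = pk_int[i],
               ms_label = c("reference", "charged"),
               proton_count = pc, dm = pc - pc[1], pk_std = pk_int[i],
               reference = c(TRUE, FALSE),
               protonated = pc == max(pc),
               dG_born = 0, dG_perm = 0, dG_ref = 0, dG_elec = 0,
               stringsAsFactors = FALSE)
  }))
  ng <- nrow(ms)
  Wg <- matrix(0, ng, ng)
  charged <- which(!ms$reference)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    Wg[charged[i], charged[j]] <- W[i, j]
  }
  ms$dpk_born <- ms$dpk_perm <- ms$dpk_ref <-
    ifelse(ms$dm == 0, NA_real_, 0)
  ms$pk_int <- ifelse(ms$dm == 0, NA_real_, ms$pk_std)
  meta <- lapply(seq_len(ns), function(i)
    list(label = ms$site_label[ms$site == i][1], site_class = site_class[i],
         pk_mod = pk_int[i]))
  new_energy_table(meta, ms, Wg, temperature = temperature)
}
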