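## titration_core: microstate populations vs pH from a SiteEnergyTable --
## exact enumeration for small systems, Metropolis Monte Carlo for large.

#' Monte Carlo sampler settings
#'
#' @param sweeps production sweeps (one sweep = one attempted move per site)
#' @param burnin discarded equilibration sweeps
#' @param nbatch number of batches for batch-mean standard errors
#' @param pair_threshold absolute site-site coupling (kcal/mol) above which
#'   a pair is eligible for simultaneous two-site moves; default two pK
#'   units
#' @param pair_prob probability that an attempted move is a pair move
#' @param acceptance_floor below this overall acceptance rate a poor-mixing
#'   warning is raised
#' @param seed optional integer; when non-NULL, \code{set.seed(seed)} is
#'   called before sampling so runs are exactly reproducible
#' @return list of class \code{mc_config}
#' @export
mc_config <- function(sweeps = 10000, burnin = 1000, nbatch = 20,
                      pair_threshold = 2 * pK_to_kcal(), pair_prob = 0.2,
                      acceptance_floor = 0.02, seed = NULL) {
  stopifnot(sweeps >= nbatch, burnin >= 0, nbatch >= 2)
  structure(as.list(environment()), class = "mc_config")
}

## singleton energy of every global microstate at one pH (kcal/mol):
## E_m = ln10 kT dm (pH - pk_std) + dG_elec;  reference microstates have
## dm = 0 and dG_elec = 0, hence energy 0.
.esingle <- function(et, pH) {
  upk <- pK_to_kcal(et$temperature)
  upk * et$ms$dm * (pH - et$ms$pk_std) + et$ms$dG_elec
}

#' Electrostatic energy of a protonation state vector
#'
#' The state energy relative to the all-reference state: singleton terms
#' (proton chemical potential against each microstate's intrinsic pK plus
#' its tautomer energy offset) plus pairwise interactions counted once per
#' pair.
#'
#' @param x integer vector, one microstate index per site (1-based, local
#'   within each site); the all-reference vector has energy 0
#' @param et \code{site_energy_table}
#' @param pH pH value
#' @return energy in kcal/mol
#' @export
state_energy <- function(x, et, pH) {
  ns <- length(unique(et$ms$site))
  stopifnot(length(x) == ns)
  offs <- match(unique(et$ms$site), et$ms$site) - 1L
  nms <- tabulate(match(et$ms$site, unique(et$ms$site)))
  if (any(x < 1 | x > nms)) stop("invalid microstate index in state vector")
  g <- offs + x
  es <- .esingle(et, pH)
  e <- sum(es[g])
  if (ns > 1) {
    for (i in 1:(ns - 1))
      for (j in (i + 1):ns)
        e <- e + et$W[g[i], g[j]]
  }
  e
}

## shared site bookkeeping
.site_layout <- function(et) {
  usite <- unique(et$ms$site)
  offs <- match(usite, et$ms$site) - 1L
  nms <- as.integer(table(factor(et$ms$site, levels = usite)))
  list(usite = usite, offs = offs, nms = nms, ns = length(usite))
}

.new_populations <- function(et, pH_grid, p, se = NULL, method = "exact",
                             acceptance = NA_real_) {
  structure(list(pH = pH_grid, p = p, se = se, ms = et$ms,
                 sites = et$sites, method = method,
                 acceptance = acceptance),
            class = "microstate_populations")
}

#' @export
print.microstate_populations <- function(x, ...) {
  cat(sprintf("microstate populations (%s): %d sites, %d pH points\n",
              x$method, length(unique(x$ms$site)), length(x$pH)))
  invisible(x)
}

#' Exact microstate populations over a pH grid
#'
#' Full enumeration of the protonation-state partition function: for every
#' microstate alpha of every site, its population is the Boltzmann-weighted
#' fraction of all state vectors in which that site occupies alpha.
#'
#' @param et \code{site_energy_table}
#' @param pH_grid numeric vector of pH values
#' @param cap refuse enumeration beyond this many state vectors
#'   (default 2^20); larger systems should use [populations_mc()]
#' @return \code{microstate_populations}: matrix \code{p} of populations
#'   (global microstate x pH)
#' @export
populations_exact <- function(et, pH_grid = seq(0, 14, 0.1), cap = 2^20) {
  lay <- .site_layout(et)
  nstates <- prod(lay$nms)
  if (nstates > cap)
    stop(sprintf(paste0("state space too large for exact enumeration ",
                        "(%g > %g); use populations_mc()"), nstates, cap))
  states <- as.matrix(expand.grid(lapply(lay$nms, seq_len)))
  gm <- sweep(states, 2, lay$offs, "+")  # global ms index per site/state
  kT <- kT_kcal(et$temperature)
  npH <- length(pH_grid)
  ng <- nrow(et$ms)

  ## pH-independent pairwise part
  epair <- numeric(nstates)
  if (lay$ns > 1) {
    for (i in 1:(lay$ns - 1))
      for (j in (i + 1):lay$ns)
        epair <- epair + et$W[cbind(gm[, i], gm[, j])]
  }
  ## pH-dependent singleton part: E = A + upk*dm_sum*pH where per state
  upk <- pK_to_kcal(et$temperature)
  a_g <- -upk * et$ms$dm * et$ms$pk_std + et$ms$dG_elec
  b_g <- upk * et$ms$dm
  A <- rowSums(matrix(a_g[gm], nstates)) + epair
  B <- rowSums(matrix(b_g[gm], nstates))

  p <- matrix(0, ng, npH)
  for (ip in seq_len(npH)) {
    E <- A + B * pH_grid[ip]
    w <- exp(-(E - min(E)) / kT)
    w <- w / sum(w)
    for (s in seq_len(lay$ns)) {
      tot <- tapply(w, gm[, s], sum)
      p[as.integer(names(tot)), ip] <- p[as.integer(names(tot)), ip] +
        as.numeric(tot)
    }
  }
  .new_populations(et, pH_grid, p, method = "exact")
}

#' Monte Carlo microstate populations over a pH grid
#'
#' Metropolis sampling with single-site moves plus simultaneous pair moves
#' for strongly coupled site pairs.  Populations carry batch-mean standard
#' errors; identical seeds give bitwise-identical output.
#'
#' @inheritParams populations_exact
#' @param mc [mc_config()]
#' @return \code{microstate_populations} with an \code{se} matrix
#' @export
populations_mc <- function(et, pH_grid = seq(0, 14, 0.1),
                           mc = mc_config()) {
  lay <- .site_layout(et)
  if (!is.null(mc$seed)) set.seed(mc$seed)
  ## coupled pairs: any |W| between two sites' microstates above threshold
  pairs <- matrix(0L, 0, 2)
  if (lay$ns > 1) {
    for (i in 1:(lay$ns - 1))
      for (j in (i + 1):lay$ns) {
        bi <- lay$offs[i] + seq_len(lay$nms[i])
        bj <- lay$offs[j] + seq_len(lay$nms[j])
        if (max(abs(et$W[bi, bj])) > mc$pair_threshold)
          pairs <- rbind(pairs, c(i - 1L, j - 1L))
      }
  }
  refs <- which(et$ms$reference) - lay$offs[et$ms$site[et$ms$reference]] - 1L
  ng <- nrow(et$ms)
  npH <- length(pH_grid)
  p <- matrix(0, ng, npH)
  se <- matrix(0, ng, npH)
  acc <- numeric(npH)
  for (ip in seq_len(npH)) {
    res <- cpp_mc_titrate(lay$offs, lay$nms, .esingle(et, pH_grid[ip]),
                          et$W, kT_kcal(et$temperature),
                          as.integer(mc$sweeps), as.integer(mc$burnin),
                          as.integer(mc$nbatch), pairs, mc$pair_prob,
                          as.integer(refs))
    p[, ip] <- res$pops
    se[, ip] <- res$se
    acc[ip] <- res$acceptance
  }
  if (mean(acc) < mc$acceptance_floor)
    warning(sprintf("poor Monte Carlo mixing: mean acceptance %.3f",
                    mean(acc)))
  .new_populations(et, pH_grid, p, se = se, method = "mc",
                   acceptance = mean(acc))
}

## populations of one site as a (local microstate x pH) matrix
.site_pop <- function(pops, site) {
  rows <- which(pops$ms$site == site)
  pops$p[rows, , drop = FALSE]
}

#' Titration curve of the protonated form of one site
#'
#' Sums the populations of the site's protonated microstate class (maximum
#' proton count) at each pH.
#'
#' @param pops \code{microstate_populations}
#' @param site site index (as in the energy table) or site label
#' @return a \code{titration_curve} (data.frame pH, value) tracking the
#'   protonated fraction
#' @export
protonated_fraction <- function(pops, site) {
  if (is.character(site)) site <- match(site, unique(pops$ms$site_label))
  rows <- which(pops$ms$site == site)
  prot <- pops$ms$protonated[rows]
  v <- colSums(pops$p[rows[prot], , drop = FALSE])
  meta <- pops$sites[[match(site, unique(pops$ms$site))]]
  new_titration_curve(pops$pH, v, site_label = meta$label,
                      pk_mod = meta$pk_mod, site_class = meta$site_class)
}

#' Degree of deprotonation of one site
#'
#' \eqn{\theta_i(pH) = 1 - } (population of the protonated microstate
#' class).
#'
#' @inheritParams protonated_fraction
#' @return a \code{titration_curve} tracking theta
#' @export
degree_of_deprotonation <- function(pops, site) {
  cv <- protonated_fraction(pops, site)
  cv$value <- 1 - cv$value
  attr(cv, "tracked") <- "deprotonated"
  cv
}

#' Write per-site titration curves as a tab-separated table
#' @param curves list of \code{titration_curve}s on a common pH grid
#' @param path output path
#' @return invisibly, `path`
#' @export
write_curves <- function(curves, path) {
  pH <- curves[[1]]$pH
  out <- data.frame(pH = sprintf("%.4f", pH))
  for (cv in curves) {
    stopifnot(isTRUE(all.equal(cv$pH, pH)))
    out[[attr(cv, "site_label")]] <- sprintf("%.8f", cv$value)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
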