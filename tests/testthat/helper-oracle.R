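## Independent brute-force oracle for microstate populations: enumerates
## every state vector explicitly and evaluates the Boltzmann sum with plain
## loops, sharing no code with the package's vectorised enumeration.
oracle_populations <- function(et, pH) {
  kT <- 0.0019872041 * et$temperature
  upk <- log(10) * kT
  usite <- unique(et$ms$site)
  nms <- vapply(usite, function(s) sum(et$ms$site == s), integer(1))
  offs <- vapply(usite, function(s) which(et$ms$site == s)[1] - 1L,
                 integer(1))
  states <- expand.grid(lapply(nms, seq_len))
  ng <- nrow(et$ms)
  p <- matrix(0, ng, length(pH))
  for (ip in seq_along(pH)) {
    logw <- numeric(nrow(states))
    for (r in seq_len(nrow(states))) {
      e <- 0
      g <- integer(length(usite))
      for (s in seq_along(usite)) {
        g[s] <- offs[s] + states[r, s]
        e <- e + upk * et$ms$dm[g[s]] * (pH[ip] - et$ms$pk_std[g[s]]) +
          et$ms$dG_elec[g[s]]
      }
      if (length(usite) > 1)
        for (i in seq_len(length(usite) - 1))
          for (j in (i + 1):length(usite))
            e <- e + et$W[g[i], g[j]]
      logw[r] <- -e / kT
    }
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    for (r in seq_len(nrow(states)))
      for (s in seq_along(usite))
        p[offs[s] + states[r, s], ip] <- p[offs[s] + states[r, s], ip] +
          w[r]
  }
  p
}

## seeded random two-state energy table with n sites
random_energy_table <- function(n, seed) {
  set.seed(seed)
  classes <- sample(c("carboxyl", "amino", "imidazole", "hydroxyl"), n,
                    replace = TRUE)
  pk <- runif(n, 2, 12)
  W <- matrix(0, n, n)
  if (n > 1) {
    vals <- runif(n * (n - 1) / 2, -1, 2.5)
    W[upper.tri(W)] <- vals
    W <- W + t(W)
  }
  make_energy_table(classes, pk, W = W)
}

## three-microstate imidazole-like site with two degenerate neutral
## tautomers (dm relative to the reference tautomer)
his_like_table <- function(pk_mod = 6.4, temperature = 298) {
  ms <- data.frame(
    site = 1L, site_label = "S1_imidazole", site_class = "imidazole",
    pk_mod = pk_mod,
    ms_label = c("NE2-H", "ND1-H", "protonated"),
    proton_count = c(1L, 1L, 2L), dm = c(0L, 0L, 1L),
    pk_std = pk_mod + log10(2),
    reference = c(TRUE, FALSE, FALSE),
    protonated = c(FALSE, FALSE, TRUE),
    dG_born = 0, dG_perm = 0, dG_ref = 0, dG_elec = 0,
    stringsAsFactors = FALSE)
  ms$dpk_born <- ms$dpk_perm <- ms$dpk_ref <- ifelse(ms$dm == 0, NA, 0)
  ms$pk_int <- ifelse(ms$dm == 0, NA, ms$pk_std)
  new_energy_table(list(list(label = "S1_imidazole",
                             site_class = "imidazole", pk_mod = pk_mod)),
                   ms, matrix(0, 3, 3), temperature = temperature)
}

## Henderson-Hasselbalch protonated fraction for an isolated site
hh_protonated <- function(pH, pk, acid = TRUE) {
  1 / (1 + 10^(pH - pk))
}

## quick PB configuration for tests that exercise the pipeline rather than
## solver accuracy
fast_pb <- function(...) {
  pb_config(grid_spacing_coarse = 1.0, grid_spacing_fine = 0.6,
            grid_padding = 10, fine_padding = 4, ...)
}
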