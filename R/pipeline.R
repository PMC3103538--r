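## End-to-end orchestration: conformer -> energies -> titration -> curves,
## snapshot averaging, regime weighting, pK extraction, reports.

#' Titrate a single conformer
#'
#' Assigns parameters if needed, detects sites (unless given), assembles
#' the site energy table by focused LPB solves and evaluates microstate
#' populations -- exactly when the state space is within \code{cap},
#' otherwise by Monte Carlo.
#'
#' @param conformer a \code{conformer}
#' @param sites optional \code{site_list} (detected when NULL)
#' @param config [pb_config()]
#' @param ph_grid pH grid (default 0..14 step 0.1)
#' @param method \code{"auto"}, \code{"exact"} or \code{"mc"}
#' @param mc [mc_config()] for the sampler path
#' @param cap exact-enumeration cap (state vectors)
#' @param termini_policy passed to [detect_sites()]
#' @return list with \code{curves} (named list of protonated-fraction
#'   curves), \code{populations}, \code{energy_table}, \code{sites}
#' @export
titrate_conformer <- function(conformer, sites = NULL,
                              config = pb_config(),
                              ph_grid = seq(0, 14, 0.1),
                              method = c("auto", "exact", "mc"),
                              mc = mc_config(), cap = 2^20,
                              termini_policy = "both") {
  method <- match.arg(method)
  if (is.null(conformer$charge))
    conformer <- assign_parameters(conformer)
  if (is.null(sites))
    sites <- detect_sites(conformer, termini_policy = termini_policy)
  et <- site_energy_terms(conformer, sites, config)
  lay <- .site_layout(et)
  nstates <- prod(lay$nms)
  if (method == "auto") method <- if (nstates <= cap) "exact" else "mc"
  pops <- if (method == "exact") populations_exact(et, ph_grid, cap = cap)
          else populations_mc(et, ph_grid, mc = mc)
  curves <- lapply(seq_len(lay$ns), function(i) protonated_fraction(pops, i))
  names(curves) <- vapply(et$sites, `[[`, character(1), "label")
  list(curves = curves, populations = pops, energy_table = et,
       sites = sites)
}

#' Titrate a conformer ensemble and average the curves over snapshots
#'
#' @param ensemble an \code{ensemble}
#' @inheritParams titrate_conformer
#' @return list with \code{curves} (snapshot-averaged, named by site),
#'   \code{per_snapshot} (list of per-conformer curve lists),
#'   \code{sites}, \code{regime}
#' @export
titrate_ensemble <- function(ensemble, sites = NULL, config = pb_config(),
                             ph_grid = seq(0, 14, 0.1),
                             method = "auto", mc = mc_config(),
                             cap = 2^20, termini_policy = "both") {
  stopifnot(inherits(ensemble, "ensemble"))
  first <- ensemble$conformers[[1]]
  if (is.null(first$charge)) first <- assign_parameters(first)
  if (is.null(sites))
    sites <- detect_sites(first, termini_policy = termini_policy)
  per_snap <- lapply(ensemble$conformers, function(cf) {
    r <- titrate_conformer(cf, sites = sites, config = config,
                           ph_grid = ph_grid, method = method, mc = mc,
                           cap = cap)
    r$curves
  })
  site_labels <- names(per_snap[[1]])
  curves <- lapply(site_labels, function(sl) {
    cv <- ensemble_average(lapply(per_snap, `[[`, sl))
    attr(cv, "regime") <- ensemble$regime
    cv
  })
  names(curves) <- site_labels
  list(curves = curves, per_snapshot = per_snap, sites = sites,
       regime = ensemble$regime)
}

## mean degree of deprotonation over the sites of given classes
.mean_theta <- function(curves, classes, resid_filter = NULL, sites = NULL) {
  sel <- vapply(curves, function(cv)
    attr(cv, "site_class") %in% classes, logical(1))
  if (!is.null(resid_filter) && !is.null(sites)) {
    lab <- vapply(sites, `[[`, character(1), "label")
    keep <- vapply(sites, function(s)
      s$resid %in% resid_filter & s$terminus == "", logical(1))
    sel <- sel & names(curves) %in% lab[keep]
  }
  if (!any(sel)) stop("no sites of class ", paste(classes, collapse = "/"),
                      " available for regime weighting")
  sub <- curves[sel]
  theta <- rowMeans(vapply(sub, function(cv) 1 - cv$value,
                           numeric(nrow(sub[[1]]))))
  new_titration_curve(sub[[1]]$pH, theta, site_label = "theta_mean",
                      tracked = "deprotonated")
}

#' Multi-regime pK(1/2) prediction
#'
#' Runs the titration pipeline on the three regime ensembles, averages the
#' curves over snapshots within each regime, derives the pH-dependent
#' regime weights from the mean carboxyl deprotonation of the glu0 ensemble
#' and the mean amino deprotonation of the lys0 ensemble, combines the
#' three regime curves per site, and extracts pK(1/2) per site plus the
#' allC-only value for comparison.
#'
#' @param ensembles named list with \code{allC}, \code{glu0}, \code{lys0}
#'   ensembles
#' @inheritParams titrate_conformer
#' @param carboxyl_scope sites entering the carboxyl theta average:
#'   \code{"all"} carboxyl-class sites (Glu, Asp, C-termini; default) or
#'   \code{"glu"} only
#' @param amino_scope sites entering the amino theta average: \code{"all"}
#'   amino-class sites (Lys, N-termini; default) or \code{"lys"} only
#' @return list with \code{pk} (data.frame: site, chain, site_key,
#'   site_class, pk_mod, pk_allc, pk_multi), \code{weights},
#'   \code{combined_curves}, \code{regime_curves}, \code{theta}
#' @export
multiph_pk <- function(ensembles, config = pb_config(),
                       ph_grid = seq(0, 14, 0.1), method = "auto",
                       mc = mc_config(), cap = 2^20,
                       termini_policy = "both",
                       carboxyl_scope = c("all", "glu"),
                       amino_scope = c("all", "lys")) {
  carboxyl_scope <- match.arg(carboxyl_scope)
  amino_scope <- match.arg(amino_scope)
  need <- c("allC", "glu0", "lys0")
  if (!all(need %in% names(ensembles)))
    stop("ensembles must be named allC, glu0, lys0")
  res <- lapply(need, function(rg)
    titrate_ensemble(ensembles[[rg]], config = config, ph_grid = ph_grid,
                     method = method, mc = mc, cap = cap,
                     termini_policy = termini_policy))
  names(res) <- need
  sites <- res$allC$sites
  theta_carb <- .mean_theta(res$glu0$curves,
                            classes = c("carboxyl", "c_terminus"),
                            resid_filter = if (carboxyl_scope == "glu")
                              "GLU" else NULL,
                            sites = sites)
  theta_amin <- .mean_theta(res$lys0$curves,
                            classes = c("amino", "n_terminus"),
                            resid_filter = if (amino_scope == "lys")
                              "LYS" else NULL,
                            sites = sites)
  w <- regime_weights(theta_carb, theta_amin)
  labels <- names(res$allC$curves)
  combined <- lapply(labels, function(sl)
    combine_regimes(list(allC = res$allC$curves[[sl]],
                         glu0 = res$glu0$curves[[sl]],
                         lys0 = res$lys0$curves[[sl]]), w))
  names(combined) <- labels
  pk <- do.call(rbind, lapply(labels, function(sl) {
    cv <- combined[[sl]]
    data.frame(site = sl,
               chain = sub(":.*$", "", sl),
               site_key = sub("^[^:]*:", "", sl),
               site_class = attr(cv, "site_class"),
               pk_mod = attr(cv, "pk_mod"),
               pk_allc = as.numeric(pk_half(res$allC$curves[[sl]])),
               pk_multi = as.numeric(pk_half(cv)),
               stringsAsFactors = FALSE)
  }))
  list(pk = pk, weights = w, combined_curves = combined,
       regime_curves = lapply(res, `[[`, "curves"),
       theta = list(carboxyl = theta_carb, amino = theta_amin))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param mode \code{"single-structure"}, \code{"single-regime"} or
#'   \code{"multi-regime"}
#' @param input for single-structure: one PDB path; single-regime: vector
#'   of PDB paths (or one multi-model file); multi-regime: named list
#'   (allC/glu0/lys0) of path vectors
#' @param out_dir output directory
#' @param regime regime tag for single-regime mode
#' @param ph_min,ph_max,ph_step pH grid
#' @param seed integer seed for any stochastic stage
#' @param pb list of [pb_config()] overrides
#' @param mc list of [mc_config()] overrides
#' @param method titration method ("auto", "exact", "mc")
#' @param termini_policy passed to [detect_sites()]
#' @param exp_table optional TSV of experimental pK values (columns
#'   \code{site, exp})
#' @param overwrite allow overwriting an existing completed output dir
#' @return list of class \code{run_config}
#' @export
run_config <- function(mode = c("multi-regime", "single-structure",
                                "single-regime"),
                       input, out_dir, regime = "allC",
                       ph_min = 0, ph_max = 14, ph_step = 0.1,
                       seed = 1, pb = list(), mc = list(),
                       method = "auto", termini_policy = "both",
                       exp_table = NULL, overwrite = FALSE) {
  mode <- match.arg(mode)
  stopifnot(ph_max > ph_min, ph_step > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with [run_config()] fields
#' @return a \code{run_config}
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full titration pipeline
#'
#' Validates the configuration, loads the input structures, runs the mode's
#' pipeline and writes per-site curves, regime weights (multi-regime mode),
#' the pK table, an accuracy report when an experimental table is supplied,
#' and a provenance log.  Reruns with the same configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [run_config()]
#' @return invisibly, the result list of the underlying pipeline call with
#'   \code{$out_dir} attached
#' @export
run_titration <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (file.exists(file.path(out, "pk.tsv")) && !isTRUE(config$overwrite))
    stop("output directory already holds a completed run: ", out,
         " (set overwrite = TRUE)")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ph_grid <- seq(config$ph_min, config$ph_max, config$ph_step)
  pbc <- do.call(pb_config, config$pb)
  mcc <- do.call(mc_config, config$mc)
  set.seed(config$seed)

  if (config$mode == "single-structure") {
    conf <- if (inherits(config$input, "conformer")) config$input
            else read_conformer(config$input)
    r <- titrate_conformer(conf, config = pbc, ph_grid = ph_grid,
                           method = config$method, mc = mcc,
                           termini_policy = config$termini_policy)
    curves <- r$curves
    pk <- do.call(rbind, lapply(names(curves), function(sl)
      data.frame(site = sl, chain = sub(":.*$", "", sl),
                 site_key = sub("^[^:]*:", "", sl),
                 pk_mod = attr(curves[[sl]], "pk_mod"),
                 pk = as.numeric(pk_half(curves[[sl]])),
                 stringsAsFactors = FALSE)))
    weights <- NULL
  } else if (config$mode == "single-regime") {
    ens <- if (inherits(config$input, "ensemble")) config$input
           else read_ensemble(config$input, regime = config$regime)
    r <- titrate_ensemble(ens, config = pbc, ph_grid = ph_grid,
                          method = config$method, mc = mcc,
                          termini_policy = config$termini_policy)
    curves <- r$curves
    pk <- do.call(rbind, lapply(names(curves), function(sl)
      data.frame(site = sl, chain = sub(":.*$", "", sl),
                 site_key = sub("^[^:]*:", "", sl),
                 pk_mod = attr(curves[[sl]], "pk_mod"),
                 pk = as.numeric(pk_half(curves[[sl]])),
                 stringsAsFactors = FALSE)))
    weights <- NULL
  } else {
    ens <- config$input
    if (!inherits(ens$allC, "ensemble"))
      ens <- list(allC = read_ensemble(config$input$allC, "allC"),
                  glu0 = read_ensemble(config$input$glu0, "glu0"),
                  lys0 = read_ensemble(config$input$lys0, "lys0"))
    r <- multiph_pk(ens, config = pbc, ph_grid = ph_grid,
                    method = config$method, mc = mcc,
                    termini_policy = config$termini_policy)
    curves <- r$combined_curves
    pk <- r$pk
    pk$pk <- pk$pk_multi
    weights <- r$weights
  }

  write_curves(curves, file.path(out, "curves.tsv"))
  if (!is.null(weights)) {
    wt <- weights
    for (cn in c("pH", "allC", "glu0", "lys0"))
      wt[[cn]] <- sprintf("%.8f", wt[[cn]])
    utils::write.table(wt, file.path(out, "weights.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_pk_report(pk, file.path(out, "pk.tsv"))
  if (!is.null(config$exp_table)) {
    expt <- read_pk_table(config$exp_table)
    merged <- merge(pk, expt, by = "site")
    rep <- pk_accuracy_report(
      merged[, c("site", "pk", "exp")], exp_column = "exp")
    utils::write.table(format(rep, digits = 6),
                       file.path(out, "stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg_echo <- config
  cfg_echo$input <- NULL
  writeLines(c(sprintf("multipk %s",
                       as.character(utils::packageVersion("multipk"))),
               sprintf("mode %s", config$mode),
               sprintf("seed %d", config$seed),
               sprintf("ph_grid %g..%g step %g", config$ph_min,
                       config$ph_max, config$ph_step),
               utils::capture.output(utils::str(cfg_echo))),
             file.path(out, "provenance.log"))
  r$out_dir <- out
  invisible(r)
}
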