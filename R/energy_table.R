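## SiteEnergyTable: per-conformer intrinsic-pK terms and the site-site
## interaction matrix, assembled from focused LPB solves.

#' Construct a site energy table
#'
#' Low-level constructor used by [site_energy_terms()] and the fixture
#' generator [make_energy_table()].
#'
#' @param sites list of per-site metadata (label, site_class, pk_mod, ...)
#' @param ms data.frame of per-microstate rows (see [site_energy_terms()])
#' @param W interaction matrix over global microstate indices, kcal/mol
#' @param temperature K
#' @param W_max_asym largest asymmetry of W before symmetrisation
#' @return object of class \code{site_energy_table}
#' @export
new_energy_table <- function(sites, ms, W, temperature = 298,
                             W_max_asym = 0) {
  stopifnot(nrow(W) == nrow(ms), ncol(W) == nrow(ms))
  if (any(!is.finite(W))) stop("non-finite interaction energies")
  structure(list(sites = sites, ms = ms, W = W, temperature = temperature,
                 W_max_asym = W_max_asym),
            class = "site_energy_table")
}

#' @export
print.site_energy_table <- function(x, ...) {
  cat(sprintf("site_energy_table: %d sites, %d microstates, T = %g K\n",
              length(x$sites), nrow(x$ms), x$temperature))
  cols <- c("site_label", "ms_label", "dm", "pk_std", "dpk_born", "dpk_perm",
            "dpk_ref", "pk_int")
  print(x$ms[, intersect(cols, names(x$ms))], digits = 3)
  invisible(x)
}

## per-site rows of the ms table
.et_site_rows <- function(et, i) which(et$ms$site == i)

#' Per-conformer electrostatic energy terms for all titratable sites
#'
#' For every non-reference microstate of every (non-fixed) site, solves the
#' LPB equation twice on identical focused grids -- once in the full protein
#' geometry and once for the excised model compound (the site's fragment
#' alone in solvent) -- with the microstate's charge difference from the
#' reference state as the source.  This yields:
#' \describe{
#'   \item{dG_born}{desolvation: difference of reaction-field self-energies
#'     between protein and model compound (grid self-energy cancels because
#'     the grids and source charges are identical)}
#'   \item{dG_perm}{interaction with the permanent (non-titratable) partial
#'     charges, minus the model compound's own background interaction}
#'   \item{dG_ref}{interaction with the other titratable groups held in
#'     their reference (neutral) protonation states}
#'   \item{W}{pairwise interaction with every non-reference microstate of
#'     every other site, symmetrised over the two solves}
#' }
#' Each term is also expressed in pK units
#' (\code{dpk_x = -dG_x / (dm ln10 kT)}) and assembled into
#' \code{pk_int = pk_std + dpk_born + dpk_perm + dpk_ref}.  Sites flagged
#' \code{fixed} (arginines by default) contribute their protonated charges
#' to the permanent background and are excluded from titration.
#'
#' @param conformer parameterised \code{conformer} (see
#'   [assign_parameters()])
#' @param sites \code{site_list} from [detect_sites()]
#' @param config [pb_config()]
#' @return a \code{site_energy_table}
#' @export
site_energy_terms <- function(conformer, sites, config = pb_config()) {
  if (is.null(conformer$charge) || is.null(conformer$radius))
    stop("conformer must be parameterised first (assign_parameters)")
  fixed <- vapply(sites, function(s) isTRUE(s$fixed), logical(1))
  free_sites <- sites[!fixed]
  if (length(free_sites) == 0) stop("no titratable (non-fixed) sites")

  bq <- conformer$charge
  ## fixed sites: overlay the protonated form as permanent background
  for (s in sites[fixed]) {
    pcs <- vapply(s$microstates, `[[`, integer(1), "proton_count")
    ms <- s$microstates[[which.max(pcs)]]
    idx <- .site_atom_idx(conformer, s)
    bq[idx] <- ms$charges[names(idx)]
  }
  coords <- as.matrix(conformer[, c("x", "y", "z")])
  atoms_df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         radius = conformer$radius)

  ns <- length(free_sites)
  gidx <- lapply(free_sites, function(s) .site_atom_idx(conformer, s))
  fidx <- lapply(free_sites, function(s) {
    fr <- .site_atom_idx(conformer, s, atoms = s$fragment)
    fr[!is.na(fr)]
  })
  all_group <- unlist(gidx, use.names = FALSE)
  perm_idx <- setdiff(seq_len(nrow(conformer)), all_group)

  ## one shared pair of focusing grids for every solve of this conformer
  grids <- list(
    coarse = .grid_from_atoms(coords, config$grid_padding,
                              config$grid_spacing_coarse),
    fine = .grid_from_atoms(coords, config$fine_padding,
                            config$grid_spacing_fine))

  ## global microstate bookkeeping
  ms_rows <- list()
  for (i in seq_len(ns)) {
    s <- free_sites[[i]]
    pcs <- vapply(s$microstates, `[[`, integer(1), "proton_count")
    refi <- which(vapply(s$microstates, `[[`, logical(1), "reference"))
    for (j in seq_along(s$microstates)) {
      m <- s$microstates[[j]]
      ms_rows[[length(ms_rows) + 1]] <- data.frame(
        site = i, site_label = s$label, site_class = s$site_class,
        pk_mod = s$pk_mod, ms_label = m$label,
        proton_count = m$proton_count, dm = m$proton_count - pcs[refi],
        pk_std = m$pk_std, reference = m$reference,
        protonated = m$proton_count == max(pcs),
        dG_born = 0, dG_perm = 0, dG_ref = 0, dG_elec = 0,
        stringsAsFactors = FALSE)
    }
  }
  ms <- do.call(rbind, ms_rows)
  ng <- nrow(ms)
  W <- matrix(0, ng, ng)
  grow <- function(i, j) which(ms$site == i)[j]  # global index of (site, ms)

  for (i in seq_len(ns)) {
    s <- free_sites[[i]]
    refi <- which(vapply(s$microstates, `[[`, logical(1), "reference"))
    refq <- s$microstates[[refi]]$charges
    gi <- gidx[[i]]
    gpts <- coords[gi, , drop = FALSE]
    frag <- fidx[[i]]
    frag_bg <- setdiff(frag, gi)
    frag_atoms <- atoms_df[frag, , drop = FALSE]
    for (j in seq_along(s$microstates)) {
      if (j == refi) next
      m <- s$microstates[[j]]
      dq <- m$charges[names(gi)] - refq[names(gi)]
      chg <- data.frame(x = gpts[, 1], y = gpts[, 2], z = gpts[, 3], q = dq)
      sol_p <- tryCatch(
        solve_system(atoms_df, chg, config, grids = grids),
        error = function(e) stop(sprintf("PB solve failed for site %s (%s): %s",
                                         s$label, m$label, conditionMessage(e))))
      sol_m <- solve_system(frag_atoms, chg, config, grids = grids)
      g <- grow(i, j)
      phi_p_self <- potential_at(sol_p, gpts)
      phi_m_self <- potential_at(sol_m, gpts)
      ms$dG_born[g] <- 0.5 * sum(dq * (phi_p_self - phi_m_self))
      dgp <- 0
      if (length(perm_idx))
        dgp <- sum(bq[perm_idx] *
                   potential_at(sol_p, coords[perm_idx, , drop = FALSE]))
      if (length(frag_bg))
        dgp <- dgp - sum(bq[frag_bg] *
                         potential_at(sol_m, coords[frag_bg, , drop = FALSE]))
      ms$dG_perm[g] <- dgp
      dgr <- 0
      for (k in seq_len(ns)) {
        if (k == i) next
        sk <- free_sites[[k]]
        refk <- which(vapply(sk$microstates, `[[`, logical(1), "reference"))
        gk <- gidx[[k]]
        kpts <- coords[gk, , drop = FALSE]
        phi_k <- potential_at(sol_p, kpts)
        dgr <- dgr + sum(sk$microstates[[refk]]$charges[names(gk)] * phi_k)
        for (l in seq_along(sk$microstates)) {
          if (l == refk) next
          dql <- sk$microstates[[l]]$charges[names(gk)] -
                 sk$microstates[[refk]]$charges[names(gk)]
          W[g, grow(k, l)] <- sum(dql * phi_k)
        }
      }
      ms$dG_ref[g] <- dgr
    }
  }
  W_max_asym <- max(abs(W - t(W)))
  W <- (W + t(W)) / 2

  ms$dG_elec <- ms$dG_born + ms$dG_perm + ms$dG_ref
  upk <- pK_to_kcal(config$temperature)
  conv <- ifelse(ms$dm == 0, NA_real_, -1 / (ms$dm * upk))
  ms$dpk_born <- ms$dG_born * conv
  ms$dpk_perm <- ms$dG_perm * conv
  ms$dpk_ref <- ms$dG_ref * conv
  ms$pk_int <- ms$pk_std + ms$dpk_born + ms$dpk_perm + ms$dpk_ref

  meta <- lapply(free_sites, function(s)
    list(label = s$label, site_class = s$site_class, pk_mod = s$pk_mod,
         chain = s$chain, resid = s$resid, resno = s$resno,
         terminus = s$terminus))
  new_energy_table(meta, ms, W, temperature = config$temperature,
                   W_max_asym = W_max_asym)
}

#' Write a site energy table to a tab-separated text file
#'
#' Two sections: \code{#MS} (per-microstate rows) and \code{#W} (non-zero
#' interaction entries as 1-based global index pairs).  The titration module
#' can run standalone from such files.
#'
#' @param et \code{site_energy_table}
#' @param path output path
#' @return invisibly, `path`
#' @export
write_energy_table <- function(et, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# multipk site energy table"), con)
  writeLines(sprintf("# temperature\t%.10g", et$temperature), con)
  writeLines("#MS", con)
  cols <- c("site", "site_label", "site_class", "pk_mod", "ms_label",
            "proton_count", "dm", "pk_std", "reference", "protonated",
            "dG_born", "dG_perm", "dG_ref", "dG_elec")
  tab <- et$ms[, cols]
  writeLines(paste(cols, collapse = "\t"), con)
  for (r in seq_len(nrow(tab)))
    writeLines(paste(vapply(tab[r, ], function(v)
      if (is.numeric(v)) sprintf("%.12g", v) else as.character(v),
      character(1)), collapse = "\t"), con)
  writeLines("#W", con)
  nz <- which(et$W != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] <= nz[, 2], , drop = FALSE]
  for (r in seq_len(nrow(nz)))
    writeLines(sprintf("%d\t%d\t%.12g", nz[r, 1], nz[r, 2],
                       et$W[nz[r, 1], nz[r, 2]]), con)
  invisible(path)
}

#' Read a site energy table written by [write_energy_table()]
#' @param path input path
#' @return a \code{site_energy_table}
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  temperature <- as.numeric(sub("^# temperature\t", "",
                                grep("^# temperature\t", lines,
                                     value = TRUE)[1]))
  ims <- which(lines == "#MS")
  iw <- which(lines == "#W")
  hdr <- strsplit(lines[ims + 1], "\t")[[1]]
  body <- lines[(ims + 2):(iw - 1)]
  ms <- utils::read.table(text = body, sep = "\t", col.names = hdr,
                          stringsAsFactors = FALSE)
  ms$reference <- as.logical(ms$reference)
  ms$protonated <- as.logical(ms$protonated)
  ng <- nrow(ms)
  W <- matrix(0, ng, ng)
  if (iw < length(lines)) {
    went <- utils::read.table(text = lines[(iw + 1):length(lines)],
                              sep = "\t",
                              col.names = c("i", "j", "w"))
    for (r in seq_len(nrow(went))) {
      W[went$i[r], went$j[r]] <- went$w[r]
      W[went$j[r], went$i[r]] <- went$w[r]
    }
  }
  upk <- pK_to_kcal(temperature)
  conv <- ifelse(ms$dm == 0, NA_real_, -1 / (ms$dm * upk))
  ms$dpk_born <- ms$dG_born * conv
  ms$dpk_perm <- ms$dG_perm * conv
  ms$dpk_ref <- ms$dG_ref * conv
  ms$pk_int <- ms$pk_std + ms$dpk_born + ms$dpk_perm + ms$dpk_ref
  sidx <- !duplicated(ms$site)
  meta <- Map(function(l, cl, pk) list(label = l, site_class = cl,
                                       pk_mod = pk),
              ms$site_label[sidx], ms$site_class[sidx], ms$pk_mod[sidx])
  new_energy_table(unname(meta), ms, W, temperature = temperature)
}
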