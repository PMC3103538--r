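## structure_io: PDB conformers, ensembles, titratable-site detection and
## charge/radius assignment.

#' Read the bundled heavy-atom parameter table
#'
#' The package ships a self-contained table of partial charges (neutral
#' reference protonation form, hydrogen charges collapsed onto parent heavy
#' atoms so each residue sums to 0 e) and dielectric-boundary radii.
#'
#' @param path path to an alternative table (columns
#'   \code{residue, atom, charge, radius}); default uses the bundled table.
#' @return data.frame with columns \code{residue, atom, charge, radius}.
#' @export
#' @examples
#' head(read_parameter_table())
read_parameter_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "heavy_atom_params.tsv", package = "multipk")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "atom", "charge", "radius") %in% names(tab)))
  if (any(!is.finite(tab$charge)) || any(tab$radius <= 0))
    stop("parameter table: charges must be finite and radii positive")
  tab
}

#' Write a parameter table to a tab-separated file
#' @param table data.frame as returned by [read_parameter_table()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_parameter_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.norm_pdb_text <- function(x) {
  if (length(x) == 1 && grepl("\n", x, fixed = TRUE))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x
}

.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      stop(sprintf("malformed PDB record at line %d: bad coordinates", i))
  }
  invisible(TRUE)
}

.conformer_from_bio3d <- function(atom, xyz = NULL, source_label = "") {
  if (!is.null(xyz)) {
    atom$x <- xyz[seq(1, length(xyz), 3)]
    atom$y <- xyz[seq(2, length(xyz), 3)]
    atom$z <- xyz[seq(3, length(xyz), 3)]
  }
  chain <- atom$chain
  chain[is.na(chain) | chain == ""] <- "A"
  insert <- atom$insert
  insert[is.na(insert)] <- ""
  conf <- data.frame(
    eleno = atom$eleno, elety = atom$elety, resid = atom$resid,
    chain = chain, resno = atom$resno, insert = insert,
    x = atom$x, y = atom$y, z = atom$z,
    stringsAsFactors = FALSE)
  key <- with(conf, paste(chain, resno, insert, resid, elety))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom in a residue: ", d)
  }
  if (any(!is.finite(as.matrix(conf[, c("x", "y", "z")]))))
    stop("non-finite coordinates in PDB input")
  structure(conf, class = c("conformer", "data.frame"),
            source_label = source_label)
}

#' Read a single protein conformer from PDB text or file
#'
#' Parses ATOM/HETATM records (via bio3d) preserving chain identity,
#' residue numbering and insertion codes.  Malformed records raise an error
#' naming the offending line; duplicate atoms within one residue are an
#' error.
#'
#' @param pdb a file path, or a character vector / single string of PDB text.
#' @param source_label snapshot identifier stored with the conformer.
#' @return an object of class \code{conformer}: a data.frame with columns
#'   \code{eleno, elety, resid, chain, resno, insert, x, y, z} (plus
#'   \code{charge} and \code{radius} after [assign_parameters()]).
#' @export
#' @examples
#' pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "ALA")))
#' f <- tempfile(fileext = ".pdb")
#' write_conformer(pep$conformer, f)
#' conf <- read_conformer(f)
#' nrow(conf)
read_conformer <- function(pdb, source_label = NULL) {
  is_file <- length(pdb) == 1 && !grepl("\n", pdb, fixed = TRUE) &&
    file.exists(pdb)
  if (is_file) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(source_label)) source_label <- basename(pdb)
  } else {
    lines <- .norm_pdb_text(pdb)
    if (is.null(source_label)) source_label <- "text"
  }
  .validate_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ## repeated atom serials across chains are legal PDB; silence the parser
  p <- withCallingHandlers(
    bio3d::read.pdb(tf, verbose = FALSE),
    warning = function(w) {
      if (grepl("duplicated element numbers", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  .conformer_from_bio3d(p$atom, source_label = source_label)
}

#' Write a conformer to a PDB file
#'
#' Coordinates are written at the format's native precision (3 decimals).
#'
#' @param conformer a \code{conformer}
#' @param path output file
#' @return invisibly, `path`
#' @export
write_conformer <- function(conformer, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(conformer[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(conformer)),
    resno = conformer$resno, resid = conformer$resid,
    eleno = conformer$eleno, elety = conformer$elety,
    chain = conformer$chain, insert = conformer$insert,
    o = rep(1, nrow(conformer)), b = rep(0, nrow(conformer)))
  invisible(path)
}

#' Bundle conformers into a regime-tagged ensemble
#'
#' @param conformers list of \code{conformer} objects sharing the same
#'   residue topology and atom order.
#' @param regime one of \code{"allC"}, \code{"glu0"}, \code{"lys0"},
#'   \code{"single"}.
#' @return an object of class \code{ensemble}.
#' @export
as_ensemble <- function(conformers,
                        regime = c("single", "allC", "glu0", "lys0")) {
  regime <- match.arg(regime)
  if (length(conformers) == 0) stop("ensemble must be non-empty")
  ref <- conformers[[1]]
  key <- function(cf) paste(cf$chain, cf$resno, cf$insert, cf$resid, cf$elety)
  k0 <- key(ref)
  for (cf in conformers[-1]) {
    if (!identical(key(cf), k0))
      stop("conformers of an ensemble must share atom order and topology")
  }
  structure(list(regime = regime, conformers = conformers),
            class = "ensemble")
}

#' Read an ensemble of conformers
#'
#' Accepts either several single-model PDB files or one multi-model
#' (MODEL/ENDMDL) file.
#'
#' @param paths character vector of PDB paths (length one for a multi-model
#'   file).
#' @inheritParams as_ensemble
#' @return an \code{ensemble}
#' @export
read_ensemble <- function(paths, regime = c("single", "allC", "glu0", "lys0")) {
  regime <- match.arg(regime)
  confs <- list()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
    for (m in seq_len(nm)) {
      xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else pdb$xyz
      confs[[length(confs) + 1]] <- .conformer_from_bio3d(
        pdb$atom, xyz = xyz,
        source_label = sprintf("%s#%d", basename(p), m))
    }
  }
  as_ensemble(confs, regime)
}

## ---- titratable sites -----------------------------------------------------

## model-compound (standard) pK values per site class
.PK_MOD <- c(carboxyl_glu = 4.4, carboxyl_asp = 4.0, amino = 10.4,
             hydroxyl = 9.6, imidazole = 6.4, guanidine = 12.0,
             n_terminus = 7.5, c_terminus = 3.8)

.STANDARD_RESID <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                     "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                     "THR", "TRP", "TYR", "VAL")

.ms <- function(label, proton_count, hpos, charges, reference = FALSE)
  list(label = label, proton_count = proton_count, hydrogen_position = hpos,
       charges = charges, reference = reference, pk_std = NA_real_)

## Absolute microstate charge sets on the titrating atoms.  The reference
## microstate charges coincide with the neutral-form parameter table.
.site_class_def <- function(resid, terminus = "") {
  if (terminus == "N") {
    return(list(site_class = "n_terminus", pk_mod = .PK_MOD[["n_terminus"]],
      atoms = c("N", "CA"), fragment = c("N", "CA"), fixed = FALSE,
      microstates = list(
        .ms("neutral", 0L, "", c(N = -0.16, CA = 0.16), reference = TRUE),
        .ms("protonated", 1L, "", c(N = 0.54, CA = 0.46)))))
  }
  if (terminus == "C") {
    return(list(site_class = "c_terminus", pk_mod = .PK_MOD[["c_terminus"]],
      atoms = c("C", "O", "OXT"), fragment = c("CA", "C", "O", "OXT"),
      fixed = FALSE,
      microstates = list(
        .ms("protonated", 1L, "OXT", c(C = 0.30, O = -0.55, OXT = 0.25),
            reference = TRUE),
        .ms("deprotonated", 0L, "", c(C = 0.10, O = -0.55, OXT = -0.55)))))
  }
  switch(resid,
    GLU = list(site_class = "carboxyl", pk_mod = .PK_MOD[["carboxyl_glu"]],
      atoms = c("CD", "OE1", "OE2"),
      fragment = c("CB", "CG", "CD", "OE1", "OE2"), fixed = FALSE,
      microstates = list(
        .ms("protonated", 1L, "OE2", c(CD = 0.30, OE1 = -0.55, OE2 = 0.25),
            reference = TRUE),
        .ms("deprotonated", 0L, "", c(CD = 0.10, OE1 = -0.55, OE2 = -0.55)))),
    ASP = list(site_class = "carboxyl", pk_mod = .PK_MOD[["carboxyl_asp"]],
      atoms = c("CG", "OD1", "OD2"),
      fragment = c("CB", "CG", "OD1", "OD2"), fixed = FALSE,
      microstates = list(
        .ms("protonated", 1L, "OD2", c(CG = 0.30, OD1 = -0.55, OD2 = 0.25),
            reference = TRUE),
        .ms("deprotonated", 0L, "", c(CG = 0.10, OD1 = -0.55, OD2 = -0.55)))),
    LYS = list(site_class = "amino", pk_mod = .PK_MOD[["amino"]],
      atoms = c("CE", "NZ"), fragment = c("CB", "CG", "CD", "CE", "NZ"),
      fixed = FALSE,
      microstates = list(
        .ms("neutral", 0L, "", c(CE = 0.25, NZ = -0.25), reference = TRUE),
        .ms("protonated", 1L, "", c(CE = 0.35, NZ = 0.65)))),
    HIS = list(site_class = "imidazole", pk_mod = .PK_MOD[["imidazole"]],
      atoms = c("ND1", "CE1", "NE2"),
      fragment = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"), fixed = FALSE,
      microstates = list(
        .ms("NE2-H", 1L, "NE2", c(ND1 = -0.40, CE1 = 0.30, NE2 = -0.10),
            reference = TRUE),
        .ms("ND1-H", 1L, "ND1", c(ND1 = -0.10, CE1 = 0.30, NE2 = -0.40)),
        .ms("protonated", 2L, "both",
            c(ND1 = 0.10, CE1 = 0.60, NE2 = 0.10)))),
    TYR = list(site_class = "hydroxyl", pk_mod = .PK_MOD[["hydroxyl"]],
      atoms = c("CZ", "OH"),
      fragment = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      fixed = FALSE,
      microstates = list(
        .ms("protonated", 1L, "OH", c(CZ = 0.15, OH = -0.15),
            reference = TRUE),
        .ms("deprotonated", 0L, "", c(CZ = 0.05, OH = -1.05)))),
    ARG = list(site_class = "guanidine", pk_mod = .PK_MOD[["guanidine"]],
      atoms = c("CD", "NE", "CZ", "NH1", "NH2"),
      fragment = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"), fixed = TRUE,
      microstates = list(
        .ms("neutral", 0L, "",
            c(CD = 0.10, NE = -0.30, CZ = 0.50, NH1 = -0.15, NH2 = -0.15),
            reference = TRUE),
        .ms("protonated", 1L, "",
            c(CD = 0.20, NE = -0.10, CZ = 0.70, NH1 = 0.10, NH2 = 0.10)))),
    NULL)
}

## statistical tautomer correction: with n_p protonated and n_d deprotonated
## microstates of equal energy, the macroscopic midpoint of the isolated
## compound sits at pk_std + log10(n_p/n_d); shift pk_std so the midpoint
## equals pk_mod.
.finish_site <- function(def, chain, resid, resno, insert, terminus) {
  pcs <- vapply(def$microstates, `[[`, integer(1), "proton_count")
  n_p <- sum(pcs == max(pcs))
  n_d <- sum(pcs == min(pcs))
  pk_std <- def$pk_mod - log10(n_p / n_d)
  def$microstates <- lapply(def$microstates, function(m) {
    m$pk_std <- pk_std
    m
  })
  ref <- vapply(def$microstates, `[[`, logical(1), "reference")
  stopifnot(sum(ref) == 1, length(def$microstates) >= 2)
  structure(c(list(
    chain = chain, resid = resid, resno = resno, insert = insert,
    terminus = terminus,
    label = if (terminus == "") sprintf("%s:%s%d%s", chain, resid, resno,
                                        insert)
            else sprintf("%s:%s%d:%sT", chain, resid, resno, terminus)),
    def), class = "titratable_site")
}

#' Detect titratable sites in a conformer
#'
#' One site per Asp/Glu/Lys/Arg/His/Tyr side chain plus (optionally) the N-
#' and C-terminal groups of each chain, each with its site class, model pK
#' and protonation-microstate catalogue.  Arginine sites are flagged
#' \code{fixed} (held protonated) by default since the guanidine pK lies far
#' above the usual pH range.  Unknown residue names give a warning and are
#' skipped.  C-terminal sites require an OXT atom.
#'
#' @param conformer a \code{conformer}
#' @param termini_policy \code{"both"} (default) or \code{"none"}.
#' @param fixed_arg hold arginines fixed in their protonated form
#'   (default TRUE).
#' @return list of \code{titratable_site} objects, class \code{site_list}.
#' @export
#' @examples
#' pep <- make_toy_peptide(toy_spec(residues = c("ALA", "GLU", "ALA")))
#' sites <- detect_sites(pep$conformer)
#' vapply(sites, `[[`, character(1), "label")
detect_sites <- function(conformer, termini_policy = c("both", "none"),
                         fixed_arg = TRUE) {
  termini_policy <- match.arg(termini_policy)
  rkey <- paste(conformer$chain, conformer$resno, conformer$insert, sep = "|")
  first <- !duplicated(rkey)
  res <- data.frame(chain = conformer$chain[first],
                    resno = conformer$resno[first],
                    insert = conformer$insert[first],
                    resid = conformer$resid[first],
                    stringsAsFactors = FALSE)
  sites <- list()
  add <- function(s) sites[[length(sites) + 1]] <<- s
  atom_names <- function(i) {
    conformer$elety[rkey == paste(res$chain[i], res$resno[i], res$insert[i],
                                  sep = "|")]
  }
  for (ch in unique(res$chain)) {
    ri <- which(res$chain == ch)
    if (termini_policy == "both") {
      i <- ri[1]
      if (all(c("N", "CA") %in% atom_names(i))) {
        def <- .site_class_def(res$resid[i], terminus = "N")
        add(.finish_site(def, ch, res$resid[i], res$resno[i], res$insert[i],
                         "N"))
      }
    }
    for (i in ri) {
      resid <- res$resid[i]
      if (!(resid %in% .STANDARD_RESID)) {
        warning("unknown residue name, skipped: ", resid, " ", ch,
                res$resno[i])
        next
      }
      def <- .site_class_def(resid)
      if (is.null(def)) next
      if (!all(def$atoms %in% atom_names(i))) {
        warning("titratable residue missing group atoms, skipped: ",
                resid, " ", ch, res$resno[i])
        next
      }
      if (def$site_class == "guanidine") def$fixed <- fixed_arg
      add(.finish_site(def, ch, resid, res$resno[i], res$insert[i], ""))
    }
    if (termini_policy == "both") {
      i <- ri[length(ri)]
      if (all(c("C", "O", "OXT") %in% atom_names(i))) {
        def <- .site_class_def(res$resid[i], terminus = "C")
        add(.finish_site(def, ch, res$resid[i], res$resno[i], res$insert[i],
                         "C"))
      }
    }
  }
  structure(sites, class = "site_list")
}

#' @export
print.site_list <- function(x, ...) {
  cat(sprintf("%d titratable sites:\n", length(x)))
  for (s in x)
    cat(sprintf("  %-16s %-11s pk_mod %.1f%s\n", s$label, s$site_class,
                s$pk_mod, if (isTRUE(s$fixed)) " [fixed]" else ""))
  invisible(x)
}

## row indices of a site's titrating atoms in the conformer, named by atom
.site_atom_idx <- function(conformer, site, atoms = site$atoms) {
  sel <- which(conformer$chain == site$chain &
               conformer$resno == site$resno &
               conformer$insert == site$insert)
  idx <- sel[match(atoms, conformer$elety[sel])]
  names(idx) <- atoms
  idx
}

#' Assign partial charges and radii to a conformer
#'
#' Looks every atom up in the parameter table (residue-specific side-chain
#' rows, \code{BB} backbone rows, \code{CTER}/OXT rows for a residue
#' carrying an OXT atom).  All residues receive their neutral reference
#' protonation form, so each residue's net charge is 0 e.
#'
#' @param conformer a \code{conformer}
#' @param parameter_table data.frame from [read_parameter_table()]
#' @return the conformer with \code{charge} and \code{radius} columns filled.
#' @export
assign_parameters <- function(conformer,
                              parameter_table = read_parameter_table()) {
  pt_key <- paste(parameter_table$residue, parameter_table$atom)
  rkey <- paste(conformer$chain, conformer$resno, conformer$insert, sep = "|")
  has_oxt <- rkey %in% rkey[conformer$elety == "OXT"]
  lookup_res <- conformer$resid
  bb <- conformer$elety %in% c("N", "CA", "C", "O")
  lookup_res[bb] <- "BB"
  cter <- has_oxt & conformer$elety %in% c("C", "O", "OXT")
  lookup_res[cter] <- "CTER"
  m <- match(paste(lookup_res, conformer$elety), pt_key)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unresolvable atom in parameter table: %s %s%d atom %s",
                 conformer$resid[bad], conformer$chain[bad],
                 conformer$resno[bad], conformer$elety[bad]))
  }
  conformer$charge <- parameter_table$charge[m]
  conformer$radius <- parameter_table$radius[m]
  conformer
}

#' Net charge per residue
#' @param conformer a parameterised \code{conformer}
#' @return data.frame with chain, resno, insert, resid, net charge
#' @export
residue_net_charge <- function(conformer) {
  if (is.null(conformer$charge)) stop("conformer has no charges assigned")
  key <- paste(conformer$chain, conformer$resno, conformer$insert, sep = "|")
  agg <- tapply(conformer$charge, key, sum)
  first <- !duplicated(key)
  out <- data.frame(chain = conformer$chain[first],
                    resno = conformer$resno[first],
                    insert = conformer$insert[first],
                    resid = conformer$resid[first],
                    stringsAsFactors = FALSE)
  out$net_charge <- as.numeric(agg[paste(out$chain, out$resno, out$insert,
                                         sep = "|")])
  out
}

## the microstate a site adopts under a fixed protonation regime
.regime_microstate <- function(site, regime) {
  pcs <- vapply(site$microstates, `[[`, integer(1), "proton_count")
  charged_idx <- switch(site$site_class,
    carboxyl   = ,
    hydroxyl   = ,
    c_terminus = which.min(pcs),   # charged form = deprotonated
    which.max(pcs))                # bases: charged form = protonated
  neutral_idx <- which(vapply(site$microstates, `[[`, logical(1),
                              "reference"))
  if (site$site_class == "hydroxyl") return(neutral_idx)  # Tyr kept neutral
  if (regime == "glu0" && site$resid == "GLU" && site$terminus == "")
    return(neutral_idx)
  if (regime == "lys0" && site$site_class == "amino" && site$terminus == "")
    return(neutral_idx)
  charged_idx
}

#' Overlay a fixed protonation regime onto a conformer's charges
#'
#' Replaces the charges of every titratable group by the microstate the
#' regime dictates (\code{allC}: all groups charged, tyrosines neutral;
#' \code{glu0}: glutamates neutral, rest charged; \code{lys0}: lysines
#' neutral, rest charged).  Used for formal-charge bookkeeping and by the
#' fixture generators; the pK machinery itself always works relative to the
#' all-neutral reference state.
#'
#' @param conformer parameterised \code{conformer}
#' @param sites \code{site_list} from [detect_sites()]
#' @param regime \code{"allC"}, \code{"glu0"} or \code{"lys0"}
#' @return conformer with overlaid charges; attribute
#'   \code{formal_charge} gives the implied integer total charge.
#' @export
apply_protonation <- function(conformer, sites,
                              regime = c("allC", "glu0", "lys0")) {
  regime <- match.arg(regime)
  formal <- 0L
  for (s in sites) {
    mi <- .regime_microstate(s, regime)
    ms <- s$microstates[[mi]]
    idx <- .site_atom_idx(conformer, s)
    conformer$charge[idx] <- ms$charges[names(idx)]
    grp <- sum(ms$charges)
    formal <- formal + as.integer(round(grp))
  }
  attr(conformer, "formal_charge") <- formal
  conformer
}
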