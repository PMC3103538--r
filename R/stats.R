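## stats_report: accuracy (deviation from experiment, Null model) and
## precision (chain-pair delta-pK) statistics.

#' Bundled reference pK table for the GCN4 leucine zipper
#'
#' Chain-averaged pK(1/2) values for the 16 titratable sites of the
#' 33-residue GCN4 leucine-zipper homodimer: model-compound pK
#' (\code{pk_mod}), single-crystal-structure calculation (\code{xray}),
#' single-regime ensemble calculation (\code{allc}), combined multi-regime
#' calculation (\code{fullmd}) and the experimental NMR values (\code{exp}).
#'
#' @return data.frame with columns \code{site, pk_mod, xray, allc, fullmd,
#'   exp}
#' @export
#' @examples
#' tab <- gcn4_reference_table()
#' mean_abs_dev(tab$pk_mod, tab$exp)   # accuracy of the Null model
gcn4_reference_table <- function() {
  read_pk_table(system.file("extdata", "gcn4_pk_reference.tsv",
                            package = "multipk"))
}

#' Read a tab-separated pK table
#' @param path file with a \code{site} column plus numeric pK columns
#' @return data.frame
#' @export
read_pk_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

.check_cols <- function(a, b) {
  if (length(a) != length(b))
    stop("columns must be aligned on the same sites")
  if (anyNA(a) || anyNA(b)) stop("missing entries in pK columns")
  invisible(TRUE)
}

#' Mean absolute deviation between two pK columns
#'
#' \eqn{(1/n) \sum |a_i - b_i|}, the accuracy summary used for comparing
#' calculated and experimental pK values.
#'
#' @param column_a,column_b numeric vectors aligned on the same sites
#' @return mean absolute deviation, pH units
#' @export
mean_abs_dev <- function(column_a, column_b) {
  .check_cols(column_a, column_b)
  mean(abs(column_a - column_b))
}

#' Root-mean-square deviation between two pK columns
#'
#' @inheritParams mean_abs_dev
#' @param denominator \code{"n"} (default) or \code{"n-1"}
#' @return rmsd, pH units
#' @export
rmsd <- function(column_a, column_b, denominator = c("n", "n-1")) {
  .check_cols(column_a, column_b)
  denominator <- match.arg(denominator)
  n <- length(column_a)
  d <- if (denominator == "n") n else n - 1
  sqrt(sum((column_a - column_b)^2) / d)
}

#' Chain-pair delta-pK summary for a homodimer
#'
#' For every homologous site pair, the signed difference
#' \eqn{\Delta pK_i = pK_{1/2,i}(chain A) - pK_{1/2,i}(chain B)} plus the
#' mean absolute value |dpK|_av -- the precision measure: symmetry demands
#' zero.
#'
#' @param pk_results data.frame with columns \code{site} (chain-independent
#'   site key), \code{chain} (exactly two chains) and \code{pk}
#' @return list with \code{per_site} (data.frame site, delta_pk) and
#'   \code{mean_abs} (|dpK|_av)
#' @export
chain_delta_summary <- function(pk_results) {
  stopifnot(all(c("site", "chain", "pk") %in% names(pk_results)))
  chains <- sort(unique(pk_results$chain))
  if (length(chains) != 2)
    stop("chain_delta_summary expects exactly two chains")
  a <- pk_results[pk_results$chain == chains[1], ]
  b <- pk_results[pk_results$chain == chains[2], ]
  unpaired <- union(setdiff(a$site, b$site), setdiff(b$site, a$site))
  if (length(unpaired))
    stop("unpaired site(s): ", paste(unpaired, collapse = ", "))
  a <- a[order(a$site), ]
  b <- b[order(b$site), ]
  per_site <- data.frame(site = a$site, delta_pk = a$pk - b$pk,
                         stringsAsFactors = FALSE)
  list(per_site = per_site, mean_abs = mean(abs(per_site$delta_pk)))
}

#' Null-model pK column
#'
#' Predicts every site's pK as its model-compound (standard) value -- the
#' structure-free accuracy baseline.
#'
#' @param sites a \code{site_list} or a data.frame carrying a \code{pk_mod}
#'   column
#' @return named numeric vector of pk_mod per site
#' @export
null_model <- function(sites) {
  if (is.data.frame(sites)) {
    v <- sites$pk_mod
    names(v) <- if (!is.null(sites$site)) sites$site else
      rownames(sites)
    return(v)
  }
  stats::setNames(vapply(sites, `[[`, numeric(1), "pk_mod"),
                  vapply(sites, `[[`, character(1), "label"))
}

#' Accuracy report for a pK table
#'
#' Mean absolute deviation and rmsd of every calculated column against the
#' experimental column, sites lacking experimental values excluded pairwise
#' (count reported).
#'
#' @param pk_table data.frame with a \code{site} column, calculated pK
#'   columns and an experimental column
#' @param exp_column name of the experimental column (default "exp")
#' @param denominator rmsd denominator policy, see [rmsd()]
#' @return data.frame with one row per calculated column: n, mean_abs_dev,
#'   rmsd
#' @export
pk_accuracy_report <- function(pk_table, exp_column = "exp",
                               denominator = "n") {
  stopifnot(exp_column %in% names(pk_table))
  num_cols <- setdiff(names(pk_table)[vapply(pk_table, is.numeric,
                                             logical(1))], exp_column)
  rows <- lapply(num_cols, function(cn) {
    ok <- !is.na(pk_table[[cn]]) & !is.na(pk_table[[exp_column]])
    data.frame(column = cn, n = sum(ok),
               mean_abs_dev = mean_abs_dev(pk_table[[cn]][ok],
                                           pk_table[[exp_column]][ok]),
               rmsd = rmsd(pk_table[[cn]][ok], pk_table[[exp_column]][ok],
                           denominator),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a pK report with stable formatting
#'
#' Sites sorted, 2-decimal display columns, byte-stable for identical
#' inputs.
#'
#' @param pk_table data.frame with a \code{site} column and numeric columns
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pk_report <- function(pk_table, path) {
  tab <- pk_table[order(pk_table$site), , drop = FALSE]
  for (cn in names(tab))
    if (is.numeric(tab[[cn]])) tab[[cn]] <- sprintf("%.2f", tab[[cn]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
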