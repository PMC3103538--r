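## multiph_combine: snapshot averaging, pH-dependent regime weights,
## regime combination and pK(1/2) extraction.

#' Construct a titration curve
#' @param pH pH grid
#' @param value tracked population at each pH (in `[0,1]`)
#' @param site_label site identifier
#' @param pk_mod model pK of the site (used to resolve multimodal curves)
#' @param site_class site class string
#' @param regime regime tag
#' @param M number of snapshots averaged into the curve
#' @param tracked which form the value tracks (default "protonated")
#' @return data.frame of class \code{titration_curve}
#' @export
new_titration_curve <- function(pH, value, site_label = "",
                                pk_mod = NA_real_, site_class = "",
                                regime = "single", M = 1L,
                                tracked = "protonated") {
  if (any(value < -1e-9 | value > 1 + 1e-9))
    stop("titration curve values must lie in [0, 1]")
  structure(data.frame(pH = pH, value = pmin(pmax(value, 0), 1)),
            class = c("titration_curve", "data.frame"),
            site_label = site_label, pk_mod = pk_mod,
            site_class = site_class, regime = regime, M = M,
            tracked = tracked)
}

.same_grid <- function(a, b) isTRUE(all.equal(a$pH, b$pH))

#' Arithmetic snapshot average of titration curves
#'
#' Pointwise mean of per-snapshot curves for one site; the number of
#' snapshots M is recorded on the result.
#'
#' @param curves list of \code{titration_curve}s sharing pH grid and site
#' @return averaged \code{titration_curve}
#' @export
ensemble_average <- function(curves) {
  stopifnot(length(curves) >= 1)
  ref <- curves[[1]]
  for (cv in curves[-1])
    if (!.same_grid(ref, cv)) stop("curves must share the same pH grid")
  vals <- rowMeans(vapply(curves, function(cv) cv$value,
                          numeric(nrow(ref))))
  new_titration_curve(ref$pH, vals,
                      site_label = attr(ref, "site_label"),
                      pk_mod = attr(ref, "pk_mod"),
                      site_class = attr(ref, "site_class"),
                      regime = attr(ref, "regime"),
                      M = sum(vapply(curves, function(cv)
                        as.integer(attr(cv, "M")), integer(1))),
                      tracked = attr(ref, "tracked"))
}

#' pH-dependent regime weights
#'
#' The weight of the acidic-regime ensemble (glu0) follows the average
#' protonation of the carboxyl groups computed from that ensemble,
#' \eqn{W_{glu0} = 1 - \bar\theta_{carb}}; the basic-regime weight follows
#' the average deprotonation of the amino groups from the lys0 ensemble,
#' \eqn{W_{lys0} = \bar\theta_{amino}}; the neutral-regime weight makes the
#' three sum to one, \eqn{W_{allC} = 1 - W_{glu0} - W_{lys0}}, clamped at
#' zero with renormalisation should the two defining curves overlap (the
#' clamping is recorded in the \code{clamped} attribute).  In the acidic
#' limit glu0 has weight one, at neutral pH allC, in the basic limit lys0.
#'
#' @param theta_carboxyl \code{titration_curve} (or data.frame pH,value):
#'   mean degree of deprotonation of the carboxyl groups in the glu0
#'   ensemble
#' @param theta_amino mean degree of deprotonation of the amino groups in
#'   the lys0 ensemble, same pH grid
#' @return data.frame of class \code{regime_weights} with columns
#'   \code{pH, allC, glu0, lys0}; rows sum to 1
#' @export
regime_weights <- function(theta_carboxyl, theta_amino) {
  if (!.same_grid(theta_carboxyl, theta_amino))
    stop("theta curves must share the same pH grid")
  tc <- theta_carboxyl$value
  ta <- theta_amino$value
  if (any(tc < -1e-9 | tc > 1 + 1e-9 | ta < -1e-9 | ta > 1 + 1e-9))
    stop("theta values must lie in [0, 1]")
  w_glu0 <- 1 - tc
  w_lys0 <- ta
  w_allc <- 1 - w_glu0 - w_lys0
  clamped <- any(w_allc < 0)
  w_allc <- pmax(w_allc, 0)
  tot <- w_allc + w_glu0 + w_lys0
  structure(data.frame(pH = theta_carboxyl$pH, allC = w_allc / tot,
                       glu0 = w_glu0 / tot, lys0 = w_lys0 / tot),
            class = c("regime_weights", "data.frame"), clamped = clamped)
}

#' Convex combination of regime-averaged titration curves
#'
#' @param curves_by_regime named list with components \code{allC},
#'   \code{glu0}, \code{lys0} (regime-averaged \code{titration_curve}s of
#'   one site); a single-regime run may pass just one curve together with
#'   \code{single_regime = TRUE}
#' @param weights \code{regime_weights} on the same pH grid
#' @param single_regime return the lone provided curve untouched
#' @return combined \code{titration_curve}
#' @export
combine_regimes <- function(curves_by_regime, weights,
                            single_regime = FALSE) {
  if (single_regime) {
    stopifnot(length(curves_by_regime) == 1)
    return(curves_by_regime[[1]])
  }
  need <- c("allC", "glu0", "lys0")
  if (!all(need %in% names(curves_by_regime)))
    stop("missing regime curve(s): ",
         paste(setdiff(need, names(curves_by_regime)), collapse = ", "))
  ref <- curves_by_regime$allC
  v <- numeric(nrow(ref))
  for (s in need) {
    cv <- curves_by_regime[[s]]
    if (!.same_grid(ref, cv) || !isTRUE(all.equal(weights$pH, ref$pH)))
      stop("curves and weights must share the same pH grid")
    v <- v + weights[[s]] * cv$value
  }
  new_titration_curve(ref$pH, v, site_label = attr(ref, "site_label"),
                      pk_mod = attr(ref, "pk_mod"),
                      site_class = attr(ref, "site_class"),
                      regime = "combined",
                      M = attr(ref, "M"), tracked = attr(ref, "tracked"))
}

#' pK(1/2): midpoint of a titration curve
#'
#' The pH at which the tracked population crosses 0.5, located by linear
#' interpolation between the bracketing grid points.  With several
#' crossings the one nearest the site's model pK is returned and the
#' \code{multimodal} attribute set; with none, NA with the
#' \code{out_of_range} attribute set.
#'
#' @param curve \code{titration_curve}
#' @param ref_pk pK used to resolve multiple crossings (defaults to the
#'   curve's \code{pk_mod} attribute, else the grid midpoint)
#' @return numeric pK value (NA if the curve never crosses 0.5) with
#'   attributes \code{multimodal} and \code{out_of_range}
#' @export
pk_half <- function(curve, ref_pk = NULL) {
  v <- curve$value - 0.5
  pH <- curve$pH
  if (is.null(ref_pk)) {
    ref_pk <- attr(curve, "pk_mod")
    if (is.null(ref_pk) || is.na(ref_pk)) ref_pk <- mean(range(pH))
  }
  hit <- which(v == 0)
  cross <- which(v[-length(v)] * v[-1] < 0)
  pks <- c(pH[hit],
           pH[cross] + (pH[cross + 1] - pH[cross]) *
             (-v[cross]) / (v[cross + 1] - v[cross]))
  if (length(pks) == 0)
    return(structure(NA_real_, multimodal = FALSE, out_of_range = TRUE))
  structure(pks[which.min(abs(pks - ref_pk))],
            multimodal = length(pks) > 1, out_of_range = FALSE)
}
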