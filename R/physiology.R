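#' Intrinsic water-use efficiency
#'
#' iWUE = A_n / g_s, umol CO2 mol-1 H2O. Vectorized.
#'
#' @param A_n Net CO2 assimilation, umol m-2 s-1.
#' @param g_s Stomatal conductance to water vapour, mol m-2 s-1; must be
#'   strictly positive where A_n is non-missing.
#' @return iWUE, umol CO2 mol-1 H2O.
#' @export
compute_iwue <- function(A_n, g_s) {
  bad <- !is.na(g_s) & g_s <= 0 & !is.na(A_n)
  if (any(bad)) stop("iWUE undefined: g_s <= 0 with A_n present")
  A_n / g_s
}

#' Leaf hydraulic conductance by the evaporative-flux method
#'
#' K_leaf = E / (psi_stem - psi_midday). Water potentials are signed
#' (negative) MPa; a transpiring leaf sits below the stem, so the
#' difference is positive. Rows with a zero or reversed gradient return
#' `NA` with a warning (a measurement artefact, not an exception), so
#' batch runs keep going.
#'
#' @param E Transpiration, mmol H2O m-2 s-1.
#' @param psi_stem,psi_midday Stem and midday leaf water potential, MPa.
#' @return K_leaf, mmol m-2 s-1 MPa-1.
#' @export
compute_K_leaf <- function(E, psi_stem, psi_midday) {
  .conductance(E, psi_stem, psi_midday, "psi_stem <= psi_midday")
}

#' Soil-to-leaf (plant) hydraulic conductance
#'
#' K_plant = E / (psi_predawn - psi_midday); same conventions and
#' degenerate-gradient handling as [compute_K_leaf()].
#'
#' @param E Transpiration, mmol H2O m-2 s-1.
#' @param psi_predawn,psi_midday Pre-dawn and midday water potential, MPa.
#' @return K_plant, mmol m-2 s-1 MPa-1.
#' @export
compute_K_plant <- function(E, psi_predawn, psi_midday) {
  .conductance(E, psi_predawn, psi_midday, "psi_predawn <= psi_midday")
}

.conductance <- function(E, psi_hi, psi_lo, what) {
  dpsi <- psi_hi - psi_lo
  bad <- !is.na(dpsi) & dpsi <= 0 & !is.na(E)
  if (any(bad)) {
    warning(sum(bad), " row(s) with ", what,
            " (reversed or zero gradient): conductance set to NA",
            call. = FALSE)
  }
  out <- E / dpsi
  out[bad] <- NA_real_
  out
}

#' Split whole-plant hydraulic resistance into leaf and rest
#'
#' R_leaf = 1/K_leaf and R_rest = 1/K_plant - R_leaf, so the serial
#' identity 1/K_plant = R_leaf + R_rest holds exactly. A negative R_rest
#' (K_leaf < K_plant, physically impossible in series) is returned but
#' flagged with a warning.
#'
#' @param K_leaf,K_plant Conductances, mmol m-2 s-1 MPa-1; must be > 0.
#' @return Data.frame with `R_leaf` and `R_rest`, MPa s m2 mmol-1.
#' @export
decompose_resistances <- function(K_leaf, K_plant) {
  ok <- is.na(K_leaf) | is.na(K_plant)
  if (any(K_leaf[!ok] <= 0) || any(K_plant[!ok] <= 0)) {
    stop("conductances must be strictly positive")
  }
  R_leaf <- 1 / K_leaf
  R_rest <- 1 / K_plant - R_leaf
  neg <- !is.na(R_rest) & R_rest < 0
  if (any(neg)) {
    warning(sum(neg), " row(s) with negative R_rest ",
            "(K_leaf < K_plant: inconsistent measurements)", call. = FALSE)
  }
  data.frame(R_leaf = R_leaf, R_rest = R_rest)
}

#' Interpolate transpiration at a given light level
#'
#' Piecewise-linear interpolation of E over PPFD-sorted light-response
#' points, used to estimate the transpiration rate at the PPFD incident at
#' leaf excision. Extrapolation beyond the measured PPFD range is refused
#' unless explicitly enabled (it then extends the terminal segments).
#'
#' @param ppfd PPFD values of the curve points, umol m-2 s-1.
#' @param E Transpiration values at those points, mmol m-2 s-1.
#' @param target PPFD at excision.
#' @param extrapolate Allow extrapolation outside the point range.
#' @return Interpolated E.
#' @export
interpolate_E_at_ppfd <- function(ppfd, E, target, extrapolate = FALSE) {
  stopifnot(length(ppfd) == length(E), length(ppfd) >= 2)
  o <- order(ppfd)
  ppfd <- ppfd[o]; E <- E[o]
  out_of_range <- target < min(ppfd) | target > max(ppfd)
  if (any(out_of_range) && !extrapolate) {
    stop("target PPFD outside [", min(ppfd), ", ", max(ppfd),
         "]; enable extrapolate to extend the terminal segments")
  }
  rule <- if (extrapolate) 2 else 1
  y <- stats::approx(ppfd, E, xout = target, rule = rule, ties = mean)$y
  if (extrapolate && any(out_of_range)) {
    # linear extension of the terminal segment rather than approx's
    # constant rule
    for (j in which(out_of_range)) {
      if (target[j] < ppfd[1]) {
        sl <- (E[2] - E[1]) / (ppfd[2] - ppfd[1])
        y[j] <- E[1] + sl * (target[j] - ppfd[1])
      } else {
        n <- length(ppfd)
        sl <- (E[n] - E[n - 1]) / (ppfd[n] - ppfd[n - 1])
        y[j] <- E[n] + sl * (target[j] - ppfd[n])
      }
    }
  }
  y
}

#' Leaf mass per area from oven-dried discs
#'
#' LMA = DW / area, g m-2.
#'
#' @param DW Disc dry weight, g.
#' @param area Disc area, m2 (> 0).
#' @return LMA, g m-2.
#' @export
compute_LMA <- function(DW, area) {
  if (any(!is.na(area) & area <= 0)) stop("disc area must be > 0")
  DW / area
}

#' Relative water content of leaf discs
#'
#' RWC = (FW - DW) / (TW - DW), as a fraction (default) or percent.
#'
#' @param FW,TW,DW Fresh, turgid and dry disc weights, g; TW must exceed
#'   DW.
#' @param percent Report as percent rather than fraction.
#' @return RWC.
#' @export
compute_RWC <- function(FW, TW, DW, percent = FALSE) {
  if (any(!is.na(TW) & !is.na(DW) & TW == DW)) {
    stop("RWC undefined: turgid weight equals dry weight")
  }
  out <- (FW - DW) / (TW - DW)
  if (percent) out * 100 else out
}

#' Append derived physiological columns to a record table
#'
#' Adds iwue, K_leaf, K_plant, R_leaf, R_rest, LMA and RWC (percent)
#' wherever the underlying measurements are present; rows lacking inputs
#' get `NA` for the corresponding derived trait.
#'
#' @param records Plant record data.frame.
#' @return `records` with derived columns appended.
#' @export
derive_physiology <- function(records) {
  r <- records
  ok_gs <- !is.na(r$g_s) & r$g_s > 0
  r$iwue <- NA_real_
  r$iwue[ok_gs] <- r$A_n[ok_gs] / r$g_s[ok_gs]
  r$K_leaf <- compute_K_leaf(r$E, r$psi_stem, r$psi_midday)
  r$K_plant <- compute_K_plant(r$E, r$psi_predawn, r$psi_midday)
  res <- suppressWarnings(
    decompose_resistances(pmax(r$K_leaf, .Machine$double.eps),
                          pmax(r$K_plant, .Machine$double.eps)))
  res$R_leaf[is.na(r$K_leaf)] <- NA_real_
  res$R_rest[is.na(r$K_leaf) | is.na(r$K_plant)] <- NA_real_
  r$R_leaf <- res$R_leaf
  r$R_rest <- res$R_rest
  if (all(c("disc_DW", "disc_area") %in% names(r))) {
    r$LMA <- compute_LMA(r$disc_DW, r$disc_area)
  }
  if (all(c("disc_FW", "disc_TW", "disc_DW") %in% names(r))) {
    ok <- !is.na(r$disc_TW) & !is.na(r$disc_DW) & r$disc_TW > r$disc_DW
    r$RWC <- NA_real_
    r$RWC[ok] <- compute_RWC(r$disc_FW[ok], r$disc_TW[ok], r$disc_DW[ok],
                             percent = TRUE)
  }
  r
}
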