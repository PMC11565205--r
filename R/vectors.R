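#' Phenotypic-change vectors in the A_n-C_i plane
#'
#' For each genotype with means in both treatments, computes the change
#' vector from well-watered to water-stressed conditions:
#' `delta_A_n = A_n(WW) - A_n(WS)`, `delta_C_i = C_i(WW) - C_i(WS)` (so
#' stress reducing both gives positive deltas), its Euclidean magnitude,
#' and its direction `theta = atan2(delta_A_n, delta_C_i)` in degrees.
#' A small theta means C_i fell much more than A_n (capacity maintained
#' under stress: the drought-resilient direction); theta near 90 means
#' A_n collapsed along with C_i. The two-argument arctangent handles
#' negative deltas continuously; rows where C_i rose under stress
#' (negative delta_C_i) are flagged.
#'
#' @param means Genotype x treatment means with `A_n` and `C_i` columns.
#' @param standardize Divide each delta by the across-genotype SD of that
#'   delta before computing magnitude and theta (unit-safe variant;
#'   default off, matching raw-scale vector analysis).
#' @return Data.frame per genotype: deltas, `magnitude`, `theta`
#'   (degrees), and a `flag_negative_dci` column. Genotypes missing a
#'   trait in either treatment are dropped with a warning.
#' @export
change_vectors <- function(means, standardize = FALSE) {
  ww <- means[means$treatment == "WW", c("genotype_id", "A_n", "C_i")]
  ws <- means[means$treatment == "WS", c("genotype_id", "A_n", "C_i")]
  m <- merge(ww, ws, by = "genotype_id", suffixes = c("_ww", "_ws"))
  ok <- stats::complete.cases(m[, -1])
  if (any(!ok)) {
    warning(sum(!ok), " genotype(s) dropped: A_n or C_i missing in one ",
            "treatment", call. = FALSE)
    m <- m[ok, , drop = FALSE]
  }
  d_an <- m$A_n_ww - m$A_n_ws
  d_ci <- m$C_i_ww - m$C_i_ws
  if (standardize) {
    d_an <- d_an / stats::sd(d_an)
    d_ci <- d_ci / stats::sd(d_ci)
  }
  out <- data.frame(genotype_id = m$genotype_id,
                    delta_A_n = d_an, delta_C_i = d_ci,
                    magnitude = sqrt(d_an^2 + d_ci^2),
                    theta = atan2(d_an, d_ci) * 180 / pi,
                    flag_negative_dci = d_ci < 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Association between theta and the shift in iWUE components
#'
#' Tests whether the direction of the stress-response vector tracks the
#' change in each iWUE component from WW to WS: Pearson correlation of
#' theta with `delta_iwue_pc(WS) - delta_iwue_pc(WW)` and with
#' `delta_iwue_gs(WS) - delta_iwue_gs(WW)` across genotypes present in
#' both treatments. Genotypes that gain capacity-driven iWUE under stress
#' are expected to have lower theta (negative correlation).
#'
#' @param vectors Output of [change_vectors()].
#' @param partition Output of [partition_iwue()] covering both treatments.
#' @return Data.frame with one row per component: r, r-squared, n,
#'   two-sided p.
#' @export
theta_component_association <- function(vectors, partition) {
  ww <- partition[partition$treatment == "WW",
                  c("genotype_id", "delta_iwue_gs", "delta_iwue_pc")]
  ws <- partition[partition$treatment == "WS",
                  c("genotype_id", "delta_iwue_gs", "delta_iwue_pc")]
  m <- merge(ww, ws, by = "genotype_id", suffixes = c("_ww", "_ws"))
  m <- merge(vectors[, c("genotype_id", "theta")], m, by = "genotype_id")
  if (nrow(m) < 3) stop("fewer than 3 genotypes matched in both treatments")
  dd_pc <- m$delta_iwue_pc_ws - m$delta_iwue_pc_ww
  dd_gs <- m$delta_iwue_gs_ws - m$delta_iwue_gs_ww
  row <- function(component, y) {
    ct <- pearson(m$theta, y)
    data.frame(component = component, r = ct$r, r_squared = ct$r_squared,
               n = ct$n, p = ct$p, stringsAsFactors = FALSE)
  }
  rbind(row("delta_delta_iwue_pc", dd_pc),
        row("delta_delta_iwue_gs", dd_gs))
}
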