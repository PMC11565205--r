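#' Fit a reference iWUE-g_s curve
#'
#' The reference curve describes how iWUE would vary with g_s alone, and
#' is the yardstick against which each genotype's observed iWUE is split
#' into a stomatal and a photosynthetic-capacity component. Two forms:
#'
#' * `"power"` (default): iWUE = a * g_s^b, fitted by least squares on
#'   log iWUE vs log g_s across all retained observations of both
#'   treatments. Must come out decreasing (b < 0).
#' * `"constant_A"`: iWUE = A_ref / g_s with A_ref the mean assimilation
#'   rate of the fitting set - the literal "constant A_n" yardstick. This
#'   is the b = -1 special case of the power form.
#'
#' @param g_s Stomatal conductances (> 0) of the fitting set.
#' @param iwue Matching iWUE values (> 0 for the power form).
#' @param form `"power"` or `"constant_A"`.
#' @param A_n Assimilation rates, required for `"constant_A"`; if absent
#'   they are recovered as iwue * g_s.
#' @return Object of class `reference_curve`: parameters, fit domain,
#'   R-squared and n.
#' @export
fit_reference_curve <- function(g_s, iwue, form = c("power", "constant_A"),
                                A_n = NULL) {
  form <- match.arg(form)
  keep <- !is.na(g_s) & !is.na(iwue)
  g_s <- g_s[keep]; iwue <- iwue[keep]
  if (length(g_s) < 5) stop("need at least 5 observations to fit a curve")
  if (any(g_s <= 0)) stop("all g_s must be > 0")
  if (form == "power") {
    if (any(iwue <= 0)) stop("power form needs iwue > 0")
    fit <- stats::lm(log(iwue) ~ log(g_s))
    b <- unname(stats::coef(fit)[2])
    a <- exp(unname(stats::coef(fit)[1]))
    if (b >= 0) {
      stop("fitted power curve is non-decreasing (b = ", signif(b, 3),
           "); try form = 'constant_A'")
    }
    pars <- c(a = a, b = b)
  } else {
    if (is.null(A_n)) A_n <- iwue * g_s else A_n <- A_n[keep]
    pars <- c(A_ref = mean(A_n, na.rm = TRUE))
  }
  pred <- .eval_curve(pars, form, g_s)
  ss_res <- sum((iwue - pred)^2)
  ss_tot <- sum((iwue - mean(iwue))^2)
  structure(list(form = form, parameters = pars,
                 domain = range(g_s),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(g_s)),
            class = "reference_curve")
}

.eval_curve <- function(pars, form, g_s) {
  if (form == "power") pars[["a"]] * g_s^pars[["b"]]
  else pars[["A_ref"]] / g_s
}

#' Evaluate a reference curve
#'
#' @param object A `reference_curve`.
#' @param g_s Conductances at which to evaluate; values outside the fit
#'   domain are evaluated but flagged via the `"extrapolated"` attribute.
#' @param ... Unused.
#' @return Predicted iWUE with attribute `extrapolated` (logical vector).
#' @export
predict.reference_curve <- function(object, g_s, ...) {
  out <- .eval_curve(object$parameters, object$form, g_s)
  attr(out, "extrapolated") <-
    !is.na(g_s) & (g_s < object$domain[1] | g_s > object$domain[2])
  out
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("Reference iWUE-g_s curve (", x$form, ")\n", sep = "")
  cat("  parameters:",
      paste(names(x$parameters), signif(x$parameters, 6), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  domain: g_s in [%.4g, %.4g]; R^2 = %.4f; n = %d\n",
              x$domain[1], x$domain[2], x$r_squared, x$n))
  invisible(x)
}

#' Partition iWUE into stomatal and capacity components
#'
#' For each genotype x treatment mean, the curve value at the genotype's
#' g_s gives the iWUE expected from conductance alone (iWUE_calc). The
#' stomatal component is its deviation from the treatment-mean iWUE,
#' `delta_iwue_gs = iWUE_calc - mean(iWUE | treatment)`, and the capacity
#' (non-stomatal) component is the remainder,
#' `delta_iwue_pc = iWUE_obs - iWUE_calc`, so the two always add to the
#' genotype's total deviation from the treatment mean.
#'
#' @param means Genotype x treatment means (from [aggregate_means()] after
#'   exclusion filtering) with columns `g_s` and `iwue`.
#' @param curve A [fit_reference_curve()] object.
#' @param treatment_means Optional named vector of treatment-mean iWUE;
#'   computed from `means` (mean over genotype means per treatment) when
#'   omitted.
#' @return Data.frame per genotype x treatment: `iwue_obs`, `iwue_calc`,
#'   `treatment_mean_iwue`, `delta_iwue_gs`, `delta_iwue_pc` and an
#'   `extrapolated` flag.
#' @export
partition_iwue <- function(means, curve, treatment_means = NULL) {
  stopifnot(inherits(curve, "reference_curve"),
            all(c("g_s", "iwue") %in% names(means)))
  if (is.null(treatment_means)) {
    treatment_means <- tapply(means$iwue, means$treatment, mean,
                              na.rm = TRUE)
  }
  calc <- predict(curve, means$g_s)
  tm <- unname(treatment_means[means$treatment])
  out <- data.frame(genotype_id = means$genotype_id,
                    treatment = means$treatment,
                    g_s = means$g_s,
                    iwue_obs = means$iwue,
                    iwue_calc = as.numeric(calc),
                    treatment_mean_iwue = tm,
                    stringsAsFactors = FALSE)
  out$delta_iwue_gs <- out$iwue_calc - out$treatment_mean_iwue
  out$delta_iwue_pc <- out$iwue_obs - out$iwue_calc
  out$extrapolated <- attr(calc, "extrapolated")
  out
}

#' Agreement between partitions under two reference curves
#'
#' Partitions the same means with two fitted curves (e.g. the global curve
#' versus one fitted on a single reference genotype) and reports the
#' Pearson correlation between the component values per component,
#' together with the paired values for inspection.
#'
#' @param means Genotype x treatment means with `g_s` and `iwue`.
#' @param curve_a,curve_b Two `reference_curve` objects fitted on the same
#'   observation set or a subset of it.
#' @param treatment_means Optional treatment-mean override passed through.
#' @return List with `agreement` (per-component r, r-squared, n, p) and
#'   `scatter` (paired component values).
#' @export
compare_reference_choices <- function(means, curve_a, curve_b,
                                      treatment_means = NULL) {
  pa <- partition_iwue(means, curve_a, treatment_means)
  pb <- partition_iwue(means, curve_b, treatment_means)
  comp <- function(col) {
    ct <- pearson(pa[[col]], pb[[col]])
    data.frame(component = col, r = ct$r, r_squared = ct$r_squared,
               n = ct$n, p = ct$p, stringsAsFactors = FALSE)
  }
  agreement <- rbind(comp("delta_iwue_gs"), comp("delta_iwue_pc"))
  scatter <- data.frame(genotype_id = pa$genotype_id,
                        treatment = pa$treatment,
                        gs_a = pa$delta_iwue_gs, gs_b = pb$delta_iwue_gs,
                        pc_a = pa$delta_iwue_pc, pc_b = pb$delta_iwue_pc,
                        stringsAsFactors = FALSE)
  list(agreement = agreement, scatter = scatter)
}

#' Fit a reference curve from a single reference genotype
#'
#' Convenience wrapper: fits the chosen form on the replicate observations
#' of one genotype only (both treatments), as an alternative yardstick to
#' the global curve.
#'
#' @param records Replicate-level records with `g_s` and `iwue` columns
#'   (see [derive_physiology()]).
#' @param genotype_id Reference genotype.
#' @param form Curve form, as in [fit_reference_curve()].
#' @return A `reference_curve`.
#' @export
fit_genotype_reference_curve <- function(records, genotype_id,
                                         form = c("power", "constant_A")) {
  sub <- records[records$genotype_id == genotype_id &
                   !is.na(records$g_s) & !is.na(records$iwue), ]
  if (nrow(sub) < 3) {
    stop("reference genotype '", genotype_id,
         "' has fewer than 3 usable observations")
  }
  if (nrow(sub) < 5) {
    # the generic fitter wants >= 5 points; a single genotype may have 6
    # (3 reps x 2 treatments) but can drop below after filtering
    stop("reference genotype '", genotype_id,
         "' has too few observations to fit a curve")
  }
  fit_reference_curve(sub$g_s, sub$iwue, form = form, A_n = sub$A_n)
}
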