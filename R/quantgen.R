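#' Two-way fixed-effects ANOVA with interaction
#'
#' Classical genotype x treatment decomposition of a trait measured on
#' replicate plants. For a balanced design the sums of squares are the
#' textbook ones; an unbalanced design (after missing-value removal)
#' drops to an unweighted-means analysis on cell means with the harmonic
#' mean cell size, with a warning. F statistics test each source against
#' the residual mean square; with a zero residual MS the F and p are
#' reported as `NA`.
#'
#' @param data Data.frame of replicate observations.
#' @param trait Response column name.
#' @param factor_a,factor_b Factor column names (default genotype and
#'   treatment).
#' @return Data.frame of class `anova_table`: one row per source
#'   (factor_a, factor_b, interaction, residual) with df, SS, MS, F, p,
#'   plus attributes `n_a`, `n_b`, `n_reps` (per-cell size or its
#'   harmonic mean) and `balanced`.
#' @export
two_way_anova <- function(data, trait, factor_a = "genotype_id",
                          factor_b = "treatment") {
  y <- data[[trait]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  keep <- !is.na(y) & !is.na(A) & !is.na(B)
  y <- y[keep]; A <- droplevels(A[keep]); B <- droplevels(B[keep])
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2 || b < 2) stop("need at least 2 levels of each factor")
  n_cell <- table(A, B)
  if (any(n_cell == 0)) {
    stop("empty cell(s): ", paste(
      apply(which(n_cell == 0, arr.ind = TRUE), 1, function(ij)
        paste(levels(A)[ij[1]], levels(B)[ij[2]], sep = " x ")),
      collapse = ", "))
  }
  cell_mean <- tapply(y, list(A, B), mean)
  balanced <- length(unique(as.vector(n_cell))) == 1
  ss_within <- sum(tapply(y, list(A, B), function(v)
    sum((v - mean(v))^2)))
  df_e <- length(y) - a * b
  if (balanced) {
    r <- as.vector(n_cell)[1]
    gm <- mean(y)
    mA <- rowMeans(cell_mean); mB <- colMeans(cell_mean)
    ss_a <- b * r * sum((mA - gm)^2)
    ss_b <- a * r * sum((mB - gm)^2)
    dev <- cell_mean - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + gm
    ss_ab <- r * sum(dev^2)
    n_reps <- r
  } else {
    warning("unbalanced design: using unweighted-means analysis on cell ",
            "means with harmonic mean cell size", call. = FALSE)
    r_h <- a * b / sum(1 / n_cell)
    gm <- mean(cell_mean)
    mA <- rowMeans(cell_mean); mB <- colMeans(cell_mean)
    ss_a <- b * r_h * sum((mA - gm)^2)
    ss_b <- a * r_h * sum((mB - gm)^2)
    dev <- cell_mean - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + gm
    ss_ab <- r_h * sum(dev^2)
    n_reps <- r_h
  }
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), df_e)
  ss <- c(ss_a, ss_b, ss_ab, ss_within)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  ms_e <- ms[4]
  f <- rep(NA_real_, 4)
  p <- rep(NA_real_, 4)
  if (!is.na(ms_e) && ms_e > 0 && df_e > 0) {
    f[1:3] <- ms[1:3] / ms_e
    p[1:3] <- stats::pf(f[1:3], df[1:3], df_e, lower.tail = FALSE)
  }
  out <- data.frame(
    source = c(factor_a, factor_b,
               paste(factor_a, factor_b, sep = ":"), "residual"),
    df = df, SS = ss, MS = ms, F = f, p = p,
    stringsAsFactors = FALSE)
  attr(out, "n_a") <- a
  attr(out, "n_b") <- b
  attr(out, "n_reps") <- n_reps
  attr(out, "balanced") <- balanced
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Variance components from ANOVA mean squares
#'
#' Two conventions:
#'
#' * `"paper_literal"`: mean squares taken directly as variances
#'   (`sigma2_g = MS_genotype`, `sigma2_gxt = MS_interaction`,
#'   `sigma2_e = MS_residual`), with the phenotypic variance assembled as
#'   `sigma2_p = sigma2_g + sigma2_gxt / n_treatments +
#'   sigma2_e / n_replicates_std`. The replicate divisor is standardized
#'   at 5 by default (one fewer than the 6 pots a genotype present in
#'   both treatments contributes, allowing for genotypes missing a
#'   treatment) and exposed as a parameter.
#' * `"ems"`: standard expected-mean-squares estimators
#'   `sigma2_e = MS_E`, `sigma2_gxt = (MS_GT - MS_E)/r`,
#'   `sigma2_g = (MS_G - MS_GT)/(r t)`, truncated at zero (with a
#'   `truncated` flag), and the same formula for `sigma2_p`.
#'
#' @param anova An `anova_table` from [two_way_anova()] with genotype as
#'   the first factor and treatment as the second.
#' @param n_treatments Number of treatments t (default taken from the
#'   table).
#' @param n_replicates_std Replicate divisor for the phenotypic variance
#'   (default 5).
#' @param convention `"paper_literal"` or `"ems"`.
#' @param n_replicates Per-cell replicate count r for the ems estimators
#'   (default taken from the table).
#' @return List of class `variance_components`: sigma2_g, sigma2_gxt,
#'   sigma2_e, sigma2_p, the convention, and a `truncated` flag.
#' @export
variance_components <- function(anova, n_treatments = NULL,
                                n_replicates_std = 5,
                                convention = c("paper_literal", "ems"),
                                n_replicates = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(anova, "anova_table"))
  ms <- anova$MS
  ms_g <- ms[1]; ms_gt <- ms[3]; ms_e <- ms[4]
  if (is.null(n_treatments)) n_treatments <- attr(anova, "n_b")
  if (is.null(n_replicates)) n_replicates <- attr(anova, "n_reps")
  truncated <- FALSE
  if (convention == "paper_literal") {
    s_g <- ms_g; s_gt <- ms_gt; s_e <- ms_e
  } else {
    s_e <- ms_e
    s_gt <- (ms_gt - ms_e) / n_replicates
    s_g <- (ms_g - ms_gt) / (n_replicates * n_treatments)
    if (s_gt < 0 || s_g < 0) truncated <- TRUE
    s_gt <- max(s_gt, 0)
    s_g <- max(s_g, 0)
  }
  s_p <- s_g + s_gt / n_treatments + s_e / n_replicates_std
  structure(list(sigma2_g = s_g, sigma2_gxt = s_gt, sigma2_e = s_e,
                 sigma2_p = s_p, n_treatments = n_treatments,
                 n_replicates_std = n_replicates_std,
                 convention = convention, truncated = truncated),
            class = "variance_components")
}

#' Broad-sense heritability
#'
#' H_b^2 = sigma2_g / sigma2_p. A zero phenotypic variance (degenerate
#' data) returns 0 with a warning rather than NaN.
#'
#' @param sigma2_g Genotypic variance.
#' @param sigma2_p Phenotypic variance.
#' @return H_b^2 in [0, 1] under a shared convention.
#' @export
heritability <- function(sigma2_g, sigma2_p) {
  if (sigma2_p == 0) {
    warning("sigma2_p = 0: degenerate data, returning H_b^2 = 0",
            call. = FALSE)
    return(0)
  }
  stopifnot(sigma2_p > 0)
  sigma2_g / sigma2_p
}

#' Genotypic and phenotypic coefficients of variation
#'
#' GCV = 100 * sigma_g / |mean| and PCV = 100 * sigma_p / |mean|, in
#' percent. For traits whose population mean is near zero or negative
#' (the iWUE deviation components), pass the substitute mean of the
#' parent trait (iWUE) instead.
#'
#' @param sigma2_g,sigma2_p Genotypic and phenotypic variances.
#' @param mean Trait mean across all measurements (non-zero).
#' @return List with `GCV_pct` and `PCV_pct`.
#' @export
gcv_pcv <- function(sigma2_g, sigma2_p, mean) {
  if (mean == 0) {
    stop("trait mean is 0: supply the substitute mean of the parent ",
         "trait (e.g. iWUE for its deviation components)")
  }
  list(GCV_pct = 100 * sqrt(sigma2_g) / abs(mean),
       PCV_pct = 100 * sqrt(sigma2_p) / abs(mean))
}

#' Fold change of genotype means within a treatment
#'
#' max/min over retained genotype means of a trait under one treatment.
#'
#' @param means Genotype x treatment means.
#' @param trait Trait column.
#' @param treatment `"WW"` or `"WS"`.
#' @return max/min ratio.
#' @export
fold_change <- function(means, trait, treatment) {
  v <- means[[trait]][means$treatment == treatment]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 genotype means")
  if (min(v) <= 0) stop("fold change undefined: minimum mean <= 0")
  max(v) / min(v)
}

#' Trait-by-trait genetic variation summary
#'
#' Builds a summary table in the style of a heritability report: per
#' trait, the grand mean across all measurements, fold changes of the
#' genotype means within each treatment, variance components from the
#' two-way genotype x treatment ANOVA, broad-sense heritability, GCV and
#' PCV. Traits whose genotype means are not strictly positive get `NA`
#' fold changes. The `mean_override` argument supports the substitute-
#' mean rule for deviation traits.
#'
#' @param records Replicate-level records (with derived columns).
#' @param means Matching genotype x treatment means (post-exclusion).
#' @param traits Trait columns to summarize.
#' @param convention Variance-component convention (see
#'   [variance_components()]).
#' @param n_replicates_std Replicate divisor for sigma2_p.
#' @param mean_override Named numeric vector of substitute means per
#'   trait.
#' @return Data.frame, one row per trait.
#' @export
trait_summary_table <- function(records, means, traits,
                                convention = "paper_literal",
                                n_replicates_std = 5,
                                mean_override = NULL) {
  rows <- lapply(traits, function(tr) {
    y <- records[[tr]]
    m_all <- mean(y, na.rm = TRUE)
    fc <- function(trt) {
      v <- means[[tr]][means$treatment == trt]
      v <- v[!is.na(v)]
      if (length(v) >= 2 && min(v) > 0) max(v) / min(v) else NA_real_
    }
    an <- tryCatch(
      suppressWarnings(two_way_anova(records, tr)),
      error = function(e) NULL)
    if (is.null(an)) {
      return(data.frame(trait = tr, mean = m_all, fold_change_WW = fc("WW"),
                        fold_change_WS = fc("WS"), sigma2_g = NA_real_,
                        sigma2_t = NA_real_, sigma2_gxt = NA_real_,
                        sigma2_e = NA_real_, sigma2_p = NA_real_,
                        H_b2 = NA_real_, GCV_pct = NA_real_,
                        PCV_pct = NA_real_, stringsAsFactors = FALSE))
    }
    vc <- variance_components(an, n_replicates_std = n_replicates_std,
                              convention = convention)
    m_use <- if (!is.null(mean_override) && tr %in% names(mean_override))
      mean_override[[tr]] else m_all
    cv <- gcv_pcv(vc$sigma2_g, vc$sigma2_p, m_use)
    data.frame(trait = tr, mean = m_all,
               fold_change_WW = fc("WW"), fold_change_WS = fc("WS"),
               sigma2_g = vc$sigma2_g, sigma2_t = an$MS[2],
               sigma2_gxt = vc$sigma2_gxt, sigma2_e = vc$sigma2_e,
               sigma2_p = vc$sigma2_p,
               H_b2 = heritability(vc$sigma2_g, vc$sigma2_p),
               GCV_pct = cv$GCV_pct, PCV_pct = cv$PCV_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
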