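#' CDF of the studentized range distribution
#'
#' Distribution of the range of k independent standard normals divided by
#' an independent chi-based scale estimate with `df` degrees of freedom,
#' the null distribution of Tukey's honest significant difference.
#' Computed by adaptive quadrature of its integral definition: the range
#' CDF is
#' \deqn{P(W \le w) = k \int \phi(z) [\Phi(z) - \Phi(z - w)]^{k-1} dz,}
#' and for finite df this is mixed over the density of
#' \eqn{S = \sqrt{\chi^2_{df}/df}}. `df = Inf` uses the range CDF
#' directly. Accuracy about 1e-6.
#'
#' @param q Quantile (>= 0).
#' @param k Number of groups (>= 2).
#' @param df Residual degrees of freedom (>= 1, or `Inf`).
#' @return P(Q <= q).
#' @export
ptukey_sr <- function(q, k, df) {
  stopifnot(k >= 2, df >= 1)
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    if (is.infinite(df)) return(.prange(qq, k))
    dS <- function(s) {
      exp((df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2) +
            (df - 1) * log(s) - df * s^2 / 2)
    }
    f <- function(s) vapply(s, function(si) dS(si) * .prange(qq * si, k),
                            numeric(1))
    stats::integrate(f, 0, Inf, rel.tol = 1e-8,
                     subdivisions = 400L)$value
  }, numeric(1))
}

.prange <- function(w, k) {
  if (w <= 0) return(0)
  g <- function(z) stats::dnorm(z) *
    (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
  k * stats::integrate(g, -Inf, Inf, rel.tol = 1e-9,
                       subdivisions = 400L)$value
}

#' Quantile of the studentized range distribution
#'
#' Inverts [ptukey_sr()] by root finding.
#'
#' @param p Probability in (0, 1).
#' @param k Number of groups.
#' @param df Residual degrees of freedom (or `Inf`).
#' @return q such that P(Q <= q) = p.
#' @export
qtukey_sr <- function(p, k, df) {
  stopifnot(p > 0, p < 1)
  stats::uniroot(function(q) ptukey_sr(q, k, df) - p,
                 lower = 1e-8, upper = 200, tol = 1e-7)$root
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All-pairs honest-significant-difference tests from group means, group
#' sizes and a residual mean square. Unequal group sizes use the
#' Tukey-Kramer harmonic-mean convention
#' (SE = sqrt(MS_E/2 * (1/n_i + 1/n_j))). Letters are assembled with the
#' insert-and-absorb algorithm, so two groups share a letter iff their
#' adjusted p >= alpha.
#'
#' @param means Named numeric vector of group means.
#' @param ns Group sizes (recycled if scalar).
#' @param ms_error Residual mean square (> 0).
#' @param df_error Residual degrees of freedom (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List of class `tukey_grouping`: `groups` (mean, n, letters) and
#'   `pairs` (difference, studentized q, adjusted p) data.frames.
#' @export
tukey_hsd <- function(means, ns, ms_error, df_error, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, ms_error > 0)
  if (df_error < 1) stop("df_error must be >= 1")
  if (length(ns) == 1) ns <- rep(ns, k)
  labels <- names(means)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  idx <- utils::combn(k, 2)
  diffs <- means[idx[1, ]] - means[idx[2, ]]
  se <- sqrt(ms_error / 2 * (1 / ns[idx[1, ]] + 1 / ns[idx[2, ]]))
  qobs <- abs(diffs) / se
  pvals <- 1 - ptukey_sr(qobs, k, df_error)
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (j in seq_len(ncol(idx))) {
    if (pvals[j] < alpha) {
      sig[idx[1, j], idx[2, j]] <- TRUE
      sig[idx[2, j], idx[1, j]] <- TRUE
    }
  }
  letters <- compact_letters(sig, order(means, decreasing = TRUE))
  groups <- data.frame(group = labels, mean = unname(means), n = ns,
                       letters = letters[labels],
                       stringsAsFactors = FALSE)
  pairs <- data.frame(group1 = labels[idx[1, ]], group2 = labels[idx[2, ]],
                      diff = unname(diffs), q = unname(qobs),
                      p_adj = unname(pvals), stringsAsFactors = FALSE)
  structure(list(groups = groups, pairs = pairs, alpha = alpha),
            class = "tukey_grouping")
}

#' Compact letter display by insert-and-absorb
#'
#' Given a symmetric logical matrix of significant pairwise differences,
#' produces letters such that two groups share a letter iff they are NOT
#' significantly different, and the letter sets are transitively
#' consistent. Deterministic: letter order follows `order_idx` (usually
#' groups sorted by mean).
#'
#' @param sig k x k logical matrix, `TRUE` = significantly different;
#'   dimnames give group labels.
#' @param order_idx Permutation of 1..k fixing letter assignment order.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(sig, order_idx = seq_len(nrow(sig))) {
  k <- nrow(sig)
  labels <- rownames(sig)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  sets <- list(seq_len(k))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    o <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[o, , drop = FALSE]
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[order(vapply(sets, function(s)
    min(match(s, order_idx)), numeric(1)))]
  out <- stats::setNames(rep("", k), labels)
  for (s in seq_along(sets)) {
    lab <- letters[s]
    for (g in sets[[s]]) out[g] <- paste0(out[g], lab)
  }
  out
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat("Tukey HSD grouping (alpha =", x$alpha, ")\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Pearson product-moment correlation with significance
#'
#' r from the covariance formula, two-sided p from the t transform with
#' n - 2 degrees of freedom, plus the least-squares fit line. Missing
#' pairs are dropped (pairwise-complete). Zero variance in either series
#' yields `NA` with a warning.
#'
#' @param x,y Numeric vectors.
#' @return List of class `correlation_result`: r, r_squared, n, p, slope,
#'   intercept.
#' @export
pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(structure(list(r = NA_real_, r_squared = NA_real_, n = n,
                          p = NA_real_, slope = NA_real_,
                          intercept = NA_real_),
                     class = "correlation_result"))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sx * sy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) < 1) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  } else 0
  slope <- sxy / sx
  structure(list(r = r, r_squared = r^2, n = n, p = p, slope = slope,
                 intercept = mean(y) - slope * mean(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (r^2 = %.4f), n = %d, p = %.3g\n",
              x$r, x$r_squared, x$n, x$p))
  invisible(x)
}

#' Haplotype-group x treatment ANOVA
#'
#' Contrasts genotypes carrying the recurrent-parent (RP) versus the
#' exotic (NRP) haplotype of one aquaporin across watering treatments.
#' The haplotype population is a genotype-level factor while treatment is
#' applied within genotype, so the default analysis is a split-plot
#' ANOVA on genotype x treatment means with two error strata: the
#' Population term is tested against genotype-within-population
#' variation, and Treatment and Population x Treatment against the
#' genotype x treatment stratum. This keeps the Population test at its
#' nominal level in the presence of genotypic variance (pooling
#' replicates of the same genotype as if independent inflates it).
#' `unit = "replicate"` instead runs the naive two-way fixed-effects
#' ANOVA on pooled replicate values, for comparison.
#'
#' @param records Replicate-level records with the trait column.
#' @param trait Trait to analyse.
#' @param aquaporin_id Which aquaporin's assignment to use.
#' @param assignments Data.frame with genotype_id, aquaporin_id, group
#'   (RP/NRP).
#' @param unit `"split_plot"` (default) or `"replicate"`.
#' @return An `anova_table`. For the split-plot analysis the sources are
#'   population, genotype(population), treatment, population:treatment,
#'   residual, with the first tested against the second.
#' @export
haplotype_anova <- function(records, trait, aquaporin_id, assignments,
                            unit = c("split_plot", "replicate")) {
  unit <- match.arg(unit)
  asg <- assignments[assignments$aquaporin_id == aquaporin_id,
                     c("genotype_id", "group")]
  if (!nrow(asg)) stop("no assignments for aquaporin ", aquaporin_id)
  if (anyDuplicated(asg$genotype_id)) {
    stop("a genotype maps to more than one group for ", aquaporin_id)
  }
  for (g in c("RP", "NRP")) {
    ids <- asg$genotype_id[asg$group == g]
    if (length(ids) < 2) stop("population ", g, " has fewer than 2 genotypes")
  }
  dat <- merge(records, asg, by = "genotype_id")
  dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
  if (unit == "replicate") {
    return(suppressWarnings(
      two_way_anova(dat, trait, factor_a = "group",
                    factor_b = "treatment")))
  }
  agg <- stats::aggregate(dat[[trait]],
                          by = list(genotype_id = dat$genotype_id,
                                    treatment = dat$treatment,
                                    group = dat$group),
                          FUN = mean)
  names(agg)[4] <- "y"
  wide <- merge(agg[agg$treatment == "WW", c("genotype_id", "group", "y")],
                agg[agg$treatment == "WS", c("genotype_id", "y")],
                by = "genotype_id", suffixes = c("_ww", "_ws"))
  n_drop <- length(unique(agg$genotype_id)) - nrow(wide)
  if (n_drop > 0) {
    warning(n_drop, " genotype(s) without both treatments dropped from ",
            "the split-plot analysis", call. = FALSE)
  }
  N <- nrow(wide)
  if (N < 4) stop("fewer than 4 genotypes with both treatments")
  pop <- factor(wide$group)
  if (nlevels(pop) < 2) stop("a population is absent after filtering")
  avg <- (wide$y_ww + wide$y_ws) / 2        # whole-plot (genotype) stratum
  d <- wide$y_ww - wide$y_ws                # within-genotype stratum
  nj <- tabulate(pop)
  # between-genotype stratum: population vs genotype(population)
  aj <- tapply(avg, pop, mean)
  gmean <- mean(avg)
  ss_pop <- 2 * sum(nj * (aj - gmean)^2)
  ss_geno <- 2 * sum((avg - aj[pop])^2)
  df_geno <- N - 2
  # within-genotype stratum: treatment, pop x treatment, residual
  dj <- tapply(d, pop, mean)
  dbar <- mean(d)
  ss_trt <- N * dbar^2 / 2
  ss_pt <- sum(nj * (dj - dbar)^2) / 2
  ss_res <- sum((d - dj[pop])^2) / 2
  df_res <- N - 2
  ms <- c(ss_pop / 1, ss_geno / df_geno, ss_trt / 1, ss_pt / 1,
          ss_res / df_res)
  f <- c(ms[1] / ms[2], NA, ms[3] / ms[5], ms[4] / ms[5], NA)
  p <- c(stats::pf(f[1], 1, df_geno, lower.tail = FALSE), NA,
         stats::pf(f[3], 1, df_res, lower.tail = FALSE),
         stats::pf(f[4], 1, df_res, lower.tail = FALSE), NA)
  out <- data.frame(
    source = c("population", "genotype(population)", "treatment",
               "population:treatment", "residual"),
    df = c(1, df_geno, 1, 1, df_res),
    SS = c(ss_pop, ss_geno, ss_trt, ss_pt, ss_res),
    MS = ms, F = f, p = p, stringsAsFactors = FALSE)
  attr(out, "n_a") <- nlevels(pop)
  attr(out, "n_b") <- 2
  attr(out, "n_reps") <- N / 2
  attr(out, "balanced") <- length(unique(nj)) == 1
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pairwise Pearson correlation matrix over traits
#'
#' All pairwise correlations among trait columns of a means table, long
#' format, pairwise-complete.
#'
#' @param means Genotype x treatment means (or any data.frame).
#' @param traits Trait columns to correlate.
#' @return Long data.frame: trait_x, trait_y, r, r_squared, n, p.
#' @export
correlation_matrix <- function(means, traits) {
  cmb <- utils::combn(traits, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    tx <- cmb[1, j]; ty <- cmb[2, j]
    res <- tryCatch(suppressWarnings(pearson(means[[tx]], means[[ty]])),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(trait_x = tx, trait_y = ty, r = NA_real_,
                 r_squared = NA_real_, n = NA_integer_, p = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(trait_x = tx, trait_y = ty, r = res$r,
                 r_squared = res$r_squared, n = res$n, p = res$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
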