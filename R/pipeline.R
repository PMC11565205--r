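#' End-to-end analysis pipeline
#'
#' Runs the full workflow — simulate or ingest, derive physiology,
#' aggregate, exclusion-filter, fit the reference curve, partition iWUE,
#' change vectors, genetic-variation summary, haplotype contrasts and the
#' pairwise correlation matrix — and writes each stage's table under
#' `out_dir` as plain CSV (plus the curve parameters as JSON and a run
#' log). Identical config and seed give byte-identical numeric outputs.
#'
#' @param input Either a [sim_config()] (the trial is simulated) or a
#'   plant-record data.frame; a simulation also supplies haplotype
#'   assignments.
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output.
#' @param assignments Optional haplotype assignments when `input` is a
#'   data.frame.
#' @param gs_floor,an_floor Exclusion-filter thresholds.
#' @param curve_form Reference-curve form (see [fit_reference_curve()]).
#' @param convention Variance-component convention for the summary table.
#' @param traits Traits for the genetic-variation summary.
#' @param alpha Family-wise alpha for the Tukey letters.
#' @return Invisible list with every stage's result (`records`, `derived`,
#'   `means`, `retained`, `excluded`, `curve`, `partition`, `vectors`,
#'   `summary`, `haplotype`, `correlations`).
#' @export
run_pipeline <- function(input, out_dir = NULL, assignments = NULL,
                         gs_floor = 0.02, an_floor = 2.0,
                         curve_form = "power",
                         convention = "paper_literal",
                         traits = c("A_n", "g_s", "iwue", "C_i",
                                    "phi_PSII", "SPAD", "psi_midday",
                                    "psi_predawn", "leaf_width", "LMA",
                                    "RWC", "biomass"),
                         alpha = 0.05) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (inherits(input, "sim_config")) {
    sim <- simulate_trial(input)
    records <- sim$records
    if (is.null(assignments)) assignments <- sim$assignments
    say("simulated trial: %d genotypes x 2 treatments, seed %d",
        input$n_genotypes, input$seed)
  } else {
    records <- input
    if (!nrow(records)) stop("empty input table")
    validate_records(records)
    say("ingested %d replicate records", nrow(records))
  }
  if (!nrow(records)) stop("empty input table")

  derived <- derive_physiology(records)
  means <- aggregate_means(derived)
  filt <- apply_exclusion_filter(means, gs_floor, an_floor)
  say("aggregated %d genotype x treatment means; excluded %d",
      nrow(means), nrow(filt$excluded))

  ret <- filt$retained
  obs <- ret[!is.na(ret$g_s) & !is.na(ret$iwue), ]
  curve <- fit_reference_curve(obs$g_s, obs$iwue, form = curve_form,
                               A_n = obs$A_n)
  part <- partition_iwue(ret, curve)
  vecs <- change_vectors(ret)
  say("fitted %s reference curve (R^2 = %.3f); %d change vectors",
      curve$form, curve$r_squared, nrow(vecs))

  traits_here <- intersect(traits, names(derived))
  summ <- trait_summary_table(derived, ret, traits_here,
                              convention = convention)
  corr <- correlation_matrix(ret, traits_here)

  hap <- NULL
  if (!is.null(assignments)) {
    hap <- lapply(unique(assignments$aquaporin_id), function(aqp) {
      tabs <- lapply(intersect(c("A_n", "g_s", "iwue"), names(derived)),
                     function(tr) {
        at <- haplotype_anova(derived, tr, aqp, assignments)
        keep <- at$source %in% c("population", "treatment",
                                 "population:treatment")
        data.frame(aquaporin = aqp, trait = tr,
                   comparison = at$source[keep], df = at$df[keep],
                   F = at$F[keep], p = at$p[keep],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, tabs)
    })
    hap <- do.call(rbind, hap)
    say("haplotype contrasts for %d aquaporin(s)",
        length(unique(hap$aquaporin)))
  }

  out <- list(records = records, derived = derived, means = means,
              retained = ret, excluded = filt$excluded, curve = curve,
              partition = part, vectors = vecs, summary = summ,
              haplotype = hap, correlations = corr)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      write_phenotype_table(df, file.path(out_dir, name))
    }
    wr(derived, "derived.csv")
    wr(means, "means.csv")
    wr(filt$excluded[, c("genotype_id", "treatment", "reason")],
       "excluded.csv")
    wr(part, "partition.csv")
    wr(vecs, "vectors.csv")
    wr(summ, "genetic_variation.csv")
    wr(hap, "haplotype_anova.csv")
    wr(corr, "correlations.csv")
    jsonlite::write_json(
      list(form = curve$form, parameters = as.list(curve$parameters),
           domain = curve$domain, r_squared = curve$r_squared,
           n = curve$n),
      file.path(out_dir, "curve.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("sorghumWUE %s",
                         as.character(utils::packageVersion("sorghumWUE"))),
                 log_lines),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}
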