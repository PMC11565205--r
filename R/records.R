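#' Numeric phenotype columns of a plant record table
#'
#' Canonical names for the per-replicate measured traits. Derived traits
#' (iWUE, conductances, LMA, RWC) are appended by [derive_physiology()].
#'
#' @return Character vector of column names.
#' @export
phenotype_traits <- function() {
  c("A_n", "g_s", "C_i", "E",
    "psi_predawn", "psi_stem", "psi_midday",
    "SPAD", "phi_PSII",
    "leaf_width", "leaf_length", "leaf_thickness",
    "disc_FW", "disc_TW", "disc_DW", "disc_area",
    "biomass")
}

#' Derived trait columns appended by derive_physiology()
#' @return Character vector of column names.
#' @export
derived_traits <- function() {
  c("iwue", "K_leaf", "K_plant", "R_leaf", "R_rest", "LMA", "RWC")
}

.id_cols <- c("genotype_id", "treatment", "replicate")

#' Read a long-format phenotype table
#'
#' Reads a CSV with one row per plant replicate into the canonical record
#' schema. Columns named differently in the source file are renamed via
#' `mapping` (canonical name -> file column name), supplied either as a
#' named list/vector or as a path to a YAML/JSON file. Non-numeric cells
#' in numeric columns become `NA` with a warning giving the count.
#'
#' @param path CSV file path.
#' @param mapping Optional column mapping, named `canonical = source`.
#' @param required Canonical columns that must be present (default:
#'   genotype_id, treatment, replicate).
#' @param delim Field delimiter, default ",".
#' @return A `data.frame` of plant records; row order preserved.
#' @export
read_phenotype_table <- function(path, mapping = NULL,
                                 required = .id_cols, delim = ",") {
  stopifnot(file.exists(path))
  mapping <- .load_mapping(mapping)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (length(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req)) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  out <- raw
  canonical_num <- c("replicate", phenotype_traits(), derived_traits())
  n_bad <- 0L
  for (cc in setdiff(names(out), c("genotype_id", "treatment"))) {
    v <- out[[cc]]
    v[v %in% c("", "NA", "NaN", "na")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (cc %in% canonical_num) {
      # canonical numeric column: coerce, count unparseable cells
      n_bad <- n_bad + sum(bad)
      out[[cc]] <- num
    } else if (!any(bad)) {
      # any other column that parses cleanly is numeric too
      out[[cc]] <- num
    } else {
      out[[cc]] <- v
    }
  }
  if (n_bad > 0) {
    warning(sprintf("%d non-numeric cell(s) set to NA while reading %s",
                    n_bad, basename(path)))
  }
  if ("treatment" %in% names(out)) out$treatment <- toupper(out$treatment)
  validate_records(out)
  out
}

.load_mapping <- function(mapping) {
  if (is.null(mapping)) return(list())
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    if (grepl("\\.json$", mapping, ignore.case = TRUE)) {
      return(as.list(jsonlite::read_json(mapping, simplifyVector = TRUE)))
    }
    if (requireNamespace("yaml", quietly = TRUE)) {
      return(as.list(yaml::read_yaml(mapping)))
    }
    stop("yaml package required to read a YAML mapping file")
  }
  as.list(mapping)
}

#' Validate plant records against schema invariants
#'
#' Checks the soft invariants of the record schema and emits warnings
#' (never errors) for physiologically inconsistent rows: a pre-dawn water
#' potential below the midday one, disc weights out of order
#' (DW <= FW <= TW), phi_PSII outside [0, 1], and non-positive g_s on rows
#' that carry an assimilation rate. Unknown treatment levels are an error.
#'
#' @param records Plant record data.frame.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records) {
  if ("treatment" %in% names(records)) {
    bad <- !(records$treatment %in% c("WW", "WS") | is.na(records$treatment))
    if (any(bad)) {
      stop("unknown treatment level(s): ",
           paste(unique(records$treatment[bad]), collapse = ", "))
    }
  }
  flag <- function(cond, msg) {
    n <- sum(cond, na.rm = TRUE)
    if (n > 0) warning(sprintf("%d row(s): %s", n, msg), call. = FALSE)
  }
  if (all(c("psi_predawn", "psi_midday") %in% names(records))) {
    flag(records$psi_predawn < records$psi_midday,
         "psi_predawn below psi_midday (reversed gradient)")
  }
  if (all(c("disc_FW", "disc_TW", "disc_DW") %in% names(records))) {
    flag(!(records$disc_DW <= records$disc_FW &
             records$disc_FW <= records$disc_TW),
         "leaf disc weights violate DW <= FW <= TW")
  }
  if ("phi_PSII" %in% names(records)) {
    flag(records$phi_PSII < 0 | records$phi_PSII > 1,
         "phi_PSII outside [0, 1]")
  }
  if (all(c("A_n", "g_s") %in% names(records))) {
    flag(!is.na(records$A_n) & !is.na(records$g_s) & records$g_s <= 0,
         "non-positive g_s on rows with A_n present")
  }
  invisible(records)
}

#' Write a phenotype table
#'
#' Plain CSV, full precision (up to 15 significant digits), so that a
#' write/read round trip reproduces every numeric field.
#'
#' @param records Plant record data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(records, path) {
  df <- records
  num <- vapply(df, is.numeric, logical(1))
  for (cc in names(df)[num]) {
    df[[cc]] <- formatC(df[[cc]], digits = 15, format = "g")
    df[[cc]][df[[cc]] %in% c("NA", " NA")] <- NA
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Aggregate replicate records to genotype x treatment means
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) per trait over
#' non-missing replicate values. A trait's SE is `NA` when only one
#' non-missing replicate contributes. The returned table is wide: one row
#' per genotype x treatment, trait means under the trait name, SEs under
#' `se.<trait>` and per-trait n under `n.<trait>`.
#'
#' @param records Plant record data.frame (may include derived columns).
#' @param traits Traits to aggregate; default all present phenotype and
#'   derived columns.
#' @return Data.frame of genotype x treatment means.
#' @export
aggregate_means <- function(records, traits = NULL) {
  if (is.null(traits)) {
    traits <- intersect(c(phenotype_traits(), derived_traits()),
                        names(records))
  }
  key <- interaction(records$genotype_id, records$treatment, drop = TRUE,
                     sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    out <- list(genotype_id = records$genotype_id[idx[1]],
                treatment = records$treatment[idx[1]],
                n_replicates = length(idx))
    for (tr in traits) {
      v <- records[[tr]][idx]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[tr]] <- if (n) mean(v) else NA_real_
      out[[paste0("se.", tr)]] <-
        if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
      out[[paste0("n.", tr)]] <- n
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$genotype_id, out$treatment), , drop = FALSE]
}

#' Exclude genotype x treatment means with collapsed gas exchange
#'
#' A mean is excluded iff both its g_s mean and its A_n mean fall below
#' their floors (joint rule). The defaults capture trial entries whose
#' stomata had effectively shut under stress, the situation in which both
#' assimilation and conductance collapse together and the iWUE ratio is no
#' longer informative.
#'
#' @param means Output of [aggregate_means()].
#' @param gs_floor g_s floor, mol m-2 s-1 (default 0.02).
#' @param an_floor A_n floor, umol m-2 s-1 (default 2.0).
#' @return List with `retained` and `excluded` data.frames; `excluded`
#'   carries a `reason` column.
#' @export
apply_exclusion_filter <- function(means, gs_floor = 0.02, an_floor = 2.0) {
  stopifnot(gs_floor >= 0, an_floor >= 0)
  gs <- means$g_s
  an <- means$A_n
  drop <- !is.na(gs) & !is.na(an) & gs < gs_floor & an < an_floor
  excluded <- means[drop, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf(
      "g_s mean %.4g < %.4g and A_n mean %.4g < %.4g",
      excluded$g_s, gs_floor, excluded$A_n, an_floor)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = means[!drop, , drop = FALSE], excluded = excluded)
}
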