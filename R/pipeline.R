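#' Build the deletion-by-phenotype 2x2 table from pipeline intermediates
#'
#' Restricts to QC-passing samples with a CASE or CONTROL assignment for
#' the phenotype (EXCLUDED samples appear in neither denominator) and
#' counts deletion carriers in each group.
#'
#' @param assignments long assignment table from [classify_cohort()].
#' @param carriers deletion-status table from [genotype_deletion()]
#'   (QC-passing samples only).
#' @param phenotype `"CVM"` or `"NEUROPSYCH"`.
#' @return An `assoc2x2` from [or_ci_chi2()], with the counts attached.
#' @export
phenotype_association <- function(assignments, carriers, phenotype) {
  a <- assignments[assignments$phenotype == phenotype, , drop = FALSE]
  a <- a[a$participant_id %in% carriers$sample_id, , drop = FALSE]
  carr <- stats::setNames(carriers$carrier, carriers$sample_id)
  is_car <- carr[a$participant_id]
  case <- a$status == "CASE"
  ctrl <- a$status == "CONTROL"
  or_ci_chi2(sum(case & is_car), sum(case & !is_car),
             sum(ctrl & is_car), sum(ctrl & !is_car))
}

resolve_codebook <- function(x) {
  if (is.null(x)) return(default_codebook())
  if (inherits(x, "codebook")) return(validate_codebook(x))
  if (is.character(x)) return(validate_codebook(read_codebook(x)))
  if (is.list(x)) return(validate_codebook(codebook(x)))
  config_error("codebook must be a path, a codebook object or a list of sets",
               field = "codebook")
}

#' Run the full association pipeline
#'
#' Executes the stages in order — obtain data (simulate or read), sample
#' QC, locus genotyping, phenotype classification, 2x2 association, and
#' (when outcomes are available) the covariate-adjusted regression
#' battery — and returns a run report with per-stage counts. Identical
#' config and seed give an identical report.
#'
#' @param config a named list (or path to a YAML file) with exactly one of:
#'   * `simulate`: arguments for [cohort_params()], or
#'   * `inputs`: named paths `participants`, `events`, `cnv_calls`,
#'     `sample_stats`, optionally `outcomes`, and `cnv_dialect`
#'     (`"penncnv_rawcnv"`, the default, or `"tsv"`);
#'
#'   plus optional `codebook` (path / object / list), `locus`
#'   (`chromosome`, `start`, `end`), `qc` (`wf_limit`, `max_cnvs`),
#'   `min_fraction`, `seed` (overrides `simulate$seed`) and
#'   `regressions` (logical; default `TRUE` when outcomes are present).
#' @return An object of class `cnv_run_report`.
#' @export
#' @examples
#' rep <- run_pipeline(list(simulate = list(n_participants = 5000, seed = 3)))
#' print(rep)
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    config_error("exactly one of 'simulate' or 'inputs' must be given",
                 field = "config")
  cb <- resolve_codebook(config$codebook)
  locus <- if (!is.null(config$locus))
    genomic_interval(config$locus$chromosome, config$locus$start,
                     config$locus$end) else bp1bp2_locus()
  wf_limit <- config$qc$wf_limit %||% 0.03
  max_cnvs <- config$qc$max_cnvs %||% 40
  min_fraction <- config$min_fraction %||% 0.95

  if (has_sim) {
    sim <- config$simulate
    if (!is.null(config$seed)) sim$seed <- config$seed
    params <- if (inherits(sim, "cohort_params")) sim
              else do.call(cohort_params, sim)
    data <- simulate_cohort(params, cb)
  } else {
    inp <- config$inputs
    for (f in c("participants", "events", "cnv_calls", "sample_stats"))
      if (is.null(inp[[f]]))
        config_error(sprintf("inputs must name a '%s' file", f),
                     field = "inputs")
    data <- list(
      participants = read_participants(inp$participants),
      events = read_events(inp$events),
      cnv_calls = parse_cnv_calls(inp$cnv_calls,
                                  dialect = inp$cnv_dialect %||% "penncnv_rawcnv"),
      sample_stats = read_sample_stats(inp$sample_stats),
      outcomes = if (!is.null(inp$outcomes)) read_outcomes(inp$outcomes)
                 else NULL,
      ground_truth = NULL)
  }

  # stage: sample QC
  qc <- sample_qc(data$sample_stats, wf_limit = wf_limit,
                  max_cnvs = max_cnvs)
  pass_ids <- qc$sample_id[qc$qc_pass]

  # stage: locus genotyping (QC-passing samples)
  carriers <- genotype_deletion(
    data$cnv_calls[data$cnv_calls$sample_id %in% pass_ids, , drop = FALSE],
    sample_ids = pass_ids, locus = locus, min_fraction = min_fraction)

  # stage: phenotype classification
  assignments <- classify_cohort(data$participants, data$events, cb)

  # stage: association
  associations <- list(
    cvm = phenotype_association(assignments, carriers, "CVM"),
    neuropsych = phenotype_association(assignments, carriers, "NEUROPSYCH"))

  # stage: regression battery
  do_reg <- config$regressions %||% !is.null(data$outcomes)
  regressions <- if (isTRUE(do_reg) && !is.null(data$outcomes))
    regression_battery(data, assignments, carriers) else NULL

  status_counts <- function(ph) {
    a <- assignments[assignments$phenotype == ph, ]
    tab <- table(a$status, useNA = "no")
    reasons <- table(a$reason[a$status == "EXCLUDED"], useNA = "no")
    list(status = as.list(tab), excluded_reasons = as.list(reasons))
  }
  counts <- list(
    n_participants = nrow(data$participants),
    n_events = nrow(data$events),
    n_cnv_calls = nrow(data$cnv_calls),
    qc_failed = as.list(table(qc$qc_reason[!qc$qc_pass])),
    n_qc_pass = length(pass_ids),
    n_carriers_qc_pass = sum(carriers$carrier),
    cvm = status_counts("CVM"),
    neuropsych = status_counts("NEUROPSYCH"))

  structure(list(counts = counts, associations = associations,
                 regressions = regressions, qc = qc, carriers = carriers,
                 assignments = assignments, data = data,
                 config = config,
                 seed = config$seed %||% (if (has_sim) data$params$seed
                                          else NA_integer_)),
            class = "cnv_run_report")
}

# assemble analysis rows and fit the cognitive/attainment/fecundity models
regression_battery <- function(data, assignments, carriers) {
  out <- data$outcomes
  part <- data$participants
  idx <- match(out$participant_id, part$participant_id)
  carr <- stats::setNames(carriers$carrier, carriers$sample_id)
  elig <- assignments[assignments$phenotype == "CVM",
                      c("participant_id", "cognitive_eligible")]
  elig_map <- stats::setNames(elig$cognitive_eligible, elig$participant_id)
  df <- data.frame(
    participant_id = out$participant_id,
    carrier = carr[out$participant_id],
    age = 2010 - part$year_of_birth[idx],
    sex = part$sex[idx],
    cognitive_eligible = elig_map[out$participant_id],
    stringsAsFactors = FALSE)
  keep <- !is.na(df$carrier)          # QC-passing, genotyped samples only
  df <- df[keep, ]; out <- out[keep, ]

  fits <- list()
  cog <- which(df$cognitive_eligible)
  for (nm in c("reaction_time", "fluid_intelligence", "numeric_memory",
               "pairs_matching")) {
    pp <- preprocess_outcome(nm, out[[nm]][cog])
    rows <- cog[pp$kept]
    fits[[nm]] <- fit_adjusted_model(nm, data.frame(
      outcome = pp$values, carrier = df$carrier[rows], age = df$age[rows],
      sex = df$sex[rows]))
    fits[[nm]]$n_removed_as_outliers <- sum(pp$removed$rule == "outlier_5sd")
  }

  qual <- out$qualification
  fits$qualifications <- fit_adjusted_model("qualifications", data.frame(
    outcome = qual, carrier = df$carrier, age = df$age, sex = df$sex))
  freq <- table(ifelse(df$carrier, "carrier", "noncarrier"),
                factor(qual, levels = c("degree", "alevels", "other")))
  attainment <- list(frequencies = freq,
                     percentages = attainment_proportions(unclass(freq)))

  ppf <- preprocess_outcome("fecundity", out$n_children, sex = df$sex)
  fec_df <- data.frame(outcome = ppf$values,
                       carrier = df$carrier[ppf$kept],
                       sex = df$sex[ppf$kept], stringsAsFactors = FALSE)
  fecundity <- fecundity_analysis(fec_df)
  fecundity$n_removed <- nrow(ppf$removed)

  list(cognitive = fits[c("reaction_time", "fluid_intelligence",
                          "numeric_memory", "pairs_matching")],
       qualifications = fits$qualifications, attainment = attainment,
       fecundity = fecundity)
}

#' @export
print.cnv_run_report <- function(x, ...) {
  ct <- x$counts
  cat("CNV association pipeline run\n")
  cat(sprintf("  participants: %d; QC pass: %d; deletion carriers (QC pass): %d\n",
              ct$n_participants, ct$n_qc_pass, ct$n_carriers_qc_pass))
  for (ph in c("cvm", "neuropsych")) {
    s <- ct[[ph]]$status
    cat(sprintf("  %s: CASE %s / CONTROL %s / EXCLUDED %s\n",
                toupper(ph), s$CASE %||% 0, s$CONTROL %||% 0,
                s$EXCLUDED %||% 0))
  }
  cat("\nCVM association:\n"); print(x$associations$cvm)
  cat("\nNeuropsychiatric association:\n"); print(x$associations$neuropsych)
  if (!is.null(x$regressions)) {
    cat("\nCarrier effects (adjusted):\n")
    for (nm in names(x$regressions$cognitive)) {
      tr <- carrier_term(x$regressions$cognitive[[nm]])
      cat(sprintf("  %-18s beta = %8.4f (se %.4f), p = %.3g\n", nm,
                  tr$estimate, tr$se, tr$p))
    }
    cat(sprintf("  fecundity interaction p = %.3g\n",
                x$regressions$fecundity$interaction_p))
  }
  invisible(x)
}

fit_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(name = f$name, family = f$family, n_used = f$n_used,
       n_removed_as_outliers = f$n_removed_as_outliers %||% NULL,
       coefficients = f$coefficients)
}

assoc_to_list <- function(a) {
  list(counts = as.list(a$counts), odds_ratio = a$odds_ratio,
       ci_low = a$ci_low, ci_high = a$ci_high, chi2 = a$chi2, p = a$p,
       prevalence_cases = a$prevalence_cases,
       prevalence_controls = a$prevalence_controls, haldane = a$haldane)
}

report_to_list <- function(x) {
  reg <- x$regressions
  list(
    schema_version = "1.0",
    seed = x$seed,
    counts = x$counts,
    associations = lapply(x$associations, assoc_to_list),
    regressions = if (!is.null(reg)) list(
      cognitive = lapply(reg$cognitive, fit_to_list),
      qualifications = fit_to_list(reg$qualifications),
      attainment = list(
        frequencies = as.data.frame.matrix(reg$attainment$frequencies),
        percentages = as.data.frame.matrix(reg$attainment$percentages)),
      fecundity = list(male = fit_to_list(reg$fecundity$male),
                       female = fit_to_list(reg$fecundity$female),
                       pooled = fit_to_list(reg$fecundity$pooled),
                       interaction_p = reg$fecundity$interaction_p,
                       n_removed = reg$fecundity$n_removed)) else NULL)
}

md_2x2 <- function(a, label_case, label_control) {
  c(sprintf("| group | deletion | no deletion | prevalence |"),
    sprintf("|---|---|---|---|"),
    sprintf("| %s | %.7g | %.7g | %.2f%% |", label_control, a$counts["c"],
            a$counts["d"], a$prevalence_controls),
    sprintf("| %s | %.7g | %.7g | %.2f%% |", label_case, a$counts["a"],
            a$counts["b"], a$prevalence_cases),
    sprintf(""),
    sprintf("OR = %.2f [95%% CI %.2f-%.2f]; Yates chi-squared = %.2f; p = %.3g",
            a$odds_ratio, a$ci_low, a$ci_high, a$chi2, a$p))
}

#' Write JSON and Markdown reports for a pipeline run
#'
#' The JSON report is the machine-readable record (schema-versioned,
#' every count reconstructible from the emitted intermediate tables); the
#' Markdown report renders the 2x2 prevalence tables, the attainment
#' table and the regression summaries for human readers. Intermediate
#' tables (`qc.tsv`, `deletion_status.tsv`, `assignments.tsv`) are
#' written alongside.
#'
#' @param report a `cnv_run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
emit_report <- function(report, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, showWarnings = FALSE, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", dir))
  paths <- c(json = file.path(dir, "report.json"),
             markdown = file.path(dir, "report.md"),
             qc = file.path(dir, "qc.tsv"),
             deletion_status = file.path(dir, "deletion_status.tsv"),
             assignments = file.path(dir, "assignments.tsv"))
  jsonlite::write_json(report_to_list(report), paths["json"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write_tsv(report$qc, paths["qc"])
  write_tsv(report$carriers, paths["deletion_status"])
  write_tsv(report$assignments, paths["assignments"])

  a <- report$associations
  md <- c("# CNV association pipeline report", "",
          sprintf("Seed: %s", report$seed), "",
          "## Deletion prevalence by phenotype", "",
          "### Congenital cardiovascular malformation", "",
          md_2x2(a$cvm, "CVM cases", "Controls"), "",
          "### Neuropsychiatric diagnoses", "",
          md_2x2(a$neuropsych, "Neuropsychiatric cases", "Controls"), "")
  reg <- report$regressions
  if (!is.null(reg)) {
    md <- c(md, "## Adjusted carrier effects", "",
            "| outcome | family | carrier estimate | SE | p | n |",
            "|---|---|---|---|---|---|")
    for (nm in names(reg$cognitive)) {
      f <- reg$cognitive[[nm]]
      tr <- carrier_term(f)
      md <- c(md, sprintf("| %s | %s | %.4f | %.4f | %.3g | %d |", nm,
                          f$family, tr$estimate, tr$se, tr$p, f$n_used))
    }
    pc <- reg$attainment$percentages
    md <- c(md, "", "## Highest qualification achieved", "",
            paste0("| group | ", paste(colnames(pc), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(pc) + 1), collapse = "|"), "|"))
    for (g in rownames(pc))
      md <- c(md, paste0("| ", g, " | ",
                         paste(sprintf("%.1f%%", pc[g, ]), collapse = " | "),
                         " |"))
    md <- c(md, "", sprintf("Fecundity interaction p = %.3g",
                            reg$fecundity$interaction_p))
  }
  writeLines(md, paths["markdown"])
  invisible(paths)
}
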