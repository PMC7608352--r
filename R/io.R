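# Readers and writers for the pipeline's plain-text formats. The
# generator writes exactly the formats the pipeline reads, so simulated
# cohorts are pipeline inputs with no adapters.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path, what) {
  if (!file.exists(path))
    config_error(sprintf("%s file '%s' does not exist", what, path),
                 field = what)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character",
                                   sample_id = "character")[
                      intersect(c("participant_id", "sample_id"),
                                strsplit(readLines(path, n = 1), "\t")[[1]])],
                    na.strings = c("NA", ""))
}

#' Read pipeline input tables
#'
#' Tab-separated files with a header row. `read_events()` expects
#' `participant_id`, `system`, `code`, `age_at_event` and optional
#' `tiebreak`; `read_sample_stats()` expects `sample_id`,
#' `waviness_factor`, `n_cnvs`.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_participants <- function(path) read_tsv(path, "participants")

#' @rdname read_participants
#' @export
read_events <- function(path) {
  ev <- read_tsv(path, "events")
  if (!"tiebreak" %in% names(ev)) ev$tiebreak <- NA_real_
  ev
}

#' @rdname read_participants
#' @export
read_sample_stats <- function(path) read_tsv(path, "sample_stats")

#' @rdname read_participants
#' @export
read_outcomes <- function(path) read_tsv(path, "outcomes")

#' @rdname read_participants
#' @export
read_ground_truth <- function(path) read_tsv(path, "ground_truth")

# PennCNV state labels by copy number (diploid autosomes)
cn_to_state <- function(cn) {
  s <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(cn)]
  if (any(is.na(s)))
    config_error("copy number must be one of 0, 1, 3, 4 for rawcnv output",
                 field = "cnv_calls")
  s
}

#' Write CNV calls as PennCNV-style rawcnv text
#'
#' One whitespace-separated line per call:
#' `chrN:start-end  numsnp=K  length=L  stateS,cn=C  sample  startsnp=...  endsnp=...`.
#'
#' @param calls CNV call data frame (see [parse_cnv_calls()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rawcnv <- function(calls, path) {
  np <- ifelse(is.na(calls$n_probes), 20L, calls$n_probes)
  lines <- sprintf(
    "chr%s:%d-%d\tnumsnp=%d\tlength=%s\tstate%d,cn=%d\t%s\tstartsnp=rs0\tendsnp=rs1",
    calls$chromosome, calls$start, calls$end, np,
    format(calls$end - calls$start + 1L, big.mark = ",", trim = TRUE),
    cn_to_state(calls$copy_number), calls$copy_number, calls$sample_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort to a directory of pipeline-ready files
#'
#' Emits `participants.tsv`, `events.tsv`, `cnv_calls.rawcnv`,
#' `sample_stats.tsv`, `outcomes.tsv` and `ground_truth.tsv`.
#'
#' @param cohort a `cnv_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    participants = file.path(dir, "participants.tsv"),
    events = file.path(dir, "events.tsv"),
    cnv_calls = file.path(dir, "cnv_calls.rawcnv"),
    sample_stats = file.path(dir, "sample_stats.tsv"),
    outcomes = file.path(dir, "outcomes.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"))
  write_tsv(cohort$participants, paths["participants"])
  write_tsv(cohort$events, paths["events"])
  write_rawcnv(cohort$cnv_calls, paths["cnv_calls"])
  write_tsv(cohort$sample_stats, paths["sample_stats"])
  write_tsv(cohort$outcomes, paths["outcomes"])
  write_tsv(cohort$ground_truth, paths["ground_truth"])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @param with_truth also read `ground_truth.tsv` when present.
#' @return A list shaped like [simulate_cohort()] output (without
#'   `params`).
#' @export
read_cohort <- function(dir, with_truth = TRUE) {
  gt_path <- file.path(dir, "ground_truth.tsv")
  list(
    participants = read_participants(file.path(dir, "participants.tsv")),
    events = read_events(file.path(dir, "events.tsv")),
    cnv_calls = parse_cnv_calls(file.path(dir, "cnv_calls.rawcnv"),
                                dialect = "penncnv_rawcnv"),
    sample_stats = read_sample_stats(file.path(dir, "sample_stats.tsv")),
    outcomes = read_outcomes(file.path(dir, "outcomes.tsv")),
    ground_truth = if (with_truth && file.exists(gt_path))
      read_ground_truth(gt_path) else NULL)
}
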