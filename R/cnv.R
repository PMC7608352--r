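#' The 15q11.2 BP1-BP2 deletion locus
#'
#' The interval between the outermost array probes covering the four genes
#' NIPA1, NIPA2, CYFIP1 and TUBGCP5: chr15:22,819,338-23,093,090 (GRCh37),
#' 1-based inclusive coordinates.
#'
#' @return A `genomic_interval`: list with `chromosome`, `start`, `end`.
#' @export
#' @examples
#' bp1bp2_locus()
bp1bp2_locus <- function() {
  genomic_interval("15", 22819338L, 23093090L)
}

#' Construct a genomic interval (1-based inclusive)
#'
#' @param chromosome chromosome label; a leading `"chr"` is stripped.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chromosome, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    config_error("interval requires integer start <= end", field = "locus")
  structure(list(chromosome = normalize_chrom(chromosome),
                 start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("chr%s:%s-%s (%s bp, 1-based inclusive)\n", x$chromosome,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start + 1L, big.mark = ",")))
  invisible(x)
}

interval_length <- function(x) x$end - x$start + 1L

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Parse CNV calls from PennCNV rawcnv text or a TSV dialect
#'
#' The `penncnv_rawcnv` dialect expects whitespace-separated lines such as
#'
#' ```
#' chr15:22819338-23093090  numsnp=132  length=273,753  state2,cn=1  S0001  startsnp=rs1  endsnp=rs2
#' ```
#'
#' The `tsv` dialect expects a header with columns
#' `sample_id`, `chromosome`, `start`, `end`, `copy_number` and optionally
#' `n_probes`. Coordinates are 1-based inclusive throughout. Calls with
#' copy number 2 are not variant calls and are rejected.
#'
#' @param path path to a call file, or a character vector of lines via
#'   `text`.
#' @param dialect `"penncnv_rawcnv"` or `"tsv"`.
#' @param text optional character vector of lines (overrides `path`).
#' @return A data frame with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `copy_number`, `n_probes` (NA when absent).
#' @export
parse_cnv_calls <- function(path = NULL, dialect = c("penncnv_rawcnv", "tsv"),
                            text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      config_error(sprintf("CNV call file '%s' does not exist", path %||% ""),
                   field = "cnv_calls")
    text <- readLines(path)
  }
  if (dialect == "penncnv_rawcnv") parse_rawcnv(text) else parse_cnv_tsv(text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_rawcnv <- function(lines) {
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(fields) < 5L)
      parse_error("expected at least 5 whitespace-separated fields", line = ln)
    m <- regmatches(fields[1],
                    regexec("^(chr)?([^:]+):([0-9,]+)-([0-9,]+)$", fields[1]))[[1]]
    if (length(m) != 5L)
      parse_error(sprintf("malformed coordinate field '%s'", fields[1]),
                  line = ln)
    start <- as.integer(gsub(",", "", m[4]))
    end <- as.integer(gsub(",", "", m[5]))
    if (is.na(start) || is.na(end))
      parse_error("coordinate out of integer range", line = ln)
    if (start > end)
      parse_error(sprintf("start %d > end %d", start, end), line = ln)
    cnf <- grep("^state[0-9]+,cn=[0-9]+$", fields, value = TRUE)
    if (length(cnf) != 1L)
      parse_error("missing or ambiguous stateK,cn=N field", line = ln)
    cn <- as.integer(sub("^state[0-9]+,cn=", "", cnf))
    if (cn == 2L)
      parse_error("copy number 2 is not a variant call", line = ln)
    nsnp <- grep("^numsnp=", fields, value = TRUE)
    n_probes <- if (length(nsnp)) as.integer(sub("^numsnp=", "", nsnp[1])) else NA_integer_
    # sample id: the field after the state field
    state_pos <- which(fields == cnf)
    if (state_pos >= length(fields))
      parse_error("missing sample identifier after cn field", line = ln)
    out[[i]] <- data.frame(sample_id = fields[state_pos + 1L],
                           chromosome = normalize_chrom(m[3]),
                           start = start, end = end, copy_number = cn,
                           n_probes = n_probes, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, out)
}

parse_cnv_tsv <- function(lines) {
  if (!length(lines) || !nzchar(trimws(lines[1]))) return(empty_calls())
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "chromosome", "start", "end", "copy_number")
  missing <- setdiff(need, names(df))
  if (length(missing))
    parse_error(sprintf("TSV is missing column(s): %s",
                        paste(missing, collapse = ", ")), line = 1L)
  if (!nrow(df)) return(empty_calls())
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad))
    parse_error("start > end or non-numeric coordinate", line = bad[1] + 1L)
  bad_cn <- which(df$copy_number == 2L)
  if (length(bad_cn))
    parse_error("copy number 2 is not a variant call", line = bad_cn[1] + 1L)
  data.frame(sample_id = as.character(df$sample_id),
             chromosome = normalize_chrom(df$chromosome),
             start = as.integer(df$start), end = as.integer(df$end),
             copy_number = as.integer(df$copy_number),
             n_probes = if ("n_probes" %in% names(df)) as.integer(df$n_probes)
                        else NA_integer_,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(sample_id = character(), chromosome = character(),
             start = integer(), end = integer(), copy_number = integer(),
             n_probes = integer(), stringsAsFactors = FALSE)
}

#' Per-sample CNV-calling quality control
#'
#' A sample fails QC when its waviness factor lies strictly outside
#' `[-wf_limit, wf_limit]` or it carries strictly more than `max_cnvs`
#' genome-wide CNV calls. The boundary values (waviness exactly +/-0.03;
#' exactly 40 calls) are retained.
#'
#' @param stats data frame with columns `sample_id`, `waviness_factor`,
#'   `n_cnvs`.
#' @param wf_limit waviness-factor magnitude above which a sample is
#'   excluded (default 0.03).
#' @param max_cnvs genome-wide call count above which a sample is excluded
#'   (default 40).
#' @return `stats` with added columns `qc_pass` (logical) and `qc_reason`
#'   (`NA`, `"waviness"` or `"cnv_count"`; waviness reported first when both
#'   fail).
#' @export
#' @examples
#' sample_qc(data.frame(sample_id = "S1", waviness_factor = 0.03, n_cnvs = 40))
sample_qc <- function(stats, wf_limit = 0.03, max_cnvs = 40) {
  need <- c("sample_id", "waviness_factor", "n_cnvs")
  missing <- setdiff(need, names(stats))
  if (length(missing))
    config_error(sprintf("sample stats missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 field = "sample_stats")
  if (any(stats$n_cnvs < 0, na.rm = TRUE))
    config_error("n_cnvs must be non-negative", field = "sample_stats")
  wavy <- abs(stats$waviness_factor) > wf_limit
  many <- stats$n_cnvs > max_cnvs
  stats$qc_pass <- !(wavy | many)
  stats$qc_reason <- ifelse(wavy, "waviness",
                            ifelse(many, "cnv_count", NA_character_))
  stats
}

# Union length of a set of 1-based inclusive intervals clipped to
# [lo, hi]. Hand-rolled sort-and-merge; the locus is a single interval so
# this is the whole overlap computation.
clipped_union_length <- function(starts, ends, lo, hi) {
  s <- pmax(as.numeric(starts), lo)
  e <- pmin(as.numeric(ends), hi)
  keep <- s <= e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

#' Genotype a deletion locus from one sample's CNV calls
#'
#' The overlap fraction is the length of the union of the sample's
#' heterozygous (copy number 1) call intervals intersected with the locus,
#' divided by the locus length, all in 1-based inclusive arithmetic. The
#' sample is a deletion carrier when the fraction reaches `min_fraction`.
#' Any copy-number-0 call overlapping the locus is anomalous (no
#' homozygous deletion is expected at this locus) and forces
#' `carrier = FALSE` with `anomaly = "homozygous_deletion_at_locus"`.
#'
#' @param calls data frame of CNV calls (see [parse_cnv_calls()]) for a
#'   single sample; an empty frame is allowed.
#' @param locus a [genomic_interval()]; defaults to [bp1bp2_locus()].
#' @param min_fraction minimum locus coverage for carrier status
#'   (default 0.95).
#' @param sample_id sample identifier to report when `calls` is empty.
#' @return One-row data frame: `sample_id`, `carrier`, `overlap_fraction`,
#'   `anomaly`.
#' @export
#' @examples
#' calls <- data.frame(sample_id = "S1", chromosome = "15",
#'                     start = 22800000L, end = 23100000L,
#'                     copy_number = 1L, n_probes = NA_integer_)
#' detect_locus_deletion(calls)
detect_locus_deletion <- function(calls, locus = bp1bp2_locus(),
                                  min_fraction = 0.95, sample_id = NULL) {
  ids <- unique(calls$sample_id)
  if (length(ids) > 1L)
    usage_error("detect_locus_deletion expects calls from a single sample")
  sid <- if (length(ids)) ids else sample_id %||% NA_character_
  on_chrom <- calls[normalize_chrom(calls$chromosome) == locus$chromosome, ,
                    drop = FALSE]
  het <- on_chrom[on_chrom$copy_number == 1L, , drop = FALSE]
  hom <- on_chrom[on_chrom$copy_number == 0L, , drop = FALSE]
  frac <- clipped_union_length(het$start, het$end, locus$start, locus$end) /
    interval_length(locus)
  anomaly <- NA_character_
  carrier <- frac >= min_fraction
  if (nrow(hom) &&
      clipped_union_length(hom$start, hom$end, locus$start, locus$end) > 0) {
    anomaly <- "homozygous_deletion_at_locus"
    carrier <- FALSE
  }
  data.frame(sample_id = sid, carrier = carrier, overlap_fraction = frac,
             anomaly = anomaly, stringsAsFactors = FALSE)
}

#' Genotype the deletion locus for every sample in a cohort
#'
#' Vectorised wrapper around the single-sample rule of
#' [detect_locus_deletion()]: samples with no copy-number-<2 call touching
#' the locus get `overlap_fraction` 0 without further work.
#'
#' @param calls data frame of CNV calls for any number of samples.
#' @param sample_ids sample identifiers to genotype (samples without calls
#'   get fraction 0); defaults to the samples present in `calls`.
#' @inheritParams detect_locus_deletion
#' @return Data frame with one row per sample: `sample_id`, `carrier`,
#'   `overlap_fraction`, `anomaly`.
#' @export
genotype_deletion <- function(calls, sample_ids = NULL,
                              locus = bp1bp2_locus(), min_fraction = 0.95) {
  if (is.null(sample_ids)) sample_ids <- unique(calls$sample_id)
  at_locus <- calls[normalize_chrom(calls$chromosome) == locus$chromosome &
                      calls$copy_number < 2L &
                      calls$start <= locus$end & calls$end >= locus$start, ,
                    drop = FALSE]
  res <- data.frame(sample_id = as.character(sample_ids), carrier = FALSE,
                    overlap_fraction = 0, anomaly = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(at_locus)) {
    per <- lapply(split(at_locus, at_locus$sample_id), detect_locus_deletion,
                  locus = locus, min_fraction = min_fraction)
    per <- do.call(rbind, per)
    idx <- match(per$sample_id, res$sample_id)
    hit <- !is.na(idx)
    res$carrier[idx[hit]] <- per$carrier[hit]
    res$overlap_fraction[idx[hit]] <- per$overlap_fraction[hit]
    res$anomaly[idx[hit]] <- per$anomaly[hit]
  }
  res
}
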