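#' Clinical code systems recognised by the phenotyping engine
#'
#' Events carry one of six coding systems: hospital diagnoses (ICD9, ICD10),
#' hospital procedures (OPCS4), touchscreen self-report (SELF_ILLNESS,
#' SELF_OPERATION) and death-register causes (DEATH). Death-register causes
#' are diagnosis codes, so codebook patterns with system `ICD9` or `ICD10`
#' also match events with system `DEATH`.
#'
#' @keywords internal
#' @name code-systems
NULL

CODE_SYSTEMS <- c("ICD9", "ICD10", "OPCS4", "SELF_ILLNESS", "SELF_OPERATION",
                  "DEATH")

# Code sets the classification cascade requires. A codebook may define more.
REQUIRED_SETS <- c(
  "syndrome_exclusions", "congenital_circulatory", "q211", "pfo_ops",
  "stroke", "atrial_fibrillation", "cvm_ops", "self_report_cvm",
  "self_report_heart_surgery", "bav_codes", "bav_exclusions",
  "control_exclusions", "neuropsych_cases", "neuropsych_control_exclusions",
  "cognitive_exclusions"
)

parse_pattern <- function(x) {
  parts <- regmatches(x, regexec("^([A-Z0-9_]+):(.+)$", x))[[1]]
  if (length(parts) != 3L)
    config_error(sprintf("pattern '%s' is not of the form SYSTEM:code", x),
                 field = "codebook")
  system <- parts[2]
  if (!system %in% CODE_SYSTEMS)
    config_error(sprintf("unknown coding system '%s' in pattern '%s'",
                         system, x), field = "codebook")
  code <- parts[3]
  prefix <- endsWith(code, "*")
  list(system = system,
       code = if (prefix) substr(code, 1L, nchar(code) - 1L) else code,
       prefix = prefix)
}

#' Construct a phenotyping codebook
#'
#' A codebook maps named code sets to lists of `"SYSTEM:pattern"` strings,
#' where a pattern is an exact code (`"ICD10:Q211"`) or a prefix ending in
#' `*` (`"ICD10:Q2*"`). The classification cascade
#' ([classify_cvm()], [classify_neuropsych()], [cognitive_eligibility()])
#' consults sets by name; [REQUIRED_SETS] lists the names it needs.
#'
#' @param sets named list; each element a character vector of
#'   `"SYSTEM:pattern"` strings.
#' @return An object of class `codebook`: a named list of parsed pattern
#'   tables.
#' @export
#' @examples
#' cb <- codebook(list(q211 = "ICD10:Q211", stroke = c("ICD10:I63*", "ICD10:I64")))
codebook <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    config_error("all code sets must be named", field = "codebook")
  parsed <- lapply(sets, function(patterns) {
    ps <- lapply(as.character(patterns), parse_pattern)
    data.frame(
      system = vapply(ps, `[[`, "", "system"),
      code   = vapply(ps, `[[`, "", "code"),
      prefix = vapply(ps, `[[`, NA, "prefix"),
      stringsAsFactors = FALSE
    )
  })
  structure(parsed, class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Phenotyping codebook with", length(x), "code sets:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %3d pattern(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Read a codebook from a YAML file
#'
#' The file holds a top-level `sets:` mapping of set names to lists of
#' `"SYSTEM:pattern"` strings. See the shipped default at
#' `system.file("extdata", "default_codebook.yaml", package = "cnvcohort")`.
#'
#' @param path path to a YAML codebook file.
#' @return A [codebook] object.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path))
    config_error(sprintf("codebook file '%s' does not exist", path),
                 field = "codebook")
  y <- yaml::read_yaml(path)
  if (is.null(y$sets))
    config_error("codebook file has no top-level 'sets' mapping",
                 field = "codebook")
  codebook(lapply(y$sets, unlist))
}

#' The shipped default codebook
#'
#' A documented stand-in for the study-specific supplementary code lists,
#' which are not redistributed here: congenital circulatory malformations as
#' the ICD-10 Q20-Q28 block (plus ICD-9 745-747), K165 as the PFO-specific
#' operation, I63/I64 stroke, I48 atrial fibrillation, I35/aortic-valve
#' procedure codes as the bicuspid-aortic-valve pattern, endocarditis as a
#' valve-disease exclusion, chromosomal/syndromic Q87/Q9x exclusions, and
#' F-chapter subsets for the neuropsychiatric case and exclusion groups.
#' Analyses of real data should supply their own curated codebook via
#' [read_codebook()].
#'
#' @param check if `TRUE` (default) verify every set in [REQUIRED_SETS] is
#'   present.
#' @return A [codebook] object.
#' @export
default_codebook <- function(check = TRUE) {
  cb <- read_codebook(system.file("extdata", "default_codebook.yaml",
                                  package = "cnvcohort"))
  if (check) validate_codebook(cb)
  cb
}

#' Validate that a codebook defines every set the cascade consults
#'
#' @param cb a [codebook] object.
#' @param required character vector of set names that must be present.
#' @return `cb`, invisibly; errors if a required set is missing.
#' @export
validate_codebook <- function(cb, required = REQUIRED_SETS) {
  missing <- setdiff(required, names(cb))
  if (length(missing))
    config_error(sprintf("codebook is missing required set(s): %s",
                         paste(missing, collapse = ", ")),
                 field = "codebook")
  invisible(cb)
}

# Exact (non-wildcard) codes of a set; the synthetic generator samples these.
exact_codes <- function(cb, set) {
  s <- cb[[set]]
  if (is.null(s) || !any(!s$prefix))
    config_error(sprintf("code set '%s' defines no exact code to emit", set),
                 field = set)
  s[!s$prefix, c("system", "code")]
}
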