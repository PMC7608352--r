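#' Match clinical events against a code set
#'
#' Patterns are `"SYSTEM:code"` strings (or a parsed codebook set): exact
#' match on the code for plain patterns, prefix match for patterns ending
#' in `*`; the coding system must match, except that diagnosis patterns
#' (`ICD9`, `ICD10`) also match `DEATH` events — death-register causes are
#' diagnosis codes, and the two code spaces cannot collide (ICD-9 codes
#' are numeric, ICD-10 codes start with a letter).
#'
#' @param events data frame with columns `participant_id`, `system`,
#'   `code`, `age_at_event` and optionally `tiebreak`.
#' @param code_set character vector of `"SYSTEM:pattern"` strings, or one
#'   element of a [codebook()].
#' @return The matching rows of `events`, sorted by
#'   `(age_at_event, tiebreak)`.
#' @export
#' @examples
#' ev <- data.frame(participant_id = "P1", system = "ICD10", code = "Q211",
#'                  age_at_event = 50, tiebreak = NA_real_)
#' match_codes(ev, "ICD10:Q2*")
match_codes <- function(events, code_set) {
  if (!is.data.frame(code_set))
    code_set <- codebook(list(s = code_set))$s
  hit <- set_membership_one(events, code_set)
  out <- events[hit, , drop = FALSE]
  tb <- if ("tiebreak" %in% names(out)) out$tiebreak else rep(NA_real_, nrow(out))
  out[order(out$age_at_event, tb, na.last = TRUE), , drop = FALSE]
}

# logical vector over rows of `events` for one parsed set
set_membership_one <- function(events, set_df) {
  n <- nrow(events)
  hit <- logical(n)
  if (!n || !nrow(set_df)) return(hit)
  ev_sys <- as.character(events$system)
  ev_code <- as.character(events$code)
  for (k in seq_len(nrow(set_df))) {
    sys_ok <- ev_sys == set_df$system[k] |
      (set_df$system[k] %in% c("ICD9", "ICD10") & ev_sys == "DEATH")
    if (set_df$prefix[k]) {
      hit <- hit | (sys_ok & startsWith(ev_code, set_df$code[k]))
    } else {
      hit <- hit | (sys_ok & ev_code == set_df$code[k])
    }
  }
  hit
}

# membership of every event in every codebook set: named list of logicals
set_membership <- function(events, cb) {
  lapply(cb, set_membership_one, events = events)
}

# ordering helpers on (age, tiebreak) ----------------------------------

# is event i strictly before event j, resolving an age tie without full
# tiebreak information as "before" (conservative toward PFO exclusion)?
strictly_before <- function(age_i, tb_i, age_j, tb_j) {
  if (age_i < age_j) return(TRUE)
  if (age_i > age_j) return(FALSE)
  if (is.na(tb_i) || is.na(tb_j)) return(TRUE)
  tb_i < tb_j
}

# is event i at or before event j? An age tie without tiebreaks counts as
# "at" (an AF code discovered during the same admission as the stroke).
at_or_before <- function(age_i, tb_i, age_j, tb_j) {
  if (age_i < age_j) return(TRUE)
  if (age_i > age_j) return(FALSE)
  if (is.na(tb_i) || is.na(tb_j)) return(TRUE)
  tb_i <= tb_j
}

assignment <- function(id, phenotype, status, reason, evidence) {
  structure(list(participant_id = id, phenotype = phenotype, status = status,
                 reason = reason, evidence = evidence),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat(sprintf("%s: %s %s%s\n", x$participant_id, x$phenotype, x$status,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  if (nrow(x$evidence)) {
    cat("evidence:\n")
    print(x$evidence, row.names = FALSE)
  }
  invisible(x)
}

get_tb <- function(ev) {
  if ("tiebreak" %in% names(ev)) as.numeric(ev$tiebreak)
  else rep(NA_real_, nrow(ev))
}

# the cascade proper; `ev` is one participant's events, `m` the membership
# list for those rows
classify_cvm_one <- function(id, ev, m) {
  tb <- get_tb(ev)
  age <- as.numeric(ev$age_at_event)
  res <- function(status, reason, idx)
    assignment(id, "CVM", status, reason, ev[idx, , drop = FALSE])

  # (1) syndromic samples are removed outright
  if (any(m$syndrome_exclusions))
    return(res("EXCLUDED", "SYNDROME", which(m$syndrome_exclusions)))

  # Q211 is ambiguous (atrial septal defect vs patent foramen ovale);
  # decide whether its evidence is voided before using it
  pfo_reason <- NULL
  pfo_idx <- integer()
  q211_idx <- which(m$q211)
  if (length(q211_idx)) {
    if (any(m$pfo_ops)) {
      pfo_reason <- "PFO_K165"
      pfo_idx <- c(q211_idx, which(m$pfo_ops))
    } else {
      qi <- q211_idx[order(age[q211_idx], tb[q211_idx], na.last = TRUE)][1]
      stroke_idx <- which(m$stroke)
      af_idx <- which(m$atrial_fibrillation)
      for (s in stroke_idx) {
        af_covered <- any(vapply(af_idx, function(a)
          at_or_before(age[a], tb[a], age[s], tb[s]), NA))
        if (!af_covered && strictly_before(age[s], tb[s], age[qi], tb[qi])) {
          pfo_reason <- "PFO_PRIOR_STROKE"
          pfo_idx <- c(s, qi)
          break
        }
      }
    }
  }

  # (2) congenital circulatory codes other than (voided) Q211
  cong_other <- m$congenital_circulatory & !m$q211
  if (any(cong_other))
    return(res("CASE", "CONGENITAL_CODE", which(cong_other)))
  if (length(q211_idx) && is.null(pfo_reason))
    return(res("CASE", "ASD_Q211", q211_idx))

  # (3) congenital-heart operations and self-report
  if (any(m$cvm_ops))
    return(res("CASE", "CVM_OPERATION", which(m$cvm_ops)))
  if (any(m$self_report_cvm))
    return(res("CASE", "SELF_REPORT_CVM", which(m$self_report_cvm)))
  hs <- m$self_report_heart_surgery & age < 18
  if (any(hs))
    return(res("CASE", "HEART_SURGERY_U18", which(hs)))

  # (4) bicuspid-aortic-valve pattern: congenital only when diagnosed < 65
  # and free of acquired-valve-disease exclusions
  bav_reason <- NULL
  bav_idx <- which(m$bav_codes)
  if (length(bav_idx)) {
    if (any(m$bav_exclusions)) {
      bav_reason <- "BAV_EXCLUSION"
      bav_idx <- c(bav_idx, which(m$bav_exclusions))
    } else if (min(age[bav_idx]) < 65) {
      return(res("CASE", "BAV_LT_65", bav_idx))
    } else {
      bav_reason <- "BAV_AGE_GE_65"
    }
  }

  # (6) remaining samples: excluded from controls, or clean controls
  if (!is.null(pfo_reason)) return(res("EXCLUDED", pfo_reason, pfo_idx))
  if (!is.null(bav_reason)) return(res("EXCLUDED", bav_reason, bav_idx))
  if (any(m$control_exclusions))
    return(res("EXCLUDED", "CONTROL_EXCLUSION_CODE",
               which(m$control_exclusions)))
  res("CONTROL", NA_character_, integer())
}

classify_neuropsych_one <- function(id, ev, m) {
  res <- function(status, reason, idx)
    assignment(id, "NEUROPSYCH", status, reason, ev[idx, , drop = FALSE])
  if (any(m$neuropsych_cases))
    return(res("CASE", "NEUROPSYCH_CODE", which(m$neuropsych_cases)))
  if (any(m$neuropsych_control_exclusions))
    return(res("EXCLUDED", "NEUROPSYCH_OTHER_F_CODE",
               which(m$neuropsych_control_exclusions)))
  res("CONTROL", NA_character_, integer())
}

check_one_participant <- function(events, participant_id) {
  ids <- unique(as.character(events$participant_id))
  if (length(ids) > 1L)
    usage_error("events belong to more than one participant")
  if (!is.null(participant_id) && length(ids) && ids != participant_id)
    usage_error(sprintf("events belong to participant '%s', not '%s'",
                        ids, participant_id))
  if (is.null(participant_id)) {
    if (!length(ids)) usage_error("participant_id required when events are empty")
    participant_id <- ids
  }
  participant_id
}

#' Classify congenital cardiovascular malformation status for one participant
#'
#' Deterministic, codebook-driven cascade over a participant's coded
#' clinical history. In order: (1) any syndromic code excludes the sample;
#' (2) congenital-circulatory diagnosis codes make it a case, except that
#' Q211 evidence is voided when the history indicates patent foramen ovale
#' rather than atrial septal defect (a PFO-specific operation code, or a
#' stroke with no atrial-fibrillation code at or before it occurring
#' strictly before the earliest Q211); (3) congenital-heart operations and
#' self-reports (self-reported heart surgery only under age 18) make a
#' case; (4) aortic-valve disease first diagnosed before 65 with no
#' acquired-valve exclusion is taken as congenital bicuspid aortic valve
#' (a case); at 65 or older, or with an exclusion code, the sample leaves
#' the control pool; (5) death-register causes participate through the
#' same sets; (6) otherwise control-exclusion codes remove the sample from
#' controls, and a clean history is a control.
#'
#' @param events data frame of one participant's events (`system`, `code`,
#'   `age_at_event`, optional `tiebreak`).
#' @param cb a [codebook()].
#' @param participant_id participant identifier (required if `events` is
#'   empty).
#' @return A `phenotype_assignment`: status `CASE`/`CONTROL`/`EXCLUDED`,
#'   a machine-readable `reason`, and the triggering `evidence` rows.
#' @export
classify_cvm <- function(events, cb, participant_id = NULL) {
  participant_id <- check_one_participant(events, participant_id)
  classify_cvm_one(participant_id, events, set_membership(events, cb))
}

#' Classify neuropsychiatric case/control status for one participant
#'
#' Any code in the neuropsychiatric case set (schizophrenia spectrum,
#' bipolar disorder, autism, intellectual disability, developmental
#' disorders) makes a case; any other mental-and-behavioural code removes
#' the participant from the control group; otherwise control.
#'
#' @inheritParams classify_cvm
#' @return A `phenotype_assignment`.
#' @export
classify_neuropsych <- function(events, cb, participant_id = NULL) {
  participant_id <- check_one_participant(events, participant_id)
  classify_neuropsych_one(participant_id, events, set_membership(events, cb))
}

#' Eligibility for the cognitive-function analyses
#'
#' Participants with any code in the `cognitive_exclusions` set (diagnoses
#' previously associated with the deletion) are removed from the whole
#' cohort before cognitive testing analyses.
#'
#' @inheritParams classify_cvm
#' @return `TRUE` when eligible.
#' @export
cognitive_eligibility <- function(events, cb, participant_id = NULL) {
  check_one_participant(events, participant_id)
  !any(set_membership_one(events, cb$cognitive_exclusions))
}

#' Classify every participant in a cohort
#'
#' Vectorised driver for [classify_cvm()] and [classify_neuropsych()]:
#' membership of every event in every codebook set is computed once, and
#' only participants with at least one set-matching event go through the
#' cascade (a history free of classifying codes is a control for both
#' phenotypes and cognitively eligible).
#'
#' @param participants data frame with at least `participant_id`.
#' @param events data frame of all events (`participant_id`, `system`,
#'   `code`, `age_at_event`, optional `tiebreak`).
#' @param cb a [codebook()]; validated against the required set names.
#' @return Data frame with one row per participant and phenotype
#'   (`participant_id`, `phenotype`, `status`, `reason`) plus a
#'   `cognitive_eligible` logical column repeated across the participant's
#'   rows.
#' @export
classify_cohort <- function(participants, events, cb) {
  validate_codebook(cb)
  ids <- as.character(participants$participant_id)
  n <- length(ids)
  cvm_status <- rep("CONTROL", n); cvm_reason <- rep(NA_character_, n)
  np_status <- rep("CONTROL", n); np_reason <- rep(NA_character_, n)
  cog <- rep(TRUE, n)

  if (nrow(events)) {
    m_all <- set_membership(events, cb)
    any_hit <- Reduce(`|`, m_all)
    active <- unique(as.character(events$participant_id[any_hit]))
    active <- intersect(active, ids)
    if (length(active)) {
      sel <- as.character(events$participant_id) %in% active
      ev_a <- events[sel, , drop = FALSE]
      m_a <- lapply(m_all, `[`, sel)
      grp <- factor(as.character(ev_a$participant_id), levels = active)
      row_split <- split(seq_len(nrow(ev_a)), grp)
      pos <- match(active, ids)
      for (j in seq_along(active)) {
        rows <- row_split[[j]]
        ev_j <- ev_a[rows, , drop = FALSE]
        m_j <- lapply(m_a, `[`, rows)
        a_cvm <- classify_cvm_one(active[j], ev_j, m_j)
        a_np <- classify_neuropsych_one(active[j], ev_j, m_j)
        i <- pos[j]
        cvm_status[i] <- a_cvm$status; cvm_reason[i] <- a_cvm$reason
        np_status[i] <- a_np$status; np_reason[i] <- a_np$reason
        cog[i] <- !any(m_j$cognitive_exclusions)
      }
    }
  }

  data.frame(
    participant_id = rep(ids, 2L),
    phenotype = rep(c("CVM", "NEUROPSYCH"), each = n),
    status = c(cvm_status, np_status),
    reason = c(cvm_reason, np_reason),
    cognitive_eligible = rep(cog, 2L),
    stringsAsFactors = FALSE
  )
}
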