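#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate a biobank-scale cohort: deletion prevalence 0.38%,
#' CVM and neuropsychiatric case fractions of roughly 0.59% and 0.72% of
#' the analysed cohort, population odds ratios 1.73 (CVM) and 1.84
#' (neuropsychiatric), a +17.8 ms carrier shift in reaction time, a
#' log-rate shift of `log(5.40/5.99)` in fluid intelligence, per-sex
#' fecundity means of 1.66/1.80 (male carrier/non-carrier) and 1.88/1.82
#' (female), qualification category probabilities matching the observed
#' carrier and non-carrier attainment tables, and QC failure rates of
#' 301/488,366 (waviness) and 1,401/488,366 (CNV-count excess).
#'
#' @param n_participants cohort size (>= 1).
#' @param deletion_prevalence probability a participant carries the
#'   heterozygous BP1-BP2 deletion.
#' @param cvm_prevalence,neuropsych_prevalence overall case probabilities
#'   for the two phenotypes (before decoy/exclusion thinning).
#' @param or_cvm,or_neuropsych target population odds ratios between
#'   carrier status and each phenotype; the non-carrier risk is solved
#'   from prevalence and OR so the configured OR is the true parameter.
#' @param decoy_rates named probabilities, drawn among true CVM controls,
#'   of histories that must route to EXCLUDED: `pfo_k165`,
#'   `pfo_prior_stroke`, `bav_ge65`, `endocarditis_valve`, `syndrome`.
#' @param neuropsych_exclusion_rate probability a neuropsychiatric
#'   control carries some other mental-and-behavioural code (routing to
#'   EXCLUDED).
#' @param control_noise_rate probability any participant carries an
#'   innocuous, non-classifying code (exercises monotone irrelevance).
#' @param cognitive_effects list of carrier effects: `reaction_time_ms`
#'   (additive), `fluid_intelligence_log_rate`, `numeric_memory_log_odds`,
#'   `pairs_matching_log_odds`.
#' @param qualification_probs list with `carrier` and `noncarrier` named
#'   probability vectors over `degree`, `alevels`, `other` (each summing
#'   to 1).
#' @param fecundity_rates list with `male` and `female` elements, each a
#'   named vector `c(carrier=, noncarrier=)` of Poisson means.
#' @param qc_fail_rates named probabilities `waviness` and `cnv_count`.
#' @param deletion_boundary_jitter_bp maximum absolute per-boundary jitter
#'   (bp) applied to carriers' locus calls; must leave the 95% overlap
#'   rule satisfiable.
#' @param background_cnv_mean Poisson mean of background autosomal CNV
#'   calls per sample.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(
    n_participants,
    deletion_prevalence = 0.0038,
    cvm_prevalence = 0.0059,
    neuropsych_prevalence = 0.0072,
    or_cvm = 1.73,
    or_neuropsych = 1.84,
    decoy_rates = c(pfo_k165 = 0.002, pfo_prior_stroke = 0.001,
                    bav_ge65 = 0.004, endocarditis_valve = 0.0005,
                    syndrome = 0.001),
    neuropsych_exclusion_rate = 0.008,
    control_noise_rate = 0.02,
    cognitive_effects = list(reaction_time_ms = 17.8,
                             fluid_intelligence_log_rate = log(5.40 / 5.99),
                             numeric_memory_log_odds = -0.35,
                             pairs_matching_log_odds = 0.15),
    qualification_probs = list(
      noncarrier = c(degree = 0.32843, alevels = 0.11242, other = 0.55915),
      carrier = c(degree = 0.22898, alevels = 0.10232, other = 0.66870)),
    fecundity_rates = list(male = c(carrier = 1.66, noncarrier = 1.80),
                           female = c(carrier = 1.88, noncarrier = 1.82)),
    qc_fail_rates = c(waviness = 301 / 488366, cnv_count = 1401 / 488366),
    deletion_boundary_jitter_bp = 5000,
    background_cnv_mean = 3,
    seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            deletion_prevalence = deletion_prevalence,
            cvm_prevalence = cvm_prevalence,
            neuropsych_prevalence = neuropsych_prevalence,
            or_cvm = or_cvm, or_neuropsych = or_neuropsych,
            decoy_rates = decoy_rates,
            neuropsych_exclusion_rate = neuropsych_exclusion_rate,
            control_noise_rate = control_noise_rate,
            cognitive_effects = cognitive_effects,
            qualification_probs = qualification_probs,
            fecundity_rates = fecundity_rates,
            qc_fail_rates = qc_fail_rates,
            deletion_boundary_jitter_bp = deletion_boundary_jitter_bp,
            background_cnv_mean = background_cnv_mean,
            seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  chk_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      config_error("must be a probability in [0, 1]", field = field)
  }
  if (is.na(p$n_participants) || p$n_participants < 1L)
    config_error("must be >= 1", field = "n_participants")
  chk_prob(p$deletion_prevalence, "deletion_prevalence")
  chk_prob(p$cvm_prevalence, "cvm_prevalence")
  chk_prob(p$neuropsych_prevalence, "neuropsych_prevalence")
  chk_prob(p$decoy_rates, "decoy_rates")
  chk_prob(p$neuropsych_exclusion_rate, "neuropsych_exclusion_rate")
  chk_prob(p$control_noise_rate, "control_noise_rate")
  chk_prob(p$qc_fail_rates, "qc_fail_rates")
  if (p$or_cvm <= 0) config_error("must be > 0", field = "or_cvm")
  if (p$or_neuropsych <= 0) config_error("must be > 0", field = "or_neuropsych")
  need_decoys <- c("pfo_k165", "pfo_prior_stroke", "bav_ge65",
                   "endocarditis_valve", "syndrome")
  if (!all(need_decoys %in% names(p$decoy_rates)))
    config_error(sprintf("must name rates: %s",
                         paste(need_decoys, collapse = ", ")),
                 field = "decoy_rates")
  if (sum(p$decoy_rates) > 1)
    config_error("decoy rates sum to more than 1", field = "decoy_rates")
  for (g in c("carrier", "noncarrier")) {
    q <- p$qualification_probs[[g]]
    if (is.null(q) || !all(c("degree", "alevels", "other") %in% names(q)))
      config_error("needs degree/alevels/other entries for both groups",
                   field = "qualification_probs")
    if (abs(sum(q) - 1) > 1e-6)
      config_error(sprintf("probabilities for '%s' sum to %.6f, not 1",
                           g, sum(q)), field = "qualification_probs")
  }
  for (s in c("male", "female")) {
    r <- p$fecundity_rates[[s]]
    if (is.null(r) || !all(c("carrier", "noncarrier") %in% names(r)) ||
        any(r <= 0))
      config_error("needs positive carrier/noncarrier means for both sexes",
                   field = "fecundity_rates")
  }
  if (p$deletion_boundary_jitter_bp < 0)
    config_error("must be non-negative", field = "deletion_boundary_jitter_bp")
  max_jitter <- max_locus_jitter()
  if (p$deletion_boundary_jitter_bp > max_jitter)
    config_error(sprintf(
      "jitter of %d bp can shrink a carrier call below 95%% locus coverage (max %d)",
      p$deletion_boundary_jitter_bp, max_jitter),
      field = "deletion_boundary_jitter_bp")
  if (p$background_cnv_mean < 0)
    config_error("must be non-negative", field = "background_cnv_mean")
  invisible(p)
}

# Largest per-boundary jitter that keeps a carrier call's worst-case
# locus coverage at or above min_fraction (1-based inclusive arithmetic).
max_locus_jitter <- function(locus = bp1bp2_locus(), min_fraction = 0.95) {
  len <- interval_length(locus)
  floor((len - ceiling(min_fraction * len)) / 2)
}

#' Solve the non-carrier risk that realises a target population odds ratio
#'
#' Given overall phenotype prevalence `p`, carrier fraction `q` and target
#' odds ratio `or`, solves `p = q*p1 + (1-q)*p0` with
#' `p1/(1-p1) = or * p0/(1-p0)` for the non-carrier risk `p0` by 1-D root
#' finding, so the configured OR is the true population parameter.
#'
#' @param p overall phenotype prevalence.
#' @param q carrier fraction.
#' @param or target odds ratio.
#' @return List with `p0` (non-carrier risk) and `p1` (carrier risk).
#' @export
#' @examples
#' solve_noncarrier_risk(0.0059, 0.0038, 1.73)
solve_noncarrier_risk <- function(p, q, or) {
  if (p <= 0 || p >= 1) config_error("prevalence must be in (0, 1)",
                                     field = "prevalence")
  if (or == 1 || q == 0) return(list(p0 = p, p1 = p))
  p1_of <- function(p0) { o <- or * p0 / (1 - p0); o / (1 + o) }
  f <- function(p0) q * p1_of(p0) + (1 - q) * p0 - p
  root <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  list(p0 = root, p1 = p1_of(root))
}

# integer uniform draw on [lo, hi], vectorised over both bounds
runif_int <- function(lo, hi) {
  lo + floor(stats::runif(length(lo)) * (hi - lo + 1))
}

# sample k (system, code) rows from the exact codes of a codebook set,
# optionally removing codes that belong to another set
sample_codes <- function(cb, set, k, minus = NULL) {
  pool <- exact_codes(cb, set)
  if (!is.null(minus)) {
    drop <- exact_codes(cb, minus)
    pool <- pool[!(paste(pool$system, pool$code) %in%
                     paste(drop$system, drop$code)), , drop = FALSE]
    if (!nrow(pool))
      config_error(sprintf("set '%s' has no exact code outside '%s'",
                           set, minus), field = set)
  }
  pool[sample.int(nrow(pool), k, replace = TRUE), , drop = FALSE]
}

ev_frame <- function(id, system, code, age, tiebreak = NA_real_) {
  data.frame(participant_id = id, system = system, code = code,
             age_at_event = age, tiebreak = tiebreak,
             stringsAsFactors = FALSE)
}

#' Emit coded clinical histories realising ground-truth labels
#'
#' True CVM cases receive one of the case-defining code paths (a
#' congenital diagnosis code, Q211 alone, Q211 with a stroke covered by
#' atrial fibrillation, a congenital-heart operation, self-reported
#' congenital heart illness, self-reported heart surgery under 18, or an
#' aortic-valve code before 65); each decoy kind receives exactly the
#' pattern that must route it to EXCLUDED (Q211 plus K165; an
#' AF-free stroke dated before Q211; aortic stenosis at 65 or older;
#' a valve code plus endocarditis; a syndrome code alongside a congenital
#' code); neuropsychiatric cases and excluded controls receive the
#' corresponding F-chapter codes; clean controls receive no classifying
#' code. A fraction of deceased cases carry their diagnosis on the death
#' register (system `DEATH`). Event ages are consistent with year of
#' birth; draws use the current RNG state.
#'
#' @param truth ground-truth data frame (`participant_id`, `true_cvm`,
#'   `true_neuropsych`; see [simulate_cohort()]).
#' @param participants matching participant table (`participant_id`,
#'   `sex`, `year_of_birth`, `deceased`).
#' @param cb a [codebook()]; every emitted branch needs at least one exact
#'   code in its set.
#' @param control_noise_rate probability of an innocuous non-classifying
#'   code per participant.
#' @param reference_year calendar year used to convert year of birth to
#'   current age (default 2010).
#' @return Data frame of events (`participant_id`, `system`, `code`,
#'   `age_at_event`, `tiebreak`).
#' @export
emit_code_history <- function(truth, participants, cb,
                              control_noise_rate = 0, reference_year = 2010) {
  validate_codebook(cb)
  stopifnot(nrow(truth) == nrow(participants))
  id <- as.character(truth$participant_id)
  age_now <- reference_year - participants$year_of_birth
  if (any(age_now < 18))
    config_error("participants must be at least 18 at the reference year",
                 field = "year_of_birth")
  deceased <- as.logical(participants$deceased)
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x

  # --- CVM case paths ---------------------------------------------------
  case_i <- which(truth$true_cvm == "case")
  if (length(case_i)) {
    paths <- sample(c("congenital", "q211", "q211_stroke_af", "cvm_op",
                      "self_illness", "heart_surgery_u18", "bav_lt65"),
                    length(case_i), replace = TRUE,
                    prob = c(0.25, 0.12, 0.05, 0.15, 0.08, 0.10, 0.25))
    pick <- function(p) case_i[paths == p]

    i <- pick("congenital")
    if (length(i)) {
      codes <- sample_codes(cb, "congenital_circulatory", length(i),
                            minus = "q211")
      a <- runif_int(rep(25L, length(i)), age_now[i])
      sys <- codes$system
      # some deceased cases are only seen on the death register
      flip <- deceased[i] & codes$system %in% c("ICD9", "ICD10") &
        stats::runif(length(i)) < 0.5
      sys[flip] <- "DEATH"
      add(ev_frame(id[i], sys, codes$code, a))
    }
    i <- pick("q211")
    if (length(i)) {
      codes <- sample_codes(cb, "q211", length(i))
      add(ev_frame(id[i], codes$system, codes$code,
                   runif_int(rep(30L, length(i)), age_now[i])))
    }
    i <- pick("q211_stroke_af")  # stroke explained by AF: Q211 stays ASD
    if (length(i)) {
      s_age <- runif_int(rep(35L, length(i)), age_now[i] - 1L)
      af <- sample_codes(cb, "atrial_fibrillation", length(i))
      st <- sample_codes(cb, "stroke", length(i))
      q <- sample_codes(cb, "q211", length(i))
      add(ev_frame(id[i], af$system, af$code, s_age, tiebreak = 0.1))
      add(ev_frame(id[i], st$system, st$code, s_age, tiebreak = 0.2))
      add(ev_frame(id[i], q$system, q$code,
                   runif_int(s_age + 1L, age_now[i])))
    }
    i <- pick("cvm_op")
    if (length(i)) {
      codes <- sample_codes(cb, "cvm_ops", length(i))
      add(ev_frame(id[i], codes$system, codes$code,
                   runif_int(rep(25L, length(i)), age_now[i])))
    }
    i <- pick("self_illness")
    if (length(i)) {
      codes <- sample_codes(cb, "self_report_cvm", length(i))
      add(ev_frame(id[i], codes$system, codes$code,
                   runif_int(rep(25L, length(i)), age_now[i])))
    }
    i <- pick("heart_surgery_u18")
    if (length(i)) {
      codes <- sample_codes(cb, "self_report_heart_surgery", length(i))
      add(ev_frame(id[i], codes$system, codes$code,
                   runif_int(rep(0L, length(i)), rep(17L, length(i)))))
    }
    i <- pick("bav_lt65")
    if (length(i)) {
      codes <- sample_codes(cb, "bav_codes", length(i))
      add(ev_frame(id[i], codes$system, codes$code,
                   runif_int(rep(35L, length(i)), pmin(64L, age_now[i]))))
    }
  }

  # --- CVM decoys: patterns that must be EXCLUDED -----------------------
  i <- which(truth$true_cvm == "pfo_k165")
  if (length(i)) {
    a <- runif_int(rep(35L, length(i)), age_now[i])
    q <- sample_codes(cb, "q211", length(i))
    k <- sample_codes(cb, "pfo_ops", length(i))
    add(ev_frame(id[i], q$system, q$code, a))
    add(ev_frame(id[i], k$system, k$code, pmin(a + 1L, age_now[i])))
  }
  i <- which(truth$true_cvm == "pfo_prior_stroke")
  if (length(i)) {
    s_age <- runif_int(rep(35L, length(i)), age_now[i] - 1L)
    st <- sample_codes(cb, "stroke", length(i))
    q <- sample_codes(cb, "q211", length(i))
    add(ev_frame(id[i], st$system, st$code, s_age))
    add(ev_frame(id[i], q$system, q$code, runif_int(s_age + 1L, age_now[i])))
  }
  i <- which(truth$true_cvm == "bav_ge65")
  if (length(i)) {
    if (any(age_now[i] < 66L))
      config_error("bav_ge65 decoys require participants aged 66+",
                   field = "decoy_rates")
    codes <- sample_codes(cb, "bav_codes", length(i))
    add(ev_frame(id[i], codes$system, codes$code,
                 runif_int(rep(65L, length(i)), age_now[i])))
  }
  i <- which(truth$true_cvm == "endocarditis_valve")
  if (length(i)) {
    codes <- sample_codes(cb, "bav_codes", length(i))
    endo <- sample_codes(cb, "bav_exclusions", length(i))
    a <- runif_int(rep(35L, length(i)), pmin(64L, age_now[i]))
    add(ev_frame(id[i], codes$system, codes$code, a))
    add(ev_frame(id[i], endo$system, endo$code, a))
  }
  i <- which(truth$true_cvm == "syndrome")
  if (length(i)) {
    syn <- sample_codes(cb, "syndrome_exclusions", length(i))
    cong <- sample_codes(cb, "congenital_circulatory", length(i),
                         minus = "q211")
    a <- runif_int(rep(20L, length(i)), age_now[i])
    add(ev_frame(id[i], syn$system, syn$code, a))
    add(ev_frame(id[i], cong$system, cong$code, a))
  }

  # --- neuropsychiatric axis -------------------------------------------
  i <- which(truth$true_neuropsych == "case")
  if (length(i)) {
    codes <- sample_codes(cb, "neuropsych_cases", length(i))
    add(ev_frame(id[i], codes$system, codes$code,
                 runif_int(rep(18L, length(i)), age_now[i])))
  }
  i <- which(truth$true_neuropsych == "excluded_other_f")
  if (length(i)) {
    codes <- sample_codes(cb, "neuropsych_control_exclusions", length(i))
    add(ev_frame(id[i], codes$system, codes$code,
                 runif_int(rep(18L, length(i)), age_now[i])))
  }

  # --- innocuous noise codes (match no set) ----------------------------
  if (control_noise_rate > 0) {
    i <- which(stats::runif(length(id)) < control_noise_rate)
    if (length(i))
      add(ev_frame(id[i], "ICD10",
                   sample(c("J459", "M545", "K219"), length(i), replace = TRUE),
                   runif_int(rep(20L, length(i)), age_now[i])))
  }

  if (!length(out))
    return(ev_frame(character(), character(), character(), numeric())[0, ])
  do.call(rbind, out)
}

#' Simulate CNV calls and per-sample QC statistics for a cohort
#'
#' Deletion carriers receive one heterozygous (copy-number 1) call
#' covering the BP1-BP2 locus, with per-boundary jitter bounded so the
#' 95% overlap rule always holds; no sample receives a copy-number-0 call
#' at the locus. Background autosomal calls (away from chromosome 15) are
#' Poisson-distributed; samples designated as count-QC failures receive
#' more than 40 calls, and waviness factors are drawn inside
#' `[-0.03, 0.03]` for passing samples and outside it for
#' waviness-QC failures.
#'
#' @param truth ground-truth data frame with `participant_id`, `carrier`
#'   and the internal columns `qc_fail_waviness`, `qc_fail_count` (as
#'   produced by [simulate_cohort()]; absent columns are treated as all
#'   `FALSE`).
#' @param params a [cohort_params()] (used for jitter and background
#'   rate).
#' @param locus the deletion locus interval.
#' @return List with `calls` (CNV call data frame) and `stats`
#'   (`sample_id`, `waviness_factor`, `n_cnvs`).
#' @export
simulate_cnv_calls <- function(truth, params, locus = bp1bp2_locus()) {
  n <- nrow(truth)
  id <- as.character(truth$participant_id)
  carrier <- as.logical(truth$carrier)
  wf_fail <- if ("qc_fail_waviness" %in% names(truth))
    truth$qc_fail_waviness else rep(FALSE, n)
  cnt_fail <- if ("qc_fail_count" %in% names(truth))
    truth$qc_fail_count else rep(FALSE, n)
  jit <- params$deletion_boundary_jitter_bp
  if (jit > max_locus_jitter(locus))
    config_error("jitter too large for the 95% overlap rule",
                 field = "deletion_boundary_jitter_bp")

  calls <- list()
  nc <- sum(carrier)
  if (nc) {
    ds <- if (jit > 0) sample.int(2L * jit + 1L, nc, replace = TRUE) - jit - 1L
          else integer(nc)
    de <- if (jit > 0) sample.int(2L * jit + 1L, nc, replace = TRUE) - jit - 1L
          else integer(nc)
    calls[[1]] <- data.frame(
      sample_id = id[carrier], chromosome = locus$chromosome,
      start = locus$start + ds, end = locus$end + de, copy_number = 1L,
      n_probes = sample(80:150, nc, replace = TRUE), stringsAsFactors = FALSE)
  }

  n_bg <- stats::rpois(n, params$background_cnv_mean)
  n_bg[cnt_fail] <- 41L + stats::rpois(sum(cnt_fail), 5)
  tot <- sum(n_bg)
  if (tot) {
    owner <- rep(seq_len(n), n_bg)
    chrom <- sample(c(1:14, 16:22), tot, replace = TRUE)
    start <- sample.int(100000000L, tot, replace = TRUE)
    len <- sample(10000:200000, tot, replace = TRUE)
    calls[[length(calls) + 1L]] <- data.frame(
      sample_id = id[owner], chromosome = as.character(chrom),
      start = start, end = start + len - 1L,
      copy_number = sample(c(1L, 3L), tot, replace = TRUE),
      n_probes = sample(10:60, tot, replace = TRUE), stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()

  wf <- stats::runif(n, -0.029, 0.029)
  nf <- sum(wf_fail)
  if (nf)
    wf[wf_fail] <- sample(c(-1, 1), nf, replace = TRUE) *
      stats::runif(nf, 0.0305, 0.12)
  stats_df <- data.frame(sample_id = id, waviness_factor = wf,
                         n_cnvs = n_bg + as.integer(carrier),
                         stringsAsFactors = FALSE)
  list(calls = calls, stats = stats_df)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Draws carrier status, phenotype ground truth at the configured
#' population odds ratios (non-carrier risk solved analytically via
#' [solve_noncarrier_risk()]), decoy and exclusion labels, coded clinical
#' histories realising those labels ([emit_code_history()]), CNV calls
#' and QC statistics ([simulate_cnv_calls()]), cognitive scores,
#' qualifications and fecundity outcomes. CVM and neuropsychiatric status
#' are drawn independently given carrier status. Deterministic given
#' `params$seed`.
#'
#' @param params a [cohort_params()].
#' @param cb codebook used to emit code histories (default
#'   [default_codebook()]).
#' @return An object of class `cnv_cohort`: list of data frames
#'   `participants`, `events`, `cnv_calls`, `sample_stats`, `outcomes`,
#'   `ground_truth`, plus the `params`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_params(2000, seed = 7))
#' head(coh$ground_truth)
simulate_cohort <- function(params, cb = default_codebook()) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  n <- params$n_participants
  reference_year <- 2010
  id <- sprintf("S%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.54, "female", "male")
  yob <- sample(1937:1970, n, replace = TRUE)
  age <- reference_year - yob
  deceased <- stats::runif(n) < 0.03
  carrier <- stats::runif(n) < params$deletion_prevalence

  wf_fail <- stats::runif(n) < params$qc_fail_rates[["waviness"]]
  cnt_fail <- stats::runif(n) < params$qc_fail_rates[["cnv_count"]]
  qc_pass <- !(wf_fail | cnt_fail)

  # CVM ground truth at the configured population OR
  r <- solve_noncarrier_risk(params$cvm_prevalence,
                             params$deletion_prevalence, params$or_cvm)
  cvm_case <- stats::runif(n) < ifelse(carrier, r$p1, r$p0)
  true_cvm <- ifelse(cvm_case, "case", "control")
  ctrl_i <- which(!cvm_case)
  if (length(ctrl_i) && sum(params$decoy_rates) > 0) {
    u <- stats::runif(length(ctrl_i))
    edges <- cumsum(params$decoy_rates)
    kind <- rep("control", length(ctrl_i))
    lower <- c(0, edges[-length(edges)])
    for (k in seq_along(edges))
      kind[u >= lower[k] & u < edges[k]] <- names(params$decoy_rates)[k]
    # the >= 65 decoy needs a participant old enough to carry that age
    kind[kind == "bav_ge65" & age[ctrl_i] < 66] <- "control"
    true_cvm[ctrl_i] <- kind
  }

  # neuropsychiatric ground truth, independent of CVM given carrier status
  rn <- solve_noncarrier_risk(params$neuropsych_prevalence,
                              params$deletion_prevalence,
                              params$or_neuropsych)
  np_case <- stats::runif(n) < ifelse(carrier, rn$p1, rn$p0)
  true_np <- ifelse(np_case, "case", "control")
  np_ctrl <- which(!np_case)
  excl <- np_ctrl[stats::runif(length(np_ctrl)) <
                    params$neuropsych_exclusion_rate]
  true_np[excl] <- "excluded_other_f"

  participants <- data.frame(participant_id = id, sex = sex,
                             year_of_birth = yob, deceased = deceased,
                             stringsAsFactors = FALSE)
  ground_truth <- data.frame(participant_id = id, carrier = carrier,
                             true_cvm = true_cvm, true_neuropsych = true_np,
                             qc_pass = qc_pass, qc_fail_waviness = wf_fail,
                             qc_fail_count = cnt_fail,
                             stringsAsFactors = FALSE)

  events <- emit_code_history(ground_truth, participants, cb,
                              control_noise_rate = params$control_noise_rate,
                              reference_year = reference_year)
  cnv <- simulate_cnv_calls(ground_truth, params)

  # --- outcomes ---------------------------------------------------------
  eff <- params$cognitive_effects
  male <- as.integer(sex == "male")
  agec <- age - 56
  reaction_time <- 480 + 1.3 * age + 8 * male +
    eff$reaction_time_ms * carrier + stats::rnorm(n, 0, 110)
  fluid <- stats::rpois(n, exp(log(5.99) - 0.004 * agec + 0.01 * male +
                                 eff$fluid_intelligence_log_rate * carrier))
  p_nm <- stats::plogis(stats::qlogis(0.55) - 0.01 * agec + 0.05 * male +
                          eff$numeric_memory_log_odds * carrier)
  nm_hi <- stats::runif(n) < p_nm
  numeric_memory <- ifelse(nm_hi, sample(7:9, n, replace = TRUE),
                           sample(3:6, n, replace = TRUE))
  p_pm <- stats::plogis(stats::qlogis(0.35) + 0.008 * agec +
                          eff$pairs_matching_log_odds * carrier)
  pm_any <- stats::runif(n) < p_pm
  pairs_matching <- ifelse(pm_any, sample(1:3, n, replace = TRUE), 0L)
  qual <- character(n)
  for (g in c("carrier", "noncarrier")) {
    idx <- if (g == "carrier") which(carrier) else which(!carrier)
    if (length(idx)) {
      pr <- params$qualification_probs[[g]]
      qual[idx] <- sample(names(pr), length(idx), replace = TRUE, prob = pr)
    }
  }
  fr <- params$fecundity_rates
  lam <- ifelse(sex == "male",
                ifelse(carrier, fr$male[["carrier"]], fr$male[["noncarrier"]]),
                ifelse(carrier, fr$female[["carrier"]], fr$female[["noncarrier"]]))
  n_children <- stats::rpois(n, lam)

  outcomes <- data.frame(participant_id = id, reaction_time = reaction_time,
                         fluid_intelligence = fluid,
                         numeric_memory = numeric_memory,
                         pairs_matching = pairs_matching,
                         qualification = qual, n_children = n_children,
                         stringsAsFactors = FALSE)

  structure(list(participants = participants, events = events,
                 cnv_calls = cnv$calls, sample_stats = cnv$stats,
                 outcomes = outcomes, ground_truth = ground_truth,
                 params = params),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (seed %d)\n",
              nrow(x$participants), x$params$seed))
  cat(sprintf("  deletion carriers: %d (%.3f%%)\n",
              sum(x$ground_truth$carrier),
              100 * mean(x$ground_truth$carrier)))
  cat(sprintf("  true CVM cases: %d; decoys: %d\n",
              sum(x$ground_truth$true_cvm == "case"),
              sum(!x$ground_truth$true_cvm %in% c("case", "control"))))
  cat(sprintf("  true neuropsychiatric cases: %d\n",
              sum(x$ground_truth$true_neuropsych == "case")))
  cat(sprintf("  events: %d; CNV calls: %d; QC-pass samples: %d\n",
              nrow(x$events), nrow(x$cnv_calls), sum(x$ground_truth$qc_pass)))
  invisible(x)
}
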