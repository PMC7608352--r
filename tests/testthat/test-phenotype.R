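test_that("code matching respects system, exact codes and prefixes", {
  ev <- evts(evt("ICD10", "Q211", 50),
             evt("ICD9", "Q211", 50),
             evt("ICD10", "Q250", 40))
  expect_equal(nrow(match_codes(ev, "ICD10:Q211")), 1L)
  m <- match_codes(ev, "ICD10:Q2*")
  expect_equal(nrow(m), 2L)
  expect_equal(m$age_at_event, c(40, 50))   # sorted by age
  expect_equal(nrow(match_codes(ev, character())), 0L)
})

test_that("death-register events match diagnosis patterns", {
  ev <- evt("DEATH", "Q250", 60)
  expect_equal(nrow(match_codes(ev, "ICD10:Q25*")), 1L)
  expect_equal(classify_cvm(ev, cb)$status, "CASE")
})

test_that("Q211 with a PFO operation code is excluded from both groups", {
  ev <- evts(evt("ICD10", "Q211", 50), evt("OPCS4", "K165", 50))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "EXCLUDED")
  expect_equal(a$reason, "PFO_K165")
})

test_that("an AF-free stroke before Q211 marks the sample as PFO", {
  ev <- evts(evt("ICD10", "I639", 48), evt("ICD10", "Q211", 49))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "EXCLUDED")
  expect_equal(a$reason, "PFO_PRIOR_STROKE")
})

test_that("a stroke explained by prior atrial fibrillation leaves Q211 as ASD", {
  ev <- evts(evt("ICD10", "I489", 47),
             evt("ICD10", "I639", 48),
             evt("ICD10", "Q211", 49))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "CASE")
  expect_equal(a$reason, "ASD_Q211")
})

test_that("a stroke after Q211 does not void the diagnosis", {
  ev <- evts(evt("ICD10", "Q211", 45), evt("ICD10", "I639", 50))
  expect_equal(classify_cvm(ev, cb)$status, "CASE")
})

test_that("same-age stroke and Q211 without tiebreaks is conservatively PFO", {
  ev <- evts(evt("ICD10", "I639", 49), evt("ICD10", "Q211", 49))
  expect_equal(classify_cvm(ev, cb)$reason, "PFO_PRIOR_STROKE")
  # with tiebreaks placing the stroke after Q211 the diagnosis stands
  ev2 <- evts(evt("ICD10", "I639", 49, tiebreak = 0.9),
              evt("ICD10", "Q211", 49, tiebreak = 0.1))
  expect_equal(classify_cvm(ev2, cb)$status, "CASE")
})

test_that("Q211 alone is an atrial septal defect case", {
  expect_equal(classify_cvm(evt("ICD10", "Q211", 50), cb)$status, "CASE")
})

test_that("voided Q211 with independent case evidence is still a case", {
  ev <- evts(evt("ICD10", "Q211", 50), evt("OPCS4", "K165", 50),
             evt("ICD10", "Q250", 55))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "CASE")
  expect_equal(a$reason, "CONGENITAL_CODE")
})

test_that("aortic-valve disease is congenital under 65 and excluded at 65+", {
  expect_equal(classify_cvm(evt("ICD10", "I350", 60), cb)$status, "CASE")
  a70 <- classify_cvm(evt("ICD10", "I350", 70), cb)
  expect_equal(a70$status, "EXCLUDED")
  expect_equal(a70$reason, "BAV_AGE_GE_65")
  # earliest qualifying age decides
  both <- evts(evt("ICD10", "I350", 60), evt("ICD10", "I351", 70))
  expect_equal(classify_cvm(both, cb)$status, "CASE")
})

test_that("endocarditis voids the bicuspid-aortic-valve inference", {
  ev <- evts(evt("ICD10", "I350", 55), evt("ICD10", "I330", 55))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "EXCLUDED")
  expect_equal(a$reason, "BAV_EXCLUSION")
})

test_that("self-reported heart surgery is a case only under 18", {
  expect_equal(classify_cvm(evt("SELF_OPERATION", "1095", 10), cb)$status,
               "CASE")
  expect_equal(classify_cvm(evt("SELF_OPERATION", "1095", 30), cb)$status,
               "CONTROL")
})

test_that("syndrome codes dominate every other rule", {
  ev <- evts(evt("ICD10", "Q871", 5), evt("ICD10", "Q250", 5),
             evt("ICD10", "I350", 50))
  a <- classify_cvm(ev, cb)
  expect_equal(a$status, "EXCLUDED")
  expect_equal(a$reason, "SYNDROME")
})

test_that("acquired-defect codes remove a sample from the control pool", {
  a <- classify_cvm(evt("ICD10", "I340", 60), cb)
  expect_equal(a$status, "EXCLUDED")
  expect_equal(a$reason, "CONTROL_EXCLUSION_CODE")
})

test_that("an empty history is a control", {
  a <- classify_cvm(evt("ICD10", "X", 1)[0, ], cb, participant_id = "P9")
  expect_equal(a$status, "CONTROL")
  expect_true(is.na(a$reason))
})

test_that("neuropsychiatric cascade: case codes, other F codes, clean controls", {
  expect_equal(classify_neuropsych(evt("ICD10", "F200", 30), cb)$status,
               "CASE")
  ex <- classify_neuropsych(evt("ICD10", "F329", 30), cb)
  expect_equal(ex$status, "EXCLUDED")
  expect_equal(ex$reason, "NEUROPSYCH_OTHER_F_CODE")
  expect_equal(classify_neuropsych(evt("ICD10", "J459", 30), cb)$status,
               "CONTROL")
})

test_that("cognitive eligibility drops carriers of excluded diagnoses only", {
  expect_false(cognitive_eligibility(evt("ICD10", "F200", 30), cb))
  expect_true(cognitive_eligibility(evt("ICD10", "F329", 30), cb))
  expect_true(cognitive_eligibility(evt("ICD10", "Q250", 30), cb))
})

test_that("classification is invariant to event order", {
  histories <- list(
    evts(evt("ICD10", "I639", 48), evt("ICD10", "Q211", 49),
         evt("ICD10", "J459", 20)),
    evts(evt("ICD10", "I489", 47), evt("ICD10", "I639", 48),
         evt("ICD10", "Q211", 49)),
    evts(evt("ICD10", "Q871", 5), evt("ICD10", "Q250", 5)),
    evts(evt("ICD10", "I350", 60), evt("ICD10", "I351", 70),
         evt("ICD10", "F200", 40)))
  set.seed(5)
  for (ev in histories) {
    ref_cvm <- classify_cvm(ev, cb)
    ref_np <- classify_neuropsych(ev, cb)
    for (i in 1:6) {
      perm <- ev[sample.int(nrow(ev)), , drop = FALSE]
      expect_equal(classify_cvm(perm, cb)$status, ref_cvm$status)
      expect_equal(classify_cvm(perm, cb)$reason, ref_cvm$reason)
      expect_equal(classify_neuropsych(perm, cb)$status, ref_np$status)
    }
  }
})

test_that("adding a non-matching event never changes an assignment", {
  histories <- list(
    evt("ICD10", "Q211", 50),
    evts(evt("ICD10", "Q211", 50), evt("OPCS4", "K165", 50)),
    evt("ICD10", "I350", 70),
    evt("ICD10", "F200", 30))
  noise <- evt("ICD10", "J459", 33)
  for (ev in histories) {
    ref <- classify_cvm(ev, cb)
    with_noise <- classify_cvm(rbind(ev, noise), cb)
    expect_equal(with_noise$status, ref$status)
    expect_equal(with_noise$reason, ref$reason)
  }
})

test_that("events from mixed participants are a usage error", {
  ev <- rbind(evt("ICD10", "Q211", 50, id = "P1"),
              evt("ICD10", "Q250", 50, id = "P2"))
  expect_error(classify_cvm(ev, cb), class = "cnv_usage_error")
})

test_that("cohort classification partitions every participant once per phenotype", {
  parts <- data.frame(participant_id = c("P1", "P2", "P3", "P4"))
  ev <- rbind(evt("ICD10", "Q250", 40, id = "P1"),
              evt("ICD10", "F200", 30, id = "P2"),
              evt("ICD10", "J459", 20, id = "P3"))
  asg <- classify_cohort(parts, ev, cb)
  expect_equal(nrow(asg), 8L)
  expect_true(all(table(asg$participant_id, asg$phenotype) == 1))
  expect_setequal(asg$status[asg$participant_id == "P4"], "CONTROL")
  expect_equal(asg$status[asg$participant_id == "P1" & asg$phenotype == "CVM"],
               "CASE")
})

test_that("excluded participants are absent from association denominators", {
  parts <- data.frame(participant_id = sprintf("P%d", 1:6))
  ev <- rbind(evt("ICD10", "Q250", 40, id = "P1"),        # case
              evt("ICD10", "I350", 70, id = "P2"),        # excluded
              evt("ICD10", "Q871", 5, id = "P3"))         # excluded
  asg <- classify_cohort(parts, ev, cb)
  carriers <- data.frame(sample_id = sprintf("P%d", 1:6),
                         carrier = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  a <- phenotype_association(asg, carriers, "CVM")
  # 1 case (P1, carrier), 3 controls (P4, P5, P6; one carrier)
  expect_equal(unname(a$counts), c(1, 0, 1, 2))
})
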