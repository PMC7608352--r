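test_that("rawcnv lines parse into calls with normalised chromosomes", {
  line <- "chr15:22819338-23093090\tnumsnp=132\tlength=273,753\tstate2,cn=1\tS0001\tstartsnp=rs1\tendsnp=rs2"
  calls <- parse_cnv_calls(text = line, dialect = "penncnv_rawcnv")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$chromosome, "15")
  expect_equal(calls$start, 22819338L)
  expect_equal(calls$end, 23093090L)
  expect_equal(calls$copy_number, 1L)
  expect_equal(calls$n_probes, 132L)
  expect_equal(calls$sample_id, "S0001")
})

test_that("parser rejects cn=2, malformed coordinates and start > end, naming the line", {
  good <- "chr1:100-200 numsnp=10 length=101 state2,cn=1 S1 startsnp=a endsnp=b"
  cn2 <- "chr1:100-200 numsnp=10 length=101 state3,cn=2 S1 startsnp=a endsnp=b"
  bad_coord <- "chr1:abc-200 numsnp=10 length=101 state2,cn=1 S1 startsnp=a endsnp=b"
  swapped <- "chr1:300-200 numsnp=10 length=101 state2,cn=1 S1 startsnp=a endsnp=b"
  expect_error(parse_cnv_calls(text = c(good, cn2)), "line 2")
  expect_error(parse_cnv_calls(text = c(good, cn2)), class = "cnv_parse_error")
  expect_error(parse_cnv_calls(text = bad_coord), class = "cnv_parse_error")
  expect_error(parse_cnv_calls(text = swapped), "start")
  expect_equal(nrow(parse_cnv_calls(text = character())), 0L)
})

test_that("TSV dialect parses and enforces the same rules", {
  tsv <- c("sample_id\tchromosome\tstart\tend\tcopy_number",
           "S1\tchr15\t22819338\t23093090\t1")
  calls <- parse_cnv_calls(text = tsv, dialect = "tsv")
  expect_equal(calls$chromosome, "15")
  expect_error(parse_cnv_calls(
    text = c("sample_id\tchromosome\tstart\tend\tcopy_number",
             "S1\t15\t10\t20\t2"), dialect = "tsv"),
    class = "cnv_parse_error")
  expect_error(parse_cnv_calls(
    text = c("sample_id\tchromosome\tstart", "S1\t15\t10"), dialect = "tsv"),
    "missing column")
})

test_that("rawcnv writing and parsing round-trip", {
  calls <- rbind(mk_call(22819338, 23093090, cn = 1, id = "S1"),
                 mk_call(500000, 600000, cn = 3, chrom = "7", id = "S2"),
                 mk_call(1000, 2000, cn = 0, chrom = "2", id = "S3"))
  calls$n_probes <- c(100L, 25L, 12L)
  path <- tempfile(fileext = ".rawcnv")
  write_rawcnv(calls, path)
  back <- parse_cnv_calls(path, dialect = "penncnv_rawcnv")
  expect_equal(back, calls)
})

test_that("sample QC retains boundary values and names the violated rule", {
  st <- data.frame(sample_id = c("A", "B", "C", "D"),
                   waviness_factor = c(-0.031, 0.03, 0, 0.05),
                   n_cnvs = c(5, 40, 41, 50))
  qc <- sample_qc(st)
  expect_equal(qc$qc_pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(qc$qc_reason, c("waviness", NA, "cnv_count", "waviness"))
})

test_that("locus genotyping: containment, absence and the 95% boundary", {
  locus <- bp1bp2_locus()
  full <- detect_locus_deletion(mk_call(22800000, 23100000), locus)
  expect_equal(full$overlap_fraction, 1)
  expect_true(full$carrier)

  none <- detect_locus_deletion(mk_call(1e6, 2e6, chrom = "7"), locus,
                                sample_id = "S1")
  expect_equal(none$overlap_fraction, 0)
  expect_false(none$carrier)

  # locus length 273,753; 95% of it is 260,065.35 bp
  at_259 <- detect_locus_deletion(
    mk_call(locus$start, locus$start + 260065L - 1L), locus)
  expect_false(at_259$carrier)
  at_260 <- detect_locus_deletion(
    mk_call(locus$start, locus$start + 260066L - 1L), locus)
  expect_true(at_260$carrier)
})

test_that("a copy-number-0 call at the locus is anomalous and never a carrier", {
  locus <- bp1bp2_locus()
  calls <- rbind(mk_call(locus$start, locus$end, cn = 1),
                 mk_call(locus$start + 1000, locus$start + 2000, cn = 0))
  res <- detect_locus_deletion(calls, locus)
  expect_equal(res$anomaly, "homozygous_deletion_at_locus")
  expect_false(res$carrier)
})

test_that("calls from multiple samples are a usage error", {
  calls <- rbind(mk_call(1, 10, id = "S1"), mk_call(1, 10, id = "S2"))
  expect_error(detect_locus_deletion(calls), class = "cnv_usage_error")
})

test_that("overlap fraction equals the per-base-pair oracle on random call sets", {
  set.seed(99)
  locus <- genomic_interval("15", 1000L, 1999L)
  for (i in 1:40) {
    calls <- random_calls(sample(1:6, 1), locus)
    res <- detect_locus_deletion(calls, locus)
    expect_equal(res$overlap_fraction, bp_overlap_oracle(calls, locus))
  }
})

test_that("overlap fraction matches an IRanges union computation", {
  set.seed(100)
  locus <- genomic_interval("15", 1000L, 1999L)
  for (i in 1:15) {
    calls <- random_calls(sample(1:6, 1), locus)
    res <- detect_locus_deletion(calls, locus)
    het <- calls[calls$copy_number == 1L, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(het$start, het$end))
    inter <- IRanges::intersect(ir, IRanges::IRanges(locus$start, locus$end))
    expect_equal(res$overlap_fraction,
                 sum(IRanges::width(inter)) / (locus$end - locus$start + 1L))
  }
})

test_that("overlap fraction is monotone in call extension and addition", {
  set.seed(101)
  locus <- genomic_interval("15", 1000L, 1999L)
  for (i in 1:20) {
    calls <- random_calls(3, locus)
    base <- detect_locus_deletion(calls, locus)$overlap_fraction
    wider <- calls
    wider$start[1] <- wider$start[1] - 50L
    wider$end[1] <- wider$end[1] + 50L
    expect_gte(detect_locus_deletion(wider, locus)$overlap_fraction, base)
    more <- rbind(calls, mk_call(1500, 1600))
    expect_gte(detect_locus_deletion(more, locus)$overlap_fraction, base)
  }
})

test_that("genotyping is invariant to call order", {
  set.seed(102)
  locus <- genomic_interval("15", 1000L, 1999L)
  calls <- random_calls(6, locus)
  ref <- detect_locus_deletion(calls, locus)
  for (i in 1:5) {
    perm <- calls[sample.int(nrow(calls)), , drop = FALSE]
    rownames(perm) <- NULL
    expect_equal(detect_locus_deletion(perm, locus)$overlap_fraction,
                 ref$overlap_fraction)
  }
})

test_that("cohort genotyping matches the single-sample rule", {
  locus <- bp1bp2_locus()
  calls <- rbind(mk_call(locus$start, locus$end, id = "S1"),
                 mk_call(locus$start, locus$start + 1000L, id = "S2"),
                 mk_call(1e6, 2e6, chrom = "3", id = "S3"))
  res <- genotype_deletion(calls, sample_ids = c("S1", "S2", "S3", "S4"),
                           locus = locus)
  expect_equal(res$carrier, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$overlap_fraction[1], 1)
  expect_equal(res$overlap_fraction[3:4], c(0, 0))
})
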