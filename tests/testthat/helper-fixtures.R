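# Shared fixtures: event builders and an independent per-base-pair
# overlap oracle.

evt <- function(system, code, age, tiebreak = NA_real_, id = "P1") {
  data.frame(participant_id = id, system = system, code = code,
             age_at_event = age, tiebreak = tiebreak,
             stringsAsFactors = FALSE)
}

evts <- function(...) do.call(rbind, list(...))

cb <- default_codebook()

mk_call <- function(start, end, cn = 1L, chrom = "15", id = "S1") {
  data.frame(sample_id = id, chromosome = chrom, start = as.integer(start),
             end = as.integer(end), copy_number = as.integer(cn),
             n_probes = NA_integer_, stringsAsFactors = FALSE)
}

# brute-force overlap fraction: count covered base pairs one by one
bp_overlap_oracle <- function(calls, locus) {
  len <- locus$end - locus$start + 1L
  covered <- logical(len)
  het <- calls[calls$copy_number == 1L &
                 sub("^chr", "", calls$chromosome) == locus$chromosome, ,
               drop = FALSE]
  for (i in seq_len(nrow(het))) {
    s <- max(het$start[i], locus$start) - locus$start + 1L
    e <- min(het$end[i], locus$end) - locus$start + 1L
    if (s <= e) covered[s:e] <- TRUE
  }
  sum(covered) / len
}

# random small call set around a miniature locus
random_calls <- function(n_calls, locus, id = "S1") {
  width <- locus$end - locus$start + 1L
  starts <- sample(seq(locus$start - width, locus$end + width), n_calls,
                   replace = TRUE)
  lens <- sample.int(2L * width, n_calls, replace = TRUE)
  cn <- sample(c(1L, 1L, 1L, 3L), n_calls, replace = TRUE)
  do.call(rbind, lapply(seq_len(n_calls), function(i)
    mk_call(starts[i], starts[i] + lens[i] - 1L, cn = cn[i], id = id)))
}
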