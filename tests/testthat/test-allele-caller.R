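make_records <- function(reads, allele, params = mapper_params("discovery")) {
  # single-end records for pileup tests: align each read individually
  rows <- lapply(names(reads), function(id) {
    h <- align_read(reads[[id]], allele, params)
    if (is.null(h)) return(NULL)
    cbind(data.frame(read_id = id, mate = 1L, stringsAsFactors = FALSE),
          h, proper_pair = TRUE, pair_score = h$score,
          seq = reads[[id]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("pileups tally cigar walks and conserve aligned bases", {
  set.seed(41)
  allele <- c(AL = rand_seq(549))
  # zero records
  p0 <- compute_pileup(data.frame(), allele, min_depth = 1)
  expect_false(p0$complete)
  expect_true(all(p0$depth == 0L))
  # uniform error-free tiling: complete, no mismatch, no het
  reads <- tiling_reads(allele, by = 3)
  rec <- make_records(reads, allele)
  p1 <- compute_pileup(rec, allele, min_depth = 1)
  expect_true(p1$complete)
  expect_length(p1$mismatch_positions, 0L)
  expect_length(p1$het_positions, 0L)
  expect_identical(unname(p1$covered_span[["len"]]), 549L)
  # conservation: tallied bases equal aligned (non-clipped) bases
  expect_identical(p1$tallied_bases, sum(dinomfrs:::cigar_ref_len(rec$cigar)) -
                     0)  # no deletions in error-free tiling
  # a variant differing at one site, deep and error-free: one mismatch, no het
  var_reads <- tiling_reads(mutate_seq(unname(allele), pos = 275), by = 2,
                            prefix = "v")
  p2 <- compute_pileup(make_records(var_reads, allele), allele, min_depth = 1)
  expect_identical(p2$mismatch_positions, 275L)
  expect_length(p2$het_positions, 0L)
  # 60/40 mixture at one site: het flagged, masked as N in the consensus
  mix <- c(tiling_reads(allele, by = 2, prefix = "w"),
           tiling_reads(mutate_seq(unname(allele), pos = 300), by = 3,
                        prefix = "m"))
  p3 <- compute_pileup(make_records(mix, allele), allele, min_depth = 1)
  expect_true(300L %in% p3$het_positions)
  expect_identical(substr(consensus_sequence(p3), 300, 300), "N")
  # record on a different allele is rejected
  bad <- make_records(reads[1], allele)
  bad$allele_id <- "OTHER"
  expect_error(compute_pileup(bad, allele), "other allele")
})

test_that("call_known demands complete, mismatch-free, homogeneous coverage", {
  set.seed(42)
  allele <- c(AL = rand_seq(549))
  full <- compute_pileup(make_records(tiling_reads(allele, by = 3), allele),
                         allele, min_depth = 1)
  expect_true(call_known(full))
  # complete but one mismatch: absent
  varp <- compute_pileup(make_records(
    tiling_reads(mutate_seq(unname(allele), pos = 100), by = 3), allele), allele,
    min_depth = 1)
  expect_false(call_known(varp))
  # incomplete but mismatch-free: absent
  half <- tiling_reads(substr(allele, 1, 300), by = 3)
  partial <- compute_pileup(make_records(half, allele), allele, min_depth = 1)
  expect_false(call_known(partial))
  # monotonicity: adding error-free reads never flips present to absent
  more <- compute_pileup(make_records(
    c(tiling_reads(allele, by = 3), tiling_reads(allele, by = 7, prefix = "x")),
    allele), allele, min_depth = 1)
  expect_true(call_known(more))
})

test_that("candidate rule is strict at both thresholds", {
  set.seed(43)
  p_500_450 <- engineered_pileup(500L, 450L)
  p_501_401 <- engineered_pileup(501L, 401L)
  p_2000_380 <- engineered_pileup(2000L, 380L)
  expect_identical(p_500_450$n_reads, 500L)
  expect_identical(unname(p_500_450$covered_span[["len"]]), 450L)
  cands <- find_candidates(list(p_500_450, p_501_401, p_2000_380))
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$n_reads, 501L)
  expect_identical(cands[[1]]$span_len, 401L)
  # a present known allele is never a candidate, however deep
  allele <- c(AL = rand_seq(549))
  deep <- compute_pileup(make_records(tiling_reads(allele, by = 1), allele),
                         allele, min_depth = 1)
  expect_length(find_candidates(list(deep)), 0L)
})

test_that("consensus is restricted to the longest covered run", {
  set.seed(44)
  allele <- c(AL = rand_seq(549))
  # coverage gap in the middle: consensus comes from the longer side
  left <- tiling_reads(substr(allele, 1, 200), by = 2, prefix = "l")
  right <- tiling_reads(substr(allele, 261, 549), by = 2, prefix = "r")
  rec <- make_records(c(left, right), allele)
  p <- compute_pileup(rec, allele, min_depth = 1)
  cons <- consensus_sequence(p)
  expect_identical(cons, unname(substr(allele, 261, 549)))
  # error-free single-allele pileup: exact substring
  p2 <- compute_pileup(make_records(left, allele), allele, min_depth = 1)
  expect_identical(consensus_sequence(p2), unname(substr(allele, 1, 200)))
  expect_error(consensus_sequence(compute_pileup(data.frame(), allele, min_depth = 1)),
               "covered span")
})

test_that("expression bins follow the read count at the marker column", {
  set.seed(45)
  allele_len <- 549L
  mk <- function(n) {
    # n reads covering trimmed column 187 (full-CDS 260)
    data.frame(read_id = sprintf("r%05d", seq_len(n)), mate = 1L,
               allele_id = "AL", ref_start = 150L, cigar = "100M",
               score = 100L, strand = "+", proper_pair = TRUE,
               edit_distance = 0L, pair_score = 200L,
               stringsAsFactors = FALSE)
  }
  expect_identical(bin_expression(mk(999), 260, 73, allele_len)$bin, "low")
  expect_identical(bin_expression(mk(1000), 260, 73, allele_len)$bin, "middle")
  expect_identical(bin_expression(mk(5000), 260, 73, allele_len)$bin, "middle")
  expect_identical(bin_expression(mk(5001), 260, 73, allele_len)$bin, "high")
  # reads not covering the marker column are not counted
  off <- mk(10)
  off$ref_start <- 200L   # spans 201-300, marker column 187 not covered
  expect_identical(bin_expression(off, 260, 73, allele_len)$n, 0L)
  expect_error(bin_expression(mk(1), 900, 73, allele_len), "outside")
})

test_that("pileup report labels present, candidate and no-call alleles", {
  set.seed(46)
  allele <- c(AL = rand_seq(549))
  present <- compute_pileup(make_records(tiling_reads(allele, by = 3), allele),
                            allele, min_depth = 1)
  cand <- engineered_pileup(800L, 450L)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  df <- write_pileup_report(list(present, cand), f)
  expect_identical(df$decision, c("present", "candidate"))
  expect_true(file.exists(f))
})
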