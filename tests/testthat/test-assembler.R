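test_that("two overlapping reads merge; a sub-threshold overlap does not", {
  set.seed(51)
  s <- rand_seq(150)
  a <- substr(s, 1, 100); b <- substr(s, 51, 150)
  ct <- assemble(c(r1 = a, r2 = b), assembly_params(min_reads_per_contig = 2))
  expect_length(ct, 1L)
  expect_identical(ct[[1]]$seq, s)
  expect_identical(ct[[1]]$n_reads, 2L)
  # same pair at 96% overlap identity under the 0.99 gate: all singletons
  b2 <- mutate_seq(b, pos = c(5, 25))   # 48/50 within the overlap
  expect_message(
    ct2 <- assemble(c(r1 = a, r2 = b2),
                    assembly_params(min_reads_per_contig = 2)),
    "singleton")
  expect_length(ct2, 0L)
  # orientation: reverse-complementing one read changes nothing
  ct3 <- assemble(c(r1 = a, r2 = revcomp(b)),
                  assembly_params(min_reads_per_contig = 2))
  expect_true(ct3[[1]]$seq %in% c(s, revcomp(s)))
  expect_error(assemble(c(r1 = a), assembly_params()), "at least 2")
})

test_that("error-free tiling reassembles the allele exactly", {
  set.seed(52)
  allele <- rand_seq(549)
  ct <- assemble(tiling_reads(allele, by = 3), assembly_params())
  expect_length(ct, 1L)
  expect_true(ct[[1]]$seq %in% c(allele, revcomp(allele)))
  # layout is internally consistent: every read matches the consensus at
  # its offset over its full length
  lay <- ct[[1]]$read_layout
  reads <- tiling_reads(allele, by = 3)
  for (k in seq_len(nrow(lay))) {
    r <- reads[[lay$read_id[k]]]
    if (lay$strand[k] == 1) r <- revcomp(r)
    expect_identical(substr(ct[[1]]$seq, lay$offset[k] + 1,
                            lay$offset[k] + nchar(r)), r)
  }
  # idempotence: assembling the contig's own layout reads reproduces it
  again <- assemble(reads, assembly_params())
  expect_identical(again[[1]]$seq, ct[[1]]$seq)
})

test_that("greedy consensus equals the exhaustive overlap-order search on tiny instances", {
  set.seed(53)
  p <- assembly_params(min_reads_per_contig = 2)
  for (case in 1:12) {
    n <- sample(4:6, 1)
    truth <- rand_seq(60 + n * 45)
    starts <- sort(sample(seq(1, nchar(truth) - 99), n))
    starts[1] <- 1
    starts[n] <- nchar(truth) - 99
    reads <- vapply(starts, function(s) substr(truth, s, s + 99), character(1))
    rc <- runif(n) < 0.5
    reads[rc] <- revcomp(reads[rc])
    names(reads) <- sprintf("q%02d", seq_len(n))
    got <- assemble(reads, p)
    got_key <- paste(sort(vapply(got, function(ct)
      min(ct$seq, revcomp(ct$seq)), character(1))), collapse = "|")
    all_results <- oracle_assemble_all(reads, p)
    expect_true(got_key %in% all_results)
    expect_length(all_results, 1L)   # order never changes the outcome here
  }
})

test_that("two-allele mixtures assemble into exactly two chimera-free contigs", {
  set.seed(54)
  for (rep in 1:20) {
    mx <- mixture_reads(len = 450, depth = 30)
    ct <- assemble(mx$reads, assembly_params())
    expect_length(ct, 2L)
    seqs <- vapply(ct, `[[`, character(1), "seq")
    canon <- vapply(seqs, function(s) min(s, revcomp(s)), character(1))
    expect_setequal(unname(canon),
                    c(min(mx$a, revcomp(mx$a)), min(mx$b, revcomp(mx$b))))
  }
})

test_that("consensus tolerates 0.5% sequencing error at 30x and above", {
  set.seed(55)
  ok <- 0L
  for (rep in 1:20) {
    allele <- rand_seq(549)
    # >= 30x everywhere, including the terminal columns
    reads <- c(tiling_reads(allele, by = 3),
               stats::setNames(rep(substr(allele, 1, 100), 15),
                               sprintf("L%02d", 1:15)),
               stats::setNames(rep(substr(allele, 450, 549), 15),
                               sprintf("R%02d", 1:15)))
    reads <- stats::setNames(dinomfrs:::apply_read_errors(unname(reads), 0.005),
                             names(reads))
    ct <- assemble(reads, assembly_params())
    if (length(ct) >= 1 && ct[[1]]$seq %in% c(allele, revcomp(allele))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 19L)
})

test_that("full-length marking measures coverage of the best-matching allele", {
  set.seed(56)
  db <- allele_db(c(A1 = rand_seq(549), A2 = rand_seq(549)))
  expect_true(mark_full_length(db$seq[["A1"]], db))
  expect_false(mark_full_length(substr(db$seq[["A1"]], 1, 300), db))
  # full-span novel sequence at ~90% identity: full length
  novel <- mutate_seq(db$seq[["A1"]], n = 55)
  expect_true(mark_full_length(novel, db))
})

test_that("clipped-read voting repairs truncated contig ends", {
  set.seed(57)
  allele <- rand_seq(549)
  reads <- c(tiling_reads(allele, by = 2),
             stats::setNames(rep(substr(allele, 1, 100), 8),
                             sprintf("L%02d", 1:8)),
             stats::setNames(rep(substr(allele, 450, 549), 8),
                             sprintf("R%02d", 1:8)))
  truncated <- substr(allele, 4, 546)
  fixed <- extend_contig_ends(truncated, reads)
  expect_identical(fixed, allele)
  # self-limiting: nothing extends beyond the transcript
  expect_identical(extend_contig_ends(allele, reads), allele)
})
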