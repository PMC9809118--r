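test_that("pairwise_differences is a validated edit distance", {
  expect_identical(pairwise_differences("ACGTACGT", "ACGTACGT"), 0L)
  expect_identical(pairwise_differences("ACGTACGT", "ACCTACGA"), 2L)
  expect_identical(pairwise_differences("ACGTACGT", "ACGACGT"), 1L)
  # RNA input is normalised, lower case accepted
  expect_identical(pairwise_differences("acgu", "ACGT"), 0L)
  expect_error(pairwise_differences("ACGX", "ACGT"), "position 4")
  # symmetry and agreement with an independent DP oracle on random pairs
  set.seed(11)
  for (i in 1:25) {
    a <- rand_seq(sample(20:60, 1))
    b <- mutate_seq(a, n = sample(1:5, 1))
    if (runif(1) < 0.5) b <- substr(b, 1, nchar(b) - sample(1:3, 1))
    expect_identical(pairwise_differences(a, b), pairwise_differences(b, a))
    expect_identical(pairwise_differences(a, b),
                     as.integer(edit_distance_oracle(a, b)))
  }
})

test_that("build_reference keeps a maximal >= min_diff subset in input order", {
  set.seed(21)
  # 32 curated entries of which 2 are near-duplicates of earlier ones,
  # then 19 additional entries all mutually distant: 49 survive
  base <- replicate(32, rand_seq(549))
  base[10] <- mutate_seq(base[3], n = 3)   # < 5 differences
  base[25] <- base[17]                     # identical
  extra <- replicate(19, rand_seq(549))
  cands <- stats::setNames(c(base, extra), sprintf("s%02d", 1:51))
  db <- build_reference(cands, min_diff = 5, quiet = TRUE)
  expect_s3_class(db, "mhc_refdb")
  expect_length(db, 49L)
  expect_identical(db$version, 0L)
  drops <- attr(db, "drops")
  expect_identical(drops$dropped_id, c("s10", "s25"))
  expect_identical(drops$kept_id, c("s03", "s17"))
  # redundancy invariant by brute force over all retained pairs
  d <- adist(db$seq)
  expect_true(min(d[upper.tri(d)]) >= 5)
  # determinism: same input order, same retained set
  db2 <- build_reference(cands, min_diff = 5, quiet = TRUE)
  expect_identical(db$seq, db2$seq)
  # single sequence
  db1 <- build_reference(c(one = rand_seq(500)), quiet = TRUE)
  expect_length(db1, 1L)
  # later-listed member of a close pair is dropped
  s <- rand_seq(100)
  db3 <- build_reference(c(a = s, b = rand_seq(100), c = mutate_seq(s, n = 4)),
                         min_diff = 5, quiet = TRUE)
  expect_identical(db3$id, c("a", "b"))
  expect_error(build_reference(character(0)))
  expect_error(build_reference(c(x = "ACGT", x = "ACGG")), "duplicate")
})

test_that("augment absorbs identical sequences and always bumps the version", {
  set.seed(22)
  db <- build_reference(stats::setNames(replicate(5, rand_seq(549)),
                                        paste0("k", 1:5)), quiet = TRUE)
  # identical contig absorbed, version still bumped
  db_a <- augment(db, c(nov1 = unname(db$seq[2])))
  expect_length(db_a, 5L)
  expect_identical(db_a$version, 1L)
  rep_a <- attr(db_a, "report")
  expect_identical(rep_a$action, "identical")
  expect_identical(rep_a$existing_id, "k2")
  # genuinely new sequence appended even when < min_diff from a known one
  near <- mutate_seq(db$seq[[1]], n = 2)
  db_b <- augment(db, c(nov2 = near))
  expect_length(db_b, 6L)
  expect_identical(db_b$provenance[["nov2"]], "novel")
  # two copies of one novel contig under different ids: one appended
  s <- rand_seq(549)
  db_c <- augment(db, c(na = s, nb = s))
  expect_length(db_c, 6L)
  expect_identical(attr(db_c, "report")$action, c("added", "identical"))
  expect_error(augment(db, c(k1 = rand_seq(549))), "collide")
})

test_that("FASTA round-trip preserves ids and sequences byte-exactly", {
  set.seed(23)
  db <- build_reference(stats::setNames(replicate(3, rand_seq(549)),
                                        c("N*11:01", "LfL2003", "U03094.1")),
                        quiet = TRUE)
  f <- tempfile(fileext = ".fa")
  on.exit(unlink(f))
  write_fasta(db, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 70))
  back <- read_allele_fasta(f)
  expect_identical(back$seq, db$seq)
  expect_identical(back$id, db$id)
  # arbitrary wrapping accepted; description after whitespace kept
  f2 <- tempfile(fileext = ".fa")
  on.exit(unlink(f2), add = TRUE)
  writeLines(c(">a1 some accession", "ACGTAC", "GT", ">a2", "ACGTACGTTT"), f2)
  back2 <- read_allele_fasta(f2)
  expect_identical(unname(back2$seq), c("ACGTACGT", "ACGTACGTTT"))
  expect_identical(unname(attr(back2, "descriptions")[["a1"]]),
                   "some accession")
})

test_that("anchored trimming recovers the exon2-exon3 span", {
  set.seed(24)
  anchor <- rand_seq(549)
  inner <- mutate_seq(anchor, n = 25)
  cand <- paste0(rand_seq(70), inner, rand_seq(90))
  tr <- trim_to_anchor(c(c1 = cand), anchor)
  expect_identical(unname(tr), inner)
})
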