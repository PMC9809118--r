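test_that("presets carry the two scoring regimes", {
  d <- mapper_params("discovery")
  v <- mapper_params("verify")
  expect_identical(c(d$match, d$mismatch, d$band, d$clip), c(1L, 4L, 100L, 5L))
  expect_identical(c(v$match, v$mismatch, v$band, v$clip), c(2L, 5L, 30L, 2L))
  o <- mapper_params("discovery", min_score = 50L)
  expect_identical(o$min_score, 50L)
  expect_error(mapper_params("discovery", nope = 1), "unknown")
})

test_that("align_read scores a perfect, a mismatched and a random read as specified", {
  set.seed(31)
  ref <- c(X = rand_seq(549))
  p <- mapper_params("discovery")
  h <- align_read(substr(ref, 101, 200), ref, p)
  expect_identical(h$score, 100L)
  expect_identical(h$edit_distance, 0L)
  expect_identical(h$cigar, "100M")
  expect_identical(h$ref_start, 100L)
  h2 <- align_read(mutate_seq(substr(ref, 101, 200), pos = 50), ref, p)
  expect_identical(h2$score, 95L)  # 99 * 1 - 4
  expect_identical(h2$edit_distance, 1L)
  expect_null(align_read(rand_seq(100), ref, p))
  expect_error(align_read(rand_seq(10), ref, p), "seed_len")
})

test_that("seed-and-extend equals the unbanded full DP whenever it reports a hit", {
  set.seed(32)
  for (preset in c("discovery", "verify")) {
    p <- mapper_params(preset)
    n_hit <- 0L
    for (i in 1:120) {
      ref <- rand_seq(sample(400:600, 1))
      st <- sample(seq_len(nchar(ref) - 100), 1)
      rd <- substr(ref, st, st + 99)
      nm <- sample(0:5, 1)
      if (nm > 0) rd <- mutate_seq(rd, n = nm)
      if (runif(1) < 0.3) {  # occasional 1 bp indel
        ch <- strsplit(rd, "")[[1]]
        pp <- sample(20:80, 1)
        ch <- if (runif(1) < 0.5) ch[-pp] else append(ch, sample(BASES, 1), pp)
        rd <- paste(ch, collapse = "")
      }
      if (runif(1) < 0.5) rd <- revcomp(rd)
      h <- align_read(rd, c(X = ref), p)
      oracle <- max(align_oracle_score(rd, ref, p),
                    align_oracle_score(revcomp(rd), ref, p))
      if (!is.null(h)) {
        n_hit <- n_hit + 1L
        expect_identical(h$score, oracle)
        # cigar consumes exactly the read
        expect_identical(dinomfrs:::cigar_read_len(h$cigar), nchar(rd))
        expect_lte(h$ref_start + dinomfrs:::cigar_ref_len(h$cigar), nchar(ref))
      } else {
        expect_lt(oracle, p$min_score + 20L)  # only low-scoring cases missed
      }
    }
    expect_gt(n_hit, 110L)
  }
})

test_that("best score is invariant under joint reverse complement", {
  set.seed(33)
  p <- mapper_params("discovery")
  for (i in 1:20) {
    ref <- rand_seq(500)
    rd <- mutate_seq(substr(ref, 151, 250), n = 3)
    h1 <- align_read(rd, c(X = ref), p)
    h2 <- align_read(revcomp(rd), c(X = revcomp(ref)), p)
    expect_identical(h1$score, h2$score)
  }
})

test_that("mismatch-free verify hits also map under discovery at the same locus", {
  set.seed(34)
  ref <- c(X = rand_seq(549))
  for (i in 1:25) {
    rd <- substr(ref, 1 + (i * 13) %% 440, (i * 13) %% 440 + 100)
    hv <- align_read(rd, ref, mapper_params("verify"))
    expect_identical(hv$edit_distance, 0L)
    hd <- align_read(rd, ref, mapper_params("discovery"))
    expect_identical(hd$ref_start, hv$ref_start)
  }
})

test_that("map_reads pairs mates and co-maps ties across alleles", {
  set.seed(35)
  al1 <- rand_seq(549)
  # allele 2 shares a 300 bp block (positions 250-549) with allele 1
  al2 <- paste0(mutate_seq(substr(al1, 1, 249), n = 25), substr(al1, 250, 549))
  db <- allele_db(c(A1 = al1, A2 = al2))
  # pair drawn from allele 1's distinctive 5' part: proper, A1 only
  r1 <- substr(al1, 1, 100); r2 <- revcomp(substr(al1, 151, 250))
  rec <- map_reads(c(p = r1), c(p = r2), db)
  expect_identical(unique(rec$allele_id), "A1")
  expect_true(all(rec$proper_pair))
  expect_identical(unique(rec$pair_score), 200L)
  # pair from the conserved block: proper on both alleles
  r1 <- substr(al1, 260, 359); r2 <- revcomp(substr(al1, 430, 529))
  rec2 <- map_reads(c(p = r1), c(p = r2), db)
  expect_setequal(unique(rec2$allele_id), c("A1", "A2"))
  expect_true(all(rec2$proper_pair))
  # chimeric pair (mates from two unrelated alleles): each mate aligns to
  # its own reference only, so no allele carries a proper pair and the
  # unpaired penalty applies
  al3 <- rand_seq(549)
  db3 <- allele_db(c(A1 = al1, A3 = al3))
  r1 <- substr(al1, 40, 139); r2 <- revcomp(substr(al3, 40, 139))
  rec3 <- map_reads(c(p = r1), c(p = r2), db3)
  expect_false(any(rec3$proper_pair))
  expect_setequal(unique(rec3$allele_id), c("A1", "A3"))
  expect_identical(unique(rec3$pair_score),
                   100L - mapper_params("discovery")$unpaired_penalty)
  # unmappable pair: empty result, not an error
  rec4 <- map_reads(c(p = rand_seq(100)), c(p = rand_seq(100)), db)
  expect_identical(nrow(rec4), 0L)
  expect_error(map_reads(character(0), character(0), db), "zero reads")
})

test_that("write_sam emits valid SAM with correct flags and tags", {
  set.seed(36)
  db <- allele_db(c(A1 = rand_seq(549)))
  f <- tempfile(fileext = ".sam")
  on.exit(unlink(f))
  # header-only for an empty record set
  empty <- map_reads(c(p = rand_seq(100)), c(p = rand_seq(100)), db)
  write_sam(empty, db, f)
  expect_true(all(startsWith(readLines(f), "@")))
  # one proper pair: flags {99, 147}, NM and AS tags, mate fields
  r1 <- substr(db$seq[[1]], 50, 149)
  r2 <- revcomp(substr(db$seq[[1]], 300, 399))
  rec <- map_reads(c(p1 = r1), c(p1 = r2), db)
  write_sam(rec, db, f)
  lines <- readLines(f)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_identical(sort(vapply(body, `[[`, character(1), 2)), c("147", "99"))
  expect_true(any(grepl("^NM:i:0$", unlist(body))))
  expect_true(any(grepl("^AS:i:100$", unlist(body))))
  # reverse-strand record carries the reverse-complemented SEQ
  rev_row <- body[[which(vapply(body, `[[`, character(1), 2) == "147")]]
  expect_identical(rev_row[[10]], substr(db$seq[[1]], 300, 399))
  expect_identical(as.integer(rev_row[[4]]), 300L)
  # the file converts cleanly to BAM
  skip_if_not_installed("Rsamtools")
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  expect_identical(Rsamtools::countBam(bam)$records, 2L)
})

test_that("FASTQ pairs are read with matching ids", {
  set.seed(37)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  on.exit(unlink(c(f1, f2)))
  writeLines(c("@r1/1 desc", "ACGTACGTACGTACGTACGT", "+",
               strrep("I", 20)), f1)
  writeLines(c("@r1/2", "TTGCACGTACGTACGTACGA", "+", strrep("I", 20)), f2)
  fq <- read_fastq_pairs(f1, f2)
  expect_identical(names(fq$r1), "r1")
  expect_identical(fq$r2[["r1"]], "TTGCACGTACGTACGTACGA")
  writeLines(c("@other/2", "ACGT", "+", "IIII"), f2)
  expect_error(read_fastq_pairs(f1, f2), "do not match")
})
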