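test_that("percent identity is a rounded global-alignment fraction", {
  set.seed(71)
  a <- rand_seq(549)
  expect_identical(percent_identity(a, a), 100.0)
  expect_identical(percent_identity(a, mutate_seq(a, n = 1)), 99.8)   # 548/549
  b39 <- mutate_seq(a, pos = seq(10, 540, length.out = 39))
  expect_identical(percent_identity(a, b39), 92.9)                    # 510/549
  expect_identical(percent_identity(a, b39), percent_identity(b39, a))
})

test_that("closest_allele maximises identity with database-order ties", {
  set.seed(72)
  a <- rand_seq(549)
  db <- c(K1 = mutate_seq(a, pos = 1:10), K2 = mutate_seq(a, pos = 101:110),
          K3 = mutate_seq(a, n = 60))
  hit <- closest_allele(a, db)
  expect_identical(hit$closest_id, "K1")   # tie with K2, earlier listed wins
  expect_identical(hit$identity, round(100 * 539 / 549, 1))
  expect_identical(closest_allele(db[["K3"]], db)$closest_id, "K3")
  expect_identical(closest_allele(db[["K3"]], db)$identity, 100.0)
})

test_that("CDS coordinates map to amino-acid positions by codon arithmetic", {
  expect_identical(cds_to_aa(256L), 86L)
  expect_identical(cds_to_aa(264L), 88L)
  expect_identical(cds_to_aa(c(1L, 3L, 4L)), c(1L, 1L, 2L))
})

test_that("translation follows the standard code with N -> X and stops as *", {
  expect_identical(translate_nt("ATGGCT"), "MA")
  expect_identical(translate_nt("CAGATACAA"), "QIQ")
  expect_identical(translate_nt("AATGGCT", 1L), "MA")  # frame offset
  expect_identical(translate_nt("TAAGCT"), "*A")
  expect_identical(translate_nt("ANTGCA"), "XA")       # fuzzy codon
  expect_identical(translate_nt("ATGGC"), "M")         # trailing partial codon
  expect_error(translate_nt("AT"), "fewer than 3")
})

test_that("contact-position clustering separates low-diversity groups", {
  set.seed(73)
  contacts <- contact_positions()
  expect_identical(nrow(contacts), 31L)
  expect_true(all(diff(contacts$position) > 0))
  # build amino-acid sequences on the numbering frame starting at residue 26
  aa_len <- 182L
  base <- paste(sample(c("A", "R", "N", "D", "G", "S", "T", "V"), aa_len,
                       TRUE), collapse = "")
  idx <- contacts$position - 26L + 1L
  set_at <- function(s, pos, ch) { substr(s, pos, pos) <- ch; s }
  scramble_off_contacts <- function(s, n = 25) {
    off <- setdiff(seq_len(aa_len), idx)
    for (p in sample(off, n)) s <- set_at(s, p, sample(c("K", "E", "Q", "L"), 1))
    s
  }
  # five alleles identical at all 31 contact positions, diverse elsewhere
  grp <- vapply(1:5, function(i) scramble_off_contacts(base), character(1))
  # one allele differing at 12 contact positions: classical
  far <- base
  for (p in idx[1:12]) far <- set_at(far, p, "W")
  aa <- stats::setNames(c(grp, far), c(paste0("g", 1:5), "solo"))
  cls <- classify_alleles(aa, contacts)
  expect_identical(cls$class_call[1:5], rep("putative non-classical", 5))
  expect_identical(cls$class_call[cls$allele_id == "solo"], "classical")
  # identical at contacts but different elsewhere: same cluster
  expect_identical(length(unique(cls$cluster[1:5])), 1L)
  # a sequence too short to span the contact set is unclassified
  cls2 <- classify_alleles(c(short = substr(base, 1, 40)), contacts)
  expect_identical(cls2$class_call, "unclassified")
  # order invariance
  cls_rev <- classify_alleles(rev(aa), contacts)
  m <- match(cls$allele_id, cls_rev$allele_id)
  expect_identical(cls$class_call, cls_rev$class_call[m])
})

test_that("gene-conversion screening needs long flanks around a divergent core", {
  set.seed(74)
  # identical pair: nothing to report
  a <- rand_seq(609)
  expect_null(detect_gene_conversion(a, a))
  # structured pair: 247 bp flank, 106 bp core with 21 differences, 256 bp flank
  core_pos <- 248:353
  b <- mutate_seq(a, pos = c(248L, 353L,
                             sample(setdiff(core_pos, c(248L, 353L)), 19)))
  rep <- detect_gene_conversion(a, b)
  expect_identical(rep$flank5_len, 247L)
  expect_identical(rep$core_start, 248L)
  expect_identical(rep$core_end, 353L)
  expect_identical(rep$flank3_len, 256L)
  expect_equal(rep$core_divergence, 21 / 106, tolerance = 1e-12)
  # uniform 5% divergence: flanks too short
  expect_null(detect_gene_conversion(a, mutate_seq(a, pos = seq(20, 600, by = 20))))
  expect_error(detect_gene_conversion(a, substr(a, 1, 100)), "equal")
})

test_that("diversity statistics summarise all-pairs differences over a window", {
  set.seed(75)
  a <- rand_seq(549)
  # two identical alleles
  st0 <- diversity_stats(c(x = a, y = a), 474, 593)
  expect_identical(st0$mean, 0)
  expect_identical(st0$max, 0L)
  expect_identical(st0$window_len, 120L)
  # three constructed alleles with pairwise window differences {10, 20, 30}
  win <- (474 - 73):(593 - 73)
  b <- mutate_seq(a, pos = win[1:10])
  cc <- mutate_seq(a, pos = win[21:40])
  st <- diversity_stats(c(a = a, b = b, c = cc), 474, 593)
  expect_identical(st$mean, 20.0)
  expect_identical(st$max, 30L)
  expect_identical(st$mean <= st$max, TRUE)
  # alleles not spanning the window are excluded with a warning
  expect_warning(
    st2 <- diversity_stats(c(a = a, b = b, short = substr(a, 1, 100)), 474, 593),
    "short")
  expect_identical(st2$n_alleles, 2L)
})

test_that("annotation table combines closest allele, translation and class", {
  set.seed(76)
  db <- allele_db(stats::setNames(replicate(3, rand_seq(549)), paste0("k", 1:3)))
  q <- mutate_seq(db$seq[[2]], n = 30)
  ann <- annotate_alleles(c(LfL2001 = q), db)
  expect_identical(ann$closest_id, "k2")
  expect_lt(ann$closest_identity, 100)
  expect_identical(nchar(ann$aa_seq), 182L)  # floor((549 - 2) / 3)
  expect_true(ann$class_call %in% c("classical", "putative non-classical",
                                    "unclassified"))
})
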