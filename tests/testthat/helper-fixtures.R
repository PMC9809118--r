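# shared fixture builders; every fixture is generated in code under a seed

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute at given positions (or n random positions) -> different base
mutate_seq <- function(seq, pos = NULL, n = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(pos)) pos <- sample(length(ch), n)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# error-free reads tiling the whole sequence at the given spacing,
# alternating orientations; guarantees both terminal bases are covered
tiling_reads <- function(seq, read_len = 100, by = 3, prefix = "t") {
  L <- nchar(seq)
  starts <- unique(c(seq(1, L - read_len + 1, by = by), L - read_len + 1))
  reads <- vapply(starts, function(s) substr(seq, s, s + read_len - 1),
                  character(1))
  rc <- seq_along(reads) %% 2 == 0
  reads[rc] <- revcomp(reads[rc])
  stats::setNames(reads, sprintf("%s%04d", prefix, seq_along(reads)))
}

# independent edit-distance oracle: plain Wagner-Fischer in R
edit_distance_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, integer(length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

# --- independent micro-assembler oracle (tiny instances) -----------------

# best suffix-prefix overlap of oriented sequences a (left) and b (right),
# evaluated ungapped at every offset; same gates as the assembler
oracle_best_overlap <- function(a, b, p) {
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  for (d in (-lb + 1):(la - 1)) {
    s <- max(0, d); e <- min(la, d + lb)
    len <- e - s
    if (len < p$min_overlap_len) next
    aa <- substr(a, s + 1, e)
    bb <- substr(b, s - d + 1, e - d)
    mm <- sum(strsplit(aa, "")[[1]] != strsplit(bb, "")[[1]])
    if ((len - mm) / len < p$min_overlap_identity) next
    sc <- 3 * (len - mm) - 5 * mm
    if (sc < p$min_overlap_score) next
    if (is.null(best) || sc > best$score) best <- list(d = d, score = sc)
  }
  best
}

# exhaustive overlap-order search: explore every order of admissible unit
# merges (units carry explicit layouts) and collect the distinct final
# consensus multisets
oracle_assemble_all <- function(reads, p) {
  orient <- function(s, st) if (st == 0) s else revcomp(s)
  unit_consensus <- function(u) {
    lo <- min(u$off)
    hi <- max(u$off + nchar(reads[u$read]))
    cnt <- matrix(0L, 4, hi - lo)
    for (k in seq_along(u$read)) {
      s <- strsplit(orient(reads[[u$read[k]]], u$strand[k]), "")[[1]]
      idx <- (u$off[k] - lo) + seq_along(s)
      for (t in seq_along(s)) {
        b <- match(s[t], BASES)
        cnt[b, idx[t]] <- cnt[b, idx[t]] + 1L
      }
    }
    paste(BASES[apply(cnt, 2, which.max)], collapse = "")
  }
  normalize <- function(u) { u$off <- u$off - min(u$off); u }
  merge_units <- function(units, i, j, d, o) {
    # place unit j (orientation o, offset d) relative to unit i's frame;
    # both units are kept normalised so consensus and frame coordinates agree
    u <- normalize(units[[i]]); v <- normalize(units[[j]])
    if (o == 1) {
      span <- max(v$off + nchar(reads[v$read]))
      v <- list(read = v$read, off = span - (v$off + nchar(reads[v$read])),
                strand = 1 - v$strand)
    }
    v$off <- v$off + d
    units[[i]] <- normalize(list(read = c(u$read, v$read), off = c(u$off, v$off),
                                 strand = c(u$strand, v$strand)))
    units[[j]] <- NULL
    units
  }
  results <- new.env()
  seen <- new.env()
  recurse <- function(units) {
    key <- paste(sort(vapply(units, function(u) paste(sort(u$read), collapse = ","),
                             character(1))), collapse = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    merged_any <- FALSE
    n <- length(units)
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        ci <- unit_consensus(units[[i]])
        cj <- unit_consensus(units[[j]])
        for (o in 0:1) {
          ov <- oracle_best_overlap(ci, if (o == 0) cj else revcomp(cj), p)
          if (!is.null(ov)) {
            merged_any <- TRUE
            recurse(merge_units(units, i, j, ov$d, o))
          }
        }
      }
    }
    if (!merged_any) {
      fin <- sort(vapply(units[vapply(units, function(u) length(u$read) >= 2,
                                      logical(1))],
                         unit_consensus, character(1)))
      canon <- vapply(fin, function(s) min(s, revcomp(s)), character(1))
      results[[paste(sort(canon), collapse = "|")]] <- TRUE
    }
    invisible()
  }
  units <- lapply(seq_along(reads), function(i)
    list(read = i, off = 0L, strand = 0L))
  recurse(units)
  ls(results)
}

# reads from a mixture of two alleles differing at >=5 positions within
# every 150 bp window, error-free, tiled at the requested depth
mixture_reads <- function(len = 450, depth = 30, read_len = 100) {
  a <- rand_seq(len)
  b <- mutate_seq(a, pos = seq(8, len - 5, by = 25))
  by <- max(1, round(read_len / depth))
  c(tiling_reads(a, read_len, by, "a"), tiling_reads(b, read_len, by, "b")) ->
    reads
  list(a = a, b = b, reads = reads)
}

# simulate a small individual and run the pipeline (shared by orchestrator
# and acceptance tests)
run_sim_individual <- function(seed, n_known = 6, n_carried = 4, n_novel = 1,
                               tiers = NULL, cfg_extra = list()) {
  cfg <- sim_config(rng_seed = seed, n_known = n_known, n_novel = n_novel,
                    divergence_range = c(0.05, 0.15))
  for (nm in names(cfg_extra)) cfg[[nm]] <- cfg_extra[[nm]]
  aset <- simulate_allele_set(cfg)
  carried <- c(aset$db$seq[seq_len(n_carried - n_novel)], aset$novel)
  if (is.null(tiers)) {
    # one high-expression allele per individual; low-bin exemplar at 800
    # (the candidate rule's >500-read floor makes substantially shallower
    # divergent alleles undetectable by construction)
    tiers <- c(6100L, rep(c(800L, 2000L), length.out = length(carried) - 1L))
  }
  cfg$depth_tiers <- stats::setNames(rep_len(tiers, length(carried)),
                                     names(carried))
  sim <- simulate_reads(carried, cfg)
  res <- run_individual(sim$r1, sim$r2, aset$db, run_config(),
                        sprintf("sim%03d", seed))
  list(cfg = cfg, aset = aset, carried = carried, sim = sim, res = res)
}

# engineered pileup with an exact read count over an exact covered span,
# every read carrying one substitution against the reference
engineered_pileup <- function(n_reads, span, allele_len = 549, read_len = 100,
                              min_depth = 5) {
  ref <- rand_seq(allele_len)
  variant <- mutate_seq(ref, pos = 50)
  # 0-based starts covering [0, span); extremes over-weighted so that the
  # terminal columns clear the coverage floor
  inner <- rep_len(seq(0L, span - read_len), max(0L, n_reads - 12L))
  starts <- sort(c(rep(0L, 6L), rep(span - read_len, 6L), inner))[seq_len(n_reads)]
  starts <- sort(starts)
  reads <- vapply(starts + 1L, function(s) substr(variant, s, s + read_len - 1),
                  character(1))
  rec <- data.frame(
    read_id = sprintf("e%05d", seq_len(n_reads)), mate = 1L,
    allele_id = "REF", ref_start = starts,
    cigar = sprintf("%dM", read_len), score = read_len, strand = "+",
    proper_pair = TRUE, edit_distance = 1L, pair_score = 2L * read_len,
    seq = reads, stringsAsFactors = FALSE)
  compute_pileup(rec, c(REF = ref), min_depth = min_depth)
}
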