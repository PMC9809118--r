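#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. The defaults emulate
#' the study conditions the pipeline targets: a 549 bp exon2-exon3 allele
#' region; 5-15% pairwise allele divergence concentrated in two
#' hypervariable windows; 2 x 100 bp proper read pairs with fragment length
#' 300 +/- 50; substitution error 0.3% per base with 1 bp indels at a tenth
#' of that rate; expression tiers spanning <1000, 1000-5000 and >5000 reads
#' at the allele-discriminating marker column. All randomness flows from
#' `rng_seed` through R's integer-state RNG, so equal seeds give
#' byte-identical outputs.
#'
#' @param rng_seed integer seed.
#' @param n_known,n_novel numbers of database and novel alleles to derive.
#' @param divergence_range target range of *pairwise* divergence between
#'   alleles; each allele diverges from the common ancestor at half a rate
#'   drawn from this range, so two alleles differ at approximately a rate
#'   inside it.
#' @param hypervariable_windows list of (start, end) trimmed-coordinate
#'   windows receiving threefold substitution density.
#' @param allele_len trimmed region length (bp).
#' @param plant_motif plant a divergent 9 bp motif at full-CDS 256-264 in
#'   the first novel allele (kept untouched in all others, so the motif
#'   allele differs there from every other allele).
#' @param read_len one of 100, 125, 150.
#' @param fragment_mean,fragment_sd fragment-length distribution.
#' @param error_rate per-base substitution error rate.
#' @param depth_tiers named integer vector: target number of read
#'   alignments covering the marker column, per allele.
#' @param transcript_flank length of the random allele-specific transcript
#'   sequence flanking the target region on each side. Real RNA-Seq
#'   fragments extend beyond the exon2-exon3 region, so its terminal
#'   positions are covered as deeply as its interior; reads partially
#'   overlapping the region align with soft-clipped flank bases.
#' @param marker_pos,cds_offset marker definition, see [bin_expression()].
#' @param min_diff minimum pairwise distance enforced between simulated
#'   alleles.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_known = 6L, n_novel = 2L,
                       divergence_range = c(0.05, 0.15),
                       hypervariable_windows = list(c(130L, 230L), c(380L, 480L)),
                       allele_len = 549L, plant_motif = TRUE,
                       read_len = 100L, fragment_mean = 300L, fragment_sd = 50L,
                       error_rate = 0.003, depth_tiers = NULL,
                       transcript_flank = 100L,
                       marker_pos = 260L, cds_offset = 73L, min_diff = 5L) {
  stopifnot(read_len %in% c(100L, 125L, 150L), n_known >= 1,
            all(divergence_range >= 0 & divergence_range <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

MOTIF_SEQ <- "CAGATACAA"
# ancestral state of the motif window: 8/9 differences from the motif
MOTIF_ANCESTRAL <- "GGCGTCGGC"

#' Simulate a set of related MHC class I alleles
#'
#' Generates a random ancestral exon2-exon3 sequence and derives
#' `n_known + n_novel` alleles by seeded substitutions at per-allele rates
#' drawn from `divergence_range`, with threefold substitution density
#' inside the hypervariable windows. When `plant_motif` is set, the first
#' novel allele carries the divergent 9 bp motif at full-CDS positions
#' 256-264 while that window stays ancestral in every other allele. All
#' pairwise distances are guaranteed >= `min_diff`.
#'
#' @param cfg a [sim_config()].
#' @return list: `db` (an `mhc_refdb` of the known alleles), `novel` (named
#'   character vector), `truth` (data frame: id, is_novel, has_motif,
#'   divergence, seq).
#' @export
simulate_allele_set <- function(cfg = sim_config()) {
  with_sim_seed(cfg$rng_seed, {
    L <- cfg$allele_len
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    motif_start <- 256L - cfg$cds_offset
    motif_idx <- motif_start:(motif_start + 8L)
    if (cfg$plant_motif) {
      anc[motif_idx] <- strsplit(MOTIF_ANCESTRAL, "")[[1]]
    }
    mutable <- setdiff(seq_len(L), if (cfg$plant_motif) motif_idx else integer(0))
    w <- rep(1, length(mutable))
    for (win in cfg$hypervariable_windows) {
      w[mutable >= win[1] & mutable <= win[2]] <- 3
    }
    n_total <- cfg$n_known + cfg$n_novel
    seqs <- character(n_total)
    rates <- numeric(n_total)
    for (i in seq_len(n_total)) {
      for (attempt in 1:50) {
        rate <- runif(1, cfg$divergence_range[1], cfg$divergence_range[2]) / 2
        nsub <- max(1L, round(rate * L))
        pos <- sample(mutable, min(nsub, length(mutable)), prob = w)
        al <- anc
        al[pos] <- vapply(al[pos], function(b) sample(setdiff(bases, b), 1),
                          character(1))
        if (cfg$plant_motif && i == cfg$n_known + 1L) {
          al[motif_idx] <- strsplit(MOTIF_SEQ, "")[[1]]
        }
        s <- paste(al, collapse = "")
        dmin <- if (i > 1) min(adist(s, seqs[seq_len(i - 1L)])) else Inf
        if (dmin >= cfg$min_diff) {
          seqs[i] <- s
          rates[i] <- rate
          break
        }
      }
      if (!nzchar(seqs[i])) {
        stop("could not generate alleles at the requested distance floor; ",
             "reduce the allele count or the floor")
      }
    }
    known_ids <- sprintf("N*%02d:01", seq_len(cfg$n_known))
    novel_ids <- if (cfg$n_novel > 0) sprintf("SIM-NOV-%02d", seq_len(cfg$n_novel))
                 else character(0)
    ids <- c(known_ids, novel_ids)
    is_novel <- c(rep(FALSE, cfg$n_known), rep(TRUE, cfg$n_novel))
    has_motif <- seq_len(n_total) == (cfg$n_known + 1L) & cfg$plant_motif &
      cfg$n_novel > 0
    db <- build_reference(stats::setNames(seqs[!is_novel], known_ids),
                          min_diff = cfg$min_diff, provenance = "curated",
                          quiet = TRUE)
    if (length(db) != cfg$n_known) {
      stop("internal error: redundancy filter removed a simulated known allele")
    }
    list(db = db,
         novel = stats::setNames(seqs[is_novel], novel_ids),
         truth = data.frame(id = ids, is_novel = is_novel,
                            has_motif = has_motif, divergence = rates,
                            seq = seqs, stringsAsFactors = FALSE))
  })
}

# apply substitution + rare 1 bp indel errors to a vector of reads
apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  rl <- nchar(reads)
  nerr <- stats::rbinom(length(reads), rl, error_rate)
  for (i in which(nerr > 0)) {
    ch <- strsplit(reads[i], "")[[1]]
    pos <- sample(length(ch), nerr[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  has_indel <- runif(length(reads)) < rl * error_rate / 10
  for (i in which(has_indel)) {
    ch <- strsplit(reads[i], "")[[1]]
    p <- sample(length(ch), 1)
    if (runif(1) < 0.5) ch <- ch[-p] else ch <- append(ch, sample(bases, 1), p)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate expression-stratified paired-end reads from a genotype
#'
#' Each allele is embedded in an allele-specific random transcript context
#' (`transcript_flank` bases on each side, emulating the rest of the mRNA).
#' Fragments are drawn from the padded transcript (length
#' normal(`fragment_mean`, `fragment_sd`) truncated to
#' `[read_len, 2*fragment_mean]`, uniform start) until the number of read
#' (mate) alignments covering the marker column reaches the allele's depth
#' tier. Mate 1 is the fragment's 5' end; mate 2 the reverse complement of
#' its 3' end. Per-base substitution errors are applied at `error_rate`,
#' 1 bp indels at a tenth of that rate. Base qualities are constant
#' Phred 35.
#'
#' @param alleles named character vector: the individual's allele sequences.
#' @param cfg a [sim_config()]; `cfg$depth_tiers` must name every allele
#'   (unnamed scalar tiers are recycled).
#' @return list of class `sim_reads`: `r1`, `r2` (named character vectors),
#'   `truth` (per-read data frame: read_id, allele, frag_start, frag_len —
#'   transcript coordinates where the target region starts at
#'   `transcript_flank + 1` — and m1_covers, m2_covers for the marker
#'   column), `marker_depth` (named integer vector of true marker-covering
#'   read counts per allele), and `flank` (the flank length used).
#' @export
simulate_reads <- function(alleles, cfg = sim_config()) {
  if (length(alleles) == 0) stop("genotype is empty")
  if (any(nchar(alleles) < cfg$read_len)) stop("allele shorter than read_len")
  tiers <- cfg$depth_tiers
  if (is.null(tiers)) tiers <- stats::setNames(rep(1000L, length(alleles)),
                                               names(alleles))
  if (is.null(names(tiers))) tiers <- stats::setNames(
    rep_len(tiers, length(alleles)), names(alleles))
  fk <- cfg$transcript_flank
  mp <- cfg$marker_pos - cfg$cds_offset + fk  # marker in transcript coords
  with_sim_seed(cfg$rng_seed + 1L, {
    rl <- cfg$read_len
    bases <- c("A", "C", "G", "T")
    tx <- vapply(unname(alleles), function(a) {
      paste0(paste(sample(bases, fk, replace = TRUE), collapse = ""), a,
             paste(sample(bases, fk, replace = TRUE), collapse = ""))
    }, character(1))
    names(tx) <- names(alleles)
    out <- list()
    for (aid in names(alleles)) {
      L <- nchar(tx[[aid]])
      need <- tiers[[aid]]
      starts <- integer(0)
      lens <- integer(0)
      got <- 0L
      while (got < need) {
        b <- max(64L, ceiling((need - got) * 1.2))
        fl <- pmin(pmax(round(rnorm(b, cfg$fragment_mean, cfg$fragment_sd)),
                        rl), min(2L * cfg$fragment_mean, L))
        st <- 1L + floor(runif(b) * (L - fl + 1))
        c1 <- st <= mp & mp <= st + rl - 1L
        c2 <- st + fl - rl <= mp & mp <= st + fl - 1L
        starts <- c(starts, st)
        lens <- c(lens, fl)
        got <- got + sum(c1) + sum(c2)
      }
      out[[aid]] <- data.frame(allele = aid, frag_start = starts,
                               frag_len = lens, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, out)
    rownames(truth) <- NULL
    truth$read_id <- sprintf("sim%06d", seq_len(nrow(truth)))
    truth$m1_covers <- truth$frag_start <= mp &
      mp <= truth$frag_start + rl - 1L
    truth$m2_covers <- truth$frag_start + truth$frag_len - rl <= mp &
      mp <= truth$frag_start + truth$frag_len - 1L
    r1 <- substr(tx[truth$allele], truth$frag_start,
                 truth$frag_start + rl - 1L)
    r2 <- revcomp(substr(tx[truth$allele],
                         truth$frag_start + truth$frag_len - rl,
                         truth$frag_start + truth$frag_len - 1L))
    r1 <- apply_read_errors(unname(r1), cfg$error_rate)
    r2 <- apply_read_errors(unname(r2), cfg$error_rate)
    names(r1) <- names(r2) <- truth$read_id
    md <- tapply(truth$m1_covers + truth$m2_covers, truth$allele, sum)
    structure(list(r1 = r1, r2 = r2,
                   truth = truth[, c("read_id", "allele", "frag_start",
                                     "frag_len", "m1_covers", "m2_covers")],
                   marker_depth = stats::setNames(as.integer(md), names(md)),
                   flank = fk),
              class = "sim_reads")
  })
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim a [simulate_reads()] result.
#' @param r1_path,r2_path output FASTQ paths.
#' @return invisible `NULL`.
#' @export
write_sim_fastq <- function(sim, r1_path, r2_path) {
  qual <- function(s) strrep(rawToChar(as.raw(33L + 35L)), nchar(s))
  wr <- function(seqs, path) {
    lines <- character(4L * length(seqs))
    lines[seq(1, by = 4, length.out = length(seqs))] <- paste0("@", names(seqs))
    lines[seq(2, by = 4, length.out = length(seqs))] <- unname(seqs)
    lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
    lines[seq(4, by = 4, length.out = length(seqs))] <- qual(unname(seqs))
    writeLines(lines, path)
  }
  wr(sim$r1, r1_path)
  wr(sim$r2, r2_path)
  invisible(NULL)
}

#' Simulate a genomic contig containing an allele split by an intron
#'
#' Builds random flanks + exon 2 + a random intron with canonical GT...AG
#' ends + exon 3 + flanks, optionally reverse-complemented, and returns the
#' planted coordinates (always on the forward strand of the emitted
#' sequence).
#'
#' @param allele allele sequence (character scalar).
#' @param intron_len intron length (>= 50).
#' @param flank_len flank length on each side (>= 0).
#' @param boundary exon2/exon3 boundary within the allele, see
#'   [split_exons()].
#' @param revcomp_out emit the reverse complement of the constructed contig.
#' @param seed integer seed.
#' @return list: `seq`, `orientation`, and planted forward-strand
#'   coordinates `exon2`, `exon3` (start, end) with `intron_len`.
#' @export
simulate_genomic_contig <- function(allele, intron_len, flank_len = 200L,
                                    boundary = 270L, revcomp_out = FALSE,
                                    seed = 1L) {
  stopifnot(intron_len >= 50)
  intron_len <- as.integer(intron_len)
  flank_len <- as.integer(flank_len)
  ex <- split_exons(allele, boundary)
  with_sim_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    intron <- paste0("GT", rnd(intron_len - 4L), "AG")
    contig <- paste0(rnd(flank_len), ex$exon2, intron, ex$exon3, rnd(flank_len))
    e2s <- flank_len + 1L
    e2e <- flank_len + nchar(ex$exon2)
    e3s <- e2e + intron_len + 1L
    e3e <- e3s + nchar(ex$exon3) - 1L
    orientation <- "forward"
    if (revcomp_out) {
      Lc <- nchar(contig)
      contig <- revcomp(contig)
      new_e2 <- c(Lc - e2e + 1L, Lc - e2s + 1L)
      new_e3 <- c(Lc - e3e + 1L, Lc - e3s + 1L)
      e2s <- new_e2[1]; e2e <- new_e2[2]
      e3s <- new_e3[1]; e3e <- new_e3[2]
      orientation <- "reverse"
    }
    list(seq = contig, orientation = orientation,
         exon2 = c(start = e2s, end = e2e),
         exon3 = c(start = e3s, end = e3e),
         intron_len = as.integer(intron_len))
  })
}
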