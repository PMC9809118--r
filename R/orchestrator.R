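#' Run configuration for the per-individual discovery loop
#'
#' Collects the thresholds of every stage. Defaults: up to 5
#' discovery/assembly rounds (convergence is usually reached in 1-3);
#' provisional novel alleles named `LfL` + a zero-padded 4-digit counter;
#' candidate rule >500 reads over >400 bp; per-position coverage floor 5;
#' expression marker at full-CDS position 260 with a 73 bp CDS offset to the
#' trimmed exon2-exon3 region; verification demands proper-pair coverage of
#' each 30 bp terminal window. Each candidate's read-pair set is
#' deterministically capped at `max_assembly_reads` (evenly spaced over the
#' id-sorted reads) before the pooled assembly.
#'
#' @param max_rounds maximum discovery rounds (>= 1).
#' @param novel_prefix,novel_counter_start provisional naming scheme.
#' @param min_depth,het_min_count,het_min_frac pileup thresholds, see
#'   [compute_pileup()].
#' @param cand_min_reads,cand_min_span candidate rule, see
#'   [find_candidates()].
#' @param marker_pos,cds_offset expression marker, see [bin_expression()].
#' @param end_window terminal window (bp) for the paired-end coverage check.
#' @param min_depth_frac verification depth-uniformity floor, see
#'   [verify_allele()].
#' @param max_assembly_reads cap on read pairs each candidate contributes
#'   to the pooled assembly.
#' @param provisional_min_len minimum length for a non-full-length contig
#'   to enter the intermediate database as a provisional entry.
#' @param full_length_min_frac see [mark_full_length()].
#' @param assembly an [assembly_params()] object.
#' @param discovery,verify [mapper_params()] objects.
#' @param rng_seed seed recorded in the configuration (the pipeline itself
#'   is deterministic; the seed is consumed by the simulator).
#' @return a list of class `run_config`.
#' @export
run_config <- function(max_rounds = 5L, novel_prefix = "LfL",
                       novel_counter_start = 2001L,
                       min_depth = 5L, het_min_count = 10L, het_min_frac = 0.05,
                       cand_min_reads = 500L, cand_min_span = 400L,
                       marker_pos = 260L, cds_offset = 73L, end_window = 30L,
                       min_depth_frac = 0.02,
                       max_assembly_reads = 1200L, provisional_min_len = 150L,
                       full_length_min_frac = 0.95,
                       assembly = assembly_params(),
                       discovery = mapper_params("discovery"),
                       verify = mapper_params("verify"),
                       rng_seed = 1L) {
  stopifnot(max_rounds >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Provisional novel-allele namer
#'
#' Returns a closure that assigns `prefix` + zero-padded 4-digit counter
#' names. Identical contig sequences (seen at any point of one run) receive
#' one name; the counter errors past 9999.
#'
#' @param start first counter value.
#' @param prefix name prefix.
#' @return function(contig_seq) -> allele id.
#' @export
new_novel_namer <- function(start = 2001L, prefix = "LfL") {
  counter <- as.integer(start)
  seen <- character(0)
  function(contig_seq) {
    hit <- match(contig_seq, seen)
    if (!is.na(hit)) return(names(seen)[hit])
    if (counter > 9999L) stop("novel-allele counter overflow past 9999")
    nm <- sprintf("%s%04d", prefix, counter)
    counter <<- counter + 1L
    seen[[nm]] <<- contig_seq
    nm
  }
}

#' Verify one allele under the stringent mapping regime
#'
#' An allele passes final verification when (i) its pileup is a present
#' known-allele call (complete, mismatch-free, no heterogeneous positions),
#' (ii) no position's depth collapses below `min_depth_frac` of the
#' allele's median depth, and (iii) each of the first and last `end_window`
#' bases is covered by at least one mate alignment belonging to a proper
#' read pair — so both sequence ends are supported by reads of intact
#' fragments rather than orphan mates. The depth-uniformity rule is the
#' quantitative form of visual alignment inspection: a spurious
#' near-duplicate of a real allele shows mismatch-free coverage whose depth
#' at its few distinguishing columns comes only from stray error reads
#' (reads disagreeing near the sequence ends soft-clip silently), orders of
#' magnitude below its median; a genuine low-expression allele co-carried
#' with a high-expression relative still keeps its distinctive columns
#' within a few percent of its tie-boosted median.
#'
#' @param records verification alignments for this allele.
#' @param allele named character scalar.
#' @param min_depth coverage floor, see [compute_pileup()].
#' @param end_window terminal window length in bp (default 30).
#' @param het_min_count,het_min_frac heterogeneity thresholds.
#' @param min_depth_frac minimum per-position depth as a fraction of the
#'   allele's median depth (default 0.02).
#' @return `TRUE` or `FALSE`.
#' @export
verify_allele <- function(records, allele, min_depth = 5L, end_window = 30L,
                          het_min_count = 10L, het_min_frac = 0.05,
                          min_depth_frac = 0.02) {
  p <- compute_pileup(records, allele, min_depth = min_depth,
                      het_min_count = het_min_count, het_min_frac = het_min_frac)
  if (!call_known(p)) return(FALSE)
  if (min(p$depth) < min_depth_frac * stats::median(p$depth)) return(FALSE)
  L <- nchar(allele)
  pp <- records[records$proper_pair, , drop = FALSE]
  if (nrow(pp) == 0) return(FALSE)
  reflen <- cigar_ref_len(pp$cigar)
  s <- pp$ref_start + 1L
  e <- pp$ref_start + reflen
  any(s <= end_window) && any(e >= L - end_window + 1L)
}

# deterministic evenly spaced subsample of candidate read ids
cap_read_ids <- function(ids, cap) {
  ids <- sort(unique(ids))
  if (length(ids) <= cap) return(ids)
  ids[unique(round(seq(1, length(ids), length.out = cap)))]
}

#' Genotype an individual by iterative mapping and reassembly
#'
#' The per-individual loop: discovery mapping against the current database;
#' known-allele calls; candidate detection; extraction of the proper read
#' pairs behind each candidate; stringent de novo assembly; full-length
#' contigs become provisional novel alleles and augment the database; the
#' loop repeats until a round adds no allele or `max_rounds` is reached.
#' A final verification mapping against the individual-complete database
#' determines the genotype: exactly the alleles passing [verify_allele()],
#' each with known/novel status and an expression bin. The returned database
#' contains the input alleles plus all *verified* novel alleles.
#'
#' @param r1,r2 FASTQ paths, or named character vectors of mate sequences.
#' @param db an `mhc_refdb`.
#' @param cfg a [run_config()].
#' @param individual_id sample label for the genotype.
#' @param namer optional [new_novel_namer()] closure shared across
#'   individuals so that names never collide.
#' @return list of class `dinomfrs_result` with elements `genotype` (class
#'   `mhc_genotype`), `db` (augmented `mhc_refdb`), `verify_records`, and
#'   `log` (per-round summaries).
#' @export
run_individual <- function(r1, r2, db, cfg = run_config(),
                           individual_id = "individual",
                           namer = NULL) {
  stopifnot(inherits(db, "mhc_refdb"))
  if (is.character(r1) && length(r1) == 1 && file.exists(r1)) {
    fq <- read_fastq_pairs(r1, r2)
    r1 <- fq$r1
    r2 <- fq$r2
  }
  if (length(r1) == 0) stop("zero reads")
  if (!identical(names(r1), names(r2))) stop("FASTQ read ids do not match")
  if (is.null(namer)) {
    namer <- new_novel_namer(cfg$novel_counter_start, cfg$novel_prefix)
  }
  novel_added <- character(0)
  provisional <- character(0)  # partial contigs grown across rounds
  rounds <- 0L
  log <- list()
  all_rec <- NULL       # per-allele discovery records, cached across rounds
  mapped <- character(0)
  repeat {
    rounds <- rounds + 1L
    work_db <- if (length(provisional)) {
      augment(db, provisional, source = "provisional")
    } else db
    todo <- setdiff(work_db$id, mapped)
    if (length(todo)) {
      newrec <- map_reads(r1, r2, work_db$seq[todo], cfg$discovery,
                          all_scores = TRUE)
      all_rec <- if (is.null(all_rec)) newrec else rbind(all_rec, newrec)
      mapped <- c(mapped, todo)
    }
    rec <- tie_filter_records(all_rec, work_db$id)
    pileups <- lapply(work_db$id, function(aid) {
      compute_pileup(rec[rec$allele_id == aid, , drop = FALSE],
                     work_db$seq[aid], min_depth = cfg$min_depth,
                     het_min_count = cfg$het_min_count,
                     het_min_frac = cfg$het_min_frac)
    })
    cands <- find_candidates(pileups, cfg$cand_min_reads, cfg$cand_min_span)
    # provisional entries are unfinished by definition: every read pair
    # with a mate aligned to one is re-extracted each round (both mates,
    # including mates reaching past the provisional ends) so assembly can
    # extend them; the usual span gate does not apply to them
    cand_ids <- vapply(cands, `[[`, character(1), "allele_id")
    for (p in pileups) {
      if (p$allele_id %in% names(provisional) &&
          !(p$allele_id %in% cand_ids) && p$n_reads > cfg$cand_min_reads) {
        cands[[length(cands) + 1L]] <- list(
          allele_id = p$allele_id, read_ids = p$all_read_ids,
          span_len = unname(p$covered_span[["len"]]), n_reads = p$n_reads)
      }
    }
    new_seqs <- character(0)
    new_provisional <- character(0)
    if (length(cands)) {
      # reads of all candidate alignments are pooled into one assembly,
      # capped per candidate. Pairs with a mate at edit distance >= 3 from
      # the candidate reference are kept preferentially: at 0.3% per-base
      # error essentially no same-allele read reaches 3 differences, so
      # these are the hidden divergent allele's reads that made the
      # alignment ambiguous, and an even subsample alone would dilute them
      # under the deep candidate's own reads. The cap is filled with an
      # even subsample of the rest; the overlap-identity guard keeps
      # co-extracted alleles apart in the assembly itself.
      ids <- unique(unlist(lapply(cands, function(cand) {
        arec <- rec[rec$allele_id == cand$allele_id &
                      rec$read_id %in% cand$read_ids, , drop = FALSE]
        eds <- tapply(arec$edit_distance, arec$read_id, max)
        inform <- sort(names(eds)[eds >= 3L])
        rest <- setdiff(cand$read_ids, inform)
        inform <- cap_read_ids(inform, cfg$max_assembly_reads)
        c(inform,
          cap_read_ids(rest, max(0L, cfg$max_assembly_reads - length(inform))))
      })))
      sel <- names(r1) %in% ids
      reads <- c(stats::setNames(r1[sel], paste0(names(r1)[sel], "/1")),
                 stats::setNames(r2[sel], paste0(names(r2)[sel], "/2")))
      contigs <- assemble(reads, cfg$assembly)
      for (ct in contigs) {
        # keep only the well-supported consensus core, then repair the
        # ends from deep clipped-read votes — but only for
        # near-full-length contigs: extending a short core from a pooled
        # read set could walk along a co-extracted allele's conserved
        # sequence and fabricate a recombinant. Reads come from whole
        # transcripts, so extension may run past the reference region;
        # the contig is then cut back to the allele frame of its closest
        # database match.
        ct <- trim_contig_core(ct, reads)
        if (nchar(ct$seq) >= 0.9 * max(nchar(db$seq))) {
          ct <- extend_contig_ends(ct, reads, cfg$discovery,
                                   min_depth = cfg$min_depth)
          ct <- trim_contig_to_frame(ct, db)
        }
        ct <- mark_full_length(ct, db, cfg$full_length_min_frac)
        if (isTRUE(ct$full_length)) {
          if (ct$seq %in% db$seq) next
          nm <- namer(ct$seq)
          new_seqs[[nm]] <- ct$seq
        } else if (nchar(ct$seq) >= cfg$provisional_min_len &&
                   !(ct$seq %in% db$seq)) {
          # ids carry the round so cached per-allele alignments are never
          # mistaken for a previous round's provisional sequence
          new_provisional[[sprintf("PROV%d.%03d", rounds,
                                   length(new_provisional) + 1L)]] <- ct$seq
        }
      }
    }
    new_seqs <- new_seqs[!duplicated(new_seqs)]
    new_provisional <- new_provisional[!duplicated(new_provisional)]
    # a provisional contig already represented by a new full-length allele
    # (or unchanged from the previous round) carries no new information
    grown <- length(setdiff(new_provisional, provisional)) > 0 &&
      !all(new_provisional %in% new_seqs)
    log[[rounds]] <- list(round = rounds, db_version = db$version,
                          n_candidates = length(cands),
                          novel = names(new_seqs) %||% character(0),
                          n_provisional = length(new_provisional))
    if (length(new_seqs)) {
      db <- augment(db, new_seqs, source = individual_id)
      novel_added <- c(novel_added, names(new_seqs))
    }
    provisional <- new_provisional
    if ((length(new_seqs) == 0 && !grown) || rounds >= cfg$max_rounds) break
  }
  # final verification against the individual-complete database
  vrec <- map_reads(r1, r2, db, cfg$verify)
  rows <- list()
  excluded <- list()
  for (aid in db$id) {
    arec <- vrec[vrec$allele_id == aid, , drop = FALSE]
    pass <- verify_allele(arec, db$seq[aid], min_depth = cfg$min_depth,
                          end_window = cfg$end_window,
                          het_min_count = cfg$het_min_count,
                          het_min_frac = cfg$het_min_frac,
                          min_depth_frac = cfg$min_depth_frac)
    if (pass) {
      eb <- bin_expression(arec, cfg$marker_pos, cfg$cds_offset,
                           nchar(db$seq[aid]))
      rows[[length(rows) + 1L]] <- data.frame(
        allele_id = aid,
        status = if (aid %in% novel_added) "novel" else "known",
        expression = eb$bin, n_reads_marker = eb$n,
        stringsAsFactors = FALSE)
    } else if (nrow(arec) > 0) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        allele_id = aid, n_reads = nrow(arec),
        reason = "insufficient evidence", stringsAsFactors = FALSE)
    }
  }
  geno_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(allele_id = character(0), status = character(0),
               expression = character(0), n_reads_marker = integer(0),
               stringsAsFactors = FALSE)
  # unverified novel alleles are not confirmed: drop them from the database
  confirmed_novel <- intersect(novel_added, geno_df$allele_id)
  failed_novel <- setdiff(novel_added, confirmed_novel)
  if (length(failed_novel)) {
    keep <- !(db$id %in% failed_novel)
    db <- allele_db(db$seq[keep], provenance = db$provenance[keep],
                    source = db$source[keep], min_diff = db$min_diff,
                    version = db$version)
  }
  genotype <- structure(list(
    individual_id = individual_id,
    alleles = geno_df,
    db_version_final = db$version,
    rounds = rounds,
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL
  ), class = "mhc_genotype")
  structure(list(genotype = genotype, db = db, verify_records = vrec,
                 log = log),
            class = "dinomfrs_result")
}

#' @export
print.mhc_genotype <- function(x, ...) {
  cat(sprintf("genotype of %s: %d alleles (%d novel), %d round(s), db version %d\n",
              x$individual_id, nrow(x$alleles),
              sum(x$alleles$status == "novel"), x$rounds, x$db_version_final))
  if (nrow(x$alleles)) print(x$alleles, row.names = FALSE)
  invisible(x)
}

#' @export
print.dinomfrs_result <- function(x, ...) {
  print(x$genotype)
  cat(sprintf("final database: %d alleles, version %d\n",
              length(x$db), x$db$version))
  invisible(x)
}

#' @export
summary.mhc_genotype <- function(object, ...) {
  tab <- table(status = object$alleles$status,
               expression = object$alleles$expression)
  cat(sprintf("%s: %d verified alleles in %d round(s)\n",
              object$individual_id, nrow(object$alleles), object$rounds))
  print(tab)
  invisible(tab)
}

#' Write a genotype as TSV
#'
#' Columns: allele_id, status, expression_bin, n_reads_marker.
#'
#' @param genotype an `mhc_genotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype <- function(genotype, path) {
  df <- genotype$alleles
  names(df)[names(df) == "expression"] <- "expression_bin"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
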