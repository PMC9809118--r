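#' Compute a per-position pileup for one allele
#'
#' Tallies bases along cigar walks (soft-clipped bases excluded; deletions
#' tallied separately; inserted bases recorded but not positionally
#' tallied). The consensus base at a position is the majority base; a
#' position is flagged heterogeneous when the second-most-common base has
#' count >= `het_min_count` and frequency >= `het_min_frac` — thresholds
#' chosen to be robust to sequencing error around 0.1-1%. A position counts
#' as covered at depth >= `min_depth`; an allele is *complete* when every
#' position is covered.
#'
#' @param records alignment records from [map_reads()], all on this allele.
#' @param allele named character scalar: the allele sequence.
#' @param min_depth per-position depth needed to count as covered
#'   (default 5).
#' @param het_min_count,het_min_frac heterogeneity thresholds.
#' @return an object of class `mhc_pileup`.
#' @export
compute_pileup <- function(records, allele, min_depth = 5L,
                           het_min_count = 10L, het_min_frac = 0.05) {
  allele_id <- names(allele) %||% NA_character_
  if (nrow(records) > 0) {
    other <- setdiff(unique(records$allele_id), allele_id)
    if (length(other)) {
      stop("records reference other allele(s): ", paste(other, collapse = ", "))
    }
  }
  L <- nchar(allele)
  ref_chars <- strsplit(unname(allele), "")[[1]]
  if (nrow(records) == 0) {
    counts <- matrix(0L, nrow = 5, ncol = L)
    ins <- 0; tallied <- 0
  } else {
    oriented <- ifelse(records$strand == "-", revcomp(records$seq), records$seq)
    pl <- .pileup_cpp(L, records$ref_start, records$cigar, oriented)
    counts <- pl$counts
    ins <- pl$ins_bases
    tallied <- pl$tallied_bases
  }
  rownames(counts) <- c("A", "C", "G", "T", "del")
  base_tot <- colSums(counts[1:4, , drop = FALSE])
  depth <- base_tot + counts[5, ]
  covered <- depth >= min_depth
  cons_idx <- max.col(t(counts[1:4, , drop = FALSE]), ties.method = "first")
  consensus <- ifelse(base_tot > 0, c("A", "C", "G", "T")[cons_idx], NA_character_)
  second <- apply(counts[1:4, , drop = FALSE], 2,
                  function(v) sort(v, decreasing = TRUE)[2])
  het <- which(covered & second >= het_min_count &
                 base_tot > 0 & second / pmax(base_tot, 1L) >= het_min_frac)
  mism <- which(covered & !is.na(consensus) & consensus != ref_chars)
  r <- rle(covered)
  span_len <- 0L; span_start <- NA_integer_; span_end <- NA_integer_
  if (any(r$values)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)[which.max(r$lengths[r$values])]
    span_len <- r$lengths[k]; span_start <- starts[k]; span_end <- ends[k]
  }
  proper_ids <- if (nrow(records)) unique(records$read_id[records$proper_pair]) else character(0)
  all_ids <- if (nrow(records)) unique(records$read_id) else character(0)
  structure(list(
    allele_id = allele_id,
    allele_seq = unname(allele),
    depth = as.integer(depth),
    base_counts = counts,
    covered_span = c(start = span_start, end = span_end, len = span_len),
    n_reads = nrow(records),
    complete = L > 0 && all(covered),
    mismatch_positions = as.integer(mism),
    het_positions = as.integer(het),
    consensus = consensus,
    min_depth = as.integer(min_depth),
    ins_bases = ins,
    tallied_bases = tallied,
    proper_read_ids = proper_ids,
    all_read_ids = all_ids
  ), class = "mhc_pileup")
}

#' @export
print.mhc_pileup <- function(x, ...) {
  cat(sprintf(
    "pileup %s: %d reads, span %d/%d bp, complete=%s, %d mismatch, %d het\n",
    x$allele_id, x$n_reads, x$covered_span[["len"]], length(x$depth),
    x$complete, length(x$mismatch_positions), length(x$het_positions)))
  invisible(x)
}

#' Call a known allele present or absent
#'
#' An allele is present in an individual exactly when its alignment shows
#' complete coverage with no mismatched and no heterogeneous positions.
#'
#' @param pileup an `mhc_pileup`.
#' @return `TRUE` (present) or `FALSE` (absent).
#' @export
call_known <- function(pileup) {
  isTRUE(pileup$complete) &&
    length(pileup$mismatch_positions) == 0 &&
    length(pileup$het_positions) == 0
}

#' Find novel-allele candidate regions
#'
#' A pileup becomes a candidate when it is *not* a present known allele, has
#' more than `min_reads` aligned reads over a covered span longer than
#' `min_span` bp, and shows at least one mismatched or heterogeneous
#' position. Contributing read ids are collected from proper pairs only.
#'
#' @param pileups list of `mhc_pileup` objects from one discovery round.
#' @param min_reads candidate rule: more than this many aligned reads
#'   (default 500, strict).
#' @param min_span candidate rule: covered span longer than this many bp
#'   (default 400, strict).
#' @return list of candidate regions (allele_id, read_ids, span_len,
#'   n_reads).
#' @export
find_candidates <- function(pileups, min_reads = 500L, min_span = 400L) {
  out <- list()
  for (p in pileups) {
    if (call_known(p)) next
    if (p$n_reads <= min_reads) next
    if (p$covered_span[["len"]] <= min_span) next
    if (length(p$mismatch_positions) + length(p$het_positions) < 1) next
    out[[length(out) + 1L]] <- list(
      allele_id = p$allele_id,
      read_ids = p$proper_read_ids,
      var_positions = sort(c(p$mismatch_positions, p$het_positions)),
      span_len = unname(p$covered_span[["len"]]),
      n_reads = p$n_reads)
  }
  out
}

#' Extract the consensus sequence of a pileup
#'
#' Majority-base string over the longest covered span, with heterogeneous
#' positions masked as `N`. Uncovered leading/trailing positions are
#' omitted. This consensus can be wrong for mixtures of divergent alleles —
#' which is exactly why candidate read sets are reassembled de novo instead
#' of trusting it.
#'
#' @param pileup an `mhc_pileup` with a non-empty covered span.
#' @return character scalar.
#' @export
consensus_sequence <- function(pileup) {
  sp <- pileup$covered_span
  if (is.na(sp[["start"]]) || sp[["len"]] == 0) stop("pileup has no covered span")
  idx <- sp[["start"]]:sp[["end"]]
  ch <- pileup$consensus[idx]
  ch[idx %in% pileup$het_positions] <- "N"
  paste(ch, collapse = "")
}

#' Bin the expression level of an allele
#'
#' Expression is estimated from the number of reads whose alignment covers a
#' single marker position: a column chosen to be allele-discriminating so
#' that the counted reads are allele specific. Counts below 1000 are `low`,
#' 1000-5000 inclusive `middle`, above 5000 `high`.
#'
#' @param records final verification alignments for one allele.
#' @param marker_pos marker position in one-based full-CDS numbering
#'   (default 260).
#' @param allele_offset number of CDS bases preceding the trimmed region
#'   (default 73, the exon 1 length), so the trimmed-coordinate column is
#'   `marker_pos - allele_offset`.
#' @param allele_len length of the allele (bp).
#' @return list with elements `bin` (`"low"`, `"middle"`, `"high"`) and `n`
#'   (the read count at the marker column).
#' @export
bin_expression <- function(records, marker_pos = 260L, allele_offset = 73L,
                           allele_len) {
  mp <- marker_pos - allele_offset
  if (mp < 1 || mp > allele_len) {
    stop(sprintf("marker position %d (trimmed coordinate %d) outside allele of length %d",
                 marker_pos, mp, allele_len))
  }
  n <- 0L
  if (nrow(records) > 0) {
    reflen <- cigar_ref_len(records$cigar)
    n <- sum(records$ref_start + 1L <= mp & records$ref_start + reflen >= mp)
  }
  bin <- if (n < 1000) "low" else if (n <= 5000) "middle" else "high"
  list(bin = bin, n = as.integer(n))
}

#' Write a pileup/candidate report as TSV
#'
#' One row per pileup: allele_id, n_reads, span_len, complete, n_mismatch,
#' n_het, decision (present / candidate / no_call).
#'
#' @param pileups list of `mhc_pileup` objects.
#' @param path output TSV path.
#' @param min_reads,min_span candidate thresholds, see [find_candidates()].
#' @return the report data frame, invisibly.
#' @export
write_pileup_report <- function(pileups, path, min_reads = 500L, min_span = 400L) {
  cand_ids <- vapply(find_candidates(pileups, min_reads, min_span),
                     `[[`, character(1), "allele_id")
  df <- do.call(rbind, lapply(pileups, function(p) {
    data.frame(allele_id = p$allele_id, n_reads = p$n_reads,
               span_len = unname(p$covered_span[["len"]]),
               complete = p$complete,
               n_mismatch = length(p$mismatch_positions),
               n_het = length(p$het_positions),
               decision = if (call_known(p)) "present"
                          else if (p$allele_id %in% cand_ids) "candidate"
                          else "no_call",
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
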