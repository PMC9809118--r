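#' Mapper scoring parameters
#'
#' Two presets mirror the two scoring regimes used for discovery and final
#' verification mapping: `discovery` (match 1, mismatch 4, band 100, clip 5)
#' is permissive, so divergent reads still land on the closest known allele;
#' `verify` (match 2, mismatch 5, band 30, clip 2) is stringent, avoiding
#' mapping of dissimilar sequence fragments. Gap penalties (open 6, extend
#' 1), the unpaired-pair penalty (17) and the exact-seed length (19) follow
#' the conventional defaults of short-read mappers; the minimum reportable
#' score (30 discovery / 40 verify) is set so that random 100-mers
#' essentially never pass.
#'
#' @param preset `"discovery"` or `"verify"`.
#' @param ... named overrides of individual fields (`match`, `mismatch`,
#'   `band`, `clip`, `gap_open`, `gap_extend`, `unpaired_penalty`,
#'   `seed_len`, `min_score`).
#' @return a list of class `mapper_params`.
#' @export
mapper_params <- function(preset = c("discovery", "verify"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "discovery") {
    list(match = 1L, mismatch = 4L, band = 100L, clip = 5L, min_score = 30L)
  } else {
    list(match = 2L, mismatch = 5L, band = 30L, clip = 2L, min_score = 40L)
  }
  p <- c(p, list(gap_open = 6L, gap_extend = 1L, unpaired_penalty = 17L,
                 seed_len = 19L, max_frag = 1000L, preset = preset))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown mapper parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  structure(p, class = "mapper_params")
}

#' Align one read against one allele
#'
#' Seed-and-extend alignment: exact seed k-mers anchor banded local
#' alignment windows (diagonal +/- `band`), scored with affine gaps and a
#' flat per-end soft-clip charge. Both strands are tried; ties are broken by
#' smaller reference start, then forward strand. Returns `NULL` when the best
#' score is below `min_score`, when no exact seed exists, or when the allele
#' is shorter than the seed length.
#'
#' @param seq read sequence (character scalar, Ns allowed).
#' @param allele allele sequence (character scalar; its name, if any, is
#'   copied to the record).
#' @param params a [mapper_params()] object.
#' @return a one-row data frame (allele_id, ref_start, cigar, score, strand,
#'   edit_distance) or `NULL`.
#' @export
align_read <- function(seq, allele, params = mapper_params("discovery")) {
  seq <- normalize_seq(seq, allow_n = TRUE, what = "read")
  al <- normalize_seq(allele, what = "allele")
  if (nchar(seq) < params$seed_len) stop("read shorter than seed_len")
  h <- .align_read_cpp(seq, al, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$band,
                       params$clip, params$seed_len, params$min_score)
  if (is.null(h)) return(NULL)
  data.frame(allele_id = names(allele) %||% NA_character_,
             ref_start = h$ref_start, cigar = h$cigar, score = h$score,
             strand = h$strand, edit_distance = h$edit_distance,
             stringsAsFactors = FALSE)
}

#' Full-matrix local alignment score (reference oracle)
#'
#' An unbanded, unseeded dynamic program over the full read x reference
#' matrix with the identical scoring model as [align_read()] (affine gaps,
#' flat per-end soft-clip charge). Used as an independent check of the
#' seed-and-extend path; one orientation only.
#'
#' @param seq,ref sequences.
#' @param params a [mapper_params()] object.
#' @return the best attainable score (integer, may be negative).
#' @export
align_oracle_score <- function(seq, ref, params = mapper_params("discovery")) {
  .sw_clip_oracle_cpp(seq, ref, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, params$clip)
}

#' Map read pairs against every allele of a reference database
#'
#' Each mate is aligned against every allele. On every allele where both
#' mates align on opposite strands with an implied fragment length between
#' the read length and `max_frag`, the pair is proper and scores the sum of
#' its mate scores; otherwise the sum is reduced by `unpaired_penalty`.
#' Records are emitted for *every* allele tying the maximal pair score:
#' reads from segments conserved between alleles intentionally count toward
#' each tied allele, because downstream per-allele coverage depends on it.
#'
#' @param r1,r2 named character vectors of mate sequences; names are read ids
#'   and must agree between mates.
#' @param db an `mhc_refdb` (or named character vector of alleles).
#' @param params a [mapper_params()] object.
#' @param all_scores emit records for every allele a mate aligns to, not
#'   only the tie-maximal ones (used internally to cache per-allele scores
#'   across discovery rounds; the tie filter is then applied with
#'   [tie_filter_records()]).
#' @return data frame with one row per aligned mate per tied allele:
#'   read_id, mate, allele_id, ref_start (0-based), cigar, score, strand,
#'   proper_pair, edit_distance, pair_score, seq (as sequenced).
#' @export
map_reads <- function(r1, r2, db, params = mapper_params("discovery"),
                      all_scores = FALSE) {
  alleles <- if (inherits(db, "mhc_refdb")) db$seq else db
  if (length(alleles) == 0) stop("empty reference database")
  if (length(r1) != length(r2)) stop("mate vectors differ in length")
  ids <- names(r1) %||% as.character(seq_along(r1))
  ids2 <- names(r2) %||% as.character(seq_along(r2))
  if (!identical(unname(ids), unname(ids2))) stop("read ids of mates do not match")
  if (length(r1) == 0) stop("zero reads")
  rec <- .map_pairs_cpp(unname(r1), unname(r2), unname(alleles),
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend, params$band, params$clip,
                        params$seed_len, params$min_score,
                        params$unpaired_penalty, params$max_frag,
                        isTRUE(all_scores))
  out <- data.frame(
    read_id = ids[rec$pair],
    mate = rec$mate,
    allele_id = names(alleles)[rec$allele],
    ref_start = rec$ref_start,
    cigar = rec$cigar,
    score = rec$score,
    strand = ifelse(rec$reverse, "-", "+"),
    proper_pair = rec$proper_pair,
    edit_distance = rec$edit_distance,
    pair_score = rec$pair_score,
    stringsAsFactors = FALSE)
  out$seq <- ifelse(out$mate == 1L, unname(r1)[rec$pair], unname(r2)[rec$pair])
  out
}

#' Reduce all-allele records to the tie-maximal records per pair
#'
#' Given records emitted with `all_scores = TRUE` (possibly accumulated
#' over several database augmentations), keeps for every read pair exactly
#' the records on the alleles tying its maximal pair score — the same
#' result a fresh [map_reads()] against the full database would produce.
#'
#' @param records data frame from [map_reads()] with `all_scores = TRUE`.
#' @param allele_ids alleles currently in the database; records on other
#'   alleles are ignored.
#' @return tie-filtered records data frame.
#' @export
tie_filter_records <- function(records, allele_ids) {
  rec <- records[records$allele_id %in% allele_ids, , drop = FALSE]
  if (nrow(rec) == 0) return(rec)
  mx <- stats::ave(rec$pair_score, rec$read_id, FUN = max)
  out <- rec[rec$pair_score == mx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a single read pair
#'
#' Convenience wrapper around [map_reads()] for one pair.
#'
#' @param pair list with elements `id`, `seq1`, `seq2`.
#' @inheritParams map_reads
#' @return see [map_reads()]; zero rows if the pair is unmappable.
#' @export
map_pair <- function(pair, db, params = mapper_params("discovery")) {
  map_reads(stats::setNames(pair$seq1, pair$id),
            stats::setNames(pair$seq2, pair$id), db, params)
}

#' Read a pair of FASTQ files
#'
#' Four-line records, Phred+33; gzip accepted. Mate ids must match after
#' stripping a trailing `/1` or `/2` and any description.
#'
#' @param r1_path,r2_path FASTQ file paths.
#' @return list with named character vectors `r1` and `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) == 0 || length(s2) == 0) stop("zero reads in FASTQ input")
  clean <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- clean(names(s1))
  id2 <- clean(names(s2))
  if (!identical(id1, id2)) stop("FASTQ read ids do not match between mates")
  list(r1 = stats::setNames(as.character(s1), id1),
       r2 = stats::setNames(as.character(s2), id2))
}

#' Write alignment records as SAM
#'
#' Emits a valid SAM file with one @SQ line per allele, 1-based positions,
#' standard FLAG bits for pairing, strand and mate fields, and NM
#' (edit distance) / AS (alignment score) tags. Reverse-strand records carry
#' the reverse-complemented SEQ, per SAM convention.
#'
#' @param records data frame from [map_reads()].
#' @param db the `mhc_refdb` the records refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, db, path) {
  alleles <- if (inherits(db, "mhc_refdb")) db$seq else db
  if (nrow(records) > 0 && !all(records$allele_id %in% names(alleles)))
    stop("records reference alleles not present in the database")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(alleles), nchar(alleles)),
           "@PG\tID:dinomfrs\tPN:dinomfrs")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(records) == 0) return(invisible(path))
  reflen <- cigar_ref_len(records$cigar)
  pos <- records$ref_start + 1L
  endpos <- records$ref_start + reflen
  key <- paste(records$read_id, records$allele_id)
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    mate_i <- which(key == key[i] & records$mate != records$mate[i])
    flag <- 1L
    if (records$proper_pair[i]) flag <- flag + 2L
    if (records$strand[i] == "-") flag <- flag + 16L
    if (records$mate[i] == 1L) flag <- flag + 64L else flag <- flag + 128L
    rnext <- "*"; pnext <- 0L; tlen <- 0L
    if (length(mate_i)) {
      j <- mate_i[1]
      if (records$strand[j] == "-") flag <- flag + 32L
      rnext <- "="
      pnext <- pos[j]
      lo <- min(records$ref_start[i], records$ref_start[j])
      hi <- max(endpos[i], endpos[j])
      tlen <- if (records$ref_start[i] <= records$ref_start[j]) hi - lo else lo - hi
    } else {
      flag <- flag + 8L
    }
    sq <- if (is.null(records$seq)) "*" else
      if (records$strand[i] == "-") revcomp(records$seq[i]) else records$seq[i]
    lines[i] <- paste(records$read_id[i], flag, records$allele_id[i], pos[i],
                      60L, records$cigar[i], rnext, pnext, tlen, sq, "*",
                      sprintf("NM:i:%d", records$edit_distance[i]),
                      sprintf("AS:i:%d", records$score[i]), sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}
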