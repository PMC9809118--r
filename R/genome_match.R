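#' Split a trimmed allele into its exon 2 and exon 3 parts
#'
#' The trimmed region is the concatenation of exon 2 and exon 3; the
#' boundary (nominally 270 bp into the region) is supplied by database
#' configuration.
#'
#' @param allele allele sequence (character scalar).
#' @param boundary one-based length of the exon 2 prefix; must satisfy
#'   `0 < boundary < nchar(allele)`.
#' @return list with `exon2` and `exon3`.
#' @export
split_exons <- function(allele, boundary = 270L) {
  allele <- normalize_seq(allele)
  L <- nchar(allele)
  if (boundary <= 0 || boundary >= L) {
    stop(sprintf("exon boundary %d out of range (0, %d)", boundary, L))
  }
  list(exon2 = substr(allele, 1L, boundary),
       exon3 = substr(allele, boundary + 1L, L))
}

# best local hit of one exon on one strand of a contig
exon_hit <- function(exon, contig) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = exon, subject = contig, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  rng <- Biostrings::subject(pa)
  list(start = Biostrings::start(rng), end = Biostrings::end(rng),
       identity = round(100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa), 1),
       score = Biostrings::score(pa))
}

#' Locate an RNA-derived allele in genomic contigs
#'
#' Exon 2 and exon 3 are aligned separately (local alignment, both strands)
#' to every contig. A hit pair is kept when both exons land on the same
#' contig in the same orientation, colinear in transcript order (exon 2
#' upstream of exon 3), with an inter-exon gap inside `intron_range` and
#' both identities at least `min_identity`. Coordinates are one-based
#' inclusive on the contig's forward strand; for reverse-orientation
#' matches each exon is printed transcript-wise, i.e. start > end.
#' `intron_len` is the number of contig bases strictly between the two exon
#' hits.
#'
#' @param alleles named character vector (or `mhc_refdb`) of allele
#'   sequences.
#' @param contigs named character vector of genomic contig sequences.
#' @param boundary exon 2 / exon 3 boundary, see [split_exons()].
#' @param min_identity minimum exon identity in percent (default 80).
#' @param intron_range admissible inter-exon gap in bp (default 50-5000).
#' @return data frame with one row per (allele, contig) match: allele_id,
#'   contig_id, orientation, exon2_start, exon2_end, exon2_identity,
#'   intron_len, exon3_start, exon3_end, exon3_identity.
#' @export
match_to_genome <- function(alleles, contigs, boundary = 270L,
                            min_identity = 80, intron_range = c(50L, 5000L)) {
  seqs <- if (inherits(alleles, "mhc_refdb")) alleles$seq else alleles
  if (length(contigs) == 0) stop("no contigs supplied")
  contigs <- normalize_seq(contigs, allow_n = TRUE, what = "contig")
  rows <- list()
  for (aid in names(seqs)) {
    ex <- split_exons(seqs[[aid]], boundary)
    for (cid in names(contigs)) {
      contig <- contigs[[cid]]
      Lc <- nchar(contig)
      rc <- revcomp(contig)
      best <- NULL
      # forward orientation: exon2 then exon3 left to right
      h2 <- exon_hit(ex$exon2, contig)
      h3 <- exon_hit(ex$exon3, contig)
      gap <- h3$start - h2$end - 1L
      if (h2$identity >= min_identity && h3$identity >= min_identity &&
          gap >= intron_range[1] && gap <= intron_range[2]) {
        best <- data.frame(
          allele_id = aid, contig_id = cid, orientation = "forward",
          exon2_start = h2$start, exon2_end = h2$end,
          exon2_identity = h2$identity, intron_len = gap,
          exon3_start = h3$start, exon3_end = h3$end,
          exon3_identity = h3$identity, score = h2$score + h3$score,
          stringsAsFactors = FALSE)
      }
      # reverse orientation: align against the reverse complement, then
      # reflect coordinates back to the forward strand (start > end)
      r2 <- exon_hit(ex$exon2, rc)
      r3 <- exon_hit(ex$exon3, rc)
      rgap <- r3$start - r2$end - 1L
      if (r2$identity >= min_identity && r3$identity >= min_identity &&
          rgap >= intron_range[1] && rgap <= intron_range[2]) {
        cand <- data.frame(
          allele_id = aid, contig_id = cid, orientation = "reverse",
          exon2_start = Lc - r2$start + 1L, exon2_end = Lc - r2$end + 1L,
          exon2_identity = r2$identity, intron_len = rgap,
          exon3_start = Lc - r3$start + 1L, exon3_end = Lc - r3$end + 1L,
          exon3_identity = r3$identity, score = r2$score + r3$score,
          stringsAsFactors = FALSE)
        if (is.null(best) || cand$score > best$score) best <- cand
      }
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  if (length(rows) == 0) {
    return(data.frame(allele_id = character(0), contig_id = character(0),
                      orientation = character(0), exon2_start = integer(0),
                      exon2_end = integer(0), exon2_identity = numeric(0),
                      intron_len = integer(0), exon3_start = integer(0),
                      exon3_end = integer(0), exon3_identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$score <- NULL
  rownames(out) <- NULL
  out
}
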