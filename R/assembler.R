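#' Assembly stringency parameters
#'
#' Gates on the pairwise read overlaps admitted into the layout: minimum
#' overlap length (40 bp), minimum overlap identity (0.99), and a minimum
#' overlap score with score = matches*3 - mismatches*5. Contigs supported by
#' fewer than `min_reads_per_contig` reads are suppressed as spurious
#' micro-contigs (candidate read sets carry >500 reads by construction, so
#' 20 is conservative). The identity and length gates carry the stringency;
#' the score gate mainly penalises mismatch-rich overlaps (its default, 120,
#' equals a clean overlap at the minimum length — a higher value would
#' reject every true overlap between 2x100 bp reads, whose best possible
#' clean overlap scores 300).
#'
#' @param min_overlap_len minimum overlap length in bp (>= 16).
#' @param min_overlap_identity minimum overlap identity in (0, 1].
#' @param min_overlap_score minimum overlap score.
#' @param min_reads_per_contig minimum supporting reads for a reported
#'   contig.
#' @param kmer k-mer size used to locate candidate overlaps.
#' @return a list of class `assembly_params`.
#' @export
assembly_params <- function(min_overlap_len = 40L, min_overlap_identity = 0.99,
                            min_overlap_score = 120L, min_reads_per_contig = 20L,
                            kmer = 16L) {
  stopifnot(min_overlap_identity > 0, min_overlap_identity <= 1,
            min_overlap_len >= 16)
  structure(list(min_overlap_len = as.integer(min_overlap_len),
                 min_overlap_identity = min_overlap_identity,
                 min_overlap_score = as.integer(min_overlap_score),
                 min_reads_per_contig = as.integer(min_reads_per_contig),
                 kmer = as.integer(kmer)),
            class = "assembly_params")
}

#' Greedy overlap-layout-consensus assembly
#'
#' Computes all pairwise read overlaps (both orientations) passing the
#' length/identity/score gates, merges the best-scoring overlap first (ties:
#' longer overlap, then lexicographic read id) and repeats to fixpoint. A
#' merge that would join two multi-read layouts must additionally agree at
#' the identity gate over the full implied consensus overlap, which keeps
#' reads from distinct co-extracted alleles in separate contigs. Consensus
#' is per-column majority over the stacked reads; a final polish removes
#' reads below the identity gate against their own consensus. Deterministic.
#'
#' @param reads named character vector of read sequences (both mates;
#'   orientation is resolved internally).
#' @param params an [assembly_params()] object.
#' @return list of contigs sorted by supporting-read count (descending);
#'   each contig is a list (class `mhc_contig`) with `seq`, `n_reads`,
#'   `read_layout` (read_id, offset, strand) and `full_length` (`NA` until
#'   [mark_full_length()]). Empty list when everything stays singleton.
#' @export
assemble <- function(reads, params = assembly_params()) {
  if (length(reads) < 2) stop("assembly needs at least 2 reads")
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  reads <- normalize_seq(reads, allow_n = TRUE, what = "read")
  res <- .assemble_cpp(unname(reads), ids,
                       params$min_overlap_len, params$min_overlap_identity,
                       params$min_overlap_score, params$min_reads_per_contig,
                       params$kmer)
  if (length(res$seq) == 0) {
    message("assembly produced no multi-read contigs (all singletons)")
    return(list())
  }
  lapply(seq_along(res$seq), function(i) {
    lay <- res$layout[res$layout$contig == i,
                      c("read_id", "offset", "strand"), drop = FALSE]
    rownames(lay) <- NULL
    structure(list(seq = res$seq[[i]], n_reads = res$n_reads[[i]],
                   read_layout = lay, full_length = NA),
              class = "mhc_contig")
  })
}

#' @export
print.mhc_contig <- function(x, ...) {
  cat(sprintf("contig: %d bp, %d supporting reads, full_length=%s\n",
              nchar(x$seq), x$n_reads, x$full_length))
  invisible(x)
}

# restrict a contig to its well-supported core: the consensus span between
# the first and last column with layout depth >= min_depth. Staircase tail
# columns at depth 1-2 can carry read errors (or error-indel shifts) into
# the consensus; the end-repair step regrows trimmed ends from deeper votes.
trim_contig_core <- function(ct, reads, min_depth = 3L) {
  lay <- ct$read_layout
  L <- nchar(ct$seq)
  depth <- integer(L)
  rl <- nchar(reads[lay$read_id])
  for (k in seq_len(nrow(lay))) {
    idx <- (lay$offset[k] + 1L):min(L, lay$offset[k] + rl[k])
    depth[idx] <- depth[idx] + 1L
  }
  ok <- which(depth >= min_depth)
  if (length(ok) == 0) return(ct)
  ct$seq <- substr(ct$seq, min(ok), max(ok))
  ct
}

#' Extend contig ends by clipped-read voting
#'
#' Reads are re-aligned to the contig; soft-clipped overhangs reaching past
#' the contig ends vote per column, and the contig is extended while the
#' column depth stays at or above `min_depth` (majority base). Repeats to
#' stability. Because reads never extend past the transcript region they
#' were drawn from, the extension is self-limiting; it repairs contig ends
#' truncated by subsampling or by the identity polish.
#'
#' @param contig an `mhc_contig` or character scalar.
#' @param reads character vector of reads (orientation resolved
#'   internally).
#' @param params a [mapper_params()] object used for the re-alignment.
#' @param min_depth minimum overhang depth per extended column.
#' @param max_iter maximum extension iterations.
#' @return the (possibly longer) contig, same type as supplied.
#' @export
extend_contig_ends <- function(contig, reads, params = mapper_params("discovery"),
                               min_depth = 5L, max_iter = 8L) {
  cseq <- if (inherits(contig, "mhc_contig")) contig$seq else contig
  out <- .extend_contig_cpp(cseq, unname(reads), params$match, params$mismatch,
                            params$gap_open, params$gap_extend, params$band,
                            params$clip, params$seed_len, params$min_score,
                            as.integer(min_depth), as.integer(max_iter))
  if (inherits(contig, "mhc_contig")) {
    contig$seq <- out
    contig
  } else out
}

#' Flag a contig as full length
#'
#' A contig is full length when its best local alignment to any database
#' allele covers at least `min_frac` of that allele's length. Only
#' full-length contigs are exported as provisional novel alleles.
#'
#' @param contig an `mhc_contig` (or a character scalar).
#' @param db an `mhc_refdb`.
#' @param min_frac minimum covered fraction of the best-matching allele
#'   (default 0.95).
#' @return the contig with `full_length` set (a logical for character
#'   input).
#' @export
mark_full_length <- function(contig, db, min_frac = 0.95) {
  seqs <- if (inherits(db, "mhc_refdb")) db$seq else db
  if (length(seqs) == 0) stop("empty reference database")
  cseq <- if (inherits(contig, "mhc_contig")) contig$seq else contig
  full <- FALSE
  for (al in seqs) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = cseq, subject = al, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
      gapOpening = 5, gapExtension = 2)
    cov <- Biostrings::width(Biostrings::subject(pa)) / nchar(al)
    if (cov >= min_frac) { full <- TRUE; break }
  }
  if (inherits(contig, "mhc_contig")) {
    contig$full_length <- full
    contig
  } else full
}

#' Trim and orient a contig to the reference allele frame
#'
#' A contig assembled from transcript reads can extend beyond the
#' exon2-exon3 region. The contig is locally aligned to every database
#' allele in both orientations; using the best match as anchor, the contig
#' is oriented like the reference and cut to the span corresponding to the
#' anchor's full length (alignment end coordinates extrapolated linearly
#' across unaligned terminal bases, which is exact for
#' substitution-dominated divergence).
#'
#' @param contig an `mhc_contig` or character scalar.
#' @param db an `mhc_refdb` (or named character vector).
#' @return the trimmed contig (same type as supplied); unchanged if no
#'   anchor aligns or the contig does not reach the anchor's frame.
#' @export
trim_contig_to_frame <- function(contig, db) {
  seqs <- if (inherits(db, "mhc_refdb")) db$seq else db
  cseq <- if (inherits(contig, "mhc_contig")) contig$seq else contig
  sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3)
  best <- NULL
  for (orient in c("+", "-")) {
    q <- if (orient == "+") cseq else revcomp(cseq)
    for (i in seq_along(seqs)) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = seqs[[i]], subject = q, type = "local",
        substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(pa)
      if (is.null(best) || sc > best$sc) {
        best <- list(sc = sc, q = q, L = nchar(seqs[[i]]),
                     ps = Biostrings::start(Biostrings::pattern(pa)),
                     pe = Biostrings::end(Biostrings::pattern(pa)),
                     ss = Biostrings::start(Biostrings::subject(pa)),
                     se = Biostrings::end(Biostrings::subject(pa)))
      }
    }
  }
  out <- cseq
  if (!is.null(best)) {
    from <- best$ss - (best$ps - 1L)
    to <- best$se + (best$L - best$pe)
    if (from >= 1 && to <= nchar(best$q)) {
      out <- substr(best$q, from, to)
    }
  }
  if (inherits(contig, "mhc_contig")) {
    contig$seq <- out
    contig
  } else out
}

#' Write contigs and their read layout to disk
#'
#' Contig consensus sequences as FASTA plus a layout TSV (read_id,
#' contig_id, offset, strand).
#'
#' @param contigs list of `mhc_contig` objects.
#' @param fasta_path,layout_path output paths.
#' @return invisible `NULL`.
#' @export
write_contigs <- function(contigs, fasta_path, layout_path) {
  if (length(contigs) == 0) {
    write_fasta(character(0), fasta_path)
    return(invisible(NULL))
  }
  names(contigs) <- sprintf("contig%03d", seq_along(contigs))
  write_fasta(vapply(contigs, `[[`, character(1), "seq"), fasta_path)
  lay <- do.call(rbind, lapply(names(contigs), function(nm) {
    d <- contigs[[nm]]$read_layout
    d$contig_id <- nm
    d[, c("read_id", "contig_id", "offset", "strand")]
  }))
  write.table(lay, layout_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
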