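#' Construct an allele reference database object
#'
#' A reference database is an ordered collection of exon2-exon3 allele
#' nucleotide sequences with provenance, a monotone version counter, and the
#' redundancy threshold it was built with. Sequences are validated
#' (ACGT only, U converted to T) but no redundancy filtering is applied here;
#' use [build_reference()] for that.
#'
#' @param seqs named character vector of nucleotide sequences; names are
#'   allele ids and must be unique.
#' @param provenance per-allele provenance, one of `"curated"`, `"external"`,
#'   `"novel"` (recycled).
#' @param source free-text accession or sample id per allele (recycled).
#' @param min_diff redundancy threshold in edit-distance units.
#' @param version version counter; incremented by [augment()].
#' @return an object of class `mhc_refdb`.
#' @export
allele_db <- function(seqs, provenance = "curated", source = NA_character_,
                      min_diff = 5L, version = 0L) {
  if (length(seqs) == 0) stop("empty allele collection")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all alleles must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate allele ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_seq(seqs, allow_n = FALSE, what = "allele")
  structure(list(
    id = ids,
    seq = stats::setNames(as.character(seqs), ids),
    provenance = stats::setNames(rep_len(provenance, length(seqs)), ids),
    source = stats::setNames(rep_len(as.character(source), length(seqs)), ids),
    version = as.integer(version),
    min_diff = as.integer(min_diff)
  ), class = "mhc_refdb")
}

#' @export
length.mhc_refdb <- function(x) length(x$seq)

#' @export
print.mhc_refdb <- function(x, ...) {
  cat(sprintf("MHC class I reference database: %d alleles, version %d, min_diff %d\n",
              length(x), x$version, x$min_diff))
  lens <- nchar(x$seq)
  cat(sprintf("  lengths %d-%d bp; provenance: %s\n", min(lens), max(lens),
              paste(sprintf("%s=%d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Edit distance between two allele sequences
#'
#' Full edit distance (substitutions plus indels), the metric underlying the
#' database redundancy filter: from every pair closer than `min_diff` the
#' later-listed member is dropped. Full edit distance rather than
#' substitution-only distance is used so that length-variant near-duplicates
#' are also caught.
#'
#' @param a,b nucleotide sequences (character scalars).
#' @return non-negative integer distance.
#' @export
pairwise_differences <- function(a, b) {
  a <- normalize_seq(a, what = "sequence a")
  b <- normalize_seq(b, what = "sequence b")
  as.integer(adist(a, b))
}

#' Build a redundancy-filtered reference database
#'
#' Scans candidates in input order and retains each sequence whose edit
#' distance to every previously retained sequence is at least `min_diff`.
#' Earlier-listed (curated-first) sequences win ties; every drop is logged
#' with both ids and recorded in the `drops` attribute.
#'
#' @param seqs named character vector of candidate allele sequences.
#' @param min_diff minimum pairwise edit distance retained (default 5).
#' @param provenance,source per-candidate metadata, see [allele_db()].
#' @param quiet suppress per-drop messages.
#' @return an `mhc_refdb` (version 0) with attribute `drops`, a data frame of
#'   (dropped_id, kept_id, distance).
#' @export
build_reference <- function(seqs, min_diff = 5L, provenance = "curated",
                            source = NA_character_, quiet = FALSE) {
  db0 <- allele_db(seqs, provenance = provenance, source = source,
                   min_diff = min_diff, version = 0L)
  keep <- logical(length(db0$seq))
  drops <- list()
  for (i in seq_along(db0$seq)) {
    kept_idx <- which(keep)
    d <- if (length(kept_idx)) {
      as.integer(adist(db0$seq[i], db0$seq[kept_idx]))
    } else integer(0)
    hit <- which(d < min_diff)
    if (length(hit)) {
      j <- kept_idx[hit[1]]
      if (!quiet) {
        message(sprintf("dropping %s: %d differences from %s (< %d)",
                        db0$id[i], d[hit[1]], db0$id[j], min_diff))
      }
      drops[[length(drops) + 1L]] <- data.frame(
        dropped_id = db0$id[i], kept_id = db0$id[j],
        distance = d[hit[1]], stringsAsFactors = FALSE)
    } else {
      keep[i] <- TRUE
    }
  }
  db <- allele_db(db0$seq[keep], provenance = db0$provenance[keep],
                  source = db0$source[keep], min_diff = min_diff, version = 0L)
  attr(db, "drops") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(dropped_id = character(0), kept_id = character(0),
               distance = integer(0), stringsAsFactors = FALSE)
  db
}

#' Augment a reference database with novel alleles
#'
#' Novel sequences identical to an existing allele are discarded (the
#' existing id is reported instead); all others are appended regardless of
#' the redundancy threshold, since genuine novel alleles may legitimately lie
#' within `min_diff` of known ones. The version counter increments by exactly
#' one per call.
#'
#' @param db an `mhc_refdb`.
#' @param novel named character vector of novel allele sequences.
#' @param source free-text origin recorded for appended alleles.
#' @return the augmented `mhc_refdb`, with attribute `report`: a data frame
#'   of (novel_id, action, existing_id) where action is `"added"` or
#'   `"identical"`.
#' @export
augment <- function(db, novel, source = NA_character_) {
  stopifnot(inherits(db, "mhc_refdb"))
  if (length(novel)) {
    novel <- normalize_seq(novel, what = "novel allele")
    coll <- intersect(names(novel), db$id)
    if (length(coll)) stop("novel ids collide with existing ids: ",
                           paste(coll, collapse = ", "))
    if (anyDuplicated(names(novel))) stop("duplicate novel ids")
  }
  seqs <- db$seq
  prov <- db$provenance
  src <- db$source
  report <- list()
  for (i in seq_along(novel)) {
    idn <- names(novel)[i]
    same <- which(seqs == novel[[i]])
    if (length(same)) {
      report[[length(report) + 1L]] <- data.frame(
        novel_id = idn, action = "identical",
        existing_id = names(seqs)[same[1]], stringsAsFactors = FALSE)
    } else {
      seqs <- c(seqs, stats::setNames(novel[i], idn))
      prov <- c(prov, stats::setNames("novel", idn))
      src <- c(src, stats::setNames(as.character(source), idn))
      report[[length(report) + 1L]] <- data.frame(
        novel_id = idn, action = "added", existing_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- allele_db(seqs, provenance = prov, source = src,
                   min_diff = db$min_diff, version = db$version + 1L)
  attr(out, "report") <- if (length(report)) do.call(rbind, report) else
    data.frame(novel_id = character(0), action = character(0),
               existing_id = character(0), stringsAsFactors = FALSE)
  out
}

#' Trim candidate sequences to an anchor's exon2-exon3 span
#'
#' Each input is locally aligned to a designated anchor allele (itself
#' already trimmed to the exon2-exon3 region) and cut to the candidate span
#' covered by that alignment. This replaces multiple-alignment-based trimming
#' with an anchored-coordinate rule.
#'
#' @param seqs named character vector of untrimmed sequences.
#' @param anchor the anchor allele sequence (character scalar).
#' @return named character vector of trimmed sequences.
#' @export
trim_to_anchor <- function(seqs, anchor) {
  anchor <- normalize_seq(anchor, what = "anchor")
  seqs <- normalize_seq(seqs, what = "candidate")
  out <- vapply(seqs, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = anchor, subject = s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
      gapOpening = 5, gapExtension = 2)
    rng <- Biostrings::subject(pa)
    substr(s, Biostrings::start(rng), Biostrings::end(rng))
  }, character(1))
  stats::setNames(out, names(seqs))
}

#' Read an allele FASTA file
#'
#' Arbitrary line wrapping is accepted; the description after the first
#' whitespace is preserved as metadata.
#'
#' @param path FASTA file path.
#' @param provenance provenance recorded for all sequences.
#' @return an `mhc_refdb` with attribute `descriptions`.
#' @export
read_allele_fasta <- function(path, provenance = "curated") {
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  db <- allele_db(stats::setNames(as.character(ss), ids),
                  provenance = provenance, source = basename(path))
  attr(db, "descriptions") <- stats::setNames(desc, ids)
  db
}

#' Write a reference database (or any named sequences) as FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param x an `mhc_refdb` or a named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "mhc_refdb")) x$seq else x
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}
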