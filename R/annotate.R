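#' Percent identity between two allele sequences
#'
#' Identity over the trimmed region as matches divided by comparison
#' columns, in percent, reported to one decimal. Equal-length pairs (the
#' usual case: alleles trimmed to one region) are compared position by
#' position, matching the direct-count convention of allele identity
#' tables; length-variant pairs are first aligned end to end (match +1,
#' mismatch/gap -1).
#'
#' @param a,b nucleotide sequences.
#' @return numeric percentage in [0, 100].
#' @export
percent_identity <- function(a, b) {
  a <- normalize_seq(a, allow_n = TRUE)
  b <- normalize_seq(b, allow_n = TRUE)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(round(100 * sum(ca == cb) / length(ca), 1))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 0, gapExtension = 1)
  columns <- nchar(as.character(Biostrings::pattern(pa)))
  round(100 * Biostrings::nmatch(pa) / columns, 1)
}

#' Closest database allele by percent identity
#'
#' @param query query sequence.
#' @param db an `mhc_refdb` or named character vector.
#' @return list with `closest_id` and `identity`; ties resolved by database
#'   order.
#' @export
closest_allele <- function(query, db) {
  seqs <- if (inherits(db, "mhc_refdb")) db$seq else db
  if (length(seqs) == 0) stop("empty reference database")
  pid <- vapply(seqs, function(s) percent_identity(query, s), numeric(1))
  i <- which.max(pid)
  list(closest_id = names(seqs)[i], identity = unname(pid[i]))
}

#' Map a CDS nucleotide position to its amino-acid position
#'
#' One-based full-CDS numbering on both sides: nucleotide 1-3 is residue 1.
#'
#' @param nt_pos one-based CDS nucleotide position (vectorised).
#' @return one-based amino-acid position(s).
#' @export
cds_to_aa <- function(nt_pos) {
  stopifnot(all(nt_pos >= 1))
  as.integer(ceiling(nt_pos / 3))
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stops rendered `*`; a trailing partial codon is
#' dropped; codons containing N translate to `X`.
#'
#' @param nt nucleotide sequence (character scalar, N allowed).
#' @param frame_offset number of leading bases to skip (0, 1 or 2).
#' @return amino-acid string.
#' @export
translate_nt <- function(nt, frame_offset = 0L) {
  nt <- normalize_seq(nt, allow_n = TRUE)
  n_cod <- (nchar(nt) - frame_offset) %/% 3
  if (n_cod < 1) stop("fewer than 3 usable bases after the frame offset")
  sub <- substr(nt, frame_offset + 1L, frame_offset + 3L * n_cod)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "solve")
  as.character(aa)
}

#' Antigen-contact amino-acid positions
#'
#' The 31 one-based amino-acid positions (full-CDS numbering, leader
#' included) lining the six pockets of the peptide-binding groove, curated
#' from the class I groove literature, with approximate pocket labels.
#' Allelic variation concentrates at these positions; near-invariance there
#' is the signature of putative non-classical alleles.
#'
#' @return data frame with columns `position` (strictly increasing, length
#'   31) and `pocket`.
#' @export
contact_positions <- function() {
  path <- system.file("extdata", "contact_positions.tsv", package = "dinomfrs")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 31, !is.unsorted(df$position, strictly = TRUE))
  df
}

# residues characteristic of the two low-variability allele groups at
# contact positions (reference residue -> group-specific residue)
NC_MARKER_RESIDUES <- list(
  group1 = c(`62` = "H", `65` = "L", `69` = "T", `91` = "I", `122` = "G",
             `161` = "R", `170` = "L", `180` = "F", `186` = "N"),
  group2 = c(`88` = "N", `181` = "V"))

#' Classify alleles as classical or putative non-classical
#'
#' Alleles are compared only at the antigen-contact positions:
#' single-linkage clusters (Hamming distance restricted to the contact set,
#' linkage threshold `max_diff`) of at least `klow` alleles whose
#' within-cluster contact diversity stays within `max_diff` are labeled
#' putative non-classical; everything else is classical. Allele pairs that
#' are identical at all contact positions but differ elsewhere land in one
#' cluster by construction. Sequences too short to cover every contact
#' position are returned unclassified. Group-specific marker residues found
#' in an allele are reported as supporting evidence.
#'
#' @param aa_seqs named character vector of translated allele sequences.
#' @param contacts contact-position data frame, see [contact_positions()].
#' @param max_diff linkage / diversity threshold in residues (default 3).
#' @param klow minimum cluster size for the non-classical label (default 3).
#' @param aa_start amino-acid position (full-CDS numbering) of the first
#'   residue of `aa_seqs` (default 26, i.e. a 73 bp CDS offset and frame
#'   offset 2).
#' @return data frame: allele_id, class_call, cluster, marker_hits.
#' @export
classify_alleles <- function(aa_seqs, contacts = contact_positions(),
                             max_diff = 3L, klow = 3L, aa_start = 26L) {
  ids <- names(aa_seqs)
  idx <- contacts$position - aa_start + 1L
  usable <- vapply(aa_seqs, function(s) all(idx >= 1 & idx <= nchar(s)),
                   logical(1))
  call <- stats::setNames(rep("unclassified", length(aa_seqs)), ids)
  cluster <- stats::setNames(rep(NA_integer_, length(aa_seqs)), ids)
  prof <- lapply(aa_seqs[usable], function(s) {
    strsplit(s, "")[[1]][idx]
  })
  n <- length(prof)
  if (n >= 1) {
    if (n == 1) {
      cl <- 1L
    } else {
      d <- matrix(0L, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d[i, j] <- d[j, i] <- sum(prof[[i]] != prof[[j]])
        }
      }
      cl <- cutree(hclust(as.dist(d), method = "single"), h = max_diff)
    }
    for (k in unique(cl)) {
      members <- which(cl == k)
      diam <- if (length(members) > 1) max(d[members, members]) else 0L
      lab <- if (length(members) >= klow && diam <= max_diff)
        "putative non-classical" else "classical"
      call[names(prof)[members]] <- lab
      cluster[names(prof)[members]] <- k
    }
  }
  hits <- vapply(seq_along(aa_seqs), function(i) {
    s <- aa_seqs[[i]]
    found <- character(0)
    for (g in names(NC_MARKER_RESIDUES)) {
      mk <- NC_MARKER_RESIDUES[[g]]
      for (p in names(mk)) {
        at <- as.integer(p) - aa_start + 1L
        if (at >= 1 && at <= nchar(s) && substr(s, at, at) == mk[[p]]) {
          found <- c(found, sprintf("p.%s%s(%s)", p, mk[[p]], g))
        }
      }
    }
    paste(found, collapse = ",")
  }, character(1))
  data.frame(allele_id = ids, class_call = unname(call),
             cluster = unname(cluster), marker_hits = hits,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen an allele pair for a gene-conversion signature
#'
#' A gene-conversion event leaves two alleles identical over long 5' and 3'
#' flanks around a short, highly divergent core. Reports the segmentation
#' when the maximal identical prefix and suffix are both at least
#' `min_flank` bp and the intervening core (>= `min_core_len` bp) diverges
#' by at least `min_core_div`; otherwise `NULL`.
#'
#' @param a,b equal-length aligned allele sequences.
#' @param min_flank minimum identical flank length (default 200).
#' @param min_core_div minimum core divergence fraction (default 0.10).
#' @param min_core_len minimum core length (default 50).
#' @return `NULL` or a list (flank5_len, core_start, core_end,
#'   core_divergence, flank3_len); coordinates one-based inclusive.
#' @export
detect_gene_conversion <- function(a, b, min_flank = 200L,
                                   min_core_div = 0.10, min_core_len = 50L) {
  a <- normalize_seq(a)
  b <- normalize_seq(b)
  if (nchar(a) != nchar(b)) stop("sequences must be of equal (aligned) length")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  L <- length(ca)
  diff <- which(ca != cb)
  if (length(diff) == 0) return(NULL)
  p <- diff[1] - 1L
  s <- L - diff[length(diff)]
  core <- (p + 1L):(L - s)
  core_div <- sum(ca[core] != cb[core]) / length(core)
  if (p < min_flank || s < min_flank || length(core) < min_core_len ||
      core_div < min_core_div) {
    return(NULL)
  }
  list(flank5_len = p, core_start = p + 1L, core_end = L - s,
       core_divergence = core_div, flank3_len = s)
}

#' Nucleotide diversity over a CDS window
#'
#' All-pairs substitution counts over the window extracted from every
#' allele (alleles not spanning the window are excluded with a warning).
#'
#' @param alleles named character vector of allele sequences (trimmed
#'   region).
#' @param window_start,window_end one-based full-CDS positions.
#' @param cds_offset CDS bases preceding the trimmed region (default 73).
#' @return list: `mean` (one decimal), `max`, `window_len`, `n_alleles`.
#' @export
diversity_stats <- function(alleles, window_start = 474L, window_end = 593L,
                            cds_offset = 73L) {
  if (length(alleles) < 2) stop("need at least 2 alleles")
  ws <- window_start - cds_offset
  we <- window_end - cds_offset
  span <- vapply(alleles, function(s) ws >= 1 && we <= nchar(s), logical(1))
  if (any(!span)) {
    warning("excluding allele(s) not spanning the window: ",
            paste(names(alleles)[!span], collapse = ", "))
  }
  win <- substr(alleles[span], ws, we)
  if (length(win) < 2) stop("fewer than 2 alleles span the window")
  n <- length(win)
  ch <- lapply(win, function(s) strsplit(s, "")[[1]])
  dd <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) dd <- c(dd, sum(ch[[i]] != ch[[j]]))
  }
  list(mean = round(mean(dd), 1), max = max(dd),
       window_len = as.integer(window_end - window_start + 1L),
       n_alleles = n)
}

#' Annotate confirmed alleles
#'
#' Builds a per-allele annotation table: closest database allele with
#' percent identity, translated amino-acid sequence, and the
#' classical / putative non-classical call with supporting marker residues.
#'
#' @param alleles named character vector of (trimmed) allele sequences.
#' @param db an `mhc_refdb` of known alleles to compare against.
#' @param frame_offset frame offset for translation (default 2, matching a
#'   73 bp CDS offset).
#' @param aa_start see [classify_alleles()].
#' @param contacts see [classify_alleles()].
#' @return data frame: allele_id, closest_id, closest_identity, aa_seq,
#'   class_call, marker_hits.
#' @export
annotate_alleles <- function(alleles, db, frame_offset = 2L, aa_start = 26L,
                             contacts = contact_positions()) {
  aa <- vapply(alleles, translate_nt, character(1),
               frame_offset = frame_offset)
  cls <- classify_alleles(aa, contacts = contacts, aa_start = aa_start)
  closest <- lapply(alleles, closest_allele, db = db)
  data.frame(
    allele_id = names(alleles),
    closest_id = vapply(closest, `[[`, character(1), "closest_id"),
    closest_identity = vapply(closest, `[[`, numeric(1), "identity"),
    aa_seq = unname(aa),
    class_call = cls$class_call,
    marker_hits = cls$marker_hits,
    stringsAsFactors = FALSE, row.names = NULL)
}
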