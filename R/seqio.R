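#' @import Biostrings
#' @importFrom stringi stri_reverse
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Genome store: named contigs with 0-based half-open slicing
#'
#' A `genome_store` holds uppercase DNA contigs (alphabet `A,C,G,T,N`) under
#' unique names. All coordinates in this package are 0-based, half-open
#' (BED convention): the interval `[start, end)` covers exactly
#' `end - start` bases.
#'
#' @param contigs named character vector of DNA sequences.
#' @param nonstandard what to do with characters outside `A,C,G,T,N`:
#'   `"error"` (default) or `"to_N"`.
#' @return an object of class `genome_store`.
#' @export
genome_store <- function(contigs, nonstandard = c("error", "to_N")) {
  nonstandard <- match.arg(nonstandard)
  if (length(contigs) == 0L) stop("genome_store: no contigs")
  nm <- names(contigs)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    stop("genome_store: all contigs must be named")
  if (anyDuplicated(nm)) stop("genome_store: duplicate contig ids: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  contigs <- toupper(as.character(contigs))
  if (any(nchar(contigs) == 0L)) stop("genome_store: empty sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    if (nonstandard == "error")
      stop("genome_store: non-nucleotide characters in contig(s): ",
           paste(nm[bad], collapse = ", "))
    contigs[bad] <- gsub("[^ACGTN]", "N", contigs[bad])
  }
  names(contigs) <- nm
  structure(list(contigs = contigs), class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp total\n")
  n <- min(6L, length(x$contigs))
  for (i in seq_len(n))
    cat("  ", names(x$contigs)[i], ": ", nchar(x$contigs[i]), " bp\n", sep = "")
  if (length(x$contigs) > n) cat("  ...\n")
  invisible(x)
}

#' Contig names and lengths
#' @param store a `genome_store`.
#' @return `contig_names`: character vector; `contig_lengths`: named integer
#'   vector of contig lengths in bp.
#' @export
contig_names <- function(store) names(store$contigs)

#' @rdname contig_names
#' @export
contig_lengths <- function(store) {
  stats::setNames(nchar(store$contigs), names(store$contigs))
}

#' Slice a contig with 0-based half-open coordinates
#'
#' Returns exactly `end - start` characters. Out-of-range requests are an
#' error, never a silent truncation.
#'
#' @param store a `genome_store`.
#' @param contig contig id.
#' @param start,end 0-based half-open interval, `0 <= start < end <= length`.
#' @return character scalar.
#' @export
gs_slice <- function(store, contig, start, end) {
  if (!contig %in% names(store$contigs)) stop("unknown contig: ", contig)
  seq <- store$contigs[[contig]]
  n <- nchar(seq)
  if (!(start >= 0 && start < end && end <= n))
    stop("invalid interval [", start, ",", end, ") on contig ", contig,
         " of length ", n)
  substr(seq, start + 1L, end)
}

#' Read a FASTA file into a genome store
#'
#' Lowercase input is uppercased; record order is preserved; duplicate ids
#' and (in strict mode) non-nucleotide characters are errors.
#'
#' @param path FASTA file.
#' @param nonstandard `"error"` or `"to_N"` for characters outside `A,C,G,T,N`.
#' @return a `genome_store`.
#' @export
read_fasta <- function(path, nonstandard = c("error", "to_N")) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_store(seqs, nonstandard = match.arg(nonstandard))
}

#' Write sequences to FASTA
#'
#' @param x a `genome_store` or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "genome_store")) x$contigs else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over its argument; `N` maps to `N`; an involution
#' (`revcomp(revcomp(x)) == x`). The empty string maps to itself.
#'
#' @param seq character vector of DNA sequences over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq))) stop("revcomp: invalid character")
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Extract an element with its flanks
#'
#' Flanks are clipped (not errored) at contig edges, with the clipping
#' recorded. Minus-strand requests return the reverse-complemented element
#' with flanks swapped and complemented, so that `left` is always the
#' element's 5' side.
#'
#' @param store a `genome_store`.
#' @param contig contig id.
#' @param start,end 0-based half-open element interval.
#' @param strand `"+"` or `"-"`.
#' @param flank_len flank length in bp (default 50).
#' @return list with `element`, `left_flank`, `right_flank`,
#'   `left_clipped`, `right_clipped` (logical flags).
#' @export
extract_copy <- function(store, contig, start, end, strand = "+",
                         flank_len = 50L) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (flank_len < 0L) stop("flank_len must be >= 0")
  if (!contig %in% names(store$contigs)) stop("unknown contig: ", contig)
  n <- nchar(store$contigs[[contig]])
  if (!(start >= 0 && start < end && end <= n))
    stop("invalid interval [", start, ",", end, ")")
  elem <- gs_slice(store, contig, start, end)
  lf_start <- max(0L, start - flank_len)
  rf_end <- min(n, end + flank_len)
  lf <- if (start > 0L) gs_slice(store, contig, lf_start, start) else ""
  rf <- if (rf_end > end) gs_slice(store, contig, end, rf_end) else ""
  l_clip <- (start - lf_start) < flank_len
  r_clip <- (rf_end - end) < flank_len
  if (strand == "-") {
    out <- list(element = revcomp(elem),
                left_flank = revcomp(rf), right_flank = revcomp(lf),
                left_clipped = r_clip, right_clipped = l_clip)
  } else {
    out <- list(element = elem, left_flank = lf, right_flank = rf,
                left_clipped = l_clip, right_clipped = r_clip)
  }
  out
}

#' Write element copies as BED6
#'
#' Columns: contig, start, end, name (`family:group` when a group id is
#' present), score (identity percent), strand. Coordinates are written
#' as stored (0-based half-open), i.e. natively BED.
#'
#' @param copies data.frame with columns `contig`, `start`, `end`,
#'   `family`, `strand` and optionally `group`, `identity`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(copies, path) {
  name <- if (!is.null(copies$group)) paste0(copies$family, ":", copies$group)
          else copies$family
  score <- if (!is.null(copies$identity)) round(copies$identity, 1) else 0
  df <- data.frame(copies$contig, copies$start, copies$end, name, score,
                   copies$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of element copies
#'
#' @param path BED file written by [write_bed()].
#' @return data.frame with columns `contig`, `start`, `end`, `family`,
#'   `group`, `identity`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  fam <- sub(":.*$", "", df$name)
  grp <- ifelse(grepl(":", df$name), sub("^[^:]*:", "", df$name), NA_character_)
  data.frame(contig = df$contig, start = df$start, end = df$end,
             family = fam, group = grp, identity = df$score,
             strand = df$strand)
}

# Hamming distance between equal-length strings (N matches nothing).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  if (nchar(a) == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# Identity over the columns of a Biostrings pairwise alignment:
# matches / alignment columns * 100 (gap columns count, N matches nothing).
aln_identity <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- p == s & p != "-" & p != "N"
  100 * sum(ok) / length(p)
}

# Substitution matrix used package-wide: match 1, mismatch -1; gaps cost 2
# per gapped column (gapOpening 0, gapExtension 2 in pairwiseAlignment).
sub_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

align_global <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(pattern, subject, type = "global",
                                substitutionMatrix = sub_mat(),
                                gapOpening = 0, gapExtension = 2)
}

align_local <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(pattern, subject, type = "local",
                                substitutionMatrix = sub_mat(),
                                gapOpening = 0, gapExtension = 2)
}
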