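#' Simulate transposon display (AFLP-style band prediction)
#'
#' For each annotated element copy, the nearest restriction site in the
#' element-side flank (default the 3' flank) within `max_frag` bp is
#' located; the predicted fragment runs from the element/flank junction to
#' the cut. A copy is retained in a selective-amplification lane when the
#' genomic base immediately 5' of the recognition site (the first base the
#' adaptor primer reads through the overhang junction) equals the
#' selective base. Bands are the retained fragment sizes merged within
#' +-1 bp. PCR efficiency and band intensity are not modeled: a band is a
#' distinct predicted size.
#'
#' @param store a [genome_store()].
#' @param copies data.frame with `contig`, `start`, `end`, `strand`
#'   (0-based half-open element coordinates).
#' @param enzyme_site recognition sequence (default BfaI, `CTAG`,
#'   cutting after the first base).
#' @param selective_base selective base read at the junction
#'   (`A`, `C`, `G` or `T`).
#' @param end which element end the TE primer amplifies from: `"3p"`
#'   (default) reads into the right flank, `"5p"` into the left.
#' @param cut_offset cut position within the recognition site (default 1,
#'   i.e. C^TAG).
#' @param max_frag maximum junction-to-site distance considered (bp).
#' @return list of class `td_profile`: `per_copy` (data.frame with
#'   `fragment` size in bp or `NA`, `site_found`, `junction_base`,
#'   `retained`), `bands` (sorted distinct merged sizes), `retained_count`,
#'   `selective_base`, `enzyme_site`.
#' @export
simulate_td <- function(store, copies, enzyme_site = "CTAG",
                        selective_base = "C", end = c("3p", "5p"),
                        cut_offset = 1L, max_frag = 1000L) {
  end <- match.arg(end)
  if (!grepl("^[ACGT]+$", enzyme_site)) stop("invalid enzyme site")
  if (!selective_base %in% c("A", "C", "G", "T"))
    stop("selective_base must be one of A, C, G, T")
  n <- nrow(copies)
  frag <- rep(NA_integer_, n)
  jb <- rep(NA_character_, n)
  site_found <- logical(n)
  for (i in seq_len(n)) {
    cn <- copies$contig[i]
    clen <- nchar(store$contigs[[cn]])
    minus <- !is.null(copies$strand) && copies$strand[i] == "-"
    read_right <- xor(end == "3p", minus)       # flank on the + strand side
    if (read_right) {
      lo <- copies$end[i]
      hi <- min(clen, lo + max_frag)
      if (hi <= lo) next
      flank <- gs_slice(store, cn, lo, hi)
    } else {
      hi <- copies$start[i]
      lo <- max(0L, hi - max_frag)
      if (hi <= lo) next
      flank <- revcomp(gs_slice(store, cn, lo, hi))
    }
    # `flank` is junction-anchored: position 1 is the base adjacent to the
    # element. Searching it for the motif or its reverse complement catches
    # recognition sites on either strand.
    p1 <- regexpr(enzyme_site, flank, fixed = TRUE)
    p2 <- regexpr(revcomp(enzyme_site), flank, fixed = TRUE)
    hitpos <- c(if (p1 > 0) p1, if (p2 > 0) p2)
    if (length(hitpos) == 0L) next
    p <- min(hitpos)
    site_found[i] <- TRUE
    frag[i] <- p - 1L + cut_offset              # junction -> cut distance
    jb[i] <- if (p > 1L) substr(flank, p - 1L, p - 1L) else ""
  }
  retained <- site_found & !is.na(jb) & jb == selective_base
  sizes <- sort(frag[retained])
  bands <- merge_bands(sizes)
  structure(list(
    per_copy = data.frame(copy_id = if (!is.null(copies$copy_id))
                            copies$copy_id else seq_len(n),
                          fragment = frag, site_found = site_found,
                          junction_base = jb, retained = retained,
                          stringsAsFactors = FALSE),
    bands = bands, retained_count = sum(retained),
    selective_base = selective_base, enzyme_site = enzyme_site),
    class = "td_profile")
}

# merge fragment sizes within +-1 bp into single bands (chain merging;
# a band is represented by the smallest size of its chain)
merge_bands <- function(sizes) {
  if (length(sizes) == 0L) return(integer(0))
  sizes <- sort(sizes)
  keep <- c(TRUE, diff(sizes) > 1L)
  sizes[keep]
}

#' @export
print.td_profile <- function(x, ...) {
  cat("in-silico transposon display (", x$enzyme_site, ", selective ",
      x$selective_base, "): ", nrow(x$per_copy), " copies, ",
      x$retained_count, " retained, ", length(x$bands), " bands\n",
      sep = "")
  invisible(x)
}
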