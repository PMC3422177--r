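#' Detect a terminal inverted repeat
#'
#' Direct terminal alignment: the reported TIR length is the longest `L`
#' such that the 5' prefix of length `L` matches the reverse complement of
#' the 3' suffix of length `L` with a mismatch fraction at most
#' `max_mismatch_frac` (default 0, i.e. exact). The best length at a
#' relaxed 10% mismatch fraction is reported alongside. Lengths below
#' `min_len` are not called (length 0). `N` never matches. Wobble pairs are
#' not counted as matches (DNA-level analysis).
#'
#' @param seq element sequence, `nchar(seq) >= 2 * min_len`.
#' @param min_len minimum TIR length to call (default 10, matching the
#'   ">10 bp termini" criterion used for autonomous-partner searches).
#' @param max_mismatch_frac mismatch fraction allowed in the called TIR.
#' @return list of class `tir_report`: `tir_len`, `mismatches`,
#'   `tir_len_relaxed`, `mismatches_relaxed`, `tir5`, `tir3`, `deca5`,
#'   `deca3` (terminal decanucleotides).
#' @export
detect_tir <- function(seq, min_len = 10L, max_mismatch_frac = 0) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L * min_len) stop("sequence too short (", n, " bp) for min_len ",
                             min_len)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(seq), "", fixed = TRUE)[[1]]
  lmax <- n %/% 2L
  pref <- s[seq_len(lmax)]
  suf_rc <- rc[seq_len(lmax)]          # revcomp of the 3' suffix, aligned
  mism <- cumsum(pref != suf_rc | pref == "N" | suf_rc == "N")

  pick <- function(frac) {
    for (L in lmax:min_len) if (mism[L] <= frac * L) return(L)
    0L
  }
  L0 <- pick(max_mismatch_frac)
  L1 <- pick(0.10)
  structure(list(
    tir_len = L0,
    mismatches = if (L0 > 0L) mism[L0] else 0L,
    tir_len_relaxed = L1,
    mismatches_relaxed = if (L1 > 0L) mism[L1] else 0L,
    tir5 = if (L0 > 0L) substr(seq, 1L, L0) else "",
    tir3 = if (L0 > 0L) substr(seq, n - L0 + 1L, n) else "",
    deca5 = substr(seq, 1L, 10L),
    deca3 = substr(seq, n - 9L, n)
  ), class = "tir_report")
}

#' @export
print.tir_report <- function(x, ...) {
  cat("TIR: ", x$tir_len, " bp (", x$mismatches, " mismatches); ",
      "relaxed <=10%: ", x$tir_len_relaxed, " bp\n",
      "5' ", x$deca5, "... / ...", x$deca3, " 3'\n", sep = "")
  invisible(x)
}

#' Detect a subterminal hairpin (stem-loop)
#'
#' Scans the 5' and 3' subterminal windows (excluding the first
#' `exclude` bases, typically the TIR) for the highest-scoring internal
#' inverted repeat with stem length at least `min_stem` and loop length
#' between 3 and `max_loop`. The stem arms must be exactly
#' reverse-complementary. Deterministic tie-break: longest stem, then
#' smallest start offset, then smallest loop.
#'
#' @param seq element sequence.
#' @param window subterminal window width in bp (default 50).
#' @param min_stem minimum stem length (default 5).
#' @param max_loop maximum loop length (default 10).
#' @param exclude bases to skip at the terminus before the window starts
#'   (e.g. the called TIR length).
#' @return list of class `hairpin_report` with one entry per end (`p5`,
#'   `p3`), each holding `present`, `stem_len`, `loop_len`, `offset`
#'   (0-based within the window).
#' @export
detect_hairpin <- function(seq, window = 50L, min_stem = 5L, max_loop = 10L,
                           exclude = 0L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (window > n %/% 2L) stop("window larger than half the sequence")
  w5 <- substr(seq, exclude + 1L, min(n, exclude + window))
  w3s <- max(1L, n - exclude - window + 1L)
  w3 <- substr(seq, w3s, n - exclude)
  structure(list(p5 = scan_hairpin(w5, min_stem, max_loop),
                 p3 = scan_hairpin(w3, min_stem, max_loop),
                 window = window, exclude = exclude),
            class = "hairpin_report")
}

scan_hairpin <- function(w, min_stem, max_loop) {
  v <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(v)
  best <- list(present = FALSE, stem_len = 0L, loop_len = NA_integer_,
               offset = NA_integer_)
  if (n < 2L * min_stem + 3L) return(best)
  comp <- chartr("ACGTN", "TGCAN", v)
  for (i in seq_len(n - 2L * min_stem - 2L)) {           # 1-based arm1 start
    for (loop in 3L:max_loop) {
      max_s <- (n - i + 1L - loop) %/% 2L                # room for both arms
      if (max_s < min_stem) next
      for (s in max_s:min_stem) {                        # longest stem first
        arm1 <- v[i:(i + s - 1L)]
        j <- i + s + loop                                # arm2 start
        arm2 <- v[j:(j + s - 1L)]
        if (all(arm1 == rev(chartr("ACGTN", "TGCAN", arm2)) &
                arm1 != "N" & arm2 != "N")) {
          if (s > best$stem_len) {
            best <- list(present = TRUE, stem_len = s, loop_len = loop,
                         offset = i - 1L)
          }
          break                                          # shorter s dominated
        }
      }
    }
  }
  best
}

#' Group families by shared terminal sequence
#'
#' Single-linkage grouping: two families link when their 5' terminal
#' prefixes share an ungapped match of length within
#' `[min_shared, max_shared]` starting at position 0, allowing up to
#' `max_mismatch` mismatches. Ungrouped families are reported as
#' singletons.
#'
#' @param consensi named character vector of family consensus sequences
#'   (each with a called TIR).
#' @param min_shared,max_shared shared-prefix length window (default 5-9,
#'   the range observed for terminal similarity among element families).
#' @param max_mismatch mismatches tolerated in the shared prefix.
#' @return data.frame `family`, `group`, `n_members` with one row per
#'   family; `group` is an integer group id.
#' @export
group_by_termini <- function(consensi, min_shared = 5L, max_shared = 9L,
                             max_mismatch = 1L) {
  n <- length(consensi)
  fam <- names(consensi)
  if (is.null(fam)) fam <- paste0("fam", seq_len(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  shared_len <- function(a, b) {
    top <- min(max_shared, nchar(a), nchar(b))
    if (top < min_shared) return(0L)
    for (L in top:min_shared) {
      if (hamming(substr(a, 1L, L), substr(b, 1L, L)) <= max_mismatch)
        return(L)
    }
    0L
  }
  if (n > 1L) {
    for (i in 2L:n) for (j in seq_len(i - 1L)) {
      if (shared_len(consensi[[i]], consensi[[j]]) >= min_shared) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gid <- match(roots, unique(roots))
  data.frame(family = fam, group = gid,
             n_members = as.integer(table(gid)[as.character(gid)]),
             stringsAsFactors = FALSE, row.names = NULL)
}
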