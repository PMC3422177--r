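#' Scan a genome for candidate AT-flanked TIR elements
#'
#' Enumerates intervals obeying the canonical AT-insertion grammar — the
#' base before the element is `A`, the base after it is `T`, the first
#' element base is `T` and the last is `A` (i.e. the element sits between
#' the `A` and the `T` of an "AT" dinucleotide) — whose termini form an
#' exact terminal inverted repeat of at least `min_tir` bp and whose
#' length lies in `[min_len, max_len]`. Keyed k-mer pairing makes the scan
#' linear-ish in genome size; with `dedupe = TRUE` (default) only the
#' maximal-TIR interval of each overlapping cluster is kept.
#'
#' Insertions on either strand produce the same plus-strand pattern
#' (`A [T...A] T` is its own reverse-complement layout), so candidates are
#' reported once with strand `"+"`.
#'
#' @param store a [genome_store()].
#' @param min_len,max_len element length bounds (defaults 50/1000 bp,
#'   the MITE-like size range).
#' @param min_tir minimum exact TIR length (default 10).
#' @param dedupe keep only the maximal-TIR interval per overlapping
#'   cluster.
#' @return data.frame `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `tir_len`.
#' @export
scan_candidates <- function(store, min_len = 50L, max_len = 1000L,
                            min_tir = 10L, dedupe = TRUE) {
  stopifnot(min_len >= 30L, min_len < max_len, min_tir >= 4L)
  rows <- list(); nr <- 0L
  for (cn in contig_names(store)) {
    seq <- store$contigs[[cn]]
    n <- nchar(seq)
    if (n < min_len + 2L) next
    at <- unlist(gregexpr("AT", seq, fixed = TRUE))
    at <- at[at > 0L]                       # 1-based position of the A
    if (length(at) < 2L) next
    # element start s (1-based, the T of an AT): s = at + 1
    ss <- at + 1L
    ss <- ss[ss + min_tir - 1L <= n]
    skey <- substring(seq, ss, ss + min_tir - 1L)
    ok <- !grepl("N", skey, fixed = TRUE)
    ss <- ss[ok]; skey <- skey[ok]
    # element end e (1-based, the A of an AT): e = at
    ee <- at[at - min_tir + 1L >= 1L]
    ekey <- revcomp(substring(seq, ee - min_tir + 1L, ee))
    ok <- !grepl("N", ekey, fixed = TRUE)
    ee <- ee[ok]; ekey <- ekey[ok]
    smap <- split(ss, skey)
    emap <- split(ee, ekey)
    common <- intersect(names(smap), names(emap))
    for (key in common) {
      s_pos <- smap[[key]]
      e_pos <- emap[[key]]
      for (s in s_pos) {
        hit <- e_pos[e_pos - s + 1L >= min_len & e_pos - s + 1L <= max_len]
        for (e in hit) {
          elem <- substr(seq, s, e)
          tl <- exact_tir_len(elem)
          if (tl < min_tir) next
          nr <- nr + 1L
          rows[[nr]] <- data.frame(contig = cn, start = s - 1L, end = e,
                                   strand = "+", tir_len = tl,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (nr == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tir_len = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (dedupe) df <- dedupe_candidates(df)
  df
}

# exact terminal inverted repeat length (no mismatches, N never matches)
exact_tir_len <- function(seq) {
  n <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- rev(chartr("ACGTN", "TGCAN", s))
  lmax <- n %/% 2L
  L <- 0L
  while (L < lmax && s[L + 1L] == rc[L + 1L] && s[L + 1L] != "N") L <- L + 1L
  L
}

# greedy non-overlapping selection: maximal-TIR intervals win their
# overlap clusters (ties by leftmost start, then shortest); remaining
# non-overlapping intervals are kept.
dedupe_candidates <- function(df) {
  keep <- list()
  for (cn in unique(df$contig)) {
    d <- df[df$contig == cn, , drop = FALSE]
    d <- d[order(-d$tir_len, d$start, d$end - d$start), , drop = FALSE]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in seq_len(nrow(d))) {
      if (any(d$start[i] < taken_e & d$end[i] > taken_s)) next
      taken_s <- c(taken_s, d$start[i])
      taken_e <- c(taken_e, d$end[i])
      keep[[length(keep) + 1L]] <- d[i, , drop = FALSE]
    }
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster scan candidates into element families
#'
#' Single-linkage clustering of candidate sequences at
#' `>= min_identity` percent full-length identity (global alignment,
#' match 1 / mismatch -1 / gap -2, identity = matches / columns). Clusters
#' reaching `min_copies` members become candidate families: each gets a
#' star-alignment consensus, a TIR report, a flank-conservation target
#' call, and (optionally) an empty-site confirmation that counts intact
#' RES among a sample of members. Automatic filters replace manual
#' inspection: consensus TIR >= `min_tir` exact, copy-length coefficient
#' of variation <= 10%, and (when `confirm_res`) at least one intact RES.
#' Families failing a filter are returned in the `rejected` attribute with
#' reasons, so the filters can be relaxed deliberately.
#'
#' @param store a [genome_store()].
#' @param candidates data.frame from [scan_candidates()].
#' @param min_identity single-linkage identity threshold (percent).
#' @param min_copies minimum cluster size to call a family (default 10,
#'   the full-length-copy threshold for candidate families).
#' @param min_tir minimum exact consensus TIR (default 10).
#' @param confirm_res require and count intact related empty sites.
#' @param res_sample number of members sampled for RES confirmation.
#' @param flank_len flank length for extraction and RES search.
#' @return list of `aton_family` objects (class `aton_family_set`):
#'   each with `family_id`, `consensus`, `members` (copies data.frame),
#'   `tir` (tir_report), `target` (target_call), `copy_number`,
#'   `res_support`, `deca5`, `deca3`.
#' @export
cluster_candidates <- function(store, candidates, min_identity = 80,
                               min_copies = 10L, min_tir = 10L,
                               confirm_res = TRUE, res_sample = 10L,
                               flank_len = 50L) {
  n <- nrow(candidates)
  if (n == 0L) return(structure(list(), class = "aton_family_set"))
  ex <- lapply(seq_len(n), function(i)
    extract_copy(store, candidates$contig[i], candidates$start[i],
                 candidates$end[i], "+", flank_len))
  seqs <- vapply(ex, `[[`, character(1), "element")
  lens <- nchar(seqs)

  # sparse single linkage: only length-compatible pairs are aligned
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 2L:n) {
      js <- which(seq_len(n) < i &
                  pmin(lens[seq_len(n)], lens[i]) /
                  pmax(lens[seq_len(n)], lens[i]) * 100 >= min_identity)
      js <- js[vapply(js, find, integer(1)) !=
                 vapply(rep(i, length(js)), find, integer(1))]
      if (length(js) == 0L) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs[js]), seqs[i], type = "global",
        substitutionMatrix = sub_mat(), gapOpening = 0, gapExtension = 2)
      ident <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      for (idx in which(ident >= min_identity)) {
        ri <- find(i); rj <- find(js[idx])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  clusters <- clusters[lengths(clusters) >= min_copies]
  clusters <- clusters[order(-lengths(clusters))]

  fams <- list(); rejected <- list()
  fam_i <- 0L
  for (cl in clusters) {
    fam_i <- fam_i + 1L
    fid <- sprintf("ATonCand-%02d", fam_i)
    members <- data.frame(
      copy_id = sprintf("%s_%03d", fid, seq_along(cl)),
      family = fid,
      contig = candidates$contig[cl],
      start = candidates$start[cl], end = candidates$end[cl],
      strand = "+",
      tir_len = candidates$tir_len[cl],
      seq = seqs[cl],
      left_flank = vapply(ex[cl], `[[`, character(1), "left_flank"),
      right_flank = vapply(ex[cl], `[[`, character(1), "right_flank"),
      stringsAsFactors = FALSE)
    aln <- align_family(members$seq, ids = members$copy_id)
    cons <- build_consensus(aln)
    tir <- detect_tir(cons, min_len = min(min_tir, 10L))
    target <- if (nrow(members) >= 5L) flank_conservation(members)
              else structure(list(profile = NULL, conserved = NULL,
                                  target = NA_character_,
                                  n_copies = nrow(members)),
                             class = "target_call")
    res_support <- NA_integer_
    if (confirm_res) {
      take <- members[seq_len(min(res_sample, nrow(members))), ]
      res_support <- 0L
      for (i in seq_len(nrow(take))) {
        rr <- retrieve_res(store, take[i, ], flank_len = flank_len)
        res_support <- res_support + sum(rr$classification == "intact_AT")
      }
    }
    cv <- stats::sd(nchar(members$seq)) / mean(nchar(members$seq))
    reasons <- character(0)
    if (tir$tir_len < min_tir) reasons <- c(reasons, "consensus TIR too short")
    if (is.finite(cv) && cv > 0.10) reasons <- c(reasons, "length CV > 10%")
    if (confirm_res && res_support == 0L)
      reasons <- c(reasons, "no intact RES")
    fam <- structure(list(family_id = fid, consensus = cons,
                          members = members, tir = tir, target = target,
                          copy_number = nrow(members),
                          res_support = res_support,
                          deca5 = tir$deca5, deca3 = tir$deca3),
                     class = "aton_family")
    if (length(reasons) == 0L) fams[[length(fams) + 1L]] <- fam
    else {
      fam$rejected_because <- reasons
      rejected[[length(rejected) + 1L]] <- fam
    }
  }
  structure(fams, rejected = rejected, class = "aton_family_set")
}

#' @export
print.aton_family <- function(x, ...) {
  cat(x$family_id, ": ", nchar(x$consensus), " bp consensus, ",
      x$copy_number, " copies, TIR ", x$tir$tir_len, " bp, target ",
      if (is.na(x$target$target)) "?" else x$target$target,
      ", intact RES support ", x$res_support, "\n", sep = "")
  invisible(x)
}

#' @export
print.aton_family_set <- function(x, ...) {
  cat("aton_family_set:", length(x), "family(ies)\n")
  for (f in x) print(f)
  rej <- attr(x, "rejected")
  if (length(rej) > 0L)
    cat("(", length(rej), "cluster(s) rejected by filters )\n")
  invisible(x)
}

#' Summary table for a family set
#'
#' One row per family: id, consensus size, copy number, intact-RES
#' support, and the terminal decanucleotides.
#'
#' @param fams an `aton_family_set` from [cluster_candidates()].
#' @return data.frame.
#' @export
family_summary <- function(fams) {
  do.call(rbind, lapply(fams, function(f)
    data.frame(family = f$family_id, size = nchar(f$consensus),
               copy_number = f$copy_number, tir_len = f$tir$tir_len,
               target = f$target$target, res_support = f$res_support,
               deca5 = f$deca5, deca3 = f$deca3,
               stringsAsFactors = FALSE)))
}

#' Find genomic fragments flanked by element termini
#'
#' Retrieves all intervals that begin with `terminal_seq` and end with its
#' reverse complement, with length in `[min_len, max_len]` — the search
#' used to hunt autonomous partner elements sharing a nonautonomous
#' family's termini. Nested and overlapping pairs all count. The layout is
#' its own reverse complement, so each fragment is reported once (strand
#' `"+"`). Each fragment is annotated with its longest open reading frame
#' over the six frames.
#'
#' @param store a [genome_store()].
#' @param terminal_seq terminal motif, length > 10.
#' @param min_len,max_len fragment length bounds (defaults 500 / 200000).
#' @param orf whether to annotate the longest ORF (can be slow on many
#'   large fragments).
#' @return data.frame `contig`, `start`, `end`, `strand`, `length`,
#'   `longest_orf` (bp, `NA` when `orf = FALSE`).
#' @export
find_flanked_fragments <- function(store, terminal_seq, min_len = 500L,
                                   max_len = 200000L, orf = TRUE) {
  terminal_seq <- toupper(terminal_seq)
  if (nchar(terminal_seq) <= 10L) stop("terminal_seq must be > 10 bp")
  rc <- revcomp(terminal_seq)
  tl <- nchar(terminal_seq)
  rows <- list(); nr <- 0L
  for (cn in contig_names(store)) {
    seq <- store$contigs[[cn]]
    fw <- unlist(gregexpr(terminal_seq, seq, fixed = TRUE))
    bw <- unlist(gregexpr(rc, seq, fixed = TRUE))
    fw <- fw[fw > 0L]; bw <- bw[bw > 0L]
    if (length(fw) == 0L || length(bw) == 0L) next
    for (s in fw) {
      e_end <- bw + tl - 1L                 # fragment end (1-based incl.)
      lens <- e_end - s + 1L
      sel <- which(lens >= min_len & lens <= max_len & bw > s)
      for (i in sel) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(contig = cn, start = s - 1L,
                                 end = e_end[i], strand = "+",
                                 length = lens[i],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (nr == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), longest_orf = integer(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$longest_orf <- NA_integer_
  if (orf) {
    for (i in seq_len(nrow(df)))
      df$longest_orf[i] <- longest_orf(
        gs_slice(store, df$contig[i], df$start[i], df$end[i]))
  }
  df[order(df$contig, df$start, df$end), , drop = FALSE]
}

# longest ORF (start..stop, in bp incl. stop) over six frames
longest_orf <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(v)
    for (frame in 0:2) {
      i <- 1L + frame
      codons <- character(0)
      idx <- seq(i, n - 2L, by = 3L)
      if (length(idx) == 0L) next
      codons <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
      starts <- which(codons == "ATG")
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      for (st in starts) {
        nx <- stops[stops > st]
        if (length(nx) > 0L) {
          len <- (min(nx) - st + 1L) * 3L
          if (len > best) best <- len
        }
      }
    }
  }
  best
}
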