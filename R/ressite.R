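#' Flank conservation profile and target-site call
#'
#' Per-position base-frequency profile over the `n_positions` flanking
#' bases on each side of a family's copies (positions `-n..-1` are the
#' last bases of the left flank, `+1..+n` the first bases of the right
#' flank). A position is conserved when its majority base reaches 90%.
#' For canonical AT-insertion elements, position -1 is a conserved `A` and
#' position +1 a conserved `T` while the remaining positions are at
#' background frequencies.
#'
#' @param copies data.frame with `left_flank`/`right_flank` columns
#'   (>= 5 copies with full flanks).
#' @param n_positions flanking positions profiled on each side.
#' @param conserved_frac majority fraction defining "conserved".
#' @return list of class `target_call`: `profile` (4 x 2n matrix of base
#'   frequencies), `conserved` (named logical), `target` (inferred target
#'   dinucleotide or `NA`).
#' @export
flank_conservation <- function(copies, n_positions = 5L,
                               conserved_frac = 0.9) {
  ok <- nchar(copies$left_flank) >= n_positions &
    nchar(copies$right_flank) >= n_positions
  copies <- copies[ok, , drop = FALSE]
  if (nrow(copies) < 5L)
    stop("flank_conservation needs >= 5 copies with full flanks")
  lf <- substr(copies$left_flank,
               nchar(copies$left_flank) - n_positions + 1L,
               nchar(copies$left_flank))
  rf <- substr(copies$right_flank, 1L, n_positions)
  m <- do.call(rbind, strsplit(paste0(lf, rf), "", fixed = TRUE))
  pos_names <- c(paste0("-", n_positions:1), paste0("+", 1:n_positions))
  prof <- sapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / nrow(m)
  })
  rownames(prof) <- c("A", "C", "G", "T")
  colnames(prof) <- pos_names
  conserved <- apply(prof, 2, max) >= conserved_frac
  maj <- rownames(prof)[apply(prof, 2, which.max)]
  target <- if (conserved[n_positions] && conserved[n_positions + 1L])
    paste0(maj[n_positions], maj[n_positions + 1L]) else NA_character_
  structure(list(profile = prof, conserved = conserved, target = target,
                 n_copies = nrow(copies)),
            class = "target_call")
}

# ---- junction parsing ------------------------------------------------------

# Anchored junction decomposition. The left/right flanks are the occupied
# locus's flanks (left ends in the target A, right starts with the target
# T). Anchors are the outer parts of the flanks that no junction edit can
# touch; the remainders (pad + target base on each side) delimit the
# observed mid segment of the empty site.
JUNCTION_PAD <- 5L

# Best ungapped offset of `pattern` in `subject`; returns list(start,
# mismatches) with 1-based start, or NULL if nothing fits.
best_ungapped <- function(pattern, subject, search_from = 1L,
                          search_to = NA_integer_) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (is.na(search_to)) search_to <- ns - np + 1L
  search_to <- min(search_to, ns - np + 1L)
  if (search_to < search_from) return(NULL)
  best <- NULL
  for (p in search_from:search_to) {
    mm <- hamming(pattern, substr(subject, p, p + np - 1L))
    if (is.null(best) || mm < best$mismatches)
      best <- list(start = p, mismatches = mm)
  }
  best
}

# Decompose an empty-site sequence relative to a flank pair.
# Returns the observed mid segment between the flank anchors together with
# the expected remainders Lrem (pad bases + target A) and Rrem (target T +
# pad bases), plus per-anchor identities.
junction_parse <- function(left_flank, right_flank, res_seq,
                           pad = JUNCTION_PAD) {
  fl <- nchar(left_flank)
  stopifnot(fl == nchar(right_flank), fl > pad + 6L)
  lanc <- substr(left_flank, 1L, fl - pad - 1L)
  ranc <- substr(right_flank, pad + 2L, fl)
  lrem <- substr(left_flank, fl - pad, fl)     # pad bases + target A
  rrem <- substr(right_flank, 1L, pad + 1L)    # target T + pad bases
  na <- nchar(lanc)
  hl <- best_ungapped(lanc, res_seq, 1L, nchar(res_seq) - na + 1L)
  if (is.null(hl)) return(NULL)
  a_end <- hl$start + na - 1L
  hr <- best_ungapped(ranc, res_seq, a_end + 1L)
  if (is.null(hr)) return(NULL)
  mid <- if (hr$start > a_end + 1L)
    substr(res_seq, a_end + 1L, hr$start - 1L) else ""
  list(lrem = lrem, rrem = rrem, mid = mid,
       left_identity = 100 * (na - hl$mismatches) / na,
       right_identity = 100 * (na - hr$mismatches) / na,
       l_anchor_end = a_end, r_anchor_start = hr$start)
}

#' Classify an empty-site junction against the target-site grammar
#'
#' Deterministic read-out of the junction edit script. The observed mid
#' segment (between the flank anchors) is decomposed into a prefix of the
#' left remainder and a suffix of the right remainder; the classification
#' follows from which target/flank bases are missing or inserted:
#' `intact_AT` (exactly `A` + `T` between intact flanks), `typeI` (both
#' target bases absent, flanks intact), `typeII` (one target base absent,
#' with or without small flank erosion), `typeIII` (both target bases
#' absent and at least one flank base deleted), `typeIV` (extra
#' non-flank bases between `A` and `T`). Junctions that fit no
#' decomposition are flagged `unclassified`, never silently binned.
#' Among equally consistent decompositions the one with the least flank
#' deletion, then the most balanced split, is preferred.
#'
#' @param rec a list/row with `lrem`, `rrem`, `mid` as produced by the
#'   internal junction parser (see [retrieve_res()]), or an `res_record`
#'   row from [retrieve_res()].
#' @return character scalar classification.
#' @export
classify_target_site <- function(rec) {
  lrem <- rec$lrem; rrem <- rec$rrem; mid <- rec$mid
  nl <- nchar(lrem); nr <- nchar(rrem); nm <- nchar(mid)
  prefix_ok <- function(i) i == 0L ||
    substr(mid, 1L, i) == substr(lrem, 1L, i)
  suffix_ok <- function(j) j == 0L ||
    substr(mid, nm - j + 1L, nm) == substr(rrem, nr - j + 1L, nr)

  if (nm > nl + nr) {
    # candidate insertion: both remainders fully present around extra bases
    if (prefix_ok(nl) && suffix_ok(nr)) return("typeIV")
    return("unclassified")
  }
  # deletion-type decompositions: mid = lrem[1..i] + rrem[(nr-j+1)..nr]
  cand <- list()
  for (i in 0:min(nl, nm)) {
    j <- nm - i
    if (j < 0L || j > nr) next
    if (prefix_ok(i) && suffix_ok(j)) {
      dl <- nl - i                      # bases missing on the left side
      dr <- nr - j                      # bases missing on the right side
      cand[[length(cand) + 1L]] <- c(dl = dl, dr = dr)
    }
  }
  if (length(cand) == 0L) {
    # same length but mismatching: insertion replacing the target?
    if (nm == nl + nr) return("unclassified")
    return("unclassified")
  }
  flank_del <- vapply(cand, function(x)
    max(x["dl"] - 1L, 0L) + max(x["dr"] - 1L, 0L), numeric(1))
  balance <- vapply(cand, function(x) abs(x["dl"] - x["dr"]), numeric(1))
  pickv <- order(flank_del, balance)[1]
  d <- cand[[pickv]]
  dl <- d[["dl"]]; dr <- d[["dr"]]
  a_missing <- dl >= 1L
  t_missing <- dr >= 1L
  fdel <- max(dl - 1L, 0L) + max(dr - 1L, 0L)
  if (!a_missing && !t_missing) return("intact_AT")
  if (a_missing && t_missing && fdel == 0L) return("typeI")
  if (a_missing && t_missing) return("typeIII")
  "typeII"                              # exactly one target base missing
}

#' Retrieve related empty sites for an element copy
#'
#' Searches the genome for loci where the copy's left and right flank
#' anchors match in the correct order and orientation at
#' `>= min_flank_identity` percent identity, separated by a short junction
#' (no element), on either strand. Occupied orthologs are excluded by the
#' junction-length bound; the source locus itself is never returned. Each
#' hit carries a parsed junction and its target-site classification.
#'
#' @param store a [genome_store()].
#' @param copy one-row data.frame (or list) with `contig`, `start`, `end`,
#'   `left_flank`, `right_flank` — flanks of length `flank_len` from the
#'   occupied locus.
#' @param flank_len flank length (default 50).
#' @param min_flank_identity minimum percent identity per flank anchor.
#' @param max_gap maximum extra junction bases beyond the intact layout.
#' @return data.frame of class `res_record` rows: `copy_id`, `contig`,
#'   `start`, `end` (0-based half-open span of the matched region),
#'   `strand`, `left_identity`, `right_identity`, `junction` (+-10 bp
#'   around the joined flanks), `mid`, `lrem`, `rrem`, `classification`.
#' @export
retrieve_res <- function(store, copy, flank_len = 50L,
                         min_flank_identity = 80, max_gap = 20L) {
  lf <- copy$left_flank; rf <- copy$right_flank
  if (nchar(lf) < flank_len || nchar(rf) < flank_len)
    stop("copy flanks shorter than flank_len")
  lf <- substr(lf, nchar(lf) - flank_len + 1L, nchar(lf))
  rf <- substr(rf, 1L, flank_len)
  pad <- JUNCTION_PAD
  lanc <- substr(lf, 1L, flank_len - pad - 1L)
  ranc <- substr(rf, pad + 2L, flank_len)
  na <- nchar(lanc)
  max_mm <- floor(na * (1 - min_flank_identity / 100))
  # intact layout: lrem (pad+1) + rrem (pad+1) bases between the anchors
  mid_max <- 2L * (pad + 1L) + max_gap
  out <- list(); no <- 0L

  # seeded location of left-anchor candidates: any exact 12-mer of the
  # anchor hits; candidates are verified by full ungapped comparison.
  k <- 12L
  soff <- seq_len(na - k + 1L)
  seeds <- substring(lanc, soff, soff + k - 1L)
  keep <- !grepl("N", seeds, fixed = TRUE)
  if (!any(keep)) return(retrieve_res_empty())
  useeds <- unique(seeds[keep])
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))
  smap <- split(soff[keep], seeds[keep])

  for (cn in contig_names(store)) {
    cseq <- store$contigs[[cn]]
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") cseq else revcomp(cseq)
      subj <- Biostrings::DNAString(sseq)
      m <- Biostrings::matchPDict(dict, subj)
      si <- Biostrings::startIndex(m)
      gpos <- unlist(si)
      if (is.null(gpos) || length(gpos) == 0L) next
      qoff <- unlist(mapply(function(kmer, nhit) rep(smap[[kmer]][1], nhit),
                            useeds, lengths(si), SIMPLIFY = FALSE),
                     use.names = FALSE)
      cand <- sort(unique(gpos - qoff + 1L))
      cand <- cand[cand >= 1L & cand + na - 1L <= clen]
      # drop near-duplicate candidate starts (same locus, several seeds)
      if (length(cand) > 1L)
        cand <- cand[c(TRUE, diff(cand) > 3L)]
      for (hstart0 in cand) {
        hb <- best_ungapped(lanc, sseq, max(1L, hstart0 - 3L), hstart0 + 3L)
        if (is.null(hb) || hb$mismatches > max_mm) next
        hstart <- hb$start
        a_end <- hstart + na - 1L
        # find the right anchor within the junction window
        hr <- best_ungapped(ranc, sseq, a_end + 1L, a_end + 1L + mid_max)
        if (is.null(hr)) next
        if (100 * (na - hr$mismatches) / na < min_flank_identity) next
        span_start <- hstart - 1L                 # 0-based in sseq
        span_end <- hr$start + na - 1L
        # back to + coordinates
        if (strand == "+") {
          g_start <- span_start; g_end <- span_end
        } else {
          g_start <- clen - span_end; g_end <- clen - span_start
        }
        # never return the source locus (flank-overlapping window around it)
        if (!is.null(copy$contig) && cn == copy$contig &&
            g_start < copy$end + flank_len &&
            g_end > copy$start - flank_len) next
        jp <- junction_parse(lf, rf,
                             substr(sseq, hstart, hr$start + na - 1L), pad)
        if (is.null(jp)) next
        hl_id <- 100 * (na - hb$mismatches) / na
        cls <- classify_target_site(jp)
        j_lo <- max(1L, a_end - 9L)
        j_hi <- min(nchar(sseq), a_end + nchar(jp$mid) + 10L)
        no <- no + 1L
        out[[no]] <- data.frame(
          copy_id = if (!is.null(copy$copy_id)) copy$copy_id else NA_character_,
          contig = cn, start = g_start, end = g_end, strand = strand,
          left_identity = round(hl_id, 2),
          right_identity = round(jp$right_identity, 2),
          junction = substr(sseq, j_lo, j_hi),
          mid = jp$mid, lrem = jp$lrem, rrem = jp$rrem,
          classification = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (no == 0L) return(retrieve_res_empty())
  df <- do.call(rbind, out)
  # one record per locus (plus- and minus-strand views are the same site)
  df <- df[!duplicated(paste(df$contig, df$start, df$end)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

retrieve_res_empty <- function() {
  data.frame(copy_id = character(0), contig = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), left_identity = numeric(0),
             right_identity = numeric(0), junction = character(0),
             mid = character(0), lrem = character(0),
             rrem = character(0), classification = character(0),
             stringsAsFactors = FALSE)
}

#' Infer the insertion scenario for a family
#'
#' For canonical elements (first base `T`, last base `A`) the
#' insertion-between-`A`-and-`T` model and the duplicated-`AT` model
#' predict byte-identical occupied loci, so the scenario is `ambiguous`.
#' For non-canonical elements the two occupied-junction bases on each side
#' decide: `AT...AT` around the element supports `duplicated_AT`, a lone
#' `A`/`T` pair supports `between_A_and_T`.
#'
#' @param copies data.frame of family copies with `seq`, `left_flank`,
#'   `right_flank`.
#' @param res_records data.frame from [retrieve_res()]; at least one
#'   intact record is required.
#' @return `"ambiguous"`, `"between_A_and_T"` or `"duplicated_AT"`.
#' @export
infer_scenario <- function(copies, res_records) {
  if (is.null(res_records) ||
      !any(res_records$classification == "intact_AT"))
    stop("infer_scenario needs at least one intact RES")
  first <- substr(copies$seq, 1L, 1L)
  last <- substr(copies$seq, nchar(copies$seq), nchar(copies$seq))
  if (all(first == "T") && all(last == "A")) return("ambiguous")
  pre2 <- substr(copies$left_flank, nchar(copies$left_flank) - 1L,
                 nchar(copies$left_flank))
  post2 <- substr(copies$right_flank, 1L, 2L)
  dup <- pre2 == "AT" & post2 == "AT"
  btw <- substr(pre2, 2L, 2L) == "A" & substr(post2, 1L, 1L) == "T" & !dup
  if (sum(dup) > sum(btw)) return("duplicated_AT")
  if (sum(btw) > sum(dup)) return("between_A_and_T")
  "ambiguous"
}

#' Tabulate RES classifications
#'
#' @param res_records data.frame from [retrieve_res()] (possibly several
#'   copies' records combined).
#' @return named integer vector of counts per classification plus an
#'   `aberrant_fraction` attribute (fraction of classified records that
#'   are type I-IV).
#' @export
res_class_counts <- function(res_records) {
  lev <- c("intact_AT", "typeI", "typeII", "typeIII", "typeIV",
           "unclassified")
  counts <- table(factor(res_records$classification, levels = lev))
  n_cls <- sum(counts[lev != "unclassified"])
  ab <- sum(counts[c("typeI", "typeII", "typeIII", "typeIV")])
  out <- as.integer(counts)
  names(out) <- lev
  attr(out, "aberrant_fraction") <- if (n_cls > 0) ab / n_cls else NA_real_
  out
}
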