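#' Map genomic copies of a repeat family
#'
#' Seed-and-extend homology search: exact k-mer seeds of the query are
#' located on both strands, seed hits are clustered by diagonal, and each
#' cluster is extended by local alignment (match 1, mismatch -1, gap -2).
#' A locus is reported once (best non-overlapping hits) when its alignment
#' reaches at least `min_identity` percent identity over at least
#' `min_coverage` percent of the query. A copy is *complete* when the
#' alignment reaches both query termini within `end_tolerance` bases and
#' covers at least 90% of the query.
#'
#' @param store a [genome_store()].
#' @param query_seq query (family representative) sequence, length >= 30.
#' @param family family id attached to the reported copies.
#' @param min_identity minimum percent identity (matches / alignment
#'   columns) of the local alignment.
#' @param min_coverage minimum percent of the query covered.
#' @param end_tolerance completeness slack at each query terminus (bp).
#' @param k seed k-mer length.
#' @param flank_len flank length extracted for each copy.
#' @return data.frame of element copies: `copy_id`, `family`, `contig`,
#'   `start`, `end` (0-based half-open), `strand`, `identity`, `coverage`,
#'   `complete`, `seq`, `left_flank`, `right_flank`.
#' @export
map_copies <- function(store, query_seq, family = "query",
                       min_identity = 90, min_coverage = 90,
                       end_tolerance = 2L, k = 12L, flank_len = 50L) {
  query_seq <- toupper(query_seq)
  qlen <- nchar(query_seq)
  if (qlen < 30L) stop("query shorter than 30 bp")
  if (qlen < k) stop("query shorter than seed length")
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)

  hits <- list(); nh <- 0L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query_seq else revcomp(query_seq)
    starts <- seq_len(qlen - k + 1L)
    kmers <- substring(q, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    if (!any(keep)) next
    dict <- Biostrings::PDict(Biostrings::DNAStringSet(unique(kmers[keep])))
    kmap <- split(starts[keep], kmers[keep])    # kmer -> query offsets
    dict_kmers <- as.character(Biostrings::DNAStringSet(unique(kmers[keep])))
    for (cn in contig_names(store)) {
      subj <- Biostrings::DNAString(store$contigs[[cn]])
      m <- Biostrings::matchPDict(dict, subj)
      gpos <- unlist(Biostrings::startIndex(m))
      if (is.null(gpos) || length(gpos) == 0L) next
      widths <- lengths(Biostrings::startIndex(m))
      qoff <- unlist(mapply(function(km, n) rep(kmap[[km]][1], n),
                            dict_kmers, widths, SIMPLIFY = FALSE),
                     use.names = FALSE)
      # NOTE: a kmer occurring at several query offsets is anchored at its
      # first offset; window padding below absorbs the difference.
      diag <- gpos - qoff
      ord <- order(diag, gpos)
      diag <- diag[ord]; gpos <- gpos[ord]
      grp <- cumsum(c(TRUE, diff(diag) > 2L * end_tolerance + 10L))
      for (g in unique(grp)) {
        d0 <- diag[grp == g][1]
        pad <- 15L
        w_start <- max(1L, d0 + 1L - pad)
        w_end <- min(nchar(subj), d0 + qlen + pad)
        if (w_end - w_start + 1L < k) next
        nh <- nh + 1L
        hits[[nh]] <- list(contig = cn, strand = strand,
                           w_start = w_start, w_end = w_end)
      }
    }
  }
  if (nh == 0L) return(empty_copies_df())

  # deduplicate identical windows (same locus hit by many seeds/strands)
  key <- vapply(hits, function(h)
    paste(h$contig, h$strand, h$w_start, h$w_end), character(1))
  hits <- hits[!duplicated(key)]

  rows <- list(); nr <- 0L
  for (h in hits) {
    window <- gs_slice(store, h$contig, h$w_start - 1L, h$w_end)
    q <- if (h$strand == "+") query_seq else revcomp(query_seq)
    pa <- align_local(q, window)
    idt <- aln_identity(pa)
    prng <- Biostrings::pattern(pa)
    srng <- Biostrings::subject(pa)
    q_start <- Biostrings::start(prng); q_end <- Biostrings::end(prng)
    cov <- 100 * (q_end - q_start + 1L) / qlen
    if (idt < min_identity || cov < min_coverage) next
    g_start <- h$w_start - 1L + Biostrings::start(srng) - 1L   # 0-based
    g_end <- h$w_start - 1L + Biostrings::end(srng)
    if (h$strand == "-") {
      # pattern was revcomp(query): terminus check in query orientation
      q_start2 <- qlen - q_end + 1L; q_end2 <- qlen - q_start + 1L
      q_start <- q_start2; q_end <- q_end2
    }
    complete <- q_start <= 1L + end_tolerance &&
      q_end >= qlen - end_tolerance && cov >= 90
    nr <- nr + 1L
    rows[[nr]] <- data.frame(contig = h$contig, start = g_start, end = g_end,
                             strand = h$strand, identity = idt,
                             coverage = cov, complete = complete,
                             score = Biostrings::score(pa),
                             stringsAsFactors = FALSE)
  }
  if (nr == 0L) return(empty_copies_df())
  df <- do.call(rbind, rows)

  # greedy non-overlap resolution by descending score
  df <- df[order(-df$score, df$contig, df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ov <- keep & df$contig == df$contig[i] &
      df$start < df$end[i] & df$end > df$start[i]
    if (!any(ov)) keep[i] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$start), , drop = FALSE]

  ex <- lapply(seq_len(nrow(df)), function(i)
    extract_copy(store, df$contig[i], df$start[i], df$end[i],
                 df$strand[i], flank_len))
  data.frame(copy_id = sprintf("%s_%03d", family, seq_len(nrow(df))),
             family = family,
             contig = df$contig, start = df$start, end = df$end,
             strand = df$strand,
             identity = round(df$identity, 2),
             coverage = round(df$coverage, 2),
             complete = df$complete,
             seq = vapply(ex, `[[`, character(1), "element"),
             left_flank = vapply(ex, `[[`, character(1), "left_flank"),
             right_flank = vapply(ex, `[[`, character(1), "right_flank"),
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_copies_df <- function() {
  data.frame(copy_id = character(0), family = character(0),
             contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), identity = numeric(0),
             coverage = numeric(0), complete = logical(0),
             seq = character(0), left_flank = character(0),
             right_flank = character(0), stringsAsFactors = FALSE)
}

#' Group byte-identical element copies at distinct loci
#'
#' Copies are partitioned by exact element-sequence equality (sequences
#' containing `N` never join a group of size > 1 with other members via the
#' `N` positions, since equality is byte-wise and `N` only equals `N`).
#' Within a group, members whose concatenated flank pairs differ at fewer
#' than `flank_distinct_min_mismatch` positions are collapsed into one
#' (suspected assembly duplicates). Groups of size 1 are retained.
#'
#' @param copies data.frame from [map_copies()] (complete copies of one
#'   family).
#' @param flank_distinct_min_mismatch minimum flank mismatches for two
#'   identical copies to count as distinct loci.
#' @return list of groups, each a list with `family`, `seq`, `size`,
#'   `members` (data.frame). Sorted by size descending, ties by leftmost
#'   genomic position.
#' @export
group_identical <- function(copies, flank_distinct_min_mismatch = 5L) {
  if (nrow(copies) == 0L) return(list())
  groups <- split(seq_len(nrow(copies)), copies$seq)
  out <- lapply(groups, function(idx) {
    # collapse members with near-identical flanks (union-find)
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (length(idx) > 1L) {
      fl <- paste0(copies$left_flank[idx], copies$right_flank[idx])
      for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1L)) {
        if (nchar(fl[a]) == nchar(fl[b]) &&
            hamming(fl[a], fl[b]) < flank_distinct_min_mismatch) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    reps <- vapply(seq_along(idx), find, integer(1))
    members <- copies[idx[!duplicated(reps)], , drop = FALSE]
    list(family = copies$family[idx[1]], seq = copies$seq[idx[1]],
         size = nrow(members), members = members)
  })
  sizes <- vapply(out, `[[`, integer(1), "size")
  first <- vapply(out, function(g)
    min(g$members$start), numeric(1))
  out <- out[order(-sizes, first)]
  names(out) <- NULL
  out
}

#' Per-family report of identical-copy groups
#'
#' @param family family id.
#' @param total_complete total number of complete copies in the family.
#' @param groups list from [group_identical()] (or a numeric vector of
#'   group sizes for table-encoded input).
#' @param te_type optional TE type annotation (e.g. `"tSINE"`,
#'   `"mTA MITE"`).
#' @return list of class `family_report` with groups labelled `a`, `b`,
#'   `c`, ... in descending size order.
#' @export
family_report <- function(family, total_complete, groups, te_type = NA) {
  sizes <- if (is.numeric(groups)) as.integer(groups)
           else vapply(groups, `[[`, integer(1), "size")
  ord <- order(-sizes)
  sizes <- sizes[ord]
  stopifnot(sum(sizes) <= max(total_complete, sum(sizes)))
  structure(list(family = family, total_complete = total_complete,
                 group_sizes = sizes,
                 group_labels = letters[seq_along(sizes)],
                 te_type = te_type),
            class = "family_report")
}

#' Rank families by identical-copy group size
#'
#' One row per identical group of at least `min_group_size` members, the
#' flashing indicator for current or very recent transposition activity.
#'
#' @param reports list of [family_report()] objects.
#' @param min_group_size minimum group size to report (>= 2).
#' @param te_type_filter optional regular expression on the TE type
#'   annotation (e.g. `"tSINE"` for the retro fraction).
#' @return data.frame `family`, `total_complete`, `group`, `size`,
#'   `te_type`, sorted by family then size descending, with attributes
#'   `n_groups` and `n_families`.
#' @export
rank_families <- function(reports, min_group_size = 10L,
                          te_type_filter = NULL) {
  stopifnot(min_group_size >= 2L)
  rows <- lapply(reports, function(r) {
    keep <- r$group_sizes >= min_group_size
    if (!any(keep)) return(NULL)
    data.frame(family = r$family, total_complete = r$total_complete,
               group = r$group_labels[keep], size = r$group_sizes[keep],
               te_type = r$te_type, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(family = character(0),
                                    total_complete = integer(0),
                                    group = character(0), size = integer(0),
                                    te_type = character(0))
  if (!is.null(te_type_filter))
    df <- df[grepl(te_type_filter, df$te_type), , drop = FALSE]
  df <- df[order(df$family, -df$size), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_groups") <- nrow(df)
  attr(df, "n_families") <- length(unique(df$family))
  df
}

#' Read a family summary table into family reports
#'
#' Expects a TSV with columns `family`, `total`, `group`, `size`,
#' `te_type`; one row per identical group (the layout of a published
#' identical-copy screen summary).
#'
#' @param path TSV file.
#' @return list of [family_report()] objects.
#' @export
read_family_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, df$family), function(d)
    family_report(d$family[1], d$total[1], d$size, d$te_type[1]))
}
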