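#' Star multiple alignment of family copies
#'
#' Every copy is globally aligned to a seed (the modal sequence: most
#' frequent, ties broken by length then lexicographic order) and the
#' pairwise alignments are merged column-wise, padding insertions relative
#' to the seed to their maximum length. Deterministic for any input order.
#'
#' @param seqs character vector of copy sequences (>= 2).
#' @param ids optional copy ids (default `copy1`, `copy2`, ...).
#' @return list of class `aton_alignment`: `matrix` (character matrix,
#'   rows = copies, `-` for gaps), `ids`, `seed`.
#' @export
align_family <- function(seqs, ids = NULL) {
  n <- length(seqs)
  if (n < 2L) stop("align_family needs >= 2 copies")
  if (is.null(ids)) ids <- paste0("copy", seq_len(n))
  seqs <- toupper(seqs)
  tab <- table(seqs)
  modal <- names(tab)[tab == max(tab)]
  modal <- modal[order(-nchar(modal), modal)]
  seed <- modal[1]
  L <- nchar(seed)

  # per copy: bases aligned to each seed position + insertions per slot
  per <- vector("list", n)
  uniq <- unique(seqs)
  aln_cache <- new.env(parent = emptyenv())
  for (u in uniq) {
    if (u == seed) {
      assign(u, list(res = strsplit(u, "", fixed = TRUE)[[1]],
                     ins = list()), envir = aln_cache)
      next
    }
    pa <- align_global(u, seed)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    res <- character(L)
    ins <- list()
    g <- 0L
    buf <- character(0)
    for (col in seq_along(s)) {
      if (s[col] == "-") {
        buf <- c(buf, p[col])
      } else {
        if (length(buf) > 0L) {
          ins[[as.character(g)]] <- paste(buf, collapse = "")
          buf <- character(0)
        }
        g <- g + 1L
        res[g] <- p[col]
      }
    }
    if (length(buf) > 0L) ins[[as.character(g)]] <- paste(buf, collapse = "")
    assign(u, list(res = res, ins = ins), envir = aln_cache)
  }
  for (i in seq_len(n)) per[[i]] <- get(seqs[i], envir = aln_cache)

  # width of each insertion slot 0..L
  slot_w <- integer(L + 1L)
  for (p in per) for (g in names(p$ins))
    slot_w[as.integer(g) + 1L] <- max(slot_w[as.integer(g) + 1L],
                                      nchar(p$ins[[g]]))
  ncol_out <- L + sum(slot_w)
  m <- matrix("-", nrow = n, ncol = ncol_out)
  for (i in seq_len(n)) {
    row <- character(0)
    p <- per[[i]]
    for (g in 0:L) {
      if (slot_w[g + 1L] > 0L) {
        insstr <- if (!is.null(p$ins[[as.character(g)]]))
          p$ins[[as.character(g)]] else ""
        row <- c(row, strsplit(formatC(insstr, width = slot_w[g + 1L],
                                       flag = "-"), "")[[1]])
      }
      if (g < L) row <- c(row, p$res[g + 1L])
    }
    row[row == " "] <- "-"
    m[i, ] <- row
  }
  rownames(m) <- ids
  structure(list(matrix = m, ids = ids, seed = seed),
            class = "aton_alignment")
}

#' Majority-rule consensus of a family alignment
#'
#' Per-column strict majority base over `A,C,G,T`; columns where gaps are
#' the majority are dropped; ties among bases are broken by the fixed
#' order A < C < G < T.
#'
#' @param aln an `aton_alignment` from [align_family()].
#' @return character scalar consensus sequence.
#' @export
build_consensus <- function(aln) {
  m <- aln$matrix
  stopifnot(ncol(m) > 0L)
  cons <- apply(m, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return(NA_character_)
    tab <- table(factor(col[col %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0L) return(NA_character_)
    names(tab)[which.max(tab)]        # which.max takes the first: A<C<G<T
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Divergence of a copy from its family consensus
#'
#' 100 minus the percent identity (matches / alignment columns) of the
#' best global alignment (match 1 / mismatch -1 / gap -2), rounded to two
#' decimals — the complement-of-similarity age proxy.
#'
#' @param copy,consensus DNA sequences.
#' @return numeric percent in `[0, 100]`.
#' @export
divergence <- function(copy, consensus) {
  stopifnot(nchar(copy) > 0L, nchar(consensus) > 0L)
  if (copy == consensus) return(0)
  pa <- align_global(copy, consensus)
  round(100 - aln_identity(pa), 2)
}

#' Divergence profile of a family
#'
#' Per-copy divergence from the consensus plus a histogram in 1%-wide
#' bins (binning by floor to integer percent).
#'
#' @param seqs character vector of copy sequences.
#' @param consensus consensus sequence (default: built from the star
#'   alignment of `seqs`).
#' @param ids optional copy ids.
#' @return list of class `divergence_profile`: `divergence` (named
#'   numeric), `bins` (integer bin left edges), `counts`.
#' @export
divergence_profile <- function(seqs, consensus = NULL, ids = NULL) {
  if (is.null(consensus))
    consensus <- build_consensus(align_family(seqs, ids))
  if (is.null(ids)) ids <- paste0("copy", seq_along(seqs))
  d <- vapply(seqs, divergence, numeric(1), consensus = consensus,
              USE.NAMES = FALSE)
  names(d) <- ids
  b <- floor(d)
  bins <- 0:max(b, 0)
  counts <- vapply(bins, function(x) sum(b == x), integer(1))
  structure(list(divergence = d, bins = bins, counts = counts),
            class = "divergence_profile")
}

#' Neighbor-joining family tree with bootstrap and subclades
#'
#' NJ on p-distances (pairwise deletion) with site-resampling bootstrap.
#' Subclades are the maximal clades all of whose internal edges (within
#' the clade) are at most `eps` substitutions/site — the identical-copy
#' clades that mark a recent expansion. The tree is arbitrarily rooted at
#' the NJ root trifurcation for clade extraction.
#'
#' @param aln an `aton_alignment` (>= 4 copies).
#' @param n_bootstrap bootstrap replicates (default 100; configurable to
#'   1000).
#' @param seed RNG seed for resampling.
#' @param eps branch-length threshold for identical-copy subclades.
#' @return list of class `family_tree`: `tree` (ape `phylo`), `newick`,
#'   `support` (0-100 per internal node), `subclade` (named integer per
#'   leaf).
#' @export
build_tree <- function(aln, n_bootstrap = 100L, seed = 1L, eps = 1e-6) {
  m <- aln$matrix
  if (nrow(m) < 4L) stop("build_tree needs >= 4 copies")
  xm <- tolower(m)
  bin <- ape::as.DNAbin(xm)
  dfun <- function(x) ape::nj(ape::dist.dna(x, model = "raw",
                                            pairwise.deletion = TRUE))
  tree <- dfun(bin)
  support <- NULL
  if (n_bootstrap > 0L) {
    set.seed(seed)
    support <- suppressWarnings(
      ape::boot.phylo(tree, bin, FUN = dfun, B = n_bootstrap, quiet = TRUE))
    support <- round(100 * support / n_bootstrap)
  }
  sub <- subclades_by_length(tree, eps)
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 support = support, subclade = sub),
            class = "family_tree")
}

# Identical-copy subclades: leaves whose tree-path (cophenetic) distance
# is <= eps, merged by single linkage. NJ attaches diverged copies at
# arbitrary points along zero-length backbones, so clade membership of a
# zero-divergence group is not stable; path-length grouping is, and
# collapses exactly the clades whose internal branches are all ~0.
subclades_by_length <- function(tree, eps) {
  nt <- length(tree$tip.label)
  D <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  ids <- stats::cutree(hc, h = eps)[tree$tip.label]
  ids <- match(ids, unique(ids))      # renumber in leaf order, deterministic
  names(ids) <- tree$tip.label
  ids
}

#' Screen ESTs for element co-transcription
#'
#' Local alignment of a family consensus against each EST (both strands),
#' keeping hits longer than `min_hit_len` bp, above `min_identity`
#' percent identity, and with a Karlin-Altschul E-value at most
#' `max_evalue` (ungapped nucleotide parameters for match +1 / mismatch
#' -1: lambda = 1.33, K = 0.621, database size = total EST bases). One
#' hit is counted per EST (its best orientation).
#'
#' @param consensus family consensus sequence.
#' @param ests named character vector of EST sequences, or a
#'   [genome_store()].
#' @param min_hit_len minimum alignment length (bp), exclusive bound.
#' @param max_evalue E-value threshold (inclusive).
#' @param min_identity percent-identity threshold, exclusive bound.
#' @return data.frame of significant hits (`est_id`, `length`,
#'   `identity`, `score`, `evalue`, `strand`) with attribute `n_ests`.
#' @export
search_ests <- function(consensus, ests, min_hit_len = 60L,
                        max_evalue = 1e-6, min_identity = 70) {
  if (inherits(ests, "genome_store")) ests <- ests$contigs
  if (length(ests) == 0L) stop("empty EST set")
  if (is.null(names(ests))) names(ests) <- paste0("est", seq_along(ests))
  lambda <- 1.33; K <- 0.621
  m <- nchar(consensus)
  n_db <- sum(nchar(ests))
  hit_one <- function(orient_seqs, strand) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(orient_seqs), consensus, type = "local",
      substitutionMatrix = sub_mat(), gapOpening = 0, gapExtension = 2)
    data.frame(est_id = names(ests),
               length = Biostrings::nchar(pa),
               identity = 100 * Biostrings::nmatch(pa) /
                 pmax(Biostrings::nchar(pa), 1L),
               score = Biostrings::score(pa),
               strand = strand, stringsAsFactors = FALSE)
  }
  fw <- hit_one(ests, "+")
  rv <- hit_one(revcomp(ests), "-")
  best <- ifelse(fw$score >= rv$score, seq_len(nrow(fw)),
                 nrow(fw) + seq_len(nrow(rv)))
  df <- rbind(fw, rv)[best, , drop = FALSE]
  df$evalue <- K * m * n_db * exp(-lambda * df$score)
  keep <- df$length > min_hit_len & df$identity > min_identity &
    df$evalue <= max_evalue
  out <- df[keep, , drop = FALSE]
  out$identity <- round(out$identity, 2)
  rownames(out) <- NULL
  attr(out, "n_ests") <- length(ests)
  out
}
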