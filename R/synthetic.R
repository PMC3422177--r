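#' Synthetic genomes with planted AT-insertion transposon families
#'
#' The generator plants TIR-bearing element families at "AT" dinucleotides
#' of an i.i.d. background genome, emits orthologous empty alleles (related
#' empty sites, RES) for a configurable fraction of insertions, rare
#' aberrant empty sites drawn from a four-type edit grammar, and an EST set
#' in which a fraction of sequences co-transcribe an element with its
#' flanks. Every planted feature is recorded in truth tables so each
#' analysis stage can be scored against known ground truth.
#'
#' @name synthetic
NULL

rand_bases <- function(n, gc = 0.38) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
}

rand_seq <- function(n, gc = 0.38) paste(rand_bases(n, gc), collapse = "")

#' Build a random TIR element with the canonical AT-insertion grammar
#'
#' The element starts with `T`, ends with `A`, and carries an exact
#' terminal inverted repeat of exactly `tir_len` bp (the base following
#' the TIR is forced to break any accidental extension).
#'
#' @param length element length in bp (>= 2*tir_len + 2).
#' @param tir_len terminal inverted repeat length in bp.
#' @param gc background GC content for the internal sequence.
#' @return character scalar element sequence.
#' @export
make_element <- function(length, tir_len, gc = 0.38) {
  if (length < 2 * tir_len + 2) stop("element too short for its TIR")
  s <- rand_bases(length, gc)
  s[1] <- "T"
  s[seq(length - tir_len + 1L, length)] <-
    rev(chartr("ACGT", "TGCA", s[seq_len(tir_len)]))
  # forbid accidental TIR extension beyond tir_len
  partner <- s[length - tir_len]          # pairs with position tir_len + 1
  bad <- chartr("ACGT", "TGCA", partner)
  if (s[tir_len + 1L] == bad)
    s[tir_len + 1L] <- sample(setdiff(c("A", "C", "G", "T"), bad), 1L)
  paste(s, collapse = "")
}

#' Mutate an element copy by i.i.d. per-base substitution
#'
#' Each base is substituted independently with probability `rate` to one of
#' the three other bases (uniformly). TIR bases are as mutable as any other.
#'
#' @param element character scalar DNA sequence.
#' @param rate substitution probability per base, in `[0, 1)`.
#' @return list with `seq` (mutated copy) and `nsub` (realized substitution
#'   count).
#' @export
mutate_copy <- function(element, rate) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  s <- strsplit(element, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  list(seq = paste(s, collapse = ""), nsub = length(hit))
}

#' Simulation specification
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: a 2 Mb background genome over 4 contigs at 38% GC, three
#' planted families with copy numbers 150/80/12, per-copy divergence
#' classes {0, 1%, 5%} allocated deterministically by family-specific
#' weights, an empty-allele (RES) fraction of 0.5, an aberrant-RES rate of
#' 0.5% over four junction edit types, and 100 ESTs of 500 bp of which 10%
#' co-transcribe a planted element.
#'
#' @param genome_length total background length in bp.
#' @param n_contigs number of background contigs.
#' @param gc background GC content.
#' @param families list of per-family specs: `name`, `length`, `tir_len`,
#'   `n_copies`, `div_classes` (named numeric, names = substitution rates,
#'   values = class weights summing to 1), optional `element` sequence.
#' @param empty_frac fraction of insertions that also emit an orthologous
#'   empty allele on the RES-bank contig.
#' @param aberrant_rate fraction of emitted empty alleles carrying an
#'   aberrant (type I-IV) junction.
#' @param aberrant_types weights over the four aberrant types.
#' @param res_context flanking context length (bp each side) copied into an
#'   empty allele.
#' @param est_n,est_len number and length of ESTs.
#' @param est_cotx_frac fraction of ESTs that co-transcribe an element.
#' @param decoy_n,decoy_length number/length of TIR-less decoy repeats
#'   planted to probe scanner specificity (default none).
#' @param seed RNG seed; `sim_genome` is deterministic given the spec.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(genome_length = 2e6,
                     n_contigs = 4,
                     gc = 0.38,
                     families = list(
                       list(name = "famA", length = 112L, tir_len = 15L,
                            n_copies = 150L,
                            div_classes = c("0" = 0.50, "0.01" = 0.40,
                                            "0.05" = 0.10)),
                       list(name = "famB", length = 144L, tir_len = 17L,
                            n_copies = 80L,
                            div_classes = c("0" = 0.25, "0.01" = 0.55,
                                            "0.05" = 0.20)),
                       list(name = "famC", length = 200L, tir_len = 12L,
                            n_copies = 12L,
                            div_classes = c("0" = 0.80, "0.01" = 0.10,
                                            "0.05" = 0.10))),
                     empty_frac = 0.5,
                     aberrant_rate = 0.005,
                     aberrant_types = c(typeI = 0.25, typeII = 0.25,
                                        typeIII = 0.25, typeIV = 0.25),
                     res_context = 150L,
                     est_n = 100L,
                     est_len = 500L,
                     est_cotx_frac = 0.10,
                     decoy_n = 0L,
                     decoy_length = 300L,
                     seed = 1L) {
  rates <- lapply(families, function(f) as.numeric(names(f$div_classes)))
  if (any(unlist(rates) < 0 | unlist(rates) >= 1))
    stop("divergence class rates must be in [0, 1)")
  if (empty_frac < 0 || empty_frac > 1 || aberrant_rate < 0 || aberrant_rate > 1)
    stop("rates must be in [0, 1]")
  structure(as.list(environment()), class = "sim_spec")
}

# Deterministic allocation of n copies over weighted classes:
# counts are the rounded cumulative weights, so they always sum to n.
alloc_classes <- function(n, weights) {
  cw <- round(cumsum(weights) / sum(weights) * n)
  counts <- diff(c(0, cw))
  rep(as.numeric(names(weights)), counts)
}

# Apply one aberrant edit to a context string whose target "AT" occupies
# 1-based positions (ctx, ctx + 1). Returns the edited string.
aberrant_edit <- function(context, ctx, type, gc = 0.38) {
  left <- substr(context, 1L, ctx - 1L)          # ends just before target A
  right <- substr(context, ctx + 2L, nchar(context))
  a <- substr(context, ctx, ctx)
  t <- substr(context, ctx + 1L, ctx + 1L)
  switch(type,
    typeI = paste0(left, right),
    typeII = if (stats::runif(1) < 0.5) paste0(left, a, right)
             else paste0(left, t, right),
    typeIII = {
      k <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5)
        paste0(substr(left, 1L, nchar(left) - k), right)
      else
        paste0(left, substr(right, k + 1L, nchar(right)))
    },
    typeIV = paste0(left, a, rand_seq(sample(1:4, 1L), gc), t, right),
    stop("unknown aberrant type: ", type))
}

#' Generate a synthetic genome with planted element families
#'
#' Deterministic for a fixed spec (including its seed). Elements are
#' inserted between the `A` and the `T` of background "AT" dinucleotides,
#' so that every occupied site reads `...A [T...A] T...`. Empty alleles
#' copy the original background context around the target site onto a
#' dedicated RES-bank contig, separated by random spacers.
#'
#' @param spec a [sim_spec()].
#' @return list of class `aton_sim` with components `store`
#'   (genome_store incl. the `resbank` contig), `families` (named founder
#'   sequences), `copies` (truth data.frame: copy_id, family, contig,
#'   start, end, strand, class_rate, nsub, seq), `res` (truth data.frame:
#'   res_id, copy_id, family, type, contig, start, end), `ests` (named
#'   character), `est_truth` (data.frame), and `spec`.
#' @export
sim_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)

  founders <- vapply(spec$families, function(f) {
    if (!is.null(f$element)) f$element
    else make_element(f$length, f$tir_len, spec$gc)
  }, character(1))
  names(founders) <- vapply(spec$families, `[[`, character(1), "name")

  clen <- rep(floor(spec$genome_length / spec$n_contigs), spec$n_contigs)
  bg <- lapply(clen, function(n) rand_bases(n, spec$gc))
  names(bg) <- paste0("contig", seq_along(bg))

  total <- sum(vapply(spec$families, function(f)
    as.integer(f$n_copies), integer(1))) + spec$decoy_n
  margin <- spec$res_context + 60L
  min_sep <- max(c(0L, vapply(spec$families, function(f)
    as.integer(f$length), integer(1)))) + 2L * spec$res_context + 100L

  chosen <- data.frame(contig = character(0), pos = integer(0))
  if (total > 0L) {
  # candidate insertion sites: background "AT" dinucleotides (A at 1-based p)
  sites <- do.call(rbind, lapply(names(bg), function(cn) {
    v <- bg[[cn]]
    p <- which(v[-length(v)] == "A" & v[-1] == "T")
    p <- p[p > margin & p < length(v) - margin]
    if (length(p) == 0L) return(NULL)
    data.frame(contig = cn, pos = p)
  }))
  if (is.null(sites) || nrow(sites) < total)
    stop("genome too short for requested copies")
  sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
  chosen <- vector("list", total)
  taken <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    if (k == total) break
    cn <- sites$contig[i]; p <- sites$pos[i]
    tk <- taken[[cn]]
    if (is.null(tk) || all(abs(tk - p) >= min_sep)) {
      k <- k + 1L
      chosen[[k]] <- sites[i, ]
      taken[[cn]] <- c(tk, p)
    }
  }
  if (k < total) stop("genome too short for requested copies")
  chosen <- do.call(rbind, chosen)
  }

  # assign copies to sites
  fam_ids <- as.character(unlist(lapply(spec$families, function(f)
    rep(f$name, f$n_copies))))
  rates <- as.numeric(unlist(lapply(spec$families, function(f)
    alloc_classes(f$n_copies, f$div_classes))))
  if (spec$decoy_n > 0L) {
    fam_ids <- c(fam_ids, rep("decoy", spec$decoy_n))
    rates <- c(rates, rep(0, spec$decoy_n))
  }
  ord <- sample.int(length(fam_ids))
  fam_ids <- fam_ids[ord]; rates <- rates[ord]

  decoy_seq <- if (spec$decoy_n > 0L) rand_seq(spec$decoy_length, spec$gc)
               else NULL

  copies <- data.frame(copy_id = sprintf("cp%03d", seq_len(total)),
                       family = fam_ids,
                       contig = chosen$contig, pos = chosen$pos,
                       class_rate = rates,
                       nsub = rep(NA_integer_, total),
                       seq = rep(NA_character_, total),
                       stringsAsFactors = FALSE)
  for (i in seq_len(total)) {
    base <- if (copies$family[i] == "decoy") decoy_seq
            else founders[[copies$family[i]]]
    m <- mutate_copy(base, copies$class_rate[i])
    copies$seq[i] <- m$seq
    copies$nsub[i] <- m$nsub
  }

  # emit empty alleles from the pre-insertion background
  ctx <- spec$res_context
  res_rows <- list(); res_pieces <- list(); nres <- 0L
  for (i in seq_len(total)) {
    if (copies$family[i] == "decoy") next
    if (stats::runif(1) >= spec$empty_frac) next
    nres <- nres + 1L
    v <- bg[[copies$contig[i]]]
    p <- copies$pos[i]
    context <- paste(v[(p - ctx + 1L):(p + ctx)], collapse = "")
    type <- "intact_AT"
    if (stats::runif(1) < spec$aberrant_rate) {
      type <- sample(names(spec$aberrant_types), 1L,
                     prob = spec$aberrant_types)
      context <- aberrant_edit(context, ctx, type, spec$gc)
    }
    res_rows[[nres]] <- data.frame(res_id = sprintf("res%03d", nres),
                                   copy_id = copies$copy_id[i],
                                   family = copies$family[i],
                                   type = type, len = nchar(context),
                                   stringsAsFactors = FALSE)
    res_pieces[[nres]] <- context
  }

  # splice elements into the background, tracking final coordinates
  contigs <- character(length(bg)); names(contigs) <- names(bg)
  copies$start <- rep(NA_integer_, total)
  copies$end <- rep(NA_integer_, total)
  for (cn in names(bg)) {
    idx <- which(copies$contig == cn)
    idx <- idx[order(copies$pos[idx])]
    v <- bg[[cn]]
    pieces <- character(0)
    last <- 0L; offset <- 0L
    for (i in idx) {
      p <- copies$pos[i]
      pieces <- c(pieces, paste(v[(last + 1L):p], collapse = ""),
                  copies$seq[i])
      copies$start[i] <- p + offset            # 0-based: element begins after A
      copies$end[i] <- copies$start[i] + nchar(copies$seq[i])
      offset <- offset + nchar(copies$seq[i])
      last <- p
    }
    pieces <- c(pieces, paste(v[(last + 1L):length(v)], collapse = ""))
    contigs[[cn]] <- paste(pieces, collapse = "")
  }

  # RES bank contig with random spacers
  res <- NULL
  if (nres > 0L) {
    res <- do.call(rbind, res_rows)
    spacers <- vapply(seq_len(nres + 1L), function(i) rand_seq(60L, spec$gc),
                      character(1))
    at <- cumsum(nchar(spacers[seq_len(nres)]) +
                 c(0L, res$len[-nres]))          # 0-based starts
    res$contig <- "resbank"
    res$start <- at
    res$end <- at + res$len
    bank <- paste0(paste0(spacers[seq_len(nres)], unlist(res_pieces),
                          collapse = ""), spacers[nres + 1L])
    contigs <- c(contigs, resbank = bank)
    res$len <- NULL
  }

  store <- genome_store(contigs)

  # ESTs: background-random, a fraction co-transcribing element + flanks
  ests <- NULL; est_truth <- NULL
  if (spec$est_n > 0L) {
    ests <- vapply(seq_len(spec$est_n), function(i)
      rand_seq(spec$est_len, spec$gc), character(1))
    names(ests) <- sprintf("est%03d", seq_len(spec$est_n))
    ncot <- round(spec$est_cotx_frac * spec$est_n)
    est_truth <- data.frame(est_id = names(ests),
                            copy_id = NA_character_,
                            family = NA_character_,
                            stringsAsFactors = FALSE)
    real <- which(copies$family != "decoy")
    if (ncot > 0L && length(real) > 0L) {
      pick <- sample(real, ncot, replace = ncot > length(real))
      for (j in seq_len(ncot)) {
        i <- pick[j]
        ins <- gs_slice(store, copies$contig[i],
                        copies$start[i] - 30L, copies$end[i] + 30L)
        pre_n <- max(0L, sample.int(spec$est_len - nchar(ins), 1L) - 1L)
        est <- paste0(rand_seq(pre_n, spec$gc), ins,
                      rand_seq(spec$est_len, spec$gc))
        ests[[j]] <- substr(est, 1L, spec$est_len)
        est_truth$copy_id[j] <- copies$copy_id[i]
        est_truth$family[j] <- copies$family[i]
      }
    }
  }

  copies$strand <- rep("+", total)
  copies$pos <- NULL
  structure(list(store = store, families = founders,
                 copies = copies[, c("copy_id", "family", "contig", "start",
                                     "end", "strand", "class_rate", "nsub",
                                     "seq")],
                 res = res, ests = ests, est_truth = est_truth, spec = spec),
            class = "aton_sim")
}

#' Generate junctions from the aberrant-empty-site edit grammar
#'
#' Produces flank pairs and the corresponding (possibly edited) empty-site
#' sequence for exercising the target-site classifier: intact sites carry
#' exactly "AT" between the flank cores; the four aberrant types delete the
#' target, delete one target base, delete into the flanks, or insert extra
#' bases between "A" and "T".
#'
#' @param n number of junctions.
#' @param types character vector (recycled over `n`) of
#'   `intact_AT`, `typeI`..`typeIV`, or `NULL` to draw uniformly over the
#'   four aberrant types.
#' @param flank_len flank length (bp).
#' @param gc background GC content.
#' @return data.frame with `left_flank`, `right_flank` (as seen at an
#'   occupied locus: left ends in the target `A`, right starts with the
#'   target `T`), `res_seq` (the empty-site sequence) and `true_type`.
#' @export
sim_junctions <- function(n, types = NULL, flank_len = 50L, gc = 0.38) {
  if (is.null(types))
    types <- sample(c("typeI", "typeII", "typeIII", "typeIV"), n,
                    replace = TRUE)
  types <- rep_len(types, n)
  out <- data.frame(left_flank = character(n), right_flank = character(n),
                    res_seq = character(n), true_type = types,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lf <- paste0(rand_seq(flank_len - 1L, gc), "A")
    rf <- paste0("T", rand_seq(flank_len - 1L, gc))
    context <- paste0(lf, rf)                  # intact empty allele
    res <- if (types[i] == "intact_AT") context
           else aberrant_edit(context, flank_len, types[i], gc)
    out$left_flank[i] <- lf
    out$right_flank[i] <- rf
    out$res_seq[i] <- res
  }
  out
}

#' Plant element copies with restriction-site-bearing flanks
#'
#' Builds a compact genome for in-silico transposon display: each copy's
#' 3' flank carries a BfaI-type recognition site at a uniform-random
#' distance from the element junction, with an i.i.d. uniform base
#' immediately 5' of the site (the base the selective primer reads).
#'
#' @param n_copies number of planted copies.
#' @param element element sequence (default: a fresh 112 bp TIR-15 element).
#' @param enzyme_site recognition sequence (default BfaI, `CTAG`).
#' @param frag_range inclusive range of junction-to-site distances (bp).
#' @param flank_len total flank length beyond the site.
#' @return list with `store` (one contig per copy) and `copies`
#'   (data.frame usable with [simulate_td()]).
#' @export
sim_td_copies <- function(n_copies, element = NULL, enzyme_site = "CTAG",
                          frag_range = c(50L, 950L), flank_len = 100L) {
  if (is.null(element)) element <- make_element(112L, 15L)
  contigs <- character(n_copies)
  starts <- integer(n_copies)
  for (i in seq_len(n_copies)) {
    d <- sample(frag_range[1]:frag_range[2], 1L)
    sel <- sample(c("A", "C", "G", "T"), 1L)
    # [left pad][A][element][T ... d-2 random ...][sel][site][tail]
    right <- paste0("T", rand_seq(d - 2L, 0.5), sel, enzyme_site,
                    rand_seq(flank_len, 0.5))
    right <- gsub(enzyme_site, "GGGG", right, fixed = TRUE) # keep 1st site = planted
    right <- paste0(substr(right, 1L, d), enzyme_site,
                    rand_seq(flank_len, 0.5))
    contigs[i] <- paste0(rand_seq(60L, 0.5), "A", element, right)
    starts[i] <- 61L
  }
  names(contigs) <- sprintf("td%03d", seq_len(n_copies))
  store <- genome_store(contigs)
  copies <- data.frame(copy_id = names(contigs), family = "td",
                       contig = names(contigs), start = starts,
                       end = starts + nchar(element), strand = "+",
                       stringsAsFactors = FALSE)
  list(store = store, copies = copies)
}

#' Write a simulated data set to a directory
#'
#' Emits `genome.fa`, `families.fa`, `copies.bed` (truth), `res.tsv`,
#' `ests.fa` into `dir`.
#'
#' @param sim an `aton_sim` from [sim_genome()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "aton_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$store, file.path(dir, "genome.fa"))
  write_fasta(sim$families, file.path(dir, "families.fa"))
  write_bed(sim$copies, file.path(dir, "copies.bed"))
  if (!is.null(sim$res))
    utils::write.table(sim$res, file.path(dir, "res.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$ests)) write_fasta(sim$ests, file.path(dir, "ests.fa"))
  invisible(dir)
}
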