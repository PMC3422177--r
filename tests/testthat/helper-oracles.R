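# Independent brute-force oracles, deliberately naive: they enumerate or
# scan exhaustively and share no code path with the package internals.

oracle_revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(seq, "")[[1]]])), collapse = "")
}

# exhaustive scan over all prefix lengths; returns longest L with mismatch
# fraction <= frac (N never matches), or 0 below min_len
oracle_tir_len <- function(seq, min_len = 10, frac = 0) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  best <- 0
  for (L in min_len:(n %/% 2)) {
    pre <- s[1:L]
    suf <- s[(n - L + 1):n]
    suf_rc <- rev(unname(c(A = "T", C = "G", G = "C", T = "A",
                           N = "N")[suf]))
    mm <- sum(pre != suf_rc | pre == "N" | suf_rc == "N")
    if (mm <= frac * L) best <- L
  }
  best
}

# ungapped sliding-window search: all (contig, 0-based start, strand) where
# the query matches with >= min_identity percent identity
oracle_map_positions <- function(contigs, query, min_identity = 90) {
  hits <- list()
  qn <- nchar(query)
  for (cn in names(contigs)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else oracle_revcomp(query)
      qv <- strsplit(q, "")[[1]]
      cv <- strsplit(contigs[[cn]], "")[[1]]
      if (length(cv) < qn) next
      for (p in 1:(length(cv) - qn + 1)) {
        idt <- 100 * sum(qv == cv[p:(p + qn - 1)]) / qn
        if (idt >= min_identity)
          hits[[length(hits) + 1]] <- data.frame(
            contig = cn, start = p - 1, strand = strand, identity = idt)
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# all (i, j) element intervals obeying the AT grammar with an exact TIR
oracle_scan <- function(contigs, min_len, max_len, min_tir) {
  out <- list()
  for (cn in names(contigs)) {
    v <- strsplit(contigs[[cn]], "")[[1]]
    n <- length(v)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (s in 2:(n - 1)) {                # 1-based first element base
      if (!(v[s - 1] == "A" && v[s] == "T")) next
      for (e in s:(min(n - 1, s + max_len - 1))) {
        len <- e - s + 1
        if (len < min_len || len > max_len) next
        if (!(v[e] == "A" && v[e + 1] == "T")) next
        ok <- TRUE
        for (k in 0:(min_tir - 1)) {
          if (v[s + k] == "N" ||
              v[s + k] != unname(comp[v[e - k]])) { ok <- FALSE; break }
        }
        if (ok) out[[length(out) + 1]] <-
          data.frame(contig = cn, start = s - 1, end = e)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# all fragments starting with term and ending with revcomp(term)
oracle_fragments <- function(contigs, term, min_len, max_len) {
  out <- list()
  tl <- nchar(term)
  rc <- oracle_revcomp(term)
  for (cn in names(contigs)) {
    seq <- contigs[[cn]]
    n <- nchar(seq)
    for (s in 1:(n - tl + 1)) {
      if (substr(seq, s, s + tl - 1) != term) next
      for (e in s:(n - tl + 1)) {
        end <- e + tl - 1
        len <- end - s + 1
        if (len < min_len || len > max_len || e <= s) next
        if (substr(seq, e, end) == rc)
          out[[length(out) + 1]] <-
            data.frame(contig = cn, start = s - 1, end = end)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# exhaustive stem-loop enumeration: is any exact stem >= min_stem with
# loop in [3, max_loop] present in the window?
oracle_hairpin_present <- function(w, min_stem, max_loop) {
  v <- strsplit(w, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in 1:n) for (s in min_stem:n) for (loop in 3:max_loop) {
    j <- i + s + loop
    if (j + s - 1 > n) next
    arm1 <- v[i:(i + s - 1)]
    arm2 <- v[j:(j + s - 1)]
    if (all(arm1 != "N" & arm2 != "N" &
            arm1 == rev(unname(comp[arm2])))) return(TRUE)
  }
  FALSE
}

# fixture path helper
screen_fixture <- function() {
  system.file("extdata", "identical_copy_screen.tsv", package = "atonscan")
}
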