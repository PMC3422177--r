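plant <- function(bg, inserts, at) {
  # insert strings at 1-based background offsets (after position at[i])
  stopifnot(!is.unsorted(at))
  out <- ""
  last <- 0
  starts <- integer(length(at))
  off <- 0
  for (i in seq_along(at)) {
    out <- paste0(out, substr(bg, last + 1, at[i]), inserts[i])
    starts[i] <- at[i] + off             # 0-based start of insert i
    off <- off + nchar(inserts[i])
    last <- at[i]
  }
  list(seq = paste0(out, substr(bg, last + 1, nchar(bg))), starts = starts)
}

test_that("map_copies finds verbatim planted copies as complete, identity 100", {
  set.seed(101)
  q <- make_element(112, 15)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  pl <- plant(bg, c(q, q, q), c(200, 500, 800))
  st <- genome_store(c(c1 = pl$seq))
  cp <- map_copies(st, q, family = "f")
  expect_equal(nrow(cp), 3)
  expect_equal(cp$start, pl$starts)
  expect_true(all(cp$identity == 100))
  expect_true(all(cp$complete))
  expect_true(all(cp$seq == q))
})

test_that("internal substitutions lower identity by the constructed amount", {
  set.seed(102)
  q <- make_element(112, 15)
  qm <- q
  for (p in c(40, 55, 70, 85))
    substr(qm, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(q, p, p))[1]
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  pl <- plant(bg, qm, 400)
  st <- genome_store(c(c1 = pl$seq))
  cp <- map_copies(st, q, family = "f")
  expect_equal(nrow(cp), 1)
  expect_equal(cp$identity, round(100 * 108 / 112, 2))   # 96.43
  expect_true(cp$complete)
})

test_that("a copy missing its first 20 bp is reported but not complete", {
  set.seed(103)
  q <- make_element(112, 15)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  pl <- plant(bg, substr(q, 21, 112), 400)
  st <- genome_store(c(c1 = pl$seq))
  cp <- map_copies(st, q, family = "f", min_coverage = 70,
                   end_tolerance = 2)
  expect_equal(nrow(cp), 1)
  expect_false(cp$complete)
})

test_that("map_copies agrees with the exhaustive sliding-window oracle", {
  set.seed(104)
  q <- make_element(100, 12)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  # planted: verbatim, 5% substituted, reverse complement
  qm <- mutate_copy(q, 0.05)$seq
  pl <- plant(bg, c(qm, q, revcomp(q)), c(800, 2000, 3200))
  contigs <- c(g = pl$seq)
  st <- genome_store(contigs)
  cp <- map_copies(st, q, family = "f")
  orc <- oracle_map_positions(contigs, q, 90)
  expect_equal(sort(cp$start), sort(orc$start))
  expect_equal(nrow(cp), 3)
})

test_that("group_identical partitions by sequence and collapses shared-flank duplicates", {
  set.seed(105)
  mk <- function(seq, lf, rf, contig = "c", start = 0)
    data.frame(copy_id = NA, family = "f", contig = contig,
               start = start, end = start + nchar(seq), strand = "+",
               identity = 100, coverage = 100, complete = TRUE, seq = seq,
               left_flank = lf, right_flank = rf,
               stringsAsFactors = FALSE)
  rs <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  e1 <- rs(80); e2 <- rs(80); e3 <- rs(80)
  copies <- rbind(mk(e1, rs(50), rs(50), start = 0),
                  mk(e1, rs(50), rs(50), start = 200),
                  mk(e1, rs(50), rs(50), start = 400),
                  mk(e2, rs(50), rs(50), start = 600),
                  mk(e3, rs(50), rs(50), start = 800))
  g <- group_identical(copies)
  expect_equal(sort(sapply(g, `[[`, "size"), decreasing = TRUE), c(3, 1, 1))

  # byte-identical flanks on different contigs: one member after collapse
  lf <- rs(50); rf <- rs(50)
  dup <- rbind(mk(e1, lf, rf, contig = "c1"), mk(e1, lf, rf, contig = "c2"))
  g2 <- group_identical(dup)
  expect_equal(length(g2), 1)
  expect_equal(g2[[1]]$size, 1)

  expect_identical(group_identical(copies[0, ]), list())
})

test_that("identical-group sizes are invariant to contig order and reverse complement", {
  set.seed(106)
  q <- make_element(90, 12)
  bg1 <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  p1 <- plant(bg1, c(q, q), c(300, 900))
  p2 <- plant(bg2, q, 700)
  sizes_of <- function(contigs) {
    cp <- map_copies(genome_store(contigs), q, family = "f")
    sort(sapply(group_identical(cp), `[[`, "size"))
  }
  a <- sizes_of(c(c1 = p1$seq, c2 = p2$seq))
  b <- sizes_of(c(c2 = p2$seq, c1 = p1$seq))
  d <- sizes_of(c(c1 = revcomp(p1$seq), c2 = p2$seq))
  expect_identical(a, b)
  expect_identical(a, d)
})

test_that("rank_families reproduces the published identical-copy screen counts", {
  reports <- read_family_table(screen_fixture())
  tab <- rank_families(reports, min_group_size = 10)
  expect_equal(attr(tab, "n_groups"), 24)
  expect_equal(attr(tab, "n_families"), 12)

  retro <- rank_families(reports, 10, te_type_filter = "tSINE")
  expect_equal(attr(retro, "n_groups"), 8)
  expect_equal(attr(retro, "n_families"), 3)

  dna <- rank_families(reports, 10, te_type_filter = "MITE|ATon")
  expect_equal(attr(dna, "n_groups"), 16)
  expect_equal(attr(dna, "n_families"), 9)

  expect_equal(nrow(rank_families(reports, min_group_size = 1000)), 0)
})

test_that("family_report labels groups a, b, c ... by descending size", {
  r <- family_report("f", 300, c(17, 146, 61), te_type = "ATon-I")
  expect_identical(r$group_sizes, c(146L, 61L, 17L))
  expect_identical(r$group_labels, c("a", "b", "c"))
})
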