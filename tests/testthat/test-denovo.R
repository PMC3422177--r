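rsd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                         collapse = "")

test_that("scan_candidates finds a planted element at its exact interval", {
  set.seed(401)
  elem <- make_element(112, 15)
  bg <- rsd(2000)
  # force an insertion site: A|elem|T at a known position
  g <- paste0(substr(bg, 1, 700), "A", elem, "T", substr(bg, 701, 2000))
  st <- genome_store(c(c1 = g))
  cand <- scan_candidates(st, min_len = 50, max_len = 1000, min_tir = 10)
  hit <- cand[cand$start == 701 & cand$end == 701 + 112, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$tir_len, 15)
})

test_that("a dinucleotide-repeat genome yields no candidates", {
  st <- genome_store(c(c1 = strrep("AC", 300)))
  expect_equal(nrow(scan_candidates(st)), 0)
})

test_that("scan_candidates equals brute-force enumeration on small genomes", {
  set.seed(402)
  for (i in 1:3) {
    contigs <- c(g = rsd(3000))
    # plant one real element so the comparison is not vacuously empty
    elem <- make_element(80, 12)
    contigs[["g"]] <- paste0(substr(contigs[["g"]], 1, 1500), "A", elem, "T",
                             substr(contigs[["g"]], 1501, 3000))
    st <- genome_store(contigs)
    got <- scan_candidates(st, min_len = 50, max_len = 500, min_tir = 8,
                           dedupe = FALSE)
    want <- oracle_scan(list(g = contigs[["g"]]), 50, 500, 8)
    key <- function(d) sort(paste(d$start, d$end))
    if (is.null(want)) expect_equal(nrow(got), 0)
    else expect_identical(key(got), key(want))
  }
})

test_that("scan output mirrors exactly under contig reverse complement", {
  set.seed(403)
  elem <- make_element(90, 12)
  g <- paste0(rsd(800), "A", elem, "T", rsd(800))
  st <- genome_store(c(c = g))
  str <- genome_store(c(c = revcomp(g)))
  a <- scan_candidates(st, min_tir = 10)
  b <- scan_candidates(str, min_tir = 10)
  n <- nchar(g)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(n - a$end, n - a$start), paste(b$start, b$end))
  expect_identical(sort(a$tir_len), sort(b$tir_len))
})

test_that("cluster_candidates promotes only clusters reaching min_copies", {
  set.seed(404)
  ex <- make_element(112, 15)
  ey <- make_element(144, 17)
  bg <- rsd(60000)
  at <- sort(sample(seq(500, 59000, by = 450), 16))
  pieces <- character(0); last <- 0
  for (i in seq_along(at)) {
    e <- if (i <= 12) ex else ey
    pieces <- c(pieces, substr(bg, last + 1, at[i]), paste0("A", e, "T"))
    last <- at[i]
  }
  g <- paste0(paste(pieces, collapse = ""), substr(bg, last + 1, nchar(bg)))
  st <- genome_store(c(c1 = g))
  cand <- scan_candidates(st)
  fams <- cluster_candidates(st, cand, min_copies = 10, confirm_res = FALSE)
  expect_equal(length(fams), 1)
  expect_gte(fams[[1]]$copy_number, 10)
  expect_equal(nchar(fams[[1]]$consensus), 112)
  expect_equal(fams[[1]]$tir$tir_len, 15)

  expect_equal(length(cluster_candidates(st, cand[0, ])), 0)
})

test_that("identical planted copies give a consensus equal to the founder", {
  set.seed(405)
  ex <- make_element(100, 12)
  aln <- align_family(rep(ex, 12))
  expect_identical(build_consensus(aln), ex)
})

test_that("find_flanked_fragments applies length bounds and matches enumeration", {
  set.seed(406)
  term <- "TAGGCCAATGC"                       # 11 bp > 10
  g1 <- paste0(rsd(100), term, rsd(978), revcomp(term), rsd(100))
  st1 <- genome_store(c(c = g1))
  fr1 <- find_flanked_fragments(st1, term, orf = FALSE)
  expect_equal(nrow(fr1), 1)
  expect_equal(fr1$length, 1000)

  g2 <- paste0(rsd(100), term, rsd(278), revcomp(term), rsd(100))
  st2 <- genome_store(c(c = g2))
  expect_equal(nrow(find_flanked_fragments(st2, term, orf = FALSE)), 0)

  # nested pairs: every in-bound (start, end) combination counts
  g3 <- paste0(rsd(50), term, rsd(200), term, rsd(400),
               revcomp(term), rsd(150), revcomp(term), rsd(50))
  st3 <- genome_store(c(c = g3))
  got <- find_flanked_fragments(st3, term, min_len = 300, max_len = 2000,
                                orf = FALSE)
  want <- oracle_fragments(list(c = g3), term, 300, 2000)
  expect_identical(paste(got$start, got$end),
                   paste(want$start, want$end))
})
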