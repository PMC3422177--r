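test_that("star alignment handles identical copies and single insertions", {
  set.seed(501)
  e <- make_element(80, 10)
  aln <- align_family(rep(e, 3))
  expect_equal(ncol(aln$matrix), 80)
  expect_false(any(aln$matrix == "-"))

  # one copy with a 2 bp insertion: exactly two gap columns for the others
  ei <- paste0(substr(e, 1, 40), "GG", substr(e, 41, 80))
  aln2 <- align_family(c(e, e, ei))
  expect_equal(ncol(aln2$matrix), 82)
  expect_equal(sum(aln2$matrix[1, ] == "-"), 2)
  expect_equal(sum(aln2$matrix[3, ] == "-"), 0)

  # column count is never below the longest copy
  expect_gte(ncol(aln2$matrix), max(nchar(c(e, ei))))
  expect_error(align_family(e), ">= 2")
})

test_that("consensus takes strict majority, drops gap columns, breaks ties A<C<G<T", {
  m <- matrix(c("A", "A", "A", "G",
                "A", "A", "G", "G",
                "-", "-", "-", "C"), nrow = 4)
  aln <- structure(list(matrix = m, ids = paste0("c", 1:4)),
                   class = "aton_alignment")
  # col1: A majority; col2: A/G tie -> A; col3: gap-majority -> dropped
  expect_identical(build_consensus(aln), "AA")
})

test_that("divergence is the complement of global-alignment identity", {
  set.seed(502)
  e <- make_element(112, 15)
  expect_equal(divergence(e, e), 0)
  em <- e
  substr(em, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(e, 50, 50))[1]
  expect_equal(divergence(em, e), round(100 * 1 / 112, 2))
})

test_that("divergence histogram modes sit at the planted rate classes", {
  set.seed(503)
  e <- make_element(100, 12)   # 100 bp: divergence bins align with counts
  seqs <- c(replicate(50, e),
            vapply(1:50, function(i) mutate_copy(e, 0.02)$seq, ""),
            vapply(1:50, function(i) mutate_copy(e, 0.08)$seq, ""))
  dp <- divergence_profile(seqs, consensus = e)
  expect_equal(sum(dp$counts), 150)
  mode_bin <- function(d) as.integer(names(which.max(table(floor(d)))))
  expect_equal(mode_bin(dp$divergence[1:50]), 0)
  expect_lte(abs(mode_bin(dp$divergence[51:100]) - 2), 1)
  expect_lte(abs(mode_bin(dp$divergence[101:150]) - 8), 1)
  expect_equal(dp$bins[which.max(dp$counts)], 0)
  # class means concentrate near 100 * rate
  expect_lt(abs(mean(dp$divergence[51:100]) - 2), 1)
  expect_lt(abs(mean(dp$divergence[101:150]) - 8), 1.5)
})

test_that("trees pair identical copies with high support and tight subclades", {
  set.seed(504)
  a <- make_element(100, 12)
  b <- mutate_copy(a, 0.10)$seq
  aln <- align_family(c(a, a, b, b), ids = c("a1", "a2", "b1", "b2"))
  tr <- build_tree(aln, n_bootstrap = 100, seed = 9)
  expect_setequal(tr$tree$tip.label, c("a1", "a2", "b1", "b2"))
  expect_equal(tr$subclade[["a1"]], tr$subclade[["a2"]])
  expect_equal(tr$subclade[["b1"]], tr$subclade[["b2"]])
  expect_false(tr$subclade[["a1"]] == tr$subclade[["b1"]])
  expect_gte(max(tr$support, na.rm = TRUE), 95)

  # all-identical family: a single subclade
  aln2 <- align_family(rep(a, 5))
  tr2 <- build_tree(aln2, n_bootstrap = 10, seed = 2)
  expect_equal(length(unique(tr2$subclade)), 1)
  expect_true(all(tr2$tree$edge.length < 1e-9))

  expect_error(build_tree(align_family(c(a, a, a)), 10), ">= 4")
})

test_that("two-founder families split into founder-true subclades", {
  set.seed(505)
  f1 <- make_element(110, 12)
  f2 <- mutate_copy(f1, 0.05)$seq
  seqs <- c(rep(f1, 10), rep(f2, 10))
  ids <- c(paste0("x", 1:10), paste0("y", 1:10))
  tr <- build_tree(align_family(seqs, ids), n_bootstrap = 20, seed = 4)
  grp <- tr$subclade
  expect_equal(length(unique(grp[paste0("x", 1:10)])), 1)
  expect_equal(length(unique(grp[paste0("y", 1:10)])), 1)
  expect_false(grp[["x1"]] == grp[["y1"]])
})

test_that("mean recovered divergence tracks the planted substitution rate", {
  set.seed(506)
  e <- make_element(112, 15)
  for (p in c(0, 0.01, 0.05)) {
    seqs <- vapply(1:40, function(i) mutate_copy(e, p)$seq, "")
    d <- vapply(seqs, divergence, numeric(1), consensus = e,
                USE.NAMES = FALSE)
    expect_lt(abs(mean(d) - 100 * p), 1)
  }
})

test_that("EST screening applies the length, identity and E-value thresholds", {
  set.seed(507)
  cons <- make_element(112, 15)
  rsx <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  ests <- stats::setNames(vapply(1:100, function(i) rsx(500), ""),
                          sprintf("e%03d", 1:100))
  # full consensus embedded (plus strand) and reverse-complemented
  ests[1] <- paste0(substr(ests[1], 1, 100), cons, substr(ests[1], 213, 500))
  ests[2] <- paste0(substr(ests[2], 1, 50), revcomp(cons),
                    substr(ests[2], 163, 500))
  # a 40 bp exact block only: below the length threshold
  ests[3] <- paste0(substr(ests[3], 1, 100), substr(cons, 20, 59),
                    substr(ests[3], 141, 500))
  hits <- search_ests(cons, ests)
  expect_setequal(hits$est_id, c("e001", "e002"))
  expect_identical(hits$strand[hits$est_id == "e002"], "-")
  expect_true(all(hits$evalue <= 1e-6))
  expect_equal(attr(hits, "n_ests"), 100)
})
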