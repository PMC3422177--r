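rs <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("flank_conservation recovers the planted A|element|T target", {
  set.seed(301)
  copies <- data.frame(
    left_flank = vapply(1:20, function(i) paste0(rs(49), "A"), ""),
    right_flank = vapply(1:20, function(i) paste0("T", rs(49)), ""))
  tc <- flank_conservation(copies)
  expect_equal(unname(tc$profile["A", "-1"]), 1)
  expect_equal(unname(tc$profile["T", "+1"]), 1)
  expect_identical(tc$target, "AT")
  expect_false(any(tc$conserved[c("-5", "-4", "-3", "-2")]))

  # uniform-random insertion context: nothing conserved
  set.seed(302)
  rand <- data.frame(left_flank = vapply(1:40, function(i) rs(50), ""),
                     right_flank = vapply(1:40, function(i) rs(50), ""))
  expect_true(is.na(flank_conservation(rand)$target))

  expect_error(flank_conservation(copies[1:4, ]), ">= 5 copies")
})

test_that("retrieve_res finds a planted empty allele and classifies it", {
  set.seed(303)
  elem <- make_element(112, 15)
  L <- paste0(rs(120), "A")                  # occupied left context + target A
  R <- paste0("T", rs(120))                  # target T + right context
  occupied <- paste0(L, elem, R)
  copy <- list(copy_id = "cp1", contig = "c1", start = 121L,
               end = 121L + 112L,
               left_flank = substr(L, nchar(L) - 49, nchar(L)),
               right_flank = substr(R, 1, 50))

  # intact empty allele on a second contig
  st <- genome_store(c(c1 = occupied, c2 = paste0(rs(30), L, R, rs(30))))
  res <- retrieve_res(st, copy)
  expect_equal(nrow(res), 1)
  expect_identical(res$classification, "intact_AT")
  expect_identical(res$contig, "c2")

  # type I: both target bases deleted from the empty allele
  noAT <- paste0(substr(L, 1, nchar(L) - 1), substr(R, 2, nchar(R)))
  st2 <- genome_store(c(c1 = occupied, c2 = paste0(rs(30), noAT, rs(30))))
  res2 <- retrieve_res(st2, copy)
  expect_equal(nrow(res2), 1)
  expect_identical(res2$classification, "typeI")

  # no second allele: empty result, and the source locus is never returned
  st3 <- genome_store(c(c1 = occupied))
  expect_equal(nrow(retrieve_res(st3, copy)), 0)
})

test_that("retrieve_res finds empty alleles planted in reverse orientation", {
  set.seed(304)
  elem <- make_element(112, 15)
  L <- paste0(rs(120), "A"); R <- paste0("T", rs(120))
  occupied <- paste0(L, elem, R)
  copy <- list(copy_id = "cp1", contig = "c1", start = 121L,
               end = 121L + 112L,
               left_flank = substr(L, nchar(L) - 49, nchar(L)),
               right_flank = substr(R, 1, 50))
  st <- genome_store(c(c1 = occupied,
                       c2 = paste0(rs(40), revcomp(paste0(L, R)), rs(40))))
  res <- retrieve_res(st, copy)
  expect_equal(nrow(res), 1)
  expect_identical(res$strand, "-")
  expect_identical(res$classification, "intact_AT")
})

test_that("the junction classifier recovers every planted edit type", {
  set.seed(305)
  j <- sim_junctions(200, types = c("intact_AT", "typeI", "typeII",
                                    "typeIII", "typeIV"))
  called <- vapply(seq_len(nrow(j)), function(i) {
    jp <- atonscan:::junction_parse(j$left_flank[i], j$right_flank[i],
                                    j$res_seq[i])
    classify_target_site(jp)
  }, character(1))
  expect_identical(called, j$true_type)
})

test_that("hand-built junction scripts classify as specified", {
  # flanks ...GCA|A  T|TGC...: intact has exactly AT between the cores
  set.seed(306)
  lf <- paste0(rs(47), "GCA")                # ends in target A
  rf <- paste0("TGC", rs(47))                # starts with target T
  intact <- paste0(lf, rf)
  jp <- atonscan:::junction_parse(lf, rf, intact)
  expect_identical(classify_target_site(jp), "intact_AT")

  # only the A left at the junction: one target base missing
  onlyA <- paste0(lf, substr(rf, 2, nchar(rf)))
  expect_identical(
    classify_target_site(atonscan:::junction_parse(lf, rf, onlyA)),
    "typeII")

  # extra bases between A and T
  extra <- paste0(lf, "GG", rf)
  expect_identical(
    classify_target_site(atonscan:::junction_parse(lf, rf, extra)),
    "typeIV")
})

test_that("infer_scenario is ambiguous for canonical elements and resolved otherwise", {
  set.seed(307)
  res_ok <- data.frame(classification = "intact_AT")
  canon <- data.frame(seq = c("TACGGA", "TAGGCA"),
                      left_flank = c("CCGA", "GTGA"),
                      right_flank = c("TGGC", "TCCA"))
  expect_identical(infer_scenario(canon, res_ok), "ambiguous")

  # hypothetical G...C element between a lone A and T
  btw <- data.frame(seq = "GCCGC", left_flank = "CCGA", right_flank = "TGGC")
  expect_identical(infer_scenario(btw, res_ok), "between_A_and_T")

  # hypothetical G...C element flanked by duplicated AT on both sides
  dup <- data.frame(seq = "GCCGC", left_flank = "CCAT", right_flank = "ATGC")
  expect_identical(infer_scenario(dup, res_ok), "duplicated_AT")

  expect_error(infer_scenario(canon, data.frame(classification = "typeI")),
               "intact RES")
})

test_that("res_class_counts tabulates and reports the aberrant fraction", {
  recs <- data.frame(classification = c(rep("intact_AT", 98), "typeI",
                                        "typeIV"))
  ct <- res_class_counts(recs)
  expect_equal(unname(ct["intact_AT"]), 98L)
  expect_equal(attr(ct, "aberrant_fraction"), 0.02)
})
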