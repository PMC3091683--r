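test_that("column scores follow the parametric scheme", {
  sch <- scoring_scheme()
  expect_equal(column_score("DIAG", 100, 100, TRUE, sch), 12)
  expect_equal(column_score("DIAG", 100, 160, FALSE, sch), 4)
  expect_equal(column_score("MERGE", c(100, 60), 160, FALSE, sch), 5)
  expect_equal(column_score("GAP", scheme = sch), -8)
  # difference cap
  expect_equal(column_score("DIAG", 30, 330, FALSE, sch), 0)
  expect_error(column_score("MERGE", c(10, 20, 30, 40), 100, FALSE, sch),
               "k_max")
  expect_error(column_score("DIAG", c(10, 20), 100, FALSE, sch), "exactly one")
})

test_that("identical structures align colinearly; first column has no phase bonus", {
  a <- mk_struct(c(100, 200, 150), acc = "a")
  b <- mk_struct(c(100, 200, 150), acc = "b")
  al <- align_structures(a, b)
  expect_equal(al$score, 34) # 10 + 12 + 12
  expect_true(al$is_colinear)
  expect_identical(vapply(al$columns, `[[`, character(1), "kind"),
                   rep("DIAG", 3L))
})

test_that("intron loss is detected as an exon merge", {
  a <- mk_struct(c(100, 60, 90), acc = "a")
  b <- mk_struct(c(160, 90), acc = "b")
  al <- align_structures(a, b)
  expect_equal(al$score, 17) # merge 5 + diag-with-phase 12
  expect_false(al$is_colinear)
  expect_identical(al$columns[[1L]]$kind, "MERGE_A")
  expect_identical(al$columns[[1L]]$a_idx, 1:2)
  expect_equal(enumerate_alignments(a, b), 17)
  # renderer marks the merge and the matched column
  txt <- render_alignment(al, a, b)
  expect_match(txt, "100\\+60")
})

test_that("single-exon structures align as one DIAG column", {
  a <- mk_struct(90, acc = "a")
  b <- mk_struct(151, acc = "b")
  al <- align_structures(a, b)
  expect_length(al$columns, 1L)
  expect_equal(al$score, column_score("DIAG", 90, 151, FALSE, scoring_scheme()))
  expect_equal(enumerate_alignments(a, b), al$score)
})

test_that("the DP matches exhaustive enumeration on random small pairs", {
  set.seed(501)
  for (i in 1:60) {
    a <- random_struct(sample(1:5, 1), acc = "a")
    b <- random_struct(sample(1:5, 1), acc = "b")
    expect_equal(align_structures(a, b)$score, enumerate_alignments(a, b),
                 info = paste(paste(a$coding_lengths, collapse = ","), "vs",
                              paste(b$coding_lengths, collapse = ",")))
  }
  expect_error(enumerate_alignments(random_struct(8, acc = "a"),
                                    random_struct(3, acc = "b")),
               "too large")
})

test_that("self-alignment is optimal and all-DIAG; score is symmetric", {
  set.seed(502)
  for (i in 1:40) {
    a <- random_struct(sample(1:6, 1), acc = "a")
    b <- random_struct(sample(1:6, 1), acc = "b")
    self <- align_structures(a, a)
    expect_true(self$is_colinear)
    ideal <- sum(vapply(seq_along(a$coding_lengths), function(k) {
      column_score("DIAG", a$coding_lengths[k], a$coding_lengths[k],
                   phase_ok = k > 1L, scheme = scoring_scheme())
    }, numeric(1)))
    expect_equal(self$score, ideal)
    expect_equal(align_structures(a, b)$score, align_structures(b, a)$score)
  }
})

test_that("widening a length difference never increases a column score", {
  sch <- scoring_scheme()
  deltas <- seq(0, 400, by = 10)
  scores <- vapply(deltas, function(d)
    column_score("DIAG", 100, 100 + d, TRUE, sch), numeric(1))
  expect_true(all(diff(scores) <= 0))
  # and through a fixed colinear alignment of equal-count structures
  base <- align_structures(mk_struct(c(90, 90, 90), acc = "a"),
                           mk_struct(c(90, 90, 90), acc = "b"))$score
  worse <- align_structures(mk_struct(c(90, 90, 90), acc = "a"),
                            mk_struct(c(90, 150, 90), acc = "b"))$score
  expect_lt(worse, base)
})

test_that("scoring schemes are configurable and validated", {
  sch <- scoring_scheme(s_max = 5, w = 0, g_gap = 1, m_merge = 1, k_max = 4)
  expect_equal(column_score("MERGE", c(10, 10, 10, 10), 40, FALSE, sch), 2)
  expect_error(scoring_scheme(g_gap = 0), "g_gap")
  expect_error(scoring_scheme(k_max = 1), "k_max")
})
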