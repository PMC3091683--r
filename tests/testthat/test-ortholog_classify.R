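test_that("colinear classification applies the three criteria in order", {
  q <- mk_struct(c(50, 150, 100, 50), acc = "q")
  expect_identical(classify_colinear(q, mk_struct(c(50, 150, 100, 50), acc = "c")),
                   "ISO1")
  expect_identical(classify_colinear(q, mk_struct(c(50, 150, 100, 53), acc = "c")),
                   "ISO2")
  expect_identical(classify_colinear(q, mk_struct(c(50, 150, 100, 51), acc = "c")),
                   "ISO3")
  # shifting the first exon by 1 breaks every downstream phase
  expect_identical(classify_colinear(q, mk_struct(c(51, 150, 100, 50), acc = "c")),
                   "NONE")
  expect_identical(classify_colinear(q, mk_struct(c(50, 150, 100), acc = "c")),
                   "NONE")
  # ISO2 needs every difference in {0,3,...,15}: 18 falls through to ISO3
  expect_identical(classify_colinear(q, mk_struct(c(50, 150, 100, 68), acc = "c")),
                   "ISO3")
})

test_that("colinear classification is symmetric", {
  set.seed(601)
  for (i in 1:100) {
    a <- random_struct(sample(2:6, 1), pool = seq(30L, 90L, 3L), acc = "a")
    b <- random_struct(length(a$coding_lengths), pool = seq(30L, 90L, 3L),
                       acc = "b")
    expect_identical(classify_colinear(a, b), classify_colinear(b, a))
  }
})

test_that("classified colinear pairs satisfy the criteria algebra", {
  set.seed(602)
  n_checked <- 0L
  for (i in 1:300) {
    n <- sample(2:6, 1)
    a <- random_struct(n, pool = 30:90, acc = "a")
    # half the partners phase-preserving by construction
    delta <- if (i %% 2 == 0) 3L * sample(-4:4, n, replace = TRUE) else
      sample(-10:10, n, replace = TRUE)
    b <- mk_struct(pmax(3L, a$coding_lengths + delta), acc = "b")
    type <- classify_colinear(a, b)
    d <- abs(a$coding_lengths - b$coding_lengths)
    if (type == "ISO1") expect_true(all(d == 0L))
    if (type == "ISO2") expect_true(all(d %in% c(0L, 3L, 6L, 9L, 12L, 15L)) &&
                                      any(d > 0L))
    if (identical(a$phases, b$phases) && n > 1L) {
      expect_true(all(d[-n] %% 3L == 0L))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("best_match keeps the highest-scoring candidate", {
  q <- mk_struct(c(60, 90, 120, 60), acc = "q", gene = "gq")
  cands <- list(mk_struct(c(60, 90, 120, 60), acc = "c1", gene = "gc"),
                mk_struct(c(60, 90, 150, 60), acc = "c2", gene = "gc"),
                mk_struct(c(90, 90, 120, 90), acc = "c3", gene = "gc"))
  rec <- best_match(q, cands)
  expect_identical(rec$best_match_accession, "c1")
  expect_identical(rec$match_type, "ISO1")
  expect_identical(rec$match_source, "CURATED")

  none <- best_match(q, list())
  expect_identical(none$match_type, "NONE")
  expect_true(is.na(none$best_match_accession))
  expect_true(is.na(none$alignment_score))
})

test_that("score ties prefer curated candidates over predictions", {
  q <- mk_struct(c(60, 90, 120), acc = "q")
  pred <- mk_struct(c(60, 90, 120), acc = "aaa", source = "PREDICTED")
  cur <- mk_struct(c(60, 90, 120), acc = "zzz", source = "CURATED")
  rec <- best_match(q, list(pred, cur))
  expect_identical(rec$best_match_accession, "zzz")
  expect_identical(rec$match_source, "CURATED")
  # among equals of one source, the smallest accession wins
  rec2 <- best_match(q, list(mk_struct(c(60, 90, 120), acc = "m2"),
                             mk_struct(c(60, 90, 120), acc = "m1")))
  expect_identical(rec2$best_match_accession, "m1")
})

test_that("a best alignment using merges yields NONE despite equal exon counts", {
  q <- mk_struct(c(100, 100, 200, 50), acc = "q")
  c1 <- mk_struct(c(200, 200, 25, 25), acc = "c1")
  al <- align_structures(q, c1)
  expect_false(al$is_colinear)
  expect_equal(al$score, enumerate_alignments(q, c1))
  rec <- best_match(q, list(c1))
  expect_identical(rec$match_type, "NONE")
  expect_identical(rec$best_match_accession, "c1")
})

test_that("cohorts aggregate to gene level and tolerate missing genes", {
  a1 <- tx_from_lengths("A1", "GA", c(60, 90, 120, 60))
  a2 <- tx_from_lengths("A2", "GA", c(60, 91, 149, 60))
  b1 <- tx_from_lengths("B1", "GB", c(60, 90, 120, 60), utr5 = 40, start = 5000)
  index_a <- gene_index(list(a1, a2))
  index_b <- gene_index(list(b1))
  pairs <- data.frame(gene_a = c("GA", "GHOST"), gene_b = c("GB", "GB2"))
  res <- suppressWarnings(classify_cohort(index_a, index_b, pairs))

  ab <- res$matches_ab[order(res$matches_ab$query_accession), ]
  expect_identical(ab$match_type, c("ISO1", "NONE"))
  expect_identical(ab$query_accession, c("A1", "A2"))
  s <- res$summary
  expect_identical(s$gene_counts_best$n_gene_pairs[
    s$gene_counts_best$match_type == "ISO1"], 1L)
  expect_identical(s$n_pairs_analyzed, 1L)
  expect_identical(s$n_pairs_skipped, 1L)
  # counts sum to totals
  tc <- s$transcript_counts
  expect_identical(sum(tc$n[tc$direction == "A->B"]), nrow(res$matches_ab))
  expect_identical(sum(tc$n[tc$direction == "B->A"]), nrow(res$matches_ba))
})

test_that("gene-level category is the strongest transcript category", {
  run <- run_cohort(generator_config(n_genes = 40, seed = 9))
  s <- run$result$summary
  recs <- rbind(run$result$matches_ab, run$result$matches_ba)
  expect_identical(sum(s$gene_counts_best$n_gene_pairs), s$n_pairs_analyzed)
  # recompute best-over-directions independently
  rank <- match(recs$match_type, c("ISO1", "ISO2", "ISO3", "NONE"))
  gene_key <- ifelse(startsWith(recs$query_gene, "GA"),
                     recs$query_gene,
                     run$cohort$pairs$gene_a[match(recs$query_gene,
                                                   run$cohort$pairs$gene_b)])
  best <- tapply(rank, gene_key, min)
  expected <- table(factor(c("ISO1", "ISO2", "ISO3", "NONE")[best],
                           levels = c("ISO1", "ISO2", "ISO3", "NONE")))
  expect_identical(as.integer(expected), s$gene_counts_best$n_gene_pairs)
})

test_that("adding predicted candidates never weakens a query", {
  cfg <- generator_config(n_genes = 80, seed = 17, predicted_fraction = 0.5)
  cohort <- suppressWarnings(generate_cohort(cfg))
  run_with <- function(inc) suppressWarnings(
    classify_cohort(cohort$index_a, cohort$index_b, cohort$pairs,
                    include_predicted = inc))
  r0 <- run_with(FALSE)$matches_ab
  r1 <- run_with(TRUE)$matches_ab
  r1 <- r1[match(r0$query_accession, r1$query_accession), ]
  lv <- c("ISO1", "ISO2", "ISO3", "NONE")
  expect_true(all(match(r1$match_type, lv) <= match(r0$match_type, lv)))
  expect_lt(sum(r1$match_type == "NONE"), sum(r0$match_type == "NONE"))
})
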