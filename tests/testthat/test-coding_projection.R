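test_that("CDS projection trims external exons and computes intron phases", {
  t <- transcript_model("NMX1", "GENE1", "chr1", "+",
                        c(0, 200, 500, 700), c(100, 350, 600, 800), 50, 750)
  cs <- suppressWarnings(project_cds(t))
  expect_identical(cs$coding_lengths, c(50L, 150L, 100L, 50L))
  expect_identical(cs$phases, c(2L, 2L, 0L))
  expect_identical(cs$n_internal_fully_coding, 2L)
  expect_identical(cs$total_exon_count, 4L)

  # same coordinates on the minus strand: transcript order reversed,
  # phases recomputed from the reversed cumulative sums
  tm <- transcript_model("NMX1", "GENE1", "chr1", "-",
                         c(0, 200, 500, 700), c(100, 350, 600, 800), 50, 750)
  csm <- suppressWarnings(project_cds(tm))
  expect_identical(csm$coding_lengths, c(50L, 100L, 150L, 50L))
  expect_identical(csm$phases, c(2L, 0L, 0L))
})

test_that("projection rejects degenerate inputs", {
  t <- transcript_model("nc", "g", "chr1", "+", 0, 100, 100, 100)
  expect_error(project_cds(t), "non-coding transcript")
  # a CDS boundary inside an intron never reaches projection: the
  # transcript constructor rejects it as malformed annotation
  expect_error(transcript_model("t", "g", "chr1", "+", c(0, 200), c(100, 300),
                                150, 250), "not exonic")
})

test_that("a CDS length not divisible by 3 warns but projects", {
  t <- tx_from_lengths("t1", "g", c(50L, 100L, 100L, 51L))
  expect_warning(cs <- project_cds(t), "not a multiple of 3")
  expect_identical(sum(cs$coding_lengths), 301L)
})

test_that("coding length is conserved and projection is strand-involutive", {
  set.seed(401)
  for (i in 1:50) {
    n <- sample(2:9, 1)
    lengths <- sample(30:300, n, replace = TRUE)
    t <- tx_from_lengths(sprintf("t%d", i), "g", lengths,
                         utr5 = sample(0:80, 1), utr3 = sample(0:80, 1),
                         strand = sample(c("+", "-"), 1))
    cs <- suppressWarnings(project_cds(t))
    expect_identical(sum(cs$coding_lengths), exonic_cds_length(t))
    expect_identical(cs$phases,
                     if (n > 1) cumsum(cs$coding_lengths)[-n] %% 3L else integer(0))
    flipped <- suppressWarnings(project_cds(mirror_flip(t)))
    expect_identical(flipped$coding_lengths, cs$coding_lengths)
    expect_identical(flipped$phases, cs$phases)
  }
})

test_that("stored phases must agree with cumulative coding lengths", {
  expect_error(coding_structure("x", "g", "CURATED", c(50L, 100L),
                                phases = 1L, n_internal_fully_coding = 0L,
                                total_exon_count = 2L),
               "disagree")
  expect_error(coding_structure("x", "g", "CURATED", c(50L, 0L),
                                phases = 2L, n_internal_fully_coding = 0L,
                                total_exon_count = 2L))
})

test_that("analysis filters require four exons and two internal fully coding exons", {
  ok <- suppressWarnings(project_cds(tx_from_lengths("a", "g", c(60, 90, 120, 60))))
  expect_true(passes_filters(ok))

  three <- suppressWarnings(project_cds(tx_from_lengths("b", "g", c(60, 90, 60))))
  v <- passes_filters(three)
  expect_false(v)
  expect_match(attr(v, "reason"), "fewer than four exons")

  # five exons but the CDS spans only the middle three: one internal
  # fully coding exon
  t <- transcript_model("c", "g", "chr1", "+",
                        c(0, 200, 400, 600, 800), c(100, 300, 500, 700, 900),
                        250, 650)
  cs <- suppressWarnings(project_cds(t))
  expect_identical(length(cs$coding_lengths), 3L)
  expect_identical(cs$n_internal_fully_coding, 1L)
  v <- passes_filters(cs)
  expect_false(v)
  expect_match(attr(v, "reason"), "internal fully coding")
})

test_that("redundancy collapsing keeps the longest representative per signature", {
  # identical internal coding exons, differing external coding portions
  short <- mk_struct(c(40, 150, 100, 40), acc = "zzz")
  long <- mk_struct(c(70, 150, 100, 70), acc = "aaa")
  out <- dedup_transcripts(list(short, long))
  expect_length(out, 1L)
  expect_identical(out[[1L]]$accession, "aaa")
  expect_identical(dedup_signature(short), dedup_signature(long))

  # same internal sizes, different frames -> kept apart
  f1 <- mk_struct(c(40, 150, 100, 40), acc = "p")
  f2 <- mk_struct(c(41, 150, 100, 39), acc = "q")
  expect_false(dedup_signature(f1) == dedup_signature(f2))
  expect_length(dedup_transcripts(list(f1, f2)), 2L)

  # equal total coding length -> lexicographically smallest accession
  tie <- dedup_transcripts(list(mk_struct(c(40, 150, 100, 40), acc = "b"),
                                mk_struct(c(40, 150, 100, 40), acc = "a")))
  expect_identical(tie[[1L]]$accession, "a")
})

test_that("dedup is idempotent on random structure sets", {
  set.seed(402)
  for (i in 1:100) {
    structs <- lapply(seq_len(sample(2:6, 1)), function(j) {
      random_struct(sample(4:7, 1), pool = seq(30L, 120L, 3L),
                    acc = sprintf("s%02d", j))
    })
    once <- dedup_transcripts(structs)
    twice <- dedup_transcripts(once)
    expect_identical(twice, once)
  }
})
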