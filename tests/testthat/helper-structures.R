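# Builders shared across the suite. Fixtures are constructed in code;
# nothing is read from disk except files the tests write themselves.

# coding structure straight from exon lengths (phases derived)
mk_struct <- function(lengths, acc = "q", gene = "g", source = "CURATED",
                      total_exons = length(lengths)) {
  lengths <- as.integer(lengths)
  n <- length(lengths)
  coding_structure(acc, gene, source, lengths,
                   phases = if (n > 1L) cumsum(lengths)[-n] %% 3L else integer(0),
                   n_internal_fully_coding = max(0L, n - 2L),
                   total_exon_count = total_exons)
}

# random structure with lengths drawn from a pool
random_struct <- function(n, pool = c(30L, 60L, 90L, 100L, 151L), acc = "q",
                          source = "CURATED") {
  mk_struct(sample(pool, n, replace = TRUE), acc = acc, source = source)
}

# transcript laid out on the plus strand from coding lengths; simple
# constant introns, partially coding external exons
tx_from_lengths <- function(acc, gene, lengths, utr5 = 10L, utr3 = 10L,
                            strand = "+", start = 1000L, intron = 100L,
                            source = "CURATED", chrom = "chr1") {
  lengths <- as.integer(lengths)
  n <- length(lengths)
  segs <- c(utr5 + lengths[1L], if (n > 2L) lengths[2:(n - 1L)],
            if (n > 1L) lengths[n] + utr3)
  m <- length(segs)
  starts <- start + c(0L, cumsum(segs + intron))[seq_len(m)]
  ends <- starts + segs
  cds_start <- starts[1L] + utr5
  cds_end <- ends[m] - utr3
  if (strand == "-") {
    mirror <- 2L * start + (ends[m] - starts[1L])
    tmp <- rev(mirror - ends)
    ends <- rev(mirror - starts)
    starts <- tmp
    cds <- c(mirror - cds_end, mirror - cds_start)
    cds_start <- cds[1L]; cds_end <- cds[2L]
  }
  transcript_model(acc, gene, chrom, strand, starts, ends,
                   cds_start, cds_end, source)
}

# independent exonic CDS length: interval intersection, no projection code
exonic_cds_length <- function(t) {
  sum(pmax(0L, pmin(t$exon_ends, t$cds_end) - pmax(t$exon_starts, t$cds_start)))
}

# coordinate mirror + strand flip of a transcript (same structure)
mirror_flip <- function(t, mirror = NULL) {
  if (is.null(mirror)) {
    mirror <- t$exon_starts[1L] + t$exon_ends[length(t$exon_ends)]
  }
  transcript_model(t$accession, t$gene_id, t$chrom,
                   if (t$strand == "+") "-" else "+",
                   rev(mirror - t$exon_ends), rev(mirror - t$exon_starts),
                   mirror - t$cds_end, mirror - t$cds_start, t$source)
}

# generate then classify a labelled cohort, silencing the expected
# non-multiple-of-3 CDS warnings some perturbation families produce
run_cohort <- function(config, include_predicted = TRUE,
                       scheme = scoring_scheme()) {
  cohort <- suppressWarnings(generate_cohort(config))
  result <- suppressWarnings(
    classify_cohort(cohort$index_a, cohort$index_b, cohort$pairs,
                    scheme = scheme, include_predicted = include_predicted))
  list(cohort = cohort, result = result)
}
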