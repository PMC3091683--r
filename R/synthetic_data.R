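# Synthetic orthologous-gene cohorts with labelled splicing divergence.
#
# Each simulated gene pair carries a ground-truth label naming the
# relationship between the species-A query transcript and its
# species-B counterpart. The perturbation families are constructed to
# be exactly the preimages of the classifier's categories:
#   ISO1              identical coding structure;
#   ISO2              1-3 exons shifted by multiples of 3 bp, each
#                     |delta| <= 15, at least one nonzero (phases are
#                     preserved automatically by 3k shifts);
#   ISO3              phase-preserving shifts outside the ISO2 band
#                     (a large internal multiple-of-3 shift, or a
#                     last-exon shift not in {0,3,...,15});
#   NONE_skip         one internal coding exon deleted;
#   NONE_introngain   one coding exon split in two (intron gained);
#   NONE_phasebreak   an internal exon shifted by delta with
#                     delta %% 3 != 0, breaking downstream phases;
#   NONE_speciesspecific  a structurally unrelated isoform set only
#                     (different coding exon count).
#
# Genomic layout of species B is drawn independently of species A
# (different chromosomes and offsets) so nothing downstream can depend
# on coordinates, only on structure.

SYNTH_LABELS <- c("ISO1", "ISO2", "ISO3", "NONE_skip", "NONE_introngain",
                  "NONE_phasebreak", "NONE_speciesspecific")

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_genes Number of orthologous gene pairs.
#' @param exon_count_range Range (min, max) of coding exons per base
#'   transcript; the minimum of 4 guarantees at least two internal
#'   fully coding exons, so every base transcript passes the analysis
#'   filters.
#' @param coding_length_range Range (bp) of per-exon coding lengths,
#'   drawn uniformly.
#' @param utr_exon_probability Probability of an extra untranslated
#'   exon on each transcript side.
#' @param minus_strand_probability Probability a transcript is laid out
#'   on the minus strand.
#' @param isoforms_per_gene_range Range of species-A isoforms per gene;
#'   isoforms beyond the first are redundant variants (same internal
#'   coding exons, different UTRs) that redundancy collapsing removes.
#' @param label_mixture Named probabilities over the seven truth
#'   labels; must sum to 1.
#' @param predicted_fraction For ISO1/ISO2/ISO3 pairs, the probability
#'   that the matching species-B transcript is emitted as PREDICTED,
#'   accompanied by a CURATED exon-skip decoy isoform. Such pairs are
#'   recovered only when predicted candidates are included.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 100L,
                             exon_count_range = c(4L, 12L),
                             coding_length_range = c(30L, 300L),
                             utr_exon_probability = 0.3,
                             minus_strand_probability = 0.5,
                             isoforms_per_gene_range = c(1L, 4L),
                             label_mixture = stats::setNames(
                               rep(1 / 7, 7), SYNTH_LABELS),
                             predicted_fraction = 0.25,
                             seed = 1L) {
  stopifnot(n_genes >= 1L,
            length(exon_count_range) == 2L, exon_count_range[1] >= 4L,
            exon_count_range[2] >= exon_count_range[1],
            length(coding_length_range) == 2L, coding_length_range[1] >= 30L,
            coding_length_range[2] >= coding_length_range[1],
            utr_exon_probability >= 0, utr_exon_probability <= 1,
            minus_strand_probability >= 0, minus_strand_probability <= 1,
            length(isoforms_per_gene_range) == 2L,
            isoforms_per_gene_range[1] >= 1L,
            isoforms_per_gene_range[2] >= isoforms_per_gene_range[1],
            predicted_fraction >= 0, predicted_fraction <= 1)
  if (is.null(names(label_mixture)) ||
      !all(names(label_mixture) %in% SYNTH_LABELS) ||
      anyDuplicated(names(label_mixture)) ||
      any(label_mixture < 0) ||
      abs(sum(label_mixture) - 1) > 1e-8) {
    stop("label_mixture must be named probabilities over ",
         paste(SYNTH_LABELS, collapse = ", "), " summing to 1", call. = FALSE)
  }
  full <- stats::setNames(rep(0, length(SYNTH_LABELS)), SYNTH_LABELS)
  full[names(label_mixture)] <- label_mixture
  structure(list(n_genes = as.integer(n_genes),
                 exon_count_range = as.integer(exon_count_range),
                 coding_length_range = as.integer(coding_length_range),
                 utr_exon_probability = utr_exon_probability,
                 minus_strand_probability = minus_strand_probability,
                 isoforms_per_gene_range = as.integer(isoforms_per_gene_range),
                 label_mixture = full,
                 predicted_fraction = predicted_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# lay out a transcript on the genome from transcript-order pieces;
# coding_lengths are 5'->3'; on the minus strand the layout is mirrored
build_transcript_model <- function(accession, gene_id, chrom, strand,
                                   coding_lengths, utr5_len = 0L, utr3_len = 0L,
                                   utr5_exons = integer(0), utr3_exons = integer(0),
                                   intron_lengths = NULL, tx_start = 10000L,
                                   source = "CURATED") {
  n <- length(coding_lengths)
  stopifnot(n >= 1L, all(coding_lengths > 0L), utr5_len >= 0L, utr3_len >= 0L)
  segs <- c(utr5_exons,
            if (n == 1L) utr5_len + coding_lengths + utr3_len else c(
              utr5_len + coding_lengths[1L],
              if (n > 2L) coding_lengths[2:(n - 1L)],
              coding_lengths[n] + utr3_len),
            utr3_exons)
  m <- length(segs)
  if (is.null(intron_lengths)) intron_lengths <- rep(500L, max(m - 1L, 0L))
  stopifnot(length(intron_lengths) == m - 1L, all(intron_lengths > 0L))
  starts <- integer(m); ends <- integer(m)
  pos <- as.integer(tx_start)
  for (i in seq_len(m)) {
    starts[i] <- pos
    ends[i] <- pos + segs[i]
    pos <- ends[i] + if (i < m) intron_lengths[i] else 0L
  }
  iu <- length(utr5_exons)
  cds_start <- starts[iu + 1L] + utr5_len
  cds_end <- ends[iu + n] - utr3_len
  if (strand == "-") {
    mirror <- 2L * as.integer(tx_start) + (ends[m] - starts[1L])
    new_starts <- rev(mirror - ends)
    new_ends <- rev(mirror - starts)
    cds <- c(mirror - cds_end, mirror - cds_start)
    starts <- new_starts; ends <- new_ends
    cds_start <- cds[1L]; cds_end <- cds[2L]
  }
  transcript_model(accession, gene_id, chrom, strand, starts, ends,
                   cds_start, cds_end, source)
}

# genomic CDS-overlap intervals of a transcript, ascending
coding_intervals <- function(t) {
  s <- pmax(t$exon_starts, t$cds_start)
  e <- pmin(t$exon_ends, t$cds_end)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

# one UTR-shuffled variant of a transcript: internal coding exons and
# the CDS are untouched, external UTR extents and UTR-only exons vary
redundant_variant <- function(base, accession) {
  ci <- coding_intervals(base)
  m <- nrow(ci)
  starts <- ci[, "start"]; ends <- ci[, "end"]
  starts[1L] <- starts[1L] - sample(0:200, 1L)
  ends[m] <- ends[m] + sample(0:200, 1L)
  if (stats::runif(1) < 0.5) {
    gap <- sample(100:1000, 1L); len <- sample(50:300, 1L)
    starts <- c(starts[1L] - gap - len, starts)
    ends <- c(starts[2L] - gap, ends)
  }
  if (stats::runif(1) < 0.5) {
    gap <- sample(100:1000, 1L); len <- sample(50:300, 1L)
    starts <- c(starts, ends[length(ends)] + gap)
    ends <- c(ends, ends[length(ends)] + gap + len)
  }
  transcript_model(accession, base$gene_id, base$chrom, base$strand,
                   starts, ends, base$cds_start, base$cds_end, base$source)
}

#' Generate transcripts redundant with a base transcript
#'
#' Returns `n` transcripts — the base plus `n - 1` variants differing
#' only in untranslated exons and the untranslated extents of the
#' external exons — all sharing the base's redundancy signature, so
#' [dedup_transcripts()] collapses them to a single representative.
#'
#' @param base A coding [transcript_model()] with at least two internal
#'   fully coding exons.
#' @param n Number of transcripts to return (including the base).
#' @param seed Integer seed.
#' @return List of `n` [transcript_model()] objects.
#' @export
generate_redundant_set <- function(base, n, seed = 1L) {
  stopifnot(inherits(base, "transcript_model"), n >= 1L)
  cs <- project_cds(base)
  if (cs$n_internal_fully_coding < 2L) {
    stop("base transcript needs at least two internal fully coding exons",
         call. = FALSE)
  }
  with_seed(seed, {
    out <- vector("list", n)
    out[[1L]] <- base
    for (i in seq_len(n - 1L)) {
      out[[i + 1L]] <- redundant_variant(base, sprintf("%s_r%d", base$accession, i))
    }
    out
  })
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# draw base coding-exon lengths; total made a multiple of 3 so the CDS
# translates cleanly
draw_coding_lengths <- function(config) {
  n <- sample1(config$exon_count_range[1L]:config$exon_count_range[2L])
  l <- sample(config$coding_length_range[1L]:config$coding_length_range[2L],
              n, replace = TRUE)
  rem <- sum(l) %% 3L
  l[n] <- l[n] - rem
  if (l[n] < config$coding_length_range[1L]) l[n] <- l[n] + 3L
  l
}

# perturb base coding lengths according to the truth label; returns
# list(lengths, events); lengths == NULL marks "resample the exon draw"
perturb_lengths <- function(lengths, label) {
  n <- length(lengths)
  ev <- character(0)
  out <- lengths
  switch(label,
    ISO1 = {},
    ISO2 = {
      idx <- sample(n, sample1(1:min(3L, n)))
      for (i in idx) {
        delta <- 3L * sample1(1:5)
        if (out[i] - delta >= 3L && stats::runif(1) < 0.5) delta <- -delta
        out[i] <- out[i] + delta
        ev <- c(ev, sprintf("shift(exon=%d,delta=%+d)", i, delta))
      }
    },
    ISO3 = {
      if (stats::runif(1) < 0.5 || n < 2L) {
        # last-exon shift outside {0,3,...,15}
        delta <- sample1(setdiff(1:60, c(3L, 6L, 9L, 12L, 15L)))
        if (out[n] - delta >= 10L && stats::runif(1) < 0.5) delta <- -delta
        out[n] <- out[n] + delta
        ev <- sprintf("shift(exon=%d,delta=%+d)", n, delta)
      } else {
        # large internal multiple-of-3 shift (phase-preserving)
        i <- sample1(seq_len(n - 1L))
        delta <- 3L * sample1(7:16)
        if (out[i] - delta >= 10L && stats::runif(1) < 0.5) delta <- -delta
        out[i] <- out[i] + delta
        ev <- sprintf("shift(exon=%d,delta=%+d)", i, delta)
      }
    },
    NONE_skip = {
      i <- sample1(2:(n - 1L))
      out <- out[-i]
      ev <- sprintf("skip(exon=%d)", i)
    },
    NONE_introngain = {
      i <- sample1(seq_len(n))
      if (out[i] < 60L) return(list(lengths = NULL, events = character(0)))
      part <- sample1(20:(out[i] - 20L))
      out <- append(out[-i], c(part, lengths[i] - part), after = i - 1L)
      ev <- sprintf("split(exon=%d,at=%d)", i, part)
    },
    NONE_phasebreak = {
      i <- sample1(2:(n - 1L))
      delta <- sample1(c(1L, 2L)) + 3L * sample1(0:4)
      if (out[i] - delta >= 10L && stats::runif(1) < 0.5) delta <- -delta
      out[i] <- out[i] + delta
      ev <- sprintf("shift(exon=%d,delta=%+d)", i, delta)
    },
    stop("unknown label ", label, call. = FALSE)
  )
  list(lengths = out, events = ev)
}

random_layout <- function(config) {
  list(chrom = sprintf("chr%d", sample1(1:22)),
       strand = if (stats::runif(1) < config$minus_strand_probability) "-" else "+",
       tx_start = sample1(10000:10000000),
       utr5_len = sample1(0:200), utr3_len = sample1(0:200),
       utr5_exons = if (stats::runif(1) < config$utr_exon_probability)
         sample1(50:300) else integer(0),
       utr3_exons = if (stats::runif(1) < config$utr_exon_probability)
         sample1(50:300) else integer(0))
}

emit_transcript <- function(accession, gene_id, coding_lengths, layout,
                            source = "CURATED") {
  n_segs <- length(coding_lengths) + length(layout$utr5_exons) +
    length(layout$utr3_exons)
  build_transcript_model(
    accession, gene_id, layout$chrom, layout$strand, coding_lengths,
    utr5_len = layout$utr5_len, utr3_len = layout$utr3_len,
    utr5_exons = layout$utr5_exons, utr3_exons = layout$utr3_exons,
    intron_lengths = sample(80:2000, max(n_segs - 1L, 0L), replace = TRUE),
    tx_start = layout$tx_start, source = source)
}

#' Generate a synthetic orthologous cohort with ground truth
#'
#' For each gene pair a species-A base transcript is drawn, its
#' species-B counterpart is built according to a truth label sampled
#' from the configured mixture, and the pair is recorded together with
#' the applied perturbations. Species-A genes may carry additional
#' redundant isoforms (collapsed by the pipeline's redundancy step).
#' When a matching counterpart is drawn PREDICTED, species B also
#' receives a CURATED exon-skip decoy so the pair is recoverable only
#' with predicted candidates included.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: `index_a`, `index_b`
#'   ([gene_index()]), `pairs` (data.frame `gene_a`/`gene_b`), `truth`
#'   (data.frame with `gene_a`, `gene_b`, `query_accession`,
#'   `expected_match_accession`, `expected_type`, `events`), and the
#'   `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    tx_a <- list(); tx_b <- list()
    truth <- vector("list", config$n_genes)
    pairs <- data.frame(gene_a = sprintf("GA%05d", seq_len(config$n_genes)),
                        gene_b = sprintf("GB%05d", seq_len(config$n_genes)))
    for (g in seq_len(config$n_genes)) {
      gene_a <- pairs$gene_a[g]; gene_b <- pairs$gene_b[g]
      label <- sample(SYNTH_LABELS, 1L, prob = config$label_mixture)
      repeat {
        base_lengths <- draw_coding_lengths(config)
        if (label == "NONE_speciesspecific") {
          n <- length(base_lengths)
          n_alt <- sample1(setdiff(max(4L, n - 2L):(n + 2L), n))
          partner <- list(
            lengths = sample(config$coding_length_range[1L]:
                               config$coding_length_range[2L],
                             n_alt, replace = TRUE),
            events = sprintf("unrelated(n_exons=%d)", n_alt))
          break
        }
        partner <- perturb_lengths(base_lengths, label)
        if (!is.null(partner$lengths)) break
      }
      acc_a <- sprintf("%s.t1", gene_a)
      acc_b <- sprintf("%s.t1", gene_b)
      base_a <- emit_transcript(acc_a, gene_a, base_lengths, random_layout(config))
      tx_a[[length(tx_a) + 1L]] <- base_a
      # redundant species-A isoforms, removed again by dedup
      n_iso <- sample1(config$isoforms_per_gene_range[1L]:
                         config$isoforms_per_gene_range[2L])
      for (r in seq_len(n_iso - 1L)) {
        tx_a[[length(tx_a) + 1L]] <-
          redundant_variant(base_a, sprintf("%s.t%d", gene_a, r + 1L))
      }
      is_match <- label %in% c("ISO1", "ISO2", "ISO3")
      predicted <- is_match && stats::runif(1) < config$predicted_fraction
      tx_b[[length(tx_b) + 1L]] <- emit_transcript(
        acc_b, gene_b, partner$lengths, random_layout(config),
        source = if (predicted) "PREDICTED" else "CURATED")
      if (predicted) {
        # curated decoy: the partner with one internal coding exon skipped
        dec <- perturb_lengths(partner$lengths, "NONE_skip")
        tx_b[[length(tx_b) + 1L]] <- emit_transcript(
          sprintf("%s.d1", gene_b), gene_b, dec$lengths, random_layout(config),
          source = "CURATED")
      }
      truth[[g]] <- data.frame(
        gene_a = gene_a, gene_b = gene_b, query_accession = acc_a,
        expected_match_accession = if (is_match) acc_b else NA_character_,
        expected_type = if (is_match) label else "NONE",
        truth_label = label,
        requires_predicted = predicted,
        events = paste(partner$events, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    structure(list(index_a = gene_index(tx_a), index_b = gene_index(tx_b),
                   pairs = pairs, truth = do.call(rbind, truth),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d gene pair(s), %d species-A and ",
                     "%d species-B transcript(s) (seed %d)\n"),
              nrow(x$pairs), length(x$index_a$transcripts),
              length(x$index_b$transcripts), x$config$seed))
  print(table(x$truth$truth_label))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same genePred and ortholog-TSV dialects the readers
#' consume: `a_curated.genepred`, `b_curated.genepred`, optionally
#' `b_predicted.genepred`, `orthologs.tsv`, `truth.tsv` and a
#' `manifest.txt` recording the configuration and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_source <- function(index, src) {
    gene_index(Filter(function(t) t$source == src, index$transcripts))
  }
  write_genepred(by_source(cohort$index_a, "CURATED"),
                 file.path(dir, "a_curated.genepred"))
  write_genepred(by_source(cohort$index_b, "CURATED"),
                 file.path(dir, "b_curated.genepred"))
  pred_b <- by_source(cohort$index_b, "PREDICTED")
  if (length(pred_b$transcripts)) {
    write_genepred(pred_b, file.path(dir, "b_predicted.genepred"))
  }
  utils::write.table(cohort$pairs, file.path(dir, "orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  cfg <- cohort$config
  manifest <- c(
    sprintf("n_genes=%d", cfg$n_genes),
    sprintf("exon_count_range=%d..%d", cfg$exon_count_range[1], cfg$exon_count_range[2]),
    sprintf("coding_length_range=%d..%d", cfg$coding_length_range[1],
            cfg$coding_length_range[2]),
    sprintf("utr_exon_probability=%g", cfg$utr_exon_probability),
    sprintf("minus_strand_probability=%g", cfg$minus_strand_probability),
    sprintf("isoforms_per_gene_range=%d..%d", cfg$isoforms_per_gene_range[1],
            cfg$isoforms_per_gene_range[2]),
    sprintf("label_mixture=%s", paste(sprintf("%s:%g", names(cfg$label_mixture),
                                              cfg$label_mixture), collapse = ",")),
    sprintf("predicted_fraction=%g", cfg$predicted_fraction),
    sprintf("seed=%d", cfg$seed))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
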