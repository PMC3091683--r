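# Iso-orthology classification of best-scoring transcript pairs.
#
# Transcripts of orthologous genes are compared through their coding
# structures under three criteria of decreasing stringency. All three
# require the same number of coding exons and elementwise equality of
# the preceding intron phases; with Delta_i the absolute difference of
# the i-th coding exon lengths:
#   ISO1  every Delta_i == 0 (identical structures);
#   ISO2  every Delta_i in {0,3,6,9,12,15}, at least one nonzero;
#   ISO3  phases equal but neither of the above (length differences of
#         any size).
# Everything else — differing exon counts, any phase mismatch, or a
# best alignment that is not colinear (intron gain/loss or gaps) — is
# NONE.

MATCH_TYPES <- c("ISO1", "ISO2", "ISO3", "NONE")

# rank 1 = most stringent; used for "strongest type" aggregation
match_type_rank <- function(type) match(type, MATCH_TYPES)

#' Classify a colinear pair of coding structures
#'
#' Applies the three iso-orthology criteria to two structures assumed
#' to correspond exon-by-exon. Returns `"NONE"` when the exon counts
#' differ or any preceding-intron phase differs.
#'
#' @param a,b [coding_structure()] objects.
#' @return One of `"ISO1"`, `"ISO2"`, `"ISO3"`, `"NONE"`.
#' @export
classify_colinear <- function(a, b) {
  stopifnot(inherits(a, "coding_structure"), inherits(b, "coding_structure"))
  if (length(a$coding_lengths) != length(b$coding_lengths)) return("NONE")
  if (!identical(a$phases, b$phases)) return("NONE")
  delta <- abs(a$coding_lengths - b$coding_lengths)
  if (all(delta == 0L)) return("ISO1")
  if (all(delta %in% c(0L, 3L, 6L, 9L, 12L, 15L))) return("ISO2")
  "ISO3"
}

empty_match_table <- function() {
  data.frame(query_accession = character(), query_gene = character(),
             best_match_accession = character(), best_match_gene = character(),
             match_source = character(), match_type = character(),
             alignment_score = numeric(), stringsAsFactors = FALSE)
}

match_record <- function(query, best = NULL, match_type = "NONE", score = NA_real_) {
  data.frame(
    query_accession = query$accession,
    query_gene = query$gene_id,
    best_match_accession = if (is.null(best)) NA_character_ else best$accession,
    best_match_gene = if (is.null(best)) NA_character_ else best$gene_id,
    match_source = if (is.null(best)) "NONE" else best$source,
    match_type = match_type,
    alignment_score = score,
    stringsAsFactors = FALSE
  )
}

#' Best structural match of a query among candidate structures
#'
#' Aligns the query against every candidate and keeps the highest
#' scoring alignment; only that alignment is considered for match type
#' assignment. Score ties are broken by preferring CURATED over
#' PREDICTED candidates, then the stronger iso-orthology category, then
#' the lexicographically smallest accession. The match type is the
#' colinear classification of the winning pair when the winning
#' alignment is colinear, and `"NONE"` otherwise (an alignment using
#' gap or merge columns signals exon skipping or intron gain/loss, not
#' a shared splicing pattern; the top-scoring candidate is still
#' reported).
#'
#' @param query A [coding_structure()].
#' @param candidates List of [coding_structure()] from the orthologous
#'   partner gene (may mix CURATED and PREDICTED sources).
#' @param scheme A [scoring_scheme()].
#' @return One-row data.frame with the match-table columns
#'   (`query_accession`, `query_gene`, `best_match_accession`,
#'   `best_match_gene`, `match_source`, `match_type`,
#'   `alignment_score`).
#' @export
best_match <- function(query, candidates, scheme = scoring_scheme()) {
  stopifnot(inherits(query, "coding_structure"))
  if (!length(candidates)) return(match_record(query))
  alns <- lapply(candidates, align_structures, a = query, scheme = scheme)
  scores <- vapply(alns, `[[`, numeric(1), "score")
  top <- which(scores == max(scores))
  if (length(top) > 1L) {
    src <- vapply(candidates[top], `[[`, character(1), "source")
    typ <- vapply(top, function(i) {
      if (alns[[i]]$is_colinear) classify_colinear(query, candidates[[i]]) else "NONE"
    }, character(1))
    acc <- vapply(candidates[top], `[[`, character(1), "accession")
    top <- top[order(match(src, c("CURATED", "PREDICTED")),
                     match_type_rank(typ), acc)]
  }
  win <- top[1L]
  type <- if (alns[[win]]$is_colinear) {
    classify_colinear(query, candidates[[win]])
  } else "NONE"
  match_record(query, candidates[[win]], type, scores[win])
}

# project, filter and deduplicate every gene of an index; returns
# per-gene structure lists plus a funnel of drop counts
prepare_structures <- function(index, verbose = FALSE) {
  stopifnot(inherits(index, "gene_index"))
  funnel <- c(transcripts = length(index$transcripts), non_coding = 0L,
              failed_filters = 0L, redundant = 0L, retained = 0L)
  genes <- lapply(index$genes, function(accs) {
    structs <- list()
    for (acc in accs) {
      t <- index$transcripts[[acc]]
      if (!is_coding(t)) {
        funnel["non_coding"] <<- funnel["non_coding"] + 1L
        next
      }
      cs <- project_cds(t)
      if (!passes_filters(cs)) {
        funnel["failed_filters"] <<- funnel["failed_filters"] + 1L
        next
      }
      structs[[length(structs) + 1L]] <- cs
    }
    if (!length(structs)) return(list())
    by_source <- split(structs, vapply(structs, `[[`, character(1), "source"))
    deduped <- unlist(lapply(by_source, dedup_transcripts), recursive = FALSE)
    funnel["redundant"] <<- funnel["redundant"] + length(structs) - length(deduped)
    funnel["retained"] <<- funnel["retained"] + length(deduped)
    unname(deduped)
  })
  if (verbose) {
    message(sprintf(paste0("prepare_structures: %d transcript(s); dropped %d ",
                           "non-coding, %d failing filters, %d redundant; %d retained"),
                    funnel["transcripts"], funnel["non_coding"],
                    funnel["failed_filters"], funnel["redundant"], funnel["retained"]))
  }
  list(genes = genes, stats = funnel)
}

classify_direction <- function(prep_q, prep_c, pairs_q, pairs_c, scheme,
                               include_predicted) {
  records <- vector("list", length(pairs_q))
  skipped <- 0L
  for (p in seq_along(pairs_q)) {
    qs <- prep_q$genes[[pairs_q[p]]]
    cs <- prep_c$genes[[pairs_c[p]]]
    if (is.null(qs) || is.null(cs)) {
      skipped <- skipped + 1L
      next
    }
    qs <- Filter(function(s) s$source == "CURATED", qs)
    if (!include_predicted) cs <- Filter(function(s) s$source == "CURATED", cs)
    if (!length(qs)) next
    records[[p]] <- do.call(rbind, lapply(qs, best_match, candidates = cs,
                                          scheme = scheme))
  }
  records <- records[!vapply(records, is.null, logical(1))]
  out <- if (length(records)) do.call(rbind, records) else empty_match_table()
  rownames(out) <- NULL
  list(records = out, skipped = skipped)
}

#' Classify a cohort of orthologous gene pairs
#'
#' Runs the full comparison in both directions. Queries are always
#' CURATED transcripts; PREDICTED transcripts only ever enlarge the
#' candidate set (when `include_predicted = TRUE`). Each index is
#' projected, filtered (at least four transcript exons and two internal
#' fully coding exons) and redundancy-collapsed before alignment. Pairs
#' referencing a gene absent from an index are counted as skipped, not
#' fatal.
#'
#' @param index_a,index_b [gene_index()] objects for the two species.
#' @param pairs Data.frame from [read_ortholog_pairs()] (columns
#'   `gene_a`, `gene_b`).
#' @param scheme A [scoring_scheme()].
#' @param include_predicted Use PREDICTED transcripts as candidates.
#' @param verbose Log the filtering funnel.
#' @return An object of class `cohort_result`: `matches_ab` and
#'   `matches_ba` (match-record data.frames), `summary` (a
#'   [cohort_summary()]), and the preparation funnels.
#' @export
classify_cohort <- function(index_a, index_b, pairs,
                            scheme = scoring_scheme(),
                            include_predicted = FALSE, verbose = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  prep_a <- prepare_structures(index_a, verbose = verbose)
  prep_b <- prepare_structures(index_b, verbose = verbose)
  ab <- classify_direction(prep_a, prep_b, pairs$gene_a, pairs$gene_b,
                           scheme, include_predicted)
  ba <- classify_direction(prep_b, prep_a, pairs$gene_b, pairs$gene_a,
                           scheme, include_predicted)
  summ <- cohort_summary(ab$records, ba$records, pairs,
                         skipped = max(ab$skipped, ba$skipped))
  structure(list(matches_ab = ab$records, matches_ba = ba$records,
                 summary = summ,
                 funnel_a = prep_a$stats, funnel_b = prep_b$stats),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d A->B and %d B->A transcript match record(s)\n",
              nrow(x$matches_ab), nrow(x$matches_ba)))
  print(x$summary)
  invisible(x)
}

count_by <- function(values, levels) {
  tab <- table(factor(values, levels = levels))
  data.frame(level = levels, n = as.integer(tab[levels]), row.names = NULL)
}

#' Summarize cohort match records
#'
#' Transcript-level counts by category and by match source for each
#' direction, plus gene-pair counts: per direction (strongest category
#' over the direction's queries of the pair) and best over both
#' directions. A gene pair with no analyzable transcript pair in either
#' direction is counted as unanalyzed.
#'
#' @param matches_ab,matches_ba Match-record data.frames.
#' @param pairs Ortholog pair data.frame.
#' @param skipped Number of pairs skipped for absent genes.
#' @return An object of class `cohort_summary`.
#' @export
cohort_summary <- function(matches_ab, matches_ba, pairs, skipped = 0L) {
  per_dir <- function(recs, direction) {
    ty <- count_by(recs$match_type, MATCH_TYPES)
    names(ty) <- c("match_type", "n")
    src <- count_by(recs$match_source, c("CURATED", "PREDICTED", "NONE"))
    names(src) <- c("match_source", "n")
    ty$direction <- direction; src$direction <- direction
    list(type = ty[, c("direction", "match_type", "n")],
         src = src[, c("direction", "match_source", "n")])
  }
  ab <- per_dir(matches_ab, "A->B")
  ba <- per_dir(matches_ba, "B->A")

  gene_best <- function(recs, gene_col) {
    if (!nrow(recs)) return(integer(0))
    tapply(match_type_rank(recs$match_type), recs[[gene_col]], min)
  }
  best_ab <- gene_best(matches_ab, "query_gene")       # keyed by gene_a
  best_ba <- gene_best(matches_ba, "query_gene")       # keyed by gene_b
  pair_rank <- rep(NA_integer_, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    r <- c(best_ab[pairs$gene_a[p]], best_ba[pairs$gene_b[p]])
    if (!all(is.na(r))) pair_rank[p] <- min(r, na.rm = TRUE)
  }
  gene_counts <- count_by(MATCH_TYPES[pair_rank[!is.na(pair_rank)]], MATCH_TYPES)
  names(gene_counts) <- c("match_type", "n_gene_pairs")
  gene_dir <- function(best, direction) {
    d <- count_by(MATCH_TYPES[best], MATCH_TYPES)
    names(d) <- c("match_type", "n_gene_pairs")
    d$direction <- direction
    d[, c("direction", "match_type", "n_gene_pairs")]
  }

  structure(list(
    transcript_counts = rbind(ab$type, ba$type),
    source_counts = rbind(ab$src, ba$src),
    gene_counts_best = gene_counts,
    gene_counts_by_direction = rbind(gene_dir(best_ab, "A->B"),
                                     gene_dir(best_ba, "B->A")),
    n_pairs = nrow(pairs),
    n_pairs_analyzed = sum(!is.na(pair_rank)),
    n_pairs_skipped = as.integer(skipped),
    n_transcripts_ab = nrow(matches_ab),
    n_transcripts_ba = nrow(matches_ba)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d gene pair(s), %d analyzed, %d skipped\n",
              x$n_pairs, x$n_pairs_analyzed, x$n_pairs_skipped))
  cat("gene pairs by best category over both directions:\n")
  print(x$gene_counts_best, row.names = FALSE)
  cat(sprintf("transcript-level records: %d (A->B), %d (B->A)\n",
              x$n_transcripts_ab, x$n_transcripts_ba))
  print(x$transcript_counts, row.names = FALSE)
  invisible(x)
}

# flat list view used by the JSON summary writer
summary_as_list <- function(s) {
  split_counts <- function(df, key) {
    out <- lapply(split(df, df$direction), function(d) {
      stats::setNames(as.list(d[[ncol(d)]]), d[[key]])
    })
    out
  }
  list(
    n_pairs = s$n_pairs,
    n_pairs_analyzed = s$n_pairs_analyzed,
    n_pairs_skipped = s$n_pairs_skipped,
    gene_pairs_best = stats::setNames(as.list(s$gene_counts_best$n_gene_pairs),
                                      s$gene_counts_best$match_type),
    gene_pairs_by_direction = split_counts(s$gene_counts_by_direction, "match_type"),
    transcripts_by_type = split_counts(s$transcript_counts, "match_type"),
    transcripts_by_source = split_counts(s$source_counts, "match_source")
  )
}
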