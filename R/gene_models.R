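# Domain types and file I/O for transcript gene models.
#
# Coordinates follow the UCSC genePred dialect throughout: 0-based,
# half-open [start, end) intervals, exons stored in ascending genomic
# order regardless of strand.

#' Construct and validate a transcript model
#'
#' A `transcript_model` is a single genomic transcript annotation: an
#' ordered set of exons, a CDS span, a strand and a source tag telling
#' curated annotations apart from computational predictions.
#'
#' All coordinates are 0-based half-open genomic positions. A
#' non-coding transcript is represented by `cds_start == cds_end`
#' (the genePred convention); coding transcripts must have both CDS
#' boundaries inside an exon, otherwise the annotation is rejected as
#' malformed (a CDS boundary inside an intron would corrupt the intron
#' phase arithmetic downstream).
#'
#' @param accession Transcript identifier, unique within an index.
#' @param gene_id Gene symbol the transcript belongs to.
#' @param chrom Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of equal length with
#'   ascending, non-overlapping exon intervals.
#' @param cds_start,cds_end CDS span (0-based half-open); equal for a
#'   non-coding transcript.
#' @param source `"CURATED"` or `"PREDICTED"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(accession, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start, cds_end,
                             source = c("CURATED", "PREDICTED")) {
  source <- match.arg(source)
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession),
            is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("transcript ", accession, ": strand must be '+' or '-'", call. = FALSE)
  }
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  n <- length(exon_starts)
  if (n == 0L || length(exon_ends) != n) {
    stop("transcript ", accession, ": exon start/end lists are empty or of unequal length",
         call. = FALSE)
  }
  if (any(exon_ends <= exon_starts)) {
    stop("transcript ", accession, ": every exon must have end > start", call. = FALSE)
  }
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))) {
    stop("transcript ", accession, ": exons must be ascending and non-overlapping",
         call. = FALSE)
  }
  if (cds_start > cds_end) {
    stop("transcript ", accession, ": cds_start > cds_end", call. = FALSE)
  }
  if (cds_start < cds_end) {
    if (cds_start < exon_starts[1L] || cds_end > exon_ends[n]) {
      stop("transcript ", accession, ": CDS span outside the transcript", call. = FALSE)
    }
    # boundary-in-exon check: start needs [s,e), end needs (s,e]
    if (!any(cds_start >= exon_starts & cds_start < exon_ends)) {
      stop("transcript ", accession, ": CDS start not exonic", call. = FALSE)
    }
    if (!any(cds_end > exon_starts & cds_end <= exon_ends)) {
      stop("transcript ", accession, ": CDS end not exonic", call. = FALSE)
    }
  }
  structure(
    list(accession = accession, gene_id = gene_id, chrom = as.character(chrom),
         strand = strand, exon_starts = exon_starts, exon_ends = exon_ends,
         cds_start = cds_start, cds_end = cds_end, source = source),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %s, %d exon(s), CDS [%d,%d), %s\n",
              x$accession, x$gene_id, x$chrom, x$strand,
              if (x$cds_start < x$cds_end) "coding" else "non-coding",
              length(x$exon_starts), x$cds_start, x$cds_end, x$source))
  invisible(x)
}

is_coding <- function(t) t$cds_start < t$cds_end

#' Build a gene index from transcript models
#'
#' A `gene_index` groups validated transcripts by gene symbol; every
#' transcript appears under exactly one gene and accessions are unique.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `gene_index` with elements `transcripts`
#'   (named by accession) and `genes` (gene_id -> character vector of
#'   accessions).
#' @export
gene_index <- function(transcripts = list()) {
  if (length(transcripts)) {
    stopifnot(all(vapply(transcripts, inherits, logical(1), "transcript_model")))
  }
  acc <- vapply(transcripts, `[[`, character(1), "accession")
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  names(transcripts) <- acc
  genes <- split(acc, vapply(transcripts, `[[`, character(1), "gene_id"))
  structure(list(transcripts = transcripts, genes = genes), class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("<gene_index> %d transcript(s) in %d gene(s)\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

#' @export
length.gene_index <- function(x) length(x$transcripts)

#' Transcripts of one gene
#'
#' @param index A [gene_index()].
#' @param gene_id Gene symbol.
#' @return List of `transcript_model` (empty if the gene is absent).
#' @export
gene_transcripts <- function(index, gene_id) {
  acc <- index$genes[[gene_id]]
  if (is.null(acc)) return(list())
  unname(index$transcripts[acc])
}

parse_comma_list <- function(s) {
  as.integer(strsplit(sub(",+$", "", s), ",", fixed = TRUE)[[1L]])
}

#' Read a genePred/refFlat-style gene model file
#'
#' Expects tab-separated lines with at least 11 fields: accession, gene
#' symbol, chromosome, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds. The exon lists are comma-separated
#' and may carry a trailing comma (UCSC convention). Lines starting
#' with `#` are skipped.
#'
#' genePred carries no provenance field, so the source tag is supplied
#' per file at load time.
#'
#' @param path Input file.
#' @param source_tag `"CURATED"` or `"PREDICTED"`, applied to every
#'   transcript in the file.
#' @return A [gene_index()].
#' @export
read_genepred <- function(path, source_tag = c("CURATED", "PREDICTED")) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  models <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) {
      stop("parse error at line ", i, ": expected >= 11 tab-separated fields, got ",
           length(f), call. = FALSE)
    }
    starts <- parse_comma_list(f[10L])
    ends <- parse_comma_list(f[11L])
    n_exp <- suppressWarnings(as.integer(f[9L]))
    if (is.na(n_exp) || anyNA(starts) || anyNA(ends)) {
      stop("parse error at line ", i, ": non-numeric exon fields", call. = FALSE)
    }
    if (n_exp != length(starts) || n_exp != length(ends)) {
      stop("validation error for accession ", f[1L],
           ": exonCount disagrees with exon lists", call. = FALSE)
    }
    k <- k + 1L
    models[[k]] <- transcript_model(
      accession = f[1L], gene_id = f[2L], chrom = f[3L], strand = f[4L],
      exon_starts = starts, exon_ends = ends,
      cds_start = as.integer(f[7L]), cds_end = as.integer(f[8L]),
      source = source_tag
    )
  }
  gene_index(models[seq_len(k)])
}

#' Write a gene index in genePred format
#'
#' Inverse of [read_genepred()]; the source tag is not serialized
#' (genePred has no field for it).
#'
#' @param index A [gene_index()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(index, path) {
  rows <- vapply(index$transcripts, function(t) {
    paste(t$accession, t$gene_id, t$chrom, t$strand,
          t$exon_starts[1L], t$exon_ends[length(t$exon_ends)],
          t$cds_start, t$cds_end, length(t$exon_starts),
          paste0(paste(t$exon_starts, collapse = ","), ","),
          paste0(paste(t$exon_ends, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(unname(rows), path)
  invisible(path)
}

#' Read an ortholog-pair table
#'
#' Two-column TSV mapping a species-A gene to its species-B ortholog.
#' An optional header row is detected (first row whose fields match
#' common column names or a `#` prefix). Exact duplicate rows are
#' collapsed; a gene participating in two different pairs violates the
#' 1:1 orthology assumption and is an error.
#'
#' @param path Input file.
#' @return A data.frame with columns `gene_a`, `gene_b`, in file order.
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(gene_a = character(), gene_b = character()))
  header_words <- c("gene_a", "gene_b", "gene", "gene_id", "human", "mouse",
                    "species_a", "species_b", "ortholog", "id")
  first <- tolower(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (startsWith(lines[[1L]], "#") || any(first %in% header_words)) {
    lines <- lines[-1L]
  }
  pairs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      stop("parse error at ortholog line ", i, ": expected two tab-separated gene IDs",
           call. = FALSE)
    }
    f[1:2]
  })
  m <- do.call(rbind, pairs)
  df <- data.frame(gene_a = m[, 1L], gene_b = m[, 2L])
  df <- df[!duplicated(df), , drop = FALSE]
  if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b)) {
    bad <- c(df$gene_a[duplicated(df$gene_a)], df$gene_b[duplicated(df$gene_b)])
    stop("non-unique ortholog mapping for: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

match_table_cols <- c("query_accession", "query_gene", "best_match_accession",
                      "best_match_gene", "match_source", "match_type",
                      "alignment_score")

#' Write a best-structural-match table
#'
#' One row per query transcript: its best-scoring structural
#' counterpart in the orthologous gene, the counterpart's source, the
#' assigned iso-orthology category, and the alignment score. Missing
#' counterparts are written as `NA`.
#'
#' @param records A data.frame of match records as produced by
#'   [best_match()]/[classify_cohort()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(records, path) {
  df <- as.data.frame(records)
  if (nrow(df) == 0L) {
    df <- data.frame(query_accession = character(), query_gene = character(),
                     best_match_accession = character(), best_match_gene = character(),
                     match_source = character(), match_type = character(),
                     alignment_score = numeric())
  }
  stopifnot(all(match_table_cols %in% names(df)))
  utils::write.table(df[match_table_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a match table written by [write_match_table()]
#'
#' @param path Input TSV.
#' @return A data.frame with the match-table columns.
#' @export
read_match_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(rep("character", 6L), "numeric"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  stopifnot(identical(names(df), match_table_cols))
  df
}
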