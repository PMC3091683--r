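# Projection of transcripts onto coding exon-intron structures.
#
# The unit of comparison downstream is not the transcript but its
# coding structure: the ordered coding-exon lengths (5'->3' in
# transcript orientation, partially coding external exons trimmed to
# their coding portion, fully non-coding exons dropped) together with
# the phase of each intron interrupting the CDS. The phase of the
# intron preceding coding exon i+1 is the cumulative coding length of
# exons 1..i modulo 3.

#' Construct a coding structure
#'
#' Usually produced by [project_cds()]; the constructor validates the
#' invariants so no inconsistent structure can enter the pipeline.
#'
#' @param accession Transcript identifier.
#' @param gene_id Gene symbol.
#' @param source `"CURATED"` or `"PREDICTED"`.
#' @param coding_lengths Positive integer vector: coding bp per coding
#'   exon, 5'->3' in transcript orientation.
#' @param phases Integer vector of length `length(coding_lengths) - 1`
#'   with values in `{0,1,2}`; `phases[i]` is the phase of the intron
#'   preceding coding exon `i + 1`. Derivable from `coding_lengths`
#'   and asserted against them.
#' @param n_internal_fully_coding Number of coding exons that are
#'   neither first nor last in the coding structure and whose whole
#'   transcript exon lies within the CDS.
#' @param total_exon_count Exon count of the parent transcript,
#'   including non-coding exons.
#' @return An object of class `coding_structure`.
#' @export
coding_structure <- function(accession, gene_id, source, coding_lengths, phases,
                             n_internal_fully_coding, total_exon_count) {
  coding_lengths <- as.integer(coding_lengths)
  phases <- as.integer(phases)
  n <- length(coding_lengths)
  stopifnot(n >= 1L, all(coding_lengths > 0L),
            length(phases) == n - 1L,
            all(phases %in% 0:2))
  expected <- cumsum(coding_lengths)[-n] %% 3L
  if (n > 1L && !identical(as.integer(expected), phases)) {
    stop("coding structure ", accession,
         ": stored phases disagree with cumulative coding lengths", call. = FALSE)
  }
  structure(
    list(accession = accession, gene_id = gene_id, source = source,
         coding_lengths = coding_lengths, phases = phases,
         n_internal_fully_coding = as.integer(n_internal_fully_coding),
         total_exon_count = as.integer(total_exon_count)),
    class = "coding_structure"
  )
}

#' @export
print.coding_structure <- function(x, ...) {
  n <- length(x$coding_lengths)
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <- sprintf("[%d]", x$coding_lengths)
  if (n > 1L) parts[seq(2L, 2L * n - 2L, by = 2L)] <- sprintf("-(%d)-", x$phases)
  cat(sprintf("<coding_structure> %s (%s, %s): %s\n", x$accession, x$gene_id,
              x$source, paste(parts, collapse = " ")))
  cat(sprintf("  %d coding exon(s), %d internal fully coding, %d transcript exon(s)\n",
              n, x$n_internal_fully_coding, x$total_exon_count))
  invisible(x)
}

#' Project a transcript onto its coding exon-intron structure
#'
#' Drops exons with no CDS overlap, trims the first and last retained
#' exons to their coding portion, and reports coding lengths 5'->3' in
#' transcript orientation (genomic order is reversed on the minus
#' strand). Intron phases are the cumulative coding lengths modulo 3.
#'
#' A coding length not divisible by 3 is accepted with a warning
#' (curated collections contain such records); the phase arithmetic is
#' unaffected.
#'
#' @param t A coding [transcript_model()].
#' @return A [coding_structure()].
#' @export
project_cds <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  if (!is_coding(t)) {
    stop("non-coding transcript: ", t$accession, call. = FALSE)
  }
  ov_start <- pmax(t$exon_starts, t$cds_start)
  ov_end <- pmin(t$exon_ends, t$cds_end)
  keep <- which(ov_end > ov_start)
  if (!length(keep)) stop("projection error: CDS overlaps no exon of ", t$accession,
                          call. = FALSE)
  lengths_genomic <- ov_end[keep] - ov_start[keep]
  # fully-coding means the whole transcript exon lies inside the CDS
  fully_genomic <- t$exon_starts[keep] >= t$cds_start & t$exon_ends[keep] <= t$cds_end
  if (t$strand == "-") {
    lengths <- rev(lengths_genomic)
    fully <- rev(fully_genomic)
  } else {
    lengths <- lengths_genomic
    fully <- fully_genomic
  }
  n <- length(lengths)
  internal <- if (n > 2L) fully[2:(n - 1L)] else logical(0)
  if (sum(lengths) %% 3L != 0L) {
    warning("CDS exonic length of ", t$accession, " (", sum(lengths),
            " bp) is not a multiple of 3", call. = FALSE)
  }
  coding_structure(
    accession = t$accession, gene_id = t$gene_id, source = t$source,
    coding_lengths = lengths,
    phases = if (n > 1L) cumsum(lengths)[-n] %% 3L else integer(0),
    n_internal_fully_coding = sum(internal),
    total_exon_count = length(t$exon_starts)
  )
}

#' Transcript filters for the orthology analysis
#'
#' A structure enters the comparison only if its parent transcript has
#' at least four exons (all exons, including untranslated ones) and the
#' coding structure has at least two internal fully coding exons.
#'
#' @param cs A [coding_structure()].
#' @return `TRUE` or `FALSE` with attribute `reason` naming the failed
#'   condition (`""` when passing).
#' @export
passes_filters <- function(cs) {
  stopifnot(inherits(cs, "coding_structure"))
  if (cs$total_exon_count < 4L) {
    return(structure(FALSE, reason = "fewer than four exons"))
  }
  if (cs$n_internal_fully_coding < 2L) {
    return(structure(FALSE, reason = "fewer than two internal fully coding exons"))
  }
  structure(TRUE, reason = "")
}

#' Redundancy signature of a coding structure
#'
#' The (size, frame) tuples of the internal coding exons, where the
#' frame of an exon is the phase of its preceding intron. Structures of
#' one gene sharing a signature carry the same internal coding
#' information and are collapsed by [dedup_transcripts()].
#'
#' @param cs A [coding_structure()].
#' @return A single string key, e.g. `"150/2;100/0"`; empty string for
#'   structures with no internal coding exon.
#' @export
dedup_signature <- function(cs) {
  n <- length(cs$coding_lengths)
  if (n <= 2L) return("")
  idx <- 2:(n - 1L)
  paste(sprintf("%d/%d", cs$coding_lengths[idx], cs$phases[idx - 1L]),
        collapse = ";")
}

#' Collapse redundant coding structures of one gene
#'
#' Structures sharing internal coding exons of the same size and
#' reading frame are represented by a single transcript: the one with
#' the greatest total coding length, ties broken by lexicographically
#' smallest accession. Output is ordered by accession for determinism.
#'
#' @param structures List of [coding_structure()] from one gene.
#' @return List with one representative per signature group.
#' @export
dedup_transcripts <- function(structures) {
  if (length(structures) <= 1L) return(structures)
  stopifnot(all(vapply(structures, inherits, logical(1), "coding_structure")))
  sig <- vapply(structures, dedup_signature, character(1))
  total <- vapply(structures, function(s) sum(s$coding_lengths), numeric(1))
  acc <- vapply(structures, `[[`, character(1), "accession")
  reps <- vapply(split(seq_along(structures), sig), function(idx) {
    best <- idx[total[idx] == max(total[idx])]
    best[order(acc[best])][1L]
  }, integer(1))
  out <- structures[reps]
  out[order(vapply(out, `[[`, character(1), "accession"))]
}

#' Write a debug dump of coding structures
#'
#' @param structures List of [coding_structure()].
#' @param path Output TSV with accession, gene, source, comma-joined
#'   coding lengths and phases, internal fully coding count and
#'   transcript exon count.
#' @return `path`, invisibly.
#' @export
write_structure_dump <- function(structures, path) {
  df <- data.frame(
    accession = vapply(structures, `[[`, character(1), "accession"),
    gene_id = vapply(structures, `[[`, character(1), "gene_id"),
    source = vapply(structures, `[[`, character(1), "source"),
    coding_lengths = vapply(structures, function(s)
      paste(s$coding_lengths, collapse = ","), character(1)),
    phases = vapply(structures, function(s)
      paste(s$phases, collapse = ","), character(1)),
    n_internal_fully_coding = vapply(structures, `[[`, integer(1),
                                     "n_internal_fully_coding"),
    total_exon_count = vapply(structures, `[[`, integer(1), "total_exon_count")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
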