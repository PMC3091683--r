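# Global alignment of coding exon-intron structures.
#
# Two coding structures are aligned column by column: a DIAG column
# pairs one exon of each structure, a MERGE column pairs 2..k_max
# adjacent exons of one structure with a single exon of the other
# (modelling an intron gained or lost since the species diverged), and
# a GAP column leaves one exon unpaired. The alignment is global: every
# exon of both structures is consumed exactly once, in order.
#
# Scoring is a transparent parametric scheme: exact length agreement
# earns s_max, each bp of length difference costs w up to a cap of
# d_cap bp, matching phases of the preceding introns earn b_phase, an
# unpaired exon costs g_gap and each merged intron boundary costs
# m_merge. The defaults make a single intron gain/loss cheaper than a
# gap pair but costlier than any colinear pairing, so colinear
# alignments win whenever exon counts agree and structures are similar.

#' Scoring scheme for structure alignment
#'
#' @param s_max Reward for a length-matched exon pair (score units).
#' @param w Penalty per bp of exon length difference.
#' @param d_cap Cap (bp) on the penalized length difference.
#' @param b_phase Bonus when both exons of a column are preceded by
#'   introns of equal phase; columns involving either first exon carry
#'   no bonus (there is no preceding intron within the CDS).
#' @param g_gap Penalty for an unpaired exon.
#' @param m_merge Penalty per merged intron boundary.
#' @param k_max Maximum exons mergeable into one column.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(s_max = 10, w = 0.1, d_cap = 100, b_phase = 2,
                           g_gap = 8, m_merge = 5, k_max = 3L) {
  stopifnot(s_max > 0, w >= 0, d_cap >= 0, b_phase >= 0,
            g_gap > 0, m_merge > 0, k_max >= 2L)
  structure(list(s_max = s_max, w = w, d_cap = d_cap, b_phase = b_phase,
                 g_gap = g_gap, m_merge = m_merge, k_max = as.integer(k_max)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(paste0("<scoring_scheme> s_max=%g w=%g/bp d_cap=%gbp ",
                     "b_phase=%g g_gap=%g m_merge=%g k_max=%d\n"),
              x$s_max, x$w, x$d_cap, x$b_phase, x$g_gap, x$m_merge, x$k_max))
  invisible(x)
}

#' Score of a single alignment column
#'
#' DIAG: `s_max - w * min(|la - lb|, d_cap) + b_phase` (bonus only if
#' `phase_ok`). MERGE of k exons: the DIAG formula applied to the
#' summed merged lengths versus the single exon, minus
#' `m_merge * (k - 1)`. GAP: `-g_gap`.
#'
#' @param kind `"DIAG"`, `"MERGE"` or `"GAP"`.
#' @param lengths_a Exon length(s) on the first side: one length for
#'   DIAG, 2..`k_max` lengths for MERGE; ignored for GAP.
#' @param length_b Single exon length on the other side; ignored for GAP.
#' @param phase_ok Whether the column's leading intron boundary has
#'   equal phase on both sides.
#' @param scheme A [scoring_scheme()].
#' @return Score in score units.
#' @export
column_score <- function(kind = c("DIAG", "MERGE", "GAP"), lengths_a = NULL,
                         length_b = NULL, phase_ok = FALSE,
                         scheme = scoring_scheme()) {
  kind <- match.arg(kind)
  if (kind == "GAP") return(-scheme$g_gap)
  if (kind == "DIAG" && length(lengths_a) != 1L) {
    stop("DIAG column takes exactly one length per side", call. = FALSE)
  }
  if (kind == "MERGE") {
    k <- length(lengths_a)
    if (k < 2L || k > scheme$k_max) {
      stop("MERGE column must merge 2..k_max exons", call. = FALSE)
    }
  }
  s <- scheme$s_max - scheme$w * min(abs(sum(lengths_a) - length_b), scheme$d_cap)
  if (isTRUE(phase_ok)) s <- s + scheme$b_phase
  if (kind == "MERGE") s <- s - scheme$m_merge * (length(lengths_a) - 1L)
  s
}

# phase comparability of a column whose leading exons are i (in a) and
# j (in b): both must have a preceding intron within the CDS
phase_ok_at <- function(i, j, phases_a, phases_b) {
  i >= 2L && j >= 2L && phases_a[i - 1L] == phases_b[j - 1L]
}

#' Align two coding structures
#'
#' Maximum-score global alignment under the scheme by dynamic
#' programming over exon prefixes, with merge moves of up to `k_max`
#' exons on either side. Traceback ties are broken deterministically:
#' DIAG over MERGE (side A before side B, fewer merged exons first)
#' over GAP on side A over GAP on side B.
#'
#' @param a,b [coding_structure()] objects.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `structure_alignment` with elements
#'   `columns` (list of columns with `kind` in DIAG/MERGE_A/MERGE_B/
#'   GAP_A/GAP_B, exon indices `a_idx`/`b_idx`, and `score`), total
#'   `score`, and `is_colinear` (`TRUE` iff every column is DIAG).
#' @export
align_structures <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(a, "coding_structure"), inherits(b, "coding_structure"))
  la <- a$coding_lengths; lb <- b$coding_lengths
  pa <- a$phases; pb <- b$phases
  n <- length(la); m <- length(lb)
  if (n == 0L || m == 0L) stop("cannot align an empty structure", call. = FALSE)
  kmax <- scheme$k_max

  S <- matrix(-Inf, n + 1L, m + 1L)
  move <- matrix("", n + 1L, m + 1L)   # move kind ending at (i,j)
  mk <- matrix(0L, n + 1L, m + 1L)     # merge width for MERGE moves
  S[1L, 1L] <- 0
  for (i in seq_len(n)) { S[i + 1L, 1L] <- -scheme$g_gap * i; move[i + 1L, 1L] <- "GAP_A" }
  for (j in seq_len(m)) { S[1L, j + 1L] <- -scheme$g_gap * j; move[1L, j + 1L] <- "GAP_B" }

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # candidates in tie-preference order; strict > keeps the first
      best <- S[i, j] + column_score("DIAG", la[i], lb[j],
                                     phase_ok_at(i, j, pa, pb), scheme)
      bmove <- "DIAG"; bk <- 0L
      for (k in 2:kmax) {
        if (i - k >= 0L) {
          i0 <- i - k + 1L
          sc <- S[i - k + 1L, j] +
            column_score("MERGE", la[i0:i], lb[j],
                         phase_ok_at(i0, j, pa, pb), scheme)
          if (sc > best) { best <- sc; bmove <- "MERGE_A"; bk <- k }
        }
      }
      for (k in 2:kmax) {
        if (j - k >= 0L) {
          j0 <- j - k + 1L
          sc <- S[i, j - k + 1L] +
            column_score("MERGE", lb[j0:j], la[i],
                         phase_ok_at(i, j0, pa, pb), scheme)
          if (sc > best) { best <- sc; bmove <- "MERGE_B"; bk <- k }
        }
      }
      sc <- S[i, j + 1L] - scheme$g_gap
      if (sc > best) { best <- sc; bmove <- "GAP_A"; bk <- 0L }
      sc <- S[i + 1L, j] - scheme$g_gap
      if (sc > best) { best <- sc; bmove <- "GAP_B"; bk <- 0L }
      S[i + 1L, j + 1L] <- best
      move[i + 1L, j + 1L] <- bmove
      mk[i + 1L, j + 1L] <- bk
    }
  }

  # traceback
  cols <- list()
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    mv <- move[i + 1L, j + 1L]
    col <- switch(mv,
      DIAG = {
        sc <- column_score("DIAG", la[i], lb[j], phase_ok_at(i, j, pa, pb), scheme)
        out <- list(kind = "DIAG", a_idx = i, b_idx = j, score = sc)
        i <- i - 1L; j <- j - 1L; out
      },
      MERGE_A = {
        k <- mk[i + 1L, j + 1L]; i0 <- i - k + 1L
        sc <- column_score("MERGE", la[i0:i], lb[j],
                           phase_ok_at(i0, j, pa, pb), scheme)
        out <- list(kind = "MERGE_A", a_idx = i0:i, b_idx = j, score = sc)
        i <- i0 - 1L; j <- j - 1L; out
      },
      MERGE_B = {
        k <- mk[i + 1L, j + 1L]; j0 <- j - k + 1L
        sc <- column_score("MERGE", lb[j0:j], la[i],
                           phase_ok_at(i, j0, pa, pb), scheme)
        out <- list(kind = "MERGE_B", a_idx = i, b_idx = j0:j, score = sc)
        i <- i - 1L; j <- j0 - 1L; out
      },
      GAP_A = {
        out <- list(kind = "GAP_A", a_idx = i, b_idx = integer(0),
                    score = -scheme$g_gap)
        i <- i - 1L; out
      },
      GAP_B = {
        out <- list(kind = "GAP_B", a_idx = integer(0), b_idx = j,
                    score = -scheme$g_gap)
        j <- j - 1L; out
      },
      stop("internal error: broken traceback", call. = FALSE)
    )
    cols[[length(cols) + 1L]] <- col
  }
  cols <- rev(cols)
  structure(
    list(columns = cols, score = S[n + 1L, m + 1L],
         is_colinear = all(vapply(cols, `[[`, character(1), "kind") == "DIAG")),
    class = "structure_alignment"
  )
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat(sprintf("<structure_alignment> score %.6g, %d column(s), %s\n",
              x$score, length(x$columns),
              if (x$is_colinear) "colinear" else "not colinear"))
  invisible(x)
}

#' Render an alignment as two rows of exon lengths
#'
#' A log-friendly plain-text view: `|` marks a length-identical DIAG
#' column, `~` a DIAG column with differing lengths, `+` joins merged
#' exon lengths, and `-` marks a gap.
#'
#' @param alignment A `structure_alignment`.
#' @param a,b The aligned [coding_structure()] objects.
#' @return A single string with three lines (row A, markers, row B).
#' @export
render_alignment <- function(alignment, a, b) {
  cell <- function(v) if (length(v)) paste(v, collapse = "+") else "-"
  top <- mid <- bot <- character(length(alignment$columns))
  for (idx in seq_along(alignment$columns)) {
    col <- alignment$columns[[idx]]
    ta <- cell(a$coding_lengths[col$a_idx])
    tb <- cell(b$coding_lengths[col$b_idx])
    mk <- switch(col$kind,
                 DIAG = if (identical(a$coding_lengths[col$a_idx],
                                      b$coding_lengths[col$b_idx])) "|" else "~",
                 MERGE_A = , MERGE_B = "+",
                 "-")
    wd <- max(nchar(ta), nchar(tb), nchar(mk))
    top[idx] <- formatC(ta, width = wd)
    mid[idx] <- formatC(mk, width = wd)
    bot[idx] <- formatC(tb, width = wd)
  }
  paste(paste(top, collapse = " "), paste(mid, collapse = " "),
        paste(bot, collapse = " "), sep = "\n")
}

#' Exhaustive-enumeration alignment oracle
#'
#' Enumerates every global alignment (with merges up to `k_max`) of two
#' small structures and returns the maximum score. Exponential in exon
#' count; intended as an independent check of [align_structures()] on
#' structures of at most `max_exons` exons.
#'
#' @param a,b [coding_structure()] objects.
#' @param scheme A [scoring_scheme()].
#' @param max_exons Size guard (default 6).
#' @return Best achievable score (numeric scalar).
#' @export
enumerate_alignments <- function(a, b, scheme = scoring_scheme(), max_exons = 6L) {
  stopifnot(inherits(a, "coding_structure"), inherits(b, "coding_structure"))
  la <- a$coding_lengths; lb <- b$coding_lengths
  if (length(la) > max_exons || length(lb) > max_exons) {
    stop("structure too large for exhaustive enumeration", call. = FALSE)
  }
  pa <- a$phases; pb <- b$phases
  n <- length(la); m <- length(lb)
  kmax <- scheme$k_max
  rec <- function(i, j) {
    # best score aligning exons i..n of a with j..m of b
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, column_score("DIAG", la[i], lb[j],
                                     phase_ok_at(i, j, pa, pb), scheme) +
                    rec(i + 1L, j + 1L))
      for (k in 2:kmax) {
        if (i + k - 1L <= n) {
          best <- max(best, column_score("MERGE", la[i:(i + k - 1L)], lb[j],
                                         phase_ok_at(i, j, pa, pb), scheme) +
                        rec(i + k, j + 1L))
        }
        if (j + k - 1L <= m) {
          best <- max(best, column_score("MERGE", lb[j:(j + k - 1L)], la[i],
                                         phase_ok_at(i, j, pa, pb), scheme) +
                        rec(i + 1L, j + k))
        }
      }
    }
    if (i <= n) best <- max(best, -scheme$g_gap + rec(i + 1L, j))
    if (j <= m) best <- max(best, -scheme$g_gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}
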