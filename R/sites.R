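# Position-level Psi evidence: locus-normalized coverage tracks, paired
# log2 fold-change metaplots around known sites, and the CMC/Mn2+
# mismatch/deletion site caller.

aln_span <- function(alignments) {
  # reference footprint of each alignment; deletions consume reference
  len <- nchar(alignments$sequence) + alignments$n_del
  cbind(start = alignments$start, end = alignments$start + len)
}

#' Per-base coverage over one locus
#'
#' @param alignments Alignment data.frame ([map_reads()] output), filtered
#'   to placements on `ref`; `count` weights each record.
#' @param ref Reference name.
#' @param ref_length Locus length in bases.
#' @param normalize Divide by the total coverage across the locus, so the
#'   track sums to 1 (comparable between libraries of different depth).
#' @return Numeric vector of length `ref_length` (a coverage track); the
#'   `normalized` attribute records the flag.
#' @export
locus_coverage <- function(alignments, ref, ref_length, normalize = TRUE) {
  depth <- numeric(ref_length)
  al <- alignments[alignments$ref == ref, , drop = FALSE]
  if (nrow(al)) {
    sp <- aln_span(al)
    for (i in seq_len(nrow(al))) {
      idx <- (sp[i, "start"] + 1L):min(sp[i, "end"], ref_length)
      depth[idx] <- depth[idx] + al$count[i]
    }
  }
  if (normalize) {
    tot <- sum(depth)
    if (tot == 0) {
      warning("zero total coverage on ", ref, ": returning all-zero track")
    } else {
      depth <- depth / tot
    }
  }
  attr(depth, "normalized") <- normalize
  depth
}

#' Per-base paired log2 fold change between two coverage tracks
#'
#' @param track_a,track_b Same-locus coverage tracks (normalized), e.g.
#'   IP/unbound or CMC/mock.
#' @param pseudocount Added to both tracks so zero-coverage positions stay
#'   finite.
#' @return Numeric vector `log2((a + c) / (b + c))`.
#' @export
paired_log2fc_track <- function(track_a, track_b, pseudocount = 1e-6) {
  if (length(track_a) != length(track_b)) {
    stop("tracks have different lengths", call. = FALSE)
  }
  log2((track_a + pseudocount) / (track_b + pseudocount))
}

roll_mean <- function(x, S) {
  if (S <= 1L) return(x)
  n <- length(x)
  half_l <- (S - 1L) %/% 2L
  half_r <- S - 1L - half_l
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half_l):min(n, i + half_r)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
}

#' Metaplot of a track around a list of sites
#'
#' Extracts windows of `+/- halfwidth` bases around each site (site at
#' offset 0), averages column-wise across sites, and smooths with a
#' centered moving average of `smooth` bases. Sites closer than `halfwidth`
#' to a locus edge contribute truncated windows and are counted.
#'
#' @param track Numeric track (e.g. a [paired_log2fc_track()]).
#' @param sites Integer vector of 0-based site positions.
#' @param halfwidth Window half-width W (default 25, as in the TE analysis;
#'   use 50 with `smooth = 12` for broader regions).
#' @param smooth Smoothing window S (default 6).
#' @return Data.frame `offset` (-W..W), `mean` (smoothed), `raw_mean`,
#'   `n_sites` contributing per column; `n_truncated` attribute.
#' @export
site_metaplot <- function(track, sites, halfwidth = 25L, smooth = 6L) {
  if (!length(sites)) stop("empty site list", call. = FALSE)
  W <- as.integer(halfwidth)
  n <- length(track)
  mat <- vapply(sites, function(p) {
    idx <- (p - W):(p + W) + 1L
    v <- rep(NA_real_, 2L * W + 1L)
    ok <- idx >= 1L & idx <= n
    v[ok] <- track[idx[ok]]
    v
  }, numeric(2L * W + 1L))
  mat <- matrix(mat, nrow = 2L * W + 1L)
  raw <- rowMeans(mat, na.rm = TRUE)
  n_sites <- rowSums(!is.na(mat))
  out <- data.frame(offset = (-W):W, mean = roll_mean(raw, smooth),
                    raw_mean = raw, n_sites = n_sites)
  attr(out, "n_truncated") <- sum(vapply(sites, function(p) {
    p - W < 0L || p + W >= n
  }, logical(1)))
  out
}

#' Per-position mismatch and deletion pileup
#'
#' Counts, at every reference position, the reads covering it, the reads
#' carrying a substitution there, and the reads with a deletion there
#' (deletions consume the reference, so a deleted position still counts as
#' covered).
#'
#' @param alignments Alignment data.frame with edit `ops`.
#' @param ref Reference name.
#' @param ref_length Locus length.
#' @return A `MismatchProfile` data.frame: `ref`, `pos` (0-based), `total`,
#'   `mismatch`, `deletion`.
#' @export
mismatch_profile <- function(alignments, ref, ref_length) {
  total <- mism <- dele <- numeric(ref_length)
  al <- alignments[alignments$ref == ref, , drop = FALSE]
  if (nrow(al)) {
    sp <- aln_span(al)
    for (i in seq_len(nrow(al))) {
      idx <- (sp[i, "start"] + 1L):min(sp[i, "end"], ref_length)
      total[idx] <- total[idx] + al$count[i]
      ops <- al$ops[[i]]
      if (nrow(ops)) {
        mm <- ops$ref_pos[ops$type == "mismatch"] + 1L
        dl <- ops$ref_pos[ops$type == "deletion"] + 1L
        mism[mm] <- mism[mm] + al$count[i]
        dele[dl] <- dele[dl] + al$count[i]
      }
    }
  }
  data.frame(ref = ref, pos = seq_len(ref_length) - 1L,
             total = total, mismatch = mism, deletion = dele,
             stringsAsFactors = FALSE)
}

#' Call Psi sites from treated vs mock mismatch profiles
#'
#' At every position with at least `min_reads` treated coverage, the pooled
#' mismatch+deletion ratio in the treated library is compared with the mock
#' ratio (mock gets a `(x + 0.5) / (n + 1)` pseudocount so unmutated mock
#' positions do not divide by zero); the position is called when the ratio
#' fold change is at least `min_fc`.
#'
#' @param treated,mock [mismatch_profile()]s of the same reference.
#' @param min_reads Treated coverage gate (default 5).
#' @param min_fc Treated/mock ratio fold-change threshold (default 1.5;
#'   a fold change exactly at the threshold passes).
#' @return A `PsiCall` data.frame: `ref`, `pos`, `evidence` (`"mismatch"`),
#'   `statistic` (the ratio fold change), `ratio_treated`, `ratio_mock`,
#'   `passed`. Rows are the evaluated positions only (treated coverage gate).
#' @export
call_mismatch_sites <- function(treated, mock, min_reads = 5L,
                                min_fc = 1.5) {
  if (!identical(treated$ref[1], mock$ref[1]) ||
      nrow(treated) != nrow(mock)) {
    stop("profiles are not from the same reference", call. = FALSE)
  }
  ev <- treated$total >= min_reads
  rt <- (treated$mismatch + treated$deletion) / treated$total
  rm_ <- (mock$mismatch + mock$deletion + 0.5) / (mock$total + 1)
  fc <- rt / rm_
  out <- data.frame(ref = treated$ref, pos = treated$pos,
                    evidence = "mismatch", statistic = fc,
                    ratio_treated = rt, ratio_mock = rm_,
                    passed = ev & fc >= min_fc,
                    stringsAsFactors = FALSE)
  out[ev, , drop = FALSE]
}

#' Per-feature mismatch-ratio calls
#'
#' The published criterion can also be read per feature rather than per
#' position: for each reference the fraction of reads carrying any
#' mismatch/deletion is compared between treated and mock with the same
#' coverage gate and fold-change rule.
#'
#' @param treated_aln,mock_aln Alignment data.frames.
#' @param min_reads,min_fc As in [call_mismatch_sites()].
#' @return Data.frame: `ref`, `reads_treated`, `ratio_treated`,
#'   `ratio_mock`, `statistic`, `passed`.
#' @export
call_mismatch_features <- function(treated_aln, mock_aln, min_reads = 5L,
                                   min_fc = 1.5) {
  summarize <- function(al) {
    dt <- data.table::data.table(ref = al$ref, count = al$count,
                                 has_ev = vapply(al$ops, nrow, 1L) > 0L)
    dt[, list(total = sum(count), with_ev = sum(count[has_ev])), by = "ref"]
  }
  t_ <- summarize(treated_aln)
  m_ <- summarize(mock_aln)
  merged <- merge(t_, m_, by = "ref", all.x = TRUE, suffixes = c("_t", "_m"))
  merged[is.na(merged$total_m), c("total_m", "with_ev_m")] <- 0L
  rt <- merged$with_ev_t / merged$total_t
  rm_ <- (merged$with_ev_m + 0.5) / (merged$total_m + 1)
  data.frame(ref = merged$ref, reads_treated = merged$total_t,
             ratio_treated = rt, ratio_mock = rm_, statistic = rt / rm_,
             passed = merged$total_t >= min_reads & rt / rm_ >= min_fc,
             stringsAsFactors = FALSE)
}

#' Map calls to their distance from the miRNA ends
#'
#' Each call is assigned to the mature annotation containing it and
#' summarized by its distance to the nearer end (5' or 3'); a call at
#' offset 0 from either end is terminal, anything else internal. Calls
#' outside every mature annotation are bucketed as unannotated.
#'
#' @param calls `PsiCall` data.frame (rows with `passed` are used).
#' @param mature Annotation data.frame restricted to mature miRNA features
#'   (0-based half-open intervals).
#' @return A list: `per_call` (call, feature, distance, end, location) and
#'   `freq` (counts by distance x end).
#' @export
terminal_position_summary <- function(calls, mature) {
  calls <- calls[calls$passed, , drop = FALSE]
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    hit <- which(mature$ref == calls$ref[i] &
                 mature$start <= calls$pos[i] & calls$pos[i] < mature$end)
    if (!length(hit)) {
      return(data.frame(ref = calls$ref[i], pos = calls$pos[i],
                        feature = NA_character_, distance = NA_integer_,
                        end = NA_character_, location = "unannotated",
                        stringsAsFactors = FALSE))
    }
    a <- mature[hit[1], ]
    d5 <- calls$pos[i] - a$start
    d3 <- (a$end - 1L) - calls$pos[i]
    end <- if (d5 <= d3) "five_prime" else "three_prime"
    data.frame(ref = calls$ref[i], pos = calls$pos[i], feature = a$name,
               distance = min(d5, d3), end = end,
               location = if (min(d5, d3) == 0L) "terminal" else "internal",
               stringsAsFactors = FALSE)
  })
  per_call <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref = character(0), pos = integer(0), feature = character(0),
               distance = integer(0), end = character(0),
               location = character(0))
  ann <- per_call[per_call$location != "unannotated", , drop = FALSE]
  freq <- as.data.frame(table(distance = ann$distance, end = ann$end),
                        stringsAsFactors = FALSE)
  freq$distance <- as.integer(freq$distance)
  list(per_call = per_call, freq = freq)
}
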