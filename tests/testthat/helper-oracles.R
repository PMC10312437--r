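# Independent oracles used by the test suite. These deliberately share no
# code with the package internals: the alignment oracle is an exhaustive
# cumulative-sum scan over every window start (not the package's banded DP),
# and the sequence helpers are re-derived from first principles.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

# All placements of `read` on one forward reference string with <= max_mm
# mismatches and <= max_del (0 or 1) internal reference deletions; per
# start, the fewest-edits-then-fewest-deletions alignment is kept.
oracle_scan_one <- function(read, refseq, max_mm, max_del) {
  rc <- strsplit(refseq, "")[[1]]
  qc <- strsplit(read, "")[[1]]
  m <- length(qc); n <- length(rc)
  ns <- n - m + 1L
  if (ns < 1L) return(NULL)
  s_idx <- seq_len(ns)
  # mismatches with no deletion: accumulate over read positions
  mm0 <- numeric(ns)
  for (j in seq_len(m)) mm0 <- mm0 + (rc[s_idx + j - 1L] != qc[j])
  best_mm <- mm0
  best_d <- integer(ns)
  if (max_del >= 1L && n - m >= 1L) {
    ns1 <- n - m      # placements consuming m + 1 reference bases
    if (ns1 >= 1L) {
      s1 <- seq_len(ns1)
      # prefix mismatches P[t, s]: read[1..t] vs ref[s..], suffix S[t, s]:
      # read[t+1..m] vs ref shifted by one (deletion after read base t)
      P <- matrix(0, nrow = m, ncol = ns1)
      acc <- numeric(ns1)
      for (j in seq_len(m)) {
        acc <- acc + (rc[s1 + j - 1L] != qc[j])
        P[j, ] <- acc
      }
      S <- matrix(0, nrow = m, ncol = ns1)
      acc <- numeric(ns1)
      for (j in m:1) {
        S[j, ] <- acc
        acc <- acc + (rc[s1 + j] != qc[j])
      }
      # deletion strictly internal: t in 1..m-1
      tot1 <- P[1, ] + S[1, ]
      for (t in 2:(m - 1L)) tot1 <- pmin(tot1, P[t, ] + S[t, ])
      upd <- tot1 <= max_mm &
        (tot1 + 1 < best_mm[s1] + best_d[s1] | best_mm[s1] > max_mm)
      best_mm[s1][upd] <- tot1[upd]
      best_d[s1][upd] <- 1L
    }
  }
  ok <- best_mm <= max_mm
  if (!any(ok)) return(NULL)
  data.frame(start = which(ok) - 1L, n_mm = as.integer(best_mm[ok]),
             n_del = best_d[ok])
}

oracle_map <- function(read, refs, max_mm, max_del) {
  rows <- list()
  for (st in c("+", "-")) {
    q <- if (st == "+") read else oracle_revcomp(read)
    for (nm in names(refs)) {
      hits <- oracle_scan_one(q, refs[[nm]], max_mm, max_del)
      if (!is.null(hits) && nrow(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref = nm, start = hits$start, strand = st, n_mm = hits$n_mm,
          n_del = hits$n_del, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$ref, out$start, out$strand), , drop = FALSE]
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_read <- function(read, n_sub = 0L, n_del = 0L) {
  ch <- strsplit(read, "")[[1]]
  if (n_sub > 0L) {
    pos <- sample(seq_along(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  if (n_del > 0L) {
    # internal reference deletion = remove a read-internal base is the
    # read-side view used to *construct* a deleted read from the reference
    pos <- sample(2:(length(ch) - 1L), n_del)
    ch <- ch[-pos]
  }
  paste(ch, collapse = "")
}
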