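# Loci-scale read alignment tolerant of modification-induced edits.
#
# References here are individual loci (an rRNA locus, tRNAs, miRNA
# precursors, TE copies), not genomes, so the aligner enumerates every
# placement of a read on every reference with at most `max_mismatch`
# substitutions and `max_deletion` reference deletions (the CMC/Mn2+
# chemistry produces mismatches and deletions; insertions are not modeled).
# A banded DP over (read position x deletions used) runs vectorized across
# all window starts of a reference, so the search is exhaustive -- every
# reported placement is provably within the edit budget and none is missed.
# Deletions are internal (flanked by read-aligned bases on both sides);
# a terminal deletion is the same alignment as a shifted start.

#' Mapping policy
#'
#' @param max_mismatch Maximum substitutions per placement (0-3).
#' @param max_deletion Maximum reference deletions per placement (0-2).
#' @param multimap `"all"` reports every best-tier placement, `"unique_only"`
#'   discards reads with more than one equally good placement, and
#'   `"best_random"` picks one of the best at random (seeded by the caller's
#'   RNG stream).
#' @param both_strands Search the minus strand as well.
#' @return A `map_policy` list.
#' @export
map_policy <- function(max_mismatch = 1L, max_deletion = 1L,
                       multimap = c("all", "unique_only", "best_random"),
                       both_strands = TRUE) {
  multimap <- match.arg(multimap)
  stopifnot(max_mismatch >= 0L, max_mismatch <= 3L,
            max_deletion >= 0L, max_deletion <= 2L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 max_deletion = as.integer(max_deletion),
                 multimap = multimap, both_strands = both_strands),
            class = "map_policy")
}

#' Build an alignment index over a reference set
#'
#' Stores the reference byte arrays used by the placement scan together with
#' an exact k-mer -> position map over both strands (minus-strand positions
#' give the forward coordinate of the k-mer's first base).
#'
#' @param ref A `reference_set` or a named character vector of sequences.
#' @param k Seed length; reads shorter than `k` are reported unmapped.
#' @return An `align_index` list.
#' @export
build_index <- function(ref, k = 12L) {
  if (inherits(ref, "reference_set")) ref <- ref$sequences
  stopifnot(is.character(ref), k > 0L)
  k <- as.integer(k)
  kmers <- list()
  for (nm in names(ref)) {
    s <- ref[[nm]]
    n <- nchar(s)
    if (n >= k) {
      starts <- seq_len(n - k + 1L)
      fwd <- substring(s, starts, starts + k - 1L)
      rc <- substring(revcomp(s), starts, starts + k - 1L)
      kmers[[length(kmers) + 1L]] <- data.table::data.table(
        kmer = c(fwd, rc), ref = nm,
        pos = c(starts - 1L, n - starts - k + 1L),
        strand = rep(c("+", "-"), each = length(starts)))
    }
  }
  kt <- if (length(kmers)) data.table::rbindlist(kmers) else {
    data.table::data.table(kmer = character(0), ref = character(0),
                           pos = integer(0), strand = character(0))
  }
  data.table::setkey(kt, kmer)
  # concatenated byte array with separator gaps longer than any read, so a
  # single vectorized scan covers every reference at once and no placement
  # can straddle two references
  gap <- 64L
  bytes <- lapply(ref, utf8ToInt)
  lens <- lengths(bytes)
  offsets <- cumsum(c(0L, lens + gap))[seq_along(bytes)]
  cat_vec <- rep.int(0L, sum(lens) + gap * length(bytes))
  for (i in seq_along(bytes)) {
    cat_vec[offsets[i] + seq_len(lens[i])] <- bytes[[i]]
  }
  structure(list(k = k, sequences = ref, bytes = bytes,
                 cat = cat_vec, gap = gap,
                 bounds = data.frame(ref = names(ref), offset = offsets,
                                     len = lens, stringsAsFactors = FALSE),
                 kmers = kt),
            class = "align_index")
}

#' Look up exact k-mer hits in an index
#' @param index An `align_index`.
#' @param kmer A k-mer string.
#' @return data.table of `ref`, `pos` (0-based first-base forward
#'   coordinate), `strand`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  ..query <- kmer
  hits <- index$kmers[index$kmers$kmer == ..query, ]
  hits[, c("ref", "pos", "strand")]
}

# Exhaustive scan of one read byte-vector against a reference byte-vector:
# thin wrapper over the compiled DP kernel (one alignment per window start:
# fewest edits, then fewest deletions).
scan_ref <- function(rb, refb, MM, D) {
  if (length(refb) < length(rb)) return(NULL)
  refpad <- c(refb, rep.int(0L, D))  # sentinel never matches a base
  out <- scan_concat_cpp(as.integer(rb), as.integer(refpad), MM, D)
  if (!nrow(out)) return(NULL)
  out
}

# Reconstruct edit ops (leftmost-optimal deletion placement) for one chosen
# placement by a small DP with traceback.
edit_ops <- function(rb, refb, start0, d_used, read_chars) {
  m <- length(rb)
  if (d_used == 0L) {
    ref_off <- start0 + seq_len(m) - 1L
    mm <- which(refb[ref_off + 1L] != rb)
    return(data.frame(ref_pos = ref_off[mm], type = rep("mismatch", length(mm)),
                      read_base = read_chars[mm], stringsAsFactors = FALSE))
  }
  D <- d_used
  cost <- matrix(Inf, nrow = m + 1L, ncol = D + 1L)
  from_del <- matrix(FALSE, nrow = m + 1L, ncol = D + 1L)
  cost[1L, 1L] <- 0
  for (j in seq_len(m)) {
    for (d in 0:D) {
      if (j >= 2L && j <= m && d >= 1L && cost[j, d] < cost[j, d + 1L]) {
        cost[j, d + 1L] <- cost[j, d]
        from_del[j, d + 1L] <- TRUE
      }
      rp <- start0 + (j - 1L) + d
      cost[j + 1L, d + 1L] <- cost[j, d + 1L] + (refb[rp + 1L] != rb[j])
    }
  }
  ops <- list()
  j <- m; d <- D
  while (j >= 1L) {
    rp <- start0 + (j - 1L) + d
    if (refb[rp + 1L] != rb[j]) {
      ops[[length(ops) + 1L]] <- data.frame(
        ref_pos = rp, type = "mismatch", read_base = read_chars[j],
        stringsAsFactors = FALSE)
    }
    j <- j - 1L
    while (j >= 1L && d >= 1L && from_del[j + 1L, d + 1L]) {
      ops[[length(ops) + 1L]] <- data.frame(
        ref_pos = start0 + j + d - 1L, type = "deletion", read_base = "",
        stringsAsFactors = FALSE)
      d <- d - 1L
    }
  }
  if (!length(ops)) {
    return(data.frame(ref_pos = integer(0), type = character(0),
                      read_base = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rev(ops))
  out[order(out$ref_pos), , drop = FALSE]
}

#' Map a single read against an index
#'
#' Enumerates all placements within the policy's edit budget on both strands
#' (minus-strand placements align the read's reverse complement against the
#' forward reference; edit ops are reported in forward reference
#' coordinates), keeps the minimal-edit tier first, and applies the
#' multimapping policy.
#'
#' @param read Read sequence (character scalar).
#' @param index An `align_index` from [build_index()].
#' @param policy A [map_policy()].
#' @return A data.frame of `AlignmentRecord`s: `ref`, `start` (0-based),
#'   `strand`, `n_mm`, `n_del`, `edits`, `n_hits` (number of equally good
#'   placements before the multimap policy), and a list column `ops`
#'   (data.frames of `ref_pos`, `type`, `read_base`). Zero rows when
#'   unmapped; the `reason` attribute says why (`"short"`, `"no_hit"`,
#'   `"multimapper"`).
#' @export
map_read <- function(read, index, policy = map_policy()) {
  stopifnot(inherits(index, "align_index"))
  empty <- function(reason) {
    out <- data.frame(ref = character(0), start = integer(0),
                      strand = character(0), n_mm = integer(0),
                      n_del = integer(0), edits = integer(0),
                      n_hits = integer(0))
    out$ops <- list()
    attr(out, "reason") <- reason
    out
  }
  if (nchar(read) < index$k) return(empty("short"))
  strands <- if (policy$both_strands) c("+", "-") else "+"
  qb_of <- qc_of <- list()
  cand <- list()
  for (st in strands) {
    q <- if (st == "+") read else revcomp(read)
    qb_of[[st]] <- utf8ToInt(q)
    qc_of[[st]] <- strsplit(q, "", fixed = TRUE)[[1]]
    sc <- scan_ref(qb_of[[st]], index$cat, policy$max_mismatch,
                   policy$max_deletion)
    if (is.null(sc)) next
    # map concatenated-scan starts back to (ref, local start); placements
    # overhanging a separator gap are off-reference and dropped
    ri <- findInterval(sc$start, index$bounds$offset)
    local <- sc$start - index$bounds$offset[ri]
    within <- local + length(qb_of[[st]]) + sc$n_del <= index$bounds$len[ri]
    if (!any(within)) next
    cand[[st]] <- data.frame(
      ref = index$bounds$ref[ri[within]], start = local[within],
      strand = st, n_mm = sc$n_mm[within], n_del = sc$n_del[within],
      edits = sc$n_mm[within] + sc$n_del[within],
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty("no_hit"))
  out <- do.call(rbind, cand)
  out <- out[order(out$edits, out$ref, out$start), , drop = FALSE]
  n_best <- sum(out$edits == out$edits[1L])
  out$n_hits <- n_best
  rownames(out) <- NULL
  keep <- switch(policy$multimap,
    all = seq_len(nrow(out)),
    unique_only = if (n_best > 1L) integer(0) else 1L,
    best_random = sample.int(n_best, 1L))
  if (!length(keep)) return(empty("multimapper"))
  out <- out[keep, , drop = FALSE]
  out$ops <- lapply(seq_len(nrow(out)), function(i) {
    st <- out$strand[i]
    edit_ops(qb_of[[st]], index$bytes[[out$ref[i]]], out$start[i],
             out$n_del[i], qc_of[[st]])
  })
  rownames(out) <- NULL
  out[, c("ref", "start", "strand", "n_mm", "n_del", "edits", "n_hits",
          "ops")]
}

#' Map a collapsed read table
#'
#' @param collapsed Data.frame with `sequence` and `count` columns (or a
#'   character vector of sequences, counted once each).
#' @param index An `align_index`.
#' @param policy A [map_policy()].
#' @return A data.frame with one row per (sequence, placement): columns of
#'   [map_read()] plus `sequence` and `count`. Unmapped sequences are
#'   tallied in the `unmapped` attribute by reason.
#' @export
map_reads <- function(collapsed, index, policy = map_policy()) {
  if (is.character(collapsed)) {
    collapsed <- data.frame(sequence = collapsed, count = 1L,
                            stringsAsFactors = FALSE)
  }
  res <- list()
  unmapped <- c(short = 0L, no_hit = 0L, multimapper = 0L)
  for (i in seq_len(nrow(collapsed))) {
    al <- map_read(collapsed$sequence[i], index, policy)
    if (!nrow(al)) {
      r <- attr(al, "reason")
      unmapped[r] <- unmapped[r] + collapsed$count[i]
      next
    }
    al$sequence <- collapsed$sequence[i]
    al$count <- collapsed$count[i]
    res[[length(res) + 1L]] <- al
  }
  out <- if (length(res)) do.call(rbind, res) else {
    al <- map_read(strrep("A", index$k), build_index(c(x = "C"), k = 1L),
                   map_policy(0L, 0L))  # typed empty frame
    al$sequence <- character(0); al$count <- integer(0)
    al
  }
  attr(out, "unmapped") <- unmapped
  out
}

## ---- SAM -------------------------------------------------------------------

ops_to_cigar <- function(ops, start0, read_len) {
  if (!nrow(ops) || !any(ops$type == "deletion")) {
    return(paste0(read_len, "M"))
  }
  del <- sort(ops$ref_pos[ops$type == "deletion"])
  cig <- character(0)
  cur <- start0
  consumed <- 0L
  for (dp in del) {
    mlen <- dp - cur
    cig <- c(cig, paste0(mlen, "M"), "1D")
    consumed <- consumed + mlen
    cur <- dp + 1L
  }
  cig <- c(cig, paste0(read_len - consumed, "M"))
  paste(cig, collapse = "")
}

#' Write alignments to a SAM file
#'
#' Emits 1-based SAM records (internal coordinates are 0-based half-open)
#' with CIGAR, NM and MD tags, so externally produced SAM can round-trip
#' through [read_sam()].
#'
#' @param alignments Output of [map_reads()].
#' @param ref Named character vector (or `reference_set`) for the header.
#' @param path Output path.
#' @export
write_sam <- function(alignments, ref, path) {
  if (inherits(ref, "reference_set")) ref <- ref$sequences
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(ref)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(ref[[nm]])), con)
  }
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    seq_out <- if (a$strand == "+") a$sequence else revcomp(a$sequence)
    ops <- a$ops[[1]]
    cigar <- ops_to_cigar(ops, a$start, nchar(a$sequence))
    md <- md_tag(ops, a$start, nchar(a$sequence))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tMD:Z:%s\tXC:i:%d",
                       sprintf("seq%d", i), if (a$strand == "+") 0L else 16L,
                       a$ref, a$start + 1L, cigar, seq_out,
                       a$n_mm + a$n_del, md, a$count), con)
  }
  invisible(path)
}

md_tag <- function(ops, start0, read_len) {
  # MD describes the reference bases at mismatches/deletions, which we do
  # not retain in ops; emit matched-run structure with placeholder base N
  # when the op table lacks reference bases (sufficient for round-tripping
  # positions and types).
  ev <- ops[order(ops$ref_pos), , drop = FALSE]
  md <- character(0)
  cur <- start0
  for (i in seq_len(nrow(ev))) {
    run <- ev$ref_pos[i] - cur
    base <- if (!is.null(ev$ref_base)) ev$ref_base[i] else "N"
    if (ev$type[i] == "mismatch") {
      md <- c(md, as.character(run), base)
    } else {
      md <- c(md, as.character(run), paste0("^", base))
    }
    cur <- ev$ref_pos[i] + 1L
  }
  ndel <- sum(ev$type == "deletion")
  tail_run <- start0 + read_len + ndel - cur
  paste(c(md, as.character(tail_run)), collapse = "")
}

parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-ZN]+|[A-ZN]", md))[[1]]
  out <- list(); off <- 0L
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      off <- off + as.integer(t)
    } else if (startsWith(t, "^")) {
      for (b in strsplit(substring(t, 2L), "")[[1]]) {
        out[[length(out) + 1L]] <- data.frame(off = off, type = "deletion",
                                              ref_base = b)
        off <- off + 1L
      }
    } else {
      out[[length(out) + 1L]] <- data.frame(off = off, type = "mismatch",
                                            ref_base = t)
      off <- off + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(off = integer(0), type = character(0), ref_base = character(0))
}

#' Read alignments from a SAM file
#'
#' Ingests externally produced SAM in place of the built-in aligner; edit
#' ops are reconstructed from CIGAR (M/D, plus S clips which are trimmed)
#' and the MD tag.
#'
#' @param path SAM path.
#' @return Alignment data.frame compatible with [map_reads()] output.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    start0 <- as.integer(f[4]) - 1L
    seq_fwd <- f[10]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f, value = TRUE)[1])
    cnt <- grep("^XC:i:", f, value = TRUE)
    count <- if (length(cnt)) as.integer(sub("^XC:i:", "", cnt[1])) else 1L
    ops <- data.frame(ref_pos = integer(0), type = character(0),
                      read_base = character(0), stringsAsFactors = FALSE)
    if (!is.na(md) && nzchar(md)) {
      ev <- parse_md(md)
      if (nrow(ev)) {
        read_off <- ev$off - cumsum(ev$type == "deletion") +
          (ev$type == "deletion")  # read base index for mismatches only
        rb <- ifelse(ev$type == "mismatch",
                     substring(seq_fwd, ev$off + 1L -
                                 c(0L, cumsum(ev$type == "deletion"))[
                                   seq_len(nrow(ev))],
                               ev$off + 1L -
                                 c(0L, cumsum(ev$type == "deletion"))[
                                   seq_len(nrow(ev))]), "")
        ops <- data.frame(ref_pos = start0 + ev$off, type = ev$type,
                          read_base = rb, stringsAsFactors = FALSE)
      }
    }
    n_del <- sum(ops$type == "deletion")
    n_mm <- sum(ops$type == "mismatch")
    row <- data.frame(ref = f[3], start = start0, strand = strand,
                      n_mm = n_mm, n_del = n_del, edits = n_mm + n_del,
                      n_hits = 1L, stringsAsFactors = FALSE)
    row$ops <- list(ops)
    row$sequence <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
    row$count <- count
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
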