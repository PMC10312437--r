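# FASTQ preprocessing: adapter trimming, kit-dialect random-base removal,
# length/quality filtering, and collapsing to unique sequences with counts.

#' Preprocessing filter policy
#'
#' @param adapter3 3' adapter sequence to trim.
#' @param dialect `"NEB"` or `"NextFlex"`; the NextFlex dialect strips the
#'   4 random nucleotides from both ends of the insert after adapter removal.
#' @param min_len,max_len Retained insert length window (nt).
#' @param min_q Phred threshold; set `min_q = 0` to disable the quality
#'   filter (length-only filtering).
#' @param q_frac Fraction of bases required to be `>= min_q`.
#' @param min_overlap Minimum adapter/read overlap to accept a trim.
#' @param drop_unmatched Discard reads in which no adapter was found
#'   (default keeps them intact).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(adapter3 = "AGATCGGAAGAGCACACGTC",
                          dialect = c("NEB", "NextFlex"),
                          min_len = 18L, max_len = 30L,
                          min_q = 0L, q_frac = 0.9,
                          min_overlap = 6L, drop_unmatched = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(min_len <= max_len, q_frac >= 0, q_frac <= 1, min_overlap >= 1)
  structure(list(adapter3 = adapter3, dialect = dialect,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_q = as.integer(min_q), q_frac = q_frac,
                 min_overlap = as.integer(min_overlap),
                 drop_unmatched = drop_unmatched),
            class = "filter_policy")
}

#' Named preprocessing presets
#'
#' Length windows used by the different analysis arms: `rrna` 15-30 nt,
#' `te` 18-30 nt, `mirna` (miRNA/siRNA enrichment) 20-25 nt, `mn2`
#' (CMC/Mn2+ mismatch analysis) 18-42 nt, and `mouse` 14-44 nt with the
#' Q20-over-90% quality requirement.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [filter_policy()].
#' @return A `filter_policy`.
#' @export
preset_policy <- function(name = c("rrna", "te", "mirna", "mn2", "mouse"),
                          ...) {
  name <- match.arg(name)
  args <- switch(name,
    rrna = list(min_len = 15L, max_len = 30L),
    te = list(min_len = 18L, max_len = 30L),
    mirna = list(min_len = 20L, max_len = 25L),
    mn2 = list(min_len = 18L, max_len = 42L),
    mouse = list(min_len = 14L, max_len = 44L, min_q = 20L, q_frac = 0.9))
  do.call(filter_policy, utils::modifyList(args, list(...)))
}

# Locate the adapter suffix in each read: the earliest position p (1-based
# insert length + 1) such that read[p..] matches a prefix of the adapter,
# with at most one mismatch when the overlap is >= 10 and none below that.
# Earliest position = longest adapter match. Returns 0-based insert lengths,
# or -1 where no adapter was found.
locate_adapter <- function(seqs, adapter, min_overlap) {
  lens <- nchar(seqs)
  res <- rep.int(-1L, length(seqs))
  todo <- seq_along(seqs)
  la <- nchar(adapter)
  for (p in 0:max(0L, max(lens) - min_overlap)) {
    if (!length(todo)) break
    cand <- todo[lens[todo] - p >= min_overlap]
    if (!length(cand)) next
    ov <- pmin(lens[cand] - p, la)
    # substring(), not substr(): the bounds vary per read
    tail_ <- substring(seqs[cand], p + 1L, p + ov)
    apre <- substring(adapter, 1L, ov)
    exact <- tail_ == apre
    # pigeonhole for the <=1 mismatch case: one half must match exactly
    near <- !exact & ov >= 10L
    if (any(near)) {
      h <- ov %/% 2L
      half1 <- substring(seqs[cand], p + 1L, p + h) ==
        substring(adapter, 1L, h)
      half2 <- substring(seqs[cand], p + h + 1L, p + ov) ==
        substring(adapter, h + 1L, ov)
      check <- near & (half1 | half2)
      if (any(check)) {
        mm <- mapply(function(a, b) {
          sum(utf8ToInt(a) != utf8ToInt(b))
        }, tail_[check], apre[check])
        ok <- logical(length(cand)); ok[check] <- mm <= 1L
        exact <- exact | ok
      }
    }
    hit <- cand[exact]
    res[hit] <- p
    todo <- setdiff(todo, hit)
  }
  res
}

#' Trim the 3' adapter (and kit random bases) from reads
#'
#' Removes the longest read suffix matching a prefix of the configured
#' adapter (minimum overlap `min_overlap`, one mismatch tolerated when the
#' overlap is at least 10 nt). Under the NextFlex dialect 4 nt are then
#' stripped from both ends of the insert. Reads with no adapter hit are kept
#' intact unless `drop_unmatched`; reads that are empty after trimming are
#' discarded.
#'
#' @param reads A data.frame with `sequence` and optionally `quality` and
#'   `id` columns (as returned by [read_fastq()]), or a character vector.
#' @param policy A [filter_policy()].
#' @return A list: `reads` (trimmed data.frame) and `discarded` (named
#'   integer vector of per-reason discard counts).
#' @export
trim_adapter <- function(reads, policy) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, stringsAsFactors = FALSE)
  }
  stopifnot(inherits(policy, "filter_policy"))
  has_q <- !is.null(reads$quality)
  pos <- locate_adapter(reads$sequence, policy$adapter3, policy$min_overlap)
  matched <- pos >= 0L
  ins_len <- ifelse(matched, pos, nchar(reads$sequence))
  out <- reads
  out$sequence <- substr(reads$sequence, 1L, ins_len)
  if (has_q) out$quality <- substr(reads$quality, 1L, ins_len)
  if (policy$dialect == "NextFlex") {
    L <- nchar(out$sequence)
    out$sequence <- substr(out$sequence, 5L, pmax(0L, L - 4L))
    if (has_q) out$quality <- substr(out$quality, 5L, pmax(0L, L - 4L))
  }
  discard <- rep(FALSE, nrow(out))
  reason <- character(0)
  if (policy$drop_unmatched) discard <- discard | !matched
  empty <- nchar(out$sequence) == 0L
  discarded <- c(no_adapter = if (policy$drop_unmatched) sum(!matched) else 0L,
                 empty_after_trim = sum(empty & !discard))
  discard <- discard | empty
  list(reads = out[!discard, , drop = FALSE], discarded = discarded)
}

#' Length- and quality-filter trimmed reads
#'
#' Retains reads whose insert length lies in `[min_len, max_len]` and, when
#' the policy carries a quality requirement, in which at least `q_frac` of
#' bases are `>= min_q` (e.g. Q20 over 90% of the read).
#'
#' @inheritParams trim_adapter
#' @return A list: `reads` and per-reason `discarded` counts.
#' @export
filter_reads <- function(reads, policy) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, stringsAsFactors = FALSE)
  }
  stopifnot(inherits(policy, "filter_policy"))
  L <- nchar(reads$sequence)
  len_ok <- L >= policy$min_len & L <= policy$max_len
  q_ok <- rep(TRUE, nrow(reads))
  if (policy$min_q > 0L && !is.null(reads$quality)) {
    qv <- phred_vectors(reads$quality)
    frac <- sum(qv >= policy$min_q) / pmax(1L, lengths(qv))
    q_ok <- frac >= policy$q_frac
  }
  keep <- len_ok & q_ok
  list(reads = reads[keep, , drop = FALSE],
       discarded = c(length = sum(!len_ok),
                     quality = sum(len_ok & !q_ok)))
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads Data.frame with a `sequence` column or a character vector.
#' @param sample Optional sample id attached to every record.
#' @return A data.frame of `CollapsedRead`s: `sequence`, `count` (and
#'   `sample` if given), ordered by decreasing count. Total counts equal the
#'   number of input reads.
#' @export
collapse_reads <- function(reads, sample = NULL) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (!length(seqs)) {
    out <- data.frame(sequence = character(0), count = integer(0))
  } else {
    tab <- table(seqs)
    out <- data.frame(sequence = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(sample)) out$sample <- if (nrow(out)) sample else character(0)
  out
}

#' Run the full preprocessing chain on one FASTQ file
#'
#' trim -> filter -> collapse, with conservation bookkeeping.
#'
#' @param path FASTQ path.
#' @param policy A [filter_policy()].
#' @param sample Sample id stored in the collapsed table.
#' @return A list: `collapsed` (data.frame), `n_input`, `discarded` (named
#'   counts; input = kept + discarded).
#' @export
preprocess_fastq <- function(path, policy, sample = basename(path)) {
  raw <- read_fastq(path)
  tr <- trim_adapter(raw, policy)
  fl <- filter_reads(tr$reads, policy)
  list(collapsed = collapse_reads(fl$reads, sample = sample),
       n_input = nrow(raw),
       n_kept = nrow(fl$reads),
       discarded = c(tr$discarded, fl$discarded))
}

#' Write a collapsed read table as FASTA
#'
#' Headers follow the `>seq{i}_x{count}` convention of collapsed small RNA
#' FASTA files.
#' @param collapsed Data.frame from [collapse_reads()].
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  seqs <- stats::setNames(collapsed$sequence,
                          sprintf("seq%d_x%d", seq_len(nrow(collapsed)),
                                  collapsed$count))
  write_fasta(path, seqs)
}
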