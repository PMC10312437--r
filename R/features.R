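# Biological feature classification and aggregation: tRNA-fragment anatomy,
# TE-family x size-class tables, repeat/piRNA-cluster categories, Argonaute
# preference, terminal-nucleotide bias and size distributions.

#' Classify a tRNA-aligned read as a tRNA fragment
#'
#' Anchoring decides the class: a fragment starting at the tRNA 5' end is a
#' 5'-tRF, one ending at the 3' terminus (the CCA tail) a 3'-tRF, anything
#' else internal. `spans_psi55` asks whether the alignment footprint covers
#' canonical position 55 (the T-loop Psi, 22 nt upstream of the 3' end of a
#' standard 76-nt CCA-tailed tRNA); `has_UNUAR` whether the read sequence
#' contains the U-N-U-A-R motif.
#'
#' @param alignment One alignment row (on a tRNA reference).
#' @param trna The tRNA's annotation row (`class == "tRNA"`).
#' @param psi55 0-based reference index of position 55; defaults to the
#'   standard-numbering position, 22 nt upstream of the 3' end.
#' @param tolerance Allowed slack (nt) in the 3'-terminus anchoring
#'   (default 0: the exact terminus is required).
#' @return One-row `TRFRecord` data.frame: `sequence`, `parent`, `isotype`,
#'   `class`, `has_cca`, `spans_psi55`, `has_unuar`, `length`.
#' @export
classify_trf <- function(alignment, trna, psi55 = trna$end - 22L,
                         tolerance = 0L) {
  if (trna$class != "tRNA") {
    stop("classify_trf requires a tRNA feature, got '", trna$class, "'",
         call. = FALSE)
  }
  span_end <- alignment$start + nchar(alignment$sequence) + alignment$n_del
  cls <- if (alignment$start == trna$start) "five_prime"
    else if (abs(span_end - trna$end) <= tolerance) "three_prime"
    else "internal"
  data.frame(
    sequence = alignment$sequence, parent = trna$name,
    isotype = trna$family, class = cls,
    has_cca = cls == "three_prime" && endsWith(alignment$sequence, "CCA"),
    spans_psi55 = alignment$start <= psi55 && psi55 < span_end,
    has_unuar = length(find_unuar(alignment$sequence)) > 0L,
    length = nchar(alignment$sequence), stringsAsFactors = FALSE)
}

#' Classify every tRNA-mapped read in an alignment table
#'
#' @param alignments Alignment data.frame ([map_reads()]).
#' @param annotation Annotation data.frame; only `class == "tRNA"` rows are
#'   used, matched by reference name.
#' @param ... Passed to [classify_trf()].
#' @return Data.frame of `TRFRecord`s, one per tRNA-mapped alignment, with
#'   `count` carried over.
#' @export
classify_trfs <- function(alignments, annotation, ...) {
  trnas <- annotation[annotation$class == "tRNA", , drop = FALSE]
  keep <- alignments$ref %in% trnas$ref
  al <- alignments[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(al)), function(i) {
    rec <- classify_trf(al[i, ], trnas[match(al$ref[i], trnas$ref), ], ...)
    rec$count <- al$count[i]
    rec
  })
  if (!length(out)) {
    return(data.frame(sequence = character(0), parent = character(0),
                      isotype = character(0), class = character(0),
                      has_cca = logical(0), spans_psi55 = logical(0),
                      has_unuar = logical(0), length = integer(0),
                      count = integer(0)))
  }
  do.call(rbind, out)
}

#' Aggregate TE-mapped reads into family x size-class counts
#'
#' A read contributes to the family of every TE copy it hits, but only once
#' per family even when it hits several copies (multimapping within a
#' family is collapsed); with `fractional = TRUE` a read hitting n distinct
#' families contributes 1/n to each. Reads outside both size classes are
#' excluded.
#'
#' @param alignments Alignment data.frame.
#' @param annotation Annotation data.frame; `class == "TE"` rows carry the
#'   family label.
#' @param size_classes Named list of closed length intervals (defaults:
#'   `small` 20-22 nt, `large` 23-25 nt).
#' @param fractional Use 1/n-family weights instead of once-per-family.
#' @return A `SizeClassTable` data.frame: `family`, `size_class`, `count`.
#' @export
aggregate_te_families <- function(alignments, annotation,
                                  size_classes = list(small = c(20L, 22L),
                                                      large = c(23L, 25L)),
                                  fractional = FALSE) {
  te <- annotation[annotation$class == "TE", , drop = FALSE]
  if (!nrow(alignments) || !nrow(te)) {
    return(data.frame(family = character(0), size_class = character(0),
                      count = numeric(0)))
  }
  sp <- aln_span(alignments)
  agr <- GenomicRanges::GRanges(alignments$ref,
                                IRanges::IRanges(sp[, "start"] + 1L,
                                                 sp[, "end"]))
  tgr <- annotation_granges(te)
  ov <- GenomicRanges::findOverlaps(agr, tgr)
  if (!length(ov)) {
    return(data.frame(family = character(0), size_class = character(0),
                      count = numeric(0)))
  }
  hits <- data.table::data.table(
    sequence = alignments$sequence[S4Vectors::queryHits(ov)],
    count = alignments$count[S4Vectors::queryHits(ov)],
    len = nchar(alignments$sequence[S4Vectors::queryHits(ov)]),
    family = te$family[S4Vectors::subjectHits(ov)])
  hits <- unique(hits, by = c("sequence", "family"))
  size_of <- function(L) {
    for (nm in names(size_classes)) {
      r <- size_classes[[nm]]
      if (L >= r[1] && L <= r[2]) return(nm)
    }
    NA_character_
  }
  hits$size_class <- vapply(hits$len, size_of, character(1))
  hits <- hits[!is.na(hits$size_class), ]
  if (fractional) {
    nfam <- hits[, list(nf = data.table::uniqueN(family)), by = "sequence"]
    hits <- merge(hits, nfam, by = "sequence")
    hits$w <- hits$count / hits$nf
  } else {
    hits$w <- as.numeric(hits$count)
  }
  out <- hits[, list(count = sum(w)), by = c("family", "size_class")]
  as.data.frame(out[order(out$family, out$size_class)])
}

#' Argonaute preference per TE family and size class
#'
#' The preferred Argonaute is the one with the highest IP/input enrichment;
#' exact ties are broken lexicographically by AGO name and flagged, and a
#' family with a single informative AGO is flagged uncontested.
#'
#' @param enrichment Data.frame: `family`, `size_class`, `ago`,
#'   `enrichment` (one row per combination; NA values are ignored).
#' @return Data.frame: `family`, `size_class`, `preferred`, `flag`
#'   (`""`, `"tie"`, `"uncontested"`, or `"none"`).
#' @export
ago_preference <- function(enrichment) {
  dt <- data.table::as.data.table(enrichment)
  pick <- function(ago, value) {
    ok <- !is.na(value)
    if (!any(ok)) return(list(preferred = "none", flag = "none"))
    ago <- ago[ok]; value <- value[ok]
    if (length(ago) == 1L) return(list(preferred = ago, flag = "uncontested"))
    top <- value == max(value)
    winners <- sort(ago[top])
    list(preferred = winners[1],
         flag = if (sum(top) > 1L) "tie" else "")
  }
  out <- dt[, pick(ago, enrichment), by = c("family", "size_class")]
  as.data.frame(out)
}

#' Categorize non-tRF reads by repeat class and piRNA cluster
#'
#' Applies the stated precedence: a read overlapping a transposon interval
#' is `"transposon"`, otherwise one overlapping a structural RNA (tRNA,
#' rRNA, snoRNA, snRNA) is `"structural"`, otherwise `"neither"`. Cluster
#' membership requires at least 1 bp overlap with a piRNA-cluster interval.
#' tRFs are expected to have been removed upstream (via [classify_trfs()]).
#'
#' @param alignments Alignment data.frame.
#' @param annotation Annotation data.frame supplying `TE` (transposon),
#'   structural-RNA and `piRNA_cluster` features.
#' @return Data.frame per read: `sequence`, `count`, `category`, `cluster`
#'   (cluster name or NA).
#' @export
categorize_repeats <- function(alignments, annotation) {
  structural_classes <- c("tRNA", "rRNA", "snoRNA", "snRNA")
  if (!nrow(alignments)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      category = character(0), cluster = character(0)))
  }
  sp <- aln_span(alignments)
  agr <- GenomicRanges::GRanges(alignments$ref,
                                IRanges::IRanges(sp[, "start"] + 1L,
                                                 sp[, "end"]))
  hit_any <- function(classes) {
    sub <- annotation[annotation$class %in% classes, , drop = FALSE]
    res <- rep(NA_character_, nrow(alignments))
    if (!nrow(sub)) return(res)
    ov <- GenomicRanges::findOverlaps(agr, annotation_granges(sub),
                                      minoverlap = 1L)
    if (length(ov)) {
      first <- !duplicated(S4Vectors::queryHits(ov))
      res[S4Vectors::queryHits(ov)[first]] <-
        sub$name[S4Vectors::subjectHits(ov)[first]]
    }
    res
  }
  te_hit <- hit_any("TE")
  st_hit <- hit_any(structural_classes)
  cl_hit <- hit_any("piRNA_cluster")
  per_aln <- data.table::data.table(
    sequence = alignments$sequence, count = alignments$count,
    is_te = !is.na(te_hit), is_st = !is.na(st_hit), cluster = cl_hit)
  out <- per_aln[, list(
    count = count[1],
    category = if (any(is_te)) "transposon" else if (any(is_st))
      "structural" else "neither",
    cluster = if (any(!is.na(cluster))) cluster[!is.na(cluster)][1]
      else NA_character_), by = "sequence"]
  as.data.frame(out)
}

#' Terminal nucleotide bias of a sequence set against a background
#'
#' Frequencies of the 5' and 3' base in the foreground and background sets
#' (count-weighted when counts are given) and the per-base log2 enrichment
#' with a pseudocount. Structural-RNA-derived sequences must be excluded
#' from both sets beforehand; passing their sequences via `structural`
#' enforces this.
#'
#' @param a,b Foreground and background: character vectors of sequences or
#'   data.frames with `sequence` and `count`.
#' @param structural Optional character vector of structural-RNA-derived
#'   sequences; an error is raised if any appears in `a` or `b`.
#' @param pseudocount Added to every base count before frequencies.
#' @return Data.frame: `end` (`five_prime`/`three_prime`), `base` (RNA
#'   alphabet), `freq_a`, `freq_b`, `log2_enrichment`.
#' @export
terminal_nt_bias <- function(a, b, structural = NULL, pseudocount = 0.5) {
  unpack <- function(x) {
    if (is.character(x)) {
      data.frame(sequence = x, count = rep(1L, length(x)),
                 stringsAsFactors = FALSE)
    } else x
  }
  a <- unpack(a); b <- unpack(b)
  if (!nrow(a) || !nrow(b)) stop("empty sequence set", call. = FALSE)
  if (!is.null(structural)) {
    bad <- intersect(c(a$sequence, b$sequence), structural)
    if (length(bad)) {
      stop("structural-RNA-derived sequences present; filter them first (",
           length(bad), " offending)", call. = FALSE)
    }
  }
  endfreq <- function(x, side) {
    base <- if (side == "five_prime") substr(x$sequence, 1L, 1L) else
      substring(x$sequence, nchar(x$sequence))
    cnt <- vapply(DNA_BASES, function(bb) sum(x$count[base == bb]),
                  numeric(1)) + pseudocount
    cnt / sum(cnt)
  }
  rows <- lapply(c("five_prime", "three_prime"), function(side) {
    fa <- endfreq(a, side); fb <- endfreq(b, side)
    data.frame(end = side, base = as_rna(DNA_BASES), freq_a = fa,
               freq_b = fb, log2_enrichment = log2(fa / fb),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read-length histogram and mode of a feature subset
#'
#' @param lengths Integer vector of read lengths (e.g. of significantly
#'   CMC-depleted 3'-tRFs); usually `nchar()` of the selected sequences.
#' @param weights Optional weights (e.g. read counts); default 1 each.
#' @return A list: `histogram` (data.frame `length`, `count`), `mode`
#'   (smallest length at the maximum; NA when empty) and `tie` flag.
#' @export
size_distribution <- function(lengths, weights = NULL) {
  if (!length(lengths)) {
    return(list(histogram = data.frame(length = integer(0),
                                       count = numeric(0)),
                mode = NA_integer_, tie = FALSE))
  }
  if (is.null(weights)) weights <- rep(1, length(lengths))
  dt <- data.table::data.table(length = as.integer(lengths), w = weights)
  hist <- dt[, list(count = sum(w)), by = "length"]
  data.table::setorder(hist, length)
  top <- hist$count == max(hist$count)
  list(histogram = as.data.frame(hist),
       mode = hist$length[which(top)[1]],
       tie = sum(top) > 1L)
}
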