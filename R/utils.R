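# Shared low-level helpers: RNG stream derivation, sequence utilities,
# FASTQ/FASTA/BED/TSV input-output.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a per-sample RNG seed from a master seed and a sample name
#'
#' Every stochastic stage draws from its own RNG stream derived from the
#' master seed and a string label, so individual samples can be regenerated
#' without replaying the whole simulation.
#'
#' @param seed Master integer seed.
#' @param name Character label (e.g. sample name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # FNV-1a over the label bytes, folded with the master seed; kept in
  # 32-bit signed range because R seeds are 32-bit integers.
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste(name, collapse = "/"))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(seed) * 69621 + h) %% 2147483646)
}

#' @keywords internal
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(derive_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 1L) {
    # byte-level fast path for per-read calls in the aligner
    b <- rev(utf8ToInt(x))
    comp <- integer(128)
    comp[utf8ToInt("ACGTNacgtn")] <- utf8ToInt("TGCANtgcan")
    return(intToUtf8(comp[b]))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Render a DNA-space sequence in RNA space
#'
#' Internally everything is stored in the DNA alphabet (T); user-facing
#' reports and motif displays use U.
#' @param x Character vector.
#' @return `x` with T replaced by U.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Scan a sequence for UNUAR motifs
#'
#' The UNUAR motif is U-N-U-A-R (R a purine) in RNA space; the central
#' (third-position) U is the pseudouridylated base. Matches may overlap.
#'
#' @param seq A single DNA-alphabet sequence (T for U).
#' @return Integer vector of 0-based indices of the modified U (third motif
#'   position); empty if no motif is present.
#' @export
find_unuar <- function(seq) {
  stopifnot(length(seq) == 1L)
  m <- gregexpr("T(?=[ACGT]TA[AG])", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L + 2L
}

## ---- FASTQ / FASTA ---------------------------------------------------------

#' Write reads to a FASTQ file
#' @param path Output path.
#' @param id,sequence,quality Equal-length character vectors.
#' @export
write_fastq <- function(path, id, sequence, quality) {
  stopifnot(length(id) == length(sequence), length(sequence) == length(quality))
  dna <- Biostrings::DNAStringSet(sequence)
  names(dna) <- id
  # Biostrings warns when width metadata is dropped on write; harmless here
  suppressWarnings(
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quality)))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path (gzip allowed).
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @keywords internal
phred_vectors <- function(quality) {
  q <- Biostrings::PhredQuality(quality)
  as(q, "IntegerList")
}

write_fasta <- function(path, sequences) {
  dna <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

## ---- annotations (BED6) ----------------------------------------------------

#' Convert a feature annotation table to GRanges
#'
#' Annotations are plain data.frames with 0-based half-open coordinates and
#' columns `name, ref, start, end, strand, class, family`.
#' @param ann Annotation data.frame.
#' @return A [GenomicRanges::GRanges] with `name`, `class`, `family` metadata.
#' @export
annotation_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$ref,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    name = ann$name, class = ann$class, family = ann$family)
}

#' Write annotations as BED6
#'
#' The BED name field packs `name|class|family`; family is recovered as the
#' text after the last pipe on import.
#' @param ann Annotation data.frame (see [annotation_granges()]).
#' @param path Output BED path.
#' @export
write_annotation_bed <- function(ann, path) {
  gr <- annotation_granges(ann)
  gr$name <- paste(ann$name, ann$class, ann$family, sep = "|")
  gr$score <- 0L
  gr$class <- NULL
  gr$family <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read annotations from BED6
#' @param path BED path.
#' @return Annotation data.frame with 0-based half-open coordinates.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  cls <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  fam <- vapply(parts, function(p) if (length(p) >= 3) p[length(p)] else "", character(1))
  data.frame(name = nm,
             ref = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             class = cls, family = fam, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @keywords internal
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
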