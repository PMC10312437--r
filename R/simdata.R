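# Synthetic small RNA libraries with known pseudouridine ground truth.
#
# Three assay chemistries are modeled on top of a shared species pool:
#   * Psi-IP: antibody capture with probability eps_psi for Psi-spanning
#     reads and eps_bg for the background; the uncaptured reads form the
#     unbound fraction.
#   * CMC (RT-stop mode): a read spanning k Psi sites is lost from the
#     treated library with probability 1 - (1 - alpha)^k; stopped cDNAs
#     lack the second adapter and never amplify, so the loss is per read,
#     not a truncation.
#   * CMC/Mn2+ (readthrough mode): at each Psi position within a read the
#     base is substituted with probability m or deleted with probability d;
#     otherwise the polymerase reads through.
#
# The internal alphabet is DNA (T); use as_rna() for display.

#' Simulation configuration
#'
#' Bundles every tunable of the generator with validation. Defaults are the
#' package's reference study conditions: capture probabilities 0.8 (Psi) vs
#' 0.05 (background), CMC adduct/RT-stop probability 0.8 per Psi,
#' Mn2+ mismatch/deletion rates 0.3/0.1 per Psi per read, 2e5 reads per
#' library, and a log-normal(0, 1) species abundance model.
#'
#' @param seed Master integer seed; every sample derives its own RNG stream
#'   from it via [derive_seed()].
#' @param genotype One of `"WT"`, `"pus7"`, `"pus10"`, `"dkc1"`. Mutant
#'   genotypes remove the corresponding enzyme's sites from the planted
#'   truth (the sequence itself is unchanged, as in a synthase knockout).
#' @param depth Reads per library.
#' @param abundance Named numeric `c(meanlog=, sdlog=)` of the log-normal
#'   species abundance model.
#' @param ip_capture Named numeric `c(bg=, psi=)` capture probabilities.
#' @param cmc_alpha Per-Psi adduct x RT-stop probability (RT-stop mode).
#' @param mn_rates Named numeric `c(mismatch=, deletion=)`, per Psi per read;
#'   the sum must not exceed 1.
#' @param base_error Background per-base sequencing error rate (applies to
#'   every emitted read in every library).
#' @param dialect Library kit dialect: `"NEB"` (no random bases) or
#'   `"NextFlex"` (4 random nucleotides on both ends of the insert).
#' @param adapter3 3' adapter sequence appended to every emitted read.
#' @param size_ranges Named list of `c(min, max)` insert length windows per
#'   RNA class (`mirna`, `trf`, `rrna`, `te_small`, `te_large`, `pirna`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genotype = c("WT", "pus7", "pus10", "dkc1"),
                       depth = 2e5,
                       abundance = c(meanlog = 0, sdlog = 1),
                       ip_capture = c(bg = 0.05, psi = 0.8),
                       cmc_alpha = 0.8,
                       mn_rates = c(mismatch = 0.3, deletion = 0.1),
                       base_error = 0.001,
                       dialect = c("NEB", "NextFlex"),
                       adapter3 = "AGATCGGAAGAGCACACGTC",
                       size_ranges = list(
                         mirna = c(20L, 22L),
                         trf = c(18L, 30L),
                         rrna = c(18L, 30L),
                         te_small = c(20L, 22L),
                         te_large = c(23L, 25L),
                         pirna = c(26L, 31L))) {
  genotype <- match.arg(genotype)
  dialect <- match.arg(dialect)
  probs <- c(ip_capture, cmc_alpha, mn_rates, base_error)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(mn_rates) > 1) {
    stop("mn_rates: mismatch + deletion must be <= 1", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  for (nm in names(size_ranges)) {
    r <- size_ranges[[nm]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop("invalid size range for class '", nm, "'", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), genotype = genotype,
                 depth = depth, abundance = abundance,
                 ip_capture = ip_capture, cmc_alpha = cmc_alpha,
                 mn_rates = mn_rates, base_error = base_error,
                 dialect = dialect, adapter3 = adapter3,
                 size_ranges = size_ranges),
            class = "sim_config")
}

# canonical tRNA geometry used throughout: standard 76-nt numbering with the
# T-loop pseudouridine at position 55 (0-based index 54), 22 nt upstream of
# the 3' end of the CCA tail.
TRNA_LEN <- 76L
PSI55_POS0 <- 54L

plant_motif <- function(seq, pos0, motif) {
  substr(seq, pos0 + 1L, pos0 + nchar(motif)) <- motif
  seq
}

force_base <- function(seq, pos0, base) plant_motif(seq, pos0, base)

# generate one tRNA body; when `unuar` a U-N-U-A-R motif is planted with its
# modified U at 0-based 32. The 3' third (downstream of the T-loop) is kept
# motif-free so that fragments anchored at the CCA end carry only the
# position-55 site.
make_trna <- function(unuar) {
  repeat {
    s <- random_dna(1, TRNA_LEN - 3L)
    s <- paste0(s, "CCA")
    s <- force_base(s, PSI55_POS0, "T")
    if (unuar) {
      s <- plant_motif(s, 30L, paste0("T", sample(DNA_BASES, 1), "TA",
                                      sample(c("A", "G"), 1)))
      s <- force_base(s, PSI55_POS0, "T")
    }
    hits <- find_unuar(s)
    # no accidental motif in the 3' half; planted site (if any) must survive
    if (!any(hits >= 45L) && (!unuar || 32L %in% hits)) return(s)
  }
}

#' Build a synthetic reference set with planted pseudouridine truth
#'
#' Constructs loci-scale references standing in for a genome plus annotation:
#' one rRNA locus with DKC1-dependent sites, eight standard 76-nt tRNAs
#' ending in CCA with the canonical position-55 site (PUS10) and a subset
#' carrying a UNUAR motif (PUS7), 24 miRNA precursors (10 with a DKC1 site in
#' the mature arm), six transposon families with three copies each (four
#' families carry Psi of unassigned enzyme class), two piRNA-cluster
#' intervals, and a few snoRNA/snRNA loci used as the structural-RNA
#' exclusion set. Coordinates are 0-based half-open; all positions with
#' planted Psi are returned as truth records.
#'
#' @param config A [sim_config()].
#' @return A list with elements `reference` (class `reference_set`: named
#'   `sequences` plus an `annotations` data.frame) and `truth` (data.frame
#'   `ref`, `pos`, `enzyme`).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "reference", {
    seqs <- list(); ann <- list(); truth <- list()
    add_ann <- function(name, ref, start, end, strand, class, family = "") {
      ann[[length(ann) + 1L]] <<- data.frame(
        name = name, ref = ref, start = as.integer(start),
        end = as.integer(end), strand = strand, class = class,
        family = family, stringsAsFactors = FALSE)
    }
    add_truth <- function(ref, pos, enzyme) {
      truth[[length(truth) + 1L]] <<- data.frame(
        ref = ref, pos = as.integer(pos), enzyme = enzyme,
        stringsAsFactors = FALSE)
    }

    # rRNA locus with 12 DKC1 sites
    rrna <- random_dna(1, 1800L)
    rrna_sites <- as.integer(round(seq(150, 1650, length.out = 12)))
    for (p in rrna_sites) rrna <- force_base(rrna, p, "T")
    seqs[["rRNA_18S"]] <- rrna
    add_ann("rRNA_18S", "rRNA_18S", 0L, 1800L, "+", "rRNA")
    for (p in rrna_sites) add_truth("rRNA_18S", p, "DKC1")

    # 8 tRNAs; the first 4 carry a UNUAR motif
    isotypes <- c("Ala-AGC", "Gly-GCC", "Glu-CTC", "Lys-CTT",
                  "Asp-GTC", "His-GTG", "Val-CAC", "Phe-GAA")
    for (i in seq_along(isotypes)) {
      nm <- paste0("tRNA-", isotypes[i])
      s <- make_trna(unuar = i <= 4L)
      seqs[[nm]] <- s
      add_ann(nm, nm, 0L, TRNA_LEN, "+", "tRNA", family = isotypes[i])
      add_truth(nm, PSI55_POS0, "PUS10")
      for (p in find_unuar(s)) add_truth(nm, p, "PUS7")
    }

    # 24 miRNA precursors, mature arm at [20, 41); 10 carry a DKC1 site at
    # offset 10 of the mature sequence
    for (i in 1:24) {
      nm <- sprintf("MIR%03d", i)
      s <- random_dna(1, 120L)
      if (i <= 10L) s <- force_base(s, 30L, "T")
      seqs[[nm]] <- s
      add_ann(nm, nm, 0L, 120L, "+", "miRNA_precursor")
      add_ann(sprintf("miR%03d", i), nm, 20L, 41L, "+", "miRNA_mature")
      if (i <= 10L) add_truth(nm, 30L, "DKC1")
    }

    # 6 TE families x 3 copies; families 1-4 carry Psi (enzyme class OTHER)
    fams <- c("ATCOPIA1", "ATGP1", "ATLINE1", "ATCOPIA2", "ATGP2", "ATMU1")
    for (f in seq_along(fams)) {
      consensus <- random_dna(1, 400L)
      for (j in 1:3) {
        nm <- sprintf("TE_%s_c%d", fams[f], j)
        s <- consensus
        mut <- sample(400L, 8L)  # ~2% divergence between copies
        for (p in mut) s <- force_base(s, p - 1L, sample(DNA_BASES, 1))
        if (f <= 4L) {
          ps <- sample(50:350, 3L)
          for (p in ps) s <- force_base(s, p, "T")
        }
        seqs[[nm]] <- s
        add_ann(nm, nm, 0L, 400L, "+", "TE", family = fams[f])
        if (f <= 4L) for (p in ps) add_truth(nm, p, "OTHER")
      }
    }

    # 2 piRNA-cluster intervals with OTHER-class sites
    for (i in 1:2) {
      nm <- sprintf("piRCluster_%d", i)
      s <- random_dna(1, 1500L)
      ps <- sample(100:1400, 6L)
      for (p in ps) s <- force_base(s, p, "T")
      seqs[[nm]] <- s
      add_ann(nm, nm, 0L, 1500L, "+", "piRNA_cluster")
      for (p in ps) add_truth(nm, p, "OTHER")
    }

    # structural exclusion set (unmodified)
    for (i in 1:2) {
      nm <- sprintf("snoRNA_%d", i)
      seqs[[nm]] <- random_dna(1, 130L)
      add_ann(nm, nm, 0L, 130L, "+", "snoRNA")
    }
    for (i in 1:2) {
      nm <- sprintf("snRNA_U%d", i)
      seqs[[nm]] <- random_dna(1, 165L)
      add_ann(nm, nm, 0L, 165L, "+", "snRNA")
    }

    truth <- do.call(rbind, truth)
    knockout <- c(pus7 = "PUS7", pus10 = "PUS10", dkc1 = "DKC1")
    if (config$genotype %in% names(knockout)) {
      truth <- truth[truth$enzyme != knockout[[config$genotype]], ,
                     drop = FALSE]
    }
    rownames(truth) <- NULL
    ref <- structure(list(sequences = unlist(seqs),
                          annotations = do.call(rbind, ann)),
                     class = "reference_set")
    validate_reference(ref)
    list(reference = ref, truth = truth)
  })
}

validate_reference <- function(ref) {
  ann <- ref$annotations
  len <- nchar(ref$sequences)[ann$ref]
  if (any(ann$start < 0 | ann$end > len)) {
    stop("annotation interval outside its reference", call. = FALSE)
  }
  trna <- ann[ann$class == "tRNA", ]
  if (nrow(trna)) {
    ends <- substr(ref$sequences[trna$ref], trna$end - 2L, trna$end)
    if (any(ends != "CCA")) stop("tRNA not ending in CCA", call. = FALSE)
  }
  invisible(ref)
}

subseq_chr <- function(sequences, ref, start0, end0) {
  substr(sequences[ref], start0 + 1L, end0)
}

#' Draw a species pool from the reference
#'
#' Samples class-appropriate small RNA species from the annotated features:
#' miRNA isoforms of 20-22 nt around each mature arm, 3'-CCA tRFs at every
#' length of the tRF window plus 5' and internal fragments, rRNA fragments
#' (including fragments spanning each planted rRNA site), TE siRNA windows in
#' the 20-22 and 23-25 size classes on both strands, piRNA-like 26-31 nt
#' reads from cluster intervals, and snoRNA/snRNA fragments. Species
#' abundances are log-normal and normalized so that expected read counts sum
#' to the configured depth. Only plus-strand species inherit planted Psi
#' sites (the antisense strand of a duplex is a different molecule).
#'
#' @param ref A `reference_set` from [build_reference()].
#' @param truth Psi truth data.frame from [build_reference()].
#' @param config A [sim_config()].
#' @return A data.frame, one row per species: `species`, `class`, `parent`,
#'   `family`, `ref`, `start`, `end`, `strand`, `length`, `sequence`,
#'   `true_abundance` (expected reads at the configured depth), `n_psi`, and
#'   a list column `psi_offsets` of 0-based Psi offsets within the sequence.
#' @export
simulate_pool <- function(ref, truth, config) {
  stopifnot(inherits(ref, "reference_set"), inherits(config, "sim_config"))
  ann <- ref$annotations
  sr <- config$size_ranges
  with_stream(config$seed, "pool", {
    rows <- list()
    add <- function(class, parent, family, rref, start, end, strand) {
      rows[[length(rows) + 1L]] <<- data.frame(
        class = class, parent = parent, family = family, ref = rref,
        start = as.integer(start), end = as.integer(end), strand = strand,
        stringsAsFactors = FALSE)
    }

    for (i in which(ann$class == "miRNA_mature")) {
      a <- ann[i, ]
      add("miRNA", a$name, "", a$ref, a$start, a$end, "+")          # 21 nt
      add("miRNA", a$name, "", a$ref, a$start, a$end - 1L, "+")     # 20 nt
      add("miRNA", a$name, "", a$ref, a$start, a$end + 1L, "+")     # 22 nt
    }

    trf3_lengths <- seq.int(sr$trf[1], min(sr$trf[2], TRNA_LEN))
    for (i in which(ann$class == "tRNA")) {
      a <- ann[i, ]
      for (L in trf3_lengths) add("tRF", a$name, a$family, a$ref,
                                  a$end - L, a$end, "+")
      for (L in c(18L, 26L, 34L, 36L, 38L)) {
        add("tRF", a$name, a$family, a$ref, a$start, a$start + L, "+")
      }
      for (k in 1:2) {
        L <- sample(seq.int(sr$trf[1], sr$trf[2]), 1)
        s0 <- sample.int(TRNA_LEN - L - 6L, 1) + 3L  # off both termini
        add("tRF", a$name, a$family, a$ref, s0, s0 + L, "+")
      }
    }

    rr <- ann[ann$class == "rRNA", ][1, ]
    rr_sites <- truth$pos[truth$ref == rr$ref]
    for (k in seq_len(60L)) {
      L <- sample(seq.int(sr$rrna[1], sr$rrna[2]), 1)
      s0 <- sample.int(rr$end - L, 1) - 1L
      add("rRNA_frag", rr$name, "", rr$ref, s0, s0 + L, "+")
    }
    for (p in rr_sites) {
      for (k in 1:3) {
        L <- sample(seq.int(sr$rrna[1], sr$rrna[2]), 1)
        off <- sample.int(L - 2L, 1)
        s0 <- max(0L, min(p - off, rr$end - L))
        add("rRNA_frag", rr$name, "", rr$ref, s0, s0 + L, "+")
      }
    }

    for (i in which(ann$class == "TE")) {
      a <- ann[i, ]
      for (cls in c("te_small", "te_large")) {
        for (k in 1:4) {
          L <- sample(seq.int(sr[[cls]][1], sr[[cls]][2]), 1)
          s0 <- sample.int(a$end - L, 1) - 1L
          add("TE_siRNA", a$name, a$family, a$ref, s0, s0 + L,
              sample(c("+", "-"), 1, prob = c(0.7, 0.3)))
        }
      }
    }

    for (i in which(ann$class == "piRNA_cluster")) {
      a <- ann[i, ]
      for (k in 1:20) {
        L <- sample(seq.int(sr$pirna[1], sr$pirna[2]), 1)
        s0 <- sample.int(a$end - L, 1) - 1L
        add("piRNA", a$name, "", a$ref, s0, s0 + L,
            sample(c("+", "-"), 1, prob = c(0.7, 0.3)))
      }
    }

    for (i in which(ann$class %in% c("snoRNA", "snRNA"))) {
      a <- ann[i, ]
      for (k in 1:3) {
        L <- sample(18:30, 1)
        s0 <- sample.int(a$end - a$start - L, 1) + a$start - 1L
        add("structural_frag", a$name, "", a$ref, s0, s0 + L, "+")
      }
    }

    pool <- do.call(rbind, rows)
    seq0 <- subseq_chr(ref$sequences, pool$ref, pool$start, pool$end)
    pool$sequence <- ifelse(pool$strand == "+", seq0, revcomp(seq0))
    pool$length <- nchar(pool$sequence)

    # collapse duplicated species (identical sequence from the same locus)
    key <- paste(pool$ref, pool$start, pool$end, pool$strand)
    pool <- pool[!duplicated(key), , drop = FALSE]
    pool$species <- sprintf("sp%04d", seq_len(nrow(pool)))

    pool$psi_offsets <- lapply(seq_len(nrow(pool)), function(i) {
      if (pool$strand[i] != "+") return(integer(0))
      p <- truth$pos[truth$ref == pool$ref[i] &
                     truth$pos >= pool$start[i] & truth$pos < pool$end[i]]
      sort(as.integer(p - pool$start[i]))
    })
    pool$n_psi <- lengths(pool$psi_offsets)

    w <- stats::rlnorm(nrow(pool), meanlog = config$abundance[["meanlog"]],
                       sdlog = config$abundance[["sdlog"]])
    pool$true_abundance <- config$depth * w / sum(w)
    rownames(pool) <- NULL
    pool[, c("species", "class", "parent", "family", "ref", "start", "end",
             "strand", "length", "sequence", "true_abundance", "n_psi",
             "psi_offsets")]
  })
}

phred_char <- function(q) intToUtf8(q + 33L)

# Emit per-read FASTQ records for a vector of per-species counts.
# `mutate` = NULL (none) or list(m=, d=) of per-Psi mismatch/deletion rates.
# Returns list(id, sequence, quality, events) where events tabulates
# per-species, per-offset substitution/deletion counts.
emit_reads <- function(pool, counts, config, prefix, mutate = NULL) {
  keep <- which(counts > 0L)
  idx <- rep.int(keep, counts[keep])
  n <- length(idx)
  if (n == 0L) {
    return(list(id = character(0), sequence = character(0),
                quality = character(0), events = NULL))
  }
  seqs <- pool$sequence[idx]
  species <- pool$species[idx]
  qhi <- phred_char(35L); qlo <- phred_char(20L)
  events <- list()

  if (!is.null(mutate)) {
    m <- mutate$m; d <- mutate$d
    for (s in keep[pool$n_psi[keep] > 0L]) {
      rows <- which(idx == s)
      offs <- pool$psi_offsets[[s]]
      # event matrix: 0 none, 1 substitute, 2 delete (per read x site)
      u <- matrix(stats::runif(length(rows) * length(offs)),
                  nrow = length(rows))
      ev <- (u < m) + 2L * (u >= m & u < m + d)
      for (r in seq_along(rows)) {
        if (all(ev[r, ] == 0L)) next
        sq <- seqs[rows[r]]
        for (j in rev(seq_along(offs))) {      # right-to-left keeps offsets valid
          o <- offs[j]
          if (ev[r, j] == 1L) {
            old <- substr(sq, o + 1L, o + 1L)
            sq <- force_base(sq, o, sample(setdiff(DNA_BASES, old), 1))
          } else if (ev[r, j] == 2L) {
            sq <- paste0(substr(sq, 1L, o), substr(sq, o + 2L, nchar(sq)))
          }
        }
        seqs[rows[r]] <- sq
      }
      events[[length(events) + 1L]] <- data.frame(
        species = pool$species[s], offset = offs,
        n_sub = colSums(ev == 1L), n_del = colSums(ev == 2L),
        n_reads = length(rows), stringsAsFactors = FALSE)
    }
  }

  lens <- nchar(seqs)
  quals <- vapply(lens, function(L) strrep(qhi, L), character(1))
  nerr <- stats::rbinom(n, lens, config$base_error)
  for (r in which(nerr > 0L)) {
    pos <- sample.int(lens[r], nerr[r])
    sq <- seqs[r]; ql <- quals[r]
    for (p in pos) {
      old <- substr(sq, p, p)
      sq <- force_base(sq, p - 1L, sample(setdiff(DNA_BASES, old), 1))
      ql <- force_base(ql, p - 1L, qlo)  # errored base gets Phred 20
    }
    seqs[r] <- sq; quals[r] <- ql
  }

  if (config$dialect == "NextFlex") {
    n4a <- random_dna(n, 4L); n4b <- random_dna(n, 4L)
    seqs <- paste0(n4a, seqs, n4b)
    quals <- paste0(strrep(qhi, 4L), quals, strrep(qhi, 4L))
  }
  seqs <- paste0(seqs, config$adapter3)
  quals <- paste0(quals, strrep(qhi, nchar(config$adapter3)))

  list(id = sprintf("%s:%s:%d", prefix, species, seq_len(n)),
       sequence = seqs, quality = quals,
       events = if (length(events)) do.call(rbind, events))
}

draw_pool_counts <- function(pool, config) {
  as.integer(stats::rmultinom(1, size = config$depth,
                              prob = pool$true_abundance)[, 1])
}

#' Simulate a Psi-IP bound/unbound library pair
#'
#' Draws one pool sample of `depth` reads and captures each read with
#' probability `ip_capture["psi"]` if its species spans at least one Psi,
#' else `ip_capture["bg"]`; captured reads form the bound fraction and all
#' others the unbound fraction, so the two fractions conserve the draw
#' exactly.
#'
#' @param pool Species pool from [simulate_pool()].
#' @param config A [sim_config()].
#' @param sample Sample label; also seeds this pair's RNG stream.
#' @param dir Output directory for FASTQ (created if needed); only used when
#'   `emit = "fastq"`.
#' @param emit `"counts"` returns per-species counts only (fast path for
#'   count-level analyses); `"fastq"` additionally writes the two FASTQ
#'   files with adapters, kit dialect bases and background errors applied.
#' @return A list: `counts` (data.frame `species`, `class`, `length`,
#'   `n_psi`, `bound`, `unbound`), and for FASTQ mode `files` (named paths)
#'   and `events`.
#' @export
simulate_ip <- function(pool, config, sample = "ip1", dir = tempdir(),
                        emit = c("counts", "fastq")) {
  emit <- match.arg(emit)
  if (config$ip_capture[["psi"]] < config$ip_capture[["bg"]]) {
    warning("eps_psi < eps_bg: expected enrichment is inverted")
  }
  with_stream(config$seed, paste0("ip_", sample), {
    n <- draw_pool_counts(pool, config)
    eps <- ifelse(pool$n_psi > 0L, config$ip_capture[["psi"]],
                  config$ip_capture[["bg"]])
    bound <- stats::rbinom(nrow(pool), n, eps)
    unbound <- n - bound
    counts <- data.frame(species = pool$species, class = pool$class,
                         length = pool$length, n_psi = pool$n_psi,
                         bound = bound, unbound = unbound,
                         stringsAsFactors = FALSE)
    out <- list(counts = counts)
    if (emit == "fastq") {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fb <- file.path(dir, paste0(sample, "_bound.fastq"))
      fu <- file.path(dir, paste0(sample, "_unbound.fastq"))
      rb <- emit_reads(pool, bound, config, paste0(sample, "_bound"))
      ru <- emit_reads(pool, unbound, config, paste0(sample, "_unbound"))
      write_fastq(fb, rb$id, rb$sequence, rb$quality)
      write_fastq(fu, ru$id, ru$sequence, ru$quality)
      out$files <- c(bound = fb, unbound = fu)
    }
    out
  })
}

#' Simulate a CMC treated/mock library pair
#'
#' In `"stop"` mode a treated-fraction read whose species spans k Psi sites
#' survives reverse transcription with probability `(1 - cmc_alpha)^k`; the
#' mock fraction has no Psi-dependent loss. In `"mn2plus"` mode no reads are
#' lost; instead each Psi position within each treated read is substituted
#' (uniform non-cognate base) or deleted at the configured `mn_rates`.
#' Both fractions are independent pool draws at the configured depth,
#' modeling two library preparations from the same RNA.
#'
#' @inheritParams simulate_ip
#' @param mode `"stop"` (RT-stop depletion) or `"mn2plus"` (readthrough
#'   mismatch/deletion).
#' @return A list: `counts` (data.frame `species`, `class`, `length`,
#'   `n_psi`, `treated`, `mock`), plus `files` and `events` in FASTQ mode.
#'   `events` tabulates per-species dropout (stop mode) or per-site
#'   substitution/deletion counts (mn2plus mode).
#' @export
simulate_cmc <- function(pool, config, mode = c("stop", "mn2plus"),
                         sample = "cmc1", dir = tempdir(),
                         emit = c("counts", "fastq")) {
  mode <- match.arg(mode)
  emit <- match.arg(emit)
  with_stream(config$seed, paste0("cmc_", mode, "_", sample), {
    n_mock <- draw_pool_counts(pool, config)
    n_t0 <- draw_pool_counts(pool, config)
    events <- NULL
    if (mode == "stop") {
      surv <- (1 - config$cmc_alpha)^pool$n_psi
      treated <- stats::rbinom(nrow(pool), n_t0, surv)
      events <- data.frame(species = pool$species,
                           drawn = n_t0, dropped = n_t0 - treated,
                           stringsAsFactors = FALSE)
    } else {
      treated <- n_t0
    }
    counts <- data.frame(species = pool$species, class = pool$class,
                         length = pool$length, n_psi = pool$n_psi,
                         treated = treated, mock = n_mock,
                         stringsAsFactors = FALSE)
    out <- list(counts = counts, events = events)
    if (emit == "fastq") {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ft <- file.path(dir, paste0(sample, "_treated.fastq"))
      fm <- file.path(dir, paste0(sample, "_mock.fastq"))
      mut <- if (mode == "mn2plus") {
        list(m = config$mn_rates[["mismatch"]], d = config$mn_rates[["deletion"]])
      }
      rt <- emit_reads(pool, treated, config, paste0(sample, "_treated"),
                       mutate = mut)
      rm_ <- emit_reads(pool, n_mock, config, paste0(sample, "_mock"))
      write_fastq(ft, rt$id, rt$sequence, rt$quality)
      write_fastq(fm, rm_$id, rm_$sequence, rm_$quality)
      out$files <- c(treated = ft, mock = fm)
      if (mode == "mn2plus") out$events <- rt$events
    }
    out
  })
}

#' Write a simulation bundle to disk
#'
#' Writes the reference FASTA, the annotation BED6, the Psi truth TSV and the
#' species table TSV so a simulated study can be re-analyzed from files.
#'
#' @param ref `reference_set`.
#' @param truth Psi truth data.frame.
#' @param pool Optional species pool to include.
#' @param dir Output directory.
#' @return Named character vector of written paths.
#' @export
write_sim_bundle <- function(ref, truth, pool = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             bed = file.path(dir, "annotations.bed"),
             truth = file.path(dir, "psi_truth.tsv"))
  write_fasta(paths[["fasta"]], ref$sequences)
  write_annotation_bed(ref$annotations, paths[["bed"]])
  write_tsv(truth, paths[["truth"]])
  if (!is.null(pool)) {
    paths[["pool"]] <- file.path(dir, "species_pool.tsv")
    flat <- pool
    flat$psi_offsets <- vapply(pool$psi_offsets, paste, character(1),
                               collapse = ",")
    write_tsv(flat, paths[["pool"]])
  }
  paths
}
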