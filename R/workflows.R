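# Ready-made simulation studies: each one wires generator -> preprocessing ->
# alignment -> statistics for a specific question, with known truth attached.

#' Sequence-level count matrix for one assay arm of a simulated study
#'
#' Draws `n_pairs` independent library pairs from a species pool (counts
#' mode; no FASTQ) and aggregates species counts to the sequence level
#' (distinct loci can emit identical sequences, e.g. TE copies).
#'
#' @param pool Species pool from [simulate_pool()].
#' @param config A [sim_config()].
#' @param arm `"ip"` (bound vs unbound) or `"cmc"` (treated vs mock,
#'   RT-stop mode).
#' @param n_pairs Number of library pairs.
#' @return A list: `counts` (sequence x sample matrix), `condition` (factor,
#'   control level first), `pair` (factor), `truth` (data.frame per
#'   sequence: `feature`, `psi`, `class`, `length`).
#' @export
arm_count_matrix <- function(pool, config, arm = c("ip", "cmc"),
                             n_pairs = 3L) {
  arm <- match.arg(arm)
  tabs <- list()
  for (i in seq_len(n_pairs)) {
    if (arm == "ip") {
      sim <- simulate_ip(pool, config, sample = paste0("p", i))
      tr <- sim$counts$bound; ct <- sim$counts$unbound
      lab <- c("bound", "unbound")
    } else {
      sim <- simulate_cmc(pool, config, mode = "stop",
                          sample = paste0("p", i))
      tr <- sim$counts$treated; ct <- sim$counts$mock
      lab <- c("treated", "mock")
    }
    tabs[[paste0(lab[1], "_p", i)]] <-
      data.frame(feature = pool$sequence, count = tr)
    tabs[[paste0(lab[2], "_p", i)]] <-
      data.frame(feature = pool$sequence, count = ct)
  }
  # species -> sequence aggregation
  tabs <- lapply(tabs, function(x) {
    dt <- data.table::as.data.table(x)[, list(count = sum(count)),
                                       by = "feature"]
    as.data.frame(dt)
  })
  counts <- build_count_matrix(tabs, feature_level = "sequence")
  samp <- colnames(counts)
  trt_lab <- if (arm == "ip") "bound" else "treated"
  condition <- factor(ifelse(startsWith(samp, trt_lab), "treatment",
                             "control"), levels = c("control", "treatment"))
  pair <- factor(sub(".*_(p\\d+)$", "\\1", samp))
  tdt <- data.table::data.table(feature = pool$sequence, psi = pool$n_psi > 0,
                                class = pool$class, length = pool$length)
  truth <- as.data.frame(tdt[, list(psi = any(psi), class = class[1],
                                    length = length[1]), by = "feature"])
  truth <- truth[match(rownames(counts), truth$feature), ]
  list(counts = counts, condition = condition, pair = pair, truth = truth)
}

# 8 standard tRNAs carrying only the position-55 site, plus 3'-CCA tRF
# species at every length of `trf_lengths` with log-normal abundances.
trf_study_inputs <- function(seed, n_trna = 8L, trf_lengths = 18:30,
                             abundance = c(meanlog = 0, sdlog = 1)) {
  cfg <- sim_config(seed = seed, abundance = abundance)
  with_stream(seed, "trf_reference", {
    seqs <- character(0)
    for (i in seq_len(n_trna)) {
      seqs[sprintf("tRNA-%02d", i)] <- make_trna(unuar = FALSE)
    }
    ann <- data.frame(name = names(seqs), ref = names(seqs), start = 0L,
                      end = TRNA_LEN, strand = "+", class = "tRNA",
                      family = names(seqs), stringsAsFactors = FALSE)
    ref <- structure(list(sequences = seqs, annotations = ann),
                     class = "reference_set")
    truth <- data.frame(ref = names(seqs), pos = PSI55_POS0,
                        enzyme = "PUS10", stringsAsFactors = FALSE)
    rows <- list()
    for (nm in names(seqs)) {
      for (L in trf_lengths) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = "tRF", parent = nm, family = nm, ref = nm,
          start = TRNA_LEN - L, end = TRNA_LEN, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    pool <- do.call(rbind, rows)
    pool$sequence <- subseq_chr(seqs, pool$ref, pool$start, pool$end)
    pool$length <- nchar(pool$sequence)
    pool$species <- sprintf("sp%04d", seq_len(nrow(pool)))
    pool$psi_offsets <- lapply(seq_len(nrow(pool)), function(i) {
      if (pool$start[i] <= PSI55_POS0) PSI55_POS0 - pool$start[i] else
        integer(0)
    })
    pool$n_psi <- lengths(pool$psi_offsets)
    w <- stats::rlnorm(nrow(pool), abundance[["meanlog"]],
                       abundance[["sdlog"]])
    pool$true_abundance <- w / sum(w)
    list(ref = ref, truth = truth, pool = pool, config = cfg)
  })
}

#' End-to-end CMC-depletion study of 3'-CCA tRNA fragments
#'
#' Simulates standard 76-nt tRNAs whose only Psi is the canonical T-loop
#' site at position 55, emits 3'-CCA tRF libraries as FASTQ for
#' `n_pairs` CMC-treated/mock pairs with per-Psi RT-stop probability
#' `dropout`, then runs the full pipeline: adapter trimming and length
#' filtering, collapsing, alignment to the tRNAs, the paired NB Wald test
#' at the sequence level, tRF classification of the significant sequences,
#' and the size distribution of the significantly depleted 3'-tRFs.
#' Fragments of at least 22 nt span position 55 (76 - 55 + 1 = 22), so the
#' expected modal depleted length is 22 nt.
#'
#' @param seed Integer seed.
#' @param depth Reads per library (default 1e5).
#' @param n_pairs CMC/mock pairs (default 3).
#' @param dropout Per-Psi adduct x RT-stop probability (default 0.9).
#' @param alpha Adjusted-p threshold for depletion calls (default 0.01).
#' @param trf_lengths 3'-tRF lengths simulated (default 18-30 nt).
#' @param n_trna Number of tRNAs (default 8).
#' @param dir Scratch directory for FASTQ.
#' @return A list: `mode` (modal depleted 3'-tRF length, nt), `tie`,
#'   `histogram`, `n_sig` (significantly depleted 3'-tRF sequences),
#'   `results` (full NB table), `n_features_tested`.
#' @export
trf_depletion_study <- function(seed, depth = 1e5, n_pairs = 3L,
                                dropout = 0.9, alpha = 0.01,
                                trf_lengths = 18:30, n_trna = 8L,
                                dir = tempfile("trfstudy")) {
  inp <- trf_study_inputs(seed, n_trna = n_trna, trf_lengths = trf_lengths)
  cfg <- sim_config(seed = seed, depth = depth, cmc_alpha = dropout)
  pool <- inp$pool
  pool$true_abundance <- pool$true_abundance * depth

  policy <- filter_policy(min_len = min(trf_lengths),
                          max_len = max(trf_lengths))
  tabs <- list()
  for (i in seq_len(n_pairs)) {
    sim <- simulate_cmc(pool, cfg, mode = "stop",
                        sample = paste0("pair", i), dir = dir,
                        emit = "fastq")
    for (fraction in c("treated", "mock")) {
      nm <- paste0(fraction, "_p", i)
      pre <- preprocess_fastq(sim$files[[fraction]], policy, sample = nm)
      tabs[[nm]] <- data.frame(feature = pre$collapsed$sequence,
                               count = pre$collapsed$count)
    }
  }
  counts <- build_count_matrix(tabs, feature_level = "sequence")
  counts <- mean_count_filter(counts, threshold = 10)
  samp <- colnames(counts)
  condition <- factor(ifelse(startsWith(samp, "treated"), "treatment",
                             "control"), levels = c("control", "treatment"))
  pair <- factor(sub(".*_(p\\d+)$", "\\1", samp))
  # treated and mock are equal-size draws of the same RNA and the RT-stop
  # loss is absolute, so the libraries share a scale by construction; a
  # median-of-ratios anchor would be distorted here because most fragment
  # lengths (>= 22 nt) span the Psi and are genuinely depleted
  res <- nb_wald_test(counts, condition, pair = pair,
                      sf = stats::setNames(rep(1, ncol(counts)),
                                           colnames(counts)))

  idx <- build_index(inp$ref, k = 12L)
  mpol <- map_policy(max_mismatch = 1L, max_deletion = 0L,
                     multimap = "unique_only")
  aln <- map_reads(data.frame(sequence = res$feature, count = 1L),
                   idx, mpol)
  trf <- classify_trfs(aln, inp$ref$annotations)
  trf3 <- trf$sequence[trf$class == "three_prime" & trf$has_cca]
  dep <- res$feature[!is.na(res$padj) & res$padj < alpha & res$log2fc < 0]
  dep3 <- intersect(dep, trf3)
  sd_ <- size_distribution(nchar(dep3))
  unlink(dir, recursive = TRUE)
  list(mode = sd_$mode, tie = sd_$tie, histogram = sd_$histogram,
       n_sig = length(dep3), results = res,
       n_features_tested = nrow(counts))
}

#' Psi recovery study: sensitivity and specificity of the IP and CMC arms
#'
#' Runs the generator under a chosen genotype at count level for both the
#' Psi-IP and the CMC RT-stop arm, tests sequence-level enrichment with the
#' paired NB engine, calls Psi features, and scores the calls against the
#' planted truth.
#'
#' @param seed Integer seed.
#' @param genotype Genotype switch passed to [sim_config()].
#' @param depth Reads per library.
#' @param n_pairs Library pairs per arm.
#' @param alpha Adjusted-p threshold.
#' @return A list: `ip`, `cmc` (full NB result tables with `psi`, `class`
#'   truth columns), `calls`, and `metrics` (sensitivity per arm for
#'   truly-Psi miRNA sequences, false-positive rate per arm among non-Psi
#'   sequences).
#' @export
recovery_study <- function(seed, genotype = "WT", depth = 2e5, n_pairs = 3L,
                           alpha = 0.01) {
  cfg <- sim_config(seed = seed, genotype = genotype, depth = depth)
  built <- build_reference(cfg)
  pool <- simulate_pool(built$reference, built$truth, cfg)

  run_arm <- function(arm) {
    am <- arm_count_matrix(pool, cfg, arm = arm, n_pairs = n_pairs)
    counts <- mean_count_filter(am$counts, threshold = 10)
    truth <- am$truth[match(rownames(counts), am$truth$feature), ]
    res <- nb_wald_test(counts, am$condition, pair = am$pair)
    res$psi <- truth$psi
    res$class <- truth$class
    res
  }
  ip <- run_arm("ip")
  cmc <- run_arm("cmc")
  calls <- call_psi_features(ip, cmc, alpha = alpha)

  sens <- function(res, sign_) {
    tp <- res$psi & res$class == "miRNA"
    if (!any(tp)) return(NA_real_)
    hit <- !is.na(res$padj) & res$padj < alpha &
      (if (sign_ > 0) res$log2fc > 0 else res$log2fc < 0)
    mean(hit[tp])
  }
  fpr <- function(res, sign_) {
    neg <- !res$psi
    hit <- !is.na(res$padj) & res$padj < alpha &
      (if (sign_ > 0) res$log2fc > 0 else res$log2fc < 0)
    mean(hit[neg])
  }
  list(ip = ip, cmc = cmc, calls = calls,
       metrics = c(ip_sensitivity = sens(ip, +1),
                   cmc_sensitivity = sens(cmc, -1),
                   ip_fpr = fpr(ip, +1), cmc_fpr = fpr(cmc, -1)))
}

#' CMC/Mn2+ site-calling study at controlled per-site depth
#'
#' Plants rRNA Psi sites, generates fragment species covering each site at
#' roughly uniform abundance, emits one treated/mock FASTQ pair under the
#' Mn2+ readthrough chemistry, and runs preprocessing, alignment (one
#' deletion tolerated), per-position pileups and the mismatch site caller.
#'
#' The study isolates the Mn2+ chemistry: background sequencing error is
#' off by default, because the published ratio thresholds carry no guard
#' against matched background noise (a position with a couple of Poisson
#' errors in the treated library and none in the mock clears a 1.5-fold
#' ratio however deep the coverage; see the methods vignette).
#'
#' Deletion events inside a homopolymer run are left-aligned by the
#' aligner (the deleted base is not identifiable within the run), so calls
#' are matched to planted sites with a small localization window
#' (`tolerance`, default 2 nt); a call farther than that from every planted
#' site counts as a false positive.
#'
#' @param seed Integer seed.
#' @param depth Total reads per library (sized so each site exceeds the
#'   target coverage; 2.5e4 gives > 500x over 12 sites).
#' @param mismatch,deletion Per-Psi per-read Mn2+ rates.
#' @param base_error Background per-base error rate (default 0).
#' @param min_reads,min_fc Caller thresholds.
#' @param tolerance Site-matching localization window (nt).
#' @return A list: `calls` (position table), `truth_sites`, `metrics`
#'   (`sensitivity`, `fpr_u` false-positive rate among non-Psi uridines
#'   with callable coverage), `coverage_at_sites`.
#' @export
mn2_site_study <- function(seed, depth = 2.5e4, mismatch = 0.3,
                           deletion = 0.1, base_error = 0,
                           min_reads = 5L, min_fc = 1.5, tolerance = 2L) {
  cfg <- sim_config(seed = seed, depth = depth,
                    mn_rates = c(mismatch = mismatch, deletion = deletion),
                    abundance = c(meanlog = 0, sdlog = 0.2),
                    base_error = base_error)
  built <- build_reference(cfg)
  ref <- built$reference
  rr <- ref$annotations[ref$annotations$class == "rRNA", ][1, ]
  truth_pos <- built$truth$pos[built$truth$ref == rr$ref]
  cfg2 <- cfg
  pool <- simulate_pool(ref, built$truth, cfg)
  pool <- pool[pool$ref == rr$ref, , drop = FALSE]
  pool$true_abundance <- depth * pool$true_abundance /
    sum(pool$true_abundance)

  sim <- simulate_cmc(pool, cfg2, mode = "mn2plus", sample = "mn1",
                      emit = "fastq")
  policy <- preset_policy("mn2")
  idx <- build_index(stats::setNames(ref$sequences[rr$ref], rr$ref), k = 12L)
  mpol <- map_policy(max_mismatch = 3L, max_deletion = 1L,
                     multimap = "unique_only")
  aln_of <- function(path, nm) {
    pre <- preprocess_fastq(path, policy, sample = nm)
    map_reads(pre$collapsed, idx, mpol)
  }
  at <- aln_of(sim$files[["treated"]], "treated")
  am <- aln_of(sim$files[["mock"]], "mock")
  len <- nchar(ref$sequences[[rr$ref]])
  pt <- mismatch_profile(at, rr$ref, len)
  pm <- mismatch_profile(am, rr$ref, len)
  calls <- call_mismatch_sites(pt, pm, min_reads = min_reads,
                               min_fc = min_fc)
  called <- calls$pos[calls$passed]
  near_truth <- function(p) vapply(p, function(x) {
    any(abs(x - truth_pos) <= tolerance)
  }, logical(1))
  is_u <- strsplit(ref$sequences[[rr$ref]], "")[[1]] == "T"
  eval_u <- calls$pos[is_u[calls$pos + 1L]]
  neg_u <- eval_u[!near_truth(eval_u)]
  recovered <- vapply(truth_pos, function(x) {
    any(abs(called - x) <= tolerance)
  }, logical(1))
  false_calls <- called[!near_truth(called)]
  unlink(sim$files)
  list(calls = calls, truth_sites = truth_pos,
       metrics = c(
         sensitivity = mean(recovered),
         fpr_u = if (length(neg_u)) mean(neg_u %in% false_calls) else 0,
         n_false_calls = length(false_calls)),
       coverage_at_sites = pt$total[truth_pos + 1L])
}

#' Genotype-contrast study of enzyme-specific CMC and IP signals
#'
#' Summarizes, for one genotype, the CMC depletion of UNUAR-containing
#' tRFs that do not span position 55 (PUS7 signal), of position-55-spanning
#' 3'-tRFs (PUS10 signal), and the IP enrichment of Psi-carrying miRNA
#' sequences (DKC1 signal). In a knockout the corresponding signal class
#' should vanish while the others persist.
#'
#' @param seed Integer seed.
#' @param genotype `"WT"`, `"pus7"`, `"pus10"` or `"dkc1"`.
#' @param depth,n_pairs,alpha Study parameters.
#' @return A list of per-class summaries: each has `n` (sequences in the
#'   class) and `n_sig` (significant in the expected direction at `alpha`).
#' @export
genotype_study <- function(seed, genotype, depth = 2e5, n_pairs = 3L,
                           alpha = 0.01) {
  cfg <- sim_config(seed = seed, genotype = genotype, depth = depth)
  built <- build_reference(cfg)
  # truth under WT identifies the sequence classes; the genotype decides
  # whether the corresponding sites exist
  wt_truth <- build_reference(sim_config(seed = seed))$truth
  pool <- simulate_pool(built$reference, built$truth, cfg)

  ann <- built$reference$annotations
  trna <- ann[ann$class == "tRNA", ]
  p55 <- stats::setNames(trna$end - 22L, trna$ref)
  is_trf <- pool$class == "tRF"
  spans55 <- is_trf & pool$start <= p55[pool$ref] &
    p55[pool$ref] < pool$end
  unuar_pos <- wt_truth[wt_truth$enzyme == "PUS7", ]
  covers_unuar <- vapply(seq_len(nrow(pool)), function(i) {
    if (!is_trf[i]) return(FALSE)
    any(unuar_pos$ref == pool$ref[i] & unuar_pos$pos >= pool$start[i] &
          unuar_pos$pos < pool$end[i])
  }, logical(1))
  class_seqs <- list(
    unuar_trf = unique(pool$sequence[covers_unuar & !spans55]),
    psi55_trf = unique(pool$sequence[spans55 & !covers_unuar]),
    psi_mirna = unique(pool$sequence[pool$class == "miRNA" &
      pool$sequence %in% {
        dk <- wt_truth[wt_truth$enzyme == "DKC1", ]
        pool$sequence[vapply(seq_len(nrow(pool)), function(i) {
          pool$class[i] == "miRNA" &&
            any(dk$ref == pool$ref[i] & dk$pos >= pool$start[i] &
                  dk$pos < pool$end[i])
        }, logical(1))]
      }]))

  cmc <- {
    am <- arm_count_matrix(pool, cfg, arm = "cmc", n_pairs = n_pairs)
    counts <- mean_count_filter(am$counts, threshold = 10)
    nb_wald_test(counts, am$condition, pair = am$pair)
  }
  ip <- {
    am <- arm_count_matrix(pool, cfg, arm = "ip", n_pairs = n_pairs)
    counts <- mean_count_filter(am$counts, threshold = 10)
    nb_wald_test(counts, am$condition, pair = am$pair)
  }
  summarize <- function(res, seqs, sign_) {
    sub <- res[res$feature %in% seqs, , drop = FALSE]
    sig <- !is.na(sub$padj) & sub$padj < alpha &
      (if (sign_ > 0) sub$log2fc > 0 else sub$log2fc < 0)
    list(n = nrow(sub), n_sig = sum(sig))
  }
  list(unuar_trf_cmc = summarize(cmc, class_seqs$unuar_trf, -1),
       psi55_trf_cmc = summarize(cmc, class_seqs$psi55_trf, -1),
       psi_mirna_ip = summarize(ip, class_seqs$psi_mirna, +1))
}
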