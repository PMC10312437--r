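test_that("sim_config validates probabilities, rates and size ranges", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(cmc_alpha = 1.2), "probabilities")
  expect_error(sim_config(mn_rates = c(mismatch = 0.7, deletion = 0.5)),
               "<= 1")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(size_ranges = list(mirna = c(22L, 20L))),
               "size range")
})

test_that("reference construction satisfies the planted-truth invariants", {
  cfg <- sim_config(seed = 4)
  b <- build_reference(cfg)
  ann <- b$reference$annotations
  seqs <- b$reference$sequences

  trna <- ann[ann$class == "tRNA", ]
  expect_gte(nrow(trna), 8L)
  expect_true(all(substr(seqs[trna$ref], trna$end - 2, trna$end) == "CCA"))
  expect_gte(sum(ann$class == "miRNA_precursor"), 20L)
  expect_gte(length(unique(ann$family[ann$class == "TE"])), 5L)
  expect_gte(sum(ann$class == "piRNA_cluster"), 2L)

  # every truth site sits on a uridine (T in DNA space)
  base_at <- substr(seqs[b$truth$ref], b$truth$pos + 1, b$truth$pos + 1)
  expect_true(all(base_at == "T"))

  # PUS10 sites at canonical position 55 (0-based 54) of 76-nt tRNAs
  p10 <- b$truth[b$truth$enzyme == "PUS10", ]
  expect_true(all(p10$pos == 54L))
  expect_setequal(p10$ref, trna$ref)

  # PUS7 sites are the third position of a UNUAR motif
  p7 <- b$truth[b$truth$enzyme == "PUS7", ]
  expect_gt(nrow(p7), 0L)
  for (i in seq_len(nrow(p7))) {
    # motif spans 0-based [pos-2, pos+2] with the modified U third
    ctx <- substr(seqs[p7$ref[i]], p7$pos[i] - 1, p7$pos[i] + 3)
    expect_match(ctx, "^T[ACGT]TA[AG]$")
  }
})

test_that("UNUAR scanning finds the motif's central U", {
  expect_identical(find_unuar("TATAG"), 2L)
  expect_identical(find_unuar("GGGGG"), integer(0))
  # multiple occurrences are all reported
  expect_identical(find_unuar("TATAATATAA"), c(2L, 7L))
})

test_that("genotype switches remove exactly their enzyme class", {
  for (g in c("pus7", "pus10", "dkc1")) {
    enz <- toupper(g)
    tr <- build_reference(sim_config(seed = 4, genotype = g))$truth
    expect_false(enz %in% tr$enzyme)
    expect_gt(nrow(tr), 0L)
  }
  wt <- build_reference(sim_config(seed = 4))$truth
  expect_setequal(unique(wt$enzyme), c("DKC1", "PUS10", "PUS7", "OTHER"))
})

test_that("species pools are deterministic and class-consistent", {
  cfg <- sim_config(seed = 8)
  b <- build_reference(cfg)
  p1 <- simulate_pool(b$reference, b$truth, cfg)
  p2 <- simulate_pool(b$reference, b$truth, cfg)
  expect_identical(p1$sequence, p2$sequence)
  expect_identical(p1$true_abundance, p2$true_abundance)

  # expected read counts sum to the configured depth
  expect_equal(sum(p1$true_abundance), cfg$depth)

  # every 3'-anchored tRF is a suffix of its tRNA and ends in CCA
  trna_seqs <- b$reference$sequences
  trf3 <- p1[p1$class == "tRF" & p1$end == 76L, ]
  expect_gt(nrow(trf3), 0L)
  for (i in seq_len(nrow(trf3))) {
    parent <- trna_seqs[[trf3$ref[i]]]
    expect_identical(trf3$sequence[i],
                     substr(parent, 77 - trf3$length[i], 76))
  }
  expect_true(all(endsWith(trf3$sequence, "CCA")))

  # length windows respected per class
  expect_true(all(p1$length[p1$class == "miRNA"] %in% 20:22))
  expect_true(all(p1$length[p1$class == "piRNA"] %in% 26:31))
  expect_true(all(p1$length[p1$class == "TE_siRNA"] %in% c(20:22, 23:25)))

  # minus-strand species never inherit plus-strand Psi truth
  expect_true(all(p1$n_psi[p1$strand == "-"] == 0L))
})

test_that("IP capture conserves the draw and matches the binomial model", {
  cfg <- sim_config(seed = 12, depth = 1e5,
                    ip_capture = c(bg = 0.05, psi = 0.8))
  b <- build_reference(cfg)
  pool <- simulate_pool(b$reference, b$truth, cfg)
  sim <- simulate_ip(pool, cfg, sample = "t1")
  cc <- sim$counts

  # conservation: bound + unbound equals the pool draw exactly
  expect_equal(sum(cc$bound) + sum(cc$unbound), cfg$depth)

  # binomial oracle: observed bound fraction of Psi species within 3 SE
  n_psi_reads <- sum(cc$bound[cc$n_psi > 0] + cc$unbound[cc$n_psi > 0])
  frac <- sum(cc$bound[cc$n_psi > 0]) / n_psi_reads
  se <- sqrt(0.8 * 0.2 / n_psi_reads)
  expect_lt(abs(frac - 0.8), 3 * se)
  n_bg <- sum(cc$bound[cc$n_psi == 0] + cc$unbound[cc$n_psi == 0])
  frac_bg <- sum(cc$bound[cc$n_psi == 0]) / n_bg
  expect_lt(abs(frac_bg - 0.05), 3 * sqrt(0.05 * 0.95 / n_bg))

  # degenerate captures
  cfg1 <- sim_config(seed = 12, depth = 2e4, ip_capture = c(bg = 0, psi = 1))
  s1 <- simulate_ip(pool, cfg1, sample = "t2")
  expect_true(all(s1$counts$unbound[s1$counts$n_psi > 0] == 0L))
  expect_true(all(s1$counts$bound[s1$counts$n_psi == 0] == 0L))

  # inverted enrichment is allowed but warned about
  cfg_inv <- sim_config(seed = 12, depth = 1e3,
                        ip_capture = c(bg = 0.5, psi = 0.1))
  expect_warning(simulate_ip(pool, cfg_inv, sample = "t3"), "inverted")
})

test_that("CMC RT-stop dropout follows 1 - (1 - alpha)^k", {
  cfg <- sim_config(seed = 13, depth = 1e5, cmc_alpha = 0.9)
  b <- build_reference(cfg)
  pool <- simulate_pool(b$reference, b$truth, cfg)
  sim <- simulate_cmc(pool, cfg, mode = "stop", sample = "t1")
  ev <- merge(sim$events, pool[, c("species", "n_psi")], by = "species")

  for (k in 1:2) {
    sub <- ev[ev$n_psi == k & ev$drawn > 0, ]
    drawn <- sum(sub$drawn); dropped <- sum(sub$dropped)
    p_exp <- 1 - (1 - 0.9)^k
    se <- sqrt(p_exp * (1 - p_exp) / drawn)
    expect_lt(abs(dropped / drawn - p_exp), 4 * se)
  }
  # full block: alpha = 1 removes every Psi-spanning read
  cfg1 <- sim_config(seed = 13, depth = 2e4, cmc_alpha = 1)
  s1 <- simulate_cmc(pool, cfg1, mode = "stop", sample = "t2")
  expect_true(all(s1$counts$treated[s1$counts$n_psi > 0] == 0L))
  # and the event log confirms zero survivors
  ev1 <- merge(s1$events, pool[, c("species", "n_psi")], by = "species")
  expect_true(all(ev1$drawn[ev1$n_psi > 0] == ev1$dropped[ev1$n_psi > 0]))
})

test_that("Mn2+ readthrough mutates Psi positions at the configured rates", {
  cfg <- sim_config(seed = 14, depth = 1e4, base_error = 0,
                    mn_rates = c(mismatch = 0.3, deletion = 0.1))
  # single-species pool with one Psi gives a clean binomial readout
  pool <- data.frame(species = "sp1", class = "tRF", parent = "x",
                     family = "", ref = "x", start = 0L, end = 24L,
                     strand = "+", length = 24L,
                     sequence = paste(rep("ACGT", 6), collapse = ""),
                     true_abundance = 1e4, n_psi = 1L,
                     stringsAsFactors = FALSE)
  pool$psi_offsets <- list(11L)
  sim <- simulate_cmc(pool, cfg, mode = "mn2plus", sample = "t1",
                      emit = "fastq")
  ev <- sim$events
  expect_equal(nrow(ev), 1L)
  se_m <- sqrt(0.3 * 0.7 / ev$n_reads)
  se_d <- sqrt(0.1 * 0.9 / ev$n_reads)
  expect_lt(abs(ev$n_sub / ev$n_reads - 0.3), 3 * se_m)
  expect_lt(abs(ev$n_del / ev$n_reads - 0.1), 3 * se_d)
  # deleted reads are one base shorter in the emitted FASTQ
  fq <- read_fastq(sim$files[["treated"]])
  ins <- nchar(fq$sequence) - nchar(cfg$adapter3)
  expect_setequal(sort(unique(ins)), c(23L, 24L))
  unlink(sim$files)
})

test_that("identical configuration reproduces byte-identical FASTQ", {
  cfg <- sim_config(seed = 21, depth = 3000)
  b <- build_reference(cfg)
  pool <- simulate_pool(b$reference, b$truth, cfg)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  s1 <- simulate_cmc(pool, cfg, mode = "mn2plus", sample = "s", dir = d1,
                     emit = "fastq")
  s2 <- simulate_cmc(pool, cfg, mode = "mn2plus", sample = "s", dir = d2,
                     emit = "fastq")
  for (f in c("treated", "mock")) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a simulation bundle round-trips through FASTA/BED/TSV", {
  cfg <- sim_config(seed = 6)
  b <- build_reference(cfg)
  d <- file.path(tempdir(), "bundle")
  paths <- write_sim_bundle(b$reference, b$truth, dir = d)
  seqs <- psiseq:::read_fasta(paths[["fasta"]])
  expect_identical(unname(seqs[names(b$reference$sequences)]),
                   unname(b$reference$sequences))
  ann <- read_annotation_bed(paths[["bed"]])
  orig <- b$reference$annotations
  m <- match(orig$name, ann$name)
  expect_false(anyNA(m))
  expect_equal(ann$start[m], orig$start)
  expect_equal(ann$end[m], orig$end)
  expect_equal(ann$class[m], orig$class)
  unlink(d, recursive = TRUE)
})
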