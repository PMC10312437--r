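test_that("the k-mer index enumerates positions on both strands", {
  idx <- build_index(c(chr = "ACGTACGT"), k = 4L)
  hits <- lookup_kmer(idx, "ACGT")
  plus <- hits[hits$strand == "+", ]
  expect_setequal(plus$pos, c(0L, 4L))
  # ACGT is its own reverse complement here, so minus-strand hits exist too
  expect_true(any(hits$strand == "-"))

  # a strand-specific k-mer is found via its reverse complement
  idx2 <- build_index(c(chr = "AAACCCGGG"), k = 3L)
  expect_identical(nrow(lookup_kmer(idx2, "TTT")[
    lookup_kmer(idx2, "TTT")$strand == "-", , drop = FALSE]), 1L)

  expect_identical(nrow(build_index(character(0), k = 4L)$kmers), 0L)
  expect_error(build_index(c(chr = "ACGT"), k = 0L))
})

test_that("mapping respects mismatch budgets and records edit ops", {
  set.seed(3)
  ref <- c(locus = random_seq(400))
  idx <- build_index(ref, k = 12L)
  read <- substr(ref[["locus"]], 101, 124)

  r0 <- map_read(read, idx, map_policy(0, 0))
  expect_identical(r0$start, 100L)
  expect_identical(r0$edits, 0L)
  expect_identical(nrow(r0$ops[[1]]), 0L)

  mm <- read
  substr(mm, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                              substr(mm, 7, 7))[1]
  expect_identical(nrow(map_read(mm, idx, map_policy(0, 0))), 0L)
  r1 <- map_read(mm, idx, map_policy(1, 0))
  expect_identical(r1$n_mm, 1L)
  expect_identical(r1$ops[[1]]$type, "mismatch")
  expect_identical(r1$ops[[1]]$ref_pos, 106L)

  # a reference deletion consumes reference, not read
  del <- paste0(substr(read, 1, 10), substr(read, 12, 24))
  r2 <- map_read(del, idx, map_policy(0, 1))
  hit <- r2[r2$start == 100L, ]
  expect_identical(hit$n_del, 1L)
  expect_identical(hit$ops[[1]]$type, "deletion")
  expect_identical(hit$ops[[1]]$ref_pos, 110L)

  # reads shorter than the seed length are reported unmapped
  short <- map_read("ACGTACGT", idx, map_policy(0, 0))
  expect_identical(nrow(short), 0L)
  expect_identical(attr(short, "reason"), "short")
})

test_that("a read and its reverse complement map to mirrored placements", {
  set.seed(4)
  ref <- c(locus = random_seq(300))
  idx <- build_index(ref, k = 10L)
  for (i in 1:10) {
    s <- sample(250, 1)
    read <- substr(ref[["locus"]], s, s + 21)
    fwd <- map_read(read, idx, map_policy(0, 0))
    rev <- map_read(oracle_revcomp(read), idx, map_policy(0, 0))
    expect_identical(sort(fwd$start), sort(rev$start))
    expect_setequal(paste(fwd$start, chartr("+-", "-+", fwd$strand)),
                    paste(rev$start, rev$strand))
  }
})

test_that("multimap policies keep all, drop, or sample the best tier", {
  ref <- c(two = paste0("AAAA", strrep("C", 30), "ACGTACGTACGTACGTACGT",
                        strrep("G", 30), "ACGTACGTACGTACGTACGT",
                        strrep("C", 10)))
  idx <- build_index(ref, k = 12L)
  read <- "ACGTACGTACGTACGTACGT"
  all_ <- map_read(read, idx, map_policy(0, 0, multimap = "all"))
  expect_gte(nrow(all_), 2L)
  expect_true(all(all_$n_hits >= 2L))
  uniq <- map_read(read, idx, map_policy(0, 0, multimap = "unique_only"))
  expect_identical(nrow(uniq), 0L)
  expect_identical(attr(uniq, "reason"), "multimapper")
  set.seed(5)
  one <- map_read(read, idx, map_policy(0, 0, multimap = "best_random"))
  expect_identical(nrow(one), 1L)
})

test_that("indexed search equals the exhaustive scan oracle", {
  set.seed(6)
  refs <- c(chrA = random_seq(1200), chrB = random_seq(800))
  idx <- build_index(refs, k = 10L)
  pol <- map_policy(max_mismatch = 2L, max_deletion = 1L, multimap = "all")
  n_checked <- 0L
  for (i in 1:200) {
    src <- sample(names(refs), 1)
    L <- sample(20:30, 1)
    s <- sample(nchar(refs[[src]]) - L, 1)
    read <- substr(refs[[src]], s, s + L - 1)
    read <- mutate_read(read, n_sub = sample(0:2, 1),
                        n_del = sample(0:1, 1))
    if (sample(c(TRUE, FALSE), 1)) read <- oracle_revcomp(read)
    got <- map_read(read, idx, pol)
    want <- oracle_map(read, refs, 2L, 1L)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(nrow(got), nrow(want))
      key <- function(x) paste(x$ref, x$start, x$strand, x$n_mm, x$n_del)
      expect_setequal(key(got), key(want))
    }
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 200L)
})

test_that("two-deletion placements are found where a handmade scan agrees", {
  set.seed(7)
  ref <- c(locus = random_seq(80))
  idx <- build_index(ref, k = 6L)
  read <- substr(ref[["locus"]], 21, 40)
  ch <- strsplit(read, "")[[1]]
  read2 <- paste(ch[-c(6, 13)], collapse = "")  # two internal deletions
  got <- map_read(read2, idx, map_policy(0, 2, multimap = "all"))
  hit <- got[got$start == 20L & got$strand == "+", ]
  expect_identical(hit$n_del, 2L)
  expect_identical(hit$n_mm, 0L)
  expect_identical(sum(hit$ops[[1]]$type == "deletion"), 2L)
})

test_that("alignments round-trip through SAM with CIGAR and MD intact", {
  set.seed(8)
  ref <- c(locus = random_seq(200))
  idx <- build_index(ref, k = 10L)
  read_ok <- substr(ref[["locus"]], 51, 74)
  read_del <- paste0(substr(read_ok, 1, 8), substr(read_ok, 10, 24))
  reads <- data.frame(sequence = c(read_ok, read_del), count = c(3L, 1L))
  aln <- map_reads(reads, idx, map_policy(1, 1, multimap = "unique_only"))
  path <- tempfile(fileext = ".sam")
  write_sam(aln, ref, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@SQ\tSN:locus\tLN:200$", lines)))
  back <- read_sam(path)
  expect_identical(nrow(back), nrow(aln))
  expect_identical(back$start, aln$start)
  expect_identical(back$n_del, aln$n_del)
  expect_identical(back$n_mm, aln$n_mm)
  expect_identical(back$count, aln$count)
  for (i in seq_len(nrow(aln))) {
    expect_identical(back$ops[[i]]$ref_pos, aln$ops[[i]]$ref_pos)
    expect_identical(back$ops[[i]]$type, aln$ops[[i]]$type)
  }
  unlink(path)
})
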