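mk_trna_ann <- function(name = "tRNA-Ala-AGC", len = 76L) {
  data.frame(name = name, ref = name, start = 0L, end = len, strand = "+",
             class = "tRNA", family = "Ala-AGC", stringsAsFactors = FALSE)
}

mk_aln_row <- function(ref, start, seq, n_del = 0L, count = 1L) {
  row <- data.frame(ref = ref, start = start, strand = "+", n_mm = 0L,
                    n_del = n_del, edits = n_del, n_hits = 1L,
                    stringsAsFactors = FALSE)
  row$ops <- list(data.frame(ref_pos = integer(0), type = character(0),
                             read_base = character(0)))
  row$sequence <- seq
  row$count <- count
  row
}

test_that("tRF classification anchors fragments and reads the geometry", {
  trna <- mk_trna_ann()
  # 22-nt 3'-CCA fragment: three_prime and spans position 55
  a22 <- mk_aln_row("tRNA-Ala-AGC", 54L, paste0(strrep("A", 19), "CCA"))
  r22 <- classify_trf(a22, trna)
  expect_identical(r22$class, "three_prime")
  expect_true(r22$has_cca)
  expect_true(r22$spans_psi55)

  # 20-nt 3'-CCA fragment misses position 55
  a20 <- mk_aln_row("tRNA-Ala-AGC", 56L, paste0(strrep("A", 17), "CCA"))
  r20 <- classify_trf(a20, trna)
  expect_identical(r20$class, "three_prime")
  expect_false(r20$spans_psi55)

  # 5' fragment and internal fragment
  a5 <- mk_aln_row("tRNA-Ala-AGC", 0L, strrep("G", 18))
  expect_identical(classify_trf(a5, trna)$class, "five_prime")
  ai <- mk_aln_row("tRNA-Ala-AGC", 10L, strrep("G", 18))
  expect_identical(classify_trf(ai, trna)$class, "internal")

  # UNUAR motif detection inside the read sequence
  am <- mk_aln_row("tRNA-Ala-AGC", 10L, paste0("GG", "TATAG", "GGGGG"))
  expect_true(classify_trf(am, trna)$has_unuar)
  expect_false(classify_trf(ai, trna)$has_unuar)

  bad <- mk_trna_ann(); bad$class <- "rRNA"
  expect_error(classify_trf(a22, bad), "tRNA feature")
})

test_that("on standard tRNAs spans_psi55 equals length >= 22 for 3'-tRFs", {
  # two independent code paths: interval arithmetic in classify_trf vs the
  # length rule forced by the geometry (position 55 is 22 nt upstream of
  # the 3' end of the CCA tail)
  trna <- mk_trna_ann()
  for (L in 18:30) {
    a <- mk_aln_row("tRNA-Ala-AGC", 76L - L,
                    paste0(strrep("A", L - 3L), "CCA"))
    rec <- classify_trf(a, trna)
    expect_identical(rec$spans_psi55, L >= 22L,
                     label = paste("length", L))
  }
})

test_that("TE aggregation counts a read once per family per size class", {
  ann <- data.frame(
    name = c("cp1", "cp2", "cp3"), ref = c("cp1", "cp2", "cp3"),
    start = 0L, end = 100L, strand = "+", class = "TE",
    family = c("FAM_A", "FAM_A", "FAM_B"), stringsAsFactors = FALSE)
  # one 21-nt read hits both copies of FAM_A; one 23-nt read hits FAM_B;
  # one 19-nt read is outside both size classes
  aln <- rbind(mk_aln_row("cp1", 0L, strrep("A", 21), count = 5L),
               mk_aln_row("cp2", 0L, strrep("A", 21), count = 5L),
               mk_aln_row("cp3", 10L, strrep("C", 23), count = 2L),
               mk_aln_row("cp3", 40L, strrep("G", 19), count = 9L))
  out <- aggregate_te_families(aln, ann)
  a_small <- out$count[out$family == "FAM_A" & out$size_class == "small"]
  expect_equal(a_small, 5)  # once per family, not once per copy
  b_large <- out$count[out$family == "FAM_B" & out$size_class == "large"]
  expect_equal(b_large, 2)
  expect_equal(sum(out$count), 7)  # the 19-nt read contributes nowhere

  # fractional mode splits a read across distinct families
  aln2 <- rbind(mk_aln_row("cp1", 0L, strrep("T", 21), count = 4L),
                mk_aln_row("cp3", 0L, strrep("T", 21), count = 4L))
  frac <- aggregate_te_families(aln2, ann, fractional = TRUE)
  expect_equal(sort(frac$count), c(2, 2))
})

test_that("Argonaute preference takes the argmax with tie and single flags", {
  e <- data.frame(family = "F", size_class = "small",
                  ago = c("AGO1", "AGO5", "AGO9"),
                  enrichment = c(0.2, 1.5, 0.7))
  out <- ago_preference(e)
  expect_identical(out$preferred, "AGO5")
  expect_identical(out$flag, "")

  tie <- e; tie$enrichment <- c(0.2, 1.0, 1.0)
  expect_identical(ago_preference(tie)$preferred, "AGO5")
  expect_identical(ago_preference(tie)$flag, "tie")

  one <- e[2, ]
  expect_identical(ago_preference(one)$flag, "uncontested")

  none <- e; none$enrichment <- NA_real_
  expect_identical(ago_preference(none)$preferred, "none")
})

test_that("repeat categories follow the stated precedence and clusters", {
  ann <- data.frame(
    name = c("LTR7", "snrna", "clus7"),
    ref = c("chr", "chr", "chr"),
    start = c(100L, 100L, 50L), end = c(200L, 130L, 400L), strand = "+",
    class = c("TE", "snRNA", "piRNA_cluster"), family = c("LTR", "", ""),
    stringsAsFactors = FALSE)
  aln <- rbind(
    mk_aln_row("chr", 110L, strrep("A", 25)),  # TE + snRNA overlap
    mk_aln_row("chr", 300L, strrep("C", 25)),  # cluster only
    mk_aln_row("chr", 500L, strrep("G", 25)))  # nothing
  out <- categorize_repeats(aln, ann)
  by_seq <- stats::setNames(out$category, out$sequence)
  expect_identical(unname(by_seq[strrep("A", 25)]), "transposon")
  expect_identical(unname(by_seq[strrep("C", 25)]), "neither")
  expect_identical(unname(by_seq[strrep("G", 25)]), "neither")
  expect_identical(out$cluster[out$sequence == strrep("C", 25)], "clus7")
  expect_true(is.na(out$cluster[out$sequence == strrep("G", 25)]))
  # the categories partition the reads
  expect_identical(nrow(out), 3L)
})

test_that("terminal nucleotide bias reports per-end enrichments", {
  a <- c("TAAAC", "TGGGC", "TCCCC", "TTTTC")  # all 5' U
  b <- c("AAAAA", "CAAAC", "GAAAG", "TAAAT")  # uniform 5' base
  out <- terminal_nt_bias(a, b, pseudocount = 0)
  u5 <- out[out$end == "five_prime" & out$base == "U", ]
  expect_equal(u5$log2_enrichment, 2)  # log2(1 / 0.25)

  same <- terminal_nt_bias(a, a, pseudocount = 0.5)
  expect_true(all(same$log2_enrichment == 0))

  expect_error(terminal_nt_bias(a, b, structural = a[1]), "structural")
  expect_error(terminal_nt_bias(character(0), b), "empty")
})

test_that("size distributions report the mode with a smallest-length tie", {
  out <- size_distribution(c(22L, 22L, 25L))
  expect_identical(out$mode, 22L)
  expect_false(out$tie)

  tie <- size_distribution(c(22L, 23L))
  expect_identical(tie$mode, 22L)
  expect_true(tie$tie)

  e <- size_distribution(integer(0))
  expect_true(is.na(e$mode))
  expect_identical(nrow(e$histogram), 0L)

  w <- size_distribution(c(22L, 30L), weights = c(1, 10))
  expect_identical(w$mode, 30L)
})
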