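null_counts <- function(seed, n = 200, npair = 3, meanlog = 4, sdlog = 1,
                        disp_meanlog = log(0.05)) {
  set.seed(seed)
  q <- rlnorm(n, meanlog, sdlog)
  sfs <- exp(runif(2 * npair, -0.4, 0.4))
  disp <- pmax(0.005, rlnorm(n, disp_meanlog, 0.5))
  cnt <- matrix(rnbinom(n * 2 * npair, mu = outer(q, sfs),
                        size = rep(1 / disp, 2 * npair)), nrow = n,
                dimnames = list(sprintf("f%04d", seq_len(n)),
                                paste0("s", seq_len(2 * npair))))
  list(counts = cnt,
       condition = factor(rep(c("control", "treatment"), npair),
                          levels = c("control", "treatment")),
       pair = factor(rep(seq_len(npair), each = 2)), disp = disp)
}

test_that("median-of-ratios size factors behave like the worked examples", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(letters[1:3], c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  ident <- matrix(c(5, 9, 14, 5, 9, 14), ncol = 2,
                  dimnames = list(letters[1:3], c("A", "B")))
  expect_equal(unname(size_factors(ident)), c(1, 1))

  # all-zero-in-some-sample fallback
  z <- matrix(c(0, 10, 5, 0), ncol = 2,
              dimnames = list(c("a", "b"), c("A", "B")))
  expect_warning(size_factors(z), "falling back")
})

test_that("scaling one library rescales only its factor and no log2FC", {
  nd <- null_counts(101)
  res1 <- nb_wald_test(nd$counts, nd$condition, pair = nd$pair)
  scaled <- nd$counts
  scaled[, 2] <- scaled[, 2] * 4L
  sf1 <- size_factors(nd$counts); sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[2] / sf1[2] / (sf2[1] / sf1[1])), 4,
               tolerance = 0.15)
  res2 <- nb_wald_test(scaled, nd$condition, pair = nd$pair)
  expect_equal(res2$log2fc, res1$log2fc, tolerance = 0.05)
})

test_that("the mean-count filter applies strict and inclusive thresholds", {
  m <- matrix(c(11, 11, 10, 10, 120, 80), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  kept <- mean_count_filter(m, threshold = 10)
  expect_setequal(rownames(kept), c("a", "c"))  # strict >10: (10,10) dropped
  clus <- mean_count_filter(m, threshold = 100, samples = "s1",
                            strict = FALSE)
  expect_setequal(rownames(clus), "c")  # >=100 on the chosen arm
  e <- mean_count_filter(m[0, , drop = FALSE], threshold = 10)
  expect_identical(nrow(e), 0L)
})

test_that("the NB Wald engine handles null, paired and degenerate designs", {
  nd <- null_counts(102)
  res <- nb_wald_test(nd$counts, nd$condition, pair = nd$pair)
  expect_true(all(is.finite(res$log2fc)))
  expect_true(all(res$padj >= res$pvalue - 1e-12, na.rm = TRUE))
  # a feature with identical counts in both conditions sits at log2FC ~ 0
  flat <- nd$counts
  flat[1, ] <- rep(50L, 6)
  sf_unit <- stats::setNames(rep(1, 6), colnames(flat))
  r <- nb_wald_test(flat, nd$condition, pair = nd$pair, sf = sf_unit)
  expect_equal(r$log2fc[r$feature == "f0001"], 0, tolerance = 1e-6)

  # fewer than 2 pairs: ratio-only report with a warning
  expect_warning(
    r1 <- nb_wald_test(nd$counts[, 1:2], nd$condition[1:2],
                       pair = nd$pair[1:2]),
    "fewer than 2 pairs")
  expect_true(all(is.na(r1$pvalue)))
  expect_true(all(is.finite(r1$log2fc)))
})

test_that("the Wald statistic matches a Poisson GLM as dispersion vanishes", {
  nd <- null_counts(103, n = 60, disp_meanlog = log(1e-4))
  set.seed(103)
  cnt <- matrix(rpois(60 * 6, outer(rlnorm(60, 4, 1), rep(1, 6))), nrow = 60,
                dimnames = dimnames(nd$counts))
  res <- nb_wald_test(cnt, nd$condition, pair = nd$pair, dispersion = 1e-8)
  sf <- size_factors(cnt)
  z_pois <- vapply(seq_len(nrow(cnt)), function(i) {
    fit <- stats::glm(cnt[i, ] ~ nd$pair + nd$condition,
                      family = stats::poisson(), offset = log(sf))
    stats::coef(summary(fit))[4, 3]
  }, numeric(1))
  rel <- abs(res$stat - z_pois) / pmax(abs(z_pois), 1e-8)
  expect_lt(max(rel, na.rm = TRUE), 0.01)
})

test_that("the paired t-test cross-check agrees with the NB engine on sign", {
  nd <- null_counts(104, n = 100)
  eff <- nd$counts
  eff[1:10, nd$condition == "treatment"] <-
    eff[1:10, nd$condition == "treatment"] * 8L
  res_nb <- nb_wald_test(eff, nd$condition, pair = nd$pair)
  res_tt <- nb_wald_test(eff, nd$condition, pair = nd$pair,
                         method = "ttest")
  strong <- paste0("f", sprintf("%04d", 1:10))
  expect_true(all(res_nb$log2fc[res_nb$feature %in% strong] > 0))
  expect_true(all(res_tt$log2fc[res_tt$feature %in% strong] > 0))
})

test_that("replicate averaging is two-stage and order-invariant", {
  x <- data.frame(feature = "f", tissue = "pollen",
                  biorep = c("b1", "b1", "b2"),
                  techrep = c("t1", "t2", "t1"),
                  log2fc = c(1.0, 3.0, 2.0))
  out <- replicate_average(x)
  expect_equal(out$log2fc, 2.0)  # mean(mean(1, 3), 2)

  # single replicate passes through
  one <- replicate_average(x[3, ])
  expect_equal(one$log2fc, 2.0)

  # permuting rows changes nothing
  perm <- replicate_average(x[c(3, 1, 2), ])
  expect_equal(perm$log2fc, out$log2fc)

  bad <- x; bad$biorep[2] <- NA; bad$sample <- c("s1", "s2", "s3")
  expect_error(replicate_average(bad), "s2")
})

test_that("Psi feature calls combine the IP and CMC arms as specified", {
  lvl <- function(df) { attr(df, "feature_level") <- "miRNA"; df }
  ip <- lvl(data.frame(feature = c("a", "b", "c"),
                       log2fc = c(2, 1.5, -1), padj = c(0.005, 0.002, 0.5)))
  cmc <- lvl(data.frame(feature = c("a", "b", "c"),
                        log2fc = c(-1.5, 0.5, -2), padj = c(0.004, 0.2, 0.3)))
  out <- call_psi_features(ip, cmc, alpha = 0.01)
  cls <- stats::setNames(out$calls$class, out$calls$feature)
  expect_identical(unname(cls["a"]), "both")
  expect_identical(unname(cls["b"]), "IP-only")
  expect_identical(unname(cls["c"]), "none")
  expect_identical(unname(out$overlap["IP_and_CMC"]), 1L)

  # degenerate threshold: no calls at alpha = 0
  none <- call_psi_features(ip, cmc, alpha = 0)
  expect_true(all(none$calls$class == "none"))

  # mismatched feature levels refuse to combine
  cmc2 <- cmc; attr(cmc2, "feature_level") <- "sequence"
  expect_error(call_psi_features(ip, cmc2), "levels differ")

  # three-way overlap with the Mn2+ caller
  withmn <- call_psi_features(ip, cmc, alpha = 0.01, mn_features = c("a"))
  expect_identical(unname(withmn$overlap["all_three"]), 1L)
})

test_that("RIP reproducibility applies pseudocounts and the 2-line rule", {
  mk <- function(tx, class, fcs) {
    # control line ratio 1; per-line IP chosen to give the target FCs
    rows <- data.frame(transcript = tx, class = class, line = "ctl",
                       ip = 1, input = 1)
    for (i in seq_along(fcs)) {
      rows <- rbind(rows, data.frame(transcript = tx, class = class,
                                     line = paste0("L", i),
                                     ip = fcs[i], input = 1))
    }
    rows
  }
  # pseudocount shifts the realized ratios, so compute the expectation the
  # same way the rule defines it
  tpm <- rbind(mk("t1", "pri_miRNA", c(1.6, 1.5, 1.0)),
               mk("t2", "pri_miRNA", c(1.6, 1.05, 1.02)))
  out <- rip_reproducibility(tpm, control = "ctl")
  expect_true(out$enriched[out$transcript == "t1"])
  expect_false(out$enriched[out$transcript == "t2"])

  # zero-abundance control stays finite via the class pseudocount
  z <- data.frame(transcript = "t3", class = "pri_miRNA",
                  line = c("ctl", "L1", "L2"), ip = c(0, 5, 5),
                  input = c(0, 1, 1))
  outz <- rip_reproducibility(z, control = "ctl")
  expect_true(all(is.finite(c(outz$fc_L1, outz$fc_L2))))

  u <- data.frame(transcript = "t4", class = "lncRNA",
                  line = c("ctl", "L1", "L2"), ip = 1, input = 1)
  expect_warning(rip_reproducibility(u, control = "ctl"), "unknown RNA class")
})

test_that("size factors agree with the reference implementation", {
  nd <- null_counts(105, n = 80)
  sf <- size_factors(nd$counts)
  ref_sf <- DESeq2::estimateSizeFactorsForMatrix(nd$counts)
  # identical up to a common rescaling
  expect_equal(unname(sf / sf[1]), unname(ref_sf / ref_sf[1]),
               tolerance = 1e-8)
})
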