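# Paired differential-enrichment engine: median-of-ratios normalization,
# moderated negative-binomial Wald tests with a pair covariate, BH
# correction, replicate-averaging rules, and the RIP reproducibility rule.

#' Assemble a count matrix from collapsed read tables
#'
#' @param tables Named list of data.frames with `sequence`/`feature` and
#'   `count` columns, one per sample (names become column names).
#' @param feature_level Label describing what the rows are (`"sequence"`,
#'   `"miRNA"`, `"tRF_isotype"`, `"TE_family_sizeclass"`, `"piRNA_cluster"`).
#' @return Integer matrix features x samples with a `feature_level`
#'   attribute.
#' @export
build_count_matrix <- function(tables, feature_level = "sequence") {
  stopifnot(length(names(tables)) == length(tables))
  key <- function(x) if (!is.null(x$feature)) x$feature else x$sequence
  feats <- sort(unique(unlist(lapply(tables, key))))
  mat <- vapply(tables, function(x) {
    v <- stats::setNames(rep.int(0L, length(feats)), feats)
    v[key(x)] <- as.integer(x$count)
    v
  }, integer(length(feats)))
  mat <- matrix(mat, nrow = length(feats),
                dimnames = list(feats, names(tables)))
  attr(mat, "feature_level") <- feature_level
  mat
}

#' Median-of-ratios size factors
#'
#' For each sample the factor is the median, over features with nonzero
#' counts in every sample, of the ratio of the count to the feature's
#' geometric mean; factors are rescaled to geometric mean 1, so multiplying
#' one library by a constant multiplies only its own factor.
#'
#' @param counts Integer matrix features x samples.
#' @return Positive numeric vector, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  lg <- log(counts)
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  if (!any(use)) {
    warning("no feature has nonzero counts in all samples; ",
            "falling back to total-count ratios")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("a sample has zero total counts", call. = FALSE)
  } else {
    sf <- apply(lg[use, , drop = FALSE], 2,
                function(col) exp(stats::median(col - geo[use])))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Mean-count feature filter
#'
#' Keeps features whose mean raw count across the chosen samples exceeds the
#' threshold. The sequence-level analyses use a strict `> 10` rule; the
#' piRNA-cluster analysis requires `>= 100` mean raw reads per sample of the
#' relevant arm (`strict = FALSE`, `samples` restricted to that arm).
#'
#' @param counts Count matrix.
#' @param threshold Mean-count threshold.
#' @param samples Optional column names/indices over which the mean is taken.
#' @param strict `TRUE` keeps `mean > threshold`; `FALSE` keeps
#'   `mean >= threshold`.
#' @return The filtered matrix (attributes preserved).
#' @export
mean_count_filter <- function(counts, threshold = 10, samples = NULL,
                              strict = TRUE) {
  if (!nrow(counts)) return(counts)
  sub <- if (is.null(samples)) counts else counts[, samples, drop = FALSE]
  m <- rowMeans(sub)
  keep <- if (strict) m > threshold else m >= threshold
  out <- counts[keep, , drop = FALSE]
  attr(out, "feature_level") <- attr(counts, "feature_level")
  out
}

estimate_dispersions <- function(norm, condition, sf) {
  base_mean <- rowMeans(norm)
  groups <- split(seq_along(condition), condition)
  nfeat <- nrow(norm)
  vsum <- numeric(nfeat); df <- 0
  for (g in groups) {
    if (length(g) < 2L) next
    vsum <- vsum + apply(norm[, g, drop = FALSE], 1, stats::var) *
      (length(g) - 1L)
    df <- df + length(g) - 1L
  }
  vpool <- vsum / max(1, df)
  mom <- (vpool - base_mean * mean(1 / sf)) / base_mean^2
  mom[!is.finite(mom)] <- NA
  floor_ <- 1e-8
  # a pooled variance on df degrees of freedom has
  # E[log v] = log E[v] + digamma(df/2) - log(df/2); working in log space
  # (for the loess trend and the geometric shrinkage) without this
  # correction systematically underestimates the dispersion and inflates
  # the Wald statistic
  logbias <- if (df >= 2) digamma(df / 2) - log(df / 2) else 0
  lmom <- log(pmax(mom, floor_)) - logbias
  mom_f <- exp(lmom)
  ok <- !is.na(mom) & mom > 1e-6 & base_mean > 0
  trend <- rep(stats::median(mom_f[ok], na.rm = TRUE), nfeat)
  if (sum(ok) >= 20L) {
    fit <- try(stats::loess(lmom[ok] ~ log(base_mean[ok]),
                            span = 0.6, degree = 1), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      pr <- try(stats::predict(fit, newdata = log(pmax(base_mean, 1e-8))),
                silent = TRUE)
      if (!inherits(pr, "try-error")) {
        tr <- exp(pr)
        trend <- ifelse(is.finite(tr), tr, trend)
      }
    }
  }
  if (all(is.na(trend))) trend <- rep(0.01, nfeat)
  trend <- pmax(trend, floor_)
  disp <- exp(0.5 * lmom + 0.5 * log(trend))
  disp[is.na(mom)] <- trend[is.na(mom)]
  out <- pmax(disp, floor_)
  attr(out, "df") <- df
  out
}

#' Paired negative-binomial Wald enrichment test
#'
#' For each feature, fits a negative-binomial log-linear model of the raw
#' counts with a pair covariate and a condition coefficient, using
#' median-of-ratios size factors as offsets. Dispersions are estimated per
#' feature by the method of moments on normalized counts and shrunk 50/50
#' (in log space) toward a loess mean-dispersion trend. The condition
#' coefficient's Wald statistic gives a two-sided p-value; BH correction is
#' applied across the tested features. The reported `log2fc` is the
#' moment estimate with a 0.5 normalized-count pseudocount on both sides
#' (always finite); the raw GLM coefficient is kept as `log2fc_mle`.
#'
#' @param counts Integer matrix features x samples (already filtered with
#'   [mean_count_filter()]; excluded features must not be present, so they
#'   do not enter the BH denominator).
#' @param condition Factor of length `ncol(counts)`; the first level is the
#'   control/denominator.
#' @param pair Optional factor pairing treatment and control libraries
#'   (library pairs prepared from the same RNA).
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param dispersion Optional fixed dispersion (scalar or per feature),
#'   bypassing estimation.
#' @param method `"glm"` (NB Wald, default) or `"ttest"` (per-pair log-ratio
#'   one-sample t-test, provided as a cross-check).
#' @return A data.frame: `feature`, `base_mean`, `log2fc`, `lfc_se`,
#'   `log2fc_mle`, `stat`, `pvalue`, `padj`, `dispersion`. With fewer than
#'   two pairs, a ratio-only report (no p-values) with a warning.
#' @export
nb_wald_test <- function(counts, condition, pair = NULL, sf = NULL,
                         dispersion = NULL, method = c("glm", "ttest")) {
  method <- match.arg(method)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2L, length(condition) == ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  trt <- condition == levels(condition)[2]
  base_mean <- rowMeans(norm)
  m_t <- rowMeans(norm[, trt, drop = FALSE])
  m_c <- rowMeans(norm[, !trt, drop = FALSE])
  lfc_mom <- log2((m_t + 0.5) / (m_c + 0.5))
  level <- attr(counts, "feature_level")

  if (!is.null(pair)) pair <- droplevels(as.factor(pair))
  n_pairs <- if (is.null(pair)) min(sum(trt), sum(!trt)) else nlevels(pair)
  if (n_pairs < 2L) {
    warning("fewer than 2 pairs: reporting ratios without p-values")
    out <- data.frame(feature = rownames(counts), base_mean = base_mean,
                      log2fc = lfc_mom, lfc_se = NA_real_,
                      log2fc_mle = NA_real_, stat = NA_real_,
                      pvalue = NA_real_, padj = NA_real_,
                      dispersion = NA_real_, stringsAsFactors = FALSE)
    attr(out, "feature_level") <- level
    return(out)
  }

  if (method == "ttest") {
    stopifnot(!is.null(pair))
    pair <- as.factor(pair)
    ratio <- vapply(levels(pair), function(p) {
      i_t <- which(pair == p & trt); i_c <- which(pair == p & !trt)
      log2((norm[, i_t[1]] + 0.5) / (norm[, i_c[1]] + 0.5))
    }, numeric(nrow(counts)))
    ratio <- matrix(ratio, nrow = nrow(counts))
    tt <- apply(ratio, 1, function(r) {
      if (stats::sd(r) == 0) return(c(NA, if (all(r == 0)) 1 else NA))
      ht <- stats::t.test(r)
      c(ht$statistic, ht$p.value)
    })
    out <- data.frame(feature = rownames(counts), base_mean = base_mean,
                      log2fc = rowMeans(ratio), lfc_se = apply(ratio, 1,
                        stats::sd) / sqrt(ncol(ratio)),
                      log2fc_mle = NA_real_, stat = tt[1, ],
                      pvalue = tt[2, ],
                      padj = stats::p.adjust(tt[2, ], "BH"),
                      dispersion = NA_real_, stringsAsFactors = FALSE)
    attr(out, "feature_level") <- level
    return(out)
  }

  if (is.null(dispersion)) {
    disp <- estimate_dispersions(norm, condition, sf)
    # estimated dispersions carry their own sampling noise; the Wald
    # statistic is referred to a t distribution with moderated degrees of
    # freedom (residual df of the dispersion estimate plus an equal prior
    # contribution from the 50/50 trend shrinkage), as in moderated
    # small-sample count frameworks
    wald_df <- 2 * attr(disp, "df")
  } else {
    disp <- rep_len(dispersion, nrow(counts))
    wald_df <- Inf  # dispersion known: normal reference
  }

  off <- log(sf)
  design <- if (!is.null(pair) && nlevels(as.factor(pair)) > 1L) {
    data.frame(pair = as.factor(pair), cond = condition)
  } else {
    data.frame(cond = condition)
  }
  fml <- if ("pair" %in% names(design)) y ~ pair + cond else y ~ cond
  beta <- se <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    dat <- design; dat$y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp[i], link = "log")
    fit <- try(suppressWarnings(
      stats::glm(fml, data = dat, family = fam, offset = off)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    # dispersion = 1: the NB theta already encodes the variance model, so
    # the Wald SE is model-based, not a residual quasi-dispersion
    cf <- summary(fit, dispersion = 1)$coefficients
    row <- grep("^cond", rownames(cf))
    if (length(row) == 1L) {
      beta[i] <- cf[row, 1]; se[i] <- cf[row, 2]
    }
  }
  stat <- beta / se
  pval <- if (is.finite(wald_df)) 2 * stats::pt(-abs(stat), df = wald_df)
    else 2 * stats::pnorm(-abs(stat))
  out <- data.frame(feature = rownames(counts), base_mean = base_mean,
                    log2fc = lfc_mom, lfc_se = se / log(2),
                    log2fc_mle = beta / log(2), stat = stat, pvalue = pval,
                    padj = stats::p.adjust(pval, "BH"), dispersion = disp,
                    stringsAsFactors = FALSE)
  attr(out, "feature_level") <- level
  out
}

#' Two-stage replicate averaging
#'
#' Averages technical replicates (separate library preparations of the same
#' RNA) within each biological replicate first, then averages biological
#' replicates, per feature and grouping condition. Permutation-invariant in
#' the replicate order.
#'
#' @param x Long data.frame with at least the value column, `biorep` and
#'   `techrep` columns, and any feature/grouping columns.
#' @param value Name of the value column (e.g. `"log2fc"`).
#' @param by Character vector of columns defining the output rows (feature
#'   and condition columns; everything except replicate ids).
#' @return Data.frame with the `by` columns and the averaged value.
#' @export
replicate_average <- function(x, value = "log2fc",
                              by = setdiff(names(x),
                                           c(value, "biorep", "techrep",
                                             "sample"))) {
  need <- c(value, "biorep", "techrep")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing replicate metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- is.na(x$biorep) | is.na(x$techrep)
  if (any(bad)) {
    who <- if (!is.null(x$sample)) paste(unique(x$sample[bad]), collapse = ", ")
      else paste(which(bad), collapse = ", ")
    stop("missing replicate metadata for sample(s): ", who, call. = FALSE)
  }
  dt <- data.table::as.data.table(x)
  stage1 <- dt[, list(.v = mean(get(value))), by = c(by, "biorep")]
  out <- stage1[, list(.v = mean(.v)), by = by]
  data.table::setnames(out, ".v", value)
  as.data.frame(out)
}

#' Combine IP and CMC enrichment into per-feature Psi calls
#'
#' A feature is IP-positive when significantly enriched in the bound
#' fraction (`padj < alpha`, `log2fc > 0`) and CMC-positive when
#' significantly depleted from the treated library (`padj < alpha`,
#' `log2fc < 0`); features positive in both get class `"both"`. When a set
#' of features with CMC/Mn2+ mismatch evidence is supplied, the three-assay
#' overlap is tabulated.
#'
#' @param ip_results,cmc_results Data.frames from [nb_wald_test()] at the
#'   same feature level.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param mn_features Optional character vector of features called by the
#'   mismatch site caller.
#' @return A list: `calls` (feature, ip_positive, cmc_positive, class) and
#'   `overlap` (named counts of the assay combinations).
#' @export
call_psi_features <- function(ip_results, cmc_results, alpha = 0.01,
                              mn_features = NULL) {
  li <- attr(ip_results, "feature_level")
  lc <- attr(cmc_results, "feature_level")
  if (!is.null(li) && !is.null(lc) && !identical(li, lc)) {
    stop("feature levels differ: ", li, " vs ", lc, call. = FALSE)
  }
  feats <- union(ip_results$feature, cmc_results$feature)
  ipp <- with(ip_results, feature[!is.na(padj) & padj < alpha & log2fc > 0])
  cmp <- with(cmc_results, feature[!is.na(padj) & padj < alpha & log2fc < 0])
  calls <- data.frame(feature = feats,
                      ip_positive = feats %in% ipp,
                      cmc_positive = feats %in% cmp,
                      stringsAsFactors = FALSE)
  calls$class <- ifelse(calls$ip_positive & calls$cmc_positive, "both",
                 ifelse(calls$ip_positive, "IP-only",
                 ifelse(calls$cmc_positive, "CMC-only", "none")))
  overlap <- c(IP = length(ipp), CMC = length(cmp),
               IP_and_CMC = length(intersect(ipp, cmp)))
  if (!is.null(mn_features)) {
    overlap <- c(overlap, Mn = length(mn_features),
                 IP_and_Mn = length(intersect(ipp, mn_features)),
                 CMC_and_Mn = length(intersect(cmp, mn_features)),
                 all_three = length(Reduce(intersect,
                                           list(ipp, cmp, mn_features))))
  }
  list(calls = calls, overlap = overlap)
}

#' RIP-seq reproducible-enrichment rule
#'
#' Given per-line IP and input abundances (TPM) for tagged lines and a
#' control, adds a class-specific pseudocount (0.1 for snRNA/snoRNA, 0.01
#' for pri-/pre-miRNA and, with a warning, for unknown classes), computes
#' per line `FC = (IP/input)_line / (IP/input)_control`, and calls a
#' transcript reproducibly enriched when `FC >= min_fc` in at least
#' `min_lines` lines.
#'
#' @param tpm Long data.frame: `transcript`, `class`, `line`, `ip`, `input`.
#' @param control Name of the control line in `line`.
#' @param min_fc Fold-change threshold (default 1.2).
#' @param min_lines Minimum number of lines passing (default 2).
#' @return Data.frame: `transcript`, per-line fold changes (`fc_<line>`),
#'   `n_pass`, `enriched`.
#' @export
rip_reproducibility <- function(tpm, control, min_fc = 1.2, min_lines = 2L) {
  stopifnot(all(c("transcript", "class", "line", "ip", "input") %in%
                  names(tpm)), control %in% tpm$line)
  known <- c(snRNA = 0.1, snoRNA = 0.1, pri_miRNA = 0.01, pre_miRNA = 0.01)
  unknown <- setdiff(unique(tpm$class), names(known))
  if (length(unknown)) {
    warning("unknown RNA class(es) ", paste0("'", unknown, "'",
                                             collapse = ", "),
            ": using pseudocount 0.01")
  }
  pc <- ifelse(tpm$class %in% names(known), known[tpm$class], 0.01)
  tpm$ratio <- (tpm$ip + pc) / (tpm$input + pc)
  ctl <- tpm[tpm$line == control, c("transcript", "ratio")]
  lines <- setdiff(unique(tpm$line), control)
  out <- data.frame(transcript = unique(tpm$transcript),
                    stringsAsFactors = FALSE)
  fc_mat <- matrix(NA_real_, nrow = nrow(out), ncol = length(lines),
                   dimnames = list(out$transcript, lines))
  for (ln in lines) {
    sub <- tpm[tpm$line == ln, c("transcript", "ratio")]
    merged <- merge(sub, ctl, by = "transcript",
                    suffixes = c("_line", "_ctl"))
    fc_mat[merged$transcript, ln] <- merged$ratio_line / merged$ratio_ctl
  }
  for (ln in lines) out[[paste0("fc_", ln)]] <- fc_mat[out$transcript, ln]
  out$n_pass <- rowSums(fc_mat >= min_fc, na.rm = TRUE)
  out$enriched <- out$n_pass >= min_lines
  out
}
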