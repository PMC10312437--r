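# Orchestration: a single YAML-able config drives simulate -> preprocess ->
# align -> count -> enrich -> sites -> classify, with a report bundle of
# TSV tables (each stamped with the config hash) and, when truth is
# available, truth-vs-call confusion tables.

#' Default run configuration
#'
#' All published thresholds are named keys with their reference values:
#' `alpha = 0.01`, `min_reads = 5`, `min_fc = 1.5`, `mean_filter = 10`,
#' `cluster_min = 100`, metaplot windows 25/6 (TE-style) and 50/12
#' (broad-region style).
#'
#' @param seed Master seed.
#' @param outdir Report directory.
#' @return Nested config list (YAML-serializable).
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("psiseq_run")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(genotype = "WT", depth = 2e4, n_pairs = 2L,
                    arms = c("ip", "cmc", "mn2")),
    preprocess = list(preset = "te", dialect = "NEB"),
    align = list(k = 12L, max_mismatch = 1L, max_deletion = 1L,
                 multimap = "all"),
    enrich = list(alpha = 0.01, mean_filter = 10),
    sites = list(min_reads = 5L, min_fc = 1.5,
                 metaplot = list(halfwidth = 25L, smooth = 6L)))
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return Config list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; returns (never raises) the list of
#' problems, empty when the config is valid. Notable cross-field rule: the
#' Mn2+ arm needs `align$max_deletion >= 1`, otherwise the deletion half of
#' the readthrough signal is invisible.
#'
#' @param config Config list.
#' @return Character vector of error messages (length 0 = ok).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$seed)) push("seed is required")
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$paths)
  if (!has_sim && !has_files) {
    push("either a simulate block or a paths block is required")
  }
  if (has_files) {
    for (p in c("reference", "annotations")) {
      if (is.null(config$paths[[p]])) {
        push(paste0("paths$", p, " is required"))
      } else if (!file.exists(config$paths[[p]])) {
        push(paste0("paths$", p, ": file not found: ", config$paths[[p]]))
      }
    }
  }
  if (has_sim) {
    if (!is.null(config$simulate$depth) && config$simulate$depth <= 0) {
      push("simulate$depth must be > 0")
    }
    g <- config$simulate$genotype
    if (!is.null(g) && !g %in% c("WT", "pus7", "pus10", "dkc1")) {
      push(paste0("unknown genotype: ", g))
    }
    bad_arms <- setdiff(config$simulate$arms, c("ip", "cmc", "mn2"))
    if (length(bad_arms)) {
      push(paste0("unknown arm(s): ", paste(bad_arms, collapse = ", ")))
    }
  }
  pr <- config$preprocess$preset
  if (!is.null(pr) && !pr %in% c("rrna", "te", "mirna", "mn2", "mouse")) {
    push(paste0("unknown preprocessing preset: ", pr))
  }
  if ("mn2" %in% config$simulate$arms &&
      !is.null(config$align$max_deletion) &&
      config$align$max_deletion < 1L) {
    push("mn2 arm requires align$max_deletion >= 1 (deletions at Psi)")
  }
  a <- config$enrich$alpha
  if (!is.null(a) && (a < 0 || a > 1)) push("enrich$alpha must be in [0, 1]")
  errs
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or ingests) the libraries for the configured assay arms and
#' runs every downstream stage, writing a TSV report bundle: per-arm count
#' matrices and enrichment tables, combined Psi calls with the assay
#' overlap, Mn2+ position calls, the rRNA metaplot matrix, and (with
#' simulated truth) a truth-vs-call confusion table. Deterministic under a
#' fixed seed; every table carries the config hash in a header comment.
#'
#' @param config Config list (see [default_run_config()]); validated first.
#' @return Invisibly, a list with the in-memory results (`enrichment`,
#'   `calls`, `overlap`, `mn2_calls`, `metaplot`, `confusion`, `files`).
#' @export
run_all <- function(config = default_run_config()) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis parameters, not the output location
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  hdr <- paste0("psiseq config=", hash, " seed=", config$seed)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$outdir, paste0(name, ".tsv"))
    write_tsv(x, p, header_comment = hdr)
    files[[name]] <<- p
    p
  }

  scfg <- sim_config(seed = config$seed,
                     genotype = config$simulate$genotype,
                     depth = config$simulate$depth,
                     dialect = config$preprocess$dialect)
  built <- stage("reference", build_reference(scfg))
  pool <- stage("pool", simulate_pool(built$reference, built$truth, scfg))
  ref <- built$reference
  n_pairs <- config$simulate$n_pairs

  policy <- preset_policy(config$preprocess$preset,
                          dialect = config$preprocess$dialect)
  idx <- build_index(ref, k = config$align$k)
  mpol <- map_policy(config$align$max_mismatch, config$align$max_deletion,
                     multimap = config$align$multimap)
  alpha <- config$enrich$alpha

  enrichment <- list()
  for (arm in intersect(config$simulate$arms, c("ip", "cmc"))) {
    am <- stage(paste0("count_", arm),
                arm_count_matrix(pool, scfg, arm = arm, n_pairs = n_pairs))
    counts <- mean_count_filter(am$counts,
                                threshold = config$enrich$mean_filter)
    emit(data.frame(feature = rownames(counts), counts,
                    check.names = FALSE), paste0("counts_", arm))
    res <- stage(paste0("enrich_", arm),
                 nb_wald_test(counts, am$condition, pair = am$pair))
    res$psi_truth <- am$truth$psi[match(res$feature, am$truth$feature)]
    res$class <- am$truth$class[match(res$feature, am$truth$feature)]
    emit(res, paste0("results_", arm))
    enrichment[[arm]] <- res
  }

  calls <- overlap <- confusion <- NULL
  if (all(c("ip", "cmc") %in% names(enrichment))) {
    cp <- stage("calls", call_psi_features(enrichment$ip, enrichment$cmc,
                                           alpha = alpha))
    calls <- cp$calls
    overlap <- cp$overlap
    truth_by_seq <- enrichment$ip$psi_truth[
      match(calls$feature, enrichment$ip$feature)]
    calls$psi_truth <- truth_by_seq
    emit(calls, "psi_calls")
    emit(data.frame(set = names(overlap), n = as.integer(overlap)),
         "assay_overlap")
    confusion <- as.data.frame(table(
      truth = ifelse(isTRUE_v(calls$psi_truth), "psi", "no_psi"),
      call = calls$class))
    emit(confusion, "confusion")
  }

  mn2_calls <- metaplot <- NULL
  if ("mn2" %in% config$simulate$arms) {
    rr <- ref$annotations[ref$annotations$class == "rRNA", ][1, ]
    mn <- stage("mn2", {
      sim <- simulate_cmc(pool, scfg, mode = "mn2plus", sample = "mn_p1",
                          dir = config$outdir, emit = "fastq")
      pre_t <- preprocess_fastq(sim$files[["treated"]], policy, "mn_treated")
      pre_m <- preprocess_fastq(sim$files[["mock"]], policy, "mn_mock")
      at <- map_reads(pre_t$collapsed, idx, mpol)
      am_ <- map_reads(pre_m$collapsed, idx, mpol)
      len <- nchar(ref$sequences[[rr$ref]])
      pt <- mismatch_profile(at, rr$ref, len)
      pm <- mismatch_profile(am_, rr$ref, len)
      cl <- call_mismatch_sites(pt, pm,
                                min_reads = config$sites$min_reads,
                                min_fc = config$sites$min_fc)
      list(calls = cl, treated = at, mock = am_, pt = pt, pm = pm)
    })
    mn2_calls <- mn$calls
    emit(mn2_calls, "mn2_sites")
    sites_rr <- built$truth$pos[built$truth$ref == rr$ref]
    if (length(sites_rr)) {
      trk_t <- locus_coverage(mn$treated, rr$ref,
                              nchar(ref$sequences[[rr$ref]]))
      trk_m <- locus_coverage(mn$mock, rr$ref,
                              nchar(ref$sequences[[rr$ref]]))
      fc <- paired_log2fc_track(trk_t, trk_m)
      metaplot <- site_metaplot(fc, sites_rr,
                                halfwidth = config$sites$metaplot$halfwidth,
                                smooth = config$sites$metaplot$smooth)
      emit(metaplot, "metaplot_rrna")
    }
  }

  emit(built$truth, "psi_truth")
  invisible(list(enrichment = enrichment, calls = calls, overlap = overlap,
                 mn2_calls = mn2_calls, metaplot = metaplot,
                 confusion = confusion, files = files,
                 config_hash = hash))
}

isTRUE_v <- function(x) !is.na(x) & x
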