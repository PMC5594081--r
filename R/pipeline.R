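#' Pipeline configuration
#'
#' All tunable parameters of the per-subject pipeline and cohort modeling,
#' with their defaults.  The configuration is hashed (md5 of its serialized
#' form) and the hash embedded in every output for provenance.
#'
#' @param bands band table.
#' @param notch_hz mains notch frequency (`NULL` to skip).
#' @param var_kept PCA variance fraction.
#' @param win_s artifact-rule window (s).
#' @param width_s,step_s sliding-window width and step (s).
#' @param n_surr surrogates per coupling test.
#' @param alpha significance level; `bonferroni` corrects over the 36 modes.
#' @param bonferroni logical.
#' @param filter_scheme `"omst"` or an arbitrary scheme name.
#' @param filter_param parameter for arbitrary schemes.
#' @param nnmf_rank NNMF rank.
#' @param k number of microstates (`NULL`: select by reconstruction error).
#' @param k_range,k_threshold selection candidates and error criterion.
#' @param max_word_len complexity-index word length.
#' @param n_shuffles complexity-index shuffles.
#' @param nested nested feature selection in the cohort models.
#' @param seed master seed.
#' @return list of class `pipeline_config` with a `hash` field.
#' @export
pipeline_config <- function(bands = default_bands(), notch_hz = 60,
                            var_kept = 0.95, win_s = 1,
                            width_s = 2.5, step_s = 0.02, n_surr = 200,
                            alpha = 0.05, bonferroni = FALSE,
                            filter_scheme = "omst", filter_param = NULL,
                            nnmf_rank = 8, k = NULL, k_range = 2:10,
                            k_threshold = 0.04, max_word_len = 7,
                            n_shuffles = 1000, nested = TRUE, seed = 1L) {
  cfg <- list(bands = bands, notch_hz = notch_hz, var_kept = var_kept,
              win_s = win_s, width_s = width_s, step_s = step_s,
              n_surr = n_surr, alpha = alpha, bonferroni = bonferroni,
              filter_scheme = filter_scheme, filter_param = filter_param,
              nnmf_rank = nnmf_rank, k = k, k_range = k_range,
              k_threshold = k_threshold, max_word_len = max_word_len,
              n_shuffles = n_shuffles, nested = nested, seed = seed)
  tf <- tempfile()
  saveRDS(cfg, tf)
  cfg$hash <- unname(tools::md5sum(tf))
  unlink(tf)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the per-subject pipeline
#'
#' Preprocess, couple (IDFCG), topologically filter, summarize (NMTS and
#' strength series), symbolize (microstates), and extract the chronnectomic
#' feature vector.  Each stage failure is reported with a stage tag.
#'
#' @param x a [recording] or a path to an EDF file.
#' @param config a [pipeline_config].
#' @param seed per-subject seed (default: the config's master seed).
#' @param out_dir optional directory: writes `features.csv`, `nmts.csv`,
#'   `strength.csv` and `meta.json` (requires jsonlite).
#' @return list of class `subject_bundle`: `idfcg`, `mask`, `nmts`,
#'   `strength`, `microstates`, `chronnectomics`, `features`, `config_hash`,
#'   `seed`.
#' @export
run_subject <- function(x, config = pipeline_config(), seed = config$seed,
                        out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  rec <- stage("input", if (inherits(x, "recording")) x else read_recording(x))
  bank <- stage("preprocess",
    preprocess_recording(rec, config$notch_hz, config$var_kept,
                         config$win_s, config$bands))
  idf <- stage("coupling",
    build_idfcg(bank, config$width_s, config$step_s, config$n_surr,
                config$alpha, config$bonferroni, seed))
  flt <- stage("topofilter",
    filter_idfcg(idf, config$filter_scheme, config$filter_param))
  nmts <- stage("netmetrics", build_nmts(idf, flt$mask))
  strg <- stage("netmetrics", strength_series(idf, flt$mask))
  ms <- stage("microstates",
    fit_microstates(nmts, k = config$k, r = config$nnmf_rank,
                    k_range = config$k_range, threshold = config$k_threshold,
                    seed = seed))
  chron <- stage("chronnectomics",
    chronnectomic_features(ms$labels, ms$k, idf$mode, strg,
                           coupling_mode_table(config$bands),
                           config$max_word_len, config$n_shuffles, seed))
  bundle <- structure(list(idfcg = idf, mask = flt$mask, nmts = nmts,
                           strength = strg, microstates = ms,
                           chronnectomics = chron,
                           features = chron$features,
                           config_hash = config$hash, seed = seed),
                      class = "subject_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(feature = names(bundle$features),
                                value = unname(bundle$features)),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(nmts, file.path(out_dir, "nmts.csv"), row.names = FALSE)
    utils::write.csv(data.frame(strength = strg),
                     file.path(out_dir, "strength.csv"), row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(config_hash = config$hash, seed = seed, k = ms$k,
             n_windows = dim(idf$strength)[1],
             version = as.character(utils::packageVersion("chronnect"))),
        file.path(out_dir, "meta.json"), auto_unbox = TRUE)
    }
  }
  bundle
}

#' Run the cohort-level analysis
#'
#' Runs every subject through the per-subject pipeline with a deterministic
#' per-subject seed, fits a group-level microstate codebook on the
#' concatenated NMTS, recomputes symbolic features under the shared
#' codebook, and fits the age-regression and (when groups are given)
#' group-classification models under LOOCV.
#'
#' @param recordings list of [recording] objects or EDF paths (>= 10).
#' @param ages numeric vector of true ages.
#' @param groups optional two-level factor for classification.
#' @param config a [pipeline_config].
#' @return list of class `cohort_report`: `features` (subjects x features),
#'   `regression`, `classification` (or `NULL`), `k`, `config_hash`.
#' @export
run_cohort <- function(recordings, ages, groups = NULL,
                       config = pipeline_config()) {
  n <- length(recordings)
  if (n < 10) stop("cohort needs at least 10 subjects")
  if (length(ages) != n) stop("ages length mismatch")
  bundles <- vector("list", n)
  for (s in seq_len(n)) {
    bundles[[s]] <- run_subject(recordings[[s]], config,
                                seed = config$seed + 1000L * s)
  }
  N_set <- unique(vapply(bundles, function(b) nrow(b$nmts), 0L))
  if (length(N_set) != 1) stop("inconsistent channel sets across subjects")
  # group-level codebook on concatenated NMTS
  Xall <- t(do.call(cbind, lapply(bundles, function(b) b$nmts)))
  Tns <- vapply(bundles, function(b) ncol(b$nmts), 0L)
  if (is.null(config$k)) {
    sel <- select_k(Xall, config$k_range, config$k_threshold,
                    config$nnmf_rank, config$seed)
    k <- sel$k; nm <- sel$nnmf; fit <- sel$fit
  } else {
    k <- config$k
    nm <- nnmf_reduce(Xall, min(config$nnmf_rank, ncol(Xall), nrow(Xall)),
                      seed = config$seed)
    fit <- neural_gas(nm$V, k, seed = config$seed)
  }
  assign_raw <- nearest_prototype(nm$V, fit$codebook)
  ord <- seriate_codebook(fit$codebook, tabulate(assign_raw, nbins = k))
  labels_all <- match(assign_raw, ord)
  stops <- cumsum(Tns); starts <- c(1, head(stops, -1) + 1)
  feats <- lapply(seq_len(n), function(s) {
    sts <- labels_all[starts[s]:stops[s]]
    chronnectomic_features(sts, k, bundles[[s]]$idfcg$mode,
                           bundles[[s]]$strength,
                           coupling_mode_table(config$bands),
                           config$max_word_len, config$n_shuffles,
                           config$seed + s)$features
  })
  Fm <- do.call(rbind, feats)
  keep <- apply(Fm, 2, function(v) stats::sd(v) > 0 && all(is.finite(v)))
  reg <- age_pipeline_loocv(Fm[, keep, drop = FALSE], ages,
                            nested = config$nested)
  cls <- NULL
  if (!is.null(groups) && nlevels(as.factor(groups)) == 2 &&
      min(table(groups)) >= 5) {
    cls <- classify_pipeline_loocv(Fm[, keep, drop = FALSE],
                                   groups, nested = config$nested,
                                   seed = config$seed)
  }
  structure(list(features = Fm, regression = reg, classification = cls,
                 k = k, config_hash = config$hash),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, k=%d microstates\n",
              nrow(x$features), x$k))
  cat(sprintf("  age regression: R2=%.3f, y=%.2fx+%.2f\n",
              x$regression$r2, x$regression$slope, x$regression$intercept))
  if (!is.null(x$classification))
    cat(sprintf("  classification: acc=%.1f%%, sens=%.1f%%, spec=%.1f%%\n",
                x$classification$accuracy, x$classification$sensitivity,
                x$classification$specificity))
  invisible(x)
}
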