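# Training the full model bundle from a sample bank and applying it to
# detected peaks (the "validation" step between peak picking and timing).

#' Train the full classifier bundle from a sample bank
#'
#' Extracts base features for the impact-versus-noise problem and extended
#' features for the rebound-versus-noise problem, selects the most
#' informative features of each by ANOVA F, and trains both classifiers.
#' Optionally runs five-fold CV on each problem.
#'
#' @param bank result of [gen_sample_bank()] or [read_bank()].
#' @param k_impact,k_rebound number of ANOVA-F-selected features for each
#'   model; `NULL` keeps all. Defaults (40; all) were chosen by grid search
#'   over the default bank: the rebound problem loses essential structure
#'   under univariate selection.
#' @param impact_cfg,ensemble_cfg model hyperparameters.
#' @param seed integer seed.
#' @param cv if `TRUE`, also compute five-fold CV reports (slower).
#' @param segment_pre_s,segment_post_s segment window around detected peaks,
#'   must match deployment (defaults 0.05 / 0.25 s).
#' @return a `court_model_bundle`: both models, selection results, segment
#'   window, and (optionally) CV reports.
#' @export
train_court_models <- function(bank, k_impact = 40L, k_rebound = NULL,
                               impact_cfg = impact_config(),
                               ensemble_cfg = ensemble_config(),
                               seed = 1L, cv = FALSE,
                               segment_pre_s = 0.05, segment_post_s = 0.25) {
  labels <- as.character(bank$labels)
  if (!all(c("noise", "rebound", "impact") %in% labels))
    stopf("bank must contain all three classes")
  base <- feature_matrix(bank$clips, "base")
  ext <- feature_matrix(bank$clips, "extended")

  imp_idx <- labels %in% c("impact", "noise")
  imp_sel <- anova_f_select(base[imp_idx, , drop = FALSE], labels[imp_idx],
                            k_impact)
  imp_x <- base[imp_idx, imp_sel$indices, drop = FALSE]
  impact_model <- train_impact_model(imp_x, labels[imp_idx], impact_cfg,
                                     derive_seed(seed, 1L))

  reb_idx <- labels %in% c("rebound", "noise")
  reb_sel <- anova_f_select(ext[reb_idx, , drop = FALSE], labels[reb_idx],
                            k_rebound)
  reb_x <- ext[reb_idx, reb_sel$indices, drop = FALSE]
  rebound_ensemble <- train_rebound_ensemble(reb_x, labels[reb_idx],
                                             ensemble_cfg,
                                             derive_seed(seed, 2L))

  cv_reports <- NULL
  if (isTRUE(cv)) {
    cv_reports <- list(
      impact = kfold_cv(imp_x, labels[imp_idx], k = 5L,
                        seed = derive_seed(seed, 3L),
                        trainer = function(x, l, s)
                          train_impact_model(x, l, impact_cfg, s)),
      rebound = kfold_cv(reb_x, labels[reb_idx], k = 5L,
                         seed = derive_seed(seed, 4L),
                         trainer = function(x, l, s)
                           train_rebound_ensemble(x, l, ensemble_cfg, s)))
  }
  structure(list(impact_model = impact_model,
                 rebound_ensemble = rebound_ensemble,
                 impact_selection = imp_sel, rebound_selection = reb_sel,
                 segment_pre_s = segment_pre_s,
                 segment_post_s = segment_post_s,
                 cv_reports = cv_reports, seed = seed,
                 version = 1L),
            class = "court_model_bundle")
}

#' @export
print.court_model_bundle <- function(x, ...) {
  cat("<court_model_bundle>\n  ")
  print(x$impact_model)
  cat("  ")
  print(x$rebound_ensemble)
  if (!is.null(x$cv_reports))
    cat(sprintf("  CV medians: impact %.4f, rebound %.4f\n",
                x$cv_reports$impact$median_accuracy,
                x$cv_reports$rebound$median_accuracy))
  invisible(x)
}

#' Save / load a model bundle archive
#'
#' The archive stores the bundle plus a content hash; loading verifies the
#' hash and errors on corruption.
#'
#' @param bundle a `court_model_bundle`.
#' @param path archive path (`.rds`).
#' @return `path` / the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "court_model_bundle"))
  # xgboost boosters carry external pointers; serialize them explicitly
  raws <- list(impact = xgboost::xgb.save.raw(bundle$impact_model$booster),
               rebound = xgboost::xgb.save.raw(bundle$rebound_ensemble$xgb))
  bundle$impact_model$booster <- NULL
  bundle$rebound_ensemble$xgb <- NULL
  payload <- list(bundle = bundle, raws = raws)
  payload$hash <- bundle_hash(payload)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  payload <- readRDS(path)
  hash <- payload$hash
  payload$hash <- NULL
  if (!identical(hash, bundle_hash(payload)))
    stopf("model archive %s failed its integrity check", path)
  bundle <- payload$bundle
  bundle$impact_model$booster <- xgboost::xgb.load.raw(payload$raws$impact)
  bundle$rebound_ensemble$xgb <- xgboost::xgb.load.raw(payload$raws$rebound)
  bundle
}

bundle_hash <- function(payload) {
  sum(as.integer(serialize(payload, NULL, version = 2)[-(1:14)])) %% 2147483647
}

#' Classify detected peaks into validated impact / rebound events
#'
#' Runs the full groundstroke chain on a clip: band-pass filtering, candidate
#' detection, feature extraction on raw-audio segments, classifier
#' validation. Impact candidates are kept when the impact model's
#' P(impact) > 0.5. For each kept impact, rebound candidates 1.5-0.4 s before
#' it are scored by the ensemble; accepted candidates (P(rebound) > 0.5)
#' compete and the highest probability wins, ties resolved toward the later
#' (closer to impact) candidate. Impacts with no accepted rebound are
#' reported unpaired.
#'
#' @param clip a normalized [audio_clip()] (raw audio).
#' @param bundle a trained `court_model_bundle`.
#' @param config a [peak_config()].
#' @param filter a [filter_spec()] for the detection band-pass.
#' @return data frame of event records: `time_s`, `label` (impact/rebound),
#'   `amplitude` (band-passed peak amplitude), `probability`, `impact_id`
#'   (pairing key; `NA` probability-less truth-style rows never occur).
#' @export
classify_events <- function(clip, bundle, config = peak_config(),
                            filter = filter_spec()) {
  stopifnot(inherits(bundle, "court_model_bundle"))
  filt <- butter_bandpass(clip, filter)
  cand <- detect_groundstroke_candidates(filt, config)
  imp <- cand$impact_candidates
  empty <- data.frame(time_s = numeric(0), label = character(0),
                      amplitude = numeric(0), probability = numeric(0),
                      impact_id = integer(0))
  if (!nrow(imp)) return(empty)

  seg_feats <- function(times, type) {
    segs <- lapply(times, function(t)
      extract_segment(clip, t, bundle$segment_pre_s, bundle$segment_post_s))
    feature_matrix(segs, type)
  }
  imp_x <- seg_feats(imp$time_s, "base")[, bundle$impact_selection$indices,
                                         drop = FALSE]
  p_imp <- predict(bundle$impact_model, imp_x)[, "impact"]
  keep <- p_imp > 0.5
  imp <- imp[keep, , drop = FALSE]
  p_imp <- p_imp[keep]
  if (!nrow(imp)) return(empty)

  windows <- window_rebound_candidates(imp, cand$lesser_candidates, config)
  all_cand <- unique(do.call(rbind, windows))
  p_reb_all <- NULL
  if (!is.null(all_cand) && nrow(all_cand)) {
    reb_x <- seg_feats(all_cand$time_s,
                       "extended")[, bundle$rebound_selection$indices,
                                   drop = FALSE]
    p_reb_all <- stats::setNames(
      predict(bundle$rebound_ensemble, reb_x)[, "rebound"],
      sprintf("%.9f", all_cand$time_s))
  }
  out <- empty
  for (i in seq_len(nrow(imp))) {
    out <- rbind(out, data.frame(
      time_s = imp$time_s[i], label = "impact", amplitude = imp$amplitude[i],
      probability = p_imp[i], impact_id = i))
    w <- windows[[i]]
    if (!nrow(w)) next
    p <- p_reb_all[sprintf("%.9f", w$time_s)]
    acc <- which(p > 0.5)
    if (!length(acc)) next
    # highest probability wins; tie -> later time (closer to the impact)
    best <- acc[order(-p[acc], -w$time_s[acc])][1]
    out <- rbind(out, data.frame(
      time_s = w$time_s[best], label = "rebound", amplitude = w$amplitude[best],
      probability = unname(p[best]), impact_id = i))
  }
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
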