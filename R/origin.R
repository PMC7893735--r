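#' Inference configuration for fragment-origin calling
#'
#' @param min_cpgs_per_fragment minimum CpG calls a fragment must have
#'   inside its DMR to be informative (joint-pattern inference needs
#'   several CpGs).
#' @param min_fragments minimum classified (non-ambiguous) fragments for a
#'   per-DMR malignant ratio to be defined; below this the ratio is
#'   missing, not zero.
#' @param llr_threshold log-likelihood-ratio band half-width: fragments
#'   with `|llr| < llr_threshold` are ambiguous.
#' @param max_len_bp,short_window length filter and ctDNA size-selection
#'   window applied before inference.
#' @param estimator `"hard"` counts hard-classified fragments (default);
#'   `"posterior"` averages per-fragment posterior malignant
#'   probabilities (equal priors) over informative fragments.
#' @return list of class `infer_config`.
#' @export
infer_config <- function(min_cpgs_per_fragment = 3L, min_fragments = 5L,
                         llr_threshold = log(2), max_len_bp = 500L,
                         short_window = c(90L, 150L),
                         estimator = c("hard", "posterior")) {
  structure(list(min_cpgs_per_fragment = as.integer(min_cpgs_per_fragment),
                 min_fragments = as.integer(min_fragments),
                 llr_threshold = llr_threshold, max_len_bp = max_len_bp,
                 short_window = short_window,
                 estimator = match.arg(estimator)),
            class = "infer_config")
}

#' Build the tissue reference panel over DMRs
#'
#' For every CpG site inside a marker DMR, the reference methylation
#' probability of each tissue group is the group mean beta over the tissue
#' methylomes, clamped into `[epsilon, 1 - epsilon]` so that no single CpG
#' can contribute an infinite log-likelihood ratio. By default only
#' hypo-DMRs enter the panel: they were selected as the candidate
#' methylation markers because cfDNA coverage is systematically higher in
#' CpG-sparse hypomethylated regions; hyper-DMRs can be kept with
#' `directions`.
#'
#' @param dmrs a `dmr_set` from [call_dmrs()].
#' @param methylomes a `tissue_methylomes` (carries its `cpg_map`).
#' @param epsilon clamp, in (0, 0.1].
#' @param directions which DMR directions to keep (default `"hypo"`).
#' @return object of class `reference_panel`: list with `dmrs` (the kept
#'   DMRs), `site_dmr` (per-map-site DMR row or NA), `p_mal`, `p_ben`
#'   (per-map-site clamped reference probabilities, NA outside the panel),
#'   and `epsilon`.
#' @export
build_reference_panel <- function(dmrs, methylomes, epsilon = 0.01,
                                  directions = "hypo") {
  if (!(epsilon > 0 && epsilon <= 0.1))
    stop("epsilon must be in (0, 0.1]", call. = FALSE)
  map <- methylomes$map
  stopifnot(inherits(map, "cpg_map"))
  grp <- methylomes$samples$group
  if (!any(grp == "malignant") || !any(grp == "benign"))
    stop("insufficient replicates: both tissue groups required", call. = FALSE)

  keep <- dmrs[dmrs$direction %in% directions, , drop = FALSE]
  sd <- site_dmr_index(map, keep)
  n_sites_in <- tabulate(sd, nbins = nrow(keep))
  if (any(n_sites_in == 0)) {
    warning(sum(n_sites_in == 0), " DMR(s) with no CpG sites excluded")
    keep <- keep[n_sites_in > 0, , drop = FALSE]
    sd <- site_dmr_index(map, keep)
  }
  in_panel <- !is.na(sd)
  p_mal <- p_ben <- rep(NA_real_, nrow(map$sites))
  beta <- methylomes$beta
  p_mal[in_panel] <- clamp(rowMeans(beta[in_panel, grp == "malignant",
                                         drop = FALSE]),
                           epsilon, 1 - epsilon)
  p_ben[in_panel] <- clamp(rowMeans(beta[in_panel, grp == "benign",
                                         drop = FALSE]),
                           epsilon, 1 - epsilon)
  structure(list(dmrs = keep, site_dmr = sd, p_mal = p_mal, p_ben = p_ben,
                 epsilon = epsilon, map = map),
            class = "reference_panel")
}

#' Per-fragment log-likelihoods under the two tissue references
#'
#' Under the independent-Bernoulli pattern model, a fragment's
#' log-likelihood under tissue group g is
#' `sum_i [ s_i * log(p_g_i) + (1 - s_i) * log(1 - p_g_i) ]` over its CpG
#' calls inside the DMR, with clamped reference probabilities guaranteeing
#' finite values.
#'
#' @param states 0/1 methylation calls of one fragment.
#' @param p_mal,p_ben reference probabilities at the corresponding sites.
#' @return named numeric `c(ll_mal, ll_ben)`.
#' @export
fragment_log_likelihood <- function(states, p_mal, p_ben) {
  stopifnot(length(states) == length(p_mal), length(p_mal) == length(p_ben))
  c(ll_mal = sum(states * log(p_mal) + (1 - states) * log1p(-p_mal)),
    ll_ben = sum(states * log(p_ben) + (1 - states) * log1p(-p_ben)))
}

#' Classify one fragment as malignant, benign or ambiguous
#'
#' The log-likelihood ratio `llr = ll_mal - ll_ben` is compared against a
#' symmetric band: `malignant` if `llr >= llr_threshold`, `benign` if
#' `llr <= -llr_threshold`, else `ambiguous` (including `llr = 0`).
#'
#' @inheritParams fragment_log_likelihood
#' @param llr_threshold band half-width (default `log(2)`).
#' @return one of `"malignant"`, `"benign"`, `"ambiguous"`.
#' @export
classify_fragment <- function(states, p_mal, p_ben, llr_threshold = log(2)) {
  ll <- fragment_log_likelihood(states, p_mal, p_ben)
  llr <- ll[["ll_mal"]] - ll[["ll_ben"]]
  if (llr >= llr_threshold) "malignant"
  else if (llr <= -llr_threshold) "benign"
  else "ambiguous"
}

#' Infer the origin of every informative fragment in a sample
#'
#' Applies the length filter and ctDNA size selection, assigns fragments
#' to panel DMRs by CpG containment, drops fragments with fewer than
#' `min_cpgs_per_fragment` calls inside their DMR (uninformative, not an
#' error), and classifies the rest by thresholded log-likelihood ratio.
#'
#' @param sample a `plasma_sample`.
#' @param panel a [build_reference_panel()].
#' @param config an [infer_config()].
#' @return data.frame with one row per informative fragment: `frag_id`,
#'   `dmr` (row in `panel$dmrs`), `n_cpgs`, `ll_mal`, `ll_ben`, `llr`,
#'   `call`, `posterior_mal`.
#' @export
infer_fragment_origins <- function(sample, panel, config = infer_config()) {
  stopifnot(inherits(panel, "reference_panel"))
  s <- filter_fragments_by_length(sample, config$max_len_bp,
                                  config$short_window)
  if (nrow(panel$dmrs) == 0 || nrow(s$frags) == 0) return(empty_origin_df())
  assign <- assign_fragments_to_dmrs(s, panel$dmrs, panel$map)
  frag_dmr <- assign[match(s$calls$frag_id, s$frags$frag_id)]
  site_dmr <- panel$site_dmr[s$calls$site]
  use <- !is.na(frag_dmr) & !is.na(site_dmr) & site_dmr == frag_dmr
  if (!any(use)) return(empty_origin_df())

  st <- s$calls$state[use]
  pm <- panel$p_mal[s$calls$site[use]]
  pb <- panel$p_ben[s$calls$site[use]]
  dt <- data.table::data.table(
    frag_id = s$calls$frag_id[use], dmr = frag_dmr[use],
    lm = st * log(pm) + (1 - st) * log1p(-pm),
    lb = st * log(pb) + (1 - st) * log1p(-pb))
  agg <- dt[, list(n_cpgs = .N, ll_mal = sum(lm), ll_ben = sum(lb)),
            by = c("frag_id", "dmr")]
  agg <- agg[agg$n_cpgs >= config$min_cpgs_per_fragment]
  if (nrow(agg) == 0) return(empty_origin_df())
  out <- as.data.frame(agg)
  out$llr <- out$ll_mal - out$ll_ben
  out$call <- ifelse(out$llr >= config$llr_threshold, "malignant",
                     ifelse(out$llr <= -config$llr_threshold, "benign",
                            "ambiguous"))
  out$posterior_mal <- stats::plogis(out$llr)
  out
}

empty_origin_df <- function() {
  data.frame(frag_id = integer(0), dmr = integer(0), n_cpgs = integer(0),
             ll_mal = numeric(0), ll_ben = numeric(0), llr = numeric(0),
             call = character(0), posterior_mal = numeric(0))
}

#' Per-DMR cfDNA malignant ratios of a plasma sample
#'
#' The malignant ratio of a DMR is the fraction of its classified
#' fragments called malignant (ambiguous fragments excluded). Ratios based
#' on fewer than `min_fragments` classified fragments are missing (`NA`),
#' which is a value, not an error. With `estimator = "posterior"` the
#' ratio is instead the mean posterior malignant probability over all
#' informative fragments.
#'
#' @param sample a `plasma_sample`.
#' @param panel a [build_reference_panel()].
#' @param config an [infer_config()].
#' @return data.frame with one row per panel DMR: `dmr_id`, `n_malignant`,
#'   `n_benign`, `n_ambiguous`, `n_informative`, `malignant_ratio`.
#' @export
malignant_ratios <- function(sample, panel, config = infer_config()) {
  orig <- infer_fragment_origins(sample, panel, config)
  nd <- nrow(panel$dmrs)
  n_mal <- n_ben <- n_amb <- integer(nd)
  post_sum <- numeric(nd); n_inf <- integer(nd)
  if (nrow(orig) > 0) {
    n_mal <- tabulate(orig$dmr[orig$call == "malignant"], nbins = nd)
    n_ben <- tabulate(orig$dmr[orig$call == "benign"], nbins = nd)
    n_amb <- tabulate(orig$dmr[orig$call == "ambiguous"], nbins = nd)
    n_inf <- tabulate(orig$dmr, nbins = nd)
    post_sum <- vapply(seq_len(nd), function(d)
      sum(orig$posterior_mal[orig$dmr == d]), numeric(1))
  }
  if (config$estimator == "hard") {
    denom <- n_mal + n_ben
    ratio <- ifelse(denom >= config$min_fragments, n_mal / pmax(denom, 1L),
                    NA_real_)
  } else {
    ratio <- ifelse(n_inf >= config$min_fragments,
                    post_sum / pmax(n_inf, 1L), NA_real_)
  }
  data.frame(dmr_id = panel$dmrs$dmr_id, n_malignant = n_mal,
             n_benign = n_ben, n_ambiguous = n_amb, n_informative = n_inf,
             malignant_ratio = ratio, stringsAsFactors = FALSE)
}

#' Build the marker-profile matrix for a set of plasma samples
#'
#' Stacks per-sample, per-DMR malignant ratios into the classifier's
#' feature matrix. DMRs missing in more than half the samples are dropped
#' with a warning; remaining missing entries are imputed with the DMR's
#' median ratio over observed *benign* samples (the conservative fill: a
#' missing marker should not look malignant), falling back to the overall
#' observed median where no benign value exists. Missingness flags are
#' retained.
#'
#' @param samples list of `plasma_sample`s.
#' @param panel a [build_reference_panel()].
#' @param labels per-sample labels (`"malignant"`/`"benign"`), used only to
#'   locate the benign group for imputation. Must be `NULL` when
#'   `impute_values` is supplied -- external (validation) cohorts are
#'   imputed with training-derived values so their labels are never
#'   touched before evaluation.
#' @param config an [infer_config()].
#' @param impute_values optional named per-DMR fill values (e.g. the
#'   discovery benign medians stored in a previous result's
#'   `benign_medians` attribute).
#' @param drop_frac drop DMRs missing in more than this fraction of
#'   samples (default 0.5; use 1 to keep every panel DMR, as required when
#'   scoring an external cohort with a fixed marker set).
#' @return object of class `marker_profiles`: list with `ratios` (samples
#'   x DMRs matrix, imputed), `missing` (logical matrix), `counts`
#'   (informative fragment counts), `dropped` (character vector of dropped
#'   DMR ids), `benign_medians` (per-DMR fill values used).
#' @export
build_marker_profiles <- function(samples, panel, labels = NULL,
                                  config = infer_config(),
                                  impute_values = NULL, drop_frac = 0.5) {
  if (is.null(impute_values) && is.null(labels))
    stop("either labels or impute_values must be given", call. = FALSE)
  if (!is.null(labels)) stopifnot(length(samples) == length(labels))
  per <- lapply(samples, malignant_ratios, panel = panel, config = config)
  ratios <- do.call(rbind, lapply(per, function(x) x$malignant_ratio))
  counts <- do.call(rbind, lapply(per, function(x) x$n_informative))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  dimnames(ratios) <- dimnames(counts) <- list(ids, panel$dmrs$dmr_id)

  miss_frac <- colMeans(is.na(ratios))
  dropped <- colnames(ratios)[miss_frac > drop_frac]
  if (length(dropped) > 0) {
    warning(length(dropped), " DMR(s) missing in > ", 100 * drop_frac,
            "% of samples dropped: ", paste(dropped, collapse = ", "))
    keep <- miss_frac <= drop_frac
    ratios <- ratios[, keep, drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  missing <- is.na(ratios)
  if (is.null(impute_values)) {
    ben <- labels == "benign"
    impute_values <- apply(ratios, 2, function(col) {
      fill <- stats::median(col[ben], na.rm = TRUE)
      if (is.na(fill)) fill <- stats::median(col, na.rm = TRUE)
      if (is.na(fill)) fill <- 0
      fill
    })
  }
  for (j in which(colSums(missing) > 0)) {
    fill <- impute_values[[colnames(ratios)[j]]]
    if (is.null(fill) || is.na(fill)) fill <- 0
    ratios[missing[, j], j] <- fill
  }
  structure(list(ratios = ratios, missing = missing, counts = counts,
                 dropped = dropped, benign_medians = impute_values),
            class = "marker_profiles")
}
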