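#' DMR planting configuration for the tissue simulator
#'
#' Controls how many differentially methylated regions are planted between
#' the malignant and benign tissue groups, their direction mix, effect size
#' and per-CpG noise. Planted DMRs coincide with gap-defined CpG runs
#' (the same segmentation [segment_candidate_regions()] uses downstream),
#' mirroring the fact that real DMRs live on CpG clusters: hyper-DMRs are
#' placed on runs overlapping CpG-dense islands and hypo-DMRs on runs
#' overlapping the sparser mid-density clusters, which reproduces the
#' higher CpG density of hyper- versus hypo-DMRs.
#'
#' @param n_dmrs number of DMRs to plant.
#' @param frac_hyper fraction planted as hyper-DMRs (higher methylation in
#'   malignant tissue); the rest are hypo-DMRs.
#' @param delta absolute planted group-mean methylation difference in
#'   (0, 1]; applied with positive sign for hyper and negative for hypo.
#' @param concentration beta-distribution concentration of per-CpG,
#'   per-sample methylation levels around the group mean.
#' @param baseline_island,baseline_other baseline (shared) mean methylation
#'   of island CpGs and of all other CpGs.
#' @param baseline_concentration concentration of the per-site baseline
#'   jitter around those anchors.
#' @param width_bp maximum planted-DMR width; runs longer than this are
#'   trimmed around their centre. Default `Inf` (use whole runs).
#' @param min_cpgs,max_gap_bp run-finding parameters, matching the
#'   defaults of [segment_candidate_regions()].
#' @param regions optional explicit planting: a data.frame with columns
#'   `chrom`, `start`, `end`, `direction` (`"hyper"`/`"hypo"`) and
#'   optionally `delta`; overrides random placement. Overlapping intervals
#'   are an error.
#' @return a list of class `dmr_spec`.
#' @export
dmr_spec <- function(n_dmrs = 20L, frac_hyper = 0.35, delta = 0.3,
                     concentration = 30, baseline_island = 0.15,
                     baseline_other = 0.85, baseline_concentration = 60,
                     width_bp = Inf, min_cpgs = 4L, max_gap_bp = 500L,
                     regions = NULL) {
  if (!is.null(regions)) {
    stopifnot(all(c("chrom", "start", "end", "direction") %in% names(regions)))
    ov <- FALSE
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) ov <- TRUE
    }
    if (ov) stop("invalid config: planted DMRs overlap", call. = FALSE)
  }
  if (abs(delta) > 1 || (n_dmrs > 0 && abs(delta) <= 0 && is.null(regions)))
    stop("invalid config: |delta| must be in (0, 1]", call. = FALSE)
  structure(list(n_dmrs = as.integer(n_dmrs), frac_hyper = frac_hyper,
                 delta = abs(delta), concentration = concentration,
                 baseline_island = baseline_island,
                 baseline_other = baseline_other,
                 baseline_concentration = baseline_concentration,
                 width_bp = width_bp, min_cpgs = as.integer(min_cpgs),
                 max_gap_bp = as.integer(max_gap_bp), regions = regions),
            class = "dmr_spec")
}

#' Simulate tissue reference methylomes with planted DMRs
#'
#' Draws per-CpG methylation levels (beta values) for `n_mal` malignant and
#' `n_ben` benign tissue samples. Outside planted DMRs the two groups share
#' the same per-site mean; inside, the malignant mean is shifted by
#' `+delta` (hyper) or `-delta` (hypo). Per-sample values are beta
#' distributed around the group mean with the configured concentration, so
#' all values are in [0, 1] without clamping. Group means that would leave
#' [0.02, 0.98] are clamped with a warning.
#'
#' @param map a [build_genome()] `cpg_map`.
#' @param n_mal,n_ben sample counts per group (defaults follow the 9
#'   malignant / 10 benign tissue design).
#' @param spec a [dmr_spec()].
#' @param seed integer seed.
#' @return a list with `methylomes` (class `tissue_methylomes`: `beta`
#'   sites-x-samples matrix, `samples` data.frame with `sample_id` and
#'   `group`, `group_means` per-site matrix with columns `malignant`,
#'   `benign`, and the `map`) and `truth` (class `sim_truth`: data.frame of
#'   planted DMRs with `chrom`, `start`, `end`, `direction`, `delta`,
#'   `n_cpgs`).
#' @export
simulate_tissue_methylomes <- function(map, n_mal = 9L, n_ben = 10L,
                                       spec = dmr_spec(), seed = 1L) {
  stopifnot(inherits(map, "cpg_map"), inherits(spec, "dmr_spec"))
  set.seed(seed)
  s <- map$sites
  n_sites <- nrow(s)

  ## per-site baseline, shared between groups
  anchor <- ifelse(s$element == "island", spec$baseline_island,
                   spec$baseline_other)
  base <- rbeta_mc(n_sites, anchor, spec$baseline_concentration)
  base <- clamp(base, 0.02, 0.98)

  ## choose planted regions
  planted <- plant_dmrs(map, spec)

  mean_ben <- base
  mean_mal <- base
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      in_r <- s$chrom == planted$chrom[i] & s$pos >= planted$start[i] &
        s$pos < planted$end[i]
      shift <- if (planted$direction[i] == "hyper") planted$delta[i] else -planted$delta[i]
      mean_mal[in_r] <- base[in_r] + shift
    }
    lo <- mean_mal < 0.02; hi <- mean_mal > 0.98
    if (any(lo | hi)) {
      warning("planted delta pushed ", sum(lo | hi),
              " site means outside [0.02, 0.98]; clamped")
      mean_mal <- clamp(mean_mal, 0.02, 0.98)
    }
  }

  n_tot <- n_mal + n_ben
  grp <- rep(c("malignant", "benign"), c(n_mal, n_ben))
  mu <- cbind(matrix(rep(mean_mal, n_mal), ncol = n_mal),
              matrix(rep(mean_ben, n_ben), ncol = n_ben))
  beta <- matrix(rbeta_mc(n_sites * n_tot, as.vector(mu), spec$concentration),
                 nrow = n_sites, ncol = n_tot)
  ids <- sprintf("%s_T%02d", ifelse(grp == "malignant", "MAL", "BEN"),
                 unlist(lapply(c(n_mal, n_ben), seq_len)))
  colnames(beta) <- ids

  meth <- structure(list(
    beta = beta,
    samples = data.frame(sample_id = ids, group = grp,
                         stringsAsFactors = FALSE),
    group_means = cbind(malignant = mean_mal, benign = mean_ben),
    map = map), class = "tissue_methylomes")
  truth <- structure(list(planted_dmrs = planted), class = "sim_truth")
  list(methylomes = meth, truth = truth)
}

# Choose planted intervals: CpG runs overlapping islands for hyper,
# clusters for hypo (falling back to densest/sparsest runs as needed).
plant_dmrs <- function(map, spec) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      delta = numeric(0), n_cpgs = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$regions)) {
    r <- spec$regions
    if (is.null(r$delta)) r$delta <- spec$delta
    r$n_cpgs <- vapply(seq_len(nrow(r)), function(i)
      sum(map$sites$chrom == r$chrom[i] & map$sites$pos >= r$start[i] &
            map$sites$pos < r$end[i]), integer(1))
    return(r[, c("chrom", "start", "end", "direction", "delta", "n_cpgs")])
  }
  if (spec$n_dmrs == 0) return(empty)

  runs <- segment_candidate_regions(map, spec$min_cpgs, spec$max_gap_bp)
  if (nrow(runs) == 0) stop("invalid config: no CpG runs to plant DMRs on",
                            call. = FALSE)
  elem <- map$sites$element
  frac_elem <- function(lo, hi, what)
    vapply(seq_along(lo), function(i)
      mean(elem[lo[i]:hi[i]] == what), numeric(1))
  f_isl <- frac_elem(runs$site_lo, runs$site_hi, "island")
  f_clu <- frac_elem(runs$site_lo, runs$site_hi, "cluster")

  n_hyper <- round(spec$frac_hyper * spec$n_dmrs)
  n_hypo <- spec$n_dmrs - n_hyper
  cand_hyper <- which(f_isl > 0.5)
  cand_hypo <- which(f_clu > 0.5)
  dens <- runs$n_cpgs / (runs$end - runs$start)
  if (length(cand_hyper) < n_hyper)
    cand_hyper <- order(dens, decreasing = TRUE)[seq_len(max(n_hyper, 1))]
  if (length(cand_hypo) < n_hypo)
    cand_hypo <- setdiff(order(dens), cand_hyper)[seq_len(max(n_hypo, 1))]
  pick <- function(cand, n) if (n == 0) integer(0) else
    sort(sample(cand, n))
  if (length(cand_hyper) < n_hyper || length(cand_hypo) < n_hypo)
    stop("invalid config: not enough eligible CpG runs to plant ",
         spec$n_dmrs, " DMRs", call. = FALSE)
  i_hyper <- pick(cand_hyper, n_hyper)
  i_hypo <- pick(cand_hypo, n_hypo)

  sel <- runs[c(i_hyper, i_hypo), , drop = FALSE]
  dir <- rep(c("hyper", "hypo"), c(length(i_hyper), length(i_hypo)))
  ## optional trimming to width_bp around the run centre
  if (is.finite(spec$width_bp)) {
    mid <- (sel$start + sel$end) / 2
    ns <- pmax(sel$start, floor(mid - spec$width_bp / 2))
    ne <- pmin(sel$end, ceiling(mid + spec$width_bp / 2))
    nc <- vapply(seq_len(nrow(sel)), function(i)
      sum(map$sites$chrom == sel$chrom[i] & map$sites$pos >= ns[i] &
            map$sites$pos < ne[i]), integer(1))
    sel$start <- ns; sel$end <- ne; sel$n_cpgs <- nc
  }
  out <- data.frame(chrom = sel$chrom, start = sel$start, end = sel$end,
                    direction = dir, delta = spec$delta, n_cpgs = sel$n_cpgs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
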