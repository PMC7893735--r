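#' Segment the CpG map into candidate regions
#'
#' Candidate regions for differential-methylation testing are maximal runs
#' of consecutive CpG sites whose inter-CpG gap never exceeds
#' `max_gap_bp`, restricted to runs with at least `min_cpgs` sites. This is
#' the standard cluster-based segmentation of WGBS DMR callers: the region,
#' not the CpG, is the unit of inference downstream.
#'
#' @param map a [build_genome()] `cpg_map`.
#' @param min_cpgs minimum CpG count per region (>= 3).
#' @param max_gap_bp maximum allowed distance between consecutive CpGs.
#' @return data.frame with one row per candidate region: `region_id`,
#'   `chrom`, `start`, `end` (0-based half-open; `end` = last site + 2),
#'   `n_cpgs`, `site_lo`, `site_hi` (row indices into `map$sites`). Sorted,
#'   non-overlapping.
#' @export
segment_candidate_regions <- function(map, min_cpgs = 4L, max_gap_bp = 500L) {
  stopifnot(inherits(map, "cpg_map"))
  if (min_cpgs < 3) stop("min_cpgs must be >= 3", call. = FALSE)
  s <- map$sites
  if (nrow(s) == 0) {
    return(data.frame(region_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_cpgs = integer(0), site_lo = integer(0),
                      site_hi = integer(0)))
  }
  new_chrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(Inf, diff(s$pos))
  brk <- new_chrom | gap > max_gap_bp
  run <- cumsum(brk)
  lo <- which(brk)
  hi <- c(lo[-1] - 1L, nrow(s))
  n <- hi - lo + 1L
  keep <- n >= min_cpgs
  out <- data.frame(region_id = seq_len(sum(keep)),
                    chrom = s$chrom[lo[keep]],
                    start = s$pos[lo[keep]],
                    end = s$pos[hi[keep]] + 2L,
                    n_cpgs = n[keep],
                    site_lo = lo[keep],
                    site_hi = hi[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions between tissue groups
#'
#' For each candidate region the per-sample mean methylation over its CpGs
#' is computed and the malignant and benign groups are compared with a
#' two-sample location test (exact Wilcoxon rank-sum by default, Welch t
#' optionally). P-values are Benjamini-Hochberg corrected across regions;
#' regions passing `q <= alpha` and `|delta| >= min_delta` are reported as
#' DMRs, with direction `hyper` (more methylated in malignancy) when
#' `delta > 0` and `hypo` when `delta < 0`. Ties in the BH ranking are
#' broken deterministically by larger `|delta|` first.
#'
#' @param regions candidate regions from [segment_candidate_regions()].
#' @param methylomes a `tissue_methylomes` object
#'   (see [simulate_tissue_methylomes()]), or any list with a numeric
#'   `beta` matrix (sites x samples) and a `samples` data.frame carrying a
#'   `group` column with values `"malignant"`/`"benign"`.
#' @param min_delta minimum absolute group-mean difference.
#' @param alpha BH-adjusted significance level.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param keep_all return all tested regions (with a `significant` flag)
#'   instead of only DMRs.
#' @return a data.frame of class `dmr_set`, sorted and non-overlapping,
#'   with columns `dmr_id`, `chrom`, `start`, `end`, `region_id`, `n_cpgs`,
#'   `mean_beta_mal`, `mean_beta_ben`, `delta`, `direction`, `p_value`,
#'   `q_value`. The number of tested regions is kept in attribute
#'   `n_tested`.
#' @export
call_dmrs <- function(regions, methylomes, min_delta = 0.2, alpha = 0.05,
                      test = c("wilcoxon", "t"), keep_all = FALSE) {
  test <- match.arg(test)
  beta <- methylomes$beta
  grp <- methylomes$samples$group
  i_mal <- which(grp == "malignant")
  i_ben <- which(grp == "benign")
  if (length(i_mal) < 2 || length(i_ben) < 2)
    stop("insufficient replicates: need >= 2 samples per group", call. = FALSE)
  if (nrow(regions) == 0) {
    out <- empty_dmr_set()
    attr(out, "n_tested") <- 0L
    return(out)
  }

  # per-region, per-sample mean beta
  site_idx <- sequence(regions$n_cpgs, from = regions$site_lo)
  reg_of_site <- rep.int(seq_len(nrow(regions)), regions$n_cpgs)
  sums <- rowsum(beta[site_idx, , drop = FALSE], reg_of_site, reorder = TRUE)
  means <- sums / regions$n_cpgs

  mb_mal <- rowMeans(means[, i_mal, drop = FALSE])
  mb_ben <- rowMeans(means[, i_ben, drop = FALSE])
  delta <- mb_mal - mb_ben

  pv <- vapply(seq_len(nrow(regions)), function(r) {
    x <- means[r, i_mal]; y <- means[r, i_ben]
    if (test == "wilcoxon")
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    else
      stats::t.test(x, y)$p.value
  }, numeric(1))

  # BH across regions, ties in rank broken by larger |delta| first
  m <- length(pv)
  ord <- order(pv, -abs(delta))
  q <- numeric(m)
  q[ord] <- rev(cummin(rev(pv[ord] * m / seq_len(m))))
  q <- pmin(q, 1)

  sig <- q <= alpha & abs(delta) >= min_delta
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, region_id = regions$region_id,
                    n_cpgs = regions$n_cpgs,
                    mean_beta_mal = mb_mal, mean_beta_ben = mb_ben,
                    delta = delta,
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    p_value = pv, q_value = q,
                    stringsAsFactors = FALSE)
  if (keep_all) {
    out$significant <- sig
  } else {
    out <- out[sig, , drop = FALSE]
  }
  out <- out[order(match(out$chrom, names(attr(regions, "chrom_lengths")) %||%
                           unique(regions$chrom)), out$start), , drop = FALSE]
  out$dmr_id <- paste0("dmr_", out$chrom, "_", out$start, recycle0 = TRUE)
  rownames(out) <- NULL
  out <- out[, c("dmr_id", setdiff(names(out), "dmr_id"))]
  class(out) <- c("dmr_set", "data.frame")
  attr(out, "n_tested") <- m
  out
}

empty_dmr_set <- function() {
  out <- data.frame(dmr_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    region_id = integer(0), n_cpgs = integer(0),
                    mean_beta_mal = numeric(0), mean_beta_ben = numeric(0),
                    delta = numeric(0), direction = character(0),
                    p_value = numeric(0), q_value = numeric(0))
  class(out) <- c("dmr_set", "data.frame")
  out
}
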