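# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A hand-built cpg_map with explicit CpG positions on one chromosome.
manual_map <- function(pos, chrom_len = 10000L, window_bp = 1000L,
                       chrom = "chr1", region_class = NULL) {
  pos <- sort(as.integer(pos))
  if (is.null(region_class)) region_class <- rep("intergenic", length(pos))
  lens <- stats::setNames(chrom_len, chrom)
  wstart <- seq(0L, chrom_len - 1L, by = window_bp)
  wend <- pmin(wstart + window_bp, chrom_len)
  cnt <- tabulate(findInterval(pos, wstart), nbins = length(wstart))
  map <- list(
    sites = data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                       gpos = as.numeric(pos),
                       region_class = factor(region_class,
                                             levels = c("promoter", "genic",
                                                        "intergenic")),
                       element = factor(rep("background", length(pos)),
                                        levels = c("background", "cluster",
                                                   "island")),
                       stringsAsFactors = FALSE),
    windows = data.frame(chrom = chrom, start = wstart, end = wend,
                         gstart = as.numeric(wstart), n_cpg = cnt,
                         cpg_density = cnt * 1000 / (wend - wstart),
                         gc = 0.4,
                         region_class = factor(rep("intergenic",
                                                   length(wstart)),
                                               levels = c("promoter",
                                                          "genic",
                                                          "intergenic")),
                         is_island = FALSE, is_promoter = FALSE,
                         stringsAsFactors = FALSE),
    islands = NULL, clusters = NULL, chrom_lengths = lens,
    offsets = cfMethDx:::chrom_offsets(lens), window_bp = window_bp,
    config = NULL)
  class(map) <- "cpg_map"
  map
}

# A hand-built plasma sample from a fragment table and optional calls.
manual_sample <- function(starts, ends, calls = NULL, chrom = "chr1",
                          sample_id = "T1", label = NA_character_) {
  n <- length(starts)
  frags <- data.frame(frag_id = seq_len(n), chrom = rep(chrom, n),
                      start = as.integer(starts), end = as.integer(ends),
                      length = as.integer(ends - starts),
                      gstart = as.numeric(starts), gend = as.numeric(ends),
                      origin = rep(NA_character_, n),
                      stringsAsFactors = FALSE)
  if (is.null(calls))
    calls <- data.frame(frag_id = integer(0), site = integer(0),
                        state = integer(0))
  structure(list(sample_id = sample_id, label = label,
                 tumor_fraction = NA_real_, frags = frags, calls = calls),
            class = "plasma_sample")
}

# A minimal reference panel over explicit DMRs of a map, with flat
# reference probabilities per DMR.
manual_panel <- function(map, dmrs, p_mal, p_ben, epsilon = 0.01) {
  dmrs$dmr_id <- paste0("dmr_", dmrs$chrom, "_", dmrs$start)
  if (is.null(dmrs$direction)) dmrs$direction <- "hypo"
  sd <- cfMethDx:::site_dmr_index(map, dmrs)
  pm <- pb <- rep(NA_real_, nrow(map$sites))
  pm[!is.na(sd)] <- rep_len(p_mal, sum(!is.na(sd)))
  pb[!is.na(sd)] <- rep_len(p_ben, sum(!is.na(sd)))
  structure(list(dmrs = dmrs, site_dmr = sd, p_mal = pm, p_ben = pb,
                 epsilon = epsilon, map = map), class = "reference_panel")
}

# Default-world fixtures (shared across files; built once).
default_map <- function() memo("map", build_genome(seed = 2024L))

default_tissues <- function() memo("tissues", {
  suppressWarnings(simulate_tissue_methylomes(
    default_map(), spec = dmr_spec(delta = 0.6), seed = 2025L))
})

# Full default studies + pipelines for seeds 1..5 (the end-to-end world).
study_pipeline <- function(seed) {
  memo(paste0("pipe", seed), {
    study <- suppressWarnings(simulate_study(seed = seed))
    res <- suppressWarnings(run_cfmeth_pipeline(study, seed = seed,
                                                n_boot = 200L))
    list(study = study, res = res)
  })
}

rbeta_fixture <- function(n) {
  set.seed(99)
  stats::rbeta(n, 8, 2)
}

# Brute-force oracle: Bernoulli-product likelihoods by explicit product.
oracle_classify <- function(states, p_mal, p_ben, thr = log(2)) {
  lik <- function(p) prod(ifelse(states == 1, p, 1 - p))
  llr <- log(lik(p_mal)) - log(lik(p_ben))
  if (llr >= thr) "malignant" else if (llr <= -thr) "benign" else "ambiguous"
}

# All 0/1 patterns of length k as a matrix (2^k rows).
all_patterns <- function(k) {
  as.matrix(expand.grid(rep(list(0:1), k)))
}
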