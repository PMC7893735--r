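#' Configuration for the synthetic genome model
#'
#' The synthetic genome is a small stand-in for the methylome substrate:
#' ordered CpG sites on a couple of chromosomes, annotated with a
#' promoter/genic/intergenic layout and per-window CpG density and GC
#' content. Three structural elements modulate local CpG density:
#'
#' * a homogeneous background (Poisson process at `cpg_rate` per bp),
#' * CpG **islands**: short dense elements (rate `island_density_mult *
#'   cpg_rate`), preferentially placed at gene promoters and snapped to the
#'   window grid, the natural home of hypermethylation markers,
#' * CpG **clusters**: wide mid-density domains (rate `cluster_cpg_rate`)
#'   in gene bodies and intergenic space, emulating the large
#'   partially/hypomethylated blocks of tumor genomes, the natural home of
#'   hypomethylation markers.
#'
#' The gene layout repeats deterministically: `intergenic_bp` of intergenic
#' space, a `promoter_bp` promoter, then a `genic_bp` gene body.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cpg_rate background CpG rate per bp.
#' @param island_count,island_width,island_density_mult number, width (bp)
#'   and density multiplier (relative to `cpg_rate`) of CpG islands.
#' @param island_shore_bp CpG-free shore flanking each island; keeps the
#'   inter-CpG gap at island edges above typical segmentation gaps so an
#'   island forms its own CpG run instead of being diluted by background
#'   flanks.
#' @param cluster_count,cluster_width,cluster_cpg_rate number, width (bp)
#'   and absolute CpG rate (per bp) of mid-density CpG clusters.
#' @param island_promoter_frac fraction of islands anchored at promoters.
#' @param window_bp width of the fixed windows used for density/GC tracks.
#' @param intergenic_bp,promoter_bp,genic_bp gene-layout period, bp.
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                          cpg_rate = 0.004,
                          island_count = 40L,
                          island_width = 2000L,
                          island_density_mult = 10,
                          island_shore_bp = 600L,
                          cluster_count = 16L,
                          cluster_width = 200000L,
                          cluster_cpg_rate = 0.03,
                          island_promoter_frac = 0.6,
                          window_bp = 2000L,
                          intergenic_bp = 14000L,
                          promoter_bp = 2000L,
                          genic_bp = 16000L) {
  cfg <- list(chrom_lengths = chrom_lengths, cpg_rate = cpg_rate,
              island_count = as.integer(island_count),
              island_width = as.integer(island_width),
              island_density_mult = island_density_mult,
              island_shore_bp = as.integer(island_shore_bp),
              cluster_count = as.integer(cluster_count),
              cluster_width = as.integer(cluster_width),
              cluster_cpg_rate = cluster_cpg_rate,
              island_promoter_frac = island_promoter_frac,
              window_bp = as.integer(window_bp),
              intergenic_bp = as.integer(intergenic_bp),
              promoter_bp = as.integer(promoter_bp),
              genic_bp = as.integer(genic_bp))
  validate_genome_config(cfg)
  class(cfg) <- "genome_config"
  cfg
}

validate_genome_config <- function(cfg) {
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    stop("invalid config: chromosome lengths must be named", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0))
    stop("invalid config: zero or negative chromosome length", call. = FALSE)
  for (f in c("cpg_rate", "island_density_mult", "cluster_cpg_rate"))
    if (cfg[[f]] < 0) stop("invalid config: negative rate '", f, "'", call. = FALSE)
  for (f in c("island_count", "cluster_count"))
    if (cfg[[f]] < 0) stop("invalid config: negative count '", f, "'", call. = FALSE)
  if (cfg$window_bp <= 0) stop("invalid config: window_bp must be positive", call. = FALSE)
  if (cfg$island_promoter_frac < 0 || cfg$island_promoter_frac > 1)
    stop("invalid config: island_promoter_frac outside [0,1]", call. = FALSE)
  invisible(cfg)
}

region_class_levels <- c("promoter", "genic", "intergenic")

# Region class of 0-based positions under the repeating gene layout.
region_class_of <- function(pos, cfg) {
  period <- cfg$intergenic_bp + cfg$promoter_bp + cfg$genic_bp
  ph <- pos %% period
  cls <- ifelse(ph < cfg$intergenic_bp, "intergenic",
                ifelse(ph < cfg$intergenic_bp + cfg$promoter_bp, "promoter", "genic"))
  factor(cls, levels = region_class_levels)
}

# Place `n` non-overlapping intervals of width `width` on a chromosome,
# avoiding `avoid` (2-col matrix of start/end), by rejection sampling.
place_intervals <- function(n, width, chrom_len, avoid = NULL, margin = 0,
                            snap = 1L, max_tries = 500L) {
  placed <- matrix(numeric(0), ncol = 2)
  if (n == 0) return(placed)
  tries <- 0L
  while (nrow(placed) < n && tries < max_tries * n) {
    tries <- tries + 1L
    s <- floor(stats::runif(1, 0, max(1, chrom_len - width)) / snap) * snap
    e <- s + width
    blocked <- FALSE
    all_iv <- rbind(placed, avoid)
    if (!is.null(all_iv) && nrow(all_iv) > 0)
      blocked <- any(s < all_iv[, 2] + margin & e > all_iv[, 1] - margin)
    if (!blocked) placed <- rbind(placed, c(s, e))
  }
  if (nrow(placed) < n)
    stop("invalid config: could not place ", n, " elements of width ", width,
         " on a chromosome of length ", chrom_len, call. = FALSE)
  placed[order(placed[, 1]), , drop = FALSE]
}

# Poisson CpG positions at `rate` within [start, end), thinned to pairwise
# distance >= 2 bp (a CpG dinucleotide occupies two bases).
poisson_sites <- function(rate, start, end) {
  n <- stats::rpois(1, rate * (end - start))
  if (n == 0) return(integer(0))
  sort(unique(floor(stats::runif(n, start, end))))
}

#' Build a synthetic CpG map
#'
#' Generates the genome model: CpG site coordinates (0-based), their
#' region-class and element annotation, and fixed-width window tracks of CpG
#' density (CpGs per kb) and GC fraction. GC is generated as an increasing
#' function of local CpG density plus noise, reproducing the usual coupling
#' of the two axes.
#'
#' @param config a [genome_config()].
#' @param seed integer seed; output is bit-identical for a given
#'   `(config, seed)` pair.
#' @return an object of class `cpg_map` with elements `sites` (data.frame:
#'   `chrom`, `pos`, `gpos`, `region_class`, `element`), `windows`
#'   (data.frame: `chrom`, `start`, `end`, `gstart`, `n_cpg`, `cpg_density`,
#'   `gc`, `region_class`, `is_island`, `is_promoter`), `islands`,
#'   `clusters`, `chrom_lengths`, `offsets`, `window_bp`, `config`.
#' @export
build_genome <- function(config = genome_config(), seed = 1L) {
  validate_genome_config(config)
  set.seed(seed)
  chroms <- names(config$chrom_lengths)
  offs <- chrom_offsets(config$chrom_lengths)
  total_len <- sum(config$chrom_lengths)

  # distribute counts across chromosomes proportionally to length
  n_cl <- stats::setNames(as.vector(
    table(factor(sample(chroms, config$cluster_count, replace = TRUE,
                        prob = config$chrom_lengths / total_len),
                 levels = chroms))), chroms)
  n_is <- stats::setNames(as.vector(
    table(factor(sample(chroms, config$island_count, replace = TRUE,
                        prob = config$chrom_lengths / total_len),
                 levels = chroms))), chroms)

  period <- config$intergenic_bp + config$promoter_bp + config$genic_bp
  sites_l <- list(); win_l <- list(); isl_l <- list(); clu_l <- list()

  for (ch in chroms) {
    L <- config$chrom_lengths[[ch]]
    ## clusters first, with breathing room
    clus <- place_intervals(n_cl[[ch]], config$cluster_width, L,
                            margin = 10000, snap = config$window_bp)
    ## islands: promoter-anchored ones first, remainder anywhere free
    prom_starts <- seq(config$intergenic_bp, max(0, L - config$island_width),
                       by = period)
    if (nrow(clus) > 0 && length(prom_starts) > 0) {
      bad <- vapply(prom_starts, function(s)
        any(s < clus[, 2] & s + config$island_width > clus[, 1]), logical(1))
      prom_starts <- prom_starts[!bad]
    }
    k_prom <- min(round(config$island_promoter_frac * n_is[[ch]]),
                  length(prom_starts))
    ps <- if (k_prom > 0) sort(sample(prom_starts, k_prom)) else numeric(0)
    # snap promoter-anchored islands to the window grid
    ps <- floor(ps / config$window_bp) * config$window_bp
    isl <- cbind(ps, ps + config$island_width)
    k_free <- n_is[[ch]] - k_prom
    if (k_free > 0) {
      free <- place_intervals(k_free, config$island_width, L,
                              avoid = rbind(isl, clus), margin = 2000,
                              snap = config$window_bp)
      isl <- rbind(isl, free)
    }
    if (nrow(isl) > 1) isl <- isl[order(isl[, 1]), , drop = FALSE]

    ## CpG positions by element
    bg <- poisson_sites(config$cpg_rate, 0, L)
    drop_in <- function(pos, iv) {
      if (length(pos) == 0 || is.null(iv) || nrow(iv) == 0) return(pos)
      idx <- findInterval(pos, iv[, 1])
      keep <- idx == 0 | pos >= iv[pmax(idx, 1), 2]
      pos[keep]
    }
    isl_shore <- if (nrow(isl) > 0)
      cbind(isl[, 1] - config$island_shore_bp,
            isl[, 2] + config$island_shore_bp)
    else isl
    bg <- drop_in(drop_in(bg, isl_shore), clus)
    ipos <- unlist(lapply(seq_len(nrow(isl)), function(i)
      poisson_sites(config$island_density_mult * config$cpg_rate,
                    isl[i, 1], isl[i, 2])), use.names = FALSE)
    cpos <- unlist(lapply(seq_len(nrow(clus)), function(i)
      poisson_sites(config$cluster_cpg_rate, clus[i, 1], clus[i, 2])),
      use.names = FALSE)

    pos <- sort(c(bg, ipos, cpos))
    pos <- pos[pos <= L - 2]
    if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 2)]

    elem <- rep("background", length(pos))
    mark <- function(pos, iv) {
      if (length(pos) == 0 || nrow(iv) == 0) return(logical(length(pos)))
      idx <- findInterval(pos, iv[, 1])
      idx >= 1 & pos < iv[pmax(idx, 1), 2]
    }
    elem[mark(pos, clus)] <- "cluster"
    elem[mark(pos, isl)] <- "island"

    sites_l[[ch]] <- data.frame(
      chrom = ch, pos = as.integer(pos), gpos = pos + offs[[ch]],
      region_class = region_class_of(pos, config),
      element = factor(elem, levels = c("background", "cluster", "island")),
      stringsAsFactors = FALSE)

    ## windows
    wstart <- seq(0, L - 1, by = config$window_bp)
    wend <- pmin(wstart + config$window_bp, L)
    cnt <- tabulate(findInterval(pos, wstart), nbins = length(wstart))
    dens <- cnt * 1000 / (wend - wstart)
    gc <- clamp(0.38 + 4.5 * dens / 1000 + stats::rnorm(length(dens), 0, 0.015),
                0.25, 0.80)
    ov_frac <- function(ws, we, iv) {
      if (nrow(iv) == 0) return(numeric(length(ws)))
      sapply(seq_along(ws), function(i) {
        o <- pmax(0, pmin(we[i], iv[, 2]) - pmax(ws[i], iv[, 1]))
        sum(o) / (we[i] - ws[i])
      })
    }
    win_l[[ch]] <- data.frame(
      chrom = ch, start = as.integer(wstart), end = as.integer(wend),
      gstart = wstart + offs[[ch]], n_cpg = cnt, cpg_density = dens, gc = gc,
      region_class = region_class_of(floor((wstart + wend) / 2), config),
      is_island = ov_frac(wstart, wend, isl) >= 0.5,
      stringsAsFactors = FALSE)
    win_l[[ch]]$is_promoter <- win_l[[ch]]$region_class == "promoter"

    if (nrow(isl) > 0)
      isl_l[[ch]] <- data.frame(chrom = ch, start = isl[, 1], end = isl[, 2])
    if (nrow(clus) > 0)
      clu_l[[ch]] <- data.frame(chrom = ch, start = clus[, 1], end = clus[, 2])
  }

  map <- list(sites = do.call(rbind, c(sites_l, list(make.row.names = FALSE))),
              windows = do.call(rbind, c(win_l, list(make.row.names = FALSE))),
              islands = if (length(isl_l)) do.call(rbind, c(isl_l, list(make.row.names = FALSE))) else NULL,
              clusters = if (length(clu_l)) do.call(rbind, c(clu_l, list(make.row.names = FALSE))) else NULL,
              chrom_lengths = config$chrom_lengths,
              offsets = offs,
              window_bp = config$window_bp,
              config = config)
  class(map) <- "cpg_map"
  map
}

#' @export
print.cpg_map <- function(x, ...) {
  cat("<cpg_map>", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      nrow(x$sites), "CpG sites,", nrow(x$windows), "windows of",
      x$window_bp, "bp\n")
  invisible(x)
}

#' CpG density of a genomic interval
#'
#' Counts CpG sites whose position falls in the half-open interval
#' `[start, end)` and scales to CpGs per kb.
#'
#' @param map a [build_genome()] `cpg_map`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds in bp.
#' @return density in CpGs per kb.
#' @export
cpg_density <- function(map, chrom, start, end) {
  stopifnot(inherits(map, "cpg_map"))
  if (end <= start) stop("invalid argument: zero-length interval", call. = FALSE)
  if (!chrom %in% names(map$chrom_lengths))
    stop("invalid argument: unknown chromosome ", chrom, call. = FALSE)
  s <- map$sites
  n <- sum(s$chrom == chrom & s$pos >= start & s$pos < end)
  n * 1000 / (end - start)
}
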