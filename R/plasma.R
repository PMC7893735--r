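#' Coverage-depletion configuration
#'
#' Fragment start positions are drawn window-wise with weight
#' `exp(-w * z) * f`, where `z` is the z-score of the window's CpG density
#' across all windows and `f = promoter_factor` in promoter windows (1
#' elsewhere). The multiplicative promoter factor -- rather than a larger
#' `w` -- guarantees promoter loss regardless of a promoter's own CpG
#' density (doubling `w` would *boost* CpG-sparse promoters, whose `z` is
#' negative). This is a minimal mechanism reproducing the observed loss of
#' cfDNA coverage in CpG-dense and promoter regions without modelling
#' nuclease biology.
#'
#' @param w depletion strength per density z-score unit.
#' @param promoter_factor multiplicative start-weight factor in promoter
#'   windows (default 0.5, i.e. the same suppression a `+1` z-score unit
#'   receives at `w = 0.5` twice over).
#' @param enabled set `FALSE` for uniform fragment placement.
#' @return a list of class `depletion_config`.
#' @export
depletion_config <- function(w = 0.5, promoter_factor = 0.5, enabled = TRUE) {
  structure(list(w = w, promoter_factor = promoter_factor, enabled = enabled),
            class = "depletion_config")
}

#' Simulate one plasma cfDNA sample
#'
#' Generates `n_fragments` methylation-called cfDNA fragments as a
#' two-component mixture: each fragment's origin is Bernoulli
#' (`tumor_fraction`) tumor vs non-tumor; its length comes from the
#' origin-specific [length_model()]; its start position is drawn with
#' density-dependent depletion ([depletion_config()]); and each covered
#' CpG's binary methylation call is Bernoulli with the origin tissue
#' group's mean methylation at that site (malignant group for tumor
#' fragments, benign group for non-tumor), then flipped with probability
#' `noise` (bisulfite conversion / sequencing error).
#'
#' @param map a [build_genome()] `cpg_map`.
#' @param refs a `tissue_methylomes` object providing the per-site group
#'   means (both groups required).
#' @param tumor_fraction fraction of tumor-derived fragments, in [0, 1].
#' @param n_fragments number of fragments.
#' @param noise per-CpG call flip probability.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param length_models per-origin length models.
#' @param depletion a [depletion_config()].
#' @param sample_id,label bookkeeping fields for cohort assembly.
#' @return an object of class `plasma_sample`: list with `sample_id`,
#'   `label`, `tumor_fraction`, `frags` (data.frame: `frag_id`, `chrom`,
#'   `start`, `end`, `length`, `gstart`, `gend`, `origin`), and `calls`
#'   (data.frame: `frag_id`, `site` (row index into `map$sites`), `state`).
#'   Per-fragment origins in `frags$origin` are the simulation ground
#'   truth.
#' @export
simulate_plasma_sample <- function(map, refs, tumor_fraction,
                                   n_fragments = 20000L, noise = 0.01,
                                   seed = NULL,
                                   length_models = default_length_models(),
                                   depletion = depletion_config(),
                                   sample_id = "S1", label = NA_character_) {
  stopifnot(inherits(map, "cpg_map"))
  if (!is.numeric(tumor_fraction) || length(tumor_fraction) != 1L ||
      is.na(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1)
    stop("invalid argument: tumor_fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gm <- refs$group_means
  if (is.null(gm) || !all(c("malignant", "benign") %in% colnames(gm)))
    stop("refs must carry per-site group means for both groups", call. = FALSE)

  w <- map$windows
  n_win <- nrow(w)
  if (depletion$enabled) {
    z <- as.vector(scale(w$cpg_density))
    if (any(is.na(z))) z <- rep(0, n_win)
    wt <- exp(-depletion$w * z) *
      ifelse(w$is_promoter, depletion$promoter_factor, 1)
  } else {
    wt <- rep(1, n_win)
  }
  wt <- wt * (w$end - w$start)  # weight per window scales with its width

  origin <- stats::rbinom(n_fragments, 1L, tumor_fraction)
  len <- integer(n_fragments)
  n_t <- sum(origin == 1L)
  if (n_t > 0) len[origin == 1L] <- sample_fragment_length(n_t, "tumor", length_models)
  if (n_t < n_fragments)
    len[origin == 0L] <- sample_fragment_length(n_fragments - n_t, "nontumor",
                                                length_models)

  widx <- sample.int(n_win, n_fragments, replace = TRUE, prob = wt)
  start <- w$start[widx] +
    floor(stats::runif(n_fragments) * (w$end[widx] - w$start[widx]))
  chrom <- w$chrom[widx]
  chlen <- as.numeric(map$chrom_lengths[chrom])
  start <- pmin(start, pmax(0, chlen - len))
  end <- start + len
  gstart <- start + map$offsets[chrom]
  gend <- gstart + len

  ## covered CpGs via the global position axis
  gpos <- map$sites$gpos
  lo <- findInterval(gstart - 0.5, gpos) + 1L
  hi <- findInterval(gend - 0.5, gpos)
  ncov <- pmax(0L, hi - lo + 1L)
  has <- ncov > 0L
  frag_of_call <- rep.int(seq_len(n_fragments)[has], ncov[has])
  site <- sequence(ncov[has], from = lo[has])
  p <- ifelse(origin[frag_of_call] == 1L, gm[site, "malignant"],
              gm[site, "benign"])
  state <- stats::rbinom(length(site), 1L, p)
  if (noise > 0) {
    flip <- stats::rbinom(length(site), 1L, noise)
    state <- as.integer(xor(state, flip))
  }

  structure(list(
    sample_id = sample_id, label = label, tumor_fraction = tumor_fraction,
    frags = data.frame(frag_id = seq_len(n_fragments), chrom = chrom,
                       start = as.integer(start), end = as.integer(end),
                       length = as.integer(len),
                       gstart = gstart, gend = gend,
                       origin = ifelse(origin == 1L, "tumor", "nontumor"),
                       stringsAsFactors = FALSE),
    calls = data.frame(frag_id = frag_of_call, site = site,
                       state = as.integer(state))),
    class = "plasma_sample")
}

#' @export
print.plasma_sample <- function(x, ...) {
  cat("<plasma_sample>", x$sample_id,
      if (!is.na(x$label)) paste0("(", x$label, ")"), "-",
      nrow(x$frags), "fragments,", nrow(x$calls), "CpG calls, tumor fraction",
      format(x$tumor_fraction), "\n")
  invisible(x)
}
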