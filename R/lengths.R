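#' Fragment-length model for cfDNA
#'
#' cfDNA fragment lengths follow a sharply peaked mono-nucleosomal
#' distribution with a small di-nucleosomal satellite. Each component is a
#' discretized asymmetric Laplace: heavier left tail (`scale_left` >
#' `scale_right`) gives the canonical sub-mononucleosomal shoulder, and a
#' modal-bin excess (`mode_boost`) models the phased over-representation of
#' the exact nucleosome + linker length, which pins the 1-bp-bin mode of the
#' sampled distribution to `mode_bp` even at moderate sample sizes.
#' Non-tumor cfDNA peaks at 167 bp; ctDNA is stochastically shorter, with a
#' default mode of 145 bp.
#'
#' @param mode_bp modal fragment length in bp.
#' @param scale_left,scale_right exponential decay scales (bp) below/above
#'   the mode.
#' @param di_mode_bp,di_scale_left,di_scale_right,di_weight location,
#'   scales and mixture weight of the di-nucleosomal peak.
#' @param mode_boost multiplicative excess of the modal 1-bp bin.
#' @param min_bp,max_bp support bounds (fragments of < `min_bp` are not
#'   recovered by library prep; `max_bp` caps the support).
#' @return a list of class `length_model` with the per-origin discrete pmf.
#' @export
length_model <- function(mode_bp = 167L, scale_left = 20, scale_right = 10,
                         di_mode_bp = 334L, di_scale_left = 30,
                         di_scale_right = 20, di_weight = 0.1,
                         mode_boost = 1.2, min_bp = 30L, max_bp = 499L) {
  stopifnot(mode_bp > min_bp, mode_bp < max_bp, di_weight >= 0, di_weight < 1,
            scale_left > 0, scale_right > 0, mode_boost >= 1)
  len <- seq.int(min_bp, max_bp)
  al <- function(m, sl, sr) {
    w <- ifelse(len <= m, exp(-(m - len) / sl), exp(-(len - m) / sr))
    w / sum(w)
  }
  main <- al(mode_bp, scale_left, scale_right)
  main[len == mode_bp] <- main[len == mode_bp] * mode_boost
  main <- main / sum(main)
  di <- al(di_mode_bp, di_scale_left, di_scale_right)
  pmf <- (1 - di_weight) * main + di_weight * di
  structure(list(lengths = len, pmf = pmf / sum(pmf), mode_bp = mode_bp),
            class = "length_model")
}

default_length_models <- function() {
  list(nontumor = length_model(),
       tumor = length_model(mode_bp = 145L, di_weight = 0.05))
}

#' Sample cfDNA fragment lengths
#'
#' Draws fragment lengths from the per-origin [length_model()]. Uses the
#' global RNG stream; call `set.seed()` for reproducibility.
#'
#' @param n number of fragments.
#' @param origin `"nontumor"` or `"tumor"`.
#' @param models a named list of [length_model()]s per origin; defaults to
#'   the nontumor-mode-167 / tumor-mode-145 pair.
#' @return integer vector of lengths in bp.
#' @export
sample_fragment_length <- function(n, origin = c("nontumor", "tumor"),
                                   models = default_length_models()) {
  origin <- match.arg(origin)
  m <- models[[origin]]
  stopifnot(inherits(m, "length_model"))
  m$lengths[sample.int(length(m$lengths), n, replace = TRUE, prob = m$pmf)]
}
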