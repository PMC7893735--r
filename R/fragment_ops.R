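#' Filter fragments by length
#'
#' Retains fragments strictly shorter than `max_len_bp` (the library-prep
#' rule that removes genomic-DNA contamination) and, if a `short_window`
#' is given, additionally restricts to lengths in `[lo, hi]` -- the size
#' selection that enriches the shorter ctDNA fragments. Order is
#' preserved; the operation is idempotent.
#'
#' @param sample a `plasma_sample` (fragments and their CpG calls are
#'   subset together).
#' @param max_len_bp retain fragments with `length < max_len_bp`.
#' @param short_window optional `c(lo, hi)` inclusive size-selection
#'   window in bp.
#' @return the filtered `plasma_sample`.
#' @export
filter_fragments_by_length <- function(sample, max_len_bp = 500L,
                                       short_window = NULL) {
  stopifnot(inherits(sample, "plasma_sample"))
  if (max_len_bp <= 0) stop("max_len_bp must be positive", call. = FALSE)
  keep <- sample$frags$length < max_len_bp
  if (!is.null(short_window)) {
    if (length(short_window) != 2L || short_window[1] > short_window[2])
      stop("short_window must be c(lo, hi) with lo <= hi", call. = FALSE)
    keep <- keep & sample$frags$length >= short_window[1] &
      sample$frags$length <= short_window[2]
  }
  out <- sample
  out$frags <- sample$frags[keep, , drop = FALSE]
  out$calls <- sample$calls[sample$calls$frag_id %in% out$frags$frag_id, ,
                            drop = FALSE]
  rownames(out$frags) <- rownames(out$calls) <- NULL
  out
}

#' Fragment-size profile
#'
#' 1-bp-binned length histogram with the modal length (ties broken toward
#' the smallest length) and the fraction of fragments inside the
#' short-selection window.
#'
#' @param x a `plasma_sample`, a data.frame with a `length` column, or a
#'   numeric vector of lengths.
#' @param short_window inclusive window for `fraction_short`.
#' @return object of class `size_profile`: list with `histogram`
#'   (data.frame `length`, `count`), `mode_bp`, `fraction_short`,
#'   `n_fragments`.
#' @export
size_profile <- function(x, short_window = c(90L, 150L)) {
  len <- if (inherits(x, "plasma_sample")) x$frags$length
         else if (is.data.frame(x)) x$length
         else x
  if (length(len) == 0) stop("empty input: no fragments", call. = FALSE)
  tab <- table(len)
  lengths <- as.integer(names(tab))
  counts <- as.integer(tab)
  mode_bp <- min(lengths[counts == max(counts)])
  structure(list(histogram = data.frame(length = lengths, count = counts),
                 mode_bp = mode_bp,
                 fraction_short = mean(len >= short_window[1] &
                                         len <= short_window[2]),
                 n_fragments = length(len)),
            class = "size_profile")
}

#' @export
print.size_profile <- function(x, ...) {
  cat("<size_profile>", x$n_fragments, "fragments, mode", x$mode_bp,
      "bp, fraction in short window", format(round(x$fraction_short, 3)), "\n")
  invisible(x)
}

check_dmrs_sorted <- function(dmrs) {
  if (nrow(dmrs) == 0) stop("invalid input: empty DMR set", call. = FALSE)
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$start, strictly = TRUE) ||
        (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])))
      stop("invalid input: DMRs must be sorted and non-overlapping",
           call. = FALSE)
  }
  invisible(dmrs)
}

# Map each site row index of `map` to the DMR (row of `dmrs`) containing
# it, NA otherwise.
site_dmr_index <- function(map, dmrs) {
  gs <- dmrs$start + map$offsets[dmrs$chrom]
  ge <- dmrs$end + map$offsets[dmrs$chrom]
  o <- order(gs)
  gs <- gs[o]; ge <- ge[o]; dmr_row <- seq_len(nrow(dmrs))[o]
  idx <- findInterval(map$sites$gpos, gs)
  hit <- idx >= 1 & map$sites$gpos < ge[pmax(idx, 1L)]
  out <- rep(NA_integer_, nrow(map$sites))
  out[hit] <- dmr_row[idx[hit]]
  out
}

#' Assign fragments to DMRs by CpG containment
#'
#' A fragment is assigned to a DMR iff at least one of its CpG calls lies
#' within the DMR's half-open interval; only CpGs carry methylation
#' evidence, so interval overlap without a contained CpG does not count.
#' A fragment whose CpGs span two DMRs goes to the DMR containing most of
#' its CpGs (ties to the leftmost). Each fragment is assigned at most
#' once.
#'
#' @param sample a `plasma_sample`.
#' @param dmrs a `dmr_set` (or data.frame with `chrom`, `start`, `end`),
#'   sorted and non-overlapping.
#' @param map the `cpg_map` the sample was simulated on (site coordinate
#'   lookup).
#' @return integer vector, one entry per fragment in `sample$frags`: the
#'   row of `dmrs` the fragment is assigned to, or `NA`. Attribute
#'   `"counts"` holds per-DMR assigned fragment counts.
#' @export
assign_fragments_to_dmrs <- function(sample, dmrs, map) {
  stopifnot(inherits(sample, "plasma_sample"), inherits(map, "cpg_map"))
  check_dmrs_sorted(dmrs)
  sd <- site_dmr_index(map, dmrs)
  calls <- sample$calls
  dmr_of_call <- sd[calls$site]
  keep <- !is.na(dmr_of_call)
  assign <- rep(NA_integer_, nrow(sample$frags))
  if (any(keep)) {
    dt <- data.table::data.table(frag_id = calls$frag_id[keep],
                                 dmr = dmr_of_call[keep])
    cnt <- dt[, .N, by = c("frag_id", "dmr")]
    data.table::setorderv(cnt, c("frag_id", "N", "dmr"), c(1L, -1L, 1L))
    best <- cnt[!duplicated(cnt$frag_id)]
    assign[match(best$frag_id, sample$frags$frag_id)] <- best$dmr
  }
  attr(assign, "counts") <- tabulate(assign, nbins = nrow(dmrs))
  assign
}

#' cfDNA enrichment score over a DMR set
#'
#' The enrichment score of a plasma sample is the mean number of assigned
#' fragments per DMR; the normalized variant rescales to fragments per DMR
#' per million sequenced fragments.
#'
#' @param sample a `plasma_sample`.
#' @param dmrs DMR set (sorted, non-overlapping); at least one DMR.
#' @param map the `cpg_map`.
#' @param per_million normalize by total fragment count x 1e6.
#' @return scalar score.
#' @export
enrichment_score <- function(sample, dmrs, map, per_million = FALSE) {
  if (is.null(dmrs) || nrow(dmrs) == 0)
    stop("invalid input: need at least one DMR", call. = FALSE)
  assign <- assign_fragments_to_dmrs(sample, dmrs, map)
  score <- sum(attr(assign, "counts")) / nrow(dmrs)
  if (per_million) score <- score / nrow(sample$frags) * 1e6
  score
}

#' Coverage by genomic region class
#'
#' Summarizes where a sample's fragments land: per region class
#' (promoter/genic/intergenic) the mean number of fragment starts per kb,
#' plus the Pearson correlation of window-wise fragment count with window
#' CpG density -- negative when CpG-dense regions are depleted.
#'
#' @param sample a `plasma_sample`.
#' @param map the `cpg_map`.
#' @return list with `class_coverage` (data.frame: `region_class`,
#'   `n_windows`, `n_fragments`, `mean_per_kb`) and
#'   `density_correlation`.
#' @export
coverage_by_region_class <- function(sample, map) {
  stopifnot(inherits(sample, "plasma_sample"), inherits(map, "cpg_map"))
  if (nrow(sample$frags) == 0) stop("empty input: no fragments", call. = FALSE)
  w <- map$windows
  widx <- findInterval(sample$frags$gstart, w$gstart)
  cnt <- tabulate(widx, nbins = nrow(w))
  kb <- (w$end - w$start) / 1000
  agg <- lapply(split(seq_len(nrow(w)), w$region_class), function(i)
    data.frame(n_windows = length(i), n_fragments = sum(cnt[i]),
               mean_per_kb = sum(cnt[i]) / sum(kb[i])))
  cc <- do.call(rbind, agg)
  cc <- cbind(region_class = rownames(cc), cc)
  rownames(cc) <- NULL
  list(class_coverage = cc,
       density_correlation = stats::cor(cnt, w$cpg_density))
}
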