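# Plain-text interchange formats: BED for intervals, TSV/CSV for tables,
# JSON for model results. All coordinates 0-based half-open (BED
# convention).

#' Write / read a CpG map
#'
#' Sites go to `cpg_sites.bed` (width-2 site intervals, with region class
#' and element in extra columns) and window tracks to `windows.tsv`.
#'
#' @param map a `cpg_map`.
#' @param dir output directory (created if needed).
#' @return `write_cpg_map()`: the directory, invisibly. `read_cpg_map()`:
#'   a `cpg_map` (chromosome lengths and window width are recovered from
#'   the sidecar `meta.tsv`).
#' @export
write_cpg_map <- function(map, dir) {
  stopifnot(inherits(map, "cpg_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- map$sites
  utils::write.table(
    data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 2L,
               region_class = s$region_class, element = s$element),
    file.path(dir, "cpg_sites.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(map$windows, file.path(dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(map$chrom_lengths),
               length = as.integer(map$chrom_lengths),
               window_bp = map$window_bp),
    file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cpg_map
#' @export
read_cpg_map <- function(dir) {
  meta <- utils::read.table(file.path(dir, "meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  bed <- utils::read.table(file.path(dir, "cpg_sites.bed"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "region_class", "element"))
  win <- utils::read.table(file.path(dir, "windows.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  lens <- stats::setNames(meta$length, meta$chrom)
  offs <- chrom_offsets(lens)
  map <- list(
    sites = data.frame(chrom = bed$chrom, pos = bed$start,
                       gpos = bed$start + offs[bed$chrom],
                       region_class = factor(bed$region_class,
                                             levels = region_class_levels),
                       element = factor(bed$element,
                                        levels = c("background", "cluster",
                                                   "island")),
                       stringsAsFactors = FALSE),
    windows = win, islands = NULL, clusters = NULL,
    chrom_lengths = lens, offsets = offs, window_bp = meta$window_bp[1],
    config = NULL)
  class(map) <- "cpg_map"
  map
}

#' Write / read tissue methylomes as TSV
#'
#' One row per CpG site (`chrom`, `pos`, then one beta column per sample);
#' sample groups go to a `<path>.samples.tsv` sidecar.
#'
#' @param methylomes a `tissue_methylomes`.
#' @param path output TSV path.
#' @param map the `cpg_map` the betas are aligned to (for reading).
#' @return `read_methylomes()`: a `tissue_methylomes` (without
#'   `group_means` recomputed; they are re-derived from the betas).
#' @export
write_methylomes <- function(methylomes, path) {
  df <- data.frame(chrom = methylomes$map$sites$chrom,
                   pos = methylomes$map$sites$pos)
  df <- cbind(df, as.data.frame(methylomes$beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(methylomes$samples, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylomes
#' @export
read_methylomes <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  samp <- utils::read.table(paste0(path, ".samples.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  beta <- as.matrix(df[, samp$sample_id, drop = FALSE])
  grp <- samp$group
  gm <- cbind(malignant = rowMeans(beta[, grp == "malignant", drop = FALSE]),
              benign = rowMeans(beta[, grp == "benign", drop = FALSE]))
  structure(list(beta = beta, samples = samp, group_means = gm, map = map),
            class = "tissue_methylomes")
}

#' Write / read plasma fragments as TSV
#'
#' Schema: `sample_id`, `chrom`, `start`, `end`, `cpg_positions`
#' (comma-joined bp positions), `cpg_states` (comma-joined 0/1).
#'
#' @param sample a `plasma_sample`.
#' @param path output TSV path.
#' @param map the `cpg_map` (site indices are written as bp positions and
#'   recovered when reading).
#' @return `read_fragments()`: a `plasma_sample` (simulation-only fields
#'   such as `origin` are absent).
#' @export
write_fragments <- function(sample, path, map) {
  stopifnot(inherits(sample, "plasma_sample"), inherits(map, "cpg_map"))
  calls <- sample$calls
  sp <- split(seq_len(nrow(calls)), calls$frag_id)
  cp <- cs <- rep("", nrow(sample$frags))
  idx <- match(names(sp), as.character(sample$frags$frag_id))
  cp[idx] <- vapply(sp, function(i)
    paste(map$sites$pos[calls$site[i]], collapse = ","), character(1))
  cs[idx] <- vapply(sp, function(i) paste(calls$state[i], collapse = ","),
                    character(1))
  df <- data.frame(sample_id = sample$sample_id,
                   chrom = sample$frags$chrom, start = sample$frags$start,
                   end = sample$frags$end, cpg_positions = cp,
                   cpg_states = cs, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(cpg_positions = "character",
                                         cpg_states = "character"))
  n <- nrow(df)
  offs <- map$offsets
  frags <- data.frame(frag_id = seq_len(n), chrom = df$chrom,
                      start = df$start, end = df$end,
                      length = df$end - df$start,
                      gstart = df$start + offs[df$chrom],
                      gend = df$end + offs[df$chrom],
                      origin = NA_character_, stringsAsFactors = FALSE)
  has <- nzchar(df$cpg_positions)
  sites_l <- lapply(which(has), function(i) {
    p <- as.integer(strsplit(df$cpg_positions[i], ",")[[1]])
    s <- as.integer(strsplit(df$cpg_states[i], ",")[[1]])
    gp <- p + offs[df$chrom[i]]
    data.frame(frag_id = i, site = match(gp, map$sites$gpos), state = s)
  })
  calls <- if (length(sites_l)) do.call(rbind, sites_l) else
    data.frame(frag_id = integer(0), site = integer(0), state = integer(0))
  structure(list(sample_id = df$sample_id[1] %||% "S1", label = NA_character_,
                 tumor_fraction = NA_real_, frags = frags, calls = calls),
            class = "plasma_sample")
}

#' Write / read a DMR set as BED6+
#'
#' Columns: chrom, start, end, name, score (`-log10 q`, capped at 1000),
#' strand ("."), then `n_cpgs`, `delta`, `direction`, `p_value`,
#' `q_value`.
#'
#' @param dmrs a `dmr_set`.
#' @param path output BED path.
#' @return `read_dmrs()`: a `dmr_set` data.frame.
#' @export
write_dmrs <- function(dmrs, path) {
  df <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                   name = dmrs$dmr_id,
                   score = round(pmin(1000, -log10(pmax(dmrs$q_value,
                                                        1e-300))), 3),
                   strand = ".", n_cpgs = dmrs$n_cpgs, delta = dmrs$delta,
                   direction = dmrs$direction, p_value = dmrs$p_value,
                   q_value = dmrs$q_value, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs
#' @export
read_dmrs <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "n_cpgs",
                                        "delta", "direction", "p_value",
                                        "q_value"))
  out <- data.frame(dmr_id = df$name, chrom = df$chrom, start = df$start,
                    end = df$end, region_id = NA_integer_,
                    n_cpgs = df$n_cpgs,
                    mean_beta_mal = NA_real_, mean_beta_ben = NA_real_,
                    delta = df$delta, direction = df$direction,
                    p_value = df$p_value, q_value = df$q_value,
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Write marker profiles as CSV
#'
#' Ratios matrix (rows = samples, columns = DMR ids) plus a companion
#' `<path>.counts.csv` of informative fragment counts.
#'
#' @param profiles a `marker_profiles`.
#' @param path output CSV path.
#' @export
write_marker_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles$ratios), path)
  utils::write.csv(as.data.frame(profiles$counts),
                   paste0(path, ".counts.csv"))
  invisible(path)
}

#' Write a model result as JSON
#'
#' @param result a `model_result` from [evaluate_model()].
#' @param path output JSON path.
#' @export
write_model_result <- function(result, path) {
  out <- list(auc = result$auc, auc_ci = result$auc_ci,
              threshold = result$threshold,
              confusion = as.list(result$confusion),
              sensitivity = result$sensitivity,
              specificity = result$specificity,
              accuracy = result$accuracy,
              stage_detection = as.list(result$stage_detection %||% list()),
              roc = result$roc, n = result$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
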