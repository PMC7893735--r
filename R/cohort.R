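#' Cohort simulation configuration
#'
#' Describes one plasma cohort: class sizes, the stage mix of the malignant
#' arm, the stage-conditional tumor-fraction distribution, sequencing depth
#' per sample, and the strength of the imaging signal. Benign samples have
#' tumor fraction exactly 0. Malignant tumor fractions are gamma
#' distributed with stage-dependent means that increase with stage; the
#' default means (DCIS 0.005, I 0.01, II 0.02, III 0.04) encode the low
#' ctDNA burden of early disease -- only their ordering matters to the
#' package's tests. Imaging (mammography/ultrasound) scores are ordinal
#' 1-5, drawn from label-shifted latent normals so that standalone imaging
#' discrimination is deliberately imperfect.
#'
#' @param n_mal,n_ben class sizes (>= 2 each).
#' @param cohort label, e.g. `"discovery"` or `"validation"`.
#' @param stage_probs named probabilities over stages `0` (DCIS), `I`,
#'   `II`, `III` for malignant samples.
#' @param stage_tf_mean named stage-conditional mean tumor fractions
#'   (monotone increasing with stage).
#' @param tf_shape gamma shape of the tumor-fraction distribution.
#' @param n_fragments,noise per-sample fragment count and per-CpG call
#'   flip probability (see [simulate_plasma_sample()]).
#' @param imaging_shift latent-normal mean shift of malignant imaging
#'   scores, in SD units (0 = imaging carries no signal).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_mal = 77L, n_ben = 77L, cohort = "discovery",
                          stage_probs = c(`0` = 0.05, I = 0.40, II = 0.33,
                                          III = 0.22),
                          stage_tf_mean = c(`0` = 0.005, I = 0.01, II = 0.02,
                                            III = 0.04),
                          tf_shape = 4,
                          n_fragments = 20000L, noise = 0.01,
                          imaging_shift = 1.0) {
  if (n_mal < 2 || n_ben < 2)
    stop("invalid config: need >= 2 samples per class", call. = FALSE)
  stopifnot(identical(names(stage_probs), c("0", "I", "II", "III")),
            identical(names(stage_tf_mean), c("0", "I", "II", "III")))
  structure(list(n_mal = as.integer(n_mal), n_ben = as.integer(n_ben),
                 cohort = cohort,
                 stage_probs = stage_probs / sum(stage_probs),
                 stage_tf_mean = stage_tf_mean, tf_shape = tf_shape,
                 n_fragments = as.integer(n_fragments), noise = noise,
                 imaging_shift = imaging_shift),
            class = "cohort_config")
}

# Ordinal 1-5 score from a latent normal; cutpoints fixed on the benign
# scale so that the shift moves malignant samples toward higher scores.
ordinal_score <- function(latent) {
  as.integer(cut(latent, breaks = c(-Inf, -0.8, 0, 0.8, 1.6, Inf),
                 labels = FALSE))
}

#' Simulate a plasma cohort with cohort table
#'
#' Draws per-sample tumor fractions (stage-conditional for malignant, 0 for
#' benign), simulates each plasma sample's fragments against the tissue
#' references, and builds the cohort record table with malignancy labels,
#' BI-RADS 4 subcategories, mammography/ultrasound ordinal scores, stage
#' and grade.
#'
#' @param map a [build_genome()] `cpg_map`.
#' @param refs a `tissue_methylomes` object (group means used as fragment
#'   emission probabilities).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param length_models,depletion forwarded to [simulate_plasma_sample()].
#' @return list with `samples` (list of `plasma_sample`) and `table`
#'   (data.frame: `sample_id`, `label`, `birads_sub`, `mammography_score`,
#'   `ultrasound_score`, `stage`, `grade`, `cohort`, `tumor_fraction`).
#' @export
simulate_cohort <- function(map, refs, config = cohort_config(), seed = 1L,
                            length_models = default_length_models(),
                            depletion = depletion_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_mal + config$n_ben
  label <- rep(c("malignant", "benign"), c(config$n_mal, config$n_ben))
  ids <- sprintf("%s_P%03d", toupper(substr(config$cohort, 1, 3)), seq_len(n))

  stages <- rep(NA_character_, n)
  stages[label == "malignant"] <- sample(names(config$stage_probs),
                                         config$n_mal, replace = TRUE,
                                         prob = config$stage_probs)
  tf <- numeric(n)
  i_mal <- which(label == "malignant")
  mu <- config$stage_tf_mean[stages[i_mal]]
  tf[i_mal] <- clamp(stats::rgamma(config$n_mal, shape = config$tf_shape,
                                   scale = mu / config$tf_shape), 0, 0.5)

  shift <- ifelse(label == "malignant", config$imaging_shift, 0)
  lat_m <- stats::rnorm(n, shift)
  lat_u <- stats::rnorm(n, shift)
  mammo <- ordinal_score(lat_m)
  ultra <- ordinal_score(lat_u)
  birads <- cut((lat_m + lat_u) / 2, breaks = c(-Inf, 0.3, 1.0, Inf),
                labels = c("4a", "4b", "4c"))

  grade <- rep(NA_integer_, n)
  stage_num <- match(stages[i_mal], names(config$stage_probs))  # 1..4
  grade[i_mal] <- clamp(stage_num - 1L +
                          sample(0:1, config$n_mal, replace = TRUE), 1L, 3L)

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- simulate_plasma_sample(
      map, refs, tumor_fraction = tf[i], n_fragments = config$n_fragments,
      noise = config$noise, seed = NULL, length_models = length_models,
      depletion = depletion, sample_id = ids[i], label = label[i])
  }

  tab <- data.frame(sample_id = ids, label = label,
                    birads_sub = as.character(birads),
                    mammography_score = mammo, ultrasound_score = ultra,
                    stage = stages, grade = grade,
                    cohort = config$cohort, tumor_fraction = tf,
                    stringsAsFactors = FALSE)
  list(samples = samples, table = tab)
}

#' Simulate a complete two-cohort study
#'
#' Convenience wrapper generating every input the pipeline needs: the
#' genome model, tissue reference methylomes with planted markers, and the
#' discovery and validation plasma cohorts. The tissue marker effect size
#' defaults to `delta = 0.6`: the handful of markers carried into the
#' plasma analysis stands in for the extreme tail of a genome-wide DMR set,
#' where effect sizes are large.
#'
#' @param genome a [genome_config()].
#' @param tissue_spec a [dmr_spec()] for the tissue simulator.
#' @param n_mal_tissue,n_ben_tissue tissue sample counts.
#' @param discovery,validation [cohort_config()]s (validation defaults to
#'   24 malignant / 25 benign).
#' @param seed integer master seed; sub-seeds are derived from it.
#' @return list with `map`, `tissues`, `tissue_truth`, `discovery`,
#'   `validation` (each cohort a list of `samples` + `table`).
#' @export
simulate_study <- function(genome = genome_config(),
                           tissue_spec = dmr_spec(delta = 0.6),
                           n_mal_tissue = 9L, n_ben_tissue = 10L,
                           discovery = cohort_config(),
                           validation = cohort_config(n_mal = 24L,
                                                      n_ben = 25L,
                                                      cohort = "validation"),
                           seed = 1L) {
  seed <- as.integer(seed) %% 100000L
  map <- build_genome(genome, seed = seed)
  tis <- simulate_tissue_methylomes(map, n_mal_tissue, n_ben_tissue,
                                    spec = tissue_spec, seed = seed + 1L)
  disc <- simulate_cohort(map, tis$methylomes, discovery, seed = seed + 2L)
  vali <- simulate_cohort(map, tis$methylomes, validation, seed = seed + 3L)
  list(map = map, tissues = tis$methylomes, tissue_truth = tis$truth,
       discovery = disc, validation = vali)
}
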