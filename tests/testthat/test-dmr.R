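test_that("segmentation follows the gap rule on hand-built maps", {
  # far-away site is dropped: run {100,150,300} kept, 5000 alone
  map <- manual_map(c(100, 150, 300, 5000))
  r <- segment_candidate_regions(map, min_cpgs = 3, max_gap_bp = 500)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100)
  expect_equal(r$end, 302)
  expect_equal(r$n_cpgs, 3)

  # all gaps small: a single region spanning first to last site
  map2 <- manual_map(seq(100, 2000, by = 100))
  r2 <- segment_candidate_regions(map2, min_cpgs = 4, max_gap_bp = 500)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 100)
  expect_equal(r2$end, 2002)

  # empty map
  map3 <- manual_map(integer(0))
  expect_equal(nrow(segment_candidate_regions(map3)), 0)

  expect_error(segment_candidate_regions(map, min_cpgs = 2), "min_cpgs")
})

test_that("identical group methylomes yield zero DMRs", {
  map <- manual_map(seq(100, 5000, by = 100))
  one <- matrix(rep(rbeta_fixture(nrow(map$sites)), 8), ncol = 8)
  meth <- list(beta = one,
               samples = data.frame(sample_id = paste0("s", 1:8),
                                    group = rep(c("malignant", "benign"),
                                                each = 4)))
  r <- segment_candidate_regions(map)
  d <- suppressWarnings(call_dmrs(r, meth))
  expect_equal(nrow(d), 0)
})

test_that("planted DMRs are recovered with the right direction and size", {
  map <- default_map()
  # plant a hypo-DMR on a mid-density cluster and a hyper-DMR on an island
  cl <- map$clusters[1, ]
  is <- map$islands[1, ]
  reg <- data.frame(chrom = c(cl$chrom, is$chrom),
                    start = as.integer(c(cl$start, is$start)),
                    end = as.integer(c(cl$end, is$end)),
                    direction = c("hypo", "hyper"),
                    delta = c(0.4, 0.3), stringsAsFactors = FALSE)
  out <- simulate_tissue_methylomes(
    map, n_mal = 9, n_ben = 10,
    spec = dmr_spec(regions = reg, concentration = 30), seed = 12)
  d <- call_dmrs(segment_candidate_regions(map), out$methylomes)
  overlaps <- function(d, r)
    d$chrom == r$chrom & d$start < r$end & d$end > r$start
  hypo <- d[overlaps(d, reg[1, ]), ]
  hyper <- d[overlaps(d, reg[2, ]), ]
  expect_gt(nrow(hypo), 0)
  expect_gt(nrow(hyper), 0)
  expect_true(all(hypo$direction == "hypo"))
  expect_true(all(hyper$direction == "hyper"))
  expect_true(all(hypo$delta >= -0.45 & hypo$delta <= -0.35))
  # direction convention: positive delta = hyper
  expect_true(all(d$delta[d$direction == "hyper"] > 0))
})

test_that("call_dmrs demands replicates and returns sorted regions", {
  map <- manual_map(seq(100, 5000, by = 100))
  set.seed(13)
  meth <- list(beta = matrix(runif(nrow(map$sites) * 3), ncol = 3),
               samples = data.frame(sample_id = c("a", "b", "c"),
                                    group = c("malignant", "benign",
                                              "benign")))
  expect_error(call_dmrs(segment_candidate_regions(map), meth),
               "insufficient replicates")

  d <- study_pipeline(1)$res$dmrs
  expect_false(is.unsorted(d$start[d$chrom == "chr1"]))
  # called DMRs are candidate regions: no overlaps within a chromosome
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    if (nrow(dd) > 1) expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
  }
})

test_that("permuting tissue labels destroys DMR calls", {
  map <- default_map()
  meth <- default_tissues()$methylomes
  n_true <- nrow(call_dmrs(segment_candidate_regions(map), meth))
  expect_gt(n_true, 0)
  set.seed(31)
  n_perm <- vapply(1:10, function(i) {
    pm <- meth
    pm$samples$group <- sample(pm$samples$group)
    nrow(suppressWarnings(call_dmrs(segment_candidate_regions(map), pm)))
  }, numeric(1))
  expect_lte(median(n_perm), 0.05 * n_true)
})

test_that("hyper-DMRs are CpG-denser than hypo-DMRs on the default world", {
  map <- default_map()
  d <- call_dmrs(segment_candidate_regions(map),
                 default_tissues()$methylomes)
  dens <- vapply(seq_len(nrow(d)), function(i)
    cpg_density(map, d$chrom[i], d$start[i], d$end[i]), numeric(1))
  expect_gt(median(dens[d$direction == "hyper"]),
            median(dens[d$direction == "hypo"]))
})
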