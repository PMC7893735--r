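test_that("length filtering follows the strict < 500 bp rule", {
  s <- manual_sample(starts = c(0, 0, 0, 0, 0),
                     ends = c(100, 167, 499, 500, 600))
  f <- filter_fragments_by_length(s, max_len_bp = 500)
  expect_equal(f$frags$length, c(100L, 167L, 499L))
  fw <- filter_fragments_by_length(s, 500, short_window = c(90, 150))
  expect_equal(fw$frags$length, 100L)
  # idempotence
  expect_identical(filter_fragments_by_length(fw, 500, c(90, 150))$frags,
                   fw$frags)
  # empty input
  e <- manual_sample(integer(0), integer(0))
  expect_equal(nrow(filter_fragments_by_length(e, 500)$frags), 0)
  expect_error(filter_fragments_by_length(s, 500, c(150, 90)), "lo <= hi")
})

test_that("size_profile histogram, mode tie-break and short fraction", {
  s <- manual_sample(rep(0, 4), rep(100, 4))
  p <- size_profile(s, short_window = c(90, 150))
  expect_equal(p$mode_bp, 100L)
  expect_equal(p$fraction_short, 1.0)
  expect_equal(sum(p$histogram$count), 4)

  # tie -> smallest length
  p2 <- size_profile(c(140, 140, 167, 167))
  expect_equal(p2$mode_bp, 140L)

  expect_error(size_profile(numeric(0)), "empty input")

  # counts conserved under permutation of input order
  set.seed(5)
  lens <- sample(c(100, 167, 200), 500, replace = TRUE)
  h1 <- size_profile(lens)$histogram
  h2 <- size_profile(sample(lens))$histogram
  expect_identical(h1, h2)
})

test_that("fragments are assigned to DMRs by CpG containment majority", {
  map <- manual_map(c(100, 150, 200, 600, 650, 700, 1200))
  dmrs <- data.frame(chrom = "chr1", start = c(90L, 590L),
                     end = c(210L, 710L), stringsAsFactors = FALSE)
  # frag 1: 2 CpGs in DMR A, 1 in DMR B -> A
  # frag 2: no CpGs in any DMR -> unassigned
  # frag 3: ends exactly at DMR B start -> no overlap (half-open)
  s <- manual_sample(
    starts = c(100, 1150, 500), ends = c(620, 1250, 590),
    calls = data.frame(frag_id = c(1L, 1L, 1L, 2L),
                       site = c(1L, 2L, 4L, 7L),
                       state = c(1L, 0L, 1L, 1L)))
  a <- assign_fragments_to_dmrs(s, dmrs, map)
  expect_equal(a[1], 1L)
  expect_true(is.na(a[2]))  # site 1200 not inside any DMR
  expect_true(is.na(a[3]))
  expect_equal(attr(a, "counts"), c(1L, 0L))

  bad <- dmrs[c(2, 1), ]
  expect_error(assign_fragments_to_dmrs(s, bad, map), "sorted")
})

test_that("enrichment score is the mean assigned count per DMR", {
  map <- manual_map(seq(100, 4000, by = 50))
  dmrs <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                     end = c(1000L, 2000L, 3000L))
  # construct fragments whose CpG calls put 2, 4, 6 fragments in the DMRs
  n <- c(2, 4, 6)
  starts <- unlist(mapply(function(k, s0) rep(s0, k), n, c(100, 1100, 2100)))
  ends <- starts + 150
  site_of <- function(pos) match(pos, map$sites$pos)
  calls <- data.frame(frag_id = seq_along(starts),
                      site = site_of(starts + 50), state = 1L)
  s <- manual_sample(starts, ends, calls)
  expect_equal(enrichment_score(s, dmrs, map), 4.0)

  # no fragment overlaps any DMR
  far <- data.frame(chrom = "chr1", start = 9000L, end = 9500L)
  expect_equal(enrichment_score(s, far, map), 0.0)
  expect_error(enrichment_score(s, far[0, ], map), "at least one DMR")

  # assignment is a partial function: counts never exceed fragments
  a <- assign_fragments_to_dmrs(s, dmrs, map)
  expect_lte(sum(attr(a, "counts")), nrow(s$frags))
})

test_that("hypo-DMRs catch more cfDNA than hyper-DMRs under depletion", {
  pipe <- study_pipeline(1)
  map <- pipe$study$map
  d <- pipe$res$dmrs
  s <- pipe$study$discovery$samples[[1]]
  hypo <- d[d$direction == "hypo", ]
  hyper <- d[d$direction == "hyper", ]
  # per-kb fragment recruitment, so region width cannot drive the contrast
  per_kb <- function(dd) {
    a <- assign_fragments_to_dmrs(s, dd, map)
    sum(attr(a, "counts")) / (sum(dd$end - dd$start) / 1000)
  }
  expect_gt(per_kb(hypo), per_kb(hyper))
  expect_gt(enrichment_score(s, hypo, map), enrichment_score(s, hyper, map))
})

test_that("coverage by region class reflects the depletion switch", {
  map <- default_map()
  refs <- default_tissues()$methylomes
  off <- simulate_plasma_sample(map, refs, 0, n_fragments = 30000, seed = 14,
                                depletion = depletion_config(enabled = FALSE))
  cov_off <- coverage_by_region_class(off, map)
  cc <- cov_off$class_coverage
  prom <- cc$mean_per_kb[cc$region_class == "promoter"]
  gen <- cc$mean_per_kb[cc$region_class == "genic"]
  expect_lt(abs(prom - gen) / gen, 0.10)

  on <- simulate_plasma_sample(map, refs, 0, n_fragments = 30000, seed = 14,
                               depletion = depletion_config(enabled = TRUE))
  cov_on <- coverage_by_region_class(on, map)
  cc2 <- cov_on$class_coverage
  prom2 <- cc2$mean_per_kb[cc2$region_class == "promoter"]
  expect_lt(prom2, cc2$mean_per_kb[cc2$region_class == "genic"])
  expect_lt(prom2, cc2$mean_per_kb[cc2$region_class == "intergenic"])
  expect_lt(cov_on$density_correlation, 0)
})
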