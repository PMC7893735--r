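test_that("reference panel clamps and averages group betas", {
  map <- manual_map(c(100, 150, 200, 250))
  dmr <- data.frame(dmr_id = "d1", chrom = "chr1", start = 90L, end = 260L,
                    direction = "hypo", stringsAsFactors = FALSE)
  beta <- cbind(rep(1, 4), rep(1, 4), c(0.2, 0.2, 0.2, 0.2),
                c(0.4, 0.4, 0.4, 0.4))
  meth <- list(beta = beta,
               samples = data.frame(sample_id = paste0("s", 1:4),
                                    group = c("malignant", "malignant",
                                              "benign", "benign")),
               map = map)
  p <- build_reference_panel(dmr, meth, epsilon = 0.01)
  in_p <- !is.na(p$site_dmr)
  expect_equal(unique(p$p_mal[in_p]), 0.99)   # clamp of mean 1.0
  expect_equal(unique(p$p_ben[in_p]), 0.3)    # mean of 0.2, 0.4

  meth_bad <- meth
  meth_bad$samples$group <- rep("malignant", 4)
  expect_error(build_reference_panel(dmr, meth_bad),
               "insufficient replicates")
  expect_error(build_reference_panel(dmr, meth, epsilon = 0.5), "epsilon")

  # DMR without CpGs is excluded with a warning
  dmr2 <- rbind(dmr, data.frame(dmr_id = "d2", chrom = "chr1",
                                start = 5000L, end = 6000L,
                                direction = "hypo"))
  expect_warning(p2 <- build_reference_panel(dmr2, meth), "no CpG sites")
  expect_equal(nrow(p2$dmrs), 1)
})

test_that("fragment log-likelihoods match hand computation", {
  ll <- fragment_log_likelihood(c(1, 1, 1), rep(0.9, 3), rep(0.5, 3))
  expect_equal(ll[["ll_mal"]], 3 * log(0.9))
  expect_equal(ll[["ll_ben"]], 3 * log(0.5))

  # symmetric reference: both likelihoods equal
  ll2 <- fragment_log_likelihood(c(1, 0, 1), rep(0.5, 3), rep(0.5, 3))
  expect_equal(ll2[["ll_mal"]], ll2[["ll_ben"]])
  expect_equal(ll2[["ll_mal"]], 3 * log(0.5))

  # clamped references keep everything finite
  expect_true(all(is.finite(
    fragment_log_likelihood(c(1, 0), c(0.99, 0.01), c(0.01, 0.99)))))
})

test_that("fragment classification matches hand computation and ties", {
  # hypo-DMR: malignant reference unmethylated; all-unmethylated fragment
  cl <- classify_fragment(rep(0, 4), rep(0.1, 4), rep(0.9, 4))
  expect_equal(cl, "malignant")  # llr = 4 * log(9) >> log 2
  expect_equal(classify_fragment(c(1, 0), c(0.5, 0.5), c(0.5, 0.5)),
               "ambiguous")     # llr = 0
})

test_that("classification agrees with the exhaustive-enumeration oracle", {
  set.seed(42)
  for (k in 2:5) {
    pats <- all_patterns(k)
    for (rep in 1:5) {
      pm <- runif(k, 0.02, 0.98)
      pb <- runif(k, 0.02, 0.98)
      for (i in seq_len(nrow(pats))) {
        expect_identical(classify_fragment(pats[i, ], pm, pb),
                         oracle_classify(pats[i, ], pm, pb))
      }
    }
  }
})

test_that("swapping references flips the sign but not the magnitude of llr", {
  set.seed(43)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    s <- rbinom(k, 1, 0.5)
    pm <- runif(k, 0.02, 0.98); pb <- runif(k, 0.02, 0.98)
    a <- fragment_log_likelihood(s, pm, pb)
    b <- fragment_log_likelihood(s, pb, pm)
    expect_equal(a[["ll_mal"]] - a[["ll_ben"]],
                 -(b[["ll_mal"]] - b[["ll_ben"]]))
  }
})

test_that("malignant ratio boundary cases and missingness policy", {
  map <- manual_map(seq(100, 400, by = 20))
  dmr <- data.frame(chrom = "chr1", start = 90L, end = 420L)
  panel <- manual_panel(map, dmr, p_mal = 0.05, p_ben = 0.95)
  mk_sample <- function(states_per_frag) {
    nf <- length(states_per_frag)
    calls <- do.call(rbind, lapply(seq_len(nf), function(i)
      data.frame(frag_id = i, site = 1:4,
                 state = states_per_frag[[i]])))
    manual_sample(rep(100, nf), rep(200, nf), calls)
  }
  # all fragments all-unmethylated -> all malignant -> ratio 1
  s1 <- mk_sample(rep(list(rep(0L, 4)), 6))
  r1 <- malignant_ratios(s1, panel)
  expect_equal(r1$malignant_ratio, 1.0)
  # all methylated -> none malignant -> 0
  s0 <- mk_sample(rep(list(rep(1L, 4)), 6))
  expect_equal(malignant_ratios(s0, panel)$malignant_ratio, 0.0)
  # below min_fragments -> missing, not zero
  s2 <- mk_sample(rep(list(rep(0L, 4)), 3))
  expect_true(is.na(malignant_ratios(s2, panel)$malignant_ratio))
})

test_that("marker profiles: completeness, imputation and dropping", {
  map <- manual_map(seq(100, 400, by = 20))
  dmrs <- data.frame(chrom = "chr1", start = c(90L, 300L),
                     end = c(290L, 420L))
  panel <- manual_panel(map, dmrs, p_mal = 0.05, p_ben = 0.95)
  # sites 1..10 are in DMR1 ([90,290) covers 100..280), 11..16 in DMR2.
  # six fragments per DMR block, separate fragments per DMR.
  mk <- function(id, blocks) {
    calls <- do.call(rbind, lapply(seq_along(blocks), function(b)
      do.call(rbind, lapply(1:6, function(i)
        data.frame(frag_id = (b - 1L) * 6L + i, site = blocks[[b]]$sites,
                   state = blocks[[b]]$state)))))
    nf <- 6L * length(blocks)
    manual_sample(rep(100, nf), rep(200, nf), calls, sample_id = id)
  }
  full1 <- mk("a", list(list(sites = 1:4, state = 1L),
                        list(sites = 12:15, state = 0L)))
  full2 <- mk("b", list(list(sites = 1:4, state = 0L),
                        list(sites = 12:15, state = 1L)))
  prof <- build_marker_profiles(list(full1, full2), panel,
                                labels = c("malignant", "benign"))
  expect_equal(dim(prof$ratios), c(2, 2))
  expect_false(any(is.na(prof$ratios)))

  # sample missing DMR2 entirely -> imputed with benign value, flagged
  miss <- mk("c", list(list(sites = 1:4, state = 0L)))
  prof2 <- build_marker_profiles(list(full1, full2, miss), panel,
                                 labels = c("malignant", "benign",
                                            "malignant"))
  expect_true(prof2$missing[3, 2])
  expect_equal(prof2$ratios[3, 2], prof2$ratios[2, 2])  # benign median

  # a DMR missing in > 50% of samples is dropped with a warning
  expect_warning(
    prof3 <- build_marker_profiles(list(miss, miss, full1), panel,
                                   labels = c("benign", "benign",
                                              "malignant")),
    "dropped")
  expect_equal(ncol(prof3$ratios), 1)
})

test_that("benign-only plasma keeps the mean malignant ratio low", {
  pipe <- study_pipeline(1)
  tab <- pipe$study$discovery$table
  ben <- tab$label == "benign"
  expect_lt(mean(pipe$res$profiles$ratios[ben, ]), 0.1)
})
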