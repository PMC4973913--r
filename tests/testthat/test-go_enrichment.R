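test_that("per-bin test is the upper-tail hypergeometric probability", {
  expect_equal(bin_term_test(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(bin_term_test(0, 10, 4, 30), 1)   # upper tail covers everything
  expect_equal(bin_term_test(10, 10, 30, 30), 1) # forced outcome
  expect_error(bin_term_test(6, 5, 6, 10), "k must be")
  expect_error(bin_term_test(2, 5, 3, 4), "<= N")
})

test_that("test probabilities match exact enumeration for every N <= 20", {
  for (N in c(3, 7, 12, 20)) {
    for (K in 0:N) {
      for (b in 1:N) {
        for (k in 0:min(b, K)) {
          if (k < max(0, b - (N - K))) next
          expect_equal(bin_term_test(k, b, K, N),
                       oracle_hyper_tail(k, b, K, N), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d b=%d k=%d", N, K, b, k))
        }
      }
    }
  }
})

make_binned_table <- function(n, seed = 1, bin_size = 10) {
  pt <- toy_table(n, seed = seed)
  rank_and_bin(pt, bin_size = bin_size)
}

test_that("enrichment profiles concentrate signal where annotations concentrate", {
  bins <- make_binned_table(20, bin_size = 10)  # 2 bins of 10
  top <- bins$accession[bins$bin == 0]
  map <- annotation_map(go = setNames(rep(list("GO:0005886"), 10), top))
  prof <- enrichment_profile(bins, map, "GO:0005886")
  expect_s3_class(prof, "bin_enrichment_profile")
  p0 <- prof$neg_log10_p[prof$bin == 0]
  p1 <- prof$neg_log10_p[prof$bin == 1]
  expect_gt(p0, p1)
  expect_equal(p1, 0)              # k = 0 -> p = 1
  expect_equal(sum(prof$k), 10L)   # conservation: bin counts sum to K
  expect_equal(unique(prof$K), 10L)
  expect_true(all(prof$p > 0 & prof$p <= 1))
})

test_that("minimum-membership and Bonferroni rules apply per bin", {
  bins <- make_binned_table(20, bin_size = 10)
  one <- bins$accession[1]
  map <- annotation_map(go = setNames(list(c("GO:0000001")), one))
  prof <- enrichment_profile(bins, map, "GO:0000001")
  expect_equal(prof$p[prof$bin == 0], 1)  # k = 1 < min_members = 2
  prof2 <- enrichment_profile(bins, map, "GO:0000001", min_members = 1)
  expect_lt(prof2$p[prof2$bin == 0], 1)
  # bonferroni multiplies by the number of terms, capped at one
  top <- bins$accession[bins$bin == 0]
  map2 <- annotation_map(go = setNames(rep(list(c("GO:0005886", "GO:0005829")),
                                           10), top))
  raw <- enrichment_profile(bins, map2, c("GO:0005886", "GO:0005829"))
  adj <- enrichment_profile(bins, map2, c("GO:0005886", "GO:0005829"),
                            adjust = "bonferroni")
  expect_equal(adj$p, pmin(raw$p * 2, 1))
  # term absent from the universe: K = 0, p = 1, warning
  expect_warning(absent <- enrichment_profile(bins, map2, "GO:9999999"),
                 "absent")
  expect_true(all(absent$p == 1))
})

test_that("profiles are invariant to row order and intensity rescaling", {
  pt <- toy_table(60, seed = 3)
  map <- annotation_map(go = setNames(rep(list("GO:0005886"), 20),
                                      pt$accession[1:20]))
  prof <- function(x) enrichment_profile(rank_and_bin(x, 15), map, "GO:0005886")
  ref <- prof(pt)
  shuffled <- pt[sample(nrow(pt)), ]
  attr(shuffled, "experiments") <- experiments(pt)
  class(shuffled) <- class(pt)
  expect_equal(prof(shuffled), ref)
  scaled <- pt
  for (e in experiments(pt)) {
    scaled[[paste0("mq:", e)]] <- scaled[[paste0("mq:", e)]] * 7.5
    scaled[[paste0("lfq:", e)]] <- scaled[[paste0("lfq:", e)]] * 7.5
  }
  got <- prof(scaled)
  got$statistic <- NULL; ref2 <- ref; ref2$statistic <- NULL
  expect_equal(got, ref2)
})

test_that("profile comparison aligns bins and flags planted enrichment", {
  pt <- toy_table(40, seed = 5)
  bins <- rank_and_bin(pt, 10)
  surface <- bins$accession[bins$bin %in% c(0, 1)]
  enriched_map <- annotation_map(go = setNames(rep(list("GO:0005886"), 20),
                                               surface))
  scattered <- annotation_map(go = setNames(rep(list("GO:0005886"), 20),
                                            bins$accession[seq(1, 40, 2)]))
  pe <- enrichment_profile(bins, enriched_map, "GO:0005886")
  pt2 <- enrichment_profile(bins, scattered, "GO:0005886")
  cmp <- compare_profiles(pe, pt2)
  expect_equal(names(cmp), c("bin", "term", "neg_log10_p_enriched",
                             "neg_log10_p_total", "delta"))
  expect_true(all(cmp$delta[cmp$bin <= 1] > 0))
  # identity comparison: all deltas zero
  self <- compare_profiles(pe, pe)
  expect_true(all(self$delta == 0))
  # mismatched binning is an error
  pe5 <- enrichment_profile(rank_and_bin(pt, 8), enriched_map, "GO:0005886")
  expect_error(compare_profiles(pe, pe5), "bin")
})
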