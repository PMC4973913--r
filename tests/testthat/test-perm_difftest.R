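make_lfq_table <- function(lfq, groups) {
  n <- nrow(lfq)
  protein_table(accession = sprintf("P%03d", seq_len(n)),
                length = rep(300L, n), pn = rep(2L, n), sc = rep(5L, n),
                mq = lfq, lfq = lfq)
}

std_groups <- function(n1 = 3, n2 = 3)
  setNames(rep(c("g1", "g2"), c(n1, n2)),
           c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2))))

test_that("preprocessing applies the min-valid detection rule", {
  g <- std_groups()
  lfq <- rbind(
    c(2^20, 2^20, 2^20, 0, 0, 0),        # full in group1 only -> retained
    c(2^20, 2^20, 0, 2^20, 2^20, 0),     # 2/3 in both -> dropped at min_valid 3
    c(2^20, 2^20, 2^20, 2^20, 2^20, 2^20))
  colnames(lfq) <- names(g)
  gm <- preprocess(make_lfq_table(lfq), g)
  expect_equal(nrow(gm$values), 2L)
  expect_equal(unname(gm$log["n_underobserved_removed"]), 1L)
  expect_true(all(is.na(gm$values[1, 4:6])))           # zeros became missing
  expect_equal(unname(gm$values[1, 1]), 20)            # log2 applied
  # flagged rows are removed before anything else
  tab <- make_lfq_table(lfq)
  tab$flags[3] <- "contaminant"
  gm2 <- preprocess(tab, g)
  expect_equal(nrow(gm2$values), 1L)
  expect_error(preprocess(make_lfq_table(lfq), c(zz = "g1", std_groups()[-1])),
               "zz")
})

test_that("imputation draws from the down-shifted column distribution", {
  g <- std_groups(2, 2)
  set.seed(30)
  lfq <- matrix(2^rnorm(4000, 30, 1), 1000, 4, dimnames = list(NULL, names(g)))
  gm <- preprocess(make_lfq_table(lfq), g, min_valid = 2)
  complete <- impute_missing(gm, seed = 1)
  expect_equal(complete$values, gm$values)  # nothing missing -> identity
  # plant missingness in one column with known stats
  gm$values[1:400, 1] <- NA
  mu <- mean(gm$values[, 1], na.rm = TRUE)
  sdev <- sd(gm$values[, 1], na.rm = TRUE)
  i1 <- impute_missing(gm, seed = 7)
  i2 <- impute_missing(gm, seed = 7)
  expect_identical(i1$values, i2$values)    # seeded determinism
  expect_false(any(is.na(i1$values)))
  expect_equal(i1$values[-(1:400), ], gm$values[-(1:400), ])  # observed untouched
  imputed <- i1$values[1:400, 1]
  expect_equal(mean(imputed), mu - 1.8 * sdev, tolerance = 0.05)
  expect_equal(sd(imputed), 0.3 * sdev, tolerance = 0.1)
  # column with < 2 observed values is an error
  gm$values[, 2] <- NA
  gm$values[1, 2] <- 25
  expect_error(impute_missing(gm, seed = 1), "fewer than 2")
})

test_that("imputed draws match the Monte-Carlo expectation at known stats", {
  g <- std_groups(2, 2)
  vals <- rep(c(28, 32), 50)  # mean 30, sd just over 2
  lfq <- matrix(2^vals, 100, 4, dimnames = list(NULL, names(g)))
  gm <- preprocess(make_lfq_table(lfq), g, min_valid = 2)
  sdev <- sd(gm$values[, 1])
  big <- do.call(rbind, lapply(1:100, function(s) {
    gmi <- gm; gmi$values[1:50, 1] <- NA
    impute_missing(gmi, seed = s)$values[1:50, 1]
  }))
  sdev <- sd(gm$values[51:100, 1])
  expect_equal(mean(big), 30 - 1.8 * sdev, tolerance = 0.05)
})

test_that("with s0 = 0 the modified statistic is the classical pooled t", {
  g <- std_groups(3, 4)
  set.seed(31)
  lfq <- matrix(2^rnorm(70 * 7, 28, 2), 70, 7, dimnames = list(NULL, names(g)))
  gm <- preprocess(make_lfq_table(lfq), g, min_valid = 3)
  res <- sam_test(gm, s0 = 0, fdr = 0.01)
  tref <- apply(gm$values, 1, function(v)
    t.test(v[1:3], v[4:7], var.equal = TRUE)$statistic)
  expect_equal(res$table$d, unname(tref), tolerance = 1e-10)
})

test_that("group relabeling symmetry and location invariance hold", {
  g <- std_groups()
  set.seed(32)
  lfq <- matrix(2^rnorm(50 * 6, 28, 2), 50, 6, dimnames = list(NULL, names(g)))
  gm <- preprocess(make_lfq_table(lfq), g)
  a <- sam_test(gm, s0 = 0.2, fdr = 0.05)
  swapped <- setNames(ifelse(g == "g1", "g2", "g1"), names(g))
  b <- sam_test(preprocess(make_lfq_table(lfq), swapped), s0 = 0.2, fdr = 0.05)
  expect_equal(b$table$d, -a$table$d)
  expect_equal(b$table$significant, a$table$significant)
  # side labels swap with the groups
  expect_equal(b$table$side, ifelse(a$table$side == "g1", "g2", "g1"))
  shift <- gm; shift$values <- gm$values + 3.7
  cshift <- sam_test(shift, s0 = 0.2, fdr = 0.05)
  expect_equal(cshift$table$d, a$table$d)
})

test_that("identical groups and degenerate designs are handled", {
  g <- std_groups()
  lfq <- matrix(2^28, 20, 6, dimnames = list(NULL, names(g)))
  gm <- preprocess(make_lfq_table(lfq), g)
  res <- sam_test(gm, s0 = 0.2, fdr = 0.05)
  expect_equal(sum(res$table$significant), 0L)
  expect_true(all(res$table$d == 0))
  gm$values <- gm$values[, 1:3, drop = FALSE]
  gm$groups <- gm$groups[1:3]
  expect_error(sam_test(gm), "2 samples per group")
})

test_that("significant calls are exactly the points beyond the threshold curve", {
  g <- std_groups(4, 4)
  set.seed(33)
  lfq <- matrix(2^rnorm(300 * 8, 27, 0.4), 300, 8,
                dimnames = list(NULL, names(g)))
  lfq[1:20, 1:4] <- lfq[1:20, 1:4] * 8  # strong 3-fold-plus changes
  gm <- preprocess(make_lfq_table(lfq), g, min_valid = 3)
  res <- sam_test(gm, s0 = 0.5, fdr = 0.01)
  expect_true(is.finite(res$cutoff))
  expect_gte(sum(res$table$significant[1:20]), 15)
  # curve is symmetric about difference 0
  expect_equal(sort(res$curve$difference), sort(-res$curve$difference))
  # |d| >= cutoff is equivalent to |diff| >= cutoff * (s0 + se)
  with(res$table, expect_equal(significant, abs(d) >= res$cutoff))
  # q-values are monotone non-increasing in |d| and match the cutoff rule
  o <- order(abs(res$table$d))
  expect_true(all(diff(res$table$q[o]) <= 1e-12))
  expect_equal(res$table$significant, res$table$q <= 0.01)
})

test_that("the end-to-end run reports provenance and honours seeds", {
  g <- std_groups(3, 3)
  set.seed(34)
  lfq <- matrix(2^rnorm(80 * 6, 25, 1), 80, 6, dimnames = list(NULL, names(g)))
  lfq[sample(length(lfq), 60)] <- 0
  tab <- make_lfq_table(lfq)
  tab$flags[1] <- "reverse"
  r1 <- run_differential(tab, g, seed = 9)
  r2 <- run_differential(tab, g, seed = 9)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$report$counts$n_input, 80L)
  expect_equal(r1$report$counts$n_flagged_removed, 1L)
  expect_equal(r1$report$counts$n_retained, nrow(r1$table))
  expect_equal(r1$report$seed, 9)
  paths <- write_diff_result(r1, tempfile(), tempfile())
  expect_true(all(file.exists(paths)))
})
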