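#' Preprocess a protein table for differential testing
#'
#' Reproduces the standard label-free preprocessing chain: remove
#' categorically flagged rows ([filter_categorical()]), treat LFQ
#' intensities of 0 as missing, log2-transform, assign samples to two
#' groups, and drop proteins without at least `min_valid` detected values in
#' at least one group ("not detected in all replicates of at least one
#' group"). `min_valid` defaults to the size of the smaller group, i.e. full
#' detection in one group; the four-replicate benchmark designs use
#' `min_valid = 3`.
#'
#' @param x a [protein_table].
#' @param groups named character vector mapping experiment labels to two
#'   group labels, e.g. `c(a1 = "sample", a2 = "sample", b1 = "control", ...)`.
#' @param min_valid minimal number of detected values required in at least
#'   one group; `NULL` for the smaller group size.
#' @return A `grouped_matrix`: list with `values` (proteins x samples log2
#'   matrix, `NA` = missing), `groups` (factor per column), and `log`
#'   (per-stage row counts).
#' @export
preprocess <- function(x, groups, min_valid = NULL) {
  stopifnot(inherits(x, "protein_table"))
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  missing_samples <- setdiff(names(groups), experiments(x))
  if (length(missing_samples))
    stop("sample(s) absent from table: ", paste(missing_samples, collapse = ", "))
  grp <- factor(groups)
  if (nlevels(grp) != 2L) stop("exactly two groups required")
  n_in <- nrow(x)
  x <- suppressMessages(filter_categorical(x))
  n_flagged <- attr(x, "n_removed")
  m <- lfq_matrix(x)[, names(groups), drop = FALSE]
  m[m == 0] <- NA
  m <- log2(m)
  if (is.null(min_valid)) min_valid <- min(table(grp))
  valid_by_group <- sapply(levels(grp), function(g)
    rowSums(!is.na(m[, grp == g, drop = FALSE])))
  keep <- apply(valid_by_group >= min_valid, 1L, any)
  structure(list(values = m[keep, , drop = FALSE],
                 groups = stats::setNames(grp, names(groups)),
                 log = c(n_input = n_in, n_flagged_removed = n_flagged,
                         n_underobserved_removed = sum(!keep),
                         n_retained = sum(keep)),
                 min_valid = min_valid),
            class = "grouped_matrix")
}

#' @export
print.grouped_matrix <- function(x, ...) {
  cat(sprintf("grouped_matrix: %d proteins x %d samples (%s); %d missing cells\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", levels(x$groups), table(x$groups)),
                    collapse = ", "),
              sum(is.na(x$values))))
  invisible(x)
}

#' Left-censored normal imputation of missing values
#'
#' Replaces each missing cell by a draw from a normal distribution shifted
#' below the observed intensity distribution of its sample column:
#' `Normal(mean_s - down_shift * sd_s, (width * sd_s)^2)`, where `mean_s`
#' and `sd_s` are computed over the observed values of column `s`. This
#' emulates the fact that values are predominantly missing because the
#' protein sits near or below the detection limit. Observed cells are never
#' touched; given a seed the result is reproducible bit for bit.
#'
#' @param gm a `grouped_matrix` from [preprocess()].
#' @param width imputation SD as a fraction of the column SD (default 0.3).
#' @param down_shift centre shift in column SDs (default 1.8).
#' @param seed optional integer seed.
#' @return The `grouped_matrix` with a complete `values` matrix.
#' @export
impute_missing <- function(gm, width = 0.3, down_shift = 1.8, seed = NULL) {
  stopifnot(inherits(gm, "grouped_matrix"), width > 0)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  m <- gm$values
  for (j in seq_len(ncol(m))) {
    obs <- m[, j][!is.na(m[, j])]
    nmiss <- sum(is.na(m[, j]))
    if (nmiss == 0L) next
    if (length(obs) < 2L)
      stop("column ", colnames(m)[j],
           " has fewer than 2 observed values; SD undefined")
    mu <- mean(obs); sdev <- stats::sd(obs)
    m[is.na(m[, j]), j] <- stats::rnorm(nmiss, mu - down_shift * sdev,
                                        width * sdev)
  }
  gm$values <- m
  gm$imputation <- c(width = width, down_shift = down_shift,
                     seed = if (is.null(seed)) NA_integer_ else seed)
  gm
}

# modified t statistic: d = (mean1 - mean2) / (pooled SE + s0)
.sam_d <- function(m, g1, s0) {
  n1 <- sum(g1); n2 <- sum(!g1)
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  se <- sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  list(d = (m1 - m2) / (se + s0), diff = m1 - m2, se = se)
}

# all group-1 column index sets, distinct up to group swap, identity first
.relabelings <- function(n, n1, n_permutations, seed = NULL) {
  total <- choose(n, n1)
  if (total <= 1000) {
    combos <- utils::combn(n, n1)
    if (n1 * 2L == n) combos <- combos[, combos[1L, ] == 1L, drop = FALSE]
    id <- which(apply(combos, 2L, function(cc) all(cc == seq_len(n1))))
    combos[, c(id, setdiff(seq_len(ncol(combos)), id)), drop = FALSE]
  } else {
    if (!is.null(seed)) set.seed(seed)
    out <- matrix(0L, n1, n_permutations + 1L)
    out[, 1L] <- seq_len(n1)
    for (j in seq_len(n_permutations) + 1L)
      out[, j] <- sort(sample.int(n, n1))
    out
  }
}

#' Permutation-based moderated t-test (SAM-style) with slope s0
#'
#' Computes per protein the modified statistic
#' `d = (mean1 - mean2) / (se + s0)` (pooled two-sample standard error plus
#' the slope constant `s0`, which damps significance of low-variance
#' proteins) and calls proteins significant beyond a cutoff `c*` chosen by
#' permutation of the group labels: `c*` is the smallest observed `|d|`
#' whose estimated false discovery rate
#' `((1 + total permuted count of |d| >= c) / (n_perm + 1)) / (observed
#' count of |d| >= c)` does not exceed `fdr`. The add-one pooled estimator
#' is used because with small replicate numbers only a handful of distinct
#' relabelings exist and the estimate must stay conservative at the extreme
#' tail. All distinct relabelings (up to group swap, excluding the observed
#' labeling) are enumerated when there are at most 1000; otherwise
#' `n_permutations` random relabelings are drawn.
#'
#' The significance boundary is also exported as a volcano threshold curve
#' in (log2 difference, -log10 p) coordinates: the set of points where
#' `|diff| = c* * (s0 + |diff|/t)`, with `t` the classical t statistic
#' corresponding to the p-value at `n1 + n2 - 2` degrees of freedom.
#'
#' @param gm a complete `grouped_matrix` (after [impute_missing()]).
#' @param s0 slope constant added to the standard error (default 0.2).
#' @param fdr target false discovery rate (default 0.01).
#' @param n_permutations random relabelings when full enumeration is not
#'   feasible (default 250).
#' @param seed optional integer seed (used only when sampling relabelings).
#' @return A `diff_result`: list with `table` (`data.frame`: `accession`,
#'   `diff` = group1 - group2 log2 difference, `d`, `p_t` (classical
#'   two-sided t p-value, for volcano plotting), `q`, `significant`,
#'   `side`), `cutoff`, `curve` (`data.frame` of `difference`,
#'   `neg_log10_p`), and `params`.
#' @export
sam_test <- function(gm, s0 = 0.2, fdr = 0.01, n_permutations = 250,
                     seed = NULL) {
  stopifnot(inherits(gm, "grouped_matrix"))
  m <- gm$values
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  grp <- gm$groups
  lv <- levels(grp)
  ord <- order(grp != lv[1L])          # group-1 columns first
  m <- m[, ord, drop = FALSE]
  grp <- grp[ord]
  n1 <- sum(grp == lv[1L]); n <- length(grp)
  if (n1 < 2L || n - n1 < 2L) stop("need at least 2 samples per group")
  obs <- .sam_d(m, grp == lv[1L], s0)
  relab <- .relabelings(n, n1, n_permutations, seed)
  perm <- relab[, -1L, drop = FALSE]
  if (ncol(perm) == 0L) stop("no non-trivial relabelings possible")
  n_perm <- ncol(perm)
  dperm <- matrix(abs(apply(perm, 2L, function(cc) {
    g <- rep(FALSE, n); g[cc] <- TRUE
    .sam_d(m, g, s0)$d
  })), nrow = nrow(m))
  dobs <- abs(obs$d)
  cand <- sort(unique(dobs))
  sorted_obs <- sort(dobs)
  r_obs <- length(dobs) - findInterval(cand - 1e-12, sorted_obs)
  all_perm <- sort(as.vector(dperm))
  tot_perm <- length(all_perm) - findInterval(cand - 1e-12, all_perm)
  est <- pmin(((tot_perm + 1) / (n_perm + 1)) / r_obs, 1)
  # q per protein: smallest estimated FDR over cutoffs that include it
  q_cand <- cummin(est)
  q <- q_cand[match(dobs, cand)]
  ok <- which(est <= fdr)
  cutoff <- if (length(ok)) cand[min(ok)] else Inf
  sig <- dobs >= cutoff
  df <- n - 2L
  p_t <- 2 * stats::pt(-abs(obs$diff / pmax(obs$se, .Machine$double.eps)), df)
  tab <- data.frame(accession = rownames(m), diff = obs$diff, d = obs$d,
                    p_t = p_t, q = q, significant = sig,
                    side = ifelse(obs$diff > 0, lv[1L], lv[2L]),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, cutoff = cutoff,
                 curve = .threshold_curve(cutoff, s0, df),
                 params = list(s0 = s0, fdr = fdr, df = df,
                               n_relabelings = n_perm,
                               groups = stats::setNames(as.character(grp),
                                                        colnames(m)),
                               seed = seed)),
            class = "diff_result")
}

# volcano significance boundary for cutoff c*: |x| = c*(s0 + |x|/t(p)),
# i.e. |x| = c* s0 t / (t - c*) for t > c*; symmetric about x = 0.
.threshold_curve <- function(cutoff, s0, df, n_points = 200) {
  if (!is.finite(cutoff))
    return(data.frame(difference = numeric(0), neg_log10_p = numeric(0)))
  tt <- cutoff * (1 + exp(seq(log(1e-3), log(1e3), length.out = n_points)))
  p <- 2 * stats::pt(-tt, df)
  x <- if (s0 > 0) cutoff * s0 * tt / (tt - cutoff) else rep(0, length(tt))
  up <- data.frame(difference = x, neg_log10_p = -log10(p))
  rbind(stats::setNames(data.frame(-rev(up$difference), rev(up$neg_log10_p)),
                        names(up)), up)
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf(
    "diff_result: %d proteins tested, %d significant (fdr %.3g, s0 %.2g, cutoff |d| >= %.3g)\n",
    nrow(x$table), sum(x$table$significant), x$params$fdr, x$params$s0,
    x$cutoff))
  invisible(x)
}

#' End-to-end differential analysis
#'
#' Runs [preprocess()], [impute_missing()] and [sam_test()] in sequence and
#' collects a machine-readable provenance report (row counts per stage,
#' parameters, seeds).
#'
#' @param x a [protein_table].
#' @param groups named character vector mapping experiment labels to two
#'   group labels (see [preprocess()]).
#' @param min_valid see [preprocess()].
#' @param width,down_shift see [impute_missing()].
#' @param s0,fdr,n_permutations see [sam_test()].
#' @param seed integer seed driving imputation and (if sampled) the
#'   permutations.
#' @return A `diff_result` (see [sam_test()]) with an additional `report`
#'   element.
#' @export
run_differential <- function(x, groups, min_valid = NULL,
                             width = 0.3, down_shift = 1.8,
                             s0 = 0.2, fdr = 0.01, n_permutations = 250,
                             seed = NULL) {
  gm <- preprocess(x, groups, min_valid)
  gm <- impute_missing(gm, width = width, down_shift = down_shift, seed = seed)
  res <- sam_test(gm, s0 = s0, fdr = fdr, n_permutations = n_permutations,
                  seed = if (is.null(seed)) NULL else seed + 1L)
  res$report <- list(
    counts = as.list(c(gm$log, n_significant = sum(res$table$significant))),
    min_valid = gm$min_valid,
    imputation = list(width = width, down_shift = down_shift),
    test = list(s0 = s0, fdr = fdr, n_permutations = n_permutations,
                n_relabelings = res$params$n_relabelings),
    seed = seed)
  res
}

#' Write differential-test artifacts
#'
#' Exports the per-protein result table and the volcano threshold-curve
#' table as TSV.
#'
#' @param res a `diff_result`.
#' @param table_path,curve_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_diff_result <- function(res, table_path = NULL, curve_path = NULL) {
  stopifnot(inherits(res, "diff_result"))
  if (!is.null(table_path))
    utils::write.table(res$table, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(curve_path))
    utils::write.table(res$curve, curve_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(table_path, curve_path))
}
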