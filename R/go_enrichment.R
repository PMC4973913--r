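#' Hypergeometric enrichment test for one intensity bin
#'
#' One-sided upper-tail probability `P(X >= k)` with
#' `X ~ Hypergeom(N, K, bin_size)`: the probability that at least `k` of the
#' `bin_size` proteins drawn from a universe of `N` proteins, `K` of which
#' carry the term, carry the term by chance. This is the per-bin Fisher's
#' exact test used by [enrichment_profile()].
#'
#' @param k annotated proteins observed in the bin.
#' @param bin_size proteins in the bin.
#' @param K annotated proteins in the universe.
#' @param N proteins in the universe.
#' @return Probability in (0, 1]. All arguments recycle.
#' @examples
#' bin_term_test(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
bin_term_test <- function(k, bin_size, K, N) {
  if (any(k < 0 | bin_size < 0 | K < 0 | N < 0)) stop("counts must be >= 0")
  if (any(bin_size > N) || any(K > N)) stop("bin_size and K must be <= N")
  if (any(k > bin_size) || any(k > K)) stop("k must be <= min(bin_size, K)")
  stats::phyper(k - 1, K, N - K, bin_size, lower.tail = FALSE)
}

#' Per-bin GO enrichment profile
#'
#' For every intensity bin (from [rank_and_bin()]) and every term, counts
#' the bin members annotated with the term and computes the one-sided
#' hypergeometric p-value against the chosen universe. The default universe
#' is the set of identified proteins of the same sample: without prior
#' knowledge of true protein abundances a whole-database universe would
#' assume a uniform abundance distribution, which enrichment of the sample
#' itself already violates; comparing two per-sample profiles
#' ([compare_profiles()]) is the intended remedy.
#'
#' Terms observed fewer than `min_members` times in a bin (default 2) are
#' reported with p = 1. With `adjust = "bonferroni"` each p-value is
#' multiplied by the number of terms tested per bin (capped at 1).
#'
#' @param bins an `intensity_bins` table from [rank_and_bin()].
#' @param annotations an [annotation_map].
#' @param terms character vector of GO identifiers and/or feature symbols
#'   (see [term_members()]).
#' @param universe `"identified"` (default) or `"custom"` (then give `N`
#'   and named `K`).
#' @param N,K custom universe size and per-term annotated counts (named by
#'   term), used when `universe = "custom"`.
#' @param min_members minimal gene products per bin for a term to be tested.
#' @param adjust `"none"` or `"bonferroni"` (across terms within each bin).
#' @return `data.frame` (class `bin_enrichment_profile`) with columns
#'   `bin`, `term`, `k`, `bin_size`, `K`, `N`, `p`, `neg_log10_p`.
#' @export
enrichment_profile <- function(bins, annotations, terms,
                               universe = c("identified", "custom"),
                               N = NULL, K = NULL, min_members = 2,
                               adjust = c("none", "bonferroni")) {
  universe <- match.arg(universe)
  adjust <- match.arg(adjust)
  stopifnot(inherits(bins, "intensity_bins"), length(terms) > 0)
  accs <- bins$accession
  members <- lapply(terms, function(tm)
    intersect(term_members(annotations, tm), accs))
  names(members) <- terms
  if (universe == "identified") {
    N <- length(accs)
    K <- vapply(members, length, integer(1))
  } else {
    if (is.null(N) || is.null(K)) stop("custom universe needs 'N' and 'K'")
    K <- K[terms]
    if (anyNA(K)) stop("'K' must be named by term")
  }
  zero <- names(K)[K == 0]
  if (length(zero))
    warning("term(s) absent from universe: ", paste(zero, collapse = ", "))
  bin_ids <- sort(unique(bins$bin))
  grid <- expand.grid(bin = bin_ids, term = terms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bin_sizes <- as.vector(table(factor(bins$bin, levels = bin_ids)))
  grid$bin_size <- bin_sizes[match(grid$bin, bin_ids)]
  grid$k <- mapply(function(b, tm)
    sum(accs[bins$bin == b] %in% members[[tm]]), grid$bin, grid$term)
  grid$K <- as.integer(K[grid$term])
  grid$N <- N
  p <- ifelse(grid$K == 0, 1,
              bin_term_test(pmin(grid$k, grid$K), grid$bin_size,
                            pmax(grid$K, 1L), grid$N))
  p[grid$k < min_members] <- 1
  if (adjust == "bonferroni") p <- pmin(p * length(terms), 1)
  grid$p <- p
  grid$neg_log10_p <- -log10(p)
  grid <- grid[order(grid$term, grid$bin),
               c("bin", "term", "k", "bin_size", "K", "N", "p", "neg_log10_p")]
  rownames(grid) <- NULL
  structure(grid, bin_size = attr(bins, "bin_size"),
            universe = universe, adjust = adjust,
            class = c("bin_enrichment_profile", "data.frame"))
}

#' Compare enrichment profiles of two samples
#'
#' Aligns the per-bin -log10(p) profiles of a (e.g. surface-enriched)
#' sample and a total-proteome sample by bin index and term, and reports
#' their difference (`delta = enriched - total`). This two-sample form makes
#' enrichment claims independent of the unknown abundance distribution of
#' the annotation universe: a term genuinely enriched by the preparation
#' shows positive deltas in the high-intensity bins.
#'
#' @param enriched,total `bin_enrichment_profile` objects built with the
#'   same `bin_size`, the same number of bins and the same term list.
#' @return `data.frame` with columns `bin`, `term`, `neg_log10_p_enriched`,
#'   `neg_log10_p_total`, `delta`.
#' @export
compare_profiles <- function(enriched, total) {
  stopifnot(inherits(enriched, "bin_enrichment_profile"),
            inherits(total, "bin_enrichment_profile"))
  if (!identical(attr(enriched, "bin_size"), attr(total, "bin_size")))
    stop("profiles built with different bin sizes")
  if (!setequal(unique(enriched$term), unique(total$term)))
    stop("profiles test different term lists")
  if (length(unique(enriched$bin)) != length(unique(total$bin)))
    stop("profiles have different numbers of bins (",
         length(unique(enriched$bin)), " vs ", length(unique(total$bin)), ")")
  a <- enriched[, c("bin", "term", "neg_log10_p")]
  b <- total[, c("bin", "term", "neg_log10_p")]
  names(a)[3] <- "neg_log10_p_enriched"
  names(b)[3] <- "neg_log10_p_total"
  out <- merge(a, b, by = c("bin", "term"), all = TRUE)
  out$delta <- out$neg_log10_p_enriched - out$neg_log10_p_total
  out <- out[order(out$term, out$bin), ]
  rownames(out) <- NULL
  out
}
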