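#' Exponentially modified protein abundance index (emPAI)
#'
#' Computes `10^(pn/po)` from the number of identified peptides (`pn`) and
#' the number of theoretically observable tryptic peptides (`po`, see
#' [count_observable()]). The default follows the form used throughout this
#' package; `classical = TRUE` subtracts 1 (the original definition of the
#' index, `10^(pn/po) - 1`).
#'
#' @param pn non-negative integer vector, identified peptides per protein.
#' @param po positive integer vector, observable peptides per protein.
#' @param classical subtract 1 from the power term?
#' @return Numeric vector. Strictly increasing in `pn` for fixed `po`.
#' @examples
#' compute_empai(5, 20)   # 10^0.25
#' @export
compute_empai <- function(pn, po, classical = FALSE) {
  if (any(!is.finite(po)) || any(po < 1)) stop("'po' must be >= 1")
  if (any(pn < 0)) stop("'pn' must be non-negative")
  if (any(pn > po))
    warning("pn > po for ", sum(pn > po),
            " protein(s); the observability model may undercount")
  10^(pn / po) - if (classical) 1 else 0
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Length-normalized spectral counts rescaled to sum to one over the table:
#' `nsaf_p = (sc_p/L_p) / sum_i(sc_i/L_i)`.
#'
#' @param x a [protein_table], or a numeric vector of spectral counts.
#' @param length protein lengths (ignored when `x` is a `protein_table`).
#' @return Named numeric vector summing to 1.
#' @export
compute_nsaf <- function(x, length = NULL) {
  if (inherits(x, "protein_table")) {
    sc <- x$sc; len <- x$length; nm <- x$accession
  } else {
    sc <- x; len <- length; nm <- names(x)
  }
  if (any(len < 1)) stop("'length' must be >= 1")
  saf <- sc / len
  tot <- sum(saf)
  if (tot == 0) stop("all spectral counts are zero; NSAF undefined")
  stats::setNames(saf / tot, nm)
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' Raw intensity divided by the number of observable tryptic peptides,
#' log-transformed (base 10 by default, following the absolute-quantification
#' literature). A raw intensity of 0 means "not detected" and yields `NA`.
#'
#' @param mq non-negative numeric vector of raw intensities.
#' @param po positive integer vector of observable peptides.
#' @param log_base 10 or 2.
#' @return Numeric vector, `NA` where not detected.
#' @examples
#' compute_ibaq(1000, 10)  # log10(100) = 2
#' @export
compute_ibaq <- function(mq, po, log_base = 10) {
  if (any(!is.finite(po)) || any(po < 1)) stop("'po' must be >= 1")
  if (any(mq < 0, na.rm = TRUE)) stop("'mq' must be non-negative")
  log_base <- match.arg(as.character(log_base), c("10", "2"))
  out <- log(mq / po, base = as.numeric(log_base))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Abundance classes on the log2 LFQ scale
#'
#' Maps mean log2 LFQ intensities to the five abundance classes
#' `-` (below 18, or not detected), `+` (18 to 23), `++` (23 to 28),
#' `+++` (28 to 33) and `++++` (33 and above). Intervals are lower-closed
#' (`[18,23)` etc.), so a value of exactly 33 is `++++`.
#'
#' @param mean_log2_lfq numeric vector; `NA` marks "not detected".
#' @param thresholds four strictly increasing cut points (default
#'   `c(18, 23, 28, 33)`).
#' @return Ordered factor with levels `-`, `+`, `++`, `+++`, `++++`.
#' @export
assign_abundance_class <- function(mean_log2_lfq,
                                   thresholds = c(18, 23, 28, 33)) {
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be four strictly increasing cut points")
  lev <- c("-", "+", "++", "+++", "++++")
  idx <- findInterval(mean_log2_lfq, thresholds) + 1L
  idx[is.na(mean_log2_lfq)] <- 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Mean LFQ intensity on the log2 scale
#'
#' Averages the raw LFQ intensities of the given experiments (zeros
#' included) and returns log2 of the mean; proteins with no detection in any
#' experiment yield `NA`. Set `method = "mean_of_log2"` to instead average
#' log2 intensities over the detected replicates.
#'
#' @param x a [protein_table].
#' @param which experiment labels (default: all).
#' @param method `"log2_of_mean"` (default) or `"mean_of_log2"`.
#' @return Named numeric vector.
#' @export
mean_log2_lfq <- function(x, which = experiments(x),
                          method = c("log2_of_mean", "mean_of_log2")) {
  method <- match.arg(method)
  m <- lfq_matrix(x)[, which, drop = FALSE]
  if (method == "log2_of_mean") {
    v <- log2(rowMeans(m))
    v[!is.finite(v)] <- NA_real_
  } else {
    lm2 <- log2(m)
    lm2[!is.finite(lm2)] <- NA
    v <- rowMeans(lm2, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
  }
  stats::setNames(v, x$accession)
}

#' Rank proteins by intensity and partition them into bins
#'
#' Sorts proteins by decreasing ranking statistic (summed raw intensity over
#' all experiments by default, as in intensity-sorted proteinGroups output)
#' and cuts the ranking into consecutive bins of `bin_size` proteins; the
#' last bin may be smaller. Ties are broken by accession so the binning is
#' deterministic and invariant to input row order.
#'
#' @param x a [protein_table].
#' @param bin_size proteins per bin (default 50).
#' @param statistic `"sum_intensity"` or `"mean_lfq"`.
#' @return `data.frame` (class `intensity_bins`) with columns `accession`,
#'   `statistic`, `rank` and 0-based `bin`; `bin_size` is kept as an
#'   attribute.
#' @export
rank_and_bin <- function(x, bin_size = 50,
                         statistic = c("sum_intensity", "mean_lfq")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(x, "protein_table"), nrow(x) > 0, bin_size >= 1)
  stat <- switch(statistic,
                 sum_intensity = rowSums(mq_matrix(x)),
                 mean_lfq = rowMeans(lfq_matrix(x)))
  ord <- order(-stat, x$accession)
  out <- data.frame(accession = x$accession[ord], statistic = unname(stat[ord]),
                    rank = seq_along(ord),
                    bin = (seq_along(ord) - 1L) %/% as.integer(bin_size),
                    stringsAsFactors = FALSE)
  structure(out, bin_size = as.integer(bin_size), ranking = statistic,
            class = c("intensity_bins", "data.frame"))
}
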