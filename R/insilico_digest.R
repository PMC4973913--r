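#' Kyte-Doolittle hydropathy values
#' @noRd
.kd <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Mean hydropathy (GRAVY) of peptides
#'
#' Kyte-Doolittle grand average of hydropathy. Letters outside the 20-letter
#' alphabet contribute 0 but count towards the length.
#'
#' @param peptides character vector of amino-acid strings.
#' @return Numeric vector.
#' @export
gravy <- function(peptides) {
  vapply(strsplit(toupper(peptides), ""), function(aa) {
    if (!length(aa)) return(NA_real_)
    v <- .kd[aa]
    v[is.na(v)] <- 0
    mean(v)
  }, numeric(1))
}

#' Charge-state proxy of peptides
#'
#' Crude electrospray charge proxy: 1 (N-terminus) plus the number of basic
#' residues (K, R, H).
#'
#' @param peptides character vector of amino-acid strings.
#' @return Integer vector.
#' @export
peptide_charge <- function(peptides) {
  up <- toupper(peptides)
  1L + nchar(up) - nchar(gsub("[KRH]", "", up))
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R; with `proline_rule = TRUE` (default) a K/R followed
#' by P is not cleaved. Returns every peptide carrying 0 to
#' `max_missed_cleavages` internal missed cleavage sites, with its position.
#' Letters outside the 20-letter alphabet are tolerated and never cleaved.
#'
#' @param sequence a single amino-acid string.
#' @param max_missed_cleavages maximum internal missed cleavages (default 2).
#' @param proline_rule suppress cleavage before proline?
#' @return `data.frame` with columns `peptide`, `start`, `end`, `missed`,
#'   ordered by `start` then `missed`.
#' @examples
#' digest("AAAAAAKCCCCCCR", max_missed_cleavages = 0)$peptide
#' @export
digest <- function(sequence, max_missed_cleavages = 2, proline_rule = TRUE) {
  stopifnot(length(sequence) == 1L, max_missed_cleavages >= 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n]
  if (proline_rule && length(cut)) cut <- cut[aa[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)                    # fragment i = (bounds[i]+1):bounds[i+1]
  nfrag <- length(bounds) - 1L
  res <- vector("list", max_missed_cleavages + 1L)
  for (m in 0:max_missed_cleavages) {
    k <- nfrag - m
    if (k < 1L) break
    i <- seq_len(k)
    res[[m + 1L]] <- data.frame(
      start = bounds[i] + 1L, end = bounds[i + m + 1L],
      missed = m, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$peptide <- substring(sequence, out$start, out$end)
  out <- out[order(out$start, out$missed), c("peptide", "start", "end", "missed")]
  rownames(out) <- NULL
  out
}

#' Observability constraints for tryptic peptides
#'
#' Bundles the filters deciding whether a digest product counts as
#' observable in an LC-MS run: peptide length window (default 6 to 35 amino
#' acids, the MaxQuant preset), missed-cleavage limit, and optional windows
#' on mean hydropathy ([gravy()]), on the charge proxy
#' ([peptide_charge()]) and on predicted retention time. The retention-time
#' filter needs a linear predictor on GRAVY, typically taken from
#' [estimate_rt_limits()].
#'
#' @param min_length,max_length peptide length window (amino acids).
#' @param max_missed_cleavages maximum internal missed cleavages.
#' @param gravy_range optional `c(min, max)` GRAVY window.
#' @param charge_range optional `c(min, max)` charge window.
#' @param rt_range optional `c(min, max)` retention-time window (same units
#'   as the data behind `rt_coef`).
#' @param rt_coef optional `c(intercept, slope)` of the linear
#'   GRAVY-to-retention-time predictor; required when `rt_range` is set.
#' @param proline_rule suppress cleavage before proline?
#' @return An `observability_params` list.
#' @export
observability_params <- function(min_length = 6, max_length = 35,
                                 max_missed_cleavages = 2,
                                 gravy_range = NULL, charge_range = NULL,
                                 rt_range = NULL, rt_coef = NULL,
                                 proline_rule = TRUE) {
  if (min_length > max_length) stop("min_length > max_length")
  if (max_missed_cleavages < 0) stop("max_missed_cleavages must be >= 0")
  if (!is.null(rt_range) && is.null(rt_coef))
    stop("'rt_range' needs 'rt_coef' (see estimate_rt_limits)")
  structure(list(min_length = min_length, max_length = max_length,
                 max_missed_cleavages = max_missed_cleavages,
                 gravy_range = gravy_range, charge_range = charge_range,
                 rt_range = rt_range, rt_coef = rt_coef,
                 proline_rule = proline_rule),
            class = "observability_params")
}

#' Count theoretically observable tryptic peptides (PO)
#'
#' Digests the sequence ([digest()]) and counts the distinct peptide
#' sequences passing every enabled observability filter. Duplicated digest
#' products within one protein are counted once.
#'
#' @param sequence a single amino-acid string.
#' @param params an [observability_params()] bundle.
#' @return Non-negative integer.
#' @examples
#' count_observable("AAAAAAKCCCCCCR")  # 3: both tryptic halves + the mc1 peptide
#' @export
count_observable <- function(sequence, params = observability_params()) {
  stopifnot(inherits(params, "observability_params"))
  peps <- unique(digest(sequence, params$max_missed_cleavages,
                        params$proline_rule)$peptide)
  len <- nchar(peps)
  keep <- len >= params$min_length & len <= params$max_length
  if (!is.null(params$gravy_range)) {
    g <- gravy(peps)
    keep <- keep & g >= params$gravy_range[1] & g <= params$gravy_range[2]
  }
  if (!is.null(params$charge_range)) {
    z <- peptide_charge(peps)
    keep <- keep & z >= params$charge_range[1] & z <= params$charge_range[2]
  }
  if (!is.null(params$rt_range)) {
    rt <- params$rt_coef[1] + params$rt_coef[2] * gravy(peps)
    keep <- keep & rt >= params$rt_range[1] & rt <= params$rt_range[2]
  }
  sum(keep)
}

#' Observable-peptide table from a FASTA file
#'
#' Reads protein sequences (UniProt-style `db|ACCESSION|NAME` headers are
#' parsed to the accession; otherwise the first whitespace-delimited token
#' is used) and computes the observable-peptide count per protein.
#'
#' @param fasta path to a FASTA file, or a `Biostrings::AAStringSet`.
#' @param params an [observability_params()] bundle.
#' @return `data.frame` with columns `accession`, `length`, `po`.
#' @export
po_table <- function(fasta, params = observability_params()) {
  seqs <- if (inherits(fasta, "AAStringSet")) fasta else
    Biostrings::readAAStringSet(fasta)
  nm <- names(seqs)
  acc <- vapply(strsplit(nm, " ", fixed = TRUE), `[[`, "", 1L)
  pipes <- grepl("^[^|]+\\|[^|]+\\|", acc)
  acc[pipes] <- vapply(strsplit(acc[pipes], "|", fixed = TRUE), `[[`, "", 2L)
  data.frame(accession = acc,
             length = Biostrings::width(seqs),
             po = vapply(as.character(seqs), count_observable,
                         integer(1), params = params, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Estimate retention-time limits from observed peptides
#'
#' Fits a linear retention-time model on mean hydropathy (GRAVY) to a table
#' of observed peptides (e.g. a whole-proteome calibration run) and returns
#' the central quantile interval of the fitted values, usable as the
#' `rt_range`/`rt_coef` pair of [observability_params()].
#'
#' @param peptides character vector of observed peptide sequences (>= 10).
#' @param rt observed retention times, same length.
#' @param probs lower/upper quantiles of the fitted values (default
#'   1st and 99th percentile).
#' @return List (class `rt_limits`) with elements `limits` (`c(min, max)`),
#'   `coef` (`c(intercept, slope)`) and `n`.
#' @export
estimate_rt_limits <- function(peptides, rt, probs = c(0.01, 0.99)) {
  if (length(peptides) != length(rt)) stop("lengths differ")
  if (length(rt) < 10L) stop("need at least 10 observations")
  if (stats::sd(rt) == 0) warning("constant retention times; degenerate interval")
  g <- gravy(peptides)
  fit <- stats::lm(rt ~ g)
  pred <- stats::fitted(fit)
  structure(list(limits = unname(stats::quantile(pred, probs)),
                 coef = unname(stats::coef(fit)), n = length(rt)),
            class = "rt_limits")
}

#' @export
print.rt_limits <- function(x, ...) {
  cat(sprintf("rt_limits: [%.3f, %.3f] from %d peptides (rt = %.3f + %.3f * GRAVY)\n",
              x$limits[1], x$limits[2], x$n, x$coef[1], x$coef[2]))
  invisible(x)
}
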