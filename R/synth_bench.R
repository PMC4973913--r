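#' Spike-in benchmark design (UPS1-in-yeast style)
#'
#' Describes a differential benchmark: a large constant background proteome
#' plus a small equimolar spike-in set measured at a series of molar
#' amounts, several replicates per condition. Intensities are generated as
#' `amount x protein response factor x log-normal replicate noise`, and
#' cells are left-censored to 0 by a logistic dropout model on the log2
#' intensity, emulating abundance-dependent missingness near the detection
#' limit.
#'
#' Defaults mirror the classic design: 48 spike proteins at 20, 6.7, 2.2,
#' 0.74 and 0.24 fmol in quadruplicate over ~1500 background proteins. The
#' default response scale puts 1 fmol at roughly 2^23.6 intensity units and
#' the dropout midpoint at 2^22.5, so the 0.24 fmol condition falls mostly
#' below the detection limit while 2.2 fmol and above are essentially fully
#' observed.
#'
#' @param n_background number of background proteins.
#' @param background_log10_mean,background_log10_sd log10-intensity
#'   distribution of the background proteome (decades).
#' @param spike_accessions accessions of the spike-in proteins.
#' @param spike_amounts named numeric vector of molar amounts (fmol); names
#'   are the condition labels.
#' @param replicates replicates per condition.
#' @param noise_cv multiplicative replicate noise, as coefficient of
#'   variation.
#' @param response_log10_mean,response_log10_sd log10 of the per-protein
#'   intensity response per fmol (mean and spread, decades).
#' @param dropout_midpoint,dropout_slope logistic detection model on log2
#'   intensity: `P(observed) = plogis((log2 I - midpoint)/slope)`.
#' @return A `spike_in_design` list.
#' @export
spike_in_design <- function(n_background = 1500,
                            background_log10_mean = 7.4,
                            background_log10_sd = 1.2,
                            spike_accessions = sprintf("UPS%02d", 1:48),
                            spike_amounts = c("20" = 20, "6.7" = 6.7,
                                              "2.2" = 2.2, "0.74" = 0.74,
                                              "0.24" = 0.24),
                            replicates = 4,
                            noise_cv = 0.2,
                            response_log10_mean = 7.1,
                            response_log10_sd = 0.25,
                            dropout_midpoint = 22.5,
                            dropout_slope = 0.5) {
  stopifnot(all(spike_amounts > 0), replicates >= 2, noise_cv >= 0)
  if (is.null(names(spike_amounts)))
    names(spike_amounts) <- as.character(spike_amounts)
  structure(as.list(environment()), class = "spike_in_design")
}

# multiplicative log-normal noise with the given CV, unit mean on log scale
.lnoise <- function(n, cv) exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))

#' Simulate a spike-in benchmark table
#'
#' Generates one [protein_table] covering all conditions of the design
#' (experiment labels `<condition>_r<replicate>`) together with the ground
#' truth: true molar amounts, true fold changes between conditions, the
#' per-protein response factors and the dropout mask. Identical seeds yield
#' identical tables.
#'
#' @param design a [spike_in_design()].
#' @param seed integer seed.
#' @return List with elements `table` (a [protein_table]; `lfq` and `mq`
#'   both carry the simulated intensities) and `truth` (list:
#'   `spike_accessions`, `amounts`, `fold_changes` (condition-pair matrix),
#'   `response`, `background_level`, `dropout_mask`, `po`).
#' @export
simulate_spike_in <- function(design = spike_in_design(), seed = 1) {
  stopifnot(inherits(design, "spike_in_design"))
  set.seed(seed)
  d <- design
  conds <- names(d$spike_amounts)
  exps <- as.vector(t(outer(conds, seq_len(d$replicates),
                            function(a, b) paste0(a, "_r", b))))
  n_s <- length(d$spike_accessions)
  n_b <- d$n_background
  acc <- c(d$spike_accessions, sprintf("BG%04d", seq_len(n_b)))
  n <- n_s + n_b
  response <- 10^stats::rnorm(n_s, d$response_log10_mean, d$response_log10_sd)
  bg_level <- 10^stats::rnorm(n_b, d$background_log10_mean,
                              d$background_log10_sd)
  true_mean <- matrix(0, n, length(exps), dimnames = list(acc, exps))
  for (ci in seq_along(conds)) {
    cols <- (ci - 1L) * d$replicates + seq_len(d$replicates)
    true_mean[seq_len(n_s), cols] <- d$spike_amounts[ci] * response
    true_mean[n_s + seq_len(n_b), cols] <- bg_level
  }
  intensity <- true_mean * matrix(.lnoise(n * length(exps), d$noise_cv),
                                  n, length(exps))
  p_obs <- stats::plogis((log2(intensity) - d$dropout_midpoint) /
                           d$dropout_slope)
  observed <- matrix(stats::runif(n * length(exps)) < p_obs, n, length(exps),
                     dimnames = dimnames(true_mean))
  intensity[!observed] <- 0
  length_aa <- c(sample(100:900, n_s, replace = TRUE),
                 sample(150:1500, n_b, replace = TRUE))
  po <- pmax(1L, as.integer(round(length_aa / 25)))
  tot <- rowSums(intensity)
  sc <- stats::rpois(n, pmin(500, tot / 2^22))
  pn <- pmin(po, stats::rpois(n, pmin(po, 1 + tot / 2^23)))
  tab <- protein_table(accession = acc, length = length_aa, pn = pn, sc = sc,
                       mq = intensity, lfq = intensity,
                       description = c(rep("spike-in standard", n_s),
                                       rep("background proteome", n_b)))
  ratio <- outer(d$spike_amounts, d$spike_amounts, "/")
  list(table = tab,
       truth = list(spike_accessions = d$spike_accessions,
                    amounts = d$spike_amounts,
                    fold_changes = ratio,
                    response = stats::setNames(response, d$spike_accessions),
                    background_level = stats::setNames(bg_level,
                                                       acc[n_s + seq_len(n_b)]),
                    dropout_mask = !observed,
                    po = stats::setNames(po, acc),
                    seed = seed))
}

#' Group assignment for two conditions of a spike-in table
#'
#' Convenience helper building the `groups` vector for
#' [run_differential()] from two condition labels of a simulated spike-in
#' table.
#'
#' @param design a [spike_in_design()].
#' @param cond1,cond2 condition labels (names of `design$spike_amounts`).
#' @return Named character vector mapping experiment labels to the two
#'   condition labels.
#' @export
spike_in_groups <- function(design, cond1, cond2) {
  stopifnot(all(c(cond1, cond2) %in% names(design$spike_amounts)))
  r <- seq_len(design$replicates)
  stats::setNames(rep(c(cond1, cond2), each = design$replicates),
                  c(paste0(cond1, "_r", r), paste0(cond2, "_r", r)))
}

#' Simulate a dilution series
#'
#' Generates one [protein_table] per molar amount of the grid (default:
#' 500 amol to 500 pmol in decade steps, i.e. six orders of magnitude) for
#' a small set of standard proteins, optionally on top of a constant
#' background proteome. Intensities follow the same
#' response-times-log-normal-noise model as [simulate_spike_in()]; spectral
#' counts and peptide numbers are generated as saturating count processes
#' (`SC ~ Poisson` of a Michaelis-Menten-type rate, `PN ~ Binomial(po, .)`),
#' so the count-based indices saturate at high input while the
#' intensity-based indices stay linear - the behaviour that limits the
#' dynamic range of counting methods.
#'
#' @param amounts_fmol ascending molar amounts (fmol).
#' @param proteins `data.frame` with columns `accession`, `length`, `po`.
#' @param n_replicates replicate experiments per amount.
#' @param noise_cv multiplicative noise CV.
#' @param response_log10_mean,response_log10_sd per-protein response factor
#'   distribution (decades per fmol).
#' @param sc_half intensity at half-maximal MS/MS sampling rate.
#' @param sc_max_per_po maximal expected spectral counts per observable
#'   peptide.
#' @param background optional [spike_in_design()]-style background: list
#'   with `n`, `log10_mean`, `log10_sd`.
#' @param seed integer seed.
#' @return List with `tables` (named list of [protein_table], one per
#'   amount) and `truth` (`proteins`, `amounts_fmol`, `response`).
#' @export
simulate_dilution_series <- function(amounts_fmol = c(0.5, 5, 50, 500,
                                                      5e3, 5e4, 5e5),
                                     proteins = data.frame(
                                       accession = c("ALBU_STD", "CASB_STD"),
                                       length = c(583L, 224L),
                                       po = c(28L, 11L)),
                                     n_replicates = 3,
                                     noise_cv = 0.2,
                                     response_log10_mean = 7.1,
                                     response_log10_sd = 0.2,
                                     sc_half = 1e10,
                                     sc_max_per_po = 5,
                                     background = NULL,
                                     seed = 1) {
  stopifnot(all(amounts_fmol > 0), !is.unsorted(amounts_fmol))
  set.seed(seed)
  np <- nrow(proteins)
  response <- 10^stats::rnorm(np, response_log10_mean, response_log10_sd)
  if (!is.null(background)) {
    bg_acc <- sprintf("BG%04d", seq_len(background$n))
    bg_level <- 10^stats::rnorm(background$n, background$log10_mean,
                                background$log10_sd)
    bg_len <- sample(150:1500, background$n, replace = TRUE)
    bg_po <- pmax(1L, as.integer(round(bg_len / 25)))
  }
  tables <- lapply(amounts_fmol, function(a) {
    mu <- a * response
    if (!is.null(background)) mu <- c(mu, bg_level)
    nr <- length(mu)
    m <- mu * matrix(.lnoise(nr * n_replicates, noise_cv), nr, n_replicates)
    colnames(m) <- paste0("r", seq_len(n_replicates))
    po <- c(proteins$po, if (!is.null(background)) bg_po)
    len <- c(proteins$length, if (!is.null(background)) bg_len)
    acc <- c(proteins$accession, if (!is.null(background)) bg_acc)
    tot <- rowSums(m)
    sc <- stats::rpois(nr, sc_max_per_po * po * tot / (tot + sc_half))
    pn <- stats::rbinom(nr, po, tot / (tot + sc_half / 30))
    protein_table(accession = acc, length = len, pn = pn, sc = sc,
                  mq = m, lfq = m)
  })
  names(tables) <- as.character(amounts_fmol)
  list(tables = tables,
       truth = list(proteins = proteins, amounts_fmol = amounts_fmol,
                    response = stats::setNames(response, proteins$accession),
                    background = background, seed = seed))
}

#' Accuracy of a quantification index over a dilution series
#'
#' Pools, over the standard proteins and amounts of a simulated dilution
#' series, the points `(log10 input, log10 index)` and reports the accuracy
#' metrics used to compare label-free indices: Pearson and Spearman
#' correlation, the fitted log-log slope, the largest absolute deviation
#' from the free regression line in orders of magnitude (`max_outlier`), and
#' the linear dynamic range: the orders of magnitude of input spanned by
#' points deviating less than `outlier_tol` orders from a unit-slope
#' (proportional-response) line, so that a saturating index scores a
#' shorter dynamic range even when its own regression fits well. With
#' `versus = "mass"` inputs are mass amounts (`molar x length`), which
#' normalizes away protein-size effects.
#'
#' @param sim result of [simulate_dilution_series()].
#' @param index one of `"PN"`, `"emPAI"`, `"SC"`, `"NSAF"`, `"MQ"`,
#'   `"LFQ"`, `"iBAQ"`.
#' @param versus `"molar"` or `"mass"`.
#' @param outlier_tol tolerance (orders of magnitude) defining the linear
#'   range.
#' @return One-row `data.frame` with `index`, `versus`, `n_points`,
#'   `pearson`, `spearman`, `slope`, `max_outlier`, `dynamic_range`.
#' @export
evaluate_accuracy <- function(sim, index = c("PN", "emPAI", "SC", "NSAF",
                                             "MQ", "LFQ", "iBAQ"),
                              versus = c("molar", "mass"),
                              outlier_tol = 1) {
  index <- match.arg(index)
  versus <- match.arg(versus)
  pr <- sim$truth$proteins
  pts <- do.call(rbind, lapply(seq_along(sim$tables), function(i) {
    tab <- sim$tables[[i]]
    rows <- match(pr$accession, tab$accession)
    amount <- sim$truth$amounts_fmol[i]
    mq <- rowMeans(mq_matrix(tab))[rows]
    lfq <- rowMeans(lfq_matrix(tab))[rows]
    val <- switch(index,
      PN = tab$pn[rows],
      SC = tab$sc[rows],
      emPAI = compute_empai(tab$pn[rows], pr$po),
      NSAF = compute_nsaf(tab)[rows],
      MQ = mq,
      LFQ = lfq,
      iBAQ = 10^compute_ibaq(mq, pr$po))   # back to linear scale for log-log fit
    data.frame(x = log10(amount * if (versus == "mass") pr$length else 1),
               y = log10(val))
  }))
  pts <- pts[is.finite(pts$y), , drop = FALSE]
  if (nrow(pts) < 3L) stop("fewer than 3 usable points")
  fit <- stats::lm(y ~ x, data = pts)
  resid <- stats::resid(fit)
  # proportionality residuals: unit-slope line with free intercept
  resid1 <- pts$y - pts$x - stats::median(pts$y - pts$x)
  inliers <- abs(resid1) < outlier_tol
  data.frame(index = index, versus = versus, n_points = nrow(pts),
             pearson = stats::cor(pts$x, pts$y),
             spearman = stats::cor(pts$x, pts$y, method = "spearman"),
             slope = unname(stats::coef(fit)[2]),
             max_outlier = max(abs(resid)),
             dynamic_range = if (any(inliers))
               diff(range(pts$x[inliers])) else 0,
             stringsAsFactors = FALSE)
}
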