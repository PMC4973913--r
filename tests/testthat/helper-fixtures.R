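# Fixtures and independent oracles shared across the suite.

# small in-memory protein table
toy_table <- function(n = 5, experiments = c("a", "b"), seed = 42) {
  set.seed(seed)
  mq <- matrix(10^runif(n * length(experiments), 5, 9), n,
               length(experiments), dimnames = list(NULL, experiments))
  protein_table(
    accession = sprintf("P%02d", seq_len(n)),
    length = sample(100:900, n, replace = TRUE),
    pn = sample(0:20, n, replace = TRUE),
    sc = sample(1:50, n, replace = TRUE),
    mq = mq, lfq = mq * runif(n * length(experiments), 0.5, 2))
}

# write a minimal MaxQuant-dialect proteinGroups file; returns the path
write_mq_fixture <- function(path = tempfile(fileext = ".txt"),
                             drop_column = NULL) {
  head_cols <- c("Protein IDs", "Majority protein IDs", "Protein names",
                 "Sequence length", "Peptides", "MS/MS count",
                 "Intensity e1", "Intensity e2",
                 "LFQ intensity e1", "LFQ intensity e2",
                 "Only identified by site", "Reverse", "Contaminant")
  rows <- list(
    c("P1;P9", "P1;P9", "alpha", "120", "4", "11",
      "1000000", "2000000", "900000", "2100000", "", "", ""),
    c("P2", "P2", "beta", "300", "7", "25",
      "5000000", "0", "4800000", "", "", "", ""),
    c("REV_P3", "REV_P3", "decoy", "210", "1", "2",
      "100", "100", "90", "80", "", "+", ""))
  keep <- !(head_cols %in% drop_column)
  lines <- c(paste(head_cols[keep], collapse = "\t"),
             vapply(rows, function(r) paste(r[keep], collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

random_sequence <- function(len, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# brute-force digestion oracle: naive scan for cleavage sites, then
# enumerate every contiguous run of <= mc+1 fragments
oracle_digest <- function(sequence, mc, proline_rule = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  sites <- integer(0)
  for (i in seq_len(length(aa) - 1)) {
    if (aa[i] %in% c("K", "R") && !(proline_rule && aa[i + 1] == "P"))
      sites <- c(sites, i)
  }
  bounds <- c(0, sites, length(aa))
  frags <- character(0)
  for (i in seq_len(length(bounds) - 1))
    frags <- c(frags, substr(sequence, bounds[i] + 1, bounds[i + 1]))
  peps <- character(0)
  for (i in seq_along(frags))
    for (m in 0:mc)
      if (i + m <= length(frags))
        peps <- c(peps, paste(frags[i:(i + m)], collapse = ""))
  peps
}

oracle_count_observable <- function(sequence, params) {
  peps <- unique(oracle_digest(sequence, params$max_missed_cleavages,
                               params$proline_rule))
  n <- 0L
  for (p in peps) {
    if (nchar(p) < params$min_length || nchar(p) > params$max_length) next
    if (!is.null(params$gravy_range)) {
      g <- gravy(p)
      if (g < params$gravy_range[1] || g > params$gravy_range[2]) next
    }
    if (!is.null(params$charge_range)) {
      z <- peptide_charge(p)
      if (z < params$charge_range[1] || z > params$charge_range[2]) next
    }
    n <- n + 1L
  }
  n
}

# exact hypergeometric upper tail by direct enumeration with choose();
# all terms are exact integers in double precision for N <= 20
oracle_hyper_tail <- function(k, b, K, N) {
  js <- k:min(b, K)
  js <- js[js >= max(0, b - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, b - js)) / choose(N, b)
}
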