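#' Protein-group tables
#'
#' A `protein_table` is a plain `data.frame` with one row per protein group
#' and a fixed set of columns: `accession`, `description`, `length`
#' (amino acids), `pn` (number of identified peptides), `sc` (summed MS/MS
#' spectral counts), one raw-intensity column `mq:<exp>` and one
#' normalized-intensity column `lfq:<exp>` per experiment, and `flags`
#' (semicolon-separated subset of `only_identified_by_site`, `reverse`,
#' `contaminant`; empty when unflagged). The experiment labels are stored in
#' the `"experiments"` attribute. An intensity of 0 means "not detected"
#' throughout the package.
#'
#' @param accession character vector of unique protein (group) accessions.
#'   For groups with several accessions the leading (razor) accession is
#'   used as key.
#' @param length integer vector of protein lengths (>= 1).
#' @param pn,sc non-negative integer vectors (identified peptides, MS/MS
#'   counts).
#' @param mq,lfq numeric matrices (proteins x experiments) of raw and LFQ
#'   intensities; column names are the experiment labels.
#' @param description optional character vector of protein descriptions.
#' @param flags optional character vector; per protein a semicolon-separated
#'   subset of the three categorical flags.
#'
#' @return A `protein_table`.
#' @examples
#' pt <- protein_table(
#'   accession = c("P1", "P2"), length = c(100L, 50L),
#'   pn = c(4L, 2L), sc = c(10L, 5L),
#'   mq = matrix(c(1e6, 2e6, 0, 4e6), 2, 2, dimnames = list(NULL, c("a", "b"))),
#'   lfq = matrix(c(1e6, 2e6, 0, 4e6), 2, 2, dimnames = list(NULL, c("a", "b")))
#' )
#' experiments(pt)
#' @export
protein_table <- function(accession, length, pn, sc, mq, lfq,
                          description = NULL, flags = NULL) {
  n <- base::length(accession)
  accession <- as.character(accession)
  if (anyDuplicated(accession))
    stop("duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  mq <- as.matrix(mq)
  lfq <- as.matrix(lfq)
  if (is.null(colnames(mq)) || is.null(colnames(lfq)))
    stop("'mq' and 'lfq' need experiment labels as column names")
  if (!identical(colnames(mq), colnames(lfq)))
    stop("experiment labels of 'mq' and 'lfq' differ")
  if (nrow(mq) != n || nrow(lfq) != n)
    stop("intensity matrices must have one row per protein")
  length <- as.integer(length)
  if (any(is.na(length)) || any(length < 1L)) stop("'length' must be >= 1")
  pn <- as.integer(pn); sc <- as.integer(sc)
  if (any(pn < 0L, na.rm = TRUE) || any(sc < 0L, na.rm = TRUE))
    stop("'pn' and 'sc' must be non-negative")
  if (any(mq < 0) || any(lfq < 0)) stop("intensities must be non-negative")
  if (is.null(description)) description <- rep("", n)
  if (is.null(flags)) flags <- rep("", n)
  bad <- setdiff(unlist(strsplit(flags[nzchar(flags)], ";", fixed = TRUE)),
                 .pt_flags)
  if (base::length(bad))
    stop("unknown flags: ", paste(bad, collapse = ", "))
  exps <- colnames(mq)
  df <- data.frame(accession = accession, description = description,
                   length = length, pn = pn, sc = sc,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (e in exps) df[[paste0("mq:", e)]] <- as.numeric(mq[, e])
  for (e in exps) df[[paste0("lfq:", e)]] <- as.numeric(lfq[, e])
  df$flags <- flags
  structure(df, experiments = exps,
            class = c("protein_table", "data.frame"))
}

.pt_flags <- c("only_identified_by_site", "reverse", "contaminant")

#' @rdname protein_table
#' @param x a `protein_table`.
#' @export
experiments <- function(x) attr(x, "experiments")

#' Raw- and LFQ-intensity matrices of a protein table
#'
#' @param x a [protein_table].
#' @return Numeric matrix (proteins x experiments) with accessions as row
#'   names; 0 marks "not detected".
#' @export
mq_matrix <- function(x) .pt_matrix(x, "mq:")

#' @rdname mq_matrix
#' @export
lfq_matrix <- function(x) .pt_matrix(x, "lfq:")

.pt_matrix <- function(x, prefix) {
  exps <- experiments(x)
  m <- as.matrix(as.data.frame(x, check.names = FALSE)[, paste0(prefix, exps),
                                                       drop = FALSE])
  dimnames(m) <- list(x$accession, exps)
  m
}

#' @export
print.protein_table <- function(x, n = 6, ...) {
  cat(sprintf("protein_table: %d protein groups, %d experiments (%s)\n",
              nrow(x), length(experiments(x)),
              paste(experiments(x), collapse = ", ")))
  print(utils::head(as.data.frame(x, check.names = FALSE), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

# ---- reading / writing -----------------------------------------------------

#' Read a protein-group table
#'
#' Reads either the tab-delimited MaxQuant `proteinGroups.txt` dialect or the
#' package's simplified internal TSV (the format written by
#' [write_protein_table()]). Empty or missing intensity cells are parsed as 0
#' ("not detected"). Experiment labels are inferred from the
#' `LFQ intensity <exp>` / `Intensity <exp>` column suffixes
#' (maxquant dialect) or from the `mq:<exp>` / `lfq:<exp>` headers (simple
#' dialect). Column-name matching for the maxquant dialect is
#' case-insensitive and can be overridden via `col_overrides` because
#' proteinGroups headers vary between MaxQuant versions.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect `"maxquant"` or `"simple"`.
#' @param col_overrides named list mapping logical column roles
#'   (`accession`, `description`, `length`, `pn`, `sc`,
#'   `only_identified_by_site`, `reverse`, `contaminant`) to actual header
#'   names, for non-standard maxquant exports.
#' @return A [protein_table].
#' @export
read_protein_groups <- function(path, dialect = c("maxquant", "simple"),
                                col_overrides = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "")
  if (dialect == "simple") .read_simple(raw) else .read_maxquant(raw, col_overrides)
}

.num0 <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  x[is.na(x)] <- 0
  x
}

.read_simple <- function(raw) {
  need <- c("accession", "description", "length", "pn", "sc", "flags")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  mqc <- grep("^mq:", names(raw), value = TRUE)
  lfqc <- grep("^lfq:", names(raw), value = TRUE)
  exps <- sub("^mq:", "", mqc)
  if (!length(exps)) stop("missing mandatory column(s): mq:<experiment>")
  if (!setequal(sub("^lfq:", "", lfqc), exps))
    stop("mq:/lfq: experiment labels disagree")
  mq <- sapply(exps, function(e) .num0(raw[[paste0("mq:", e)]]))
  lfq <- sapply(exps, function(e) .num0(raw[[paste0("lfq:", e)]]))
  if (nrow(raw) == 1L) { mq <- t(mq); lfq <- t(lfq) }
  colnames(mq) <- colnames(lfq) <- exps
  flags <- raw$flags
  flags[is.na(flags)] <- ""
  protein_table(accession = raw$accession,
                description = ifelse(is.na(raw$description), "", raw$description),
                length = raw$length, pn = .num0(raw$pn), sc = .num0(raw$sc),
                mq = mq, lfq = lfq, flags = flags)
}

.read_maxquant <- function(raw, col_overrides = list()) {
  lc <- tolower(names(raw))
  pick <- function(role, candidates, mandatory = TRUE) {
    if (!is.null(col_overrides[[role]])) {
      j <- match(tolower(col_overrides[[role]]), lc)
      if (is.na(j)) stop("override column not found: ", col_overrides[[role]])
      return(j)
    }
    j <- match(tolower(candidates), lc)
    j <- j[!is.na(j)]
    if (!length(j)) {
      if (mandatory) stop("missing mandatory column: ", candidates[[1]])
      return(NA_integer_)
    }
    j[[1]]
  }
  j_acc <- pick("accession", c("Majority protein IDs", "Protein IDs"))
  j_desc <- pick("description", c("Protein names", "Fasta headers"), FALSE)
  j_len <- pick("length", c("Sequence length"))
  j_pn <- pick("pn", c("Peptides"))
  j_sc <- pick("sc", c("MS/MS count", "MS/MS Count"))
  j_site <- pick("only_identified_by_site", c("Only identified by site"))
  j_rev <- pick("reverse", c("Reverse"))
  j_con <- pick("contaminant", c("Contaminant", "Potential contaminant"))

  lfqc <- grep("^lfq intensity .+", lc)
  if (!length(lfqc)) stop("missing mandatory column: LFQ intensity <experiment>")
  exps <- sub("^lfq intensity ", "", lc[lfqc])
  mq_idx <- match(paste0("intensity ", exps), lc)
  if (anyNA(mq_idx))
    stop("missing mandatory column: Intensity ",
         exps[which(is.na(mq_idx))[1]])
  acc <- vapply(strsplit(as.character(raw[[j_acc]]), ";", fixed = TRUE),
                `[[`, "", 1L)
  if (anyDuplicated(acc))
    stop("duplicate accessions: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  plus <- function(j) !is.na(raw[[j]]) & trimws(as.character(raw[[j]])) == "+"
  fl <- cbind(only_identified_by_site = plus(j_site),
              reverse = plus(j_rev), contaminant = plus(j_con))
  flags <- apply(fl, 1L, function(r) paste(colnames(fl)[r], collapse = ";"))
  mq <- sapply(seq_along(exps), function(i) .num0(raw[[mq_idx[i]]]))
  lfq <- sapply(seq_along(exps), function(i) .num0(raw[[lfqc[i]]]))
  if (nrow(raw) == 1L) { mq <- t(mq); lfq <- t(lfq) }
  colnames(mq) <- colnames(lfq) <- exps
  protein_table(accession = acc,
                description = if (is.na(j_desc)) NULL else
                  ifelse(is.na(raw[[j_desc]]), "", as.character(raw[[j_desc]])),
                length = .num0(raw[[j_len]]), pn = .num0(raw[[j_pn]]),
                sc = .num0(raw[[j_sc]]), mq = mq, lfq = lfq, flags = flags)
}

#' Write a protein table in the simple TSV dialect
#'
#' The written file round-trips through
#' `read_protein_groups(dialect = "simple")` field by field.
#'
#' @param x a [protein_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(x, path) {
  utils::write.table(as.data.frame(x, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove categorically flagged protein groups
#'
#' Drops every row carrying any of the three categorical MaxQuant
#' annotations (only identified by site, reverse, contaminant), which mark
#' unreliable spectrum matches or supposed contaminants. A row carrying
#' several flags is removed (and counted) once. Idempotent.
#'
#' @param x a [protein_table].
#' @return The filtered `protein_table`; the number of removed rows is
#'   reported via `message()` and stored in the `"n_removed"` attribute.
#' @export
filter_categorical <- function(x) {
  stopifnot(inherits(x, "protein_table"))
  keep <- !nzchar(x$flags)
  out <- x[keep, , drop = FALSE]
  attr(out, "experiments") <- experiments(x)
  class(out) <- class(x)
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " flagged protein group(s) removed")
  out
}
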