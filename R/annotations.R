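#' Protein annotation maps
#'
#' An `annotation_map` links protein accessions to (i) a deduplicated set of
#' GO identifiers and (ii) a set of boolean surfaceome features used by the
#' cell-surface classifier: `GA` (GPI-anchored), `TM` (transmembrane), `SP`
#' (signal peptide), `PM` (plasma membrane), `ECS`/`ECR`/`ECM`
#' (extracellular space/region/matrix). Accessions absent from the source
#' file are absent from the map ("unannotated"), not mapped to an empty set.
#'
#' @name annotation_map
NULL

.surface_features <- c("GA", "TM", "SP", "PM", "ECS", "ECR", "ECM")

#' Build an annotation map from R objects
#'
#' @param go named list: accession -> character vector of GO identifiers.
#' @param features named list: accession -> character vector drawn from
#'   `GA, TM, SP, PM, ECS, ECR, ECM`.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(go = list(), features = list()) {
  go <- lapply(go, function(x) sort(unique(as.character(x))))
  features <- lapply(features, function(x) {
    x <- unique(as.character(x))
    bad <- setdiff(x, .surface_features)
    if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
    x
  })
  structure(list(go = go, features = features), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d accessions with GO terms, %d with features\n",
              length(x$go), length(x$features)))
  invisible(x)
}

#' Read protein annotations
#'
#' Accepts three tab-delimited layouts, auto-detected from the header /
#' first data line:
#' * two-column `accession<TAB>GO-id` (with or without a header line);
#' * GAF 2.x (comment lines starting with `!`; accession in column 2, GO id
#'   in column 5);
#' * wide feature table: `accession` column plus 0/1 columns named
#'   `GA, TM, SP, PM, ECS, ECR, ECM` (any subset).
#'
#' Malformed GO identifiers (not `GO:` + 7 digits) are skipped with a
#' warning; duplicated (accession, term) lines are deduplicated.
#'
#' @param path file path.
#' @return An [annotation_map].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty annotation file: ", path)
  gaf <- startsWith(lines[[1]], "!")
  body <- lines[!startsWith(lines, "!")]
  if (!length(body)) stop("empty annotation file: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (gaf || length(fields[[1]]) >= 15L) {
    acc <- vapply(fields, function(f) f[[2]], "")
    term <- vapply(fields, function(f) f[[5]], "")
    return(.go_map(acc, term))
  }
  header <- fields[[1]]
  if (any(header %in% .surface_features)) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    accn <- if ("accession" %in% names(df)) "accession" else names(df)[[1]]
    featcols <- intersect(.surface_features, names(df))
    features <- lapply(seq_len(nrow(df)), function(i)
      featcols[as.logical(.num0(unlist(df[i, featcols])))])
    names(features) <- df[[accn]]
    return(annotation_map(features = features[lengths(features) > 0]))
  }
  # plain two-column layout, tolerate a header line
  if (identical(tolower(header[1:2]), c("accession", "go_term")) ||
      identical(tolower(header[1:2]), c("accession", "term")))
    fields <- fields[-1]
  if (!length(fields)) stop("empty annotation file: ", path)
  acc <- vapply(fields, function(f) f[[1]], "")
  term <- vapply(fields, function(f) if (length(f) >= 2L) f[[2]] else "", "")
  .go_map(acc, term)
}

.go_map <- function(acc, term) {
  ok <- grepl("^GO:[0-9]{7}$", term)
  if (any(!ok))
    warning(sum(!ok), " line(s) with malformed GO identifier skipped")
  acc <- acc[ok]; term <- term[ok]
  if (!length(acc)) stop("no valid GO annotations found")
  annotation_map(go = split(term, acc))
}

#' Query an annotation map
#'
#' `ann_terms()` / `ann_features()` return the GO-term / feature set of one
#' accession (`character(0)` plus an `"unannotated"` attribute when the
#' accession is absent). `is_annotated()` is vectorized.
#'
#' @param map an [annotation_map].
#' @param accession accession string(s).
#' @return Character vector of terms or features; logical vector for
#'   `is_annotated()`.
#' @export
ann_terms <- function(map, accession) {
  stopifnot(inherits(map, "annotation_map"))
  v <- map$go[[accession]]
  if (is.null(v)) structure(character(0), unannotated = TRUE) else v
}

#' @rdname ann_terms
#' @export
ann_features <- function(map, accession) {
  stopifnot(inherits(map, "annotation_map"))
  v <- map$features[[accession]]
  if (is.null(v)) structure(character(0), unannotated = TRUE) else v
}

#' @rdname ann_terms
#' @export
is_annotated <- function(map, accession) {
  stopifnot(inherits(map, "annotation_map"))
  accession %in% c(names(map$go), names(map$features))
}

#' Accessions carrying a given GO term or feature
#'
#' @param map an [annotation_map].
#' @param term a GO identifier (matched against term sets) or one of the
#'   feature symbols `GA, TM, SP, PM, ECS, ECR, ECM` (matched against
#'   feature sets).
#' @return Character vector of accessions.
#' @export
term_members <- function(map, term) {
  stopifnot(inherits(map, "annotation_map"))
  if (term %in% .surface_features)
    return(names(map$features)[vapply(map$features, function(f)
      term %in% f, NA)])
  names(map$go)[vapply(map$go, function(g) term %in% g, NA)]
}
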