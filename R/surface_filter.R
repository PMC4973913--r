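#' Boolean cell-surface classifier
#'
#' A protein is accepted as a cell-surface protein if it is GPI-anchored
#' (`GA`) or transmembrane (`TM`) and assigned to the plasma membrane
#' (`PM`), or if it carries a signal peptide (`SP`) and is assigned to the
#' extracellular space (`ECS`), region (`ECR`) or matrix (`ECM`):
#'
#' `((GA | TM) & PM) | (SP & (ECS | ECR | ECM))`
#'
#' The expression uses positive evidence only: additional (even conflicting)
#' annotations never turn a surface call negative, so the classifier is
#' monotone in the feature set. The first matching clause is recorded in the
#' order `GA&PM`, `TM&PM`, `SP&EC`.
#'
#' @param features character vector, subset of
#'   `GA, TM, SP, PM, ECS, ECR, ECM` (order and duplication irrelevant).
#' @return List with elements `is_surface` (logical) and `matched_clause`
#'   (`"GA&PM"`, `"TM&PM"`, `"SP&EC"` or `"none"`).
#' @examples
#' classify_surface(c("GA", "PM"))$is_surface   # TRUE (GPI-anchored receptor)
#' classify_surface("TM")$is_surface            # FALSE (no PM assignment)
#' @export
classify_surface <- function(features) {
  features <- unique(as.character(features))
  bad <- setdiff(features, .surface_features)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  has <- .surface_features %in% features
  names(has) <- .surface_features
  clause <- if (has["GA"] && has["PM"]) "GA&PM"
    else if (has["TM"] && has["PM"]) "TM&PM"
    else if (has["SP"] && (has["ECS"] || has["ECR"] || has["ECM"])) "SP&EC"
    else "none"
  list(is_surface = clause != "none", matched_clause = clause)
}

#' Cell-surface calls for a protein table
#'
#' Applies [classify_surface()] to every protein of a (categorically
#' filtered) table using the feature flags of an annotation map, and
#' attaches abundance classes ([assign_abundance_class()]) per sample group.
#' Unannotated proteins are called non-surface with a warning count and
#' `annotated = FALSE`.
#'
#' @param x a [protein_table], ideally after [filter_categorical()].
#' @param annotations an [annotation_map] carrying feature flags.
#' @param groups optional named list mapping group labels to experiment
#'   labels; per group the mean log2 LFQ ([mean_log2_lfq()]) is classed and
#'   reported as column `class_<group>`.
#' @param thresholds abundance-class cut points, see
#'   [assign_abundance_class()].
#' @return `data.frame` with columns `accession`, `annotated`, `is_surface`,
#'   `matched_clause` and one `class_<group>` column per group.
#' @export
surface_list <- function(x, annotations, groups = NULL,
                         thresholds = c(18, 23, 28, 33)) {
  stopifnot(inherits(x, "protein_table"), inherits(annotations, "annotation_map"))
  annotated <- x$accession %in% names(annotations$features)
  calls <- lapply(x$accession, function(a)
    classify_surface(ann_features(annotations, a)))
  out <- data.frame(accession = x$accession, annotated = annotated,
                    is_surface = vapply(calls, `[[`, NA, "is_surface"),
                    matched_clause = vapply(calls, `[[`, "", "matched_clause"),
                    stringsAsFactors = FALSE)
  if (any(!annotated))
    warning(sum(!annotated), " unannotated protein(s) called non-surface")
  for (g in names(groups)) {
    out[[paste0("class_", g)]] <-
      assign_abundance_class(mean_log2_lfq(x, groups[[g]]), thresholds)
  }
  out
}
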