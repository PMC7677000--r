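# Compound annotation of screened features by accurate-mass match within a
# ppm tolerance, nutrient exclusion, and the final unique candidate list.

PROTON_MASS <- 1.007276  # Da

#' Read a compound library
#'
#' A delimited table with columns `name`, `cas`, `formula`,
#' `monoisotopic_mass` (Da) and `is_nutrient` (logical flag for common
#' microbial nutrient compounds, which are excluded from bioassays). The
#' packaged library (`system.file("extdata", "compound_library.tsv",
#' package = "symbioscreen")`) contains the ten candidate metabolites plus
#' the four nutrient compounds of the onion-maggot screen.
#'
#' @param path Path to the library file; defaults to the packaged library.
#' @return data.frame with the columns above.
#' @export
read_compound_library <- function(path = system.file("extdata",
                                                     "compound_library.tsv",
                                                     package = "symbioscreen")) {
  lib <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("name", "cas", "formula", "monoisotopic_mass", "is_nutrient")
  if (!all(req %in% names(lib)))
    stop("compound library must have columns: ", paste(req, collapse = ", "))
  if (any(lib$monoisotopic_mass <= 0)) stop("masses must be positive")
  if (anyDuplicated(lib$cas)) stop("duplicate CAS in library")
  lib$is_nutrient <- as.logical(lib$is_nutrient)
  lib
}

#' Match a feature to library compounds within a ppm tolerance
#'
#' For positive-mode features the expected m/z of a compound is its
#' monoisotopic mass plus the proton mass (\[M+H\]+); for negative mode,
#' minus the proton mass (\[M-H\]-). A compound is annotated when the signed
#' relative deviation `(mz - expected)/expected * 1e6` is within
#' `tol_ppm` in magnitude. Matches are sorted by absolute ppm error.
#'
#' @param feature A one-row data.frame (or list) with `feature_id`, `mz`
#'   and `ion_mode`.
#' @param library Compound library data.frame (see
#'   [read_compound_library()]).
#' @param tol_ppm Tolerance in parts per million (default 10; must be
#'   positive).
#' @return data.frame of annotations: `feature_id`, `name`, `cas`,
#'   `formula`, `adduct`, `ppm_error`, `is_nutrient`.
#' @export
ppm_match <- function(feature, library, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (!nrow(library)) stop("library must be nonempty")
  mode <- feature$ion_mode
  adduct <- if (mode == "positive") "[M+H]+" else "[M-H]-"
  expected <- library$monoisotopic_mass +
    if (mode == "positive") PROTON_MASS else -PROTON_MASS
  ppm <- (feature$mz - expected) / expected * 1e6
  hit <- which(abs(ppm) <= tol_ppm)
  out <- data.frame(feature_id = rep(feature$feature_id, length(hit)),
                    name = library$name[hit], cas = library$cas[hit],
                    formula = library$formula[hit],
                    adduct = rep(adduct, length(hit)),
                    ppm_error = ppm[hit],
                    is_nutrient = library$is_nutrient[hit],
                    stringsAsFactors = FALSE)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Annotate every feature of a candidate table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `ion_mode`
#'   (one row per feature; duplicated feature ids are matched once).
#' @param library Compound library data.frame.
#' @param tol_ppm Tolerance in ppm (default 10).
#' @return Concatenated [ppm_match()] results.
#' @export
annotate_features <- function(features, library, tol_ppm = 10) {
  features <- unique(features[c("feature_id", "mz", "ion_mode")])
  res <- lapply(seq_len(nrow(features)),
                function(i) ppm_match(features[i, ], library, tol_ppm))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(feature_id = character(), name = character(),
                      cas = character(), formula = character(),
                      adduct = character(), ppm_error = numeric(),
                      is_nutrient = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Drop annotations of nutrient compounds
#'
#' Compounds flagged as common microbial nutrients (for this screen:
#' l-tyrosine, l-sorbose, l-leucine, l-valine) are removed from the
#' annotation list before bioassays; each exclusion is reported.
#'
#' @param annotations Annotation data.frame with an `is_nutrient` column.
#' @return The annotation data.frame without nutrient rows.
#' @export
exclude_nutrients <- function(annotations) {
  drop <- which(annotations$is_nutrient)
  for (i in drop)
    message("excluding nutrient compound: ", annotations$name[i],
            " (", annotations$cas[i], ")")
  out <- annotations[setdiff(seq_len(nrow(annotations)), drop), ,
                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Finalize the unique candidate compound list
#'
#' Joins annotations onto candidate rows by feature id (keeping, per row,
#' the closest-ppm annotation; exact ties are all kept and flagged
#' ambiguous), then de-duplicates by CAS across strains and ion modes.
#' When `annotations` is `NULL` the candidate table must already carry
#' `compound`/`cas` columns (as the transcribed published candidate table
#' does).
#'
#' @param candidate_table Candidate data.frame from [run_cascade()] or
#'   [read_candidate_table()].
#' @param annotations Optional annotation data.frame from
#'   [annotate_features()] (after [exclude_nutrients()]).
#' @return data.frame of unique compounds sorted by name: `compound`,
#'   `cas`, `n_support`, `strains`, `ion_modes`, `ambiguous`, with the
#'   supporting candidate rows in a `support` list column.
#' @export
finalize_candidates <- function(candidate_table, annotations = NULL) {
  ct <- candidate_table
  if (!nrow(ct))
    return(data.frame(compound = character(), cas = character(),
                      n_support = integer(), strains = character(),
                      ion_modes = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(annotations)) {
    if (!all(c("compound", "cas") %in% names(ct)))
      stop("candidate table lacks compound/cas columns and no annotations ",
           "were given")
    ct$ambiguous <- FALSE
  } else {
    joined <- lapply(seq_len(nrow(ct)), function(i) {
      ann <- annotations[annotations$feature_id == ct$feature_id[i], ,
                         drop = FALSE]
      if (!nrow(ann)) return(NULL)
      best <- min(abs(ann$ppm_error))
      ann <- ann[abs(abs(ann$ppm_error) - best) < 1e-9, , drop = FALSE]
      row <- ct[rep(i, nrow(ann)), , drop = FALSE]
      row$compound <- ann$name
      row$cas <- ann$cas
      row$ambiguous <- nrow(ann) > 1L
      row
    })
    ct <- do.call(rbind, joined)
    if (is.null(ct) || !nrow(ct))
      return(finalize_candidates(candidate_table[0, ]))
  }
  split_rows <- split(ct, ct$cas)
  out <- do.call(rbind, lapply(split_rows, function(rows) {
    data.frame(compound = rows$compound[1], cas = rows$cas[1],
               n_support = nrow(rows),
               strains = paste(sort(unique(rows$strain)), collapse = ","),
               ion_modes = paste(sort(unique(rows$ion_mode)), collapse = ","),
               ambiguous = any(rows$ambiguous),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound), , drop = FALSE]
  out$support <- lapply(split_rows, identity)[match(out$cas,
                                                    names(split_rows))]
  rownames(out) <- NULL
  out
}

#' Read a candidate table from delimited text
#'
#' Reads the candidate-table layout written by the cascade (and used by the
#' packaged transcription of the published 32-row candidate table,
#' `system.file("extdata", "table1_candidates.tsv",
#' package = "symbioscreen")`): `feature_id`, `rt_seconds`, `mz`,
#' `ion_mode`, `ratio_vs_b313`, `p_value`, `vip`, `strain`, and optionally
#' `compound` and `cas`.
#'
#' @param path Path to the delimited file (tab-separated).
#' @return data.frame of candidate rows.
#' @export
read_candidate_table <- function(path) {
  ct <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  req <- c("feature_id", "rt_seconds", "mz", "ion_mode", "ratio_vs_b313",
           "p_value", "vip", "strain")
  if (!all(req %in% names(ct)))
    stop("candidate table must have columns: ", paste(req, collapse = ", "))
  ct
}
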