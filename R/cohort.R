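#' Variant classes counted as non-synonymous
#'
#' The default set follows the usual whole-exome TMB convention: protein-
#' changing point mutations, indels, and splice/start disruptions. The rule
#' is configuration; pass a different vector where a cohort's calling
#' pipeline used another convention.
#'
#' @return Character vector of MAF `Variant_Classification` values.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Is a variant classification non-synonymous?
#'
#' Case-insensitive membership in the configured class set. Unknown classes
#' return `FALSE`; one aggregated warning lists them.
#'
#' @param variant_class Character vector of MAF variant classifications.
#' @param classes Class set counted as non-synonymous.
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(variant_class,
                             classes = nonsynonymous_classes()) {
  vc <- toupper(variant_class)
  known <- toupper(c(classes, "Silent", "Synonymous", "3'UTR", "5'UTR",
                     "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
                     "lincRNA", "Splice_Region", "Targeted_Region",
                     "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"))
  unknown <- setdiff(unique(vc), known)
  if (length(unknown))
    warning("unknown variant classification(s) treated as synonymous: ",
            paste(unknown, collapse = ", "))
  vc %in% toupper(classes)
}

#' Read a MAF-style somatic mutation table
#'
#' Tab-separated with a header containing at least `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification`; lines starting with
#' `#` are skipped and extra columns ignored.
#'
#' @param path Path to the MAF TSV.
#' @return Data frame with columns `sample_id`, `gene`, `variant_class`,
#'   `protein_change` (NA when absent), one row per variant call.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                "Variant_Classification")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("MAF is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene = toupper(as.character(df$Hugo_Symbol)),
    variant_class = as.character(df$Variant_Classification),
    protein_change = if ("HGVSp_Short" %in% names(df))
      as.character(df$HGVSp_Short) else rep(NA_character_, nrow(df)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) && any(!nzchar(out$sample_id) | !nzchar(out$gene)))
    stop("MAF contains empty sample or gene identifiers")
  out
}

#' Write a mutation table back to MAF-style TSV
#' @param mutations Data frame as returned by [read_maf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(
    Hugo_Symbol = mutations$gene,
    Tumor_Sample_Barcode = mutations$sample_id,
    Variant_Classification = mutations$variant_class,
    HGVSp_Short = mutations$protein_change,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_columns <- c("sample_id", "response", "best_response",
                       "pfs_months", "pfs_event", "os_months", "os_event",
                       "histology", "sex", "smoking", "pdl1", "treatment",
                       "tmb", "tnb")

#' Read a clinical table
#'
#' TSV with header; required columns `sample_id`, `response`, `pfs_months`,
#' `pfs_event`. Optional: `best_response`, `os_months`, `os_event`,
#' covariates (`histology`, `sex`, `smoking`, `pdl1`, `treatment`) and
#' pre-computed `tmb`/`tnb`. Response values other than DCB/NDB map to
#' `"unknown"` with a warning; `"NE"` best-response tokens map to `"PD/NE"`.
#'
#' @param path Path to the clinical TSV.
#' @return Data frame, one row per patient, `sample_id` unique.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  required <- c("sample_id", "response", "pfs_months", "pfs_event")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  resp <- toupper(trimws(as.character(df$response)))
  resp[resp == "UNKNOWN"] <- NA_character_
  bad <- !(resp %in% c("DCB", "NDB")) & !is.na(resp)
  if (any(bad)) {
    warning(sum(bad), " unparseable response value(s) mapped to 'unknown'")
    resp[bad] <- "unknown"
  }
  resp[is.na(resp)] <- "unknown"
  df$response <- resp
  if ("best_response" %in% names(df)) {
    br <- toupper(trimws(as.character(df$best_response)))
    br[br %in% c("CR", "PR", "CR/PR")] <- "CR/PR"
    br[br %in% c("PD", "NE", "PD/NE")] <- "PD/NE"
    br[br == "SD"] <- "SD"
    br[!(br %in% c("CR/PR", "SD", "PD/NE"))] <- NA_character_
    df$best_response <- br
  } else df$best_response <- NA_character_
  for (col in c("pfs_months", "os_months", "tmb", "tnb")) {
    if (col %in% names(df)) {
      df[[col]] <- as.numeric(df[[col]])
      if (any(df[[col]] < 0, na.rm = TRUE))
        stop("negative values in clinical column ", col)
    } else df[[col]] <- NA_real_
  }
  for (col in c("pfs_event", "os_event")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
    else df[[col]] <- NA_integer_
  }
  for (col in c("histology", "sex", "smoking", "pdl1", "treatment")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    else df[[col]] <- as.character(df[[col]])
  }
  df[, .clinical_columns]
}

#' Write a clinical table
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  cols <- intersect(.clinical_columns, names(clinical))
  utils::write.table(clinical[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble a cohort from clinical and mutation tables
#'
#' Mutations whose `sample_id` has no clinical record are dropped with a
#' message giving the count (mirroring the attrition real merged cohorts
#' show), never an error.
#'
#' @param clinical Clinical data frame ([read_clinical()]).
#' @param mutations Mutation data frame ([read_maf()]).
#' @param name Cohort label.
#' @return An object of class `cohort`: list with `clinical`, `mutations`,
#'   `name`.
#' @export
cohort <- function(clinical, mutations, name = "cohort") {
  stopifnot(is.data.frame(clinical), is.data.frame(mutations))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id in clinical table")
  orphan <- !(mutations$sample_id %in% clinical$sample_id)
  if (any(orphan)) {
    message(sum(orphan), " mutation row(s) dropped: sample_id absent from ",
            "clinical table")
    mutations <- mutations[!orphan, , drop = FALSE]
  }
  structure(list(clinical = clinical, mutations = mutations, name = name),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d patients, %d mutation rows\n", x$name,
              nrow(x$clinical), nrow(x$mutations)))
  invisible(x)
}

#' Per-sample tumor mutational burden
#'
#' TMB is the count of non-synonymous mutations per sample (a burden, so
#' repeated hits in one gene each count — unlike pathway alteration, which
#' is a state). Samples with a clinical record but no mutation rows get 0,
#' so downstream joins never drop patients silently. The raw count is the
#' default unit; give `per_mb` (capture size in megabases) to rescale.
#'
#' @param cohort A `cohort`.
#' @param classes Non-synonymous class set.
#' @param per_mb Optional capture size in Mb; when given, counts are divided
#'   by it.
#' @return Named numeric vector over all clinical `sample_id`s.
#' @export
compute_tmb <- function(cohort, classes = nonsynonymous_classes(),
                        per_mb = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  mut <- cohort$mutations
  keep <- if (nrow(mut)) is_nonsynonymous(mut$variant_class, classes)
          else logical(0)
  counts <- table(factor(mut$sample_id[keep],
                         levels = cohort$clinical$sample_id))
  tmb <- as.numeric(counts)
  names(tmb) <- cohort$clinical$sample_id
  if (!is.null(per_mb)) {
    stopifnot(is.numeric(per_mb), per_mb > 0)
    tmb <- tmb / per_mb
  }
  tmb
}
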