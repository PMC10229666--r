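# Cohort tables: reading, writing, and deterministic binary feature encoding.

cohort_required_cols <- c("patient_id", "mutated_genes", "karyotype",
                          "survival_months", "event")
cohort_numeric_cols <- c("age", "blast_pct", "hemoglobin", "platelets",
                         "wbc", "survival_months")

split_gene_field <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    sort(unique(trimws(strsplit(s, ",")[[1]])))
  })
}

new_mds_cohort <- function(tbl) {
  class(tbl) <- c("mds_cohort", class(tbl))
  tbl
}

#' Read a cohort table
#'
#' Reads a TSV/CSV per-patient cohort table into a cohort tibble. Mandatory
#' columns: `patient_id`, `mutated_genes` (comma-separated gene symbols, empty
#' for none), `karyotype` (a category from [karyotype_levels()] or a raw
#' string resolvable through [karyotype_aliases()]), `survival_months`,
#' `event` (0/1). Recognized optional columns: `age`, `sex`, `blast_pct`,
#' `hemoglobin`, `platelets`, `wbc`, `diagnosis`, `treatment_flags`
#' (comma-separated), `response`, `true_cluster`. Unparseable numeric entries
#' become `NA`, never zero.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param schema An [cohort_schema()] object (currently used for validation
#'   context only; encoding happens in [encode_features()]).
#' @return A tibble of class `mds_cohort`; `mutated_genes` and
#'   `treatment_flags` are list-columns of character vectors, `karyotype` a
#'   factor over [karyotype_levels()].
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_cohort(raw)
}

#' Coerce a data frame to a cohort tibble
#'
#' Applies the same parsing and validation as [read_cohort()] to an in-memory
#' data frame.
#'
#' @param x A data frame with the columns documented in [read_cohort()].
#' @return A tibble of class `mds_cohort`.
#' @export
as_cohort <- function(x) {
  tbl <- tibble::as_tibble(x)
  missing_cols <- setdiff(cohort_required_cols, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("cohort table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  tbl$patient_id <- as.character(tbl$patient_id)
  if (!is.list(tbl$mutated_genes)) {
    tbl$mutated_genes <- split_gene_field(tbl$mutated_genes)
  }
  if ("treatment_flags" %in% names(tbl) && !is.list(tbl$treatment_flags)) {
    tbl$treatment_flags <- split_gene_field(tbl$treatment_flags)
  }

  kt <- normalize_karyotype(tbl$karyotype)
  bad <- which(is.na(kt))
  if (length(bad)) {
    abort(paste0(
      "unmappable karyotype string(s) in row(s) ",
      paste(head(bad, 10L), collapse = ", "),
      if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
      ": ", paste(unique(as.character(tbl$karyotype[head(bad, 5L)])),
                  collapse = "; ")))
  }
  tbl$karyotype <- factor(kt, levels = karyotype_levels())

  for (col in intersect(cohort_numeric_cols, names(tbl))) {
    tbl[[col]] <- suppressWarnings(as.numeric(tbl[[col]]))
  }
  tbl$event <- suppressWarnings(as.integer(tbl$event))
  if (any(!tbl$event %in% c(0L, 1L), na.rm = TRUE)) {
    abort("`event` must be 0/1.")
  }
  if (any(tbl$survival_months < 0, na.rm = TRUE)) {
    abort("`survival_months` must be >= 0.")
  }
  if ("blast_pct" %in% names(tbl)) {
    out_of_range <- which(tbl$blast_pct < 0 | tbl$blast_pct > 100)
    if (length(out_of_range)) {
      warn(sprintf("blast_pct outside [0, 100] in %d row(s); set to NA.",
                   length(out_of_range)))
      tbl$blast_pct[out_of_range] <- NA_real_
    }
  }
  new_mds_cohort(tbl)
}

#' Write a cohort table
#'
#' Serializes a cohort tibble back to the TSV dialect [read_cohort()] accepts
#' (list-columns collapsed with commas). `read_cohort(write_cohort(x))` is an
#' identity on the parsed fields.
#'
#' @param cohort A `mds_cohort` tibble.
#' @param path Output file path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in c("mutated_genes", "treatment_flags")) {
    if (col %in% names(out) && is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], paste, character(1), collapse = ",")
    }
  }
  out$karyotype <- as.character(out$karyotype)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Encode a cohort into the binary feature matrix
#'
#' Deterministically encodes patient records into the 0/1 matrix the
#' clustering pipeline consumes: one indicator per schema gene (1 iff the
#' gene is mutated), one indicator per pathway group (1 iff any member gene
#' is mutated), and eight mutually exclusive karyotype one-hots. Gene and
#' pathway columns with carrier frequency below
#' `schema$min_feature_frequency` are dropped and reported via the
#' `dropped_features` attribute; karyotype columns are always kept so every
#' row has exactly one active category.
#'
#' @param cohort A `mds_cohort` tibble (see [read_cohort()]).
#' @param schema A [cohort_schema()].
#' @return A tibble of class `mds_features`: `patient_id` plus one 0/1 column
#'   per retained feature, in schema order. Attributes: `schema`,
#'   `dropped_features`.
#' @examples
#' coh <- as_cohort(data.frame(
#'   patient_id = c("p1", "p2"), mutated_genes = c("SF3B1", ""),
#'   karyotype = c("NK", "complex"), survival_months = c(10, 2),
#'   event = c(0, 1)))
#' encode_features(coh, cohort_schema(genes = c("SF3B1", "TP53")))
#' @export
encode_features <- function(cohort, schema = cohort_schema()) {
  if (nrow(cohort) == 0L) abort("`cohort` must be non-empty.")
  genes <- schema$gene_list
  gene_mat <- vapply(genes, function(g) {
    vapply(cohort$mutated_genes, function(s) as.integer(g %in% s), integer(1))
  }, integer(nrow(cohort)))
  gene_mat <- matrix(gene_mat, nrow = nrow(cohort),
                     dimnames = list(NULL, genes))

  path_mat <- NULL
  if (length(schema$pathway_groups)) {
    path_mat <- vapply(schema$pathway_groups, function(members) {
      vapply(cohort$mutated_genes,
             function(s) as.integer(length(intersect(members, s)) > 0L),
             integer(1))
    }, integer(nrow(cohort)))
    path_mat <- matrix(path_mat, nrow = nrow(cohort),
                       dimnames = list(NULL, names(schema$pathway_groups)))
  }

  levs <- schema$karyotype_levels
  kt_mat <- vapply(levs, function(l) as.integer(cohort$karyotype == l),
                   integer(nrow(cohort)))
  kt_mat <- matrix(kt_mat, nrow = nrow(cohort), dimnames = list(NULL, levs))

  soft <- cbind(gene_mat, path_mat)
  dropped <- character(0)
  if (schema$min_feature_frequency > 0) {
    freq <- colMeans(soft)
    dropped <- colnames(soft)[freq < schema$min_feature_frequency]
    if (length(dropped)) {
      inform(paste0("dropped ", length(dropped),
                    " feature(s) below min_feature_frequency: ",
                    paste(dropped, collapse = ", ")))
      soft <- soft[, setdiff(colnames(soft), dropped), drop = FALSE]
    }
  }

  values <- cbind(soft, kt_mat)
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(patient_id = cohort$patient_id), out)
  structure(out, class = c("mds_features", class(tibble::tibble())),
            schema = schema, dropped_features = dropped)
}

#' Extract the numeric feature matrix
#'
#' @param features A `mds_features` tibble from [encode_features()] (or any
#'   data frame with `patient_id` plus numeric 0/1 columns).
#' @return Numeric matrix with patient ids as row names.
#' @export
as_feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "patient_id" %in% names(features))
  m <- as.matrix(features[setdiff(names(features), "patient_id")])
  storage.mode(m) <- "double"
  rownames(m) <- features$patient_id
  m
}

#' Write / read an encoded feature matrix as TSV
#'
#' Plain TSV with a header row and `patient_id` as the first column, so the
#' binary matrix round-trips bit-exactly through text.
#'
#' @param features A `mds_features` tibble.
#' @param path Output TSV path.
#' @return `path` invisibly for the writer; a `mds_features` tibble for the
#'   reader (schema attribute not recoverable from the file).
#' @export
write_features <- function(features, path) {
  readr::write_tsv(tibble::as_tibble(features), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  structure(tbl, class = c("mds_features", class(tibble::tibble())))
}
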