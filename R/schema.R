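# Feature schema: which genes, pathway groupings and karyotype categories are
# turned into binary features.

#' Karyotype categories used by the encoder
#'
#' The eight mutually exclusive cytogenetic categories a patient can carry.
#' `NK` is normal karyotype; `complex` means three or more clonal
#' abnormalities; all remaining abnormalities fall into `other_abnormal`.
#'
#' @return Character vector of the eight category names, in encoding order.
#' @export
karyotype_levels <- function() {
  c("NK", "del5q", "del7q", "del20q", "trisomy8", "delY",
    "complex", "other_abnormal")
}

# Precedence when a raw karyotype string carries several (fewer than three)
# qualifying abnormalities. Complex always wins; otherwise the clinically
# dominant lesion is kept.
karyotype_precedence <- function() {
  c("complex", "del7q", "del5q", "del20q", "trisomy8", "delY", "other_abnormal")
}

#' Default myeloid gene panel
#'
#' A 40-gene targeted panel of recurrently mutated myeloid genes
#' (splicing factors, epigenetic modifiers, transcription factors, signaling
#' and tumor suppressors). Any gene list can be supplied to
#' [cohort_schema()] instead.
#'
#' @return Character vector of 40 gene symbols.
#' @export
mds_gene_panel <- function() {
  c("TET2", "SF3B1", "ASXL1", "SRSF2", "DNMT3A", "RUNX1", "TP53", "U2AF1",
    "ZRSR2", "STAG2", "EZH2", "CBL", "NRAS", "KRAS", "JAK2", "IDH1", "IDH2",
    "BCOR", "BCORL1", "ETV6", "GATA2", "NF1", "PHF6", "PPM1D", "PTPN11",
    "RAD21", "SETBP1", "WT1", "FLT3", "NPM1", "CEBPA", "CUX1", "DDX41",
    "GNAS", "GNB1", "KIT", "MPL", "PRPF8", "RIT1", "SH2B3")
}

#' Alias table mapping raw karyotype strings to categories
#'
#' Lower-cased, trimmed raw strings (common ISCN shorthand and free text) are
#' mapped to one of [karyotype_levels()]. Strings containing several
#' abnormality tokens (separated by `/` or `;`) are resolved by counting:
#' three or more qualifying abnormalities are `complex`, otherwise the fixed
#' precedence complex > del7q > del5q > del20q > trisomy8 > delY >
#' other_abnormal decides.
#'
#' @return Named character vector: names are raw strings, values categories.
#' @export
karyotype_aliases <- function() {
  c("nk" = "NK", "normal" = "NK", "46,xx" = "NK", "46,xy" = "NK",
    "normal karyotype" = "NK",
    "del5q" = "del5q", "del(5q)" = "del5q", "-5" = "del5q", "5q-" = "del5q",
    "del7q" = "del7q", "del(7q)" = "del7q", "-7" = "del7q", "7q-" = "del7q",
    "del20q" = "del20q", "del(20q)" = "del20q", "-20" = "del20q",
    "20q-" = "del20q",
    "trisomy8" = "trisomy8", "+8" = "trisomy8", "trisomy 8" = "trisomy8",
    "dely" = "delY", "-y" = "delY",
    "complex" = "complex",
    "other_abnormal" = "other_abnormal", "other" = "other_abnormal",
    "abnormal" = "other_abnormal")
}

#' Build a feature schema for cohort encoding
#'
#' The schema fixes the ordered gene list, optional pathway groupings (a
#' pathway indicator is 1 when any member gene is mutated), the karyotype
#' category order, and an optional minimum feature frequency below which
#' gene/pathway columns are dropped from the encoded matrix.
#'
#' @param genes Ordered character vector of gene symbols (unique).
#' @param pathways Named list of character vectors; each entry defines one
#'   pathway indicator column named after the list entry. Default: a
#'   `RAS_pathway` group (NRAS, KRAS, PTPN11, CBL, NF1, RIT1).
#' @param min_feature_frequency Gene/pathway columns whose carrier fraction is
#'   below this are dropped (karyotype one-hots are always kept so each row
#'   retains exactly one active category). Default 0 (keep all).
#' @return An object of class `mds_schema`.
#' @examples
#' sch <- cohort_schema(genes = c("TET2", "SF3B1", "TP53"))
#' sch$gene_list
#' @export
cohort_schema <- function(genes = mds_gene_panel(),
                          pathways = list(
                            RAS_pathway = c("NRAS", "KRAS", "PTPN11",
                                            "CBL", "NF1", "RIT1")),
                          min_feature_frequency = 0) {
  genes <- as.character(genes)
  if (length(genes) == 0L) abort("`genes` must be non-empty.")
  if (anyDuplicated(genes)) abort("`genes` must be unique.")
  if (length(pathways)) {
    if (is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
      abort("every entry of `pathways` must be named.")
    }
    clash <- intersect(names(pathways), genes)
    if (length(clash)) {
      abort(paste0("pathway names clash with gene symbols: ",
                   paste(clash, collapse = ", ")))
    }
  }
  check_scalar_number(min_feature_frequency, "min_feature_frequency", 0, 1)
  structure(
    list(gene_list = genes,
         pathway_groups = lapply(pathways, as.character),
         karyotype_levels = karyotype_levels(),
         min_feature_frequency = min_feature_frequency),
    class = "mds_schema")
}

#' @export
print.mds_schema <- function(x, ...) {
  cat("<mds_schema>\n")
  cat("  genes:", length(x$gene_list), "\n")
  cat("  pathways:", if (length(x$pathway_groups))
    paste(names(x$pathway_groups), collapse = ", ") else "(none)", "\n")
  cat("  karyotype levels:", paste(x$karyotype_levels, collapse = ", "), "\n")
  cat("  min feature frequency:", x$min_feature_frequency, "\n")
  invisible(x)
}

# Map raw karyotype strings to the 8 categories. Returns a character vector
# with NA where no mapping exists.
normalize_karyotype <- function(x, aliases = karyotype_aliases()) {
  raw <- trimws(tolower(as.character(x)))
  levs <- karyotype_levels()
  out <- rep(NA_character_, length(raw))

  direct <- match(raw, tolower(levs))
  out[!is.na(direct)] <- levs[direct[!is.na(direct)]]
  hit <- is.na(out) & raw %in% names(aliases)
  out[hit] <- unname(aliases[raw[hit]])

  # multi-abnormality strings: split, map tokens, apply count rule/precedence
  todo <- which(is.na(out) & nzchar(raw))
  for (i in todo) {
    toks <- trimws(strsplit(raw[i], "[/;]")[[1]])
    toks <- toks[nzchar(toks)]
    mapped <- unname(aliases[toks])
    mapped[is.na(mapped)] <- levs[match(toks[is.na(mapped)], tolower(levs))]
    if (any(is.na(mapped)) || length(mapped) == 0L) next
    abn <- setdiff(unique(mapped), "NK")
    if (length(abn) == 0L) {
      out[i] <- "NK"
    } else if (length(abn) >= 3L || "complex" %in% abn) {
      out[i] <- "complex"
    } else {
      prec <- karyotype_precedence()
      out[i] <- prec[min(match(abn, prec))]
    }
  }
  out
}
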