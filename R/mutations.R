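# Mutation tables: TSV reading/writing, validation and region filtering.

#' @keywords internal
MUTATION_COLUMNS <- c("protein_id", "pdb_id", "chain", "position",
                      "wt_aa", "mut_aa", "region", "label")

#' @keywords internal
parse_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ifelse(x %in% c("1", "+1", "disease", "pathogenic"), 1,
  ifelse(x %in% c("-1", "benign", "polymorphism"), -1,
  ifelse(x %in% c("", "na", "nan", "unlabeled", "unlabelled", "."),
         NA_real_, NaN)))
}

#' Read a mutation table
#'
#' Reads a TSV with header columns protein_id, pdb_id, chain, position,
#' wt_aa, mut_aa, region, label. Amino acids may be one- or three-letter
#' codes (normalized to one-letter); labels may be +1/-1, disease/benign or
#' empty (unlabeled). Malformed rows raise an error naming the offending
#' line numbers.
#'
#' @param path TSV file path.
#' @return data.frame with one validated record per row; `label` is +1, -1
#'   or NA.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    out <- data.frame(protein_id = character(0), pdb_id = character(0),
                      chain = character(0), position = integer(0),
                      wt_aa = character(0), mut_aa = character(0),
                      region = character(0), label = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rec <- data.frame(
    protein_id = trimws(df$protein_id),
    pdb_id = trimws(df$pdb_id),
    chain = trimws(df$chain),
    position = suppressWarnings(as.integer(df$position)),
    wt_aa = aa_normalize(df$wt_aa),
    mut_aa = aa_normalize(df$mut_aa),
    region = toupper(trimws(df$region)),
    label = parse_label(df$label),
    stringsAsFactors = FALSE)
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(what, " (line ",
                     paste(which(bad) + 1L, collapse = ", "), ")"))
    }
  }
  flag(is.na(rec$position), "non-integer position")
  flag(is.na(rec$wt_aa), "unrecognized wt_aa")
  flag(is.na(rec$mut_aa), "unrecognized mut_aa")
  flag(!is.na(rec$wt_aa) & !is.na(rec$mut_aa) & rec$wt_aa == rec$mut_aa,
       "wt_aa equals mut_aa")
  flag(!rec$region %in% REGION_CODES, "region code outside {M,L,I,O,S,T}")
  flag(is.nan(rec$label), "unparseable label")
  flag(nchar(rec$chain) != 1, "chain must be a single character")
  if (length(problems) > 0) {
    stop("invalid mutation table rows: ", paste(problems, collapse = "; "))
  }
  rec
}

#' Write a mutation table (inverse of [read_mutation_table()])
#' @param records mutation record data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_mutation_table <- function(records, path) {
  out <- records[, MUTATION_COLUMNS]
  out$label <- ifelse(is.na(out$label), "",
                      sprintf("%+d", as.integer(out$label)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter mutation records by topology region
#'
#' Only mutations in transmembrane regions are modelled by this package; the
#' default keeps code "M" (membrane). Reentrant-loop ("L") and other
#' topology codes can be included explicitly.
#'
#' @param records mutation record data.frame.
#' @param keep non-empty subset of c("M","L","I","O","S","T").
#' @return the order-preserving subset of `records`.
#' @export
filter_by_region <- function(records, keep = "M") {
  stopifnot(length(keep) > 0, all(keep %in% REGION_CODES))
  records[records$region %in% keep, , drop = FALSE]
}
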