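#' Construct an alignment object
#'
#' An alignment is a character matrix of single upper-case bases with one row
#' per individual (rownames are sample ids) and one column per site. All
#' sequences must have identical length; sample ids must be unique.
#'
#' @param seqs Character matrix (rows = samples, columns = sites) or a named
#'   character vector / list of equal-length sequence strings.
#' @param sample_ids Sample identifiers; defaults to names/rownames of `seqs`.
#' @return An object of class `mt_alignment` (a character matrix).
#' @export
mt_alignment <- function(seqs, sample_ids = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) seqs <- as.list(seqs)
  if (is.list(seqs)) {
    if (is.null(sample_ids)) sample_ids <- names(seqs)
    chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
    lens <- lengths(chars)
    if (length(unique(lens)) > 1) {
      bad <- sample_ids[lens != stats::median(lens)]
      abort(paste0(
        "Alignment is ragged: record(s) ",
        paste(bad, collapse = ", "),
        " differ in length (lengths ", paste(unique(lens), collapse = "/"), ")."
      ))
    }
    seqs <- do.call(rbind, chars)
  }
  seqs <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  if (is.null(sample_ids)) sample_ids <- rownames(seqs)
  if (is.null(sample_ids)) sample_ids <- paste0("seq", seq_len(nrow(seqs)))
  if (anyDuplicated(sample_ids)) abort("Sample ids must be unique.")
  if (nrow(seqs) < 1 || ncol(seqs) < 1) abort("Alignment must have n >= 1 and L >= 1.")
  bad <- setdiff(unique(as.vector(seqs)), .DNA_ALPHABET)
  if (length(bad)) {
    abort(paste0("Unknown residue(s) in alignment: ", paste(bad, collapse = ", ")))
  }
  rownames(seqs) <- sample_ids
  colnames(seqs) <- NULL
  structure(seqs, class = c("mt_alignment", "matrix", "array"))
}

#' @export
`[.mt_alignment` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("mt_alignment", "matrix", "array")
  out
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat(sprintf("<mt_alignment> %d sequences x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and U is mapped to T. All records must have the
#' same length; a ragged file is a hard error naming the offending records.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An [mt_alignment()] object.
#' @export
read_alignment <- function(path) {
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE),
    error = function(e) abort(paste0("Cannot read FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(recs) == 0) abort(paste0("FASTA file '", path, "' contains no records."))
  seqs <- vapply(recs, function(x) paste(as.character(x), collapse = ""), character(1))
  mt_alignment(as.list(seqs), sample_ids = names(recs))
}

#' Write an alignment to FASTA (70-column wrapped)
#'
#' @param a An [mt_alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(a, path) {
  lines <- character(0)
  for (i in seq_len(nrow(a))) {
    s <- paste(a[i, ], collapse = "")
    body <- substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s)))
    lines <- c(lines, paste0(">", rownames(a)[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample_id lineage group subgroup`; "." denotes
#' an empty subgroup.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns sample_id, lineage, group, subgroup.
#' @export
read_sample_table <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample_id", "lineage", "group", "subgroup")
  missing <- setdiff(needed, names(s))
  if (length(missing)) {
    abort(paste0("Sample table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(s$sample_id)) abort("Sample ids in sample table must be unique.")
  if (any(is.na(s$lineage) | s$lineage == "")) abort("Every sample needs a non-empty lineage.")
  s$subgroup[is.na(s$subgroup)] <- "."
  s[needed]
}

#' Write a sample metadata table
#' @param s Tibble with sample_id, lineage, group, subgroup.
#' @param path Output path.
#' @export
write_sample_table <- function(s, path) {
  s$subgroup[is.na(s$subgroup) | s$subgroup == ""] <- "."
  readr::write_tsv(s, path)
  invisible(path)
}

#' Usable alignment columns under a missing-data policy
#'
#' Under `complete_deletion` a column is usable only if every record carries
#' an unambiguous base (A/C/G/T); gaps, N and IUPAC ambiguity codes disqualify
#' the column. Under `pairwise_deletion` every column is usable and exclusion
#' happens per sequence pair at comparison time.
#'
#' @param a An [mt_alignment()].
#' @param policy `"complete_deletion"` (default) or `"pairwise_deletion"`.
#' @return Integer vector of 1-based usable column indices.
#' @export
usable_sites <- function(a, policy = c("complete_deletion", "pairwise_deletion")) {
  policy <- match.arg(policy)
  if (policy == "pairwise_deletion") return(seq_len(ncol(a)))
  ok <- matrix(a %in% .DNA_STRICT, nrow = nrow(a))
  sites <- which(colSums(ok) == nrow(a))
  if (length(sites) == 0) {
    abort("No usable sites remain under complete deletion.")
  }
  sites
}

# Logical matrix: which cells hold unambiguous bases.
strict_mask <- function(a) matrix(a %in% .DNA_STRICT, nrow = nrow(a))
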