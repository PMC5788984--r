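#' Collapse aligned sequences into haplotypes
#'
#' Haplotype identity is decided on the usable sites only (see
#' [usable_sites()]): records made identical by excluded columns merge.
#' Haplotypes are ordered by descending total frequency, ties broken by first
#' occurrence in the alignment, and labelled `H1`, `H2`, ... unless a label
#' map is supplied.
#'
#' @param a An [mt_alignment()].
#' @param s Sample table (tibble with `sample_id` and the grouping column).
#'   Samples listed in `s` but absent from the alignment are skipped with a
#'   warning; alignment records absent from `s` are ignored.
#' @param policy Missing-data policy for haplotype identity.
#' @param group_col Column of `s` used for per-group frequencies.
#' @param labels Optional character vector of labels (recycled in rank order).
#' @return A tibble with columns `label`, `sequence` (representative
#'   full-length sequence), `total`, and one frequency column per group, with
#'   attributes `site_mask` (1-based usable columns) and `groups`.
#' @export
collapse_haplotypes <- function(a, s = NULL,
                                policy = c("complete_deletion", "pairwise_deletion"),
                                group_col = "group", labels = NULL) {
  policy <- match.arg(policy)
  if (is.null(s)) {
    s <- tibble(sample_id = rownames(a), lineage = "all", group = "all", subgroup = ".")
  }
  missing <- setdiff(s$sample_id, rownames(a))
  if (length(missing)) {
    warn(paste0(
      "Skipping ", length(missing), " sample(s) absent from the alignment: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
    s <- s[s$sample_id %in% rownames(a), , drop = FALSE]
  }
  if (nrow(s) == 0) abort("No samples shared between alignment and sample table.")
  a <- a[s$sample_id, , drop = FALSE]
  mask <- if (policy == "complete_deletion") usable_sites(a) else seq_len(ncol(a))
  key <- apply(a[, mask, drop = FALSE], 1, paste, collapse = "")
  first <- match(unique(key), key)
  tot <- as.vector(table(key)[unique(key)])
  ord <- order(-tot, first)
  keys <- unique(key)[ord]
  grp <- s[[group_col]]
  groups <- unique(grp)
  freq <- matrix(0L, nrow = length(keys), ncol = length(groups),
                 dimnames = list(NULL, groups))
  for (g in groups) {
    tg <- table(key[grp == g])
    freq[match(names(tg), keys), g] <- as.integer(tg)
  }
  if (is.null(labels)) labels <- paste0("H", seq_along(keys))
  out <- tibble(
    label = labels[seq_along(keys)],
    sequence = apply(a[match(keys, key), , drop = FALSE], 1, paste, collapse = ""),
    total = rowSums(freq)
  )
  out <- dplyr::bind_cols(out, as_tibble(freq))
  attr(out, "site_mask") <- mask
  attr(out, "groups") <- groups
  class(out) <- c("haplotype_tbl", class(out))
  out
}

#' Write a haplotype table to TSV
#' @param ht Result of [collapse_haplotypes()].
#' @param path Output path.
#' @export
write_haplotype_table <- function(ht, path) {
  readr::write_tsv(as_tibble(ht), path)
  invisible(path)
}

# Character matrix of the sequences behind an alignment or haplotype table.
seq_matrix <- function(x) {
  if (inherits(x, "mt_alignment")) return(unclass(x))
  if (is.data.frame(x) && all(c("label", "sequence") %in% names(x))) {
    m <- do.call(rbind, strsplit(x$sequence, ""))
    rownames(m) <- x$label
    return(m)
  }
  abort("Expected an mt_alignment or a haplotype table.")
}

#' Pairwise mutation-step (difference) matrix
#'
#' Counts differing sites between every pair of sequences. Under
#' `complete_deletion`, comparison is restricted to columns unambiguous in
#' every record; under `pairwise_deletion` each pair is compared on the
#' columns unambiguous in both members.
#'
#' @param x An [mt_alignment()] or a haplotype table.
#' @param policy Missing-data policy.
#' @return A symmetric integer matrix with zero diagonal, labelled by sample
#'   id or haplotype label.
#' @export
pairwise_diff_matrix <- function(x, policy = c("complete_deletion", "pairwise_deletion")) {
  policy <- match.arg(policy)
  m <- seq_matrix(x)
  ok <- matrix(m %in% .DNA_STRICT, nrow = nrow(m))
  if (policy == "complete_deletion") {
    keep <- colSums(ok) == nrow(m)
    if (!any(keep)) abort("No usable sites remain under complete deletion.")
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  # matches via one-hot encoding; BLAS does the pair loop
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in .DNA_STRICT) {
    xb <- (m == b) * 1
    matches <- matches + tcrossprod(xb)
  }
  compared <- tcrossprod(ok * 1)
  d <- round(compared - matches)
  storage.mode(d) <- "integer"
  diag(d) <- 0L
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
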