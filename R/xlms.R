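#' Cross-link sets from monomer- and dimer-enriched fractions
#'
#' `crosslinks()` canonicalises a table of residue-pair cross-links
#' (position1 <= position2, residues carried along) so links can be
#' compared across samples by their position pair. `read_crosslinks()`
#' reads the documented CSV dialect: columns `pos1`, `res1`, `pos2`,
#' `res2`, `sample`, optional `score`; header required.
#'
#' @param df data.frame with columns `pos1`, `res1`, `pos2`, `res2`, and
#'   optionally `sample`, `score`.
#' @param sample optional sample label applied to all rows.
#' @return data.frame of class `crosslinks` (canonical ordering, duplicate
#'   position pairs collapsed).
#' @export
crosslinks <- function(df, sample = NULL) {
  df <- as.data.frame(df)
  stopifnot(all(c("pos1", "res1", "pos2", "res2") %in% names(df)))
  if (!is.null(sample)) df$sample <- sample
  if (is.null(df$sample)) df$sample <- NA_character_
  if (is.null(df$score)) df$score <- NA_real_
  swap <- df$pos1 > df$pos2
  tmp_p <- df$pos1[swap]; df$pos1[swap] <- df$pos2[swap]
  df$pos2[swap] <- tmp_p
  tmp_r <- df$res1[swap]; df$res1[swap] <- df$res2[swap]
  df$res2[swap] <- tmp_r
  df$res1 <- toupper(df$res1); df$res2 <- toupper(df$res2)
  key <- paste(df$pos1, df$pos2, sep = "-")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$pos1, df$pos2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("crosslinks", "data.frame")
  df
}

#' @rdname crosslinks
#' @param path CSV file.
#' @export
read_crosslinks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("pos1", "res1", "pos2", "res2", "sample"), names(df))
  if (length(missing))
    stop("cross-link table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  crosslinks(df)
}

#' Chemically admissible residue pairs for amine-reactive cross-linking
#'
#' BS3-style NHS-ester chemistry links lysines to lysine, serine, tyrosine
#' or threonine; the admissible unordered residue pairs are K-K, K-S, K-Y
#' and K-T.
#'
#' @param res1,res2 1-letter residue codes (vectorised).
#' @return Logical vector.
#' @examples
#' is_linkable("K", "K")  # TRUE
#' is_linkable("S", "K")  # TRUE, order-insensitive
#' is_linkable("K", "R")  # FALSE
#' @export
is_linkable <- function(res1, res2) {
  res1 <- toupper(res1); res2 <- toupper(res2)
  ok <- c("S", "Y", "T", "K")
  (res1 == "K" & res2 %in% ok) | (res2 == "K" & res1 %in% ok)
}

.xl_key <- function(links) paste(links$pos1, links$pos2, sep = "-")

#' Classify links by their fraction of origin
#'
#' Links found only in the monomer-enriched fraction are putative
#' intra-molecular contacts; links unique to the dimer-enriched fraction
#' are putative inter-molecular contacts; links present in both are
#' reported as `shared`. The three sets are disjoint and exhaustive over
#' the union of inputs (link identity is the canonical position pair).
#'
#' @param monomer_links,dimer_links [crosslinks()] tables.
#' @return Object of class `xl_classification`: list with `intra`, `inter`,
#'   `shared` crosslink tables.
#' @export
classify_by_sample <- function(monomer_links, dimer_links) {
  m <- crosslinks(monomer_links); d <- crosslinks(dimer_links)
  mk <- .xl_key(m); dk <- .xl_key(d)
  out <- list(intra = m[!mk %in% dk, , drop = FALSE],
              inter = d[!dk %in% mk, , drop = FALSE],
              shared = m[mk %in% dk, , drop = FALSE])
  out <- lapply(out, function(x) { rownames(x) <- NULL; x })
  structure(out, class = "xl_classification")
}

#' @export
print.xl_classification <- function(x, ...) {
  cat("<xl_classification> intra:", nrow(x$intra), " inter:", nrow(x$inter),
      " shared:", nrow(x$shared), "\n")
  invisible(x)
}

#' Enforce that self-links are inter-molecular
#'
#' A cross-link between the same residue position on both peptides (e.g. a
#' lysine bridged to the identical lysine) is only possible between two
#' copies of the protein, so it is necessarily inter-molecular. Self-links
#' are annotated accordingly; any self-link classified in the
#' monomer-unique (intra) set is reported as an inconsistency.
#'
#' @param classification an [classify_by_sample()] result.
#' @return The classification with a `self_link`/`inter_molecular`
#'   annotation added to each table and an `inconsistencies` data.frame
#'   attached (zero rows when clean). A warning is emitted for
#'   inconsistencies; they are never silently dropped.
#' @export
assert_self_links_inter <- function(classification) {
  stopifnot(inherits(classification, "xl_classification"))
  annotate <- function(x, forced_inter) {
    x$self_link <- x$pos1 == x$pos2
    x$inter_molecular <- forced_inter | x$self_link
    x
  }
  classification$intra <- annotate(classification$intra, FALSE)
  classification$inter <- annotate(classification$inter, TRUE)
  classification$shared <- annotate(classification$shared, FALSE)
  bad <- classification$intra[classification$intra$self_link, , drop = FALSE]
  attr(classification, "inconsistencies") <- bad
  if (nrow(bad))
    warning(nrow(bad), " self-link(s) in the monomer-unique set are ",
            "inconsistent with an intra-molecular assignment (positions: ",
            paste(bad$pos1, collapse = ", "), ")")
  classification
}

#' Region-by-region contact matrix of cross-links
#'
#' Counts classified links by the annotated regions containing their two
#' endpoints. Overlapping regions are resolved by the first-by-start rule;
#' links with an endpoint in no region are dropped from the matrix. The
#' matrix is symmetric and its total equals the number of links with both
#' endpoints in annotated regions.
#'
#' @param links a [crosslinks()] table.
#' @param regions data.frame with `label`, `start`, `end`.
#' @return Symmetric integer matrix (regions x regions) of class
#'   `contact_matrix`.
#' @export
contact_matrix <- function(links, regions) {
  regions <- regions[order(regions$start), , drop = FALSE]
  labels <- regions$label
  assign_region <- function(pos) {
    hit <- which(pos >= regions$start & pos <= regions$end)
    if (length(hit)) labels[hit[1L]] else NA_character_
  }
  mat <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (i in seq_len(nrow(links))) {
    r1 <- assign_region(links$pos1[i]); r2 <- assign_region(links$pos2[i])
    if (is.na(r1) || is.na(r2)) next
    mat[r1, r2] <- mat[r1, r2] + 1L
    if (r1 != r2) mat[r2, r1] <- mat[r2, r1] + 1L
  }
  structure(mat, class = c("contact_matrix", class(mat)))
}

#' Concordance of inter-molecular links with HDX-protected regions
#'
#' Fraction of inter-molecular cross-links with at least one endpoint
#' within `window` residues of any protected region (as called by
#' [call_protected_regions()] or supplied as a `start`/`end` data.frame).
#'
#' @param inter_links a [crosslinks()] table of inter-molecular links.
#' @param protected_regions data.frame with `start`, `end`.
#' @param window slack in residues (default 0).
#' @return Fraction in \[0, 1\] (0 when there are no protected regions;
#'   `NaN` never returned — zero links give 0).
#' @export
hdx_concordance <- function(inter_links, protected_regions, window = 0L) {
  stopifnot(window >= 0)
  if (nrow(inter_links) == 0L) return(0)
  if (is.null(protected_regions) || nrow(protected_regions) == 0L) return(0)
  near <- function(pos) {
    any(pos >= protected_regions$start - window &
          pos <= protected_regions$end + window)
  }
  hits <- vapply(seq_len(nrow(inter_links)), function(i)
    near(inter_links$pos1[i]) || near(inter_links$pos2[i]), logical(1))
  mean(hits)
}
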