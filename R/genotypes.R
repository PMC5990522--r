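#' Call ternary genotypes from allele depths
#'
#' For every (cell, somatic event) pair, calls `missing` when the total
#' depth is below `min_total` (no data available), `present` when the
#' alternate depth reaches `min_alt` AND the VAF reaches `min_vaf`, and
#' `absent` otherwise. The depth rule follows the convention that fewer than
#' 10 reads carry no usable information at an amplicon; the presence rule
#' additionally guards against single stray reads, which are
#' indistinguishable from amplification error.
#'
#' @param matrix An `allele_depth_matrix`, normally QC-filtered.
#' @param min_total Total depth below which the call is missing (default 10).
#' @param min_alt Minimum alternate reads for a presence call (default 2).
#' @param min_vaf Minimum VAF for a presence call (default 0.10).
#' @return A `genotype_matrix`: integer matrix (cells x somatic events) with
#'   1 = present, 0 = absent, `NA` = missing, and a `compartment` attribute.
#' @export
call_genotypes <- function(matrix, min_total = 10, min_alt = 2,
                           min_vaf = 0.10) {
  loci <- intersect(somatic_loci(matrix$panel), colnames(matrix$ref))
  if (length(loci) == 0) stop_fmt("panel has no somatic loci in matrix")
  ref <- matrix$ref[, loci, drop = FALSE]
  alt <- matrix$alt[, loci, drop = FALSE]
  tot <- ref + alt
  g <- matrix(0L, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  g[alt >= min_alt & tot > 0 & alt / pmax(tot, 1L) >= min_vaf] <- 1L
  g[tot < min_total] <- NA_integer_
  genotype_matrix(g, matrix$cells$compartment)
}

#' Construct a genotype matrix
#'
#' @param g Integer matrix (cells x events), entries 1 (present), 0
#'   (absent) or `NA` (missing); needs cell_id rownames and event colnames.
#' @param compartment Per-cell labels, recycled if length 1.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(g, compartment = "unknown") {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (!all(g %in% c(0L, 1L, NA_integer_)))
    stop_fmt("genotype entries must be 0, 1 or NA")
  if (nrow(g) > 0 && (is.null(rownames(g)) || is.null(colnames(g))))
    stop_fmt("genotype matrix needs cell_id rownames and event colnames")
  structure(g, compartment = rep_len(as.character(compartment), nrow(g)),
            class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d cells x %d somatic events\n",
              nrow(x), ncol(x)))
  cat(sprintf("  present %.1f%%, absent %.1f%%, missing %.1f%%\n",
              100 * mean(x == 1L, na.rm = TRUE) * (1 - mean(is.na(x))),
              100 * mean(x == 0L, na.rm = TRUE) * (1 - mean(is.na(x))),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Write / read a genotype matrix
#'
#' Tab-separated wide format: `cell_id`, `compartment`, then one column per
#' event holding the tokens `present`, `absent` or `missing` (missing is a
#' dedicated token, never an empty string). `read_genotype_matrix` is the
#' exact inverse: `read(write(g))` equals `g`.
#'
#' @param g A `genotype_matrix`.
#' @param path File path.
#' @return `write_genotype_matrix`: `path` invisibly;
#'   `read_genotype_matrix`: a `genotype_matrix`.
#' @export
write_genotype_matrix <- function(g, path) {
  df <- data.frame(cell_id = rownames(g) %||% character(0),
                   compartment = attr(g, "compartment"),
                   stringsAsFactors = FALSE)
  for (ev in colnames(g)) df[[ev]] <- gt_to_token(g[, ev])
  if (nrow(g) == 0) {
    # header-only file still needs the event columns
    df <- df[0, c("cell_id", "compartment", colnames(g)), drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("cell_id", "compartment") %in% names(df)))
    stop_fmt("genotype file %s: need cell_id and compartment columns", path)
  evs <- setdiff(names(df), c("cell_id", "compartment"))
  g <- matrix(NA_integer_, nrow(df), length(evs),
              dimnames = list(df$cell_id, evs))
  for (ev in evs) g[, ev] <- token_to_gt(df[[ev]])
  genotype_matrix(g, if (nrow(df) > 0) df$compartment else "unknown")
}

#' Jaccard distance between two cell genotype vectors
#'
#' Restricted to events non-missing in both cells:
#' `d = 1 - |present in both| / |present in either|`. Two cells with no
#' present events among their shared informative events are identical
#' (d = 0); cells sharing no informative events at all get d = 1, flagged
#' via attribute `"no_overlap"`.
#'
#' @param g1,g2 Integer vectors (1/0/NA) over the same events.
#' @return Distance in \[0, 1\].
#' @export
jaccard_distance <- function(g1, g2) {
  if (length(g1) != length(g2)) stop_fmt("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(structure(1, no_overlap = TRUE))
  a <- g1[ok] == 1L; b <- g2[ok] == 1L
  uni <- sum(a | b)
  if (uni == 0) return(0)
  1 - sum(a & b) / uni
}

#' Pairwise Jaccard distance matrix over cells
#'
#' Vectorised pairwise-complete version of [jaccard_distance()]: each pair
#' uses only the events observed in both cells. Pairs with no shared
#' informative events get distance 1 and are counted in attribute
#' `"n_no_overlap"`.
#'
#' @param g A `genotype_matrix`.
#' @return Symmetric numeric matrix of distances (zero diagonal).
#' @export
jaccard_matrix <- function(g) {
  P <- matrix(as.numeric(!is.na(g) & g == 1L), nrow(g), ncol(g))
  O <- matrix(as.numeric(!is.na(g)), nrow(g), ncol(g))
  inter <- tcrossprod(P)                      # present in both (both observed)
  PO <- tcrossprod(P, O)                      # present in i, observed in j
  uni <- PO + t(PO) - inter                   # present in either, both observed
  shared <- tcrossprod(O)                     # events observed in both
  d <- 1 - inter / uni
  d[uni == 0] <- 0                            # no presents among shared events
  no_ov <- shared == 0
  d[no_ov] <- 1                               # no shared informative events
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  attr(d, "n_no_overlap") <- (sum(no_ov) - sum(diag(no_ov))) / 2
  d
}
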