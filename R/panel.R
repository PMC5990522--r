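#' Read a variant panel
#'
#' A variant panel catalogues the targeted amplicons: somatic events (SNVs,
#' indels, fusions, deletions) that define the tumor genotype, and
#' heterozygous germline SNPs used exclusively for per-cell quality control.
#'
#' The file is tab-separated with a header naming at least `locus_id`,
#' `class` (`somatic` or `germline_het`) and `event_type` (`SNV`, `indel`,
#' `fusion`, `deletion` or `other`). Optional columns: `chrom`, `pos`
#' (1-based, as in VCF; empty for fusions/deletions, which are identified by
#' `locus_id` alone) and `label`.
#'
#' @param path Path to a tab-separated panel file.
#' @return A `variant_panel`: a data frame with one row per locus, entry
#'   order preserved, plus class attribute.
#' @seealso [read_depth_matrix()], [write_panel()]
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("locus_id", "class", "event_type")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop_fmt("panel %s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_fmt("panel %s: no entries", path)
  as_variant_panel(df, where = path)
}

#' Construct and validate a variant panel from a data frame
#'
#' @param df Data frame with columns `locus_id`, `class`, `event_type` and
#'   optionally `chrom`, `pos`, `label`.
#' @param where Label used in error messages.
#' @return A validated `variant_panel`.
#' @export
as_variant_panel <- function(df, where = "panel") {
  if (nrow(df) == 0) stop_fmt("%s: no entries", where)
  dup <- df$locus_id[duplicated(df$locus_id)]
  if (length(dup) > 0)
    stop_fmt("%s: duplicate locus_id: %s", where, paste(unique(dup), collapse = ", "))
  ok_class <- c("somatic", "germline_het")
  bad <- which(!df$class %in% ok_class)
  if (length(bad) > 0)
    stop_fmt("%s: unknown class token '%s' (line %d)", where, df$class[bad[1]],
             bad[1] + 1L)
  ok_type <- c("SNV", "indel", "fusion", "deletion", "other")
  bad <- which(!df$event_type %in% ok_type)
  if (length(bad) > 0)
    stop_fmt("%s: unknown event_type token '%s' (line %d)", where,
             df$event_type[bad[1]], bad[1] + 1L)
  if (is.null(df$chrom)) df$chrom <- NA_character_
  if (is.null(df$label)) df$label <- df$locus_id
  df$pos <- if (is.null(df$pos)) NA_integer_ else {
    suppressWarnings(as.integer(df$pos))
  }
  df <- df[, c("locus_id", "class", "event_type", "chrom", "pos", "label")]
  rownames(df) <- NULL
  class(df) <- c("variant_panel", "data.frame")
  df
}

#' Write a variant panel to a tab-separated file
#'
#' @param panel A `variant_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.variant_panel <- function(x, ...) {
  n_som <- sum(x$class == "somatic")
  n_ger <- sum(x$class == "germline_het")
  cat(sprintf("Variant panel: %d loci (%d somatic, %d germline het SNPs)\n",
              nrow(x), n_som, n_ger))
  tab <- table(x$event_type[x$class == "somatic"])
  if (length(tab) > 0)
    cat("  somatic types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

somatic_loci <- function(panel) panel$locus_id[panel$class == "somatic"]
germline_loci <- function(panel) panel$locus_id[panel$class == "germline_het"]
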