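#' Construct an allele-depth matrix
#'
#' The central container for targeted single-cell amplicon counts: one
#' reference and one alternate read count per (cell, locus) pair, plus an
#' optional compartment label per cell (`blast`, `cd34_progenitor`,
#' `remission` or `unknown`).
#'
#' @param ref,alt Integer matrices (cells x loci) of reference / alternate
#'   read depths; identical dimnames required.
#' @param panel A `variant_panel`; every column name must resolve to a panel
#'   locus.
#' @param compartment Character vector of per-cell labels, recycled if
#'   length 1.
#' @return An `allele_depth_matrix` (list with `ref`, `alt`, `cells`,
#'   `panel`).
#' @export
allele_depth_matrix <- function(ref, alt, panel,
                                compartment = "unknown") {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop_fmt("ref and alt depth matrices must have identical dimensions")
  if (is.null(rownames(ref)) || is.null(colnames(ref)))
    stop_fmt("depth matrices need cell_id rownames and locus_id colnames")
  if (!identical(dimnames(ref), dimnames(alt)))
    stop_fmt("ref and alt depth matrices must have identical dimnames")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0))
    stop_fmt("allele depths must be non-negative integers")
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  unknown <- setdiff(colnames(ref), panel$locus_id)
  if (length(unknown) > 0)
    stop_fmt("locus_id not in panel: %s", paste(unknown, collapse = ", "))
  compartment <- rep_len(as.character(compartment), nrow(ref))
  ok <- c("blast", "cd34_progenitor", "remission", "unknown")
  if (!all(compartment %in% ok))
    stop_fmt("unknown compartment label(s): %s",
             paste(setdiff(compartment, ok), collapse = ", "))
  structure(list(
    ref = ref, alt = alt,
    cells = data.frame(cell_id = rownames(ref), compartment = compartment,
                       stringsAsFactors = FALSE),
    panel = panel
  ), class = "allele_depth_matrix")
}

#' @export
print.allele_depth_matrix <- function(x, ...) {
  cat(sprintf("Allele-depth matrix: %d cells x %d loci\n",
              nrow(x$ref), ncol(x$ref)))
  tab <- table(x$cells$compartment)
  cat("  compartments:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  median total depth: %.0f\n", stats::median(x$ref + x$alt)))
  invisible(x)
}

#' @export
dim.allele_depth_matrix <- function(x) dim(x$ref)

#' Subset an allele-depth matrix by cells and/or loci
#' @param x An `allele_depth_matrix`.
#' @param cells,loci Character vectors (ids) or index vectors; `NULL` keeps all.
#' @return An `allele_depth_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, loci = NULL) {
  if (is.null(cells)) cells <- rownames(x$ref)
  if (is.null(loci)) loci <- colnames(x$ref)
  idx <- if (is.character(cells)) match(cells, rownames(x$ref)) else cells
  allele_depth_matrix(x$ref[idx, loci, drop = FALSE],
                      x$alt[idx, loci, drop = FALSE],
                      x$panel,
                      x$cells$compartment[idx])
}

#' Read an allele-depth matrix from a tab-separated file
#'
#' Two dialects are auto-detected from the header. Long format has columns
#' `cell_id`, `locus_id`, `ref_depth`, `alt_depth` and optionally
#' `compartment`. Wide format has `cell_id`, optionally `compartment`, and a
#' pair of columns `<locus>.ref` / `<locus>.alt` per locus. Pairs absent
#' from a long-format file are filled with depth 0/0 (amplicon failure is
#' expected); the number of fill-ins is recorded in the `"fill_ins"`
#' attribute.
#'
#' @param path Path to the file.
#' @param panel A `variant_panel`; every locus in the file must be listed.
#' @return An `allele_depth_matrix` with attribute `fill_ins`.
#' @export
read_depth_matrix <- function(path, panel) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (all(c("cell_id", "locus_id", "ref_depth", "alt_depth") %in% header)) {
    read_depth_long(path, panel)
  } else if ("cell_id" %in% header && any(grepl("\\.ref$", header))) {
    read_depth_wide(path, panel)
  } else {
    stop_fmt("depth file %s: unrecognised header dialect", path)
  }
}

read_depth_long <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- which(df$ref_depth < 0 | df$alt_depth < 0)
  if (length(bad) > 0)
    stop_fmt("negative depth for cell %s, locus %s",
             df$cell_id[bad[1]], df$locus_id[bad[1]])
  unknown <- setdiff(unique(df$locus_id), panel$locus_id)
  if (length(unknown) > 0)
    stop_fmt("locus_id not in panel: %s", paste(unknown, collapse = ", "))
  cells <- sort(unique(df$cell_id))
  loci <- panel$locus_id
  ref <- matrix(0L, length(cells), length(loci), dimnames = list(cells, loci))
  alt <- ref
  i <- cbind(match(df$cell_id, cells), match(df$locus_id, loci))
  if (anyDuplicated(paste(df$cell_id, df$locus_id)))
    stop_fmt("duplicate (cell_id, locus_id) rows in %s", path)
  ref[i] <- as.integer(df$ref_depth)
  alt[i] <- as.integer(df$alt_depth)
  comp <- if ("compartment" %in% names(df)) {
    vapply(cells, function(cl) df$compartment[match(cl, df$cell_id)], "")
  } else "unknown"
  out <- allele_depth_matrix(ref, alt, panel, comp)
  attr(out, "fill_ins") <- length(cells) * length(loci) - nrow(df)
  out
}

read_depth_wide <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ref_cols <- grep("\\.ref$", names(df), value = TRUE)
  loci <- sub("\\.ref$", "", ref_cols)
  alt_cols <- paste0(loci, ".alt")
  miss <- setdiff(alt_cols, names(df))
  if (length(miss) > 0)
    stop_fmt("wide depth file %s: missing column(s) %s", path,
             paste(miss, collapse = ", "))
  ref <- as.matrix(df[, ref_cols, drop = FALSE])
  alt <- as.matrix(df[, alt_cols, drop = FALSE])
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    bad <- which(ref < 0 | alt < 0, arr.ind = TRUE)[1, ]
    stop_fmt("negative depth for cell %s, locus %s",
             df$cell_id[bad[1]], loci[bad[2]])
  }
  fill <- sum(is.na(ref)) + sum(is.na(alt))
  ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
  dimnames(ref) <- dimnames(alt) <- list(df$cell_id, loci)
  ord <- order(df$cell_id)
  comp <- if ("compartment" %in% names(df)) df$compartment[ord] else "unknown"
  out <- allele_depth_matrix(ref[ord, , drop = FALSE], alt[ord, , drop = FALSE],
                             panel, comp)
  attr(out, "fill_ins") <- fill
  out
}

#' Write an allele-depth matrix as a long-format TSV
#'
#' @param x An `allele_depth_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_matrix <- function(x, path) {
  cells <- rownames(x$ref); loci <- colnames(x$ref)
  df <- data.frame(
    cell_id = rep(cells, times = length(loci)),
    locus_id = rep(loci, each = length(cells)),
    ref_depth = as.vector(x$ref),
    alt_depth = as.vector(x$alt),
    compartment = rep(x$cells$compartment, times = length(loci)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cell_id, df$locus_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bulk VAF table
#'
#' Tab-separated file with columns `locus_id` and `vaf` (fractions in
#' \[0, 1\]).
#'
#' @param path Path to the file.
#' @return Named numeric vector of VAFs.
#' @export
read_bulk_vaf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "vaf") %in% names(df)))
    stop_fmt("bulk VAF file %s: need columns locus_id, vaf", path)
  if (any(df$vaf < 0 | df$vaf > 1))
    stop_fmt("bulk VAF outside [0,1] for locus %s",
             df$locus_id[which(df$vaf < 0 | df$vaf > 1)[1]])
  stats::setNames(df$vaf, df$locus_id)
}

#' Export somatic panel loci as a minimal VCFv4.2 file
#'
#' Interoperability export: SNVs and indels are written as ordinary records
#' (REF/ALT taken from the panel label when parseable, `N` placeholders
#' otherwise); fusions and deletions become symbolic-ALT records
#' (`<FUS>`, `<DEL>`). Pooled single-cell VAFs are written to the INFO
#' field when a depth matrix is supplied. Loci without coordinates sort last
#' on a synthetic contig.
#'
#' @param panel A `variant_panel`.
#' @param path Output path.
#' @param matrix Optional `allele_depth_matrix` used to annotate pooled VAFs.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, matrix = NULL) {
  som <- panel[panel$class == "somatic", , drop = FALSE]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=clonetrace",
    "##ALT=<ID=FUS,Description=\"Gene fusion detected by targeted amplicon\">",
    "##ALT=<ID=DEL,Description=\"Deletion detected by targeted amplicon\">",
    "##INFO=<ID=SCVAF,Number=1,Type=Float,Description=\"Pooled single-cell VAF\">",
    "##INFO=<ID=EVT,Number=1,Type=String,Description=\"Panel event type\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- vapply(seq_len(nrow(som)), function(i) {
    e <- som[i, ]
    alt <- switch(e$event_type, fusion = "<FUS>", deletion = "<DEL>", "N")
    info <- sprintf("EVT=%s", e$event_type)
    if (!is.null(matrix) && e$locus_id %in% colnames(matrix$ref)) {
      v <- aggregate_vaf(matrix, e$locus_id)
      if (!is.na(v)) info <- sprintf("%s;SCVAF=%.4f", info, v)
    }
    sprintf("%s\t%s\t%s\tN\t%s\t.\t.\t%s",
            ifelse(is.na(e$chrom), "NA", e$chrom),
            ifelse(is.na(e$pos), "0", as.character(e$pos)),
            e$locus_id, alt, info)
  }, "")
  writeLines(c(lines, rows), path)
  invisible(path)
}
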