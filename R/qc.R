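#' Per-cell locus drop-out rate
#'
#' Fraction of germline heterozygous SNPs in one cell whose total read depth
#' (ref + alt) falls below `min_reads`. Locus drop-out (LDO) indicates
#' regions of the single-cell genome that failed to amplify.
#'
#' @param ref,alt Integer vectors of per-SNP depths for one cell, restricted
#'   to germline heterozygous SNPs.
#' @param min_reads Minimum total depth for a SNP to count as covered
#'   (default 4, i.e. SNPs with fewer than 4 reads are dropped-out).
#' @return Fraction in \[0, 1\].
#' @export
locus_dropout_rate <- function(ref, alt, min_reads = 4) {
  if (length(ref) == 0)
    stop_fmt("QC undefined: no germline heterozygous SNPs available")
  mean(ref + alt < min_reads)
}

#' Per-cell allelic drop-out rate
#'
#' Among germline heterozygous SNPs with total depth at least `min_reads`,
#' the fraction whose minor-allele fraction `min(VAF, 1 - VAF)` falls below
#' `minor_frac`: a truly heterozygous SNP reading as (near-)homozygous means
#' one allele failed to amplify. Returns 0 when no SNP reaches `min_reads`.
#'
#' @inheritParams locus_dropout_rate
#' @param minor_frac Minor-allele fraction below which a covered SNP counts
#'   as allelic drop-out (default 0.10).
#' @return Fraction in \[0, 1\].
#' @export
allelic_dropout_rate <- function(ref, alt, min_reads = 4, minor_frac = 0.10) {
  if (length(ref) == 0)
    stop_fmt("QC undefined: no germline heterozygous SNPs available")
  tot <- ref + alt
  covered <- tot >= min_reads
  if (!any(covered)) return(0)
  vaf <- alt[covered] / tot[covered]
  mean(pmin(vaf, 1 - vaf) < minor_frac)
}

#' Per-cell combined drop-out rate
#'
#' Fraction of germline heterozygous SNPs affected by locus drop-out OR
#' allelic drop-out — a per-SNP union, each SNP counted once. Locus drop-out
#' takes precedence: ADO is undefined below `min_reads`.
#'
#' @inheritParams allelic_dropout_rate
#' @return Fraction in \[0, 1\].
#' @export
combined_dropout_rate <- function(ref, alt, min_reads = 4, minor_frac = 0.10) {
  if (length(ref) == 0)
    stop_fmt("QC undefined: no germline heterozygous SNPs available")
  tot <- ref + alt
  ldo <- tot < min_reads
  vaf <- ifelse(tot > 0, alt / tot, 0)
  ado <- !ldo & pmin(vaf, 1 - vaf) < minor_frac
  mean(ldo | ado)
}

#' Per-cell quality-control table
#'
#' Computes LDO, ADO and combined drop-out rates on the panel's germline
#' heterozygous SNPs for every cell, and flags cells passing the combined
#' cutoff (strict `<`).
#'
#' @param matrix An `allele_depth_matrix` whose panel contains germline
#'   heterozygous SNPs.
#' @param min_reads,minor_frac See [locus_dropout_rate()],
#'   [allelic_dropout_rate()].
#' @param max_combined Cells with combined rate strictly below this pass QC
#'   (default 1/3).
#' @return Data frame (class `cell_qc`) with one row per cell: `cell_id`,
#'   `compartment`, `n_snps_evaluated`, `ldo_rate`, `ado_rate`,
#'   `combined_rate`, `passed`.
#' @export
cell_qc <- function(matrix, min_reads = 4, minor_frac = 0.10,
                    max_combined = 1 / 3) {
  snps <- germline_loci(matrix$panel)
  snps <- intersect(snps, colnames(matrix$ref))
  if (length(snps) == 0)
    stop_fmt("QC undefined: no germline heterozygous SNPs in matrix")
  ref <- matrix$ref[, snps, drop = FALSE]
  alt <- matrix$alt[, snps, drop = FALSE]
  n <- nrow(ref)
  ldo <- ado <- comb <- numeric(n)
  for (i in seq_len(n)) {
    ldo[i] <- locus_dropout_rate(ref[i, ], alt[i, ], min_reads)
    ado[i] <- allelic_dropout_rate(ref[i, ], alt[i, ], min_reads, minor_frac)
    comb[i] <- combined_dropout_rate(ref[i, ], alt[i, ], min_reads, minor_frac)
  }
  out <- data.frame(
    cell_id = rownames(ref),
    compartment = matrix$cells$compartment,
    n_snps_evaluated = length(snps),
    ldo_rate = ldo, ado_rate = ado, combined_rate = comb,
    passed = comb < max_combined,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cell_qc", "data.frame")
  out
}

#' Filter low-quality cells on combined drop-out
#'
#' Retains cells whose combined LDO+ADO rate on the germline heterozygous
#' SNPs is strictly below `max_combined` (default: less than one-third of
#' SNPs affected). Retention percentages per compartment are attached as
#' attribute `"retention"`.
#'
#' @inheritParams cell_qc
#' @return List with `matrix` (retained `allele_depth_matrix`) and `qc`
#'   (the full `cell_qc` table for all input cells).
#' @export
filter_cells <- function(matrix, min_reads = 4, minor_frac = 0.10,
                         max_combined = 1 / 3) {
  qc <- cell_qc(matrix, min_reads, minor_frac, max_combined)
  keep <- which(qc$passed)
  retained <- if (length(keep) > 0) {
    subset_cells(matrix, cells = keep)
  } else NULL
  ret <- vapply(split(qc$passed, qc$compartment),
                function(p) 100 * mean(p), numeric(1))
  attr(qc, "retention") <- ret
  list(matrix = retained, qc = qc)
}

#' Pooled single-cell VAF at one locus
#'
#' Sum of alternate depths over cells divided by the summed total depth —
#' the single-cell analogue of a bulk VAF.
#'
#' @param matrix An `allele_depth_matrix` (normally already QC-filtered).
#' @param locus_id A locus present in the matrix.
#' @return Fraction, or `NA` when the pooled depth is zero.
#' @export
aggregate_vaf <- function(matrix, locus_id) {
  if (!locus_id %in% colnames(matrix$ref))
    stop_fmt("unknown locus: %s", locus_id)
  num <- sum(matrix$alt[, locus_id])
  den <- num + sum(matrix$ref[, locus_id])
  if (den == 0) return(NA_real_)
  num / den
}

#' Compare bulk and pooled single-cell VAFs
#'
#' One row per somatic locus shared between the bulk table and the matrix,
#' with the difference (single-cell minus bulk) and a Spearman rank
#' correlation summary over the shared loci. Consistently negative
#' differences indicate normal-cell admixture diluting the single-cell VAFs.
#'
#' @param bulk Named numeric vector of bulk VAFs (see [read_bulk_vaf()]).
#' @param matrix An `allele_depth_matrix`.
#' @return Data frame with columns `locus_id`, `bulk_vaf`, `sc_vaf`,
#'   `difference`; attributes `correlation` (Spearman, `NA` when fewer than
#'   3 shared loci with defined VAFs) and `n_shared`.
#' @export
vaf_concordance <- function(bulk, matrix) {
  shared <- intersect(names(bulk),
                      intersect(somatic_loci(matrix$panel), colnames(matrix$ref)))
  if (length(shared) == 0) stop_fmt("no shared somatic loci between bulk and matrix")
  sc <- vapply(shared, function(l) aggregate_vaf(matrix, l), numeric(1))
  out <- data.frame(locus_id = shared, bulk_vaf = unname(bulk[shared]),
                    sc_vaf = unname(sc),
                    difference = unname(sc - bulk[shared]),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$sc_vaf)
  attr(out, "correlation") <- if (sum(ok) >= 3) {
    suppressWarnings(stats::cor(out$bulk_vaf[ok], out$sc_vaf[ok],
                                method = "spearman"))
  } else NA_real_
  attr(out, "n_shared") <- length(shared)
  out
}

#' @export
print.cell_qc <- function(x, ...) {
  cat(sprintf("Cell QC: %d cells, %d germline SNPs; %d passed (%.1f%%)\n",
              nrow(x), x$n_snps_evaluated[1], sum(x$passed),
              100 * mean(x$passed)))
  cat(sprintf("  median LDO %.3f, ADO %.3f, combined %.3f\n",
              stats::median(x$ldo_rate), stats::median(x$ado_rate),
              stats::median(x$combined_rate)))
  invisible(x)
}

#' Drop-out histograms for a QC table
#'
#' Three side-by-side histograms of per-cell LDO, ADO and combined rates,
#' with the combined cutoff marked.
#'
#' @param x A `cell_qc` table.
#' @param max_combined Cutoff drawn on the combined panel.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.cell_qc <- function(x, max_combined = 1 / 3, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::hist(x$ldo_rate, main = "Locus drop-out", xlab = "rate",
                 col = "grey70", ...)
  graphics::hist(x$ado_rate, main = "Allelic drop-out", xlab = "rate",
                 col = "grey70", ...)
  graphics::hist(x$combined_rate, main = "Combined", xlab = "rate",
                 col = "grey70", ...)
  graphics::abline(v = max_combined, lty = 2, col = "red")
  invisible(x)
}
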