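# Synthetic targeted single-cell data with known clonal structure,
# acquisition order and noise.

#' Specify a clone model
#'
#' A clone model fixes the ground truth for a simulated sample: the somatic
#' events partitioned into ordered acquisition groups, the clones (each a
#' union of whole groups) with their population frequencies, the number of
#' heterozygous germline QC SNPs, and an optional clone mixture for the
#' CD34+CD38- multipotent progenitor compartment.
#'
#' @param groups Named list of character vectors: the somatic events in
#'   true order of acquisition (each list element is one co-acquired
#'   group).
#' @param clones Data frame with columns `clone_id`, `genotype` (list
#'   column or `;`-separated string of group names whose union is the
#'   clone's genotype; empty for wild-type) and `frequency`.
#' @param n_snps Number of germline heterozygous QC SNPs (default 32).
#' @param progenitor_mix Optional named numeric vector: clone frequencies
#'   for simulated progenitor cells (defaults to the diagnostic mix).
#' @return A `clone_model`.
#' @export
clone_model <- function(groups, clones, n_snps = 32, progenitor_mix = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (abs(sum(clones$frequency) - 1) > 1e-9)
    stop_fmt("clone frequencies must sum to 1 (got %.6f)", sum(clones$frequency))
  geno <- lapply(clones$genotype, function(gset) {
    gset <- gset[nzchar(gset)]
    unknown <- setdiff(gset, names(groups))
    if (length(unknown) > 0)
      stop_fmt("clone genotype refers to unknown group(s): %s",
               paste(unknown, collapse = ", "))
    sort(unlist(groups[gset], use.names = FALSE))
  })
  if (!is.null(progenitor_mix)) {
    stopifnot(all(names(progenitor_mix) %in% clones$clone_id))
    progenitor_mix <- progenitor_mix / sum(progenitor_mix)
  }
  structure(list(groups = groups,
                 clones = data.frame(clone_id = clones$clone_id,
                                     frequency = clones$frequency,
                                     stringsAsFactors = FALSE),
                 clone_events = stats::setNames(geno, clones$clone_id),
                 n_snps = n_snps,
                 progenitor_mix = progenitor_mix),
            class = "clone_model")
}

#' Specify simulation noise
#'
#' @param mean_depth Mean per-amplicon sequencing depth; depths are drawn
#'   from a negative binomial with this mean (default 40).
#' @param depth_dispersion Negative-binomial size parameter (default 10;
#'   smaller = more overdispersed).
#' @param ldo_prob Per-(cell, locus) amplification-failure probability; a
#'   failed locus gets 0-3 reads (default 0.05).
#' @param ado_prob Per-(cell, locus) allele-loss probability at
#'   heterozygous sites; the allele fraction collapses to 0 or 1 (default
#'   0.10).
#' @param fp_prob Per-(cell, locus) probability of alternate-read leakage
#'   into an unmutated locus (default 0.01).
#' @param seed Integer seed making the simulation reproducible (default 1).
#' @return A `noise_config`.
#' @export
noise_config <- function(mean_depth = 40, depth_dispersion = 10,
                         ldo_prob = 0.05, ado_prob = 0.10, fp_prob = 0.01,
                         seed = 1L) {
  probs <- c(ldo_prob, ado_prob, fp_prob)
  if (any(probs < 0 | probs > 1)) stop_fmt("noise probabilities must lie in [0, 1]")
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 ldo_prob = ldo_prob, ado_prob = ado_prob, fp_prob = fp_prob,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Simulate an allele-depth matrix from a clone model
#'
#' Each cell is assigned a clone multinomially by frequency. Per locus, the
#' amplicon fails entirely with probability `ldo_prob` (0-3 reads);
#' otherwise the depth is negative-binomial. At a heterozygous site
#' (mutated somatic locus or germline SNP) the allele fraction is centred
#' at 0.5 (Beta(20, 20)) and collapses to 0 or 1 with probability
#' `ado_prob` (allelic drop-out); at an unmutated somatic locus alternate
#' reads leak in with probability `fp_prob` at a low Beta(2, 10) fraction.
#' Germline SNPs are heterozygous in every cell before noise. Optional
#' progenitor cells are drawn from the model's `progenitor_mix` and
#' labelled `cd34_progenitor`; diagnostic cells are labelled `blast`.
#'
#' @param model A `clone_model`.
#' @param noise A `noise_config`.
#' @param n_cells Number of diagnostic cells.
#' @param n_progenitors Number of additional progenitor cells (default 0;
#'   requires `model$progenitor_mix`).
#' @param seed Seed overriding `noise$seed`.
#' @return List with `matrix` (an `allele_depth_matrix`), `truth` (data
#'   frame: cell_id, clone_id, compartment) and `panel`.
#' @export
simulate_cells <- function(model, noise = noise_config(), n_cells,
                           n_progenitors = 0, seed = noise$seed) {
  set.seed(seed)
  events <- sort(unlist(model$groups, use.names = FALSE))
  snps <- sprintf("SNP%02d", seq_len(model$n_snps))
  panel <- as_variant_panel(data.frame(
    locus_id = c(events, snps),
    class = c(rep("somatic", length(events)), rep("germline_het", length(snps))),
    event_type = c(ifelse(grepl("fusion|juxtaposition|rearrangement", events), "fusion",
                   ifelse(grepl("^del", events), "deletion",
                   ifelse(grepl("ins$|fs$", events), "indel", "SNV"))),
                   rep("SNV", length(snps))),
    stringsAsFactors = FALSE
  ), where = "simulated panel")

  clone_ids <- model$clones$clone_id
  assign_diag <- sample(clone_ids, n_cells, replace = TRUE,
                        prob = model$clones$frequency)
  assign_mpp <- character(0)
  if (n_progenitors > 0) {
    mix <- model$progenitor_mix
    if (is.null(mix)) stop_fmt("model has no progenitor_mix; cannot simulate progenitors")
    assign_mpp <- sample(names(mix), n_progenitors, replace = TRUE, prob = mix)
  }
  cell_ids <- c(sprintf("cell_%04d", seq_len(n_cells)),
                if (n_progenitors > 0) sprintf("mpp_%04d", seq_len(n_progenitors)))
  compartment <- c(rep("blast", n_cells), rep("cd34_progenitor", n_progenitors))
  assignments <- c(assign_diag, assign_mpp)
  n <- length(cell_ids)
  loci <- c(events, snps)
  L <- length(loci)

  # heterozygous truth: germline SNPs everywhere; somatic events where mutated
  het <- matrix(FALSE, n, L, dimnames = list(cell_ids, loci))
  het[, snps] <- TRUE
  for (cl in clone_ids) {
    rows <- assignments == cl
    if (any(rows) && length(model$clone_events[[cl]]) > 0)
      het[rows, model$clone_events[[cl]]] <- TRUE
  }
  somatic_cols <- matrix(rep(loci %in% events, each = n), n, L)

  # depths
  failed <- matrix(stats::runif(n * L) < noise$ldo_prob, n, L)
  depth <- matrix(stats::rnbinom(n * L, mu = noise$mean_depth,
                                 size = noise$depth_dispersion), n, L)
  depth[failed] <- sample(0:3, sum(failed), replace = TRUE)

  # allele fractions
  frac <- matrix(0, n, L)
  frac[het] <- stats::rbeta(sum(het), 20, 20)
  collapse <- het & matrix(stats::runif(n * L) < noise$ado_prob, n, L)
  frac[collapse] <- sample(c(0, 1), sum(collapse), replace = TRUE)
  leak <- !het & somatic_cols & matrix(stats::runif(n * L) < noise$fp_prob, n, L)
  frac[leak] <- stats::rbeta(sum(leak), 2, 10)

  alt <- matrix(stats::rbinom(n * L, size = depth, prob = frac), n, L,
                dimnames = list(cell_ids, loci))
  ref <- depth - alt
  dimnames(ref) <- dimnames(alt)

  list(matrix = allele_depth_matrix(ref, alt, panel, compartment),
       truth = data.frame(cell_id = cell_ids, clone_id = assignments,
                          compartment = compartment, stringsAsFactors = FALSE),
       panel = panel)
}

#' Patient presets reproducing the four published T-ALL clone architectures
#'
#' Returns a clone model encoding the printed clone structure of one of the
#' four patients, the published diagnostic cell count, and a progenitor
#' mixture. Per-clone genotypes assign 24 somatic events per patient
#' (the published average), partitioned across acquisition groups
#' consistently with the textual clone descriptions; event labels follow
#' the published gene names where given and synthetic labels otherwise.
#' The per-clone genotypes are reconstructions from the published cluster
#' descriptions, not tabulated data.
#'
#' * `X09` (187 cells): wild-type 1%, MED12-bearing early clone 1%,
#'   intermediate 25% (adds the TCF7-SPI1 fusion and NRAS G12D),
#'   intermediate 7% (additionally carries the 9p21 deletion, a side
#'   branch), dominant 66% (all remaining events incl. late NOTCH1).
#' * `XB37` (115 cells): one wild-type cell (frequency 1/115), early
#'   STAT5B-bearing clone 5%, intermediate 16% lacking the ELOVL2 mutation
#'   and BCL11B insertion, dominant with every event (remainder, ~78%).
#' * `XB41` (251 cells): wild-type 1.6%, 2% lacking the NKX2-1AS1-TRDC
#'   fusion plus the CMTM5/NOTCH1 mutations, 2% lacking only CMTM5/NOTCH1,
#'   dominant with every event (remainder, ~94%).
#' * `XB47` (96 cells): wild-type 26%, ANKRD36-only 25%, 9% lacking the
#'   N4BP2 mutation and CNOT3 insertion, 12% lacking only N4BP2, dominant
#'   28%.
#'
#' @param name One of `"X09"`, `"XB37"`, `"XB41"`, `"XB47"`.
#' @return List with `model` (a `clone_model`), `n_cells` and
#'   `n_progenitors`.
#' @export
patient_preset <- function(name = c("X09", "XB37", "XB41", "XB47")) {
  name <- match.arg(name)
  syn <- function(k, tag) sprintf("VAR%02d_%s", seq_len(k), tag)
  preset <- switch(name,
    X09 = {
      groups <- list(
        pre_leukemic = c("MED12_P22L", "KLF9_P31L", "SDK1_V1300M", syn(1, "X09")),
        fusion_ras = c("TCF7_SPI1_fusion", "NRAS_G12D", "TBL1XR1_D85E",
                       "NOTUM_S406L", "ACOX1_S482N", "RPL26L1_R115Q",
                       syn(4, "X09b")),
        del9p21 = c("del_9p21_CDKN2A", "del_9p21_CDKN2B"),
        late_notch = c("NOTCH1_F1606ins", "PCDHA10_E342K", syn(6, "X09c"))
      )
      clones <- data.frame(
        clone_id = c("wildtype", "med12_only", "intermediate", "int_9p21", "dominant"),
        frequency = c(0.01, 0.01, 0.25, 0.07, 0.66), stringsAsFactors = FALSE)
      clones$genotype <- list(character(0), "pre_leukemic",
                              c("pre_leukemic", "fusion_ras"),
                              c("pre_leukemic", "fusion_ras", "del9p21"),
                              c("pre_leukemic", "fusion_ras", "late_notch"))
      list(groups = groups, clones = clones, n_cells = 187L, n_prog = 20L,
           mix = c(wildtype = 0.3, med12_only = 0.4, intermediate = 0.3))
    },
    XB37 = {
      groups <- list(
        pre_leukemic = c("STAT5B_N642H", "CDKN2A_D68Stop", syn(3, "XB37")),
        fusion_block = c("STIL_TAL1_fusion", "LMO2_TRD_juxtaposition",
                         "NOTCH1_V1605ins", "FAT2_3522fs", "SLCO3A1_654fs",
                         syn(12, "XB37b")),
        late_pair = c("ELOVL2_mut", "BCL11B_A732ins")
      )
      wt <- 1 / 115
      clones <- data.frame(
        clone_id = c("wildtype", "early", "intermediate", "dominant"),
        frequency = c(wt, 0.05, 0.16, 1 - wt - 0.05 - 0.16),
        stringsAsFactors = FALSE)
      clones$genotype <- list(character(0), "pre_leukemic",
                              c("pre_leukemic", "fusion_block"),
                              c("pre_leukemic", "fusion_block", "late_pair"))
      list(groups = groups, clones = clones, n_cells = 115L, n_prog = 10L,
           mix = c(wildtype = 0.8, early = 0.2))
    },
    XB41 = {
      groups <- list(
        pre_leukemic = c("RPL10_R98S", "PHIP_P259L", "del_14q11",
                         "NKX2-1_rearrangement", syn(17, "XB41")),
        fusion = "NKX2-1AS1_TRDC_fusion",
        late_pair = c("CMTM5_R8W", "NOTCH1_L1600P")
      )
      clones <- data.frame(
        clone_id = c("wildtype", "minus_fusion_late", "minus_late", "dominant"),
        frequency = c(0.016, 0.02, 0.02, 1 - 0.016 - 0.04),
        stringsAsFactors = FALSE)
      clones$genotype <- list(character(0), "pre_leukemic",
                              c("pre_leukemic", "fusion"),
                              c("pre_leukemic", "fusion", "late_pair"))
      list(groups = groups, clones = clones, n_cells = 251L, n_prog = 20L,
           mix = c(wildtype = 0.3, minus_fusion_late = 0.5, minus_late = 0.2))
    },
    XB47 = {
      groups <- list(
        ankrd36 = "ANKRD36_mut",
        main_block = c("NOTCH1_L1600P", "NOTCH1_Y2490Stop", "del_9p21_CDKN2A",
                       "NKX2-1_rearrangement", "SLC6A18_T91M", "PPP4C_D54K",
                       syn(15, "XB47")),
        cnot3 = "CNOT3_R745ins",
        n4bp2 = "N4BP2_N1670S"
      )
      clones <- data.frame(
        clone_id = c("wildtype", "ankrd36_only", "int_minus_both",
                     "int_minus_n4bp2", "dominant"),
        frequency = c(0.26, 0.25, 0.09, 0.12, 0.28), stringsAsFactors = FALSE)
      clones$genotype <- list(character(0), "ankrd36",
                              c("ankrd36", "main_block"),
                              c("ankrd36", "main_block", "cnot3"),
                              c("ankrd36", "main_block", "cnot3", "n4bp2"))
      list(groups = groups, clones = clones, n_cells = 96L, n_prog = 10L,
           mix = c(wildtype = 0.8, ankrd36_only = 0.2))
    }
  )
  model <- clone_model(preset$groups, preset$clones, n_snps = 32,
                       progenitor_mix = preset$mix)
  list(model = model, n_cells = preset$n_cells,
       n_progenitors = preset$n_prog)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `depths.tsv` (long format), `panel.tsv`, `truth.tsv` and
#' `config.txt` into a directory. Regenerating with the same seed
#' reproduces byte-identical files.
#'
#' @param sim Result of [simulate_cells()].
#' @param noise The `noise_config` used (recorded in `config.txt`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(sim, noise, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(depths = file.path(dir, "depths.tsv"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.txt"))
  write_depth_matrix(sim$matrix, paths["depths"])
  write_panel(sim$panel, paths["panel"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("%s=%s", names(unclass(noise)),
                     vapply(unclass(noise), format, "")), paths["config"])
  invisible(paths)
}
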