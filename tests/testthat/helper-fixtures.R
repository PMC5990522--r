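# in-code fixtures shared across test files

# panel with n_som somatic SNVs (EV01..) and n_germ germline SNPs (SNP01..)
make_panel <- function(n_som = 2, n_germ = 2) {
  as_variant_panel(data.frame(
    locus_id = c(sprintf("EV%02d", seq_len(n_som)), sprintf("SNP%02d", seq_len(n_germ))),
    class = c(rep("somatic", n_som), rep("germline_het", n_germ)),
    event_type = "SNV",
    stringsAsFactors = FALSE
  ))
}

# depth matrix from per-locus ref/alt vectors (cells x loci)
make_adm <- function(ref, alt, panel, compartment = "blast") {
  cells <- sprintf("c%02d", seq_len(nrow(ref)))
  dimnames(ref) <- dimnames(alt) <- list(cells, panel$locus_id[seq_len(ncol(ref))])
  allele_depth_matrix(ref, alt, panel, compartment)
}

# genotype matrix from an integer matrix (1/0/NA)
make_gm <- function(m, compartment = "blast") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("EV%02d", seq_len(ncol(m)))
  genotype_matrix(m, compartment)
}

# noiseless genotype matrix for clones given as event-index sets
make_clone_gm <- function(clone_sets, sizes, n_events,
                          compartment = "blast") {
  rows <- do.call(rbind, mapply(function(set, n) {
    row <- integer(n_events)
    row[set] <- 1L
    matrix(rep(row, n), nrow = n, byrow = TRUE)
  }, clone_sets, sizes, SIMPLIFY = FALSE))
  make_gm(rows, compartment)
}

# named list of event vectors -> list of event_group objects (ids G1..Gm)
as_groups <- function(lst) {
  lapply(seq_along(lst), function(i)
    structure(list(group_id = paste0("G", i), events = unname(lst[[i]])),
              class = "event_group"))
}

# direct (independent) implementation of the order score: explicit loops
# over cells, states and events, no shared code with order_log_score
oracle_order_score <- function(group_events_list, g, alpha, beta) {
  m <- length(group_events_list)
  states <- vector("list", m + 1)
  states[[1]] <- character(0)
  for (k in seq_len(m)) states[[k + 1]] <- c(states[[k]], group_events_list[[k]])
  total <- 0
  for (i in seq_len(nrow(g))) {
    likes <- numeric(m + 1)
    for (k in seq_len(m + 1)) {
      L <- 1
      for (e in colnames(g)) {
        call <- g[i, e]
        if (is.na(call)) next
        in_state <- e %in% states[[k]]
        L <- L * if (call == 1L) {
          if (in_state) 1 - beta else alpha
        } else {
          if (in_state) beta else 1 - alpha
        }
      }
      likes[k] <- L
    }
    total <- total + log(mean(likes))
  }
  total
}

# brute-force Jaccard distance on two ternary vectors via explicit sets
oracle_jaccard <- function(a, b) {
  keep <- which(!is.na(a) & !is.na(b))
  if (length(keep) == 0) return(1)
  pa <- keep[a[keep] == 1L]; pb <- keep[b[keep] == 1L]
  u <- union(pa, pb)
  if (length(u) == 0) return(0)
  1 - length(intersect(pa, pb)) / length(u)
}
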