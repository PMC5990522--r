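# Clonal deconvolution: Jaccard hierarchical clustering seeded,
# likelihood-refined assignment of cells to clones.

#' Cluster cells into clones
#'
#' Cells are clustered on the pairwise-complete Jaccard distance between
#' their ternary genotypes with agglomerative (default average-linkage)
#' clustering, as in heatmap-style clonal analyses of targeted single-cell
#' data. Because allelic drop-out flips individual calls at rates comparable
#' to the genotype difference between nested subclones, the dendrogram alone
#' cannot reliably resolve clones that differ by one or two events. The tree
#' is therefore over-cut (at `2 * max_k` leaves-level clusters) and the
#' partition is polished under an explicit error model:
#'
#' * each cluster's consensus genotype is computed ([clone_consensus()]);
#' * every cell is reassigned to the consensus maximising its genotype
#'   likelihood with false-present rate `alpha` and false-absent rate
#'   `beta` (missing calls carry no information), iterated to convergence;
#' * clusters that coincidental call errors could have produced are merged
#'   away: a cluster A is explainable as noise on cluster B when, given the
#'   events distinguishing their consensus genotypes (absences arise by
#'   drop-out at rate `beta`, presences by leakage at rate `alpha`), the
#'   expected number of cells showing exactly that error pattern makes a
#'   cluster of A's size unsurprising (one-sided Poisson tail above
#'   `p_merge`). Genuine rare clones survive this test because their
#'   distinguishing pattern is far too improbable to arise by chance —
#'   e.g. a single wild-type cell among mutated clones, or an
#'   early-ancestor cell whose extra events would require simultaneous
#'   false-present calls — whereas two or three cells sharing a
#'   coincidental double drop-out do not.
#'
#' The final number of clusters is capped at `max_k`; if every cell shares
#' one genotype a single cluster is returned with a warning. Clusters are
#' labelled `C1..Ck` by decreasing consensus mutation count, so `C1` is the
#' most-mutated (dominant) clone; a cluster with an empty consensus
#' present-set is the wild-type population.
#'
#' @param g A `genotype_matrix` (QC-filtered cells x somatic events).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param min_k,max_k Bounds on the reported number of clusters
#'   (defaults 2 and 8).
#' @param alpha False-present rate of a genotype call (default 0.01).
#' @param beta False-absent rate of a genotype call (default 0.07: half of
#'   a typical 10% allelic drop-out collapses to the reference allele, plus
#'   borderline-depth calls missing the presence thresholds).
#' @param p_merge Tail probability above which a cluster counts as
#'   explainable by call errors on another cluster and is merged
#'   (default 0.05).
#' @param refine Set `FALSE` to skip likelihood refinement and merging and
#'   return the plain dendrogram cut at the largest relative merge-height
#'   gap within `[min_k, max_k]`.
#' @return A `clone_set`: list with `assignments` (named cluster label per
#'   cell), `clusters` (per-cluster table: id, size, frequency, consensus
#'   mutation count, wild-type flag), `consensus` (clusters x events,
#'   1/0/NA-ambiguous), `hclust` (the dendrogram), `params`.
#' @export
cluster_cells <- function(g, linkage = "average", min_k = 2, max_k = 8,
                          alpha = 0.01, beta = 0.07, p_merge = 0.05,
                          refine = TRUE) {
  if (nrow(g) < 2) stop_fmt("clustering needs at least 2 cells, got %d", nrow(g))
  ord <- order(rownames(g))                 # canonical cell order
  g <- genotype_matrix(unclass(g)[ord, , drop = FALSE],
                       attr(g, "compartment")[ord])
  d <- jaccard_matrix(g)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)

  if (!refine) {
    k <- gap_cut_k(hc, min_k, max_k)
    labels <- stats::cutree(hc, k)
  } else {
    k_init <- max(min(nrow(g) - 1L, 2L * max_k), 2L)
    labels <- stats::cutree(hc, k_init)
    labels <- refine_labels(g, labels, alpha, beta)
    labels <- merge_clusters(g, labels, alpha, beta, p_merge, max_k)
    for (round in 1:3) {
      before <- labels
      labels <- split_clusters(g, labels, alpha, beta, p_merge, max_k)
      labels <- merge_clusters(g, labels, alpha, beta, p_merge, max_k)
      if (identical(sort(unname(table(before))), sort(unname(table(labels)))))
        break
    }
  }
  if (length(unique(labels)) == 1)
    warning("no clonal substructure detected: all cells share one genotype cluster")

  cons <- clone_consensus(g, labels)
  n_mut <- rowSums(cons == 1L, na.rm = TRUE)
  sizes <- as.vector(table(labels)[rownames(cons)])
  # label C1..Ck by decreasing mutation count, then size
  ord_cl <- order(-n_mut, -sizes, rownames(cons))
  new_ids <- stats::setNames(paste0("C", seq_along(ord_cl)), rownames(cons)[ord_cl])
  labels <- unname(new_ids[as.character(labels)])
  names(labels) <- rownames(g)
  cons <- cons[rownames(cons)[ord_cl], , drop = FALSE]
  rownames(cons) <- unname(new_ids)
  sizes <- sizes[ord_cl]; n_mut <- n_mut[ord_cl]
  clusters <- data.frame(
    cluster_id = rownames(cons),
    n_cells = sizes,
    frequency = sizes / nrow(g),
    n_events = n_mut,
    wildtype = n_mut == 0,
    stringsAsFactors = FALSE
  )
  structure(list(assignments = labels, clusters = clusters, consensus = cons,
                 hclust = hc,
                 params = list(linkage = linkage, min_k = min_k, max_k = max_k,
                               alpha = alpha, beta = beta, p_merge = p_merge,
                               refine = refine)),
            class = "clone_set")
}

# largest relative gap in the last merge heights, k bounded to [min_k, max_k]
gap_cut_k <- function(hc, min_k, max_k) {
  n <- length(hc$height) + 1L
  ks <- seq(max(min_k, 2L), min(max_k, n - 1L))
  # cutting into k clusters separates merges above height h[n-k]
  h <- c(0, sort(hc$height))
  ratio <- vapply(ks, function(k) {
    lo <- h[n - k + 1L]; hi <- h[n - k + 2L]
    if (lo <= 0) Inf else hi / lo
  }, numeric(1))
  ks[which.max(ratio)]
}

# per-cell log-likelihood of each consensus genotype
# cons: clusters x events (1/0/NA); returns cells x clusters
genotype_loglik <- function(g, cons, alpha, beta) {
  P <- matrix(as.numeric(!is.na(g) & g == 1L), nrow(g), ncol(g))
  A <- matrix(as.numeric(!is.na(g) & g == 0L), nrow(g), ncol(g))
  S <- matrix(as.numeric(!is.na(cons) & cons == 1L), nrow(cons), ncol(cons))
  U <- matrix(as.numeric(!is.na(cons)), nrow(cons), ncol(cons)) # defined events
  # present call: log(1-beta) if in clone else log(alpha)
  # absent call:  log(beta)   if in clone else log(1-alpha)
  ll <- P %*% t(S) * log(1 - beta) + P %*% t(U - S) * log(alpha) +
    A %*% t(S) * log(beta) + A %*% t(U - S) * log(1 - alpha)
  dimnames(ll) <- list(rownames(g), rownames(cons))
  ll
}

refine_labels <- function(g, labels, alpha, beta, max_iter = 30L) {
  labels <- as.character(labels)
  for (iter in seq_len(max_iter)) {
    cons <- clone_consensus(g, labels)
    ll <- genotype_loglik(g, cons, alpha, beta)
    # ties: keep current label when it is among the maxima, else first id
    best <- colnames(ll)[max.col(ll, ties.method = "first")]
    cur_ll <- ll[cbind(seq_len(nrow(ll)), match(labels, colnames(ll)))]
    top_ll <- ll[cbind(seq_len(nrow(ll)), match(best, colnames(ll)))]
    new <- ifelse(top_ll > cur_ll + 1e-9, best, labels)
    if (identical(new, labels)) break
    labels <- new
  }
  labels
}

# Probability that a cluster like A arises from call errors on cluster B.
# A member of A supports the distinction when it exhibits at least 80% of
# the events distinguishing the two consensus genotypes (called absent
# where A lacks an event of B - drop-out at rate beta - and called present
# where A carries an extra event - leakage at rate alpha). The number of
# supporting cells expected by chance among the cells of A and B together
# is Poisson with mean n * P(a B-cell shows such a pattern); a
# look-elsewhere factor choose(E, d) accounts for the d distinguishing
# events having been selected among the E panel events by the clustering
# itself.
explainability <- function(g, labels, cons, a, b, n_b, alpha, beta,
                           exhibit_frac = 0.8) {
  ca <- cons[a, ]; cb <- cons[b, ]
  ok <- !is.na(ca) & !is.na(cb)
  e_abs <- which(ok & cb == 1L & ca == 0L) # absences: drop-out at rate beta
  e_pres <- which(ok & ca == 1L & cb == 0L) # presences: leakage at rate alpha
  d_abs <- length(e_abs); d_pres <- length(e_pres)
  if (d_abs + d_pres == 0) return(1)       # indistinguishable consensus
  t_abs <- ceiling(exhibit_frac * d_abs); t_pres <- ceiling(exhibit_frac * d_pres)
  mem <- unclass(g)[labels == a, , drop = FALSE]
  ma <- mem[, e_abs, drop = FALSE]; mp <- mem[, e_pres, drop = FALSE]
  n_conf <- sum(rowSums(!is.na(ma) & ma == 0L) >= t_abs &
                  rowSums(!is.na(mp) & mp == 1L) >= t_pres)
  p0 <- stats::pbinom(t_abs - 1, d_abs, beta, lower.tail = FALSE) *
    stats::pbinom(t_pres - 1, d_pres, alpha, lower.tail = FALSE)
  lambda <- (nrow(mem) + n_b) * p0
  min(1, exp(stats::ppois(n_conf - 1, lambda, lower.tail = FALSE, log.p = TRUE) +
               lchoose(ncol(g), d_abs + d_pres)))
}

explainability_matrix <- function(g, labels, alpha, beta) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cons <- clone_consensus(g, labels)
  sizes <- as.vector(table(factor(labels, ids)))
  p <- matrix(0, k, k, dimnames = list(ids, ids))     # p[a, b]: A noise on B
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    p[a, b] <- explainability(g, labels, cons, ids[a], ids[b], sizes[b],
                              alpha, beta)
  }
  p
}

merge_clusters <- function(g, labels, alpha, beta, p_merge, max_k) {
  labels <- as.character(labels)
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) <= 1) break
    p <- explainability_matrix(g, labels, alpha, beta)
    over <- length(ids) > max_k
    if (max(p) <= p_merge && !over) break
    cand <- which(p == max(p), arr.ind = TRUE)
    a <- ids[cand[1, 1]]; b <- ids[cand[1, 2]]
    labels[labels == a] <- b
    labels <- refine_labels(g, labels, alpha, beta, max_iter = 5L)
  }
  labels
}

# Propose splitting each cluster on events called present in an intermediate
# fraction of its members (the signature of two clones sharing one cluster);
# a split is kept only when neither half is explainable as call errors on
# the other.
split_clusters <- function(g, labels, alpha, beta, p_merge, max_k) {
  labels <- as.character(labels)
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) >= max_k) break
    accepted <- FALSE
    for (id in ids[order(-table(factor(labels, ids)))]) {
      mem <- which(labels == id)
      if (length(mem) < 4) next
      sub <- unclass(g)[mem, , drop = FALSE]
      npres <- colSums(sub == 1L, na.rm = TRUE)
      nobs <- colSums(!is.na(sub))
      frac <- ifelse(nobs > 0, npres / nobs, 0)
      cand_ev <- colnames(g)[nobs > 0 & npres >= 2 & (nobs - npres) >= 2 &
                               frac >= 0.1 & frac <= 0.9]
      for (ev in cand_ev[order(-pmin(frac[cand_ev], 1 - frac[cand_ev]))]) {
        trial <- labels
        new_id <- paste0(id, ".", ev)
        trial[mem[!is.na(sub[, ev]) & sub[, ev] == 0L]] <- new_id
        trial <- refine_labels(g, trial, alpha, beta, max_iter = 10L)
        if (length(unique(trial[mem])) < 2 ||
            !all(c(id, new_id) %in% trial)) next
        p <- explainability_matrix(g, trial, alpha, beta)
        if (p[new_id, id] <= p_merge && p[id, new_id] <= p_merge) {
          labels <- trial
          accepted <- TRUE
          break
        }
      }
      if (accepted) break
    }
    if (!accepted) break
  }
  labels
}

#' Consensus genotype per clone
#'
#' An event is `present` (1) in a clone when present in more than half of
#' the clone's non-missing calls, `absent` (0) when present in fewer than
#' half, and ambiguous (`NA`) at an exact tie or when every call is missing.
#'
#' @param g A `genotype_matrix`.
#' @param labels Cluster label per cell (same order as rows of `g`).
#' @return Integer matrix (clusters x events) with 1/0/NA entries.
#' @export
clone_consensus <- function(g, labels) {
  labels <- as.character(labels)
  ids <- sort(unique(labels))
  out <- matrix(NA_integer_, length(ids), ncol(g),
                dimnames = list(ids, colnames(g)))
  for (id in ids) {
    sub <- unclass(g)[labels == id, , drop = FALSE]
    npres <- colSums(sub == 1L, na.rm = TRUE)
    nobs <- colSums(!is.na(sub))
    val <- rep(NA_integer_, ncol(g))
    val[nobs > 0 & npres * 2 > nobs] <- 1L
    val[nobs > 0 & npres * 2 < nobs] <- 0L
    out[id, ] <- val
  }
  out
}

#' Partial-order (nesting) report over clone genotypes
#'
#' For every ordered clone pair, tests whether the first clone's consensus
#' present-set is a subset of the second's (ambiguous events excluded).
#' A strictly nested chain of clones is the signature of stepwise linear
#' evolution; subset relations violated in both directions indicate
#' branching, which is flagged.
#'
#' @param clones A `clone_set`.
#' @return Data frame of ordered pairs (`from`, `to`, `nested`), with
#'   attributes `linear` (TRUE when the clones form a single chain) and
#'   `branching_pairs` (pairs nested in neither direction).
#' @export
nesting_report <- function(clones) {
  cons <- clones$consensus
  ids <- rownames(cons)
  sets <- lapply(ids, function(i) colnames(cons)[!is.na(cons[i, ]) & cons[i, ] == 1L])
  names(sets) <- ids
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$nested <- mapply(function(a, b) all(sets[[a]] %in% sets[[b]]),
                         pairs$from, pairs$to)
  rownames(pairs) <- NULL
  comparable <- vapply(seq_len(nrow(pairs)), function(i) {
    rev <- pairs$nested[pairs$from == pairs$to[i] & pairs$to == pairs$from[i]]
    pairs$nested[i] || isTRUE(rev[1])
  }, logical(1))
  branching <- pairs[!comparable & !duplicated(t(apply(
    cbind(pairs$from, pairs$to), 1, sort))), c("from", "to")]
  attr(pairs, "linear") <- nrow(branching) == 0
  attr(pairs, "branching_pairs") <- branching
  pairs
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("Clone set: %d clusters over %d cells\n",
              nrow(x$clusters), length(x$assignments)))
  cl <- x$clusters
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  %s%s: %d cells (%.1f%%), %d events\n", cl$cluster_id[i],
                if (cl$wildtype[i]) " [wild-type]" else "",
                cl$n_cells[i], 100 * cl$frequency[i], cl$n_events[i]))
  invisible(x)
}

#' @export
summary.clone_set <- function(object, ...) {
  nest <- nesting_report(object)
  print(object)
  cat(if (attr(nest, "linear")) "Hierarchy: linear (stepwise)\n"
      else sprintf("Hierarchy: branching (%d incomparable pair(s))\n",
                   nrow(attr(nest, "branching_pairs"))))
  invisible(list(clusters = object$clusters, nesting = nest))
}

#' Heatmap of a clone set
#'
#' Cells x events heatmap in the three-colour encoding standard for
#' targeted single-cell genotype figures: present red, absent black,
#' missing grey. Cells are ordered by cluster then dendrogram order; white
#' gaps separate clusters.
#'
#' @param x A `clone_set`.
#' @param g The `genotype_matrix` that was clustered.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.clone_set <- function(x, g, ...) {
  g <- unclass(g)[names(x$assignments), , drop = FALSE]
  ord <- order(match(x$assignments, x$clusters$cluster_id),
               match(names(x$assignments), x$hclust$labels[x$hclust$order]))
  m <- t(g[ord, , drop = FALSE])
  z <- m; z[is.na(z)] <- 2L                      # 0 absent, 1 present, 2 missing
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                  col = c("black", "firebrick2", "grey75"),
                  zlim = c(0, 2), axes = FALSE, xlab = "cells (by cluster)",
                  ylab = "", main = "Somatic events per cell")
  graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.6)
  bounds <- cumsum(table(factor(x$assignments, x$clusters$cluster_id)))
  graphics::abline(v = utils::head(bounds, -1) + 0.5, col = "white", lwd = 2)
  invisible(x)
}
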