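# Order-of-acquisition inference: group indistinguishable events, enumerate
# candidate orders, score each against the single-cell genotype evidence.

#' Group events with indistinguishable presence patterns
#'
#' Events acquired together (or so close in time that no sampled cell
#' separates them) have identical presence patterns and cannot be ordered;
#' they are merged into one event group so that enumeration runs over
#' groups, not raw events. Pattern similarity is the Jaccard similarity of
#' the presence vectors over rows where both events are non-missing; pairs
#' at or above `merge_similarity` are merged greedily in order of
#' decreasing similarity (single-linkage). Two events never co-observed
#' stay separate.
#'
#' When a cluster assignment is supplied the patterns are the clone
#' consensus calls (one row per clone) rather than raw per-cell calls.
#' Consensus patterns are denoised by the majority vote, so co-acquired
#' events match exactly while events separated by any clone differ; this is
#' the recommended mode and the one [run_pipeline()] uses. Raw per-cell
#' patterns are noisy at realistic allelic drop-out and suit near-noiseless
#' data only.
#'
#' @param g A `genotype_matrix`.
#' @param merge_similarity Jaccard similarity at or above which two event
#'   patterns merge (default 0.95).
#' @param clusters Optional cluster label per cell (or a `clone_set`);
#'   switches pattern rows to clone consensus genotypes.
#' @return List of `event_group`s: each a list with `group_id` and
#'   `events`; groups partition the events deterministically.
#' @export
group_events <- function(g, merge_similarity = 0.95, clusters = NULL) {
  if (ncol(g) < 1) stop_fmt("no somatic events to group")
  pat <- if (is.null(clusters)) unclass(g) else {
    labels <- if (inherits(clusters, "clone_set")) clusters$assignments else clusters
    clone_consensus(g, labels)
  }
  E <- ncol(pat)
  evs <- colnames(pat)
  parent <- seq_len(E)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (E > 1) {
    pairs <- utils::combn(E, 2)
    sim <- apply(pairs, 2, function(ij) {
      a <- pat[, ij[1]]; b <- pat[, ij[2]]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) return(-1)               # never co-observed: keep separate
      uni <- sum(a[ok] == 1L | b[ok] == 1L)
      if (uni == 0) return(1)                # both never present: indistinguishable
      sum(a[ok] == 1L & b[ok] == 1L) / uni
    })
    ord <- order(-sim, pairs[1, ], pairs[2, ])
    for (idx in ord) {
      if (sim[idx] < merge_similarity) break
      i <- find(pairs[1, idx]); j <- find(pairs[2, idx])
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  roots <- vapply(seq_len(E), find, integer(1))
  groups <- split(evs, roots)
  # stable order: by first member's column position
  groups <- groups[order(vapply(groups, function(m) match(m[1], evs), integer(1)))]
  lapply(seq_along(groups), function(i)
    structure(list(group_id = paste0("G", i), events = sort(groups[[i]])),
              class = "event_group"))
}

# internal: per-cell evidence matrices and per-group tallies
order_evidence <- function(g, groups) {
  evs <- colnames(g)
  covered <- unlist(lapply(groups, `[[`, "events"))
  miss <- setdiff(evs, covered)
  if (length(miss) > 0)
    stop_fmt("event(s) not covered by any group: %s", paste(miss, collapse = ", "))
  P <- matrix(as.numeric(!is.na(g) & g == 1L), nrow(g), ncol(g),
              dimnames = dimnames(g))
  A <- matrix(as.numeric(!is.na(g) & g == 0L), nrow(g), ncol(g),
              dimnames = dimnames(g))
  Gm <- t(vapply(groups, function(gr) as.numeric(evs %in% gr$events),
                 numeric(length(evs))))
  list(PG = P %*% t(Gm),                     # cells x groups: present calls per group
       AG = A %*% t(Gm),                     # cells x groups: absent calls per group
       nP = rowSums(P), nA = rowSums(A))
}

#' Log-score of one order of acquisition
#'
#' A candidate order of the event groups implies nested genotype states
#' `S0 = wild-type, S1, ..., Sm` (Sk = union of the first k groups). Each
#' cell is modelled as a noisy observation of one of those states with a
#' uniform prior over states: for a cell in state `Sk`, a non-missing call
#' is correct with probability `1 - beta` (present, event in state) or
#' `1 - alpha` (absent, event not in state), and erroneous otherwise.
#' The cell's contribution is `log(mean_k L(cell | Sk))`; the order's score
#' sums over cells. A cell with every event missing contributes exactly 0.
#' Cells of every compartment are included.
#'
#' @param ordering Order of acquisition: a list of `event_group`s (or a
#'   character vector of group ids resolved against `groups`).
#' @param g A `genotype_matrix`.
#' @param alpha False-present rate, in (0, 1) (default 0.01).
#' @param beta False-absent rate, in (0, 1) (default 0.15, absorbing
#'   allelic drop-out).
#' @return Log-likelihood of the data under the ordering (a single number).
#' @export
order_log_score <- function(ordering, g, alpha = 0.01, beta = 0.15) {
  check_rates(alpha, beta)
  groups <- as_group_list(ordering)
  ev <- order_evidence(g, groups)
  score_perm(seq_along(groups), ev, alpha, beta)
}

check_rates <- function(alpha, beta) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_fmt("alpha must lie in (0, 1)")
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop_fmt("beta must lie in (0, 1)")
}

as_group_list <- function(x) {
  if (inherits(x, "event_group")) return(list(x))
  if (is.character(x))
    x <- lapply(seq_along(x), function(i)
      structure(list(group_id = paste0("G", i), events = x[i]),
                class = "event_group"))
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "event_group")))
  x
}

row_cumsum <- function(x) {
  if (ncol(x) <= 1L) return(x)
  t(apply(x, 1, cumsum))
}

# score one permutation of group indices given evidence tallies
score_perm <- function(perm, ev, alpha, beta) {
  a <- log((1 - beta) / alpha)               # gain per present call in state
  b <- log(beta / (1 - alpha))               # penalty per absent call in state
  base <- ev$nP * log(alpha) + ev$nA * log(1 - alpha)   # all-outside state S0
  cp <- cbind(0, row_cumsum(ev$PG[, perm, drop = FALSE]))
  ca <- cbind(0, row_cumsum(ev$AG[, perm, drop = FALSE]))
  ll <- base + cp * a + ca * b               # cells x (m+1) state log-likelihoods
  sum(row_logsumexp(ll)) - nrow(cp) * log(ncol(cp))
}

#' Enumerate and rank orders of acquisition
#'
#' Scores candidate orders of the event groups with [order_log_score()]'s
#' model and returns the top `top_k`, ranked by non-increasing log-score
#' with lexicographic tie-breaking on the group-id sequence. All `m!`
#' permutations are scored exhaustively when the number of groups is at
#' most `max_exhaustive_groups`; beyond that a deterministic beam search
#' over partial orders is used and the report is flagged approximate.
#'
#' @inheritParams order_log_score
#' @param g A `genotype_matrix`.
#' @param groups List of `event_group`s (see [group_events()]).
#' @param top_k Number of ranked orders to keep (default 100).
#' @param max_exhaustive_groups Exhaustive-enumeration limit (default 8).
#' @param beam_width Beam width for the approximate path (default 500).
#' @return An `order_report`: list with `ranked` (data frame: rank,
#'   log_score, order string), `orders` (list of group-id sequences),
#'   `groups`, `stability` (per adjacent pair of the rank-1 order, the
#'   likelihood-weighted fraction of ranked orders agreeing with that
#'   relative order),
#'   `approximate`, `params`.
#' @export
enumerate_and_rank <- function(g, groups, alpha = 0.01, beta = 0.15,
                               top_k = 100, max_exhaustive_groups = 8,
                               beam_width = 500) {
  check_rates(alpha, beta)
  groups <- as_group_list(groups)
  m <- length(groups)
  if (m < 1) stop_fmt("need at least one event group")
  ev <- order_evidence(g, groups)
  ids <- vapply(groups, `[[`, "", "group_id")
  approximate <- m > max_exhaustive_groups
  perms <- if (!approximate) all_permutations(m)
           else beam_permutations(ev, m, alpha, beta, beam_width)
  scores <- vapply(perms, score_perm, numeric(1), ev = ev,
                   alpha = alpha, beta = beta)
  strings <- vapply(perms, function(p) paste(ids[p], collapse = " > "), "")
  ord <- order(-scores, strings)
  keep <- utils::head(ord, top_k)
  ranked <- data.frame(rank = seq_along(keep), log_score = scores[keep],
                       order = strings[keep], stringsAsFactors = FALSE)
  orders <- lapply(perms[keep], function(p) ids[p])
  structure(list(ranked = ranked, orders = orders, groups = groups,
                 stability = pair_stability(orders, ranked$log_score),
                 approximate = approximate,
                 params = list(alpha = alpha, beta = beta, top_k = top_k,
                               beam_width = if (approximate) beam_width else NA)),
            class = "order_report")
}

all_permutations <- function(m) {
  if (m == 1) return(list(1L))
  sub <- all_permutations(m - 1L)
  out <- vector("list", m * length(sub))
  idx <- 1L
  for (first in seq_len(m)) {
    rest <- setdiff(seq_len(m), first)
    for (s in sub) {
      out[[idx]] <- c(first, rest[s])
      idx <- idx + 1L
    }
  }
  out
}

# deterministic beam search over order prefixes; partial prefixes are scored
# with the prefix states plus the full state (so unplaced groups are treated
# as a single final block)
beam_permutations <- function(ev, m, alpha, beta, beam_width) {
  score_prefix <- function(prefix) {
    a <- log((1 - beta) / alpha); b <- log(beta / (1 - alpha))
    base <- ev$nP * log(alpha) + ev$nA * log(1 - alpha)
    cp <- cbind(0, row_cumsum(ev$PG[, prefix, drop = FALSE]), rowSums(ev$PG))
    ca <- cbind(0, row_cumsum(ev$AG[, prefix, drop = FALSE]), rowSums(ev$AG))
    sum(row_logsumexp(base + cp * a + ca * b)) - nrow(cp) * log(ncol(cp))
  }
  beam <- list(list(prefix = integer(0), score = 0))
  for (step in seq_len(m)) {
    cand <- list()
    for (node in beam) {
      for (nxt in setdiff(seq_len(m), node$prefix)) {
        pre <- c(node$prefix, nxt)
        cand[[length(cand) + 1L]] <- list(prefix = pre, score = score_prefix(pre))
      }
    }
    sc <- vapply(cand, `[[`, numeric(1), "score")
    key <- vapply(cand, function(x) paste(x$prefix, collapse = ","), "")
    beam <- cand[utils::head(order(-sc, key), beam_width)]
  }
  lapply(beam, `[[`, "prefix")
}

# Support for the rank-1 relative order of each adjacent pair: the
# likelihood-weighted fraction of ranked orders agreeing with it. Weighting
# by exp(log_score) is essential because the ranked list contains every
# permutation for small group counts; an unweighted fraction would sit near
# one half even for decisively ordered pairs.
pair_stability <- function(orders, log_scores) {
  top <- orders[[1]]
  if (length(top) < 2) return(numeric(0))
  w <- exp(log_scores - max(log_scores))
  out <- numeric(length(top) - 1)
  names(out) <- paste(utils::head(top, -1), utils::tail(top, -1), sep = " < ")
  for (i in seq_len(length(top) - 1)) {
    a <- top[i]; b <- top[i + 1]
    agree <- vapply(orders, function(o) match(a, o) < match(b, o), logical(1))
    out[i] <- sum(w[agree]) / sum(w)
  }
  out
}

#' Consensus stepwise summary of an order report
#'
#' Renders the rank-1 order as discrete steps of mutation accumulation.
#' Adjacent groups whose relative order is supported by fewer than
#' `min_support` of the ranked orders are collapsed into a single step and
#' annotated as closely related in time.
#'
#' @param report An `order_report`.
#' @param min_support Support threshold in \[0, 1\] (default 0.6).
#' @return Data frame with one row per step: `step`, `groups` (ids joined
#'   with `+`), `events`, `support` (minimum adjacent-pair support inside
#'   the step, `NA` for singleton steps), `co_occurring` flag.
#' @export
consensus_order <- function(report, min_support = 0.6) {
  top <- report$orders[[1]]
  stab <- report$stability
  breaks <- which(stab >= min_support)
  step_of <- cumsum(c(1, as.numeric(seq_along(stab) %in% breaks)))
  ev_by_id <- stats::setNames(lapply(report$groups, `[[`, "events"),
                              vapply(report$groups, `[[`, "", "group_id"))
  steps <- split(seq_along(top), step_of)
  out <- data.frame(
    step = seq_along(steps),
    groups = vapply(steps, function(i) paste(top[i], collapse = "+"), ""),
    events = vapply(steps, function(i)
      paste(unlist(ev_by_id[top[i]]), collapse = ","), ""),
    support = vapply(steps, function(i) {
      if (length(i) == 1) NA_real_ else min(stab[utils::head(i, -1)])
    }, numeric(1)),
    co_occurring = vapply(steps, function(i) length(i) > 1, logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Sensitivity of the inferred order to multipotent progenitor cells
#'
#' Re-runs the whole order-inference algorithm (clonal clustering, event
#' grouping, order ranking) with the `cd34_progenitor` compartment excluded
#' and compares the rank-1 orders at the event level. A robust mutational
#' hierarchy should not depend on the progenitor compartment.
#'
#' Removing cells can remove the only carriers of an intermediate genotype
#' state, in which case adjacent event groups become indistinguishable and
#' merge; the inferred order then loses resolution without contradicting
#' the original. The comparison therefore distinguishes `identical` (same
#' groups in the same sequence), `consistent` (no event pair ordered one
#' way in one rank-1 order and the other way in the other: the hierarchy is
#' unchanged up to resolution) and the Kendall rank correlation over event
#' pairs whose relative order both runs resolve.
#'
#' @inheritParams enumerate_and_rank
#' @param merge_similarity Passed to [group_events()].
#' @param cluster_args Named list of extra arguments for [cluster_cells()].
#' @return List with `applicable`, `identical`, `consistent`,
#'   `kendall_tau`, `order_all`, `order_blasts` (each a list of event-set
#'   steps).
#' @export
compartment_sensitivity <- function(g, alpha = 0.01, beta = 0.15,
                                    top_k = 100, merge_similarity = 0.95,
                                    cluster_args = list()) {
  comp <- attr(g, "compartment")
  is_mpp <- comp == "cd34_progenitor"
  if (!any(is_mpp) || sum(!is_mpp) < 2)
    return(list(applicable = FALSE, identical = NA, consistent = NA,
                kendall_tau = NA_real_, order_all = NULL, order_blasts = NULL))
  run_one <- function(gg) {
    cs <- do.call(cluster_cells, c(list(gg), cluster_args))
    groups <- group_events(gg, merge_similarity, clusters = cs)
    rep <- enumerate_and_rank(gg, groups, alpha, beta, top_k)
    ids <- vapply(groups, `[[`, "", "group_id")
    lapply(rep$orders[[1]], function(id) groups[[match(id, ids)]]$events)
  }
  o_all <- run_one(g)
  o_bl <- run_one(genotype_matrix(unclass(g)[!is_mpp, , drop = FALSE],
                                  comp[!is_mpp]))
  cmp <- compare_event_orders(o_all, o_bl)
  c(list(applicable = TRUE), cmp,
    list(order_all = o_all, order_blasts = o_bl))
}

# compare two orders given as lists of event sets: rank events, count
# concordant/discordant pairs among those resolved by both
compare_event_orders <- function(o1, o2) {
  rank_of <- function(o) {
    r <- unlist(lapply(seq_along(o), function(i) stats::setNames(rep(i, length(o[[i]])), o[[i]])))
    r
  }
  r1 <- rank_of(o1); r2 <- rank_of(o2)
  evs <- intersect(names(r1), names(r2))
  conc <- disc <- 0L
  if (length(evs) > 1) {
    pairs <- utils::combn(evs, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      s1 <- sign(r1[a] - r1[b]); s2 <- sign(r2[a] - r2[b])
      if (s1 == 0 || s2 == 0) next
      if (s1 == s2) conc <- conc + 1L else disc <- disc + 1L
    }
  }
  list(identical = identical(lapply(o1, sort), lapply(o2, sort)),
       consistent = disc == 0L,
       kendall_tau = if (conc + disc > 0) (conc - disc) / (conc + disc)
                     else NA_real_)
}

#' @export
print.order_report <- function(x, ...) {
  cat(sprintf("Order report: %d group(s), %d ranked order(s)%s\n",
              length(x$groups), nrow(x$ranked),
              if (x$approximate) " [approximate: beam search]" else ""))
  n <- min(5, nrow(x$ranked))
  for (i in seq_len(n))
    cat(sprintf("  #%d  %.3f  %s\n", x$ranked$rank[i], x$ranked$log_score[i],
                x$ranked$order[i]))
  if (nrow(x$ranked) > n) cat(sprintf("  ... %d more\n", nrow(x$ranked) - n))
  invisible(x)
}

#' @export
summary.order_report <- function(object, ...) {
  print(object)
  steps <- consensus_order(object)
  cat("Consensus steps:\n")
  for (i in seq_len(nrow(steps)))
    cat(sprintf("  step %d: %s%s\n", steps$step[i], steps$events[i],
                if (steps$co_occurring[i]) " (closely related in time)" else ""))
  invisible(steps)
}

#' Step diagram of the consensus order
#'
#' Draws the consensus steps left to right with the events acquired at
#' each step annotated above it.
#'
#' @param x An `order_report`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.order_report <- function(x, ...) {
  steps <- consensus_order(x)
  n <- nrow(steps)
  graphics::plot(seq_len(n), rep(0, n), pch = 8, cex = 2, xlim = c(0.5, n + 0.5),
                 ylim = c(-1, 1.5), axes = FALSE, xlab = "", ylab = "",
                 main = "Consensus order of acquisition")
  if (n > 1) graphics::arrows(seq_len(n - 1) + 0.15, 0, seq_len(n) - 0.15 + 1,
                              0, length = 0.08)
  labels <- vapply(strsplit(steps$events, ","), paste, "", collapse = "\n")
  graphics::text(seq_len(n), 0.25, labels, adj = c(0.5, 0), cex = 0.7)
  invisible(x)
}
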