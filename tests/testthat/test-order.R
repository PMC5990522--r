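test_that("events with identical presence patterns merge into one group", {
  g <- make_gm(rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L)))
  groups <- group_events(g)
  sets <- lapply(groups, `[[`, "events")
  expect_equal(length(groups), 2)
  expect_true(any(vapply(sets, identical, TRUE, c("EV01", "EV02"))))
})

test_that("events never co-observed stay in separate groups", {
  g <- make_gm(rbind(c(1L, NA), c(NA, 1L), c(1L, NA)))
  expect_length(group_events(g), 2)
})

test_that("co-acquired blocks are recovered at zero noise", {
  # 24 events in 6 blocks of 4; clones are the prefix states
  blocks <- split(1:24, rep(1:6, each = 4))
  sets <- lapply(1:6, function(k) unlist(blocks[1:k]))
  g <- make_clone_gm(c(list(integer(0)), sets), c(4, rep(6, 6)), 24)
  groups <- group_events(g)
  expect_length(groups, 6)
  got <- lapply(groups, function(x) sort(match(x$events, colnames(g))))
  expect_setequal(got, lapply(blocks, as.integer))
  # consensus-pattern mode gives the same partition here
  cs <- cluster_cells(g)
  expect_length(group_events(g, clusters = cs), 6)
})

test_that("an all-missing cell contributes exactly zero to any order", {
  groups <- as_groups(list(A = "EV01", B = "EV02"))
  g1 <- make_gm(rbind(c(1L, 0L)))
  g2 <- make_gm(rbind(c(1L, 0L), c(NA, NA)))
  for (ord in list(groups, rev(groups)))
    expect_equal(order_log_score(ord, g1), order_log_score(ord, g2))
})

test_that("the single-event closed form matches", {
  g <- make_gm(matrix(1L, 1, 1))
  alpha <- 0.01; beta <- 0.15
  expect_equal(order_log_score(as_groups(list(A = "EV01")), g, alpha, beta),
               log((alpha + (1 - beta)) / 2))
})

test_that("order scores match an independent summation oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n_ev <- sample(2:4, 1); n_cells <- sample(2:10, 1)
    g <- make_gm(matrix(sample(c(0L, 1L, NA), n_ev * n_cells, TRUE,
                               prob = c(.35, .5, .15)), n_cells, n_ev))
    n_groups <- sample(1:n_ev, 1)
    membership <- sort(sample(seq_len(n_groups), n_ev, replace = TRUE))
    glist <- split(colnames(g), membership)
    alpha <- runif(1, 0.005, 0.2); beta <- runif(1, 0.05, 0.4)
    expect_equal(order_log_score(as_groups(glist), g, alpha, beta),
                 oracle_order_score(unname(glist), unclass(g), alpha, beta),
                 tolerance = 1e-9)
  }
})

test_that("noiseless prefix-sampled cells rank the generating order first", {
  set.seed(17)
  for (rep in 1:5) {
    n_ev <- 5
    perm <- sample(n_ev)
    sets <- lapply(0:n_ev, function(k) perm[seq_len(k)])
    g <- make_clone_gm(sets, rep(50 %/% 6 + 1, 6), n_ev)
    groups <- as_groups(as.list(stats::setNames(colnames(g), colnames(g))))
    rep_out <- enumerate_and_rank(g, groups, alpha = 0.01, beta = 0.01,
                                  top_k = 120)
    expect_equal(nrow(rep_out$ranked), 120)   # 5! orders enumerated
    ids <- vapply(groups, `[[`, "", "group_id")
    want <- ids[perm]
    expect_equal(rep_out$orders[[1]], want)
  }
})

test_that("enumeration returns every order for small group counts", {
  g1 <- make_clone_gm(list(integer(0), 1), c(5, 5), 1)
  rep1 <- enumerate_and_rank(g1, as_groups(list(A = "EV01")))
  expect_equal(nrow(rep1$ranked), 1)
  g <- make_clone_gm(list(1, 1:2, 1:3), c(5, 5, 5), 3)
  groups <- as_groups(list(A = "EV01", B = "EV02", C = "EV03"))
  rep3 <- enumerate_and_rank(g, groups)
  expect_equal(nrow(rep3$ranked), 6)
  expect_false(rep3$approximate)
  # scores are sorted non-increasing
  expect_true(all(diff(rep3$ranked$log_score) <= 1e-12))
})

test_that("beam search agrees with exhaustive enumeration on the top order", {
  set.seed(23)
  g <- make_gm(matrix(sample(c(0L, 1L, NA), 80, TRUE, prob = c(.3, .6, .1)),
                      16, 5))
  groups <- as_groups(as.list(stats::setNames(colnames(g), colnames(g))))
  exact <- enumerate_and_rank(g, groups)
  beam <- enumerate_and_rank(g, groups, max_exhaustive_groups = 2,
                             beam_width = 500)
  expect_true(beam$approximate)
  expect_equal(beam$orders[[1]], exact$orders[[1]])
  expect_equal(beam$ranked$log_score[1], exact$ranked$log_score[1])
})

test_that("score is invariant to cell order and scales under replication", {
  set.seed(9)
  g <- make_gm(matrix(sample(c(0L, 1L, NA), 40, TRUE), 8, 5))
  groups <- as_groups(list(A = c("EV01", "EV02"), B = c("EV03", "EV04"),
                           C = "EV05"))
  perms <- clonetrace:::all_permutations(3)
  sc <- function(gg) vapply(perms, function(p)
    order_log_score(groups[p], gg), numeric(1))
  base <- sc(g)
  shuf <- sample(nrow(g))
  expect_equal(sc(genotype_matrix(unclass(g)[shuf, , drop = FALSE], "blast")),
               base)
  # duplicating every cell doubles each score: ranking preserved
  gdup <- genotype_matrix(rbind(unclass(g), unclass(g)), "blast")
  expect_equal(sc(gdup), 2 * base)
  expect_equal(order(sc(gdup)), order(base))
})

test_that("rate parameters outside (0,1) are rejected", {
  g <- make_gm(matrix(1L, 2, 1))
  grp <- as_groups(list(A = "EV01"))
  expect_error(order_log_score(grp, g, alpha = 0), "alpha")
  expect_error(order_log_score(grp, g, beta = 1), "beta")
})

test_that("consensus steps merge weakly ordered adjacent groups", {
  # all top orders identical: one group per step, no merges
  g <- make_clone_gm(list(1, 1:2, 1:3), c(8, 8, 8), 3)
  groups <- as_groups(list(A = "EV01", B = "EV02", C = "EV03"))
  rep_out <- enumerate_and_rank(g, groups)
  steps <- consensus_order(rep_out)
  expect_equal(nrow(steps), 3)
  expect_false(any(steps$co_occurring))

  # a report where two equally likely orders swap a pair merges that pair
  fake <- rep_out
  fake$orders <- rep(list(c("G1", "G2", "G3"), c("G2", "G1", "G3")), 5)
  fake$stability <- clonetrace:::pair_stability(fake$orders, rep(0, 10))
  steps2 <- consensus_order(fake)
  expect_equal(nrow(steps2), 2)
  expect_true(steps2$co_occurring[1])

  # a single group renders as a single step
  g1 <- make_clone_gm(list(integer(0), 1), c(5, 5), 1)
  rep1 <- enumerate_and_rank(g1, as_groups(list(A = "EV01")))
  expect_equal(nrow(consensus_order(rep1)), 1)
})

test_that("compartment sensitivity is not applicable without progenitors", {
  g <- make_clone_gm(list(1, 1:2), c(5, 5), 2)
  out <- compartment_sensitivity(g)
  expect_false(out$applicable)
})

test_that("progenitors mirroring blast genotypes leave the order unchanged", {
  g <- make_clone_gm(list(integer(0), 1:2, 1:4), c(4, 8, 8), 4)
  extra <- make_clone_gm(list(integer(0), 1:2), c(3, 3), 4, "cd34_progenitor")
  rownames(extra) <- paste0("p", seq_len(nrow(extra)))
  gall <- genotype_matrix(rbind(unclass(g), unclass(extra)),
                          c(attr(g, "compartment"), attr(extra, "compartment")))
  out <- compartment_sensitivity(gall)
  expect_true(out$applicable)
  expect_true(out$identical)
  expect_true(out$consistent)
  expect_equal(out$kendall_tau, 1)
})
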