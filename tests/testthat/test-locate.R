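dm1 <- delay_model(mu = 1, sigma2 = 0.25)

test_that("TRBS scores by residual variance against hop distances", {
  # deterministic front: beta = 1 makes the true source's residuals all zero
  for (seed in 1:5) {
    g <- random_connected_graph(25, 0.2, seed)
    src <- withr::with_seed(seed, sample.int(25, 1))
    r <- run_si(g, 1, source = src, seed = seed)
    ob <- observe(r, seq_len(25))
    st <- score_trbs(g, ob, delay_model(1))
    expect_true(src %in% st$argmax_set)
    expect_equal(max(st$scores), 0)
    expect_true(all(st$scores <= 0))
  }

  # hand example: path 1-2-3, observers {1, 3} with times (2, 0), mu = 1
  ob <- observer_set(c(1, 3), c(2, 0))
  st <- score_trbs(path_graph(3), ob, delay_model(mu = 1, sigma2 = 1))
  expect_true(3 %in% st$argmax_set)
  expect_equal(st$scores[3], 0)

  # shift invariance
  g <- random_connected_graph(20, 0.2, 3)
  obs <- c(2, 9, 17)
  ob1 <- observer_set(obs, c(1, 4, 2))
  ob2 <- observer_set(obs, c(1, 4, 2) + 10)
  expect_equal(score_trbs(g, ob1, dm1)$scores,
               score_trbs(g, ob2, dm1)$scores)
})

test_that("PC scores are correlations with the expected extremes", {
  p4 <- path_graph(4)
  # from candidate 1 the observers {2,3,4} are at distances (1,2,3)
  st <- score_pc(p4, observer_set(2:4, c(2, 4, 6)))
  expect_equal(st$scores[1], 1)
  st2 <- score_pc(p4, observer_set(2:4, c(3, 2, 1)))
  expect_equal(st2$scores[1], -1)

  for (seed in 1:5) {
    g <- random_connected_graph(25, 0.2, seed)
    r <- run_si(g, 0.4, seed = seed)
    ob <- observe(r, place_rnd(g, 8, seed = seed))
    sc <- score_pc(g, ob)$scores
    expect_true(all(sc >= -2 & sc <= 1))
    expect_true(all(sc[sc > -2] >= -1))
  }
})

test_that("PC flags degenerate inputs", {
  # all observer distances equal from the star centre -> sentinel -2
  st5 <- star_graph(5)
  ob <- observer_set(c(2, 3, 4), c(1, 2, 3))
  sc <- score_pc(st5, ob)
  expect_equal(sc$scores[1], -2)
  expect_false(1 %in% sc$argmax_set)

  # zero variance in the observed times -> uniform sentinel, flagged
  ob0 <- observer_set(c(2, 3, 4), c(1, 1, 1))
  sc0 <- score_pc(st5, ob0)
  expect_true(sc0$degenerate)
  expect_equal(length(sc0$argmax_set), 6)
})

test_that("LPTV recovers exact-delay sources on star and path", {
  st5 <- star_graph(4)
  r <- run_si(st5, 1, source = 1, seed = 1)
  ob <- observe(r, 2:5)
  sc <- score_lptv(st5, ob, delay_model(1))
  expect_true(1 %in% sc$argmax_set)

  p5 <- path_graph(5)
  r2 <- run_si(p5, 1, source = 3, seed = 1)
  ob2 <- observe(r2, c(1, 5))
  sc2 <- score_lptv(p5, ob2, delay_model(1))
  expect_true(3 %in% sc2$argmax_set)

  expect_error(score_lptv(p5, observer_set(1, 0), delay_model(1)),
               "at least 2")
})

test_that("LPTV argmax is invariant to observer input order", {
  g <- random_connected_graph(20, 0.2, 11)
  r <- run_si(g, 0.5, source = 4, seed = 2)
  obs <- c(3, 8, 12, 19)
  ob_a <- observe(r, obs)
  ob_b <- observe(r, rev(obs))
  expect_equal(score_lptv(g, ob_a, dm1)$argmax_set,
               score_lptv(g, ob_b, dm1)$argmax_set)
  expect_equal(score_epl(g, ob_a, dm1)$argmax_set,
               score_epl(g, ob_b, dm1)$argmax_set)
})

test_that("LPTV matches the exhaustive ML oracle on Gaussian-delay trees", {
  agree <- 0
  n_rep <- 50
  for (seed in seq_len(n_rep)) {
    n <- withr::with_seed(seed, sample(8:15, 1))
    tr <- random_tree(n, seed)
    src <- withr::with_seed(seed + 1000, sample.int(n, 1))
    times <- withr::with_seed(seed + 2000,
                              gaussian_tree_times(tr, src, 1, 0.1))
    obs <- withr::with_seed(seed + 3000,
                            sort(sample.int(n, max(3, n %/% 2))))
    ob <- observer_set(obs, times[obs])
    st <- score_lptv(tr, ob, delay_model(mu = 1, sigma2 = 0.01))
    oracle <- tree_ml_argmax(tr, obs, times[obs], 1, 0.01)
    if (length(intersect(st$argmax_set, oracle)) > 0) agree <- agree + 1
  }
  expect_gte(agree / n_rep, 0.98)
})

test_that("GMLA equals LPTV on the restricted observer set and climbs to the source", {
  for (seed in 1:5) {
    g <- random_connected_graph(40, 0.12, seed)
    r <- run_si(g, 0.5, seed = seed)
    ob <- observe(r, place_rnd(g, 12, seed = seed))
    sc_g <- score_gmla(g, ob, dm1)
    k0 <- max(5, ceiling(sqrt(40)))
    keep <- order(ob$times, ob$nodes)[seq_len(min(k0, 12))]
    ob_r <- observer_set(ob$nodes[keep], ob$times[keep])
    sc_l <- score_lptv(g, ob_r, dm1)
    ev <- sc_g$evaluated_set
    expect_gt(length(ev), 0)
    expect_equal(sc_g$scores[ev], sc_l$scores[ev], tolerance = 1e-10)
  }

  # star with source at the centre: the climb stops at the centre
  st5 <- star_graph(4)
  r <- run_si(st5, 1, source = 1, seed = 1)
  ob <- observe(r, c(2, 3, 4))
  sc <- score_gmla(st5, ob, delay_model(1))
  expect_true(1 %in% sc$argmax_set)
})

test_that("nodes the GMLA climb never visits get the maximum rank", {
  p <- path_graph(30)
  r <- run_si(p, 1, source = 2, seed = 1)
  ob <- observe(r, c(1, 3, 5))
  sc <- score_gmla(p, ob, delay_model(1))
  expect_false(30 %in% sc$evaluated_set)
  expect_equal(rank_of(sc, 30), 30)
})

test_that("pessimistic competition ranks", {
  st <- score_table(c(3, 1, 2, 3, NA), "x")
  expect_equal(rank_of(st, 2), 4)   # worst evaluated
  expect_equal(rank_of(st, 1), 2)   # tied at the top, placed last
  expect_equal(rank_of(st, 4), 2)
  expect_equal(rank_of(st, 5), 5)   # never evaluated -> N
  st_u <- score_table(c(5, 1), "x")
  expect_equal(rank_of(st_u, 1), 1)
})

test_that("EPL agrees with LPTV on trees and shortens multi-path arrivals", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(8:15, 1))
    tr <- random_tree(n, seed)
    src <- withr::with_seed(seed + 500, sample.int(n, 1))
    times <- withr::with_seed(seed + 600,
                              gaussian_tree_times(tr, src, 1, 0.1))
    obs <- withr::with_seed(seed + 700, sort(sample.int(n, max(3, n %/% 2))))
    ob <- observer_set(obs, times[obs])
    dm <- delay_model(mu = 1, sigma2 = 0.01)
    expect_equal(score_epl(tr, ob, dm)$argmax_set,
                 score_lptv(tr, ob, dm)$argmax_set)
  }

  # two parallel paths shorten the expected arrival below L * mu
  c4 <- cycle_graph(4)
  dm <- delay_model(mu = 2, sigma2 = 1)
  adj <- silocate:::sorted_adj(c4)
  d3 <- bfs_distances(c4, 3)
  sig3 <- silocate:::sp_counts_from(adj, d3)
  mv <- silocate:::epl_mean_var(adj, d3, sig3, 1, 3, dm, cap = 64)
  theta <- sqrt(2 * 2 * dm$sigma2)    # two rho = 0 paths of length 2
  expect_equal(mv[1], 2 * dm$mu - theta * stats::dnorm(0))
  expect_lt(mv[1], 2 * dm$mu)
})

test_that("scorers are deterministic and dispatchable by name", {
  g <- random_connected_graph(20, 0.2, 5)
  r <- run_si(g, 0.5, seed = 5)
  ob <- observe(r, place_rnd(g, 6, seed = 5))
  for (m in c("lptv", "trbs", "pc", "gmla", "epl")) {
    s1 <- locate_source(g, ob, m, dm = dm1)
    s2 <- locate_source(g, ob, m, dm = dm1)
    expect_identical(s1$scores, s2$scores)
    expect_equal(s1$method, m)
  }
  expect_error(locate_source(g, ob, "lptv"), "delay_model")
})
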