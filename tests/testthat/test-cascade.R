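test_that("round criteria follow the stringency schedule", {
  base <- cluster_criterion(min_id = 0.20, min_cov = 0.80)
  for (sens in c("faster", "fast", "default")) {
    eff <- round_criterion(base, round_spec(sens))
    expect_equal(eff$min_id, 0.27)
    expect_equal(eff$min_cov, 0.87)
  }
  sens_round <- round_criterion(base, round_spec("sensitive"))
  expect_equal(sens_round$min_cov, 0.85)
  expect_equal(sens_round$min_id, 0.20)  # identity unchanged
  for (sens in c("very-sensitive", "ultra-sensitive")) {
    eff <- round_criterion(base, round_spec(sens))
    expect_equal(eff$min_id, base$min_id)
    expect_equal(eff$min_cov, base$min_cov)
  }
  # clamping at 1
  high <- cluster_criterion(min_id = 0.95, min_cov = 0.98)
  eff <- round_criterion(high, round_spec("fast"))
  expect_equal(eff$min_id, 1.0)
  expect_equal(eff$min_cov, 1.0)
})

test_that("search depth is 1 early, 3 late, 2 for the linear-mode third round", {
  expect_equal(search_depth_for_round(1), 1L)
  expect_equal(search_depth_for_round(2, "linear"), 1L)
  expect_equal(search_depth_for_round(3), 3L)
  expect_equal(search_depth_for_round(4), 3L)
  expect_equal(search_depth_for_round(6), 3L)
  expect_equal(search_depth_for_round(3, "linear"), 2L)
})

test_that("cascade configurations chain 2 to 6 rounds, linear first", {
  expect_error(default_cascade(1), "2 to 6")
  expect_error(default_cascade(7), "2 to 6")
  cfg <- default_cascade(4)
  expect_equal(cfg$rounds[[1]]$stage, "linear-with-minimizers")
  expect_equal(cfg$rounds[[1]]$window, 12L)
  expect_equal(cfg$rounds[[2]]$stage, "linear")
  expect_equal(cfg$rounds[[3]]$stage, "all-vs-all")
  sens <- vapply(cfg$rounds, `[[`, character(1), "sensitivity")
  expect_equal(sens, c("faster", "fast", "default", "sensitive"))
})

test_that("all-vs-all round: symmetry, pruning, and edge correctness", {
  twin <- sequence_db(c("a", "b"), rep(random_aa(120), 2))
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  e <- all_vs_all_round(twin, crit, "ultra-sensitive")
  expect_setequal(paste(e$from, e$to), c("1 2", "2 1"))

  # length ratio 0.5 under bi c = 0.8, eps = 0.05: never aligned
  s <- random_aa(200)
  db <- sequence_db(c("long", "half"), c(s, substr(s, 1, 100)))
  e2 <- all_vs_all_round(db, crit, "ultra-sensitive")
  expect_equal(nrow(e2), 0L)

  # epsilon-pruned edges equal the unpruned exhaustive edge set
  sim <- simulate_families(family_spec(families = 5, members = c(3L, 6L),
                                       root_length = c(60L, 150L),
                                       truncation = c(0, 0.15),
                                       singletons = 10L, seed = 19L))
  pruned <- all_vs_all_round(sim$db, crit, "ultra-sensitive")
  ap <- t(combn(length(sim$db), 2))
  full <- hits_to_edges(align_pairs(sim$db, ap[, 1], ap[, 2]), crit, sim$db)
  expect_setequal(paste(pruned$from, pruned$to), paste(full$from, full$to))
})

test_that("cascade clusters families and leaves unrelated sequences apart", {
  # mutually dissimilar sequences stay singletons
  lone <- random_db(8, c(80, 300), prefix = "solo")
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  cl <- cascade_cluster(lone, crit)
  expect_equal(length(representatives(cl)), 8L)

  # one family at ~95% identity collapses to a single cluster, matching the
  # single-round exhaustive graph + vertex cover oracle
  set.seed(23)
  root <- random_aa(150)
  fam <- sequence_db(sprintf("m%02d", 1:8),
                     c(root, vapply(1:7, function(i)
                       mutate_to_identity(root, 0.95), character(1))))
  cl2 <- cascade_cluster(fam, crit)
  expect_equal(length(representatives(cl2)), 1L)
  ap <- t(combn(8, 2))
  oracle_edges <- hits_to_edges(align_pairs(fam, ap[, 1], ap[, 2]), crit, fam)
  oracle <- greedy_vertex_cover(align_graph(fam$id, oracle_edges, fam$length), 1)
  expect_equal(length(representatives(oracle)), 1L)

  # representative counts never increase across rounds
  sim <- simulate_families(family_spec(families = 5, singletons = 10,
                                       seed = 29L))
  cl3 <- cascade_cluster(sim$db, crit)
  reps <- attr(cl3, "rounds")$representatives
  expect_true(all(diff(reps) <= 0))
  expect_setequal(names(cl3), sim$db$id)
})

test_that("member-representative chains re-align under the base criterion", {
  sim <- simulate_families(family_spec(families = 4, members = c(6L, 6L),
                                       singletons = 5L, seed = 37L))
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  cl <- cascade_cluster(sim$db, crit)
  history <- attr(cl, "history")
  # walk each member's chain of per-round representatives; every hop must
  # satisfy the (stringency-free) base criterion
  for (m in sample(names(cl), 10)) {
    cur <- m
    for (h in history) {
      nxt <- unclass(h)[[cur]]
      if (nxt != cur) {
        hit <- align_pairs(sim$db, match(nxt, sim$db$id),
                           match(cur, sim$db$id))
        expect_true(passes_criterion(hit, crit))
      }
      cur <- nxt
    }
    expect_equal(cur, unclass(cl)[[m]])
  }
})

test_that("clustering is deterministic for identical inputs", {
  sim <- simulate_families(family_spec(families = 4, singletons = 8, seed = 41L))
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  a <- cascade_cluster(sim$db, crit)
  b <- cascade_cluster(sim$db, crit)
  expect_identical(unclass(a), unclass(b))
})

test_that("linear mode uses only linear stages and more shapes add edges", {
  sim <- simulate_families(family_spec(families = 5, members = c(5L, 5L),
                                       singletons = 10L, seed = 43L))
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  cl <- linclust(sim$db, crit)
  stages <- attr(cl, "rounds")$stage
  expect_false("all-vs-all" %in% stages)
  expect_equal(attr(cl, "rounds")$depth, c(1L, 1L, 2L))
  expect_setequal(names(cl), sim$db$id)

  # one weight-10 shape vs the 30-shape set: candidate edges only grow
  shapes30 <- cascclust:::builtin_linear_shapes()
  e1 <- linear_round(sim$db, crit, shapes30[1])
  e30 <- linear_round(sim$db, crit, shapes30)
  expect_true(all(paste(e1$from, e1$to) %in% paste(e30$from, e30$to)))
})

test_that("incremental addition preserves old assignments and partitions the union", {
  sim <- simulate_families(family_spec(families = 4, members = c(5L, 5L),
                                       singletons = 6L, seed = 47L))
  crit <- cluster_criterion(min_id = 0.3, min_cov = 0.8, cov_mode = "bi")
  existing <- cascade_cluster(sim$db, crit)
  rep_db <- db_subset(sim$db, representatives(existing))

  # a new sequence identical to a representative joins it
  new1 <- sequence_db(c("newA", "newB"),
                      c(rep_db$seq[1], random_aa(180)))
  merged <- add_sequences(existing, rep_db, new1, crit)
  expect_equal(unclass(merged)[["newA"]], rep_db$id[1])
  # the dissimilar one becomes its own singleton
  expect_equal(unclass(merged)[["newB"]], "newB")
  expect_setequal(names(merged), c(names(existing), new1$id))
  expect_equal(unclass(merged)[names(existing)],
               unclass(existing)[names(existing)])

  expect_error(add_sequences(existing, rep_db,
                             db_subset(sim$db, 1L), crit), "collide")
})
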