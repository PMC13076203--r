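arch1 <- function(ids, label) {
  a <- lapply(ids, function(i) label)
  names(a) <- ids
  a
}

test_that("sensitivity implements the architecture-recall formula", {
  # 4 sequences of architecture X: 3 co-clustered, 1 elsewhere
  cl <- clustering(c(a = "a", b = "a", c = "a", d = "d", e = "d"))
  arch <- c(arch1(c("a", "b", "c", "d"), "X"), arch1("e", "Y"))
  res <- evaluate_clustering(cl, arch)
  per <- structure(res$per_sequence$sensitivity, names = res$per_sequence$id)
  expect_equal(unname(per[c("a", "b", "c")]), rep(3 / 4, 3))
  expect_equal(unname(per[["d"]]), 1 / 4)
  expect_equal(mean(per[c("a", "b", "c", "d")]), 0.625)
  expect_equal(sequence_sensitivity("d", cl, arch), 1 / 4)

  # unique architecture scores 1 wherever it lands
  expect_equal(sequence_sensitivity("e", cl, arch), 1.0)
})

test_that("precision counts clan-equivalent members of the cluster", {
  cl <- clustering(c(a = "a", b = "a", c = "a", d = "a", s = "s"))
  arch <- c(arch1(c("a", "b", "c"), "X"), arch1("d", "Y"), arch1("s", "Z"))
  res <- evaluate_clustering(cl, arch)
  per <- structure(res$per_sequence$precision, names = res$per_sequence$id)
  expect_equal(unname(per[c("a", "b", "c")]), rep(3 / 4, 3))
  expect_equal(unname(per[["d"]]), 1 / 4)
  expect_equal(unname(per[["s"]]), 1.0)  # singleton cluster

  # same clan => mutually precise
  clans <- c(X = "CL1", Y = "CL1")
  res2 <- evaluate_clustering(cl, arch, clans)
  per2 <- structure(res2$per_sequence$precision, names = res2$per_sequence$id)
  expect_equal(unname(per2[c("a", "b", "c", "d")]), rep(1.0, 4))
  expect_equal(sequence_precision("d", cl, arch, clans), 1.0)

  # clan equivalence is positional and length-aware
  arch3 <- list(p = c("X", "Y"), q = c("Y", "X"), r = c("X", "Y", "X"))
  cl3 <- clustering(c(p = "p", q = "p", r = "p"))
  res3 <- evaluate_clustering(cl3, arch3)
  expect_true(all(res3$per_sequence$precision == 1 / 3))
  res3c <- evaluate_clustering(cl3, arch3, c(X = "C", Y = "C"))
  pr <- structure(res3c$per_sequence$precision, names = res3c$per_sequence$id)
  expect_equal(unname(pr[["p"]]), 2 / 3)  # p ~ q under the clan map, not r
})

test_that("evaluation fixed points hold exactly", {
  sim <- simulate_families(family_spec(families = 6, members = c(4L, 6L),
                                       singletons = 8L, seed = 53L))
  truth <- sim$truth
  res <- evaluate_clustering(truth$clustering, truth$architectures,
                             truth$clans)
  expect_identical(res$mean_sensitivity, 1.0)
  expect_identical(res$mean_precision, 1.0)

  ids <- names(truth$clustering)
  singles <- clustering(structure(ids, names = ids))
  res_s <- evaluate_clustering(singles, truth$architectures, truth$clans)
  expect_identical(res_s$mean_precision, 1.0)
  akey <- vapply(truth$architectures[ids], paste, character(1), collapse = ",")
  class_size <- table(akey)
  expect_equal(res_s$mean_sensitivity,
               mean(1 / as.vector(class_size[akey])))

  big <- clustering(structure(rep(ids[1], length(ids)), names = ids))
  res_b <- evaluate_clustering(big, truth$architectures, truth$clans)
  expect_identical(res_b$mean_sensitivity, 1.0)
  ckey <- vapply(truth$architectures[ids], function(l) {
    cs <- truth$clans
    paste(ifelse(l %in% names(cs), unname(cs[l]), l), collapse = ",")
  }, character(1))
  cls_size <- table(ckey)
  expect_equal(res_b$mean_precision,
               mean(as.vector(cls_size[ckey])) / length(ids))
})

test_that("evaluation equals the naive quadratic recomputation", {
  set.seed(59)
  for (k in 1:5) {
    n <- 40
    ids <- sprintf("q%02d", seq_len(n))
    reps <- ids[1:8]
    cl <- clustering(structure(c(reps, reps[sample(8, n - 8, TRUE)]),
                               names = c(reps, ids[-(1:8)])))
    labels <- c("X", "Y", "Z", "W")
    ann_ids <- sample(ids, 30)
    arch <- lapply(ann_ids, function(i)
      sample(labels, sample(1:2, 1), replace = TRUE))
    names(arch) <- ann_ids
    clans <- c(X = "C1", Y = "C1")
    res <- evaluate_clustering(cl, arch, clans)
    ref <- naive_eval(cl, arch, clans)
    expect_equal(res$per_sequence$sensitivity, unname(ref$sens))
    expect_equal(res$per_sequence$precision, unname(ref$prec))
    expect_equal(res$mean_sensitivity, mean(ref$sens))
  }
})

test_that("merging helps sensitivity, splitting helps precision, labels are immaterial", {
  set.seed(61)
  ids <- sprintf("q%02d", 1:30)
  arch <- lapply(seq_along(ids), function(k) sample(c("X", "Y", "Z"), 1))
  names(arch) <- ids
  reps <- ids[1:6]
  asg <- structure(c(reps, reps[sample(6, 24, TRUE)]),
                   names = c(reps, ids[-(1:6)]))
  cl <- clustering(asg)
  base <- evaluate_clustering(cl, arch)

  # merge clusters 1 and 2
  merged_asg <- ifelse(asg == reps[2], reps[1], asg)
  names(merged_asg) <- names(asg)
  merged <- evaluate_clustering(clustering(merged_asg), arch)
  expect_true(all(merged$per_sequence$sensitivity >=
                  base$per_sequence$sensitivity))

  # split cluster 1 into singletons
  in1 <- names(asg)[asg == reps[1]]
  split_asg <- asg; split_asg[in1] <- in1
  split <- evaluate_clustering(clustering(split_asg), arch)
  expect_true(all(split$per_sequence$precision >=
                  base$per_sequence$precision))

  # relabeling representatives does not change the metrics
  relab <- vapply(split(names(asg), asg),
                  function(x) sort(x, decreasing = TRUE)[1], character(1))
  relab_cl <- clustering(structure(unname(relab[asg]), names = names(asg)))
  res_rel <- evaluate_clustering(relab_cl, arch)
  expect_equal(res_rel$per_sequence$sensitivity, base$per_sequence$sensitivity)
  expect_equal(res_rel$per_sequence$precision, base$per_sequence$precision)

  # annotated id missing from the clustering is an integrity error
  expect_error(evaluate_clustering(cl, c(arch, arch1("zz", "X"))), "absent")
})
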