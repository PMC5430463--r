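mk_aln <- function(pairs, aligner = NA_character_) {
  ppi_alignment(pairs, "S", "T", aligner = aligner)
}

test_that("unify takes the union of mappings and records per-pair support", {
  f1 <- mk_aln(rbind(c("a", "x")), "A1")
  f2 <- mk_aln(rbind(c("a", "x"), c("b", "y")), "A2")
  u <- unify_alignments(list(f1, f2))
  expect_equal(nrow(u$pairs), 2L)
  key <- paste(u$pairs$source, u$pairs$target)
  expect_setequal(key, c("a x", "b y"))
  expect_equal(u$support[[which(key == "a x")]], c("A1", "A2"))
  expect_equal(u$support[[which(key == "b y")]], "A2")
  expect_equal(u$pairs$support_count[which(key == "a x")], 2L)

  single <- unify_alignments(list(f2))
  expect_equal(nrow(single$pairs), 2L)
  expect_true(all(single$pairs$support_count == 1L))
})

test_that("disjoint alignments stack; |pairs| is bounded by the sum of sizes", {
  set.seed(51)
  net1 <- random_network(10, 0.3, "S", "a")
  net2 <- random_network(40, 0.2, "T", "b")
  chunks <- split(network_nodes(net2)[1:40], rep(1:4, each = 10))
  disjoint <- lapply(chunks, function(tg)
    ppi_alignment(cbind(network_nodes(net1), sample(tg, 10)), "S", "T"))
  u <- unify_alignments(disjoint, labels = paste0("d", 1:4))
  expect_equal(nrow(u$pairs), 40L)
  for (rep in 1:10) {
    alns <- replicate(3, random_injection(net1, net2), simplify = FALSE)
    u2 <- unify_alignments(alns, labels = paste0("r", 1:3))
    expect_lte(nrow(u2$pairs), sum(vapply(alns, alignment_size, integer(1L))))
  }
  mixed <- ppi_alignment(rbind(c("a01", "b01")), "S", "ELSEWHERE")
  expect_error(unify_alignments(list(disjoint[[1]], mixed)), "network pair")
})

test_that("coverage curves start at 0, are monotone, and honour set unions", {
  v2 <- sprintf("t%02d", 1:10)
  net2 <- ppi_network(v2, rbind(c("t01", "t02")), "T")
  nested <- lapply(c(6, 4, 2), function(k)
    ppi_alignment(cbind(sprintf("s%02d", 1:k), v2[1:k]), "S", "T"))
  curve <- coverage_curve(nested, net2, side = "target")
  expect_equal(curve, c(0, 0.6, 0.6, 0.6))  # nested images, largest first
  rep_curve <- coverage_curve(nested[c(1, 1, 1)], net2)
  expect_equal(rep_curve, c(0, 0.6, 0.6, 0.6))

  set.seed(52)
  net1 <- random_network(8, 0.3, "S", "s")
  big <- random_network(15, 0.3, "T", "t")
  for (rep in 1:20) {
    alns <- replicate(4, random_injection(net1, big), simplify = FALSE)
    cv <- coverage_curve(alns, big)
    expect_equal(cv[1], 0)
    expect_true(all(diff(cv) >= -1e-12) && all(cv <= 1 + 1e-12))
  }
})

test_that("soft clusters group sources by shared target and re-flatten exactly", {
  u <- unify_alignments(list(mk_aln(rbind(c("a", "x"), c("b", "y")), "A1"),
                             mk_aln(rbind(c("b", "x"), c("a", "y")), "A2")))
  cl <- soft_clusters(u)
  expect_setequal(cl[["x"]], c("a", "b"))
  expect_setequal(cl[["y"]], c("a", "b"))
  flat <- flatten_clusters(cl)
  expect_setequal(paste(flat$source, flat$target),
                  paste(u$pairs$source, u$pairs$target))

  one_to_one <- soft_clusters(unify_alignments(list(mk_aln(rbind(c("a", "x"), c("b", "y"))))))
  expect_true(all(lengths(one_to_one) == 1L))
  shared <- soft_clusters(unify_alignments(list(mk_aln(rbind(c("a", "z"))),
                                                mk_aln(rbind(c("b", "z"))),
                                                mk_aln(rbind(c("c", "z"))))))
  expect_length(shared, 1L)
  expect_setequal(shared[["z"]], c("a", "b", "c"))
})

test_that("flatten round-trips on random unions and through unified-mapping files", {
  set.seed(53)
  net1 <- random_network(10, 0.3, "S", "a")
  net2 <- random_network(20, 0.3, "T", "b")
  for (rep in 1:15) {
    alns <- replicate(3, random_injection(net1, net2), simplify = FALSE)
    u <- unify_alignments(alns, labels = paste0("f", 1:3))
    flat <- flatten_clusters(soft_clusters(u))
    expect_setequal(paste(flat$source, flat$target),
                    paste(u$pairs$source, u$pairs$target))
  }
  u <- unify_alignments(replicate(3, random_injection(net1, net2), simplify = FALSE),
                        labels = paste0("f", 1:3))
  path <- withr::local_tempfile()
  write_unified(u, path)
  back <- read_unified(path, "S", "T")
  expect_equal(back$pairs$source, u$pairs$source)
  expect_equal(back$pairs$target, u$pairs$target)
  expect_equal(back$support, u$support)
})

test_that("transfer consistency scores clusters against target annotations", {
  cl <- structure(list(x = c("a", "b"), y = "c", z = "d"),
                  class = "soft_clustering")
  ann_src <- annotation_set(list(a = "T1", b = "T2", c = "T3", d = "T4"), "GO-BP")
  # x annotated and consistent via b; y annotated, inconsistent; z unannotated
  ann_tgt <- annotation_set(list(x = "T2", y = "T9"), "GO-BP")
  expect_equal(transfer_consistency(cl, ann_src, ann_tgt), 0.5)

  miss <- annotation_set(list(x = "T9", y = "T9"), "GO-BP")
  expect_equal(transfer_consistency(cl, ann_src, miss), 0)
  none <- annotation_set(list(other = "T1"), "GO-BP")
  expect_warning(expect_true(is.na(transfer_consistency(cl, ann_src, none))))
})

test_that("unifying partial alignments covers more targets than any single one", {
  set.seed(54)
  gains <- replicate(25, {
    spec <- synthetic_spec(n1 = 30L, n2 = 40L, seed = sample.int(1e6, 1L))
    sim <- make_network_pair(spec)
    # each alignment drops a random third of the planted pairs
    alns <- lapply(1:3, function(i) {
      keep <- sort(sample.int(30L, 20L))
      ppi_alignment(sim$planted$pairs[keep, ], "G1", "G2",
                    aligner = paste0("part", i))
    })
    u <- unify_alignments(alns)
    best_single <- max(vapply(alns, function(a)
      length(unique(a$pairs$target)), integer(1L)))
    length(unique(u$pairs$target)) - best_single
  })
  expect_gt(mean(gains), 0)
  expect_true(all(gains >= 0))
})
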