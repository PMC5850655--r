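# NJ construction, bipartitions, topology identity, rooting, induced
# subtrees, Newick I/O.

test_that("NJ recovers the quartet topology from an additive matrix", {
  tr <- parse_newick("((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(d)
  expect_true(same_topology(nj, tr))
  # and it is the least-squares optimum over all three quartet topologies
  expect_true(same_topology(nj, best_ls_topology(d)))
})

test_that("NJ is consistent on random additive matrices (exhaustive oracle)", {
  set.seed(31)
  for (rep in 1:10) {
    gen <- random_additive(6, min_len = 0.1)
    nj <- neighbor_joining(gen$d)
    expect_true(same_topology(nj, gen$tree))
    expect_true(same_topology(nj, best_ls_topology(gen$d)))
  }
})

test_that("NJ edge cases: 3 taxa, zero matrix, validation", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  star <- neighbor_joining(d3)
  expect_equal(sort(star$tip.label), c("a", "b", "c"))
  expect_equal(star$Nnode, 1)
  # three-point formulas: a = (3+4-5)/2 = 1, b = 2, c = 3
  expect_equal(sort(star$edge.length), c(1, 2, 3))

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- neighbor_joining(z)
  expect_equal(length(tz$tip.label), 4)
  expect_true(all(tz$edge.length == 0))
  expect_length(split_keys(tz), 1) # some binary resolution

  asym <- z; asym[1, 2] <- 1e-6
  expect_error(neighbor_joining(asym), "not symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  # negative branch estimates are clamped to zero
  set.seed(5)
  noisy <- random_additive(6)$d + matrix(runif(36, 0, 1e-4), 6, 6)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  expect_true(all(neighbor_joining(noisy)$edge.length >= 0))
})

test_that("bipartitions enumerate interior branches canonically", {
  q <- parse_newick("((A,B),(C,D));")
  bp <- bipartitions(q)
  expect_length(bp, 1)
  expect_equal(bp[[1]]$side_a, c("A", "B"))
  expect_equal(bp[[1]]$side_b, c("C", "D"))

  cat5 <- parse_newick("((((A,B),C),D),E);")
  sides <- lapply(bipartitions(cat5), function(s) sort(s$side_b))
  expect_length(sides, 2)
  expect_true(any(sapply(sides, identical, c("C", "D", "E"))))
  expect_true(any(sapply(sides, identical, c("D", "E"))))

  star4 <- parse_newick("(A,B,C,D);")
  expect_length(split_keys(star4), 0)

  # split count conservation: n - 3 for binary unrooted trees
  set.seed(9)
  for (n in 5:8) {
    tr <- ape::unroot(ape::rtree(n))
    expect_length(split_keys(tr), n - 3)
  }
})

test_that("same_topology matches an independent Robinson-Foulds oracle", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_false(same_topology(t1, t2))
  t1b <- t1; t1b$edge.length <- runif(nrow(t1$edge))
  expect_true(same_topology(t1, t1b))
  expect_error(same_topology(t1, parse_newick("((A,B),(C,E));")),
               "different leaf sets")

  set.seed(17)
  for (rep in 1:50) {
    a <- ape::unroot(ape::rtree(8))
    b <- ape::unroot(ape::rtree(8)) # same t1..t8 leaf set as a
    rf <- phangorn::RF.dist(a, b)
    expect_equal(same_topology(a, b), rf == 0)
    # and a rerepresented copy is always identical
    expect_true(same_topology(a, rerepresent(a)))
    expect_equal(phangorn::RF.dist(a, rerepresent(a)), 0)
  }
})

test_that("same_topology is an equivalence relation", {
  set.seed(23)
  a <- ape::unroot(ape::rtree(7))
  b <- rerepresent(a)
  c <- rerepresent(b)
  expect_true(same_topology(a, a))                        # reflexive
  expect_equal(same_topology(a, b), same_topology(b, a))  # symmetric
  expect_true(!same_topology(a, b) || !same_topology(b, c) || same_topology(a, c))
})

test_that("outgroup rooting defines the expected clades", {
  q <- parse_newick("((A,B),(C,D));")
  r <- root_at(q, "D")
  expect_true(ape::is.rooted(r))
  clades <- lapply(enumerate_clades(r), `[[`, "clade_taxa")
  expect_true(any(sapply(clades, identical, c("A", "B"))))
  expect_true(any(sapply(clades, identical, c("A", "B", "C"))))

  # rooting then unrooting is a topology no-op
  expect_true(same_topology(ape::unroot(r), q))

  # rooting at A vs B gives different clade sets sharing {C,D}
  ca <- lapply(enumerate_clades(root_at(q, "A")), `[[`, "clade_taxa")
  cb <- lapply(enumerate_clades(root_at(q, "B")), `[[`, "clade_taxa")
  expect_true(any(sapply(ca, identical, c("C", "D"))))
  expect_true(any(sapply(cb, identical, c("C", "D"))))
  expect_false(identical(ca, cb))

  expect_error(root_at(q, "Z"), "not in tree")
})

test_that("induced subtrees restrict the split set", {
  cat5 <- parse_newick("((((A,B),C),D),E);")
  s3 <- induced_subtree(cat5, c("A", "B", "C"))
  expect_equal(sort(s3$tip.label), c("A", "B", "C"))
  expect_length(split_keys(s3), 0)

  expect_true(same_topology(induced_subtree(cat5, cat5$tip.label), cat5))

  t <- parse_newick("(((A,B),C),(D,E));")
  s4 <- induced_subtree(t, c("A", "C", "D", "E"))
  expect_true(same_topology(s4, parse_newick("((A,C),(D,E));")))

  expect_error(induced_subtree(cat5, c("A", "B")), "at least 3")
  expect_error(induced_subtree(cat5, c("A", "B", "Z")), "not in tree")
})

test_that("Newick I/O round-trips and writes support labels", {
  t <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_equal(length(t$tip.label), 4)
  expect_length(split_keys(t), 1)

  expect_error(parse_newick("((A,B),(C,D);"), "malformed")

  expect_equal(format_support_label(97, 100), "97|100")
  expect_equal(format_support_label(100, NA), "100|NA")

  set.seed(3)
  tr <- ape::rtree(10)
  back <- parse_newick(write_newick(tr))
  expect_true(same_topology(back, tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  # Pb|Ps annotation lands on the right internal nodes
  r <- root_at(parse_newick("((A,B),(C,D));"), "D")
  pb <- c("A,B" = 97, "A,B,C" = 93)
  ps <- c("A,B" = NA, "A,B,C" = 100)
  txt <- write_newick(r, annotation = "pb_ps", pb = pb, ps = ps)
  expect_match(txt, "97|NA", fixed = TRUE)
  expect_match(txt, "93|100", fixed = TRUE)
  reparsed <- parse_newick(txt)
  expect_true(same_topology(reparsed, r))
  expect_true("97|NA" %in% reparsed$node.label)
})
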