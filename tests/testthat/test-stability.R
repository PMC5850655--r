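# Clade enumeration, closest outgroups, and the subtree stability statistic.

test_that("clade enumeration on a rooted caterpillar", {
  r <- root_at(parse_newick("((((s1,s2),s3),s4),s5);"), "s5")
  recs <- enumerate_clades(r)
  clades <- lapply(recs, `[[`, "clade_taxa")
  expect_true(any(sapply(clades, identical, c("s1", "s2"))))
  expect_true(any(sapply(clades, identical, c("s1", "s2", "s3"))))
  expect_true(any(sapply(clades, identical, c("s1", "s2", "s3", "s4"))))
  eligible <- sapply(recs, `[[`, "eligible")
  names(eligible) <- sapply(clades, paste, collapse = ",")
  expect_false(eligible[["s1,s2"]])                  # two-taxon clade
  expect_true(eligible[["s1,s2,s3"]])
  expect_false(eligible[["s1,s2,s3,s4"]])            # child of root: no outgroup
  expect_equal(recs[[which(sapply(clades, identical, c("s1", "s2", "s3", "s4")))]]$reason,
               "no-outgroup")
  # ordering: increasing size
  expect_true(!is.unsorted(lengths(clades)))
})

test_that("balanced quartet has only two-taxon clades and errors unrooted", {
  r <- root_at(parse_newick("((A,B),C,D);"), "D")
  # rooted at D: clades {A,B} (size 2) and {A,B,C} (child of root)
  recs <- enumerate_clades(r)
  expect_false(any(sapply(recs, `[[`, "eligible")))

  # balanced rooted quartet: both clades are two-taxon, none eligible
  bal <- enumerate_clades(parse_newick("((A,B),(C,D));"))
  expect_setequal(sapply(bal, function(x) paste(x$clade_taxa, collapse = ",")),
                  c("A,B", "C,D"))
  expect_false(any(sapply(bal, `[[`, "eligible")))

  expect_error(enumerate_clades(parse_newick("((A,B),C,D);")), "root")
})

test_that("an 8-leaf rooted tree has n-2 clades below the root", {
  set.seed(13)
  tr <- root_at(ape::unroot(ape::rtree(8)), "t8")
  expect_length(enumerate_clades(tr), 6)
})

test_that("closest outgroups are exactly the sister-group leaves", {
  # ladder of 1..6 with a sister clade of 7..11, rooted by taxon 12:
  txt <- "(((((((1,2),3),4),5),6),((7,8),(9,(10,11)))),12);"
  r <- root_at(parse_newick(txt), "12")
  recs <- enumerate_clades(r)
  clades <- sapply(recs, function(x) paste(x$clade_taxa, collapse = ","))
  rec123 <- recs[[which(clades == "1,2,3")]]
  expect_equal(closest_outgroups(rec123), "4")
  rec1_4 <- recs[[which(clades == "1,2,3,4")]]
  expect_equal(closest_outgroups(rec1_4), "5")
  rec1_6 <- recs[[which(clades == "1,2,3,4,5,6")]]
  expect_equal(closest_outgroups(rec1_6), c("10", "11", "7", "8", "9"))
  expect_setequal(closest_outgroups(rec1_6), as.character(7:11))
})

test_that("ps arithmetic: ps = 100 s/N and the mean is unweighted", {
  aln <- simulate_alignment(caterpillar_tree(7, 0.05, 0.05), 600, seed = 4)
  tree <- neighbor_joining(distance_matrix(aln))
  stab <- suppressMessages(suppressWarnings(
    stability_profile(aln, tree, root_outgroup = "t7",
                      replicates = 25, seed = 4)))
  eligible <- Filter(function(s) !is.na(s$ps_mean), stab)
  expect_gt(length(eligible), 0)
  for (s in eligible) {
    expect_equal(s$per_outgroup$ps, 100 * s$per_outgroup$s / s$per_outgroup$N)
    expect_equal(s$ps_mean, mean(s$per_outgroup$ps))
    expect_true(all(s$per_outgroup$s >= 0 & s$per_outgroup$s <= s$per_outgroup$N))
    expect_true(all(s$per_outgroup$N == 25))
  }
})

test_that("identity bootstrap gives ps = 100 for every eligible clade", {
  aln <- gappy_signal_alignment(7, 600, seed = 21)
  tree <- neighbor_joining(distance_matrix(aln))
  stab <- suppressMessages(suppressWarnings(
    stability_profile(aln, tree, root_outgroup = aln$taxa[7],
                      replicates = 20, seed = 1, identity_bootstrap = TRUE)))
  eligible <- Filter(function(s) !is.na(s$ps_mean), stab)
  expect_gt(length(eligible), 0)
  for (s in eligible) {
    expect_equal(s$ps_mean, 100)
    expect_true(all(s$per_outgroup$s == s$per_outgroup$N))
  }
})

test_that("single-outgroup stability validates its inputs", {
  aln <- simulate_alignment(caterpillar_tree(6, 0.05, 0.05), 300, seed = 6)
  tree <- neighbor_joining(distance_matrix(aln))
  recs <- enumerate_clades(root_at(tree, "t6"))
  clades <- sapply(recs, function(x) paste(x$clade_taxa, collapse = ","))
  rec2 <- recs[[which(clades == "t1,t2")]]
  expect_error(ps_single_outgroup(aln, tree, rec2, "t3", replicates = 10),
               "two-taxon")
  rec3 <- recs[[which(clades == "t1,t2,t3")]]
  expect_error(suppressWarnings(ps_single_outgroup(aln, tree, rec3, "t6", replicates = 10)),
               "not a closest-outgroup")
  res <- suppressWarnings(ps_single_outgroup(aln, tree, rec3, "t4",
                                             replicates = 10, seed = 3))
  expect_equal(res$N, 10)
  expect_equal(res$ps, 100 * res$s / 10)
})

test_that("ps_averaged equals single-outgroup runs and is order-invariant", {
  aln <- simulate_alignment(
    parse_newick("((((a:.05,b:.05):.05,c:.05):.05,(d:.05,(e:.05,f:.05):.05):.05):.05,g:.1);"),
    500, seed = 9)
  tree <- neighbor_joining(distance_matrix(aln))
  recs <- enumerate_clades(root_at(tree, "g"))
  ab_c <- Filter(function(r) r$eligible && length(r$sister_taxa) > 1, recs)
  expect_gt(length(ab_c), 0) # this fixture yields a multi-outgroup clade
  rec <- ab_c[[1]]
  avg <- suppressWarnings(ps_averaged(aln, tree, rec, replicates = 20, seed = 2))
  expect_equal(avg$ps_mean, mean(avg$per_outgroup$ps))
  # each per-outgroup row must equal an independent single-outgroup run,
  # whatever order the outgroups are evaluated in
  for (og in rev(closest_outgroups(rec))) {
    single <- suppressWarnings(ps_single_outgroup(aln, tree, rec, og,
                                                  replicates = 20, seed = 2))
    row <- avg$per_outgroup[avg$per_outgroup$outgroup == og, ]
    expect_equal(row$s, single$s)
    expect_equal(row$ps, single$ps)
  }
})

test_that("stability under no signal stays well below certainty", {
  # zero-length internal branch above {t1,t2,t3}: the subtree resolution is
  # arbitrary, so its stability must not look certain
  true <- zero_branch_above(caterpillar_tree(8, 0.05, 0.05), c("t1", "t2", "t3"))
  aln <- simulate_alignment(true, 2000, seed = 1)
  tree <- neighbor_joining(distance_matrix(aln))
  stab <- suppressMessages(suppressWarnings(
    stability_profile(aln, tree, root_outgroup = "t8",
                      replicates = 200, seed = 1)))
  strong <- setdiff(split_keys(true),
                    substab:::.split_key(c("t1", "t2", "t3"), true$tip.label))
  amb <- ambiguous_clades(stab, strong, region = c("t1", "t2", "t3"))
  expect_gt(length(amb), 0)
  for (s in amb) expect_lte(s$ps_mean, 90)
})
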