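test_that("parse_newick reads supports, rescales 0-1 values, rejects bad input", {
  tr <- parse_newick("(A:1,(B:1,C:1)90:1);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(support_values(tr), c(NA, 90))

  rescaled <- parse_newick("(A:1,(B:1,C:1)0.9:1);")
  expect_equal(support_values(rescaled), c(NA, 90))

  expect_error(parse_newick("(A,(A,B));"), "duplicate leaf labels")
  expect_error(parse_newick("(A,(B,C);"), "character")
  expect_error(parse_newick("(A,(B,C))"), ";")

  # branch-comment support (RAxML bipartition style), behind the switch
  tr2 <- parse_newick("(A:1,(B:1,C:1):0.5[85]);", support_in_comments = TRUE)
  expect_equal(support_values(tr2), c(NA, 85))
})

test_that("write_newick round-trips and omits absent supports", {
  nwk <- "(A:1,(B:1,C:1)90:1);"
  again <- write_newick(parse_newick(nwk))
  expect_true(trees_equal(parse_newick(nwk), parse_newick(again)))
  expect_equal(support_values(parse_newick(again)), c(NA, 90))

  plain <- parse_newick("(A:1,(B:2,C:3):1);")
  expect_false(grepl(")[0-9]", write_newick(plain)))

  poly <- parse_newick("(A,B,C,(D,E));")
  expect_equal(parse_newick(write_newick(poly))$Nnode, 2L)
})

test_that("parse/write identity holds on random trees (property)", {
  set.seed(20260911)
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    tr <- ape::rtree(n)
    tr <- set_support(tr, sample(0:100, tr$Nnode, replace = TRUE))
    attr(tr, "rooted") <- TRUE
    back <- parse_newick(write_newick(tr))
    expect_true(trees_equal(tr, back))
    expect_equal(support_values(back), support_values(tr))
  }
})

test_that("reroot_on_outgroup separates outgroups, signals otherwise", {
  tr <- parse_newick("(A,B,(C,(O1,O2)));")
  rooted <- reroot_on_outgroup(tr, c("O1", "O2"))
  expect_true(is_rooted(rooted))
  sets <- lapply(clades_of(rooted), `[[`, "taxa")
  expect_true(any(vapply(sets, setequal, logical(1), y = c("O1", "O2"))) ||
                any(vapply(sets, setequal, logical(1), y = c("A", "B", "C"))))

  expect_error(reroot_on_outgroup(parse_newick("(A,B,(O1,(C,O2)));"),
                                  c("O1", "O2")),
               class = "nonmonophyletic_outgroup")
  expect_error(reroot_on_outgroup(parse_newick("(A,B,(C,D));"),
                                  c("O1", "O2")),
               class = "not_rootable")
})

test_that("reroot_on_outgroup is idempotent and preserves path lengths", {
  set.seed(42)
  for (i in 1:25) {
    tr <- ape::rtree(8, tip.label = c(paste0("t", 1:6), "O1", "O2"))
    tr <- ape::unroot(tr)
    rooted <- tryCatch(reroot_on_outgroup(tr, c("O1", "O2")),
                       tree_rooting_error = function(e) NULL)
    if (is.null(rooted)) next
    s <- sort(tr$tip.label)
    expect_equal(sort(tip_dist(rooted)[s, s][upper.tri(diag(8))]),
                 sort(tip_dist(tr)[s, s][upper.tri(diag(8))]))
    again <- reroot_on_outgroup(rooted, c("O1", "O2"))
    expect_equal(sort(tip_dist(again)[s, s][upper.tri(diag(8))]),
                 sort(tip_dist(rooted)[s, s][upper.tri(diag(8))]))
  }
})

test_that("clades_of enumerates non-trivial clades of rooted trees only", {
  tr <- parse_newick("((A,B)80,(C,D)60);")
  attr(tr, "rooted") <- TRUE
  cl <- clades_of(tr)
  expect_length(cl, 2L)
  sets <- lapply(cl, `[[`, "taxa")
  expect_true(any(vapply(sets, setequal, logical(1), y = c("A", "B"))))
  supp <- vapply(cl, `[[`, numeric(1), "support")
  expect_setequal(supp, c(80, 60))

  star <- parse_newick("(A,B,C,D);")
  attr(star, "rooted") <- TRUE
  expect_length(clades_of(star), 0L)

  cat4 <- parse_newick("(((A,B),C),D);")
  catsets <- lapply(clades_of(cat4), `[[`, "taxa")
  expect_length(catsets, 2L)
  expect_true(any(vapply(catsets, setequal, logical(1), y = c("A", "B", "C"))))

  unrooted <- parse_newick("(A,B,(C,D));")
  expect_false(is_rooted(unrooted))
  expect_error(clades_of(unrooted), "rooted")
})

test_that("restrict_clade and clades_conflict follow set semantics", {
  expect_setequal(restrict_clade(clade(c("A", "B", "C")), c("A", "B", "D")),
                  c("A", "B"))
  expect_length(restrict_clade(clade(c("A", "B")), c("C", "D")), 0L)
  expect_setequal(restrict_clade(clade(c("A", "B")), c("A", "B")), c("A", "B"))

  expect_true(clades_conflict(c("A", "B"), c("A", "C")))
  expect_false(clades_conflict(c("A", "B"), c("A", "B", "C")))  # nested
  expect_false(clades_conflict(c("A", "B"), c("C", "D")))        # disjoint
})

test_that("clades_conflict is symmetric and never self-conflicting (property)", {
  set.seed(3)
  universe <- LETTERS[1:8]
  for (i in 1:200) {
    x <- sample(universe, sample(2:6, 1))
    y <- sample(universe, sample(2:6, 1))
    expect_identical(clades_conflict(x, y), clades_conflict(y, x))
    expect_false(clades_conflict(x, x))
    expect_false(clades_conflict(x, universe))
  }
})

test_that("tip_to_tip_depth measures the longest leaf path", {
  expect_equal(tip_to_tip_depth(
    parse_newick("(A:0.30,B:0.05,(C:0.05,D:0.05):0.05);")), 0.40)
  expect_equal(tip_to_tip_depth(parse_newick("(A:1,B:1);")), 2)
  # ultrametric depth-h rooted tree has tip-to-tip depth 2h
  expect_equal(tip_to_tip_depth(parse_newick("((A:1,B:1):1,(C:1,D:1):1);")), 4)
  expect_equal(tip_to_tip_depth(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
                                mode = "root_to_tip"), 2)
  expect_error(tip_to_tip_depth(parse_newick("(A:1,(B,C):1);")),
               "branch lengths")
})
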