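test_that("parent-vector parsing builds the documented tree", {
  tr <- read_mutation_tree("0 1 1", dialect = "parent_vector")
  expect_equal(n_mutations(tr), 3L)
  expect_equal(tr$parent[-1], c(0L, 1L, 1L))
  expect_equal(unname(tr$outdegree), c(1L, 2L, 0L, 0L))
})

test_that("malformed inputs are rejected", {
  expect_error(read_mutation_tree("2 1"), "malformed tree")
  expect_error(read_mutation_tree("", dialect = "parent_vector"), "malformed tree")
  expect_error(read_mutation_tree("0 1 x"), "malformed tree")
  expect_error(read_mutation_tree("0 1", dialect = "nonsense"), "unsupported format")
  expect_error(mutation_tree(c(0L, 3L, 2L)), "malformed tree") # 2-3 cycle
})

test_that("DOT digraphs parse, including re-rooting a labeled root", {
  star <- read_mutation_tree("digraph{0->1;0->2;}", dialect = "dot")
  expect_equal(unname(star$outdegree), c(2L, 0L, 0L))
  # root node carrying a mutation label gets a synthetic wild-type above it
  txt <- 'digraph{a [label="TP53"]; b [label="KRAS"]; a->b;}'
  tr <- read_mutation_tree(txt, dialect = "dot")
  expect_equal(n_mutations(tr), 2L)
  expect_equal(tr$label[-1], c("TP53", "KRAS"))
  expect_equal(tr$parent[-1], c(0L, 1L))
  expect_error(read_mutation_tree("digraph{0->1;2->1;}", dialect = "dot"),
               "malformed tree")
})

test_that("write/read round-trips preserve trees in both dialects", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_tree(sample(3:12, 1))
    pv <- write_mutation_tree(tr, dialect = "parent_vector")
    expect_equal(read_mutation_tree(pv)$parent, tr$parent)
    dot <- write_mutation_tree(tr, dialect = "dot")
    back <- read_mutation_tree(dot, dialect = "dot")
    expect_equal(back$parent, tr$parent)
    expect_equal(back$label, tr$label)
  }
})

test_that("structural invariants hold on random trees", {
  set.seed(21)
  for (i in 1:10) {
    tr <- random_tree(sample(4:15, 1))
    n <- n_mutations(tr)
    expect_equal(sum(tr$outdegree), n)
    sz <- subtree_sizes(tr)
    for (k in 0:n) {
      kids <- tr$children[[k + 1]]
      expect_equal(sz[k + 1], 1L + sum(sz[kids + 1]))
    }
    expect_equal(sz[1], n + 1L)
    expect_setequal(subtree_nodes(tr, 0L), 0:n)
  }
})

test_that("mutation profiles apply gains and losses along root paths", {
  chain <- mutation_tree(c(0L, 1L), label = c("A", "B"))
  expect_equal(sort(mutation_profiles(chain)[["2"]]), c("A", "B"))
  expect_equal(mutation_profiles(chain)[["0"]], character(0))

  lossy <- mutation_tree(c(0L, 1L), label = c("A", "A"), loss = c(FALSE, TRUE))
  expect_equal(mutation_profiles(lossy)[["2"]], character(0))

  star <- mutation_tree(c(0L, 0L), label = c("A", "B"))
  expect_equal(mutation_profiles(star)[["1"]], "A")
  expect_equal(mutation_profiles(star)[["2"]], "B")

  bad <- mutation_tree(c(0L, 1L), label = c("A", "B"), loss = c(FALSE, TRUE))
  expect_error(mutation_profiles(bad), "inconsistent loss")
})

test_that("genotype matrices round-trip and reject bad codes", {
  m <- matrix(c(0L, 1L, 3L, 1L, 0L, 1L), nrow = 3)
  gm <- genotype_matrix(m, alpha = 0.1, beta = 1e-5)
  expect_equal(read_genotype_matrix(write_genotype_matrix(gm))$data, m)
  # SCITE orientation transposes on disk but round-trips
  expect_equal(read_genotype_matrix(write_genotype_matrix(gm, scite = TRUE),
                                    scite = TRUE)$data, m)
  expect_error(read_genotype_matrix("0 1 2"), "invalid genotype code")
  expect_error(read_genotype_matrix("   "), "no cells")
  expect_error(genotype_matrix(matrix(integer(0), 0, 0)), "no cells")
})

test_that("Newick export is a valid ultrametric binary phylogeny", {
  skip_if_not_installed("ape")
  set.seed(31)
  tr <- random_tree(7)
  th <- c(1, runif(7, 0.5, 2))
  fit <- optimize_times(tr, th, horizon = 5)
  nwk <- as_newick(tr, fit$times, 5, default_orderings(tr))
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), n_mutations(tr) + 1L)
  expect_true(ape::is.binary(ph))
  depths <- ape::node.depth.edgelength(ph)[seq_len(ape::Ntip(ph))]
  # ultrametric: every clone sampled at H (root stalk carried as root.edge)
  expect_lt(diff(range(depths)), 1e-6)
  expect_equal(depths[1] + ph$root.edge, 5, tolerance = 1e-6)
})

test_that("DOT output colors nodes by rate when rates are given", {
  tr <- mutation_tree(c(0L, 1L, 1L))
  txt <- write_mutation_tree(tr, dialect = "dot", rates = c(NA, 1, 2, 3))
  expect_match(txt, "fillcolor")
  expect_match(txt, "#2CA02C", ignore.case = TRUE) # lowest rate is green
})
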