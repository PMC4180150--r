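test_that("progressive alignment handles identities, gaps and length bounds", {
  two <- progressive_align(c(a = "MCCQPSCC", b = "MCCQPSCC"))
  expect_equal(unname(two["a"]), "MCCQPSCC")
  expect_false(any(grepl("-", two)))

  # one gap column; pairwise score equals the global alignment oracle
  pa <- progressive_align(c(x = "ACDE", y = "ADE"), gap_open = -10,
                          gap_extend = -1)
  expect_equal(nchar(pa[["x"]]), 4L)
  expect_equal(sum(strsplit(pa[["y"]], "")[[1]] == "-"), 1L)
  B <- kapkit:::aa_alphabet()
  oracle <- Biostrings::pairwiseAlignment("ACDE", "ADE", type = "global",
                                          substitutionMatrix = B,
                                          gapOpening = 9, gapExtension = 1)
  cols <- cbind(strsplit(pa[["x"]], "")[[1]], strsplit(pa[["y"]], "")[[1]])
  sc <- sum(apply(cols, 1, function(r) {
    if (any(r == "-")) NA else B[r[1], r[2]]
  }), na.rm = TRUE) - 10  # one gap of length 1
  expect_equal(sc, Biostrings::score(oracle))

  # alignment length at least the longest input, rows equal length
  set.seed(4)
  prots <- setNames(vapply(1:6, function(i)
    paste(sample(kapkit:::AA20, sample(30:60, 1), TRUE), collapse = ""), ""),
    paste0("p", 1:6))
  aln <- progressive_align(prots)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_gte(nchar(aln[[1]]), max(nchar(prots)))
  expect_error(progressive_align(c(a = "ACDE")), "at least 2")
})

test_that("p-distances follow the stated deletion modes", {
  expect_equal(p_distance_matrix(c(a = "ACDE", b = "ACDE"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "ACDE", b = "ACDF"))["a", "b"], 0.25)
  expect_equal(p_distance_matrix(c(a = "AC-E", b = "ACDE"),
                                 gap_mode = "pairwise")["a", "b"], 0)
  # complete deletion drops the gapped column for every pair
  D <- p_distance_matrix(c(a = "AC-E", b = "ACDE", c = "TCDE"),
                         gap_mode = "complete")
  expect_equal(D["a", "c"], 1 / 3)
  expect_error(p_distance_matrix(c(a = "--AA", b = "BB--")), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  # fixed 4-taxon additive case: ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  D["A","B"] <- D["B","A"] <- 3
  D["A","C"] <- D["C","A"] <- 5
  D["A","D"] <- D["D","A"] <- 6
  D["B","C"] <- D["C","B"] <- 6
  D["B","D"] <- D["D","B"] <- 7
  D["C","D"] <- D["D","C"] <- 7
  tr <- neighbor_joining(D)
  # the AB|CD split is the only zero-residual quartet under least squares
  fits <- lapply(list(list(c(1,2), c(3,4)), list(c(1,3), c(2,4)),
                      list(c(1,4), c(2,3))), function(s)
                        oracle_ls_quartet(D, s))
  expect_equal(which.min(vapply(fits, `[[`, 0, "rss")), 1L)
  expect_lt(fits[[1]]$rss, 1e-20)
  ab <- ape::getMRCA(ape::root(tr, "D"), c("A", "B"))
  expect_equal(sort(ape::extract.clade(ape::root(tr, "D"), ab)$tip.label),
               c("A", "B"))
  # NJ branch lengths equal the least-squares (true) lengths
  m <- ape::cophenetic.phylo(tr)
  expect_equal(m[rownames(D), colnames(D)], D, tolerance = 1e-10)

  # random additive 5-8 taxon matrices: topology and path lengths recovered
  set.seed(10)
  for (n in 5:8) {
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    Dm <- ape::cophenetic.phylo(true)
    rec <- neighbor_joining(Dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), rec)), 0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(Dm), colnames(Dm)], Dm,
                 tolerance = 1e-8)
  }

  # equidistant 3 taxa resolve with equal branches
  D3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  t3 <- neighbor_joining(D3)
  expect_equal(unname(t3$edge.length), rep(1, 3))

  # two taxa: a single edge of total length d
  t2 <- neighbor_joining(matrix(c(0, 1.4, 1.4, 0), 2, 2,
                                dimnames = list(c("x","y"), c("x","y"))))
  expect_equal(sum(t2$edge.length), 1.4)
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("x","y"), c("x","y")))
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap interior-branch support behaves as a support measure", {
  set.seed(6)
  # clade (a,b) shares 50 diagnostic columns; the rest is random noise
  base <- function() paste(sample(kapkit:::AA20, 60, TRUE), collapse = "")
  diag_block <- paste(rep("W", 50), collapse = "")
  other <- function() paste(sample(c("A", "S"), 50, TRUE), collapse = "")
  aln <- c(a = paste0(base(), diag_block), b = paste0(base(), diag_block),
           c = paste0(base(), other()), d = paste0(base(), other()),
           e = paste0(base(), other()))
  tr <- interior_branch_support(aln, reps = 200, seed = 2)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100, na.rm = TRUE))
  rooted <- ape::root(tr, "e")
  ab_node <- ape::getMRCA(rooted, c("a", "b"))
  ab_support <- as.integer(rooted$node.label[ab_node - length(rooted$tip.label)])
  expect_gte(ab_support, 95)

  # support invariant to row order
  tr2 <- interior_branch_support(aln[c(3, 1, 5, 2, 4)], reps = 200, seed = 2)
  rooted2 <- ape::root(tr2, "e")
  ab2 <- as.integer(rooted2$node.label[ape::getMRCA(rooted2, c("a", "b")) -
                                         length(rooted2$tip.label)])
  expect_lt(abs(ab_support - ab2), 10)
  expect_error(interior_branch_support(aln[1:3]), ">= 4")
})
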