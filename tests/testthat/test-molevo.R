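test_that("modified Nei-Gojobori matches the enumeration oracle on key codon pairs", {
  # identical CDS
  d0 <- nei_gojobori("ATGGCT", "ATGGCT")
  expect_equal(d0$dS, 0)
  expect_equal(d0$dN, 0)

  # synonymous change: TTT -> TTC (Phe/Phe)
  d1 <- nei_gojobori("TTT", "TTC")
  o1 <- oracle_ng("TTT", "TTC")
  expect_equal(d1$dN, 0)
  expect_gt(d1$dS, 0)
  expect_equal(d1$dS, o1$dS, tolerance = 1e-12)
  expect_equal(d1$S_sites, o1$S, tolerance = 1e-12)

  # nonsynonymous change: AAA -> AGA (Lys/Arg)
  d2 <- nei_gojobori("AAA", "AGA")
  o2 <- oracle_ng("AAA", "AGA")
  expect_equal(d2$dS, 0)
  expect_gt(d2$dN, 0)
  expect_equal(d2$dN, o2$dN, tolerance = 1e-12)
  expect_equal(d2$N_sites, o2$N, tolerance = 1e-12)

  # multi-position codon pair exercising path averaging
  d3 <- nei_gojobori("TTTAAA", "TTCCGA")
  o3 <- oracle_ng("TTTAAA", "TTCCGA")
  expect_equal(d3$dS, o3$dS, tolerance = 1e-12)
  expect_equal(d3$dN, o3$dN, tolerance = 1e-12)

  # site counts always partition 3 per compared codon
  expect_equal(d3$S_sites + d3$N_sites, 6)
  expect_error(nei_gojobori("TTT", "TTTAAA"), "differ")
  expect_error(nei_gojobori("TGATTT", "TGATTC"), "stop")
})

test_that("Nei-Gojobori is symmetric and oracle-exact on random CDS pairs", {
  set.seed(23)
  gc <- kapkit:::genetic_code()
  sense <- names(gc)[gc != "*"]
  for (i in 1:8) {
    c1 <- paste(sample(sense, 40, TRUE), collapse = "")
    c2 <- strsplit(c1, "")[[1]]
    mut <- sample(length(c2), 10)
    c2[mut] <- sample(c("A","C","G","T"), 10, TRUE)
    c2 <- paste(c2, collapse = "")
    if (any(gc[substring(c2, seq(1, nchar(c2), 3),
                         seq(3, nchar(c2), 3))] == "*")) next
    a <- nei_gojobori(c1, c2)
    b <- nei_gojobori(c2, c1)
    expect_equal(a$dS, b$dS, tolerance = 1e-12)
    expect_equal(a$dN, b$dN, tolerance = 1e-12)
    o <- oracle_ng(c1, c2)
    expect_equal(a$dS, o$dS, tolerance = 1e-12)
    expect_equal(a$dN, o$dN, tolerance = 1e-12)
  }
})

test_that("with R = 1 site counts reduce to unweighted counts over all sense codons", {
  gc <- kapkit:::genetic_code()
  sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  for (codon in sense) {
    s_unweighted <- 0
    for (p in 1:3) {
      nsyn <- 0; nvalid <- 0
      for (b in setdiff(bases, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        nvalid <- nvalid + 1
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) nsyn <- nsyn + 1
      }
      s_unweighted <- s_unweighted + nsyn / nvalid
    }
    expect_equal(kapkit:::.codon_syn_sites(codon, R = 1, gc = as.list(gc)),
                 s_unweighted, tolerance = 1e-12)
  }
})

test_that("synonymous-only divergence gives dS > 0 with dN = 0", {
  set.seed(31)
  gc <- kapkit:::genetic_code()
  by_aa <- split(names(gc), gc)
  prot <- paste(sample(c("L","S","R","A","G","P","T","V"), 60, TRUE),
                collapse = "")
  c1 <- kapkit:::back_translate(prot)
  co <- substring(c1, seq(1, nchar(c1), 3), seq(3, nchar(c1), 3))
  # synonymous single-nucleotide point changes only
  n_changed <- 0
  for (k in sample(60, 30)) {
    if (n_changed >= 10) break
    alts <- setdiff(by_aa[[gc[[co[k]]]]], co[k])
    one_off <- alts[vapply(alts, function(a)
      sum(strsplit(a, "")[[1]] != strsplit(co[k], "")[[1]]) == 1, TRUE)]
    if (length(one_off)) { co[k] <- sample(one_off, 1); n_changed <- n_changed + 1 }
  }
  c2 <- paste(co, collapse = "")
  d <- nei_gojobori(c1, c2)
  expect_gt(d$dS, 0)
  expect_equal(d$dN, 0)
})

test_that("GC content statistics handle thirds and Ns", {
  expect_equal(unname(nucleotide_composition("GGCCGG")), c(100, 100))
  expect_equal(unname(nucleotide_composition("ATATAT")), c(0, 0))
  expect_equal(unname(nucleotide_composition("ATGGCC")[["GC3"]]), 100)
  # Ns excluded from numerator and denominator
  comp <- nucleotide_composition("ATGNNN")
  expect_equal(unname(comp[["GC"]]), 100 / 3)
  expect_error(nucleotide_composition(""), "empty")
})

test_that("divergence-GC correlations report r, the fitted line and errors", {
  su <- data.frame(subfamily = paste0("K", 1:5), class = "HS",
                   mean_dS = c(0.5, 0.4, 0.3, 0.2, 0.1),
                   GC = c(30, 40, 50, 60, 70), GC3 = c(20, 35, 50, 65, 80))
  res <- divergence_vs_gc(su)
  expect_equal(res$pooled$dS_vs_GC$r, -1, tolerance = 1e-12)
  expect_equal(res$pooled$dS_vs_GC$slope, -0.01, tolerance = 1e-12)
  expect_equal(res$pooled$dS_vs_GC3$r, -1, tolerance = 1e-12)
  su$GC <- 50
  expect_error(divergence_vs_gc(su), "zero variance")
})

test_that("count correlations separate homogenized from independent classes", {
  counts <- rbind(matrix(c(4, 4, 4, 8, 8, 8, 2, 2, 2), 3, 3, byrow = TRUE),
                  matrix(c(1, 9, 4, 7, 2, 6, 3, 8, 1), 3, 3, byrow = TRUE))
  rownames(counts) <- paste0("K", 1:6)
  colnames(counts) <- paste0("sp", 1:3)
  cmap <- setNames(c(rep("HS", 3), rep("HGT", 3)), rownames(counts))
  res <- count_correlation(counts, cmap)
  expect_equal(unname(res$HS), rep(1, 3))             # identical count vectors
  expect_true(all(abs(c(res$HS, res$HGT)) <= 1))
  expect_error(count_correlation(counts[1:4, ], setNames(c("HS","HS","HS","HGT"),
                                                         paste0("K", 1:4))),
               "< 2 subfamilies")
})

test_that("subfamily summaries assemble mean dS with composition", {
  sim <- default_test_sim(seed = 41, pseudo_prob = 0, conversion_rate = 0)
  intact <- sim$truth[sim$truth$status == "intact", ]
  cds_by <- split(intact$cds, intact$subfamily)
  cmap <- setNames(sim$panel$class, sim$panel$subfamily)
  su <- subfamily_summary(cds_by, cmap)
  expect_equal(nrow(su), length(cds_by))
  expect_true(all(su$GC >= 0 & su$GC <= 100))
  expect_true(all(su$mean_dS >= 0, na.rm = TRUE))
})
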