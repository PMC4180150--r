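# composition rows for the six HGT and a sample of HS subfamilies: mean
# percentages of cysteine, glycine and tyrosine reported for the family
TAB3 <- data.frame(
  subfamily = c("KRTAP1", "KRTAP2", "KRTAP3", "KRTAP4", "KRTAP5", "KRTAP9",
                "KRTAP10", "KRTAP11", "KRTAP12", "KRTAP13", "KRTAP16",
                "KRTAP17", "KRTAP24", "KRTAP25", "KRTAP26", "KRTAP27",
                "KRTAP28", "KRTAP29", "KRTAP6", "KRTAP7", "KRTAP8",
                "KRTAP19", "KRTAP20", "KRTAP21"),
  cys = c(25.98, 28.83, 19.65, 34.84, 33.67, 35.30, 25.92, 12.84, 22.54,
          11.11, 19.24, 36.09, 9.73, 8.17, 10.38, 8.87, 38.43, 16.25,
          14.37, 7.82, 6.15, 8.07, 10.62, 17.88),
  gly = c(9.68, 4.35, 3.92, 3.29, 23.00, 3.57, 1.95, 6.86, 4.26, 10.67,
          1.89, 28.93, 5.89, 3.92, 6.58, 4.33, 30.92, 6.13,
          39.89, 20.26, 22.47, 35.88, 32.08, 34.32),
  tyr = c(1.70, 0.52, 1.29, 0.72, 0.36, 1.81, 0.73, 2.64, 1.11, 7.71,
          2.24, 0.15, 6.55, 7.52, 4.36, 2.04, 1.20, 2.29,
          22.07, 11.76, 19.15, 18.18, 25.05, 21.10),
  stringsAsFactors = FALSE)

fake_profile <- function(cys, gly, tyr) {
  structure(numeric(20), class = "composition_profile",
            cys = cys, gly = gly, tyr = tyr, gly_tyr = gly + tyr)
}

test_that("integrity classification distinguishes intact, partial, pseudogene", {
  slen <- c(s1 = 10000L)
  pseudo <- list(n_lesions = 1L, has_start = TRUE, has_stop = TRUE,
                 scaffold = "s1", start = 100L, end = 400L)
  expect_equal(classify_integrity(pseudo, slen), "pseudogene")
  partial_no_stop <- list(n_lesions = 0L, has_start = TRUE, has_stop = FALSE,
                          scaffold = "s1", start = 100L, end = 400L)
  expect_equal(classify_integrity(partial_no_stop, slen), "partial")
  partial_edge <- list(n_lesions = 0L, has_start = TRUE, has_stop = TRUE,
                       scaffold = "s1", start = 9500L, end = 10000L)
  expect_equal(classify_integrity(partial_edge, slen), "partial")
  intact <- list(n_lesions = 0L, has_start = TRUE, has_stop = TRUE,
                 scaffold = "s1", start = 100L, end = 400L)
  expect_equal(classify_integrity(intact, slen), "intact")
})

test_that("composition profiles count residues correctly", {
  p <- composition_profile("CCCCCGGGGY")
  expect_equal(attr(p, "cys"), 50)
  expect_equal(attr(p, "gly"), 40)
  expect_equal(attr(p, "tyr"), 10)
  expect_equal(sum(p), 100)

  p2 <- composition_profile("AAAA")
  expect_equal(p2[["A"]], 100)
  expect_equal(sum(composition_profile("MAC*")), 100)  # stop excluded
  expect_error(composition_profile("ACDEZ1"), "non-amino-acid")
  expect_error(composition_profile("**"), "empty")

  # multinomial sampling: each residue fraction within 4 SD of 5%
  set.seed(2)
  aa <- paste(sample(kapkit:::AA20, 1000, replace = TRUE), collapse = "")
  prof <- composition_profile(aa)
  sd4 <- 4 * 100 * sqrt(0.05 * 0.95 / 1000)
  expect_true(all(abs(prof - 5) < sd4))
})

test_that("compositional classes partition profile space as documented", {
  expect_equal(assign_class(fake_profile(35, 5, 1)), "HS_ultrahigh")
  expect_equal(assign_class(fake_profile(15, 5, 5)), "HS_high")
  expect_equal(assign_class(fake_profile(8, 35, 20)), "HGT")
  # boundary: exactly 30% cysteine is high-sulfur, not ultrahigh
  expect_equal(assign_class(fake_profile(30, 5, 1)), "HS_high")
  # totality over a profile grid
  for (cys in seq(0, 60, by = 7)) for (gt in seq(0, 70, by = 9)) {
    cl <- assign_class(fake_profile(cys, gt / 2, gt / 2))
    expect_true(cl %in% c("HGT", "HS_high", "HS_ultrahigh"))
  }
})

test_that("family-mean compositions reproduce the published class lists", {
  cls <- vapply(seq_len(nrow(TAB3)), function(i)
    assign_class(fake_profile(TAB3$cys[i], TAB3$gly[i], TAB3$tyr[i])), "")
  hgt <- TAB3$subfamily[cls == "HGT"]
  expect_setequal(hgt, c("KRTAP6", "KRTAP7", "KRTAP8", "KRTAP19", "KRTAP20",
                         "KRTAP21"))
  ultra <- TAB3$subfamily[cls == "HS_ultrahigh"]
  expect_setequal(ultra, c("KRTAP4", "KRTAP5", "KRTAP9", "KRTAP17", "KRTAP28"))
})

test_that("subfamily assignment uses reciprocal identity with a floor", {
  sim <- default_test_sim(seed = 51, pseudo_prob = 0)
  panel <- sim$panel
  ref <- names(panel$protein)[1]
  res <- assign_subfamily(panel$protein[[ref]], panel)
  expect_equal(res$subfamily, panel$subfamily[[ref]])
  expect_equal(res$confidence, 1)

  # low identity falls below the floor
  set.seed(1)
  junk <- paste(sample(c("H","K","R","D","E","N","Q","I","L","V"), 80, TRUE),
                collapse = "")
  expect_equal(assign_subfamily(junk, panel, floor = 0.6)$subfamily,
               "unassigned")
  expect_error(assign_subfamily("ACDE", list(protein = list())), "empty")

  # motif veto: assigned subfamily's motif missing while another matches
  panel2 <- list(protein = c(A = "MCCCPSCCCPS", B = "MGGYGGYGGYG"),
                 subfamily = c(A = "KRTAP_A", B = "KRTAP_B"))
  lib <- list(KRTAP_A = "CCCPS", KRTAP_B = "GGYG")
  hit <- assign_subfamily("MCCCPSCCCPS", panel2, motif_library = lib)
  expect_equal(hit$subfamily, "KRTAP_A")
})

test_that("cluster assignment groups by gap threshold in coordinate order", {
  one <- data.frame(scaffold = "s", start = 100L, end = 500L)
  expect_equal(cluster_assignment(one)$cluster_id, 1L)

  gaps <- c(5000L, 5000L, 500000L, 5000L)
  starts <- cumsum(c(0L, 400L + gaps))
  df <- data.frame(scaffold = "s", start = starts, end = starts + 400L)
  cl <- cluster_assignment(df, gap_threshold = 200000L)$cluster_id
  expect_equal(cl, c(1L, 1L, 1L, 2L, 2L))

  # clusters recovered on a simulated genome match the planted clusters
  sim <- simulate_repertoire(sim_config(seed = 61, n_clusters = 5,
                                        genes_per_cluster = c(3, 4),
                                        gene_length = c(60, 100)))
  ann <- cluster_assignment(sim$truth, gap_threshold = 200000L)
  expect_equal(length(unique(ann$cluster_id)), 5L)
  tab <- table(ann$cluster_id, ann$cluster)
  expect_true(all(rowSums(tab > 0) == 1))   # one recovered per planted cluster
})

test_that("pseudogenized genes never classify as intact", {
  # a lesion within the two terminal codons is parsimony-equivalent to one or
  # two diverged terminal residues and can legitimately be read as a
  # truncated (partial) model, and a frameshift inside a sequence repeat can
  # admit an equally parsimonious in-frame reading; interior premature stops
  # must always be detected, detection overall must be high, and no
  # pseudogenized gene may ever come back intact
  set.seed(77)
  slen <- c(frag = 100000L)
  n_pseudo <- 0L
  n_interior <- 0L; n_interior_detected <- 0L
  for (i in 1:100) {
    prot <- paste(sample(c("A","S","T","G","C","Y","P","Q","V","L"),
                         sample(50:90, 1), TRUE), collapse = "")
    cds <- paste0("ATG", kapkit:::back_translate(prot), "TAA")
    pg <- pseudogenize(cds, 1)
    ta <- translated_align(paste0("M", prot), pg$cds)
    n_lesions <- length(ta$frameshifts) + length(ta$internal_stops)
    complete_orf <- any(find_orfs(pg$cds, min_codons = 40)$codons >=
                          0.9 * (nchar(cds) / 3))
    cand <- list(n_lesions = n_lesions,
                 has_start = n_lesions == 0L && complete_orf,
                 has_stop = n_lesions == 0L && complete_orf,
                 scaffold = "frag", start = 1000L, end = 2000L)
    status <- classify_integrity(cand, slen)
    expect_true(status %in% c("pseudogene", "partial"))
    if (status == "pseudogene") n_pseudo <- n_pseudo + 1L
    interior_stop <- all(pg$lesions$kind == "premature_stop") &&
      all(pg$lesions$position >= 9 & pg$lesions$position < nchar(cds) - 9)
    if (interior_stop) {
      n_interior <- n_interior + 1L
      if (status == "pseudogene") n_interior_detected <- n_interior_detected + 1L
    }
  }
  expect_equal(n_interior_detected, n_interior)
  expect_gte(n_pseudo, 95L)
})
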