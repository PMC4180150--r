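# Synthetic genomes with tandem KRTAP-like gene clusters and known truth.
# The simulator emulates the processes the downstream analyses assume:
# duplication within clusters, HKY substitution, gene conversion with optional
# GC-biased resolution, pseudogenization by frameshift/premature-stop lesions,
# and scaffold fragmentation mimicking low-coverage assemblies.

#' Simulation configuration
#'
#' Assemble (and validate) the parameter set for [simulate_repertoire()].
#' Defaults describe a small mammalian-like KRTAP repertoire: five tandem
#' clusters of short (60-300 codon) single-exon genes, 80% of clusters from
#' the cysteine-rich (HS) class, transition/transversion ratio 2, moderate
#' intra-cluster divergence, and a pseudogene fraction of 0.2.
#'
#' @param seed Integer seed; every stochastic step derives from it.
#' @param n_clusters Number of tandem clusters (one subfamily each).
#' @param genes_per_cluster Length-2 integer range of genes per cluster.
#' @param class_mix Fraction of clusters drawn from the HS class (rest HGT).
#' @param gene_length Length-2 range of gene length in codons (ATG and stop
#'   codon included).
#' @param repeat_unit Named list with peptide repeat motifs `HS` and `HGT`.
#' @param kappa HKY transition/transversion rate ratio.
#' @param branch_scale Mean branch length (substitutions/site) of the
#'   within-cluster gene tree.
#' @param conversion_rate Expected number of conversion tracts per ordered
#'   gene pair within a cluster.
#' @param tract_mean Mean conversion tract length (nt, geometric).
#' @param gbgc_bias Probability that a converted A/T vs G/C heterology
#'   resolves to the G/C allele; 0.5 = unbiased.
#' @param pseudo_prob Per-gene probability of carrying disruptive lesions.
#' @param fragmentation Expected number of scaffold breaks per cluster
#'   (Poisson); breaks landing inside genes truncate them.
#' @param intergenic_length Length-2 range of intergenic spacer lengths (nt).
#' @param intergenic_gc GC fraction of intergenic spacers.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 5L,
                       genes_per_cluster = c(4L, 8L),
                       class_mix = 0.8,
                       gene_length = c(60L, 300L),
                       repeat_unit = list(HS = "CCQPSCCQTS", HGT = "GGYGGLGSYG"),
                       kappa = 2,
                       branch_scale = 0.04,
                       conversion_rate = 0,
                       tract_mean = 100,
                       gbgc_bias = 0.7,
                       pseudo_prob = 0.2,
                       fragmentation = 0,
                       intergenic_length = c(2000L, 8000L),
                       intergenic_gc = 0.45) {
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              genes_per_cluster = as.integer(genes_per_cluster),
              class_mix = class_mix, gene_length = as.integer(gene_length),
              repeat_unit = repeat_unit, kappa = kappa,
              branch_scale = branch_scale, conversion_rate = conversion_rate,
              tract_mean = tract_mean, gbgc_bias = gbgc_bias,
              pseudo_prob = pseudo_prob, fragmentation = fragmentation,
              intergenic_length = as.integer(intergenic_length),
              intergenic_gc = intergenic_gc)
  probs <- c(class_mix = class_mix, gbgc_bias = gbgc_bias,
             pseudo_prob = pseudo_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (kappa <= 0) stop("kappa must be > 0")
  if (tract_mean < 1) stop("tract_mean must be >= 1")
  if (gbgc_bias < 0.5) stop("gbgc_bias is a probability of strong resolution, >= 0.5")
  if (cfg$gene_length[1] < 10) stop("genes shorter than 10 codons are not supported")
  class(cfg) <- "sim_config"
  cfg
}

# HKY transition probability matrix for branch length t (subs/site)
hky_pmat <- function(t, kappa, pi = c(A = .25, C = .25, G = .25, T = .25)) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in bases) for (j in bases) if (i != j) {
    is_ti <- any(transitions[, 1] == i & transitions[, 2] == j)
    Q[i, j] <- pi[j] * if (is_ti) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  eg <- eigen(Q)
  P <- eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
  P <- pmax(Re(P), 0)
  P <- P / rowSums(P)
  dimnames(P) <- list(bases, bases)
  P
}

# evolve a CDS along branch length t under HKY; the first codon (ATG), the
# final stop and the reading frame are preserved, and substitutions creating
# in-frame internal stops are reverted so that lesions alone decide status.
evolve_cds <- function(cds, t, kappa) {
  if (t <= 0) return(cds)
  P <- hky_pmat(t, kappa)
  bases <- colnames(P)
  ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
  idx <- match(ch, bases)
  new <- vapply(idx, function(i) sample(bases, 1L, prob = P[i, ]), "")
  # protect start and terminal stop codons
  n <- length(ch)
  new[1:3] <- ch[1:3]
  new[(n - 2):n] <- ch[(n - 2):n]
  out <- paste(new, collapse = "")
  bad <- internal_stop_codons(out)
  if (length(bad)) {
    for (b in bad) {
      pos <- (b - 1L) * 3L + 1L
      substr(out, pos, pos + 2L) <- substr(cds, pos, pos + 2L)
    }
  }
  out
}

# random ancestral protein for a compositional class: tandem copies of the
# class repeat unit with stochastic residue turnover
ancestral_protein <- function(n_codons, class, motif) {
  core <- n_codons - 2L   # minus Met and stop
  unit <- strsplit(motif, "", fixed = TRUE)[[1L]]
  aa <- rep(unit, length.out = core)
  background <- c("A", "S", "T", "P", "V", "L", "R", "Q", "F", "N")
  flip <- runif(core) < 0.25
  aa[flip] <- sample(background, sum(flip), replace = TRUE)
  paste(c("M", aa), collapse = "")
}

# back-translate a protein choosing uniformly among synonymous codons
back_translate <- function(protein) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste(codons, collapse = "")
}

#' Apply a gene-conversion tract with GC-biased resolution
#'
#' Within `tract`, acceptor sites are overwritten by the donor, except that at
#' heterologous weak/strong sites (A/T on one sequence, G/C on the other) the
#' G/C allele is kept with probability `gbgc_bias` regardless of direction.
#'
#' @param acceptor,donor Equal-length DNA strings (aligned paralogs).
#' @param tract_start,tract_end 0-based half-open tract bounds.
#' @param gbgc_bias Probability of resolving a W/S heterology to G/C.
#' @return The converted acceptor string.
#' @export
apply_gene_conversion <- function(acceptor, donor, tract_start, tract_end,
                                  gbgc_bias = 0.5) {
  n <- nchar(acceptor)
  if (nchar(donor) != n) stop("acceptor and donor must have equal length")
  if (tract_start < 0 || tract_end > n || tract_start >= tract_end)
    stop("conversion tract out of bounds")
  a <- strsplit(acceptor, "", fixed = TRUE)[[1L]]
  d <- strsplit(donor, "", fixed = TRUE)[[1L]]
  idx <- seq.int(tract_start + 1L, tract_end)
  strong <- c("G", "C")
  for (i in idx) {
    if (a[i] == d[i]) next
    a_strong <- a[i] %in% strong
    d_strong <- d[i] %in% strong
    if (xor(a_strong, d_strong)) {
      keep_strong <- runif(1) < gbgc_bias
      a[i] <- if (keep_strong) (if (a_strong) a[i] else d[i]) else
        (if (a_strong) d[i] else a[i])
    } else {
      a[i] <- d[i]
    }
  }
  paste(a, collapse = "")
}

#' Introduce disruptive lesions into an intact CDS
#'
#' Lesions are drawn uniformly from 1-nt insertion, 1-nt deletion and point
#' mutation to a premature stop; none touch the first or last codon.
#'
#' @param cds Intact CDS (starts ATG, ends with a stop, length divisible by 3).
#' @param n_lesions Number of lesions (>= 1).
#' @param kinds Optional character vector forcing lesion kinds, from
#'   `c("frameshift_ins", "frameshift_del", "premature_stop")`.
#' @return List with `cds` (mutated) and `lesions` (data frame of 0-based
#'   positions relative to the original CDS, and kinds).
#' @export
pseudogenize <- function(cds, n_lesions = 1L, kinds = NULL) {
  if (n_lesions < 1L) stop("n_lesions must be >= 1")
  n_codons <- nchar(cds) %/% 3L
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS must start with ATG")
  stops <- c("TAA", "TAG", "TGA")
  if (is.null(kinds))
    kinds <- sample(c("frameshift_ins", "frameshift_del", "premature_stop"),
                    n_lesions, replace = TRUE)
  if (length(kinds) != n_lesions) stop("kinds must have length n_lesions")
  target_codons <- sample(2:(n_codons - 1L), n_lesions,
                          replace = n_lesions > n_codons - 2L)
  lesions <- data.frame(position = integer(n_lesions), kind = kinds,
                        stringsAsFactors = FALSE)
  # apply right-to-left so recorded (original) coordinates stay valid
  ord <- order(target_codons, decreasing = TRUE)
  out <- cds
  for (i in ord) {
    codon_i <- target_codons[i]
    pos0 <- (codon_i - 1L) * 3L            # 0-based codon start
    if (kinds[i] == "premature_stop") {
      codon <- substr(out, pos0 + 1L, pos0 + 3L)
      # single point mutation reaching a stop codon, if one exists
      cands <- list()
      for (p in 1:3) for (b in c("A", "C", "G", "T")) {
        mut <- codon
        substr(mut, p, p) <- b
        if (mut != codon && mut %in% stops) cands[[length(cands) + 1L]] <- mut
      }
      mut <- if (length(cands)) cands[[sample.int(length(cands), 1L)]] else
        stops[sample.int(3L, 1L)]
      out <- paste0(substr(out, 1L, pos0), mut,
                    substr(out, pos0 + 4L, nchar(out)))
      lesions$position[i] <- pos0
    } else if (kinds[i] == "frameshift_del") {
      del_at <- pos0 + sample.int(3L, 1L)  # 1-based within current string
      out <- paste0(substr(out, 1L, del_at - 1L),
                    substr(out, del_at + 1L, nchar(out)))
      lesions$position[i] <- del_at - 1L
    } else {
      ins_at <- pos0 + sample.int(3L, 1L)
      out <- paste0(substr(out, 1L, ins_at - 1L),
                    sample(c("A", "C", "G", "T"), 1L),
                    substr(out, ins_at, nchar(out)))
      lesions$position[i] <- ins_at - 1L
    }
  }
  list(cds = out, lesions = lesions[order(lesions$position), , drop = FALSE])
}

#' Simulate a KRTAP-like repertoire with known truth
#'
#' Generates one scaffold per tandem cluster (more if fragmentation breaks
#' scaffolds), with genes of the cluster's subfamily placed in tandem,
#' separated by random intergenic spacers. Same-cluster paralogs descend from
#' one ancestral gene along a random gene tree under HKY; gene conversion and
#' pseudogenization are applied afterwards, and everything is recorded in a
#' per-gene truth table.
#'
#' @param config A [sim_config()].
#' @return List with `scaffolds` (named DNA strings), `truth` (data frame: one
#'   row per emitted gene with interval, subfamily, class, status, lesions,
#'   conversion tracts and stored CDS) and `panel` (reference panel: list with
#'   `dna`, `protein`, `subfamily` for the per-subfamily ancestral genes).
#' @export
simulate_repertoire <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scaffolds <- list()
  truth <- list()
  panel_dna <- character(); panel_prot <- character()
  panel_sub <- character(); panel_cls <- character()

  for (k in seq_len(config$n_clusters)) {
    subfam <- paste0("KRTAP", k)
    cls <- if (k <= round(config$class_mix * config$n_clusters)) "HS" else "HGT"
    n_codons <- sample(seq(config$gene_length[1L], config$gene_length[2L]), 1L)
    prot <- ancestral_protein(n_codons, cls, config$repeat_unit[[cls]])
    anc <- paste0(back_translate(prot), sample(c("TAA", "TAG", "TGA"), 1L))

    panel_dna[subfam] <- anc
    panel_prot[subfam] <- prot
    panel_sub[subfam] <- subfam
    panel_cls[subfam] <- cls

    n_genes <- sample(seq(config$genes_per_cluster[1L],
                          config$genes_per_cluster[2L]), 1L)
    # gene tree: random topology, exponential branch lengths
    genes <- character(n_genes)
    if (n_genes == 1L) {
      genes[1L] <- evolve_cds(anc, stats::rexp(1, 1 / config$branch_scale),
                              config$kappa)
    } else {
      tr <- ape::rtree(n_genes, rooted = TRUE,
                       br = function(n) stats::rexp(n, 1 / config$branch_scale))
      tr <- ape::reorder.phylo(tr, "cladewise")
      node_seq <- vector("list", n_genes + tr$Nnode)
      node_seq[[n_genes + 1L]] <- anc
      for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
        node_seq[[child]] <- evolve_cds(node_seq[[par]], tr$edge.length[e],
                                        config$kappa)
      }
      genes <- unlist(node_seq[seq_len(n_genes)])
    }

    # gene conversion among paralogs (equal length by construction)
    tracts <- rep(list(character()), n_genes)
    if (config$conversion_rate > 0 && n_genes > 1L) {
      for (a in seq_len(n_genes)) for (d in seq_len(n_genes)) {
        if (a == d) next
        n_tr <- stats::rpois(1L, config$conversion_rate)
        len_nt <- nchar(genes[a])
        for (t in seq_len(n_tr)) {
          tl <- min(len_nt, 1L + stats::rgeom(1L, 1 / config$tract_mean))
          ts <- sample.int(len_nt - tl + 1L, 1L) - 1L
          genes[a] <- apply_gene_conversion(genes[a], genes[d], ts, ts + tl,
                                            config$gbgc_bias)
          tracts[[a]] <- c(tracts[[a]], sprintf("%s:%d-%d", paste0("g", d), ts, ts + tl))
        }
      }
      # conversion may assemble an in-frame stop from intact donors; revert those
      for (a in seq_len(n_genes)) {
        bad <- internal_stop_codons(genes[a])
        for (b in bad) {
          pos <- (b - 1L) * 3L + 1L
          substr(genes[a], pos, pos + 2L) <- substr(anc, pos, pos + 2L)
        }
      }
    }

    # pseudogenization
    statuses <- rep("intact", n_genes)
    lesion_str <- rep("", n_genes)
    for (g in seq_len(n_genes)) {
      if (runif(1) < config$pseudo_prob) {
        pg <- pseudogenize(genes[g], n_lesions = 1L + stats::rpois(1L, 0.5))
        genes[g] <- pg$cds
        statuses[g] <- "pseudogene"
        lesion_str[g] <- paste(sprintf("%d:%s", pg$lesions$position,
                                       pg$lesions$kind), collapse = ",")
      }
    }

    # assemble the cluster scaffold: spacer, gene, spacer, gene, ...
    scafname <- sprintf("cluster%d", k)
    spacer_len <- function() sample(seq(config$intergenic_length[1L],
                                        config$intergenic_length[2L]), 1L)
    seqparts <- character(0)
    pos <- 0L
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      sp <- random_dna(spacer_len(), config$intergenic_gc)
      seqparts <- c(seqparts, sp); pos <- pos + nchar(sp)
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "+") genes[g] else revcomp(genes[g])
      rows[[g]] <- data.frame(
        gene_id = sprintf("%s_g%d", scafname, g), scaffold = scafname,
        start = pos, end = pos + nchar(placed), strand = strand,
        subfamily = subfam, class = cls, cluster = k, status = statuses[g],
        lesions = lesion_str[g],
        conversion_tracts = paste(tracts[[g]], collapse = ";"),
        cds = genes[g], stringsAsFactors = FALSE)
      seqparts <- c(seqparts, placed); pos <- pos + nchar(placed)
    }
    seqparts <- c(seqparts, random_dna(spacer_len(), config$intergenic_gc))
    scafseq <- paste(seqparts, collapse = "")
    cluster_truth <- do.call(rbind, rows)

    # fragmentation: Poisson breaks; genes hit by a break are truncated
    n_breaks <- if (config$fragmentation > 0)
      stats::rpois(1L, config$fragmentation) else 0L
    if (n_breaks > 0L) {
      brk <- sort(sample.int(nchar(scafseq) - 1L, min(n_breaks, 5L)))
      bounds <- c(0L, brk, nchar(scafseq))
      for (p in seq_len(length(bounds) - 1L)) {
        pname <- sprintf("%s_part%d", scafname, p)
        p0 <- bounds[p]; p1 <- bounds[p + 1L]
        scaffolds[[pname]] <- substr(scafseq, p0 + 1L, p1)
        sel <- cluster_truth$start < p1 & cluster_truth$end > p0
        if (!any(sel)) next
        piece <- cluster_truth[sel, , drop = FALSE]
        for (r in seq_len(nrow(piece))) {
          s <- max(piece$start[r], p0); e <- min(piece$end[r], p1)
          truncated <- (s != piece$start[r]) || (e != piece$end[r])
          if (e - s < 60L) next                      # fragment too small: gene lost
          keep <- piece[r, , drop = FALSE]
          keep$scaffold <- pname
          keep$start <- s - p0; keep$end <- e - p0
          if (truncated) {
            # stored cds clipped to the survived piece, on the gene's own strand
            off0 <- s - piece$start[r]; off1 <- piece$end[r] - e
            cl <- if (keep$strand == "+") c(off0, off1) else c(off1, off0)
            keep$cds <- substr(piece$cds[r], cl[1L] + 1L,
                               nchar(piece$cds[r]) - cl[2L])
            if (keep$status == "intact") keep$status <- "partial"
          }
          truth[[length(truth) + 1L]] <- keep
        }
      }
    } else {
      scaffolds[[scafname]] <- scafseq
      truth[[length(truth) + 1L]] <- cluster_truth
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(scaffolds = scaffolds, truth = truth,
       panel = list(dna = panel_dna, protein = panel_prot,
                    subfamily = panel_sub, class = panel_cls))
}

#' Write a simulated repertoire to disk
#'
#' Emits `genome.fasta`, `truth.gff3` and `truth.tsv` into `dir`.
#' @param sim Result of [simulate_repertoire()].
#' @param dir Output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(unlist(sim$scaffolds), file.path(dir, "genome.fasta"))
  iv <- lapply(seq_len(nrow(sim$truth)), function(i)
    genomic_interval(sim$truth$scaffold[i], sim$truth$start[i],
                     sim$truth$end[i], sim$truth$strand[i]))
  at <- lapply(seq_len(nrow(sim$truth)), function(i)
    c(ID = sim$truth$gene_id[i], subfamily = sim$truth$subfamily[i],
      status = sim$truth$status[i]))
  write_gff3(iv, file.path(dir, "truth.gff3"), attributes = at)
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate species-by-subfamily gene-count tables
#'
#' Emulates the two repertoire regimes the count-correlation contrast is
#' designed to separate: a homogenized regime in which all species share one
#' per-subfamily expansion profile (counts Poisson around shared means), and
#' an independent regime in which every species draws its own means.
#'
#' @param n_species,n_subfamilies Table dimensions.
#' @param shared If `TRUE`, one expansion profile is shared by all species.
#' @param mean_range Range of per-subfamily expected counts.
#' @return Integer matrix (subfamilies x species).
#' @export
simulate_count_table <- function(n_species = 10L, n_subfamilies = 8L,
                                 shared = TRUE, mean_range = c(2, 20)) {
  lam <- function() stats::runif(n_subfamilies, mean_range[1L], mean_range[2L])
  counts <- matrix(0L, n_subfamilies, n_species,
                   dimnames = list(paste0("SF", seq_len(n_subfamilies)),
                                   paste0("sp", seq_len(n_species))))
  profile <- lam()
  for (s in seq_len(n_species)) {
    mu <- if (shared) profile else lam()
    counts[, s] <- stats::rpois(n_subfamilies, mu)
  }
  counts
}
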