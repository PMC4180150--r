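# Codon site models and likelihood-ratio tests for positive selection.
# Goldman-Yang rate matrix over the 61 sense codons, F3x4 (or equal) codon
# frequencies, site classes mixed per model (M0, M1a, M2a, M7, M8), maximum
# likelihood by bounded numerical optimization, NEB site posteriors.

.codon_env <- new.env(parent = emptyenv())

sense_codons <- function() {
  if (is.null(.codon_env$codons)) {
    gc <- genetic_code()
    .codon_env$codons <- names(gc)[gc != "*"]
    .codon_env$aa <- gc[.codon_env$codons]
  }
  .codon_env$codons
}

# precomputed single-nucleotide-difference structure of the 61x61 matrix
.codon_pairs <- function() {
  if (!is.null(.codon_env$pairs)) return(.codon_env$pairs)
  codons <- sense_codons()
  aa <- genetic_code()[codons]
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  ii <- jj <- integer(0); ti <- syn <- logical(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffpos <- which(cm[i, ] != cm[j, ])
    if (length(diffpos) != 1L) next
    a <- cm[i, diffpos]; b <- cm[j, diffpos]
    ii <- c(ii, i); jj <- c(jj, j)
    ti <- c(ti, .is_transition(a, b))
    syn <- c(syn, aa[i] == aa[j])
  }
  .codon_env$pairs <- list(i = ii, j = jj, transition = ti, synonymous = syn)
  .codon_env$pairs
}

#' Build a codon alignment object
#'
#' Validates the invariants (equal lengths divisible by 3, no internal stop
#' codons, >= 3 rows) and encodes the data as site patterns over the 61 sense
#' codons. Codons containing gaps or ambiguous bases are treated as missing.
#'
#' @param cds Named character vector of aligned CDS strings.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(cds) {
  cds <- unlist(cds)
  if (length(cds) < 3L) stop("need >= 3 sequences")
  lens <- nchar(cds)
  if (length(unique(lens)) != 1L) stop("rows differ in length")
  if (lens[1L] %% 3L != 0L) stop("length not divisible by 3")
  codons <- sense_codons()
  gc <- genetic_code()
  idx <- lapply(cds, function(s) {
    co <- split_codons(s)
    if (any(!is.na(gc[co]) & gc[co] == "*"))
      stop("internal stop codon in sequence")
    match(co, codons)        # NA for gap/ambiguous codons
  })
  tipmat <- do.call(rbind, idx)     # ntip x nsite
  key <- apply(tipmat, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  patmat <- tipmat[, upat, drop = FALSE]
  weights <- as.numeric(table(key)[key[upat]])
  site_of_pattern <- match(key, key[upat])
  structure(list(ids = names(cds), cds = cds,
                 n_codons = unname(lens[1L]) %/% 3L,
                 patterns = patmat, weights = weights,
                 site_pattern = site_of_pattern),
            class = "codon_alignment")
}

# F3x4 codon frequencies from observed position-specific base composition
f3x4_frequencies <- function(aln) {
  codons <- sense_codons()
  cm <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (s in aln$cds) {
    co <- split_codons(s)
    for (p in 1:3) {
      b <- substr(co, p, p)
      tb <- table(factor(b, levels = bases))
      freq[p, ] <- freq[p, ] + as.numeric(tb)
    }
  }
  freq <- freq / rowSums(freq)
  pi <- freq[1L, cm[, 1L]] * freq[2L, cm[, 2L]] * freq[3L, cm[, 3L]]
  pi / sum(pi)
}

# eigen machinery for one (kappa, omega): returns transform matrices and the
# mean substitution rate under pi (for branch-length normalization)
.gy_eig <- function(kappa, omega, pi) {
  pr <- .codon_pairs()
  n <- length(pi)
  w <- ifelse(pr$transition, kappa, 1) * ifelse(pr$synonymous, 1, omega)
  A <- matrix(0, n, n)
  A[cbind(pr$i, pr$j)] <- w
  A[cbind(pr$j, pr$i)] <- w
  sq <- sqrt(pi)
  B <- A * (sq %o% sq)                      # symmetrized off-diagonal
  diag_q <- -as.vector(A %*% pi)            # Q[i,i]
  diag(B) <- diag_q
  rate <- -sum(pi * diag_q)
  eg <- eigen(B, symmetric = TRUE)
  list(U = eg$vectors, Ut = t(eg$vectors), lambda = eg$values, sq = sq,
       osc = (1 / sq) %o% sq, rate = rate)
}

.p_matrix <- function(eig, t) {
  E <- eig$U * rep(exp(eig$lambda * t), each = nrow(eig$U))
  P <- (E %*% eig$Ut) * eig$osc
  P[P < 0] <- 0
  P
}

# conditional site likelihoods for one rate class (vector over patterns);
# dense pruning implemented in C++ (see src/pruning.cpp)
.class_site_lik <- function(eig, tlen, tree_pre, patterns, pi) {
  pat <- patterns
  pat[is.na(pat)] <- 0L
  as.vector(cpp_class_site_lik(eig$U, eig$lambda, eig$sq, pi,
                               tree_pre$child, tree_pre$parent, tlen,
                               pat, tree_pre$n_nodes, tree_pre$root))
}

# reference R implementation of the same pruning, kept for cross-checking
.class_site_lik_r <- function(eig, tlen, tree_pre, patterns, pi) {
  nt <- nrow(patterns)
  npat <- ncol(patterns)
  n61 <- length(pi)
  partial <- vector("list", tree_pre$n_nodes)
  for (e in seq_along(tree_pre$child)) {
    ch <- tree_pre$child[e]; pa <- tree_pre$parent[e]
    P <- .p_matrix(eig, tlen[e])
    if (ch <= nt) {
      obs <- patterns[ch, ]
      down <- matrix(0, n61, npat)
      known <- !is.na(obs)
      down[, known] <- P[, obs[known], drop = FALSE]   # P[x -> observed codon]
      if (any(!known)) down[, !known] <- rowSums(P)
    } else {
      down <- P %*% partial[[ch]]
    }
    partial[[pa]] <- if (is.null(partial[[pa]])) down else partial[[pa]] * down
  }
  as.vector(pi %*% partial[[tree_pre$root]])
}

.prepare_tree <- function(tree, ids) {
  if (!setequal(tree$tip.label, ids))
    stop("tree leaves do not match alignment ids")
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ord <- match(tree$tip.label, ids)   # tip k in tree = row ord[k] of patterns
  list(child = tree$edge[, 2L], parent = tree$edge[, 1L],
       edge_length = tree$edge.length,
       n_nodes = max(tree$edge), root = length(tree$tip.label) + 1L,
       tip_row = ord, tree = tree)
}

# site-class decomposition (proportions and omegas) for each model
.model_classes <- function(model, par, beta_categories) {
  switch(model,
    M0 = list(p = 1, omega = par$omega),
    M1a = list(p = c(par$p0, 1 - par$p0), omega = c(par$omega0, 1)),
    M2a = list(p = c(par$p0, par$p1, 1 - par$p0 - par$p1),
               omega = c(par$omega0, 1, par$omega2)),
    M7 = {
      k <- beta_categories
      q <- stats::qbeta((2 * seq_len(k) - 1) / (2 * k), par$p, par$q)
      list(p = rep(1 / k, k), omega = pmin(q, 1 - 1e-8))
    },
    M8 = {
      k <- beta_categories
      q <- stats::qbeta((2 * seq_len(k) - 1) / (2 * k), par$p, par$q)
      list(p = c(rep(par$p0 / k, k), 1 - par$p0),
           omega = c(pmin(q, 1 - 1e-8), par$omega1))
    },
    stop("unknown model: ", model))
}

# parameter vector <-> transformed (unconstrained) space
.par_template <- function(model) {
  switch(model,
    M0 = c(log_kappa = log(2), log_scale = 0, log_omega = log(0.3)),
    M1a = c(log_kappa = log(2), log_scale = 0, logit_p0 = 0.85,
            logit_w0 = -1.4),
    M2a = c(log_kappa = log(2), log_scale = 0, a1 = 1, a2 = 0.5,
            logit_w0 = -1.4, log_w2m1 = 0),
    M7 = c(log_kappa = log(2), log_scale = 0, log_p = log(0.5),
           log_q = log(1)),
    M8 = c(log_kappa = log(2), log_scale = 0, logit_p0 = 2,
           log_p = log(0.5), log_q = log(1), log_w1m1 = 0))
}

.decode_par <- function(model, x) {
  inv_logit <- function(z) 1 / (1 + exp(-z))
  kappa <- exp(x[["log_kappa"]]); scale <- exp(x[["log_scale"]])
  par <- switch(model,
    M0 = list(omega = exp(x[["log_omega"]])),
    M1a = list(p0 = inv_logit(x[["logit_p0"]]),
               omega0 = inv_logit(x[["logit_w0"]])),
    M2a = {
      e1 <- exp(x[["a1"]]); e2 <- exp(x[["a2"]])
      z <- e1 + e2 + 1
      list(p0 = e1 / z, p1 = e2 / z,
           omega0 = inv_logit(x[["logit_w0"]]),
           omega2 = 1 + exp(x[["log_w2m1"]]))
    },
    M7 = list(p = min(exp(x[["log_p"]]), 99), q = min(exp(x[["log_q"]]), 99)),
    M8 = list(p0 = inv_logit(x[["logit_p0"]]),
              p = min(exp(x[["log_p"]]), 99), q = min(exp(x[["log_q"]]), 99),
              omega1 = 1 + exp(x[["log_w1m1"]])))
  par$kappa <- kappa; par$scale <- scale
  par
}

.site_lik_matrix <- function(par, model, pi, tree_pre, patterns,
                             beta_categories) {
  cls <- .model_classes(model, par, beta_categories)
  eigs <- lapply(cls$omega, function(w) .gy_eig(par$kappa, w, pi))
  rho <- sum(cls$p * vapply(eigs, `[[`, 0, "rate"))
  tl <- tree_pre$edge_length * par$scale / rho
  L <- vapply(eigs, function(e)
    .class_site_lik(e, tl, tree_pre, patterns, pi), numeric(ncol(patterns)))
  list(L = as.matrix(L), p = cls$p, omega = cls$omega)
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the Goldman-Yang codon-model likelihood over kappa, a global
#' branch-length scale and the model's site-class parameters, with F3x4 (or
#' equal) codon frequencies. The beta distributions of M7/M8 are discretized
#' into `beta_categories` equal-probability bins. Optimization uses
#' Nelder-Mead on transformed (unconstrained) parameters with `n_restarts`
#' jittered restarts; deterministic for a fixed seed.
#'
#' @param aln A [codon_alignment()] (or named character vector of CDSs).
#' @param tree An `ape::phylo` tree whose tips match the alignment ids.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param n_restarts Random restarts beyond the default start.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param beta_categories Discretization bins for M7/M8.
#' @param freq_model `"F3x4"` or `"equal"`.
#' @param seed Seed for restart jitter.
#' @param start Optional named start vector (transformed scale) overriding
#'   the default.
#' @return Object of class `site_model_fit`: `model`, `lnL`, `parameters`
#'   (kappa, scale, class proportions and omegas), `np`, plus the inputs
#'   needed for posterior computation.
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M1a", "M2a", "M7", "M8"),
                           n_restarts = 3L, tol = 1e-6, beta_categories = 10L,
                           freq_model = c("F3x4", "equal"), seed = 1L,
                           start = NULL) {
  model <- match.arg(model)
  freq_model <- match.arg(freq_model)
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  tree_pre <- .prepare_tree(tree, aln$ids)
  # rows indexed by tree tip number
  patterns <- aln$patterns[match(tree_pre$tree$tip.label, aln$ids), ,
                           drop = FALSE]
  pi <- if (freq_model == "F3x4") f3x4_frequencies(aln) else
    rep(1 / 61, 61)
  wts <- aln$weights
  nll <- function(x) {
    par <- .decode_par(model, stats::setNames(x, names(x0)))
    slm <- try(.site_lik_matrix(par, model, pi, tree_pre, patterns,
                                beta_categories), silent = TRUE)
    if (inherits(slm, "try-error")) return(1e10)
    lik <- as.vector(slm$L %*% slm$p)
    if (any(!is.finite(lik)) || any(lik <= 0)) return(1e10)
    -sum(wts * log(lik))
  }
  x0 <- .par_template(model)
  if (!is.null(start)) x0[names(start)] <- start
  set.seed(seed)
  starts <- c(list(x0), lapply(seq_len(n_restarts), function(i)
    x0 + stats::rnorm(length(x0), 0, 0.5)))
  best <- NULL
  for (s in starts) {
    names(s) <- names(x0)
    opt <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 300, reltol = tol * 1e-2)),
      error = function(e) NULL)
    if (is.null(opt) || opt$value >= 1e9)
      opt <- stats::optim(s, nll, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = tol * 1e-2))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  xhat <- stats::setNames(best$par, names(x0))
  par <- .decode_par(model, xhat)
  slm <- .site_lik_matrix(par, model, pi, tree_pre, patterns, beta_categories)
  structure(list(model = model, lnL = -best$value, parameters = par,
                 class_proportions = slm$p, class_omegas = slm$omega,
                 np = length(x0), transformed = xhat,
                 pi = pi, beta_categories = beta_categories,
                 aln = aln, tree_pre = tree_pre, patterns = patterns,
                 convergence = best$convergence),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("Codon site model %s: lnL = %.6f\n", x$model, x$lnL))
  cat(sprintf("  kappa = %.4f, tree scale = %.4f\n",
              x$parameters$kappa, x$parameters$scale))
  cat("  class proportions:", paste(sprintf("%.4f", x$class_proportions),
                                    collapse = " "), "\n")
  cat("  class omegas:     ", paste(sprintf("%.4f", x$class_omegas),
                                    collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.site_model_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}

# NEB posterior that each site belongs to each class under a fit
.neb_posteriors <- function(fit) {
  slm <- .site_lik_matrix(fit$parameters, fit$model, fit$pi, fit$tree_pre,
                          fit$patterns, fit$beta_categories)
  num <- sweep(slm$L, 2L, slm$p, `*`)
  post_pat <- num / rowSums(num)
  post_pat[fit$aln$site_pattern, , drop = FALSE]   # per original site
}

#' Likelihood-ratio test between nested site models
#'
#' Fits the null and alternative models (M1a vs M2a, or M7 vs M8), computes
#' 2(lnL_alt - lnL_null) floored at zero, a chi-square p-value with 2 degrees
#' of freedom, and the sites whose NEB posterior for the positive-selection
#' class exceeds `posterior_cutoff` under the alternative. The alternative fit
#' is warm-started from the null fit.
#'
#' @param aln A [codon_alignment()] or named CDS vector.
#' @param tree `ape::phylo` tree.
#' @param comparison `"M1a_vs_M2a"` or `"M7_vs_M8"`.
#' @param posterior_cutoff NEB posterior threshold for reporting sites.
#' @param ... Passed to [fit_site_model()].
#' @return Object of class `site_model_lrt`: `null_fit`, `alt_fit`,
#'   `two_delta_lnl`, `df`, `p`, `selected_sites` (data frame site/posterior).
#' @export
site_model_lrt <- function(aln, tree,
                           comparison = c("M1a_vs_M2a", "M7_vs_M8"),
                           posterior_cutoff = 0.95, ...) {
  comparison <- match.arg(comparison)
  models <- if (comparison == "M1a_vs_M2a") c("M1a", "M2a") else c("M7", "M8")
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  null_fit <- fit_site_model(aln, tree, models[1L], ...)
  nx <- null_fit$transformed
  warm <- if (comparison == "M1a_vs_M2a") {
    # map the M1a optimum onto M2a with a small positive-selection class
    p0 <- 1 / (1 + exp(-nx[["logit_p0"]]))
    p1 <- (1 - p0) * 0.9
    p2 <- max(1e-3, 1 - p0 - p1)
    c(log_kappa = nx[["log_kappa"]], log_scale = nx[["log_scale"]],
      a1 = log(p0 / p2), a2 = log(p1 / p2),
      logit_w0 = nx[["logit_w0"]], log_w2m1 = 0)
  } else {
    c(log_kappa = nx[["log_kappa"]], log_scale = nx[["log_scale"]],
      logit_p0 = 2.5, log_p = nx[["log_p"]], log_q = nx[["log_q"]],
      log_w1m1 = 0)
  }
  alt_fit <- fit_site_model(aln, tree, models[2L], start = warm, ...)
  two_delta <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  p <- stats::pchisq(two_delta, df = 2, lower.tail = FALSE)
  post <- .neb_posteriors(alt_fit)
  pos_class <- which.max(alt_fit$class_omegas)    # the class allowed omega > 1
  sel <- which(post[, pos_class] > posterior_cutoff)
  structure(list(comparison = comparison, null_fit = null_fit,
                 alt_fit = alt_fit, two_delta_lnl = two_delta, df = 2L,
                 p = p,
                 selected_sites = data.frame(site = sel,
                                             posterior = post[sel, pos_class])),
            class = "site_model_lrt")
}

#' @export
print.site_model_lrt <- function(x, ...) {
  cat(sprintf("%s: 2*deltaLnL = %.5f (df = %d, p = %.4g)\n",
              x$comparison, x$two_delta_lnl, x$df, x$p))
  cat(sprintf("  lnL %s = %.6f, lnL %s = %.6f\n", x$null_fit$model,
              x$null_fit$lnL, x$alt_fit$model, x$alt_fit$lnL))
  if (nrow(x$selected_sites))
    cat("  sites with NEB posterior above cutoff:",
        paste(x$selected_sites$site, collapse = " "), "\n")
  invisible(x)
}

#' Simulate a codon alignment under a site model
#'
#' Sites draw an omega class from `proportions`/`omegas`; codons evolve along
#' the tree under the Goldman-Yang model with the mixture-normalized rate.
#'
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon site).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion rate ratio.
#' @param proportions,omegas Site-class mixture.
#' @param pi Codon frequencies (default uniform over the 61 sense codons).
#' @param seed Integer seed.
#' @return Named character vector of CDS strings (one per tip).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2,
                                     proportions = 1, omegas = 0.3,
                                     pi = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  codons <- sense_codons()
  stopifnot(length(proportions) == length(omegas),
            abs(sum(proportions) - 1) < 1e-8)
  eigs <- lapply(omegas, function(w) .gy_eig(kappa, w, pi))
  rho <- sum(proportions * vapply(eigs, `[[`, 0, "rate"))
  tree <- ape::reorder.phylo(ape::unroot(tree), "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cls <- sample.int(length(omegas), n_codons, replace = TRUE,
                    prob = proportions)
  node_state <- matrix(NA_integer_, max(tree$edge), n_codons)
  node_state[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    t <- tree$edge.length[e] / rho
    for (k in unique(cls)) {
      P <- .p_matrix(eigs[[k]], t)
      sites <- which(cls == k)
      par_states <- node_state[pa, sites]
      for (s0 in unique(par_states)) {
        grp <- sites[par_states == s0]
        node_state[ch, grp] <- sample.int(61L, length(grp), replace = TRUE,
                                          prob = P[s0, ])
      }
    }
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(codons[node_state[i, ]], collapse = ""), "")
  stats::setNames(out, tree$tip.label)
}
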