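# Repertoire tabulation: species x subfamily count tables in the
# "total(pseudo)" convention, pseudogenization rates, subfamily presence and
# Dollo gain/loss mapping on a species tree.

#' Load a repertoire count table
#'
#' Parses a TSV whose first columns are `subfamily` and `class` and whose
#' remaining columns hold one species each, with cells `"total(pseudo)"` (a
#' bare integer means zero pseudogenes). Invariants are validated and
#' violations reported by cell.
#'
#' @param path Path to the TSV.
#' @return Object of class `repertoire_table`: `species`, `subfamilies`,
#'   `class` (named by subfamily), and integer matrices `total` and `pseudo`
#'   (subfamilies x species).
#' @export
load_repertoire_table <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0L) stop("empty repertoire table: ", path)
  if (!all(c("subfamily", "class") %in% names(df)))
    stop("repertoire table needs 'subfamily' and 'class' columns")
  species <- setdiff(names(df), c("subfamily", "class"))
  subfam <- df$subfamily
  parse_cell <- function(cell, sf, sp) {
    m <- regmatches(cell, regexec("^(\\d+)(?:\\((\\d+)\\))?$", cell))[[1L]]
    if (length(m) == 0L)
      stop(sprintf("invalid cell '%s' at subfamily %s, species %s",
                   cell, sf, sp))
    tot <- as.integer(m[2L])
    pse <- if (nzchar(m[3L])) as.integer(m[3L]) else 0L
    if (pse > tot)
      stop(sprintf("pseudogene count exceeds total in cell '%s' at %s/%s",
                   cell, sf, sp))
    c(tot, pse)
  }
  total <- pseudo <- matrix(0L, nrow(df), length(species),
                            dimnames = list(subfam, species))
  for (r in seq_len(nrow(df))) for (s in species) {
    v <- parse_cell(as.character(df[[s]][r]), subfam[r], s)
    total[r, s] <- v[1L]; pseudo[r, s] <- v[2L]
  }
  structure(list(species = species, subfamilies = subfam,
                 class = stats::setNames(df$class, subfam),
                 total = total, pseudo = pseudo),
            class = "repertoire_table")
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat(sprintf("Repertoire table: %d subfamilies x %d species; %d genes (%d pseudogenes)\n",
              length(x$subfamilies), length(x$species), sum(x$total),
              sum(x$pseudo)))
  invisible(x)
}

#' Pseudogenization rates
#'
#' Per species, 100 x (pseudogenes / all gene copies); plus the pooled rate
#' over all species and the mean of the per-species rates. Species with zero
#' detected genes are flagged `NA`.
#'
#' @param table A `repertoire_table`.
#' @return List with `per_species` (data frame: species, total, pseudo, rate,
#'   rate_rounded), `pooled`, `mean_of_species`.
#' @export
pseudogenization_rates <- function(table) {
  tot <- colSums(table$total); pse <- colSums(table$pseudo)
  rate <- ifelse(tot > 0, 100 * pse / tot, NA_real_)
  list(per_species = data.frame(species = table$species, total = tot,
                                pseudo = pse, rate = rate,
                                rate_rounded = round(rate),
                                row.names = NULL),
       pooled = 100 * sum(pse) / sum(tot),
       mean_of_species = mean(rate, na.rm = TRUE))
}

#' Subfamily presence
#'
#' Presence means total count (any status) at or above `threshold`. Presence
#' counts are reported out of `denominator` recognized subfamilies.
#'
#' @param table A `repertoire_table`.
#' @param threshold Minimum copies for presence.
#' @param denominator Number of recognized subfamilies.
#' @return List with `presence` (logical matrix subfamilies x species),
#'   `per_species` (named integer counts) and `denominator`.
#' @export
subfamily_presence <- function(table, threshold = 1L, denominator = 30L) {
  pres <- table$total >= threshold
  list(presence = pres,
       per_species = colSums(pres),
       denominator = denominator)
}

#' Dollo gain/loss mapping of subfamilies on a species tree
#'
#' Each subfamily is gained exactly once, at the most recent common ancestor
#' of the species possessing it; losses are the maximal subtrees below the
#' gain node containing no possessing species. Ancestral repertoires follow
#' from the reconstruction (present at a node iff the node lies in the gain
#' subtree and retains a possessing descendant).
#'
#' @param presence Logical matrix (subfamilies x species) as from
#'   [subfamily_presence()].
#' @param species_tree `ape::phylo`; leaves must cover the possessing species.
#' @return Object of class `gain_loss_map`: per-subfamily data frame
#'   (`subfamily`, `gain_node`, `n_losses`, `loss_nodes`), `node_repertoire`
#'   (list: subfamilies present per node), and the tree. Subfamilies absent
#'   everywhere are flagged in `absent`.
#' @export
dollo_gain_loss <- function(presence, species_tree) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  missing_sp <- setdiff(colnames(presence)[colSums(presence) > 0],
                        tr$tip.label)
  if (length(missing_sp))
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  # children lists and subtree tip sets
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  n_nodes <- max(tr$edge)
  tipset <- vector("list", n_nodes)
  po <- ape::reorder.phylo(tr, "postorder")
  for (i in seq_len(ntip)) tipset[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    tipset[[pa]] <- c(tipset[[pa]], tipset[[ch]])
  }
  parent_of <- integer(n_nodes)
  parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]
  rows <- list()
  node_rep <- rep(list(character()), n_nodes)
  absent <- character()
  for (sf in rownames(presence)) {
    have <- colnames(presence)[presence[sf, ]]
    if (!length(have)) { absent <- c(absent, sf); next }
    gain <- if (length(have) == 1L) match(have, tr$tip.label) else
      ape::getMRCA(tr, have)
    # nodes in the gain subtree that retain a possessing descendant
    in_subtree <- which(vapply(seq_len(n_nodes), function(nd)
      nd == gain || (length(tipset[[nd]]) &&
                       all(tipset[[nd]] %in% tipset[[gain]]) &&
                       .is_descendant(nd, gain, parent_of)), TRUE))
    retains <- vapply(in_subtree, function(nd)
      any(tipset[[nd]] %in% have), TRUE)
    present_nodes <- in_subtree[retains]
    # losses: maximal empty subtrees = empty nodes whose parent retains
    empty_nodes <- setdiff(in_subtree, present_nodes)
    losses <- empty_nodes[parent_of[empty_nodes] %in% present_nodes]
    for (nd in present_nodes)
      node_rep[[nd]] <- c(node_rep[[nd]], sf)
    rows[[sf]] <- data.frame(subfamily = sf, gain_node = gain,
                             n_losses = length(losses),
                             loss_nodes = paste(losses, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  structure(list(events = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 node_repertoire = node_rep, tree = tr, absent = absent),
            class = "gain_loss_map")
}

.is_descendant <- function(node, anc, parent_of) {
  while (node != 0L) {
    if (node == anc) return(TRUE)
    node <- parent_of[node]
  }
  FALSE
}

#' @export
print.gain_loss_map <- function(x, ...) {
  cat(sprintf("Dollo gain/loss map: %d subfamilies mapped, %d absent everywhere\n",
              nrow(x$events), length(x$absent)))
  cat(sprintf("  total losses: %d\n", sum(x$events$n_losses)))
  invisible(x)
}

#' Path to a packaged data file
#' @param file File name under the package's `extdata`.
#' @return Absolute path.
#' @export
kapkit_extdata <- function(file) {
  system.file("extdata", file, package = "kapkit", mustWork = TRUE)
}
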