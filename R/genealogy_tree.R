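#' Convert a genealogy to an ape phylogeny of population lineages
#'
#' Builds the full lineage-level tree of a simulated genealogy: one tip per
#' population lineage ever born (labelled `L<lineage_id>`), internal nodes at
#' splitting events, branch lengths in Myr. Extirpated lineages end at their
#' extirpation time, so the full tree is generally non-ultrametric; restricted
#' to extant tips it is ultrametric by construction.
#'
#' @param g A [simulate_genealogy()] result.
#' @return An object of class `phylo`.
#' @export
genealogy_phylo <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  ln <- g$lineages
  N <- nrow(ln)
  labs <- paste0("L", ln$lineage_id)
  if (N == 1L)
    return(single_tip_phylo(labs, ln$end_time - ln$origin_time))

  # attach node of lineage i (the split that created it); lineage ids are in
  # birth order, so the first-born non-root lineage's attach node is the root
  # and gets ape's conventional number N+1
  node <- c(NA_integer_, N + seq_len(N - 1L))
  ch <- 2:N
  o <- order(ln$parent_id[ch], ch)
  chs <- ch[o]                      # children grouped by parent, birth order
  ps <- ln$parent_id[ch][o]
  first <- !duplicated(ps)
  prev_sib <- c(NA_integer_, chs[-length(chs)])

  # edge into each attach node comes from the previous node on the parent's
  # path: the parent's own attach node for a first child, otherwise the
  # previous sibling's. The founder has no attach node, so the first-born
  # crown split (the root) has no incoming edge.
  prev_node <- ifelse(first, node[ps], node[prev_sib])
  prev_time <- ifelse(first, ln$origin_time[ps], ln$origin_time[prev_sib])
  keep <- !is.na(prev_node)
  e_int <- cbind(prev_node[keep], node[chs][keep])
  l_int <- ln$origin_time[chs][keep] - prev_time[keep]

  # tip edge leaves the last node on the lineage's own path
  last <- !duplicated(ps, fromLast = TRUE)
  tip_from <- node
  tip_time <- ln$origin_time
  tip_from[ps[last]] <- node[chs[last]]
  tip_time[ps[last]] <- ln$origin_time[chs[last]]
  e_tip <- cbind(tip_from, seq_len(N))
  l_tip <- ln$end_time - tip_time

  phy <- list(edge = rbind(e_int, e_tip),
              edge.length = c(l_int, l_tip),
              tip.label = labs,
              Nnode = N - 1L)
  storage.mode(phy$edge) <- "integer"
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

single_tip_phylo <- function(label, depth) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = depth,
                 tip.label = label,
                 Nnode = 1L),
            class = "phylo")
}

#' Prune a genealogy to a species tree with one random representative per
#' species
#'
#' For every extant species one surviving population lineage is chosen
#' uniformly at random to represent it; all other lineages are pruned and the
#' induced subtree is returned with internal nodes at the original splitting
#' times. Tips are labelled `s<species_id>`. The result is ultrametric, with
#' tip depth equal to the crown age of the induced tree. A single-species
#' genealogy yields a degenerate one-tip tree.
#'
#' @param g A [simulate_genealogy()] result with at least one extant lineage.
#' @param seed Optional integer seed for the representative draw; if `NULL`
#'   the current RNG stream is used.
#' @return An ultrametric `phylo` object with one tip per extant species; the
#'   attribute `"representatives"` maps each tip label to the lineage_id of
#'   the chosen representative.
#' @export
sample_species_tree <- function(g, seed = NULL) {
  stopifnot(inherits(g, "genealogy"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ln <- g$lineages
  ext <- ln[ln$fate == "extant", ]
  if (nrow(ext) == 0L)
    stop("genealogy has no extant lineages", call. = FALSE)
  groups <- split(ext$lineage_id, ext$species_id)   # sorted by species_id
  reps <- vapply(groups, function(ids) ids[sample.int(length(ids), 1L)], 0L)
  sp_lab <- paste0("s", names(groups))
  names(reps) <- sp_lab

  if (length(reps) == 1L) {
    out <- single_tip_phylo(sp_lab, g$params$duration)
    attr(out, "representatives") <- reps
    return(out)
  }

  phy <- genealogy_phylo(g)
  sub <- ape::keep.tip(phy, paste0("L", reps))
  sub$tip.label <- sp_lab[match(sub$tip.label, paste0("L", reps))]
  attr(sub, "representatives") <- reps
  sub
}
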