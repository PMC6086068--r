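# Independent oracles and hand-built fixtures used across the test files.
# Everything here is deliberately brute force and independent of the code
# paths it checks.

# all-pairs sister identification: two tips are sisters iff they alone form
# a monophyletic group (checked with ape::is.monophyletic, the textbook
# definition, pair by pair)
brute_sister_pairs <- function(tree) {
  tips <- sort(tree$tip.label)
  out <- list()
  for (i in seq_along(tips)[-length(tips)]) {
    for (j in seq((i + 1), length(tips))) {
      pair <- c(tips[i], tips[j])
      if (ape::is.monophyletic(tree, pair))
        out[[length(out) + 1L]] <- pair
    }
  }
  if (!length(out)) return(matrix(character(0), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

# root-to-node depths by explicit path sums over the edge matrix
brute_node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  depth <- rep(NA_real_, n_node)
  root <- length(tree$tip.label) + 1L
  depth[root] <- 0
  e <- tree$edge
  repeat {
    todo <- which(!is.na(depth[e[, 1]]) & is.na(depth[e[, 2]]))
    if (!length(todo)) break
    depth[e[todo, 2]] <- depth[e[todo, 1]] + tree$edge.length[todo]
  }
  depth
}

# all-pairs path-length matrix from the depths: d(a,b) = depth(a) + depth(b)
# - 2 depth(mrca)
brute_cophenetic <- function(tree) {
  tips <- tree$tip.label
  depth <- brute_node_depths(tree)
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m <- ape::getMRCA(tree, c(tips[i], tips[j]))
      d[i, j] <- d[j, i] <- depth[i] + depth[j] - 2 * depth[m]
    }
  }
  d
}

# pairwise divergence times of extant lineages straight from the genealogy
# event records, without building any tree: follow both parent chains to
# their first shared lineage; the paths separate at the earlier of the two
# child-origin times on that lineage.
genealogy_divergence <- function(g, a, b) {
  ln <- g$lineages
  chain <- function(x) {
    ids <- x
    while (!is.na(ln$parent_id[ids[length(ids)]]))
      ids <- c(ids, ln$parent_id[ids[length(ids)]])
    ids
  }
  ca <- chain(a); cb <- chain(b)
  common <- intersect(ca, cb)
  L <- common[1]                       # first shared lineage on a's chain
  child_on <- function(ch) if (ch[1] == L) Inf else
    ln$origin_time[ch[which(ch == L) - 1L]]
  t_split <- min(child_on(ca), child_on(cb))
  t_split
}

# plain constant-rate birth-death tip-count simulator (counts only), crown
# start with two independent sides, conditioned on both sides surviving
bd_count_side <- function(lambda, mu, Tmax) {
  t <- 0; n <- 1L
  repeat {
    rate <- n * (lambda + mu)
    if (rate == 0) return(n)
    t <- t + stats::rexp(1L, rate)
    if (t >= Tmax) return(n)
    if (stats::runif(1L) < lambda / (lambda + mu)) n <- n + 1L
    else { n <- n - 1L; if (n == 0L) return(0L) }
  }
}

bd_count_crown <- function(lambda, mu, Tmax) {
  repeat {
    n1 <- bd_count_side(lambda, mu, Tmax)
    n2 <- bd_count_side(lambda, mu, Tmax)
    if (n1 > 0L && n2 > 0L) return(n1 + n2)
  }
}

# deterministic replicate seeds for long recovery loops
derive_seed_acc <- function(x, r) {
  as.integer((round(x * 1000) * 7919 + r * 104729) %% 2147483647)
}

# assemble a genealogy object by hand from an event table
make_genealogy <- function(df, duration, start = "crown") {
  params <- pbd_params(1, 1, 1, duration = duration)
  df$lineage_id <- seq_len(nrow(df))
  structure(list(params = params, seed = NULL, n_restarts = 0L,
                 start = start, conditioning = "none", lineages = df),
            class = "genealogy")
}

# Fig. 1c-style fixture: two good crown species; lineage 3 splits from side
# 1 and converts (founding species 3); lineage 4 budded off lineage 3 before
# the conversion and never converts, so at the end it is a second population
# of species 3. Three extant species, one of them multi-population.
fixture_three_species <- function(duration = 6) {
  make_genealogy(data.frame(
    parent_id = c(NA, 1L, 1L, 3L),
    origin_time = c(0, 0, 1, 2),
    end_time = rep(duration, 4),
    fate = rep("extant", 4),
    conversion_time = c(NA, NA, 3, NA),
    species_id = c(1L, 2L, 3L, 3L),
    species_id_at_birth = c(1L, 2L, 1L, 1L),
    species_founder = c(TRUE, TRUE, TRUE, FALSE),
    status = c("good", "good", "good", "incipient"),
    crown_side = c(1L, 2L, 1L, 1L)), duration)
}

# founder species extirpated, two converted species extant
fixture_root_extinct <- function(duration = 6) {
  make_genealogy(data.frame(
    parent_id = c(NA, 1L, 1L, 2L),
    origin_time = c(0, 0, 1, 2.5),
    end_time = c(5, duration, duration, 4),
    fate = c("extirpated", "extant", "extant", "extirpated"),
    conversion_time = c(NA, NA, 2, NA),
    species_id = c(1L, 2L, 3L, 2L),
    species_id_at_birth = c(1L, 2L, 1L, 2L),
    species_founder = c(TRUE, TRUE, TRUE, FALSE),
    status = c("good", "good", "good", "incipient"),
    crown_side = c(1L, 2L, 1L, 2L)), duration)
}
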