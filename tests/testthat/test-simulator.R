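test_that("with all rates zero only the crown lineages exist", {
  p <- pbd_params(0, 0, 0, duration = 6)
  g <- simulate_genealogy(p, seed = 1)
  expect_equal(nrow(g$lineages), 2L)
  expect_true(all(g$lineages$fate == "extant"))
  expect_equal(g$lineages$end_time, c(6, 6))
  expect_equal(extant_richness(g), 2L)          # crown = two good species
  g2 <- simulate_genealogy(p, seed = 1, start = "crown_incipient")
  expect_equal(extant_richness(g2), 1L)         # incipient daughter variant
  g3 <- simulate_genealogy(p, seed = 1, start = "stem")
  expect_equal(nrow(g3$lineages), 1L)
})

test_that("without conversion no species beyond the founders ever arises", {
  p <- pbd_params(0.9, 0, 0.2, duration = 6)
  for (s in 1:10) {
    g <- simulate_genealogy(p, seed = 100 + s)
    expect_equal(extant_richness(g), 2L)
    expect_equal(sort(unique(g$lineages$species_id)), c(1L, 2L))
    gi <- simulate_genealogy(p, seed = 100 + s, start = "crown_incipient")
    expect_equal(extant_richness(gi), 1L)
    expect_equal(unique(gi$lineages$species_id), 1L)
  }
})

test_that("hand-built genealogies give the expected species counts", {
  expect_equal(extant_richness(fixture_three_species()), 3L)
  expect_equal(extant_richness(fixture_root_extinct()), 2L)
})

test_that("event records satisfy the structural invariants", {
  p <- pbd_params(1.16, 0.5, 0.6, duration = 6)
  for (s in 1:8) {
    g <- simulate_genealogy(p, seed = 200 + s)
    ln <- g$lineages
    # the two crown lineages both start at time zero as good species
    expect_equal(which(is.na(ln$parent_id)), 1L)
    expect_equal(ln$origin_time[1:2], c(0, 0))
    expect_equal(ln$status[1:2], c("good", "good"))
    expect_equal(ln$species_id[1:2], c(1L, 2L))
    # time ordering and containment
    expect_true(all(ln$origin_time >= 0 & ln$origin_time <= ln$end_time))
    expect_true(all(ln$end_time <= g$params$duration + 1e-12))
    has_par <- !is.na(ln$parent_id)
    expect_true(all(ln$origin_time[has_par] >=
                      ln$origin_time[ln$parent_id[has_par]]))
    expect_true(all(ln$origin_time[has_par] <=
                      ln$end_time[ln$parent_id[has_par]]))
    cv <- !is.na(ln$conversion_time)
    expect_true(all(ln$conversion_time[cv] >= ln$origin_time[cv] &
                      ln$conversion_time[cv] <= ln$end_time[cv]))
    # extant <=> survives to the present
    expect_equal(ln$fate == "extant", ln$end_time == g$params$duration)
    # every species has exactly one founding event
    founders <- ln$species_id[ln$species_founder]
    expect_equal(sort(founders), sort(unique(ln$species_id)))
    expect_false(any(duplicated(founders)))
    # at-birth identity is the parent's identity frozen at the birth time
    # (crown founders are exempt: they carry their own species from origin)
    for (i in setdiff(which(has_par), 2L)) {
      pa <- ln$parent_id[i]
      if (!is.na(ln$conversion_time[pa]) &&
          ln$origin_time[i] >= ln$conversion_time[pa])
        expect_equal(ln$species_id_at_birth[i], ln$species_id[pa])
      else
        expect_equal(ln$species_id_at_birth[i], ln$species_id_at_birth[pa])
    }
    # end-state identity: non-founders carry their parent's final species
    nf <- has_par & !ln$species_founder
    expect_equal(ln$species_id[nf], ln$species_id[ln$parent_id[nf]])
    # richness never exceeds extant lineage count, equal iff all species
    # are single-population
    ext <- ln[ln$fate == "extant", ]
    expect_lte(extant_richness(g), nrow(ext))
    expect_equal(extant_richness(g) == nrow(ext),
                 !any(duplicated(ext$species_id)))
  }
})

test_that("identical seeds reproduce the genealogy bit for bit", {
  p <- pbd_params(1.13, 0.15, 0.3, duration = 6)
  g1 <- simulate_genealogy(p, seed = 77)
  g2 <- simulate_genealogy(p, seed = 77)
  expect_identical(g1$lineages, g2$lineages)
  expect_identical(g1$n_restarts, g2$n_restarts)
})

test_that("pure-splitting lineage growth matches the branching-process mean", {
  # mu' = chi = 0: the lineage count is two independent Yule processes, so
  # E[N(T)] = 2 exp(lambda' T); checked at lambda' = 0.5, T = 6 over 2000
  # replicates against the exact expectation
  p <- pbd_params(0.5, 0, 0, duration = 6)
  set.seed(321)
  n <- vapply(1:2000, function(i)
    sum(simulate_genealogy(p)$lineages$fate == "extant"), 0L)
  expected <- 2 * exp(0.5 * 6)
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 4 * se)
})

test_that("instant conversion reduces the process to plain birth-death", {
  # chi >> lambda': every new lineage converts at once, so species counts of
  # the pruned tree must match a plain crown birth-death process simulated
  # with an independent minimal counter (both-sides-survive conditioning)
  la <- 0.3; mu <- 0.1; Tm <- 8; nrep <- 5000
  p <- pbd_params(la, 1e6, mu, duration = Tm)
  set.seed(99)
  tips_pbd <- vapply(1:nrep, function(i)
    extant_richness(simulate_genealogy(p)), 0L)
  tips_bd <- vapply(1:nrep, function(i) bd_count_crown(la, mu, Tm), 0L)
  se_diff <- sqrt(stats::var(tips_pbd) / nrep + stats::var(tips_bd) / nrep)
  expect_lt(abs(mean(tips_pbd) - mean(tips_bd)), 4 * se_diff)
  expect_gt(stats::sd(tips_pbd) / stats::sd(tips_bd), 0.85)
  expect_lt(stats::sd(tips_pbd) / stats::sd(tips_bd), 1.15)
})

test_that("invalid parameters are rejected", {
  expect_error(pbd_params(-1, 0.5, 0.6, duration = 6), ">= 0")
  expect_error(pbd_params(Inf, 0.5, 0.6, duration = 6), "finite")
  expect_error(pbd_params(1, 0.5, 0.6, duration = 0), "> 0")
})
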