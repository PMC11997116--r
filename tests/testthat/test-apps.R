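test_that("jagged-end profiles recover the planted overhang and conserve counts", {
  sim <- simulate_jagged_library(jag = 5L, ends = "both", n_molecules = 150,
                                 length = 200, depth = 5, seed = 301)
  set.seed(302)
  calls <- truth_to_calls(sim, sensitivity = 0.96, fpr = 0.01)
  prof <- jagged_end_profile(calls, sim$molecules, D = 30L)
  # inside the jag the level approximates the caller's sensitivity, beyond
  # it the false-positive rate
  expect_lt(abs(mean(prof$level[prof$distance <= 4]) - 0.96), 0.05)
  expect_lt(abs(mean(prof$level[prof$distance >= 7]) - 0.01), 0.01)
  expect_gt(mean(prof$level[prof$distance <= 4]),
            10 * mean(prof$level[prof$distance >= 7]))
  # count conservation: sum of per-distance n equals the labelled calls in range
  lens <- vapply(sim$molecules, function(m) nchar(m$sequence), 0L)
  names(lens) <- vapply(sim$molecules, `[[`, "", "molecule_id")
  d <- ifelse(calls$strand_mode == "watson",
              lens[calls$molecule_id] - 1L - calls$position, calls$position)
  expect_equal(sum(prof$n), sum(d <= 30))
})

test_that("a zero-jag library is flat at the false-positive rate", {
  sim <- simulate_jagged_library(jag = 0L, ends = "both", n_molecules = 80,
                                 length = 200, depth = 5, seed = 303)
  set.seed(304)
  calls <- truth_to_calls(sim, sensitivity = 0.96, fpr = 0.01)
  prof <- jagged_end_profile(calls, sim$molecules, D = 30L)
  expect_lt(max(prof$level, na.rm = TRUE), 0.06)
  expect_lt(abs(mean(prof$level, na.rm = TRUE) - 0.01), 0.01)
})

test_that("anchor periodicity recovers pure pulse-train periods exactly", {
  for (P in c(120L, 180L, 240L)) {
    g <- 0:8000
    lab <- ifelse((g %% P) < 10, "modified", "unmodified")
    calls <- data.frame(molecule_id = "m", position = g, strand_mode = "watson",
                        mod_type = "6mA", score = 0.5, label = lab, depth = 3L,
                        chrom = "c", genome_pos = g, stringsAsFactors = FALSE)
    ap <- anchor_periodicity(calls, anchors = 4000L, span = 1000L, bin = 10L)
    expect_equal(ap$estimated_period, P, tolerance = 10 / P)
    aps <- anchor_periodicity(calls, anchors = 4000L, span = 1000L, bin = 10L,
                              method = "spectrum")
    expect_equal(aps$estimated_period, P, tolerance = 0.1)
  }
})

test_that("a flat profile yields no period, and sparse coverage is missing", {
  set.seed(305)
  g <- 0:4000
  calls <- data.frame(molecule_id = "m", position = g, strand_mode = "watson",
                      mod_type = "6mA", score = 0.5,
                      label = sample(c("modified", "unmodified"), length(g), TRUE,
                                     prob = c(0.05, 0.95)),
                      depth = 3L, chrom = "c", genome_pos = g,
                      stringsAsFactors = FALSE)
  ap <- anchor_periodicity(calls, anchors = 2000L)
  expect_true(is.na(ap$estimated_period))
  few <- calls[1:20, ]
  expect_true(is.na(anchor_periodicity(few, anchors = 10L)$estimated_period))
})

test_that("period estimates are stable under doubling the library", {
  sim1 <- simulate_accessibility_track(n_molecules = 1000, length = 400, depth = 2,
                                       seed = 306)
  sim2 <- simulate_accessibility_track(n_molecules = 2000, length = 400, depth = 2,
                                       seed = 306)
  set.seed(307)
  p1 <- anchor_periodicity(truth_to_calls(sim1), sim1$anchors)$estimated_period
  p2 <- anchor_periodicity(truth_to_calls(sim2), sim2$anchors)$estimated_period
  expect_equal(p1, p2, tolerance = 10 / 180)
})

test_that("motif enrichment recovers GATC from a Dam library and respects the null", {
  sim <- simulate_dam_genome(p_motif = 0.95, p_bg = 0.01, n_molecules = 60,
                             length = 600, depth = 2, seed = 308)
  set.seed(309)
  calls <- truth_to_calls(sim, sensitivity = 0.96, fpr = 0.01)
  res <- motif_enrichment(calls, sim$molecules)
  expect_equal(res$motif[1], "GATC")
  expect_equal(res$a_index[1], 1L)
  expect_equal(res$level[1], 0.95 * 0.96, tolerance = 0.03)
  # permutation safety: shuffling labels destroys all significant enrichment
  perm <- calls
  perm$label <- sample(perm$label)
  resp <- motif_enrichment(perm, sim$molecules)
  bonf <- 0.001 / nrow(resp)   # family-wise 0.1% over all tested words
  expect_equal(sum(resp$enrichment > 2 & resp$p < bonf), 0L)
  expect_error(motif_enrichment(calls[0, ], sim$molecules), "no labelled")
})

test_that("origin scores match the closed-form log-likelihood ratio", {
  panel <- reference_panel(1:5, rep(0.9, 5), rep(0.1, 5))
  profiles <- structure(list(list(molecule_id = "m1", positions = 1:5,
                                  genome_pos = 1:5, states = rep(1L, 5),
                                  n_cpg = 5L)),
                        class = "methylation_profiles")
  sc <- molecule_origin_score(profiles, panel)
  expect_equal(sc$molecules$score, plogis(log(9)), tolerance = 1e-12)
  expect_equal(sc$molecules$score, 0.9, tolerance = 1e-12)
  # identical panels: every molecule is neutral
  panel0 <- reference_panel(1:5, rep(0.7, 5), rep(0.7, 5))
  expect_equal(molecule_origin_score(profiles, panel0)$molecules$score, 0.5)
  # antisymmetry: swapping the classes reflects the score around 0.5
  swapped <- reference_panel(1:5, rep(0.1, 5), rep(0.9, 5))
  expect_equal(molecule_origin_score(profiles, swapped)$molecules$score,
               1 - sc$molecules$score, tolerance = 1e-12)
})

test_that("origin scoring skips missing sites and enforces the CpG minimum", {
  panel <- reference_panel(c(1L, 3L), c(0.9, 0.9), c(0.1, 0.1))
  profiles <- structure(list(
    list(molecule_id = "a", positions = c(1L, 2L, 3L), genome_pos = c(1L, 2L, 3L),
         states = c(1L, 1L, NA_integer_), n_cpg = 2L),
    list(molecule_id = "b", positions = 99L, genome_pos = 99L,
         states = 1L, n_cpg = 1L)),
    class = "methylation_profiles")
  sc <- molecule_origin_score(profiles, panel, min_cpg = 1L)
  expect_equal(nrow(sc$molecules), 1L)          # molecule b: all sites missing
  expect_equal(sc$n_excluded, 1L)
  expect_equal(sc$n_sites_missing, 2L)          # site 2 of a, site 99 of b
  expect_equal(sc$molecules$n_used, 1L)         # only site 1 of molecule a scored
})

test_that("sample-level origin scores separate two synthetic populations", {
  set.seed(310)
  sites <- 1:40
  panel <- reference_panel(sites, p_a = rep(0.8, 40), p_b = rep(0.2, 40))
  draw_sample <- function(p_tumor_like) {
    profiles <- lapply(1:50, function(i) {
      n <- sample(3:8, 1)
      s <- sort(sample(sites, n))
      p <- if (runif(1) < p_tumor_like) 0.8 else 0.2
      list(molecule_id = sprintf("m%d", i), positions = s, genome_pos = s,
           states = rbinom(n, 1, p), n_cpg = n)
    })
    molecule_origin_score(structure(profiles, class = "methylation_profiles"),
                          panel)$sample_score
  }
  cases <- replicate(12, draw_sample(0.5))
  controls <- replicate(12, draw_sample(0.1))
  expect_gte(roc_auc(c(cases, controls), rep(1:0, each = 12)), 0.95)
})
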