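test_that("identical configurations give byte-identical fixtures", {
  cfg <- sim_config(n_molecules = 6, length = 150, depth = 5,
                    placement = list(rule = "cpg", p = 0.5), seed = 99)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_molecules(simulate_dataset(cfg)$molecules, f1)
  write_molecules(simulate_dataset(cfg)$molecules, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the output
  cfg$seed <- 100L
  f3 <- withr::local_tempfile()
  write_molecules(simulate_dataset(cfg)$molecules, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("a unit footprint leaves 6mA and uA kinetics indistinguishable", {
  null_eff <- modification_effect("6mA", ipd_center = 1, pw_center = 1)
  sim <- simulate_dataset(sim_config(
    n_molecules = 30, length = 400, depth = 10,
    effects = list(`6mA` = null_eff),
    placement = list(rule = "all_a", p = 0.5, strands = "watson"), seed = 21))
  tk <- paste(sim$truth$molecule_id, sim$truth$position)
  mod <- c(); un <- c()
  for (m in sim$molecules) {
    a <- which(m$chars == "A") - 1L
    is_m <- paste(m$molecule_id, a) %in% tk
    mod <- c(mod, m$ipd_w[a[is_m] + 1])
    un <- c(un, m$ipd_w[a[!is_m] + 1])
  }
  ks <- suppressWarnings(stats::ks.test(sample(mod, 1000), sample(un, 1000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted 6mA footprint reproduces the modified/unmodified median IPD ratio", {
  sim <- simulate_dataset(sim_config(
    n_molecules = 150, length = 500, depth = 40,
    placement = list(rule = "all_a", p = 0.03, strands = "watson"), seed = 11))
  mod <- c(); un <- c()
  for (m in sim$molecules) {
    tp <- sim$truth$position[sim$truth$molecule_id == m$molecule_id]
    a <- which(m$chars == "A") - 1L
    near <- vapply(a, function(p) sum(abs(tp - p) <= 6), 0L)
    is_m <- a %in% tp
    mod <- c(mod, m$ipd_w[a[is_m & near == 1L] + 1])    # isolated modified
    un <- c(un, m$ipd_w[a[!is_m & near == 0L] + 1])     # away from any footprint
  }
  ratio <- median(mod) / median(un)
  expect_gt(ratio, 4.1 * 0.9)
  expect_lt(ratio, 4.1 * 1.1)
})

test_that("footprints are local: positions far from every truth site stay baseline", {
  sim <- simulate_dataset(sim_config(
    n_molecules = 40, length = 400, depth = 10,
    placement = list(rule = "all_a", p = 0.02, strands = "watson"), seed = 31))
  null <- simulate_dataset(sim_config(n_molecules = 40, length = 400, depth = 10,
                                      placement = list(rule = "none"), seed = 32))
  far <- c()
  for (m in sim$molecules) {
    tp <- sim$truth$position[sim$truth$molecule_id == m$molecule_id]
    a <- which(m$chars == "A") - 1L
    ok <- vapply(a, function(p) length(tp) == 0L || min(abs(tp - p)) > 10L, NA)
    far <- c(far, m$ipd_w[a[ok] + 1])
  }
  base <- unlist(lapply(null$molecules, function(m)
    m$ipd_w[which(m$chars == "A")]))
  ks <- suppressWarnings(stats::ks.test(sample(far, 1000), sample(base, 1000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("Dam placement methylates GATC adenines at the configured rates", {
  sim <- simulate_dam_genome(p_motif = 1, p_bg = 0, n_molecules = 20,
                             length = 400, depth = 2, seed = 5)
  for (m in sim$molecules[1:5]) {
    occ <- gregexpr("GATC", m$sequence, fixed = TRUE)[[1]]
    expected <- if (occ[1] == -1) integer(0) else sort(c(occ, occ + 1L))
    got <- sort(sim$truth$position[sim$truth$molecule_id == m$molecule_id])
    expect_equal(got, expected)   # A of GATC on both strands, exactly
  }
  sim2 <- simulate_dam_genome(p_motif = 0.95, p_bg = 0.01, n_molecules = 150,
                              length = 600, depth = 2, seed = 6)
  n_motif_sites <- 0L; n_bg_sites <- 0L; hit_motif <- 0L; hit_bg <- 0L
  for (m in sim2$molecules) {
    occ <- gregexpr("GATC", m$sequence, fixed = TRUE)[[1]]
    motif_key <- if (occ[1] == -1) character(0) else
      c(paste(m$molecule_id, occ, "watson"), paste(m$molecule_id, occ + 1L, "crick"))
    a <- which(m$chars == "A") - 1L; t <- which(m$chars == "T") - 1L
    all_key <- c(paste(m$molecule_id, a, "watson"), paste(m$molecule_id, t, "crick"))
    truth_key <- paste(sim2$truth$molecule_id, sim2$truth$position, sim2$truth$strand)
    n_motif_sites <- n_motif_sites + length(motif_key)
    n_bg_sites <- n_bg_sites + length(all_key) - length(motif_key)
    hit_motif <- hit_motif + sum(motif_key %in% truth_key)
    hit_bg <- hit_bg + sum(setdiff(all_key, motif_key) %in% truth_key)
  }
  expect_equal(hit_motif / n_motif_sites, 0.95, tolerance = 0.05)
  expect_equal(hit_bg / n_bg_sites, 0.01, tolerance = 0.5)
})

test_that("jagged fill-in places 6mA exactly in the overhang complement", {
  sim <- simulate_jagged_library(jag = 5L, ends = "right", n_molecules = 10,
                                 length = 120, depth = 3, seed = 2)
  for (m in sim$molecules) {
    tr <- sim$truth[sim$truth$molecule_id == m$molecule_id, ]
    a_tail <- which(m$chars == "A") - 1L
    a_tail <- a_tail[a_tail >= 120 - 5]
    expect_setequal(tr$position, a_tail)   # every A in the filled 5 nt, only there
    if (nrow(tr) > 0) expect_true(all(tr$strand == "watson"))
  }
  expect_true(all(sim$jags$jag_right == 5L))
  # left-end overhangs are filled on the Crick strand (Watson T positions)
  siml <- simulate_jagged_library(jag = 4L, ends = "left", n_molecules = 10,
                                  length = 120, depth = 3, seed = 3)
  expect_true(all(siml$truth$strand == "crick"))
  expect_true(all(siml$truth$position < 4L))
  # zero jag length: no 6mA anywhere
  sim0 <- simulate_jagged_library(jag = 0L, ends = "both", n_molecules = 10,
                                  length = 120, depth = 3, seed = 4)
  expect_equal(nrow(sim0$truth), 0L)
  # jag lengths follow the configured distribution
  simu <- simulate_jagged_library(jag = c(2L, 10L), n_molecules = 150,
                                  length = 120, depth = 2, seed = 5)
  expect_equal(mean(c(simu$jags$jag_left, simu$jags$jag_right)), 6, tolerance = 0.1)
})

test_that("accessibility placement is flat at zero amplitude and validates its config", {
  sim <- simulate_accessibility_track(amplitude = 0, base = 0.2, n_molecules = 80,
                                      length = 300, depth = 2, seed = 8)
  offs <- c(); hit <- c()
  for (m in sim$molecules) {
    tp <- sim$truth$position[sim$truth$molecule_id == m$molecule_id]
    a <- which(m$chars == "A") - 1L
    g <- m$start + a
    d <- vapply(g, function(x) min(abs(sim$anchors - x)), 0)
    offs <- c(offs, d)
    hit <- c(hit, a %in% tp)
  }
  near <- mean(hit[offs < 300]); far <- mean(hit[offs > 600])
  expect_equal(near, far, tolerance = 0.25)   # no distance structure
  expect_lt(abs(mean(hit) - 0.2), 0.03)
  expect_error(simulate_accessibility_track(amplitude = 0.9, base = 0.2),
               "base \\+ amplitude")
  expect_error(sim_config(placement = list(rule = "periodic", base = 0.1,
                                           amplitude = 0.2, period = -5)),
               "period")
  expect_error(sim_config(placement = list(rule = "cpg", p = 1.2)), "probabilities")
})
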