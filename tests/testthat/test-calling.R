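test_that("5mC calling labels a strongly methylated molecule at the cutoff", {
  model <- tiny_5mC_model()
  sim_pos <- simulate_dataset(sim_config(n_molecules = 3, length = 300,
                                         cpg_rate = 0.03, depth = 20,
                                         placement = list(rule = "cpg", p = 1),
                                         seed = 201))
  sim_neg <- simulate_dataset(sim_config(n_molecules = 3, length = 300,
                                         cpg_rate = 0.03, depth = 20,
                                         placement = list(rule = "none"),
                                         seed = 202))
  cfg <- call_config(width = 11L)
  pos_calls <- do.call(rbind, lapply(sim_pos$molecules, call_5mC, model, cfg))
  neg_calls <- do.call(rbind, lapply(sim_neg$molecules, call_5mC, model, cfg))
  expect_gt(mean(pos_calls$label == "modified"), 0.85)
  expect_gt(mean(neg_calls$label == "unmodified"), 0.85)
  expect_true(all(pos_calls$label == ifelse(pos_calls$score > 0.5,
                                            "modified", "unmodified")))
})

test_that("molecules without CpGs give empty call sets", {
  model <- tiny_5mC_model()
  m <- flat_molecule(strrep("AT", 60))
  expect_equal(nrow(call_5mC(m, model, call_config(width = 11L))), 0L)
})

test_that("edge CpGs become no_call when adapters are off, and scores ignore the cutoff", {
  model <- tiny_5mC_model()
  set.seed(203)
  sq <- paste0("ATCGCG", paste(sample(c("A", "T", "G"), 60, TRUE), collapse = ""),
               "CG", paste(sample(c("A", "T", "G"), 30, TRUE), collapse = ""))
  m <- noisy_molecule(sq, depth = 10)
  cfg_off <- call_config(width = 11L, use_adapters = FALSE)
  calls <- call_5mC(m, model, cfg_off)
  expect_true(all(calls$label[calls$position <= 4] == "no_call"))
  expect_true(all(is.na(calls$score[calls$label == "no_call"])))
  # changing the cutoff changes labels monotonically but never the scores
  c30 <- call_5mC(m, model, call_config(cutoff = 0.3, width = 11L))
  c70 <- call_5mC(m, model, call_config(cutoff = 0.7, width = 11L))
  expect_equal(c30$score, c70$score)
  expect_true(all(!(c30$label == "unmodified" & c70$label == "modified")))
})

test_that("duplex calling on a zero-depth strand degrades to no_call with a notice", {
  model <- tiny_5mC_model()
  set.seed(204)
  m <- noisy_molecule(paste0(strrep("AT", 30), "CG", strrep("TA", 30)), depth = 5)
  m$depth_c <- 0L
  expect_message(calls <- call_5mC(m, model, call_config(width = 11L)),
                 "zero subread depth")
  expect_true(all(calls$label == "no_call"))
})

test_that("two-stage gating follows the score rules", {
  expect_equal(smrtcall:::two_stage_label(0.2, NA, 0.5), "uC")   # gate wins
  expect_equal(smrtcall:::two_stage_label(0.9, 0.8, 0.5), "5hmC")
  expect_equal(smrtcall:::two_stage_label(0.9, 0.3, 0.5), "5mC")
  expect_equal(smrtcall:::two_stage_label(0.5, 0.9, 0.5), "uC")  # boundary: <= cutoff
})

test_that("iterative 6mA confounder masking calls the planted site deterministically", {
  model <- tiny_6mA_model()
  # one isolated 6mA (full kinetic footprint) in an unmodified molecule
  sim <- simulate_dataset(sim_config(n_molecules = 1, length = 200, depth = 20,
                                     placement = list(rule = "none"), seed = 205))
  m <- sim$molecules[[1]]
  a <- which(m$chars == "A") - 1L
  tgt <- a[which.min(abs(a - 100))]
  eff <- modification_effect("6mA")
  idx <- tgt + eff$offsets + 1L
  keep <- idx >= 1L & idx <= 200L
  m$ipd_w[idx[keep]] <- m$ipd_w[idx[keep]] * eff$ipd_factor[keep]
  m$pw_w[idx[keep]] <- m$pw_w[idx[keep]] * eff$pw_factor[keep]
  cfg3 <- call_config(strand_mode = "watson", width = 11L, max_6mA_iterations = 3L)
  c3 <- call_6mA_iterative(m, model, cfg3)
  expect_equal(c3$label[c3$position == tgt], "modified")
  # labels always agree with scores at the cutoff, and reruns are identical
  expect_equal(c3$label, ifelse(c3$score > 0.5, "modified", "unmodified"))
  expect_identical(c3, call_6mA_iterative(m, model, cfg3))
  # no adenines on the called strand -> empty call set
  m2 <- flat_molecule(strrep("TG", 60))
  expect_equal(nrow(call_6mA_iterative(m2, model,
                                       call_config(strand_mode = "watson", width = 11L))), 0L)
  expect_error(call_6mA_iterative(m, model, call_config(width = 11L)),
               "strand-specific")
})

test_that("region levels follow call arithmetic and recombine additively", {
  calls <- data.frame(
    molecule_id = "m1", position = 0:24, strand_mode = "watson", mod_type = "6mA",
    score = 0.9, label = c(rep("modified", 19), "unmodified", rep("no_call", 5)),
    depth = 5L, chrom = "c1", genome_pos = 100:124, stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "c1", start = c(100, 100, 110, 200),
                        end = c(125, 110, 125, 300),
                        name = c("all", "left", "right", "empty"))
  lv <- region_level(calls, regions)
  expect_equal(lv$level[1], 0.95)                       # 19 of 20 labelled
  expect_true(is.na(lv$level[4]))                       # uncovered: missing, not 0
  # weighted recombination of the two halves equals the whole
  n <- lv$n_modified + lv$n_unmodified
  expect_equal((lv$level[2] * n[2] + lv$level[3] * n[3]) / (n[2] + n[3]),
               lv$level[1])
  # a region covering only no_call sites is missing
  lv2 <- region_level(calls, data.frame(chrom = "c1", start = 120, end = 125))
  expect_true(is.na(lv2$level))
  expect_error(region_level(calls, local({
    f <- tempfile(); writeLines("c1\tx\t10", f); f
  })), "line 1")
})

test_that("molecule profiles partition labelled calls and drop empty molecules", {
  calls <- data.frame(
    molecule_id = rep(c("a", "b", "c"), times = c(3, 2, 2)),
    position = c(5L, 1L, 9L, 4L, 8L, 1L, 2L),
    strand_mode = "duplex", mod_type = "5mC", score = 0.5,
    label = c("modified", "unmodified", "modified", "no_call", "modified",
              "no_call", "no_call"),
    depth = 3L, chrom = NA_character_, genome_pos = NA_integer_,
    stringsAsFactors = FALSE)
  expect_message(pr <- molecule_profiles(calls), "all sites no_call")
  expect_length(pr, 2L)
  a <- pr[[1]]
  expect_equal(a$positions, c(1L, 5L, 9L))              # ordered by position
  expect_equal(a$states, c(0L, 1L, 1L))
  expect_equal(a$n_cpg, 3L)
  # conservation: total n_cpg equals the number of labelled calls
  expect_equal(sum(vapply(pr, `[[`, 0L, "n_cpg")),
               sum(calls$label %in% c("modified", "unmodified")))
})
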