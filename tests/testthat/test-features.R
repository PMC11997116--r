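test_that("edge windows are padded from adapters and flagged, else no-call", {
  set.seed(2)
  sq <- paste0("ATCCG", paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = ""),
               "CGTTA")
  m <- noisy_molecule(sq)
  w <- extract_window(m, 3L, "5mC", 21L, "duplex", use_adapters = TRUE)
  expect_true(w$valid)
  expect_equal(sum(w$matrix[, "adapter"]), 7)       # 10 - 3 rows come from the flank
  expect_equal(unname(w$matrix[1, "relpos"]), -1)
  expect_equal(unname(w$matrix[11, "relpos"]), 0)
  # without adapters the same site is a no-call (the no-call region)
  w0 <- extract_window(m, 3L, "5mC", 21L, "duplex", use_adapters = FALSE)
  expect_false(w0$valid)
  expect_null(w0$matrix)
  # an interior site needs no padding
  wmid <- extract_window(m, 50L, "6mA", 21L, "watson", use_adapters = FALSE,
                         check_base = FALSE)
  expect_true(wmid$valid)
  expect_equal(sum(wmid$matrix[, "adapter"]), 0)
  # one-hot columns sum to 1 on every row
  expect_true(all(rowSums(wmid$matrix[, c("A", "C", "G", "T")]) == 1))
  expect_error(extract_window(m, 200L, "5mC"), "out of range")
  expect_error(extract_window(m, 1L, "5mC"), "not the C of a CpG")
})

test_that("median50 normalization matches hand-computed values and clamps extremes", {
  sq <- strrep("A", 101)
  m <- flat_molecule(sq, value = 0.4, adapters = FALSE)
  w <- normalize_median50(extract_window(m, 50L, "6mA", 21L, "watson"), m)
  expect_true(all(abs(w$matrix[, "ipd"] - 1) < 1e-12))  # x / median(x) on a constant
  m2 <- flat_molecule(sq, value = 0.2, adapters = FALSE)
  m2$ipd_w[51] <- 0.8                                   # target stands out
  w2 <- normalize_median50(extract_window(m2, 50L, "6mA", 21L, "watson"), m2)
  expect_equal(unname(w2$matrix[11, "ipd"]), 4)         # 0.8 / median 0.2
  # epsilon floor + extreme-value cap
  m3 <- flat_molecule(sq, value = 0, adapters = FALSE)
  m3$ipd_w[51] <- 0.3
  expect_message(
    w3 <- suppressWarnings(
      normalize_median50(extract_window(m3, 50L, "6mA", 21L, "watson"), m3,
                         norm_spec("median50", epsilon = 1e-3))),
    "epsilon")
  expect_equal(unname(w3$matrix[11, "ipd"]), 10)        # 300 clamped to 10
  # all-zero channel -> zeros with a warning
  expect_warning(
    w4 <- suppressMessages(
      normalize_median50(extract_window(m3, 50L, "6mA", 21L, "watson"), m3,
                         norm_spec("median50"))),
    "all-zero")
  expect_true(all(w4$matrix[, "pw"] == 0))
})

test_that("thymine-median normalization divides by same-strand thymines and masks confounders", {
  sq <- paste(rep(c("T", "A"), 60), collapse = "")
  m <- flat_molecule(sq, value = 0.2, adapters = FALSE)
  m$ipd_w[62] <- 0.8     # adenine at 0-based position 61
  w <- normalize_by_thymine(extract_window(m, 61L, "6mA", 21L, "watson"), m,
                            norm_spec("thymine-median", confounder_positions = 63L))
  expect_equal(unname(w$matrix[11, "ipd"]), 4)     # 0.8 over thymine median 0.2
  expect_equal(unname(w$matrix[13, "ipd"]), 1)     # confounder masked to exactly 1
  expect_equal(unname(w$matrix[13, "pw"]), 1)
  expect_identical(unname(w$matrix[13, "ipd"]), 1) # exact, not approximate
  # IPD and PW divisors are computed separately
  m2 <- flat_molecule(sq, value = 0.2, adapters = FALSE)
  m2$pw_w <- rep(0.5, nchar(sq))
  m2$ipd_w[62] <- 0.8; m2$pw_w[62] <- 1.0
  w2 <- normalize_by_thymine(extract_window(m2, 61L, "6mA", 21L, "watson"), m2)
  expect_equal(unname(w2$matrix[11, "ipd"]), 4)
  expect_equal(unname(w2$matrix[11, "pw"]), 2)
  # no thymine in the molecule at all -> error
  m3 <- flat_molecule(strrep("A", 101), adapters = FALSE)
  expect_error(normalize_by_thymine(extract_window(m3, 50L, "6mA", 21L, "watson"), m3),
               "no thymine")
})

test_that("normalized windows are invariant to the molecule-wide kinetic scale", {
  set.seed(5)
  sq <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  m <- noisy_molecule(sq)
  a_pos <- which(m$chars == "A") - 1L
  p <- a_pos[a_pos > 30 & a_pos < 90][1]
  scaled <- m
  for (f in c("ipd_w", "pw_w", "ipd_c", "pw_c")) {
    scaled[[f]] <- 3.7 * scaled[[f]]
    scaled$adapter_left[[f]] <- 3.7 * scaled$adapter_left[[f]]
    scaled$adapter_right[[f]] <- 3.7 * scaled$adapter_right[[f]]
  }
  for (spec in list(norm_spec("median50"), norm_spec("thymine-median"))) {
    w1 <- normalize_window(extract_window(m, p, "6mA", 21L, "watson"), m, spec)
    w2 <- normalize_window(extract_window(scaled, p, "6mA", 21L, "watson"), scaled, spec)
    expect_equal(w1$matrix, w2$matrix, tolerance = 1e-12)
  }
})

test_that("callable sites cover every target with adapters and shrink without", {
  set.seed(6)
  sq <- paste0("CGT", paste(sample(c("A", "T", "G"), 44, TRUE), collapse = ""),
               "CG", paste(sample(c("A", "T", "G"), 46, TRUE), collapse = ""), "ACGTT")
  m <- noisy_molecule(sq)   # CpG cytosines at 0, 47 and 96 (length 100)
  expect_equal(target_sites(m, "5mC", "duplex"), c(0L, 47L, 96L))
  expect_equal(callable_sites(m, "5mC", 21L, "duplex", use_adapters = TRUE),
               c(0L, 47L, 96L))                       # 100% callable
  expect_equal(callable_sites(m, "5mC", 21L, "duplex", use_adapters = FALSE), 47L)
  m_no_cpg <- flat_molecule(strrep("AT", 40), adapters = FALSE)
  expect_length(callable_sites(m_no_cpg, "5mC"), 0L)
  # crick-strand cytosine of the CpG sits one position downstream
  expect_equal(target_sites(m, "5mC", "crick"), c(1L, 48L, 97L))
})

test_that("windows support the width sweep used for the plateau analysis", {
  set.seed(9)
  m <- noisy_molecule(paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""))
  p <- (which(m$chars == "A") - 1L)
  p <- p[p > 60 & p < 90][1]
  for (wd in c(5L, 11L, 21L, 31L, 41L)) {
    w <- normalize_window(extract_window(m, p, "6mA", wd, "watson"), m,
                          norm_spec("thymine-median", span = max(50L, wd)))
    expect_true(w$valid)
    expect_equal(nrow(w$matrix), wd)
  }
})

test_that("duplex encoding aligns Crick kinetics base-paired in Watson coordinates", {
  set.seed(10)
  sq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  m <- noisy_molecule(sq)
  p <- 40L
  ww <- extract_window(m, p, "6mA", 21L, "watson", check_base = FALSE)
  wc <- extract_window(m, p, "6mA", 21L, "crick", check_base = FALSE)
  wd <- encode_duplex(ww, wc)
  direct <- extract_window(m, p, "6mA", 21L, "duplex", check_base = FALSE)
  expect_equal(wd$matrix, direct$matrix)
  # involution oracle: the crick channel re-extracted from the reverse
  # complement equals the original watson channel
  r <- rc_molecule(m)
  wr <- extract_window(r, nchar(sq) - 1L - p, "6mA", 21L, "duplex", check_base = FALSE)
  expect_equal(unname(wr$matrix[, "ipd_c"]), rev(unname(direct$matrix[, "ipd_w"])))
  # zero-depth strand: duplex extraction refuses and points at single-strand mode
  m0 <- m; m0$depth_c <- 0L
  expect_error(extract_window(m0, p, "6mA", 21L, "duplex", check_base = FALSE),
               "single-strand")
  expect_error(encode_duplex(ww, ww), "crick-mode")
})

test_that("window stacking validates layouts and rejects no-call windows", {
  set.seed(11)
  m <- noisy_molecule(paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
                      adapters = FALSE)
  p <- (which(m$chars == "A") - 1L)
  good <- extract_window(m, p[p > 20 & p < 60][1], "6mA", 21L, "watson")
  bad <- extract_window(m, p[p < 5][1], "6mA", 21L, "watson")
  expect_error(windows_to_array(list(good, bad)), "no-call")
  x <- windows_to_array(list(good, good))
  expect_equal(dim(x), c(2L, 21L, 8L))
  expect_equal(attr(x, "layout_id"), "single-v1")
  wd <- extract_window(m, p[p > 20 & p < 60][1], "6mA", 21L, "duplex",
                       check_base = FALSE)
  expect_error(windows_to_array(list(good, wd)), "mix layouts")
})
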