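# Downstream applications of per-molecule modification calls: jagged-end
# profiling of cfDNA, nucleosome periodicity around anchor sites, de novo
# 6mA motif enrichment, and reference-panel molecule-origin scoring.

#' 6mA level as a function of distance from the 3' end
#'
#' End repair of a 5' protruding (jagged) cfDNA end incorporates 6mA into
#' the 3' end of the opposite strand, so the 6mA level rises near 3' ends.
#' For every strand of every molecule, each labelled adenine call is binned
#' by its distance from that strand's 3' end (Watson: the last position;
#' Crick: Watson position 0), and the 6mA level per distance is
#' `modified / (modified + unmodified)` pooled over molecules.
#'
#' @param calls Strand-specific 6mA calls.
#' @param molecules The molecules the calls came from (for lengths).
#' @param D Maximum distance from the 3' end (default 30).
#' @return Data frame of class `"end_profile"`: `distance` (0..D), `level`
#'   (`NA` where no adenine was called at that distance) and `n`.
#' @export
jagged_end_profile <- function(calls, molecules, D = 30L) {
  lens <- stats::setNames(vapply(molecules, function(m) nchar(m$sequence), 0L),
                          vapply(molecules, `[[`, "", "molecule_id"))
  calls <- calls[calls$label %in% c("modified", "unmodified"), , drop = FALSE]
  if (any(!calls$molecule_id %in% names(lens)))
    stop("calls reference molecules not in the supplied list")
  L <- lens[calls$molecule_id]
  d <- ifelse(calls$strand_mode == "watson", L - 1L - calls$position, calls$position)
  keep <- d >= 0L & d <= D
  d <- d[keep]
  mod <- calls$label[keep] == "modified"
  out <- data.frame(distance = 0:D, level = NA_real_, n = 0L)
  if (length(d) > 0L) {
    tot <- table(factor(d, levels = 0:D))
    hit <- table(factor(d[mod], levels = 0:D))
    out$n <- as.integer(tot)
    out$level <- ifelse(out$n > 0L, as.integer(hit) / as.integer(tot), NA_real_)
  }
  class(out) <- c("end_profile", "data.frame")
  out
}

# index of the first local maximum of v whose value clears `floor`
# (sub-threshold wiggles in the autocorrelation are noise, not periods)
first_local_max <- function(v, floor = -Inf) {
  n <- length(v)
  if (n < 3L) return(NA_integer_)
  for (i in 2:(n - 1L))
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L] && v[i] > floor) return(i)
  NA_integer_
}

#' Periodicity of 6mA levels around anchor sites
#'
#' Bins the 6mA level by signed offset from the nearest anchor and
#' estimates the dominant period of the offset profile: the lag of the
#' first non-zero-lag local maximum of the mean-subtracted autocorrelation
#' (`method = "acf"`, default) or the inverse of the peak periodogram
#' frequency (`method = "spectrum"`). A period is reported as missing when
#' fewer than 3 bins are covered or no autocorrelation peak clears a
#' white-noise floor (normal quantile at level 0.01 Bonferroni-adjusted
#' over the tested lags, scaled by `1 / sqrt(n_bins)`).
#'
#' @param calls 6mA calls carrying reference coordinates (`genome_pos`).
#' @param anchors Integer vector of anchor positions (same coordinates).
#' @param span Half-width of the offset range in bp (default 1000).
#' @param bin Offset bin width in bp (default 10).
#' @param method Period estimator, `"acf"` or `"spectrum"`.
#' @return List of class `"anchor_profile"`: `profile` (data frame
#'   `offset`, `level`, `n`), `estimated_period` (bp, or `NA`), `method`.
#' @export
anchor_periodicity <- function(calls, anchors, span = 1000L, bin = 10L,
                               method = c("acf", "spectrum")) {
  method <- match.arg(method)
  calls <- calls[calls$label %in% c("modified", "unmodified") &
                   !is.na(calls$genome_pos), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no labelled calls with reference coordinates")
  off <- vapply(calls$genome_pos, function(g) g - anchors[which.min(abs(anchors - g))], 0)
  keep <- abs(off) <= span
  off <- off[keep]
  mod <- calls$label[keep] == "modified"
  br <- seq(-span - bin / 2, span + bin / 2, by = bin)
  centers <- (head(br, -1) + tail(br, -1)) / 2
  f <- cut(off, breaks = br, include.lowest = TRUE)
  n <- as.integer(table(f))
  hit <- as.integer(table(f[mod]))
  level <- ifelse(n > 0L, hit / n, NA_real_)
  profile <- data.frame(offset = centers, level = level, n = n)
  covered <- sum(n > 0L)
  period <- NA_real_
  if (covered >= 3L) {
    v <- level
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v <- v - mean(v)
    if (method == "acf") {
      lag_max <- floor(length(v) / 2)
      ac <- as.numeric(acf(v, lag.max = lag_max, plot = FALSE,
                           demean = FALSE)$acf)
      noise_floor <- stats::qnorm(1 - 0.01 / lag_max) / sqrt(length(v))
      lag <- first_local_max(ac, floor = noise_floor) - 1L  # acf[1] is lag 0
      if (!is.na(lag) && lag >= 1L) period <- lag * bin
    } else {
      sp <- spec.pgram(v, plot = FALSE, detrend = FALSE, taper = 0)
      pk <- which.max(sp$spec)
      if (sp$spec[pk] > 4 * mean(sp$spec)) period <- bin / sp$freq[pk]
    }
  }
  structure(list(profile = profile, estimated_period = period, method = method),
            class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat(sprintf("<anchor_profile> %d bins; estimated period: %s\n",
              nrow(x$profile),
              if (is.na(x$estimated_period)) "none detected"
              else sprintf("%.0f bp (%s)", x$estimated_period, x$method)))
  invisible(x)
}

iupac_merge <- function(words) {
  m <- do.call(rbind, strsplit(words, ""))
  code <- c(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R", AT = "W",
            CG = "S", CT = "Y", GT = "K", ACG = "V", ACT = "H", AGT = "D",
            CGT = "B", ACGT = "N")
  paste(apply(m, 2L, function(col) {
    code[[paste(sort(unique(col)), collapse = "")]]
  }), collapse = "")
}

#' De novo 6mA motif enrichment
#'
#' Exhaustive short-word enrichment: for every contiguous word of length
#' `k_range` and every gapped pair of 3-mers (gap lengths `gap_range`)
#' containing an adenine at a fixed index, computes the 6mA level at that
#' adenine across all of the word's occurrences among the called sites,
#' against the overall background adenine 6mA level. Sequence contexts of
#' Crick-strand calls are reverse-complemented, so both strands contribute
#' in motif orientation. Words are ranked by the upper-tail exact binomial
#' p-value of their level against the background (raw enrichment is
#' noise-dominated for rare words); the `enrichment` column is
#' `level / max(background, eps)`.
#' Top words whose single-mismatch neighbours of equal length and adenine
#' index have enrichment within 10% are merged into an IUPAC consensus.
#'
#' @param calls Labelled 6mA calls.
#' @param molecules Molecules providing the sequence context.
#' @param k_range Contiguous word lengths (default 4:6).
#' @param gapped Also score gapped 3-mer pairs (default TRUE).
#' @param gap_range Gap lengths for gapped pairs (default 4:10).
#' @param min_sites Minimum occurrences for a word to be reported.
#' @return Data frame of class `"motif_results"`, one row per word:
#'   `motif`, `a_index` (0-based adenine index), `n_sites`, `level`,
#'   `background_level`, `enrichment`, `p`, `consensus` -- sorted by `p`.
#' @export
motif_enrichment <- function(calls, molecules, k_range = 4:6, gapped = TRUE,
                             gap_range = 4:10, min_sites = 30L) {
  calls <- calls[calls$label %in% c("modified", "unmodified"), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no labelled adenine calls")
  half <- 16L
  seqs <- stats::setNames(vapply(molecules, `[[`, "", "sequence"),
                          vapply(molecules, `[[`, "", "molecule_id"))
  pad <- strrep("N", half)
  ctx <- character(nrow(calls))
  for (id in unique(calls$molecule_id)) {
    sel <- calls$molecule_id == id
    padded <- paste0(pad, seqs[[id]], pad)
    ctx[sel] <- substring(padded, calls$position[sel] + 1L,
                          calls$position[sel] + 2L * half + 1L)
  }
  cr <- calls$strand_mode == "crick"
  if (any(cr)) {
    rc_chr <- function(s) chartr("ACGTN", "TGCAN", vapply(
      strsplit(s, ""), function(x) paste(rev(x), collapse = ""), ""))
    ctx[cr] <- rc_chr(ctx[cr])
  }
  mod <- calls$label == "modified"
  bg <- mean(mod)
  center <- half + 1L
  keys <- list(); mods <- list(); k_i <- 1L
  add <- function(word, key_suffix) {
    ok <- !grepl("N", word, fixed = TRUE)
    if (!any(ok)) return()
    keys[[k_i]] <<- paste0(word[ok], key_suffix)
    mods[[k_i]] <<- mod[ok]
    k_i <<- k_i + 1L
  }
  for (k in k_range) for (j in 0:(k - 1L))
    add(substring(ctx, center - j, center - j + k - 1L), sprintf("\t%d", j))
  if (gapped) for (a in 0:2) for (g in gap_range) {
    left <- substring(ctx, center - a, center - a + 2L)
    right <- substring(ctx, center - a + 3L + g, center - a + 5L + g)
    add(paste0(left, "(N", g, ")", right), sprintf("\t%d", a))
  }
  key <- unlist(keys)
  modv <- unlist(mods)
  agg <- rowsum(cbind(hit = as.integer(modv), n = 1L), key)
  parts <- strsplit(rownames(agg), "\t", fixed = TRUE)
  res <- data.frame(motif = vapply(parts, `[[`, "", 1L),
                    a_index = as.integer(vapply(parts, `[[`, "", 2L)),
                    n_sites = as.integer(agg[, "n"]),
                    level = agg[, "hit"] / agg[, "n"],
                    stringsAsFactors = FALSE)
  res <- res[res$n_sites >= min_sites, , drop = FALSE]
  res$background_level <- bg
  res$enrichment <- res$level / max(bg, 1e-6)
  res$p <- stats::pbinom(res$level * res$n_sites - 1L, res$n_sites, bg,
                         lower.tail = FALSE)
  res <- res[order(res$p, -res$n_sites), , drop = FALSE]
  rownames(res) <- NULL
  # IUPAC consensus over single-mismatch neighbours with similar enrichment
  res$consensus <- res$motif
  top <- head(which(!grepl("(", res$motif, fixed = TRUE)), 50L)
  for (i in top) {
    w <- res$motif[i]
    cand <- res$motif[res$a_index == res$a_index[i] &
                        nchar(res$motif) == nchar(w) &
                        abs(res$enrichment - res$enrichment[i]) <=
                          0.1 * res$enrichment[i]]
    nb <- cand[vapply(cand, function(v)
      sum(strsplit(v, "")[[1L]] != strsplit(w, "")[[1L]]) == 1L, NA)]
    if (length(nb) > 0L) res$consensus[i] <- iupac_merge(c(w, nb))
  }
  class(res) <- c("motif_results", "data.frame")
  res
}

#' Reference methylation panel for molecule-origin scoring
#'
#' Per-CpG-site methylation probabilities under two origins (class A, e.g.
#' tumor-like, and class B, e.g. background tissue), keyed by site
#' coordinate. Probabilities are shrunk into `(pseudocount, 1 -
#' pseudocount)` so log-likelihood ratios stay finite.
#'
#' @param site Integer site keys (reference coordinates).
#' @param p_a,p_b Methylation probabilities per site under each class.
#' @param pseudocount Shrinkage bound (default 0.01).
#' @return Data frame of class `"reference_panel"`.
#' @export
reference_panel <- function(site, p_a, p_b, pseudocount = 0.01) {
  stopifnot(length(site) == length(p_a), length(p_a) == length(p_b),
            pseudocount > 0, pseudocount < 0.5)
  clamp <- function(p) pmin(pmax(p, pseudocount), 1 - pseudocount)
  structure(data.frame(site = as.integer(site), p_a = clamp(p_a), p_b = clamp(p_b)),
            class = c("reference_panel", "data.frame"))
}

#' Molecule-origin score from methylation profiles
#'
#' Compares each molecule's binary CpG methylation profile with the
#' per-site probabilities of two reference classes: the per-molecule score
#' is the logistic of the average per-CpG Bernoulli log-likelihood ratio
#' (class A over class B), so 0.5 is neutral and 1 favors class A. The
#' per-sample score is the mean over scored molecules. Sites absent from
#' the panel are skipped (and counted); molecules with fewer than
#' `min_cpg` scorable sites are excluded.
#'
#' @param profiles A [molecule_profiles()] result.
#' @param panel A [reference_panel()].
#' @param min_cpg Minimum scorable CpGs per molecule (default 1).
#' @return List with `molecules` (data frame `molecule_id`, `n_cpg`,
#'   `n_used`, `score`), `sample_score`, `n_excluded`, `n_sites_missing`.
#' @export
molecule_origin_score <- function(profiles, panel, min_cpg = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  llr_a <- log(panel$p_a / panel$p_b)
  llr_u <- log((1 - panel$p_a) / (1 - panel$p_b))
  missing_total <- 0L
  rows <- lapply(profiles, function(pr) {
    sites <- if (all(is.na(pr$genome_pos))) pr$positions else pr$genome_pos
    ok <- !is.na(pr$states)
    idx <- match(sites[ok], panel$site)
    miss <- is.na(idx)
    missing_total <<- missing_total + sum(miss)
    st <- pr$states[ok][!miss]
    idx <- idx[!miss]
    if (length(st) < min_cpg) return(NULL)
    llr <- mean(ifelse(st == 1L, llr_a[idx], llr_u[idx]))
    data.frame(molecule_id = pr$molecule_id, n_cpg = pr$n_cpg,
               n_used = length(st), score = plogis(llr),
               stringsAsFactors = FALSE)
  })
  kept <- do.call(rbind, rows)
  list(molecules = kept,
       sample_score = if (is.null(kept)) NA_real_ else mean(kept$score),
       n_excluded = length(profiles) - if (is.null(kept)) 0L else nrow(kept),
       n_sites_missing = missing_total)
}
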