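# Simulation-to-windows builders: turn simulated libraries into labelled,
# normalized window sets for training and evaluating scorers. These define
# the package's standard desk-scale experiments.

collect_windows <- function(sim, picks, mod_type, strand_mode, width,
                            spec_for = NULL, quota = Inf) {
  mols <- sim$molecules
  xs <- list(); ys <- list(); ds <- list()
  taken <- 0L
  for (r in seq_len(nrow(picks))) {
    if (taken >= quota) break
    mol <- mols[[picks$mol[r]]]
    p <- picks$position[r]
    w <- extract_window(mol, p, mod_type, width, strand_mode, use_adapters = TRUE)
    if (!w$valid) next
    spec <- if (is.null(spec_for)) norm_spec("median50") else spec_for(mol, p)
    w <- normalize_window(w, mol, spec)
    taken <- taken + 1L
    xs[[taken]] <- w$matrix
    ys[[taken]] <- picks$label[r]
    ds[[taken]] <- w$depth
  }
  if (taken == 0L) stop("no valid windows collected")
  ch <- ncol(xs[[1L]])
  x <- array(0, dim = c(taken, width, ch),
             dimnames = list(NULL, NULL, colnames(xs[[1L]])))
  for (i in seq_len(taken)) x[i, , ] <- xs[[i]]
  attr(x, "layout_id") <- attr(window_layout(strand_mode), "layout_id")
  list(x = x, y = unlist(ys), depth = unlist(ds))
}

cpg_picks <- function(sim, strand_mode = "duplex") {
  rows <- lapply(seq_along(sim$molecules), function(i) {
    pos <- target_sites(sim$molecules[[i]], "5mC", strand_mode)
    if (length(pos) == 0L) return(NULL)
    data.frame(mol = i, position = pos)
  })
  do.call(rbind, rows)
}

#' Simulate labelled CpG methylation windows
#'
#' The standard paired-library experiment: one fully methylated library
#' (every CpG carries the modification) and one fully unmethylated
#' library, both drawn from the same kinetic model, windowed at their CpG
#' cytosines and median50-normalized. `n_per_class` windows per class are
#' returned with binary labels.
#'
#' @param n_per_class Windows per class.
#' @param mod_type Modification planted in the positive library
#'   (`"5mC"` or `"5hmC"`).
#' @param depth Per-strand subread depth (scalar or `c(min, max)`).
#' @param seed Seed (two sub-seeds are derived for the two libraries).
#' @param width,strand_mode Window geometry.
#' @param molecule_length,cpg_rate,kinetics,effects Passed to [sim_config()].
#' @return List with `x` (feature array), `y` (labels, 1 = modified),
#'   `depth` (per-window subread depth).
#' @export
simulate_mC_windows <- function(n_per_class = 2000L, mod_type = "5mC", depth = 20L,
                                seed = 1L, width = 21L, strand_mode = "duplex",
                                molecule_length = 800L, cpg_rate = 0.03,
                                kinetics = kinetic_model(),
                                effects = NULL) {
  if (is.null(effects))
    effects <- stats::setNames(list(modification_effect(mod_type)), mod_type)
  n_mol <- ceiling(1.4 * n_per_class / (molecule_length * cpg_rate * 0.7))
  one <- function(p, sub_seed, label) {
    sim <- simulate_dataset(sim_config(
      n_molecules = n_mol, length = molecule_length, cpg_rate = cpg_rate,
      depth = depth, kinetics = kinetics, effects = effects,
      placement = list(rule = "cpg", p = p, mod_type = mod_type),
      seed = sub_seed))
    picks <- cpg_picks(sim, strand_mode)
    picks$label <- label
    collect_windows(sim, picks, mod_type, strand_mode, width, quota = n_per_class)
  }
  pos <- one(1, seed, 1L)
  neg <- one(0, seed + 1000003L, 0L)
  x <- array(0, dim = c(dim(pos$x)[1L] + dim(neg$x)[1L], width, dim(pos$x)[3L]),
             dimnames = dimnames(pos$x))
  x[seq_len(dim(pos$x)[1L]), , ] <- pos$x
  x[dim(pos$x)[1L] + seq_len(dim(neg$x)[1L]), , ] <- neg$x
  attr(x, "layout_id") <- attr(pos$x, "layout_id")
  list(x = x, y = c(pos$y, neg$y), depth = c(pos$depth, neg$depth))
}

#' Simulate three-class CpG windows (uC / 5mC / 5hmC)
#'
#' One library in which each CpG is independently assigned a class; used
#' to train and evaluate the two-stage 5hmC workflow. Returns the class
#' per window alongside the features.
#'
#' @param n_windows Total windows to collect.
#' @param class_probs Named class probabilities (uC, 5mC, 5hmC).
#' @inheritParams simulate_mC_windows
#' @return List with `x`, `class` (character vector), `depth`.
#' @export
simulate_cpg_class_windows <- function(n_windows = 3000L,
                                       class_probs = c(uC = 1 / 3, `5mC` = 1 / 3, `5hmC` = 1 / 3),
                                       depth = 20L, seed = 1L, width = 21L,
                                       strand_mode = "duplex",
                                       molecule_length = 800L, cpg_rate = 0.03,
                                       kinetics = kinetic_model(),
                                       effects = list(`5mC` = modification_effect("5mC"),
                                                      `5hmC` = modification_effect("5hmC"))) {
  n_mol <- ceiling(1.4 * n_windows / (molecule_length * cpg_rate * 0.7))
  sim <- simulate_dataset(sim_config(
    n_molecules = n_mol, length = molecule_length, cpg_rate = cpg_rate,
    depth = depth, kinetics = kinetics, effects = effects,
    placement = list(rule = "cpg_classes", class_probs = class_probs),
    seed = seed))
  truth_key <- paste(sim$truth$molecule_id, sim$truth$position)
  picks <- cpg_picks(sim, strand_mode)
  ids <- vapply(sim$molecules, `[[`, "", "molecule_id")
  m <- match(paste(ids[picks$mol], picks$position), truth_key)
  picks$label <- ifelse(is.na(m), "uC", sim$truth$mod_type[m])
  cw <- collect_windows(sim, picks, "5xC", strand_mode, width, quota = n_windows)
  list(x = cw$x, class = cw$y, depth = cw$depth)
}

#' Simulate labelled 6mA windows with confounder-masked normalization
#'
#' One library in which a fraction `p_modified` of the called strand's
#' adenines carry 6mA: positive windows are the true 6mA sites, negative
#' windows the remaining (unmodified) adenines of the same molecules, so
#' negatives include unmodified adenines lying inside the kinetic
#' footprint of a neighboring 6mA -- the confounded case the masking is
#' designed to resolve. During normalization every other true 6mA site
#' inside a window is declared a confounder and masked to 1 (training with
#' known truth). Windows are single-strand (Watson) and thymine-median
#' normalized; classes are trimmed to `n_per_class` each.
#'
#' @inheritParams simulate_mC_windows
#' @param p_modified Fraction of adenines modified in the library.
#' @return List with `x`, `y`, `depth`.
#' @export
simulate_6mA_windows <- function(n_per_class = 2000L, depth = 20L, seed = 1L,
                                 width = 21L, molecule_length = 800L,
                                 p_modified = 0.5, kinetics = kinetic_model()) {
  n_mol <- ceiling(2.6 * n_per_class / (molecule_length * 0.29))
  sim <- simulate_dataset(sim_config(
    n_molecules = n_mol, length = molecule_length, depth = depth,
    kinetics = kinetics,
    placement = list(rule = "all_a", p = p_modified, strands = "watson"),
    seed = seed))
  truth_by_mol <- split(sim$truth$position[sim$truth$strand == "watson"],
                        sim$truth$molecule_id[sim$truth$strand == "watson"])
  ids <- vapply(sim$molecules, `[[`, "", "molecule_id")
  picks <- do.call(rbind, lapply(seq_along(sim$molecules), function(i) {
    pos <- target_sites(sim$molecules[[i]], "6mA", "watson")
    if (length(pos) == 0L) return(NULL)
    data.frame(mol = i, position = pos,
               label = as.integer(pos %in% truth_by_mol[[ids[i]]]))
  }))
  # interleave so both classes fill up before any quota cut
  picks <- picks[order(stats::ave(seq_len(nrow(picks)), picks$label,
                                  FUN = seq_along)), ]
  spec_for <- function(mol, p) {
    norm_spec("thymine-median",
              confounder_positions = setdiff(truth_by_mol[[mol$molecule_id]], p))
  }
  cw <- collect_windows(sim, picks, "6mA", "watson", width, spec_for = spec_for,
                        quota = Inf)
  keep <- unlist(lapply(split(seq_along(cw$y), cw$y), head, n_per_class))
  x <- cw$x[keep, , , drop = FALSE]
  attr(x, "layout_id") <- attr(cw$x, "layout_id")
  list(x = x, y = cw$y[keep], depth = cw$depth[keep])
}

#' Simulate a library with CpGs at every distance from the fragment ends
#'
#' Plants CpG cytosines at alternating offsets 0-20 from the left end,
#' mirrored near the right end, plus one interior site, so that across the
#' library every end distance 0-21 is represented. Used to quantify the
#' no-call region at fragment ends and its rescue by adapter padding.
#'
#' @param n_molecules,length,depth,seed Passed to [sim_config()].
#' @return A `"sim_dataset"`.
#' @export
simulate_edge_cpg_library <- function(n_molecules = 500L, length = 120L,
                                      depth = 10L, seed = 1L) {
  edge_cpgs <- function(L) {
    o <- sample(0:1, 1L)
    sort(unique(c(seq(o, 20L, 2L), L %/% 2L, L - 2L - seq(o, 20L, 2L))))
  }
  simulate_dataset(sim_config(n_molecules = n_molecules, length = length,
                              depth = depth, cpg_positions = edge_cpgs,
                              placement = list(rule = "none"), seed = seed))
}

#' Callable fraction of CpG sites, overall and by end distance
#'
#' @param sim A `"sim_dataset"` (or list of molecules).
#' @param width Window width.
#' @param use_adapters Pad edge windows from the adapter flanks.
#' @return List with `percent` (callable CpGs as a percentage of all CpGs)
#'   and `by_distance` (data frame `distance` from the nearest fragment
#'   end, `n`, `fraction` callable).
#' @export
callable_cpg_summary <- function(sim, width = 21L, use_adapters = TRUE) {
  mols <- if (inherits(sim, "sim_dataset")) sim$molecules else sim
  dist_all <- integer(0); ok_all <- logical(0)
  for (m in mols) {
    pos <- target_sites(m, "5mC", "duplex")
    if (length(pos) == 0L) next
    callable <- pos %in% callable_sites(m, "5mC", width, "duplex", use_adapters)
    dist_all <- c(dist_all, pmin(pos, nchar(m$sequence) - 1L - pos))
    ok_all <- c(ok_all, callable)
  }
  by_d <- do.call(rbind, lapply(sort(unique(dist_all)), function(d) {
    sel <- dist_all == d
    data.frame(distance = d, n = sum(sel), fraction = mean(ok_all[sel]))
  }))
  list(percent = 100 * mean(ok_all), by_distance = by_d)
}

#' Mean thymine-median-normalized value at unmodified adenines
#'
#' The calibration experiment behind 6mA normalization: adenine and
#' thymine kinetics are drawn i.i.d. from one truncated-normal
#' distribution symmetric about its median (no modification, no per-pass
#' noise), every interior adenine is windowed and thymine-median
#' normalized, and the normalized target values are averaged. Under a
#' symmetric shared distribution the expected value is 1, up to the small
#' upward convexity bias of dividing by a finite-sample median.
#'
#' @param n_sites Number of adenine sites to average over.
#' @param seed Integer seed.
#' @param location,scale Parameters of the shared truncated-normal
#'   baseline.
#' @return List with `mean`, `n`, and the per-site values in `values`.
#' @export
normalized_uA_mean <- function(n_sites = 100000L, seed = 1L,
                               location = 0.5, scale = 0.1) {
  one <- rep(location, 4L); names(one) <- BASES
  sc <- rep(scale, 4L); names(sc) <- BASES
  km <- kinetic_model(family = "normal", ipd_location = one, ipd_scale = sc,
                      pw_location = one, pw_scale = sc, pass_noise_sd = 0)
  mol_len <- 1000L
  n_mol <- ceiling(1.15 * n_sites / (mol_len * 0.29))
  sim <- simulate_dataset(sim_config(n_molecules = n_mol, length = mol_len,
                                     depth = 10L, kinetics = km,
                                     placement = list(rule = "none"),
                                     adapters = FALSE, seed = seed))
  vals <- numeric(n_sites)
  taken <- 0L
  for (m in sim$molecules) {
    if (taken >= n_sites) break
    for (p in target_sites(m, "6mA", "watson")) {
      if (taken >= n_sites) break
      w <- extract_window(m, p, "6mA", 21L, "watson", use_adapters = FALSE)
      if (!w$valid) next
      w <- normalize_by_thymine(w, m, norm_spec("thymine-median"))
      taken <- taken + 1L
      vals[taken] <- unname(w$matrix[11L, "ipd"])
    }
  }
  vals <- vals[seq_len(taken)]
  list(mean = mean(vals), n = taken, values = vals)
}
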