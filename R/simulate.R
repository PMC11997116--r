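# Synthetic SMRT kinetics with ground truth. The generator reproduces the
# phenomenology the calling stack relies on: per-base-identity log-normal-like
# kinetic baselines (unmodified adenine and thymine identical), multiplicative
# modification footprints decaying over a few flanking nucleotides,
# per-strand subread depth with multiplicative per-pass noise (so aggregation
# accuracy grows with depth), adapter flanks with unmodified kinetics, and
# the placement rules behind each application: CpG methylation classes,
# WGA-style all-adenine 6mA, Dam GATC 6mA, jagged-end fill-in 6mA, and
# accessibility-driven periodic 6mA around anchor sites.

#' Default SMRT bell-style adapter sequence used by the simulator
#' @export
DEFAULT_ADAPTER <- "ATCTCTCTCTTTTCCTCCTCCTCCGTTGTTGTTGTTGAGAGAGAT"

#' Baseline kinetic distributions per base identity
#'
#' Location/scale parameters of the per-position baseline kinetic value for
#' each base identity, for IPD and PW separately, plus the magnitude of the
#' multiplicative per-pass noise. For the `"lognormal"` family location/scale
#' are meanlog/sdlog; for `"normal"` they are mean/sd (truncated at 0); for
#' `"uniform"` the range is `location +/- scale` (truncated at 0). Per-pass
#' values are the position baseline times `exp(N(0, pass_noise_sd^2))`, so
#' the aggregated value converges to the baseline as subread depth grows.
#'
#' Defaults give unmodified adenine and thymine identical IPD baselines with
#' median 0.22 (the scale of unmodified adenine kinetics used throughout).
#'
#' @param family `"lognormal"` (default), `"normal"` or `"uniform"`.
#' @param ipd_location,ipd_scale,pw_location,pw_scale Named numeric vectors
#'   over A/C/G/T.
#' @param pass_noise_sd Standard deviation (log scale) of per-pass
#'   multiplicative noise; must be positive or zero.
#' @return An object of class `"kinetic_model"`.
#' @export
kinetic_model <- function(family = c("lognormal", "normal", "uniform"),
                          ipd_location = log(c(A = 0.22, C = 0.26, G = 0.24, T = 0.22)),
                          ipd_scale = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          pw_location = log(c(A = 0.45, C = 0.50, G = 0.48, T = 0.45)),
                          pw_scale = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          pass_noise_sd = 0.6) {
  family <- match.arg(family)
  for (v in list(ipd_scale, pw_scale))
    if (any(v <= 0)) stop("kinetic_model: all scales must be > 0")
  if (pass_noise_sd < 0) stop("kinetic_model: pass_noise_sd must be >= 0")
  chk <- function(v) if (!all(BASES %in% names(v)))
    stop("kinetic_model: parameter vectors must be named over A/C/G/T")
  for (v in list(ipd_location, ipd_scale, pw_location, pw_scale)) chk(v)
  structure(list(family = family,
                 ipd_location = ipd_location[BASES], ipd_scale = ipd_scale[BASES],
                 pw_location = pw_location[BASES], pw_scale = pw_scale[BASES],
                 pass_noise_sd = pass_noise_sd),
            class = "kinetic_model")
}

# draw per-position baselines for a vector of base identities
draw_baseline <- function(bases, km, kind) {
  loc <- km[[paste0(kind, "_location")]][bases]
  sc <- km[[paste0(kind, "_scale")]][bases]
  n <- length(bases)
  switch(km$family,
         lognormal = rlnorm(n, loc, sc),
         normal = pmax(rnorm(n, loc, sc), 0),
         uniform = pmax(runif(n, loc - sc, loc + sc), 0))
}

#' Multiplicative kinetic footprint of one modification type
#'
#' A modified base slows the polymerase at the modified position and, to a
#' lesser degree, at flanking positions. The footprint is a map from offset
#' (in the modified strand's 5'->3' frame) to a multiplicative factor >= 1
#' applied to the baseline kinetic location; by default a Gaussian decay
#' around the modified base. Default central IPD factors: 6mA 4.1 (the
#' ratio of modified to unmodified adenine median IPD, 0.90/0.22), 5mC 1.6,
#' 5hmC 1.3; central PW factors 1.3/1.2/1.1.
#'
#' @param mod_type `"5mC"`, `"5hmC"` or `"6mA"`.
#' @param ipd_center,pw_center Central multiplicative factors (>= 1);
#'   defaults per `mod_type` as above.
#' @param decay_sd Gaussian decay scale of the footprint, in nt.
#' @param support Half-width of the footprint support; factors are exactly 1
#'   beyond `support` offsets (support must be <= 10 so the footprint stays
#'   inside one measurement window).
#' @param strand_scope `"template-strand-only"` (default): the footprint
#'   affects the kinetics of the strand carrying the modified base;
#'   `"both"`: both strands.
#' @return An object of class `"modification_effect"`.
#' @export
modification_effect <- function(mod_type = c("5mC", "5hmC", "6mA"),
                                ipd_center = NULL, pw_center = NULL,
                                decay_sd = 1.5, support = 5L,
                                strand_scope = c("template-strand-only", "both")) {
  mod_type <- match.arg(mod_type)
  strand_scope <- match.arg(strand_scope)
  defaults <- list(`5mC` = c(1.6, 1.2), `5hmC` = c(1.3, 1.1), `6mA` = c(4.1, 1.3))
  if (is.null(ipd_center)) ipd_center <- defaults[[mod_type]][1L]
  if (is.null(pw_center)) pw_center <- defaults[[mod_type]][2L]
  if (ipd_center < 1 || pw_center < 1)
    stop("modification_effect: footprint factors must be >= 1")
  if (support > 10L) stop("modification_effect: support must be <= 10")
  offs <- -support:support
  shape <- exp(-offs^2 / (2 * decay_sd^2))
  structure(list(mod_type = mod_type,
                 offsets = offs,
                 ipd_factor = 1 + (ipd_center - 1) * shape,
                 pw_factor = 1 + (pw_center - 1) * shape,
                 strand_scope = strand_scope),
            class = "modification_effect")
}

#' Simulator configuration
#'
#' @param n_molecules Number of molecules to generate.
#' @param length Molecule length: a scalar or `c(min, max)` for uniform
#'   integer draws.
#' @param gc GC content of the random background sequence.
#' @param cpg_rate Expected density of planted CpG dinucleotides (per nt).
#' @param cpg_positions Optional function `function(L)` returning the exact
#'   0-based positions of CpG cytosines to plant, overriding `cpg_rate`.
#' @param depth Per-strand subread depth: a scalar or `c(min, max)` for
#'   uniform integer draws per molecule per strand.
#' @param kinetics A [kinetic_model].
#' @param effects Named list of [modification_effect]s keyed by mod type;
#'   defaults provide all three modification types.
#' @param placement Modification placement rule, a list with element `rule`
#'   and rule parameters: `"none"`; `"cpg"` (`p`, `mod_type`): each CpG is
#'   symmetrically modified with probability `p`; `"cpg_classes"`
#'   (`class_probs` named over uC/5mC/5hmC): per-CpG class draw;
#'   `"all_a"` (`p`, `strands`): WGA-style 6mA on adenines; `"dam"`
#'   (`p_motif`, `p_bg`): GATC-adenine 6mA on both strands plus background;
#'   `"periodic"` (`base`, `amplitude`, `period`, `anchors`, `contig_len`):
#'   accessibility-driven 6mA with raised-cosine offset weighting around
#'   anchor sites; `"jagged"` (`jag`, `ends`): 5' overhang fill-in 6mA.
#' @param adapters Attach adapter flanks with unmodified baseline kinetics.
#' @param adapter_seq Adapter sequence (>= 10 nt).
#' @param aggregation Pass aggregation statistic, `"mean"` or `"median"`.
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_molecules = 100L, length = 400L, gc = 0.42,
                       cpg_rate = 0.02, cpg_positions = NULL,
                       depth = 20L, kinetics = kinetic_model(),
                       effects = list(`5mC` = modification_effect("5mC"),
                                      `5hmC` = modification_effect("5hmC"),
                                      `6mA` = modification_effect("6mA")),
                       placement = list(rule = "none"),
                       adapters = TRUE, adapter_seq = DEFAULT_ADAPTER,
                       aggregation = c("mean", "median"), seed = 1L) {
  aggregation <- match.arg(aggregation)
  stopifnot(n_molecules >= 1, all(length >= 50), gc > 0, gc < 1,
            cpg_rate >= 0, all(depth >= 0), nchar(adapter_seq) >= 10)
  probs <- unlist(placement[names(placement) %in%
                              c("p", "p_motif", "p_bg", "base", "amplitude")])
  if (any(probs < 0 | probs > 1))
    stop("sim_config: placement probabilities must lie in [0, 1]")
  if (identical(placement$rule, "periodic")) {
    if (is.null(placement$period) || placement$period <= 0)
      stop("sim_config: periodic placement needs period > 0")
    if (placement$base + placement$amplitude > 1)
      stop("sim_config: periodic placement needs base + amplitude <= 1")
  }
  structure(list(n_molecules = as.integer(n_molecules), length = length,
                 gc = gc, cpg_rate = cpg_rate, cpg_positions = cpg_positions,
                 depth = depth, kinetics = kinetics, effects = effects,
                 placement = placement, adapters = adapters,
                 adapter_seq = adapter_seq, aggregation = aggregation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_scalar <- function(spec) {
  if (length(spec) == 1L) return(as.integer(spec))
  as.integer(sample(spec[1L]:spec[2L], 1L))
}

gen_sequence <- function(L, gc, cpg_rate, cpg_positions = NULL) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(BASES, L, replace = TRUE, prob = p)
  cpg <- if (!is.null(cpg_positions)) cpg_positions(L) else {
    n_cpg <- rbinom(1L, max(L - 2L, 0L), cpg_rate)
    if (n_cpg > 0L) sort(sample(0:(L - 2L), min(n_cpg, L %/% 4L))) else integer(0)
  }
  cpg <- cpg[cpg >= 0 & cpg <= L - 2L]
  cpg <- cpg[c(TRUE, diff(cpg) >= 2L)]      # non-overlapping CG blocks
  if (length(cpg) > 0L) {
    s[cpg + 1L] <- "C"
    s[cpg + 2L] <- "G"
  }
  s
}

truth_row <- function(id, pos, strand, mod) {
  data.frame(molecule_id = id, position = as.integer(pos), strand = strand,
             mod_type = mod, stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(molecule_id = character(0), position = integer(0),
             strand = character(0), mod_type = character(0),
             stringsAsFactors = FALSE)
}

# watson A positions are adenines on Watson; crick adenines pair Watson T
a_sites <- function(s, strands = c("watson", "crick")) {
  out <- list()
  if ("watson" %in% strands)
    out$w <- data.frame(position = which(s == "A") - 1L, strand = "watson")
  if ("crick" %in% strands)
    out$c <- data.frame(position = which(s == "T") - 1L, strand = "crick")
  do.call(rbind, out)
}

cpg_c_positions <- function(s) which(s[-length(s)] == "C" & s[-1L] == "G") - 1L

place_modifications <- function(id, s, cfg, gstart) {
  pl <- cfg$placement
  L <- length(s)
  switch(pl$rule,
    none = empty_truth(),
    cpg = {
      cpos <- cpg_c_positions(s)
      hit <- cpos[runif(length(cpos)) < pl$p]
      mod <- if (is.null(pl$mod_type)) "5mC" else pl$mod_type
      if (length(hit) == 0L) return(empty_truth())
      rbind(truth_row(id, hit, "watson", mod),
            truth_row(id, hit + 1L, "crick", mod))
    },
    cpg_classes = {
      cpos <- cpg_c_positions(s)
      if (length(cpos) == 0L) return(empty_truth())
      cls <- sample(names(pl$class_probs), length(cpos), replace = TRUE,
                    prob = pl$class_probs)
      keep <- cls != "uC"
      if (!any(keep)) return(empty_truth())
      rbind(truth_row(id, cpos[keep], "watson", cls[keep]),
            truth_row(id, cpos[keep] + 1L, "crick", cls[keep]))
    },
    all_a = {
      p <- if (is.null(pl$p)) 1 else pl$p
      strands <- if (is.null(pl$strands)) c("watson", "crick") else pl$strands
      sites <- a_sites(s, strands)
      if (is.null(sites) || nrow(sites) == 0L) return(empty_truth())
      sites <- sites[runif(nrow(sites)) < p, , drop = FALSE]
      if (nrow(sites) == 0L) return(empty_truth())
      truth_row(id, sites$position, sites$strand, "6mA")
    },
    dam = {
      occ <- gregexpr("GATC", paste(s, collapse = ""), fixed = TRUE)[[1L]]
      motif <- if (occ[1L] == -1L)
        data.frame(position = integer(0), strand = character(0)) else
        rbind(data.frame(position = occ - 1L + 1L, strand = "watson"),
              data.frame(position = occ - 1L + 2L, strand = "crick"))
      all_a <- a_sites(s)
      key <- paste(all_a$position, all_a$strand)
      inmotif <- key %in% if (nrow(motif) > 0L) paste(motif$position, motif$strand) else character(0)
      p <- ifelse(inmotif, pl$p_motif, pl$p_bg)
      hit <- all_a[runif(nrow(all_a)) < p, , drop = FALSE]
      if (nrow(hit) == 0L) return(empty_truth())
      truth_row(id, hit$position, hit$strand, "6mA")
    },
    periodic = {
      sites <- a_sites(s)
      if (is.null(sites) || nrow(sites) == 0L) return(empty_truth())
      gpos <- gstart + sites$position
      d <- vapply(gpos, function(g) {
        i <- which.min(abs(pl$anchors - g))
        g - pl$anchors[i]
      }, 0)
      w <- (1 + cos(2 * pi * d / pl$period)) / 2
      p <- pmin(pmax(pl$base + pl$amplitude * w, 0), 1)
      hit <- sites[runif(nrow(sites)) < p, , drop = FALSE]
      if (nrow(hit) == 0L) return(empty_truth())
      truth_row(id, hit$position, hit$strand, "6mA")
    },
    jagged = {
      # handled in simulate_dataset (needs the per-end jag bookkeeping)
      empty_truth()
    },
    stop("unknown placement rule: ", pl$rule)
  )
}

apply_footprints <- function(base_w, base_c, truth, effects, kind) {
  L <- length(base_w)
  for (i in seq_len(nrow(truth))) {
    eff <- effects[[truth$mod_type[i]]]
    if (is.null(eff)) stop("no modification_effect configured for ", truth$mod_type[i])
    f <- eff[[paste0(kind, "_factor")]]
    p <- truth$position[i]
    # offsets are in the modified strand's 5'->3' frame: Watson-increasing
    # for watson-strand modifications, Watson-decreasing for crick
    if (truth$strand[i] == "watson") {
      idx <- p + eff$offsets + 1L
      keep <- idx >= 1L & idx <= L
      base_w[idx[keep]] <- base_w[idx[keep]] * f[keep]
      if (eff$strand_scope == "both") {
        idxc <- p - eff$offsets + 1L
        keep <- idxc >= 1L & idxc <= L
        base_c[idxc[keep]] <- base_c[idxc[keep]] * f[keep]
      }
    } else {
      idx <- p - eff$offsets + 1L
      keep <- idx >= 1L & idx <= L
      base_c[idx[keep]] <- base_c[idx[keep]] * f[keep]
      if (eff$strand_scope == "both") {
        idxw <- p + eff$offsets + 1L
        keep <- idxw >= 1L & idxw <= L
        base_w[idxw[keep]] <- base_w[idxw[keep]] * f[keep]
      }
    }
  }
  list(w = base_w, c = base_c)
}

agg_noise <- function(depth, L, sd, method) {
  if (depth == 0L) return(rep(0, L))
  if (sd == 0) return(rep(1, L))
  m <- matrix(exp(rnorm(depth * L, 0, sd)), nrow = depth)
  if (method == "mean") colMeans(m) else apply(m, 2L, median)
}

sim_adapter <- function(seq, km, depth_w, depth_c, method) {
  s <- seq_chars(seq)
  sc <- unname(COMPLEMENT[s])
  list(sequence = seq,
       ipd_w = draw_baseline(s, km, "ipd") * agg_noise(depth_w, length(s), km$pass_noise_sd, method),
       pw_w = draw_baseline(s, km, "pw") * agg_noise(depth_w, length(s), km$pass_noise_sd, method),
       ipd_c = draw_baseline(sc, km, "ipd") * agg_noise(depth_c, length(s), km$pass_noise_sd, method),
       pw_c = draw_baseline(sc, km, "pw") * agg_noise(depth_c, length(s), km$pass_noise_sd, method))
}

#' Simulate a library of molecules with ground-truth modifications
#'
#' Draws per-position kinetic baselines from the configured [kinetic_model]
#' by base identity, multiplies in the modification footprints at the
#' ground-truth sites placed by the configured rule, simulates per-strand
#' subread depth with multiplicative per-pass noise, aggregates passes onto
#' consensus coordinates, and attaches adapter flanks carrying unmodified
#' baseline kinetics. Output is byte-identical for identical configurations
#' (the seed is part of the configuration).
#'
#' @param config A [sim_config].
#' @return An object of class `"sim_dataset"`: a list with `molecules` (list
#'   of [molecule_kinetics]), `truth` (data frame `molecule_id`, `position`
#'   (0-based), `strand`, `mod_type`), plus rule-specific extras (`jags`,
#'   `anchors`) and the echoed `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  km <- config$kinetics
  pl <- config$placement
  molecules <- vector("list", config$n_molecules)
  truths <- vector("list", config$n_molecules)
  jags <- if (identical(pl$rule, "jagged")) vector("list", config$n_molecules) else NULL
  contig_len <- if (!is.null(pl$contig_len)) pl$contig_len else NULL
  for (i in seq_len(config$n_molecules)) {
    id <- sprintf("mol%05d", i)
    L <- draw_scalar(config$length)
    s <- gen_sequence(L, config$gc, config$cpg_rate, config$cpg_positions)
    gstart <- if (!is.null(contig_len)) sample.int(max(contig_len - L, 1L), 1L) - 1L else NA_integer_
    if (identical(pl$rule, "jagged")) {
      jag_of <- function() {
        for (try in 1:50) {
          J <- draw_scalar(pl$jag)
          if (J < L) return(J)
          message(sprintf("molecule %s: resampling jag length %d >= molecule length %d", id, J, L))
        }
        stop("jag length distribution incompatible with molecule length")
      }
      ends <- if (is.null(pl$ends)) "both" else pl$ends
      jl <- if (ends %in% c("both", "left")) jag_of() else 0L
      jr <- if (ends %in% c("both", "right")) jag_of() else 0L
      truth <- empty_truth()
      # left 5' Watson overhang: Crick fill-in covers Watson [0, jl), 6mA at
      # every Crick adenine (Watson T); right end symmetric on Watson
      if (jl > 0L) {
        pos <- which(s[seq_len(jl)] == "T") - 1L
        if (length(pos) > 0L) truth <- rbind(truth, truth_row(id, pos, "crick", "6mA"))
      }
      if (jr > 0L) {
        pos <- which(s[(L - jr + 1L):L] == "A") + (L - jr) - 1L
        if (length(pos) > 0L) truth <- rbind(truth, truth_row(id, pos, "watson", "6mA"))
      }
      jags[[i]] <- data.frame(molecule_id = id, jag_left = jl, jag_right = jr,
                              stringsAsFactors = FALSE)
    } else {
      truth <- place_modifications(id, s, config, gstart)
    }
    sc <- unname(COMPLEMENT[s])
    base <- list(
      ipd = apply_footprints(draw_baseline(s, km, "ipd"), draw_baseline(sc, km, "ipd"),
                             truth, config$effects, "ipd"),
      pw = apply_footprints(draw_baseline(s, km, "pw"), draw_baseline(sc, km, "pw"),
                            truth, config$effects, "pw"))
    dw <- draw_scalar(config$depth)
    dc <- draw_scalar(config$depth)
    mol <- molecule_kinetics(
      id, paste(s, collapse = ""),
      ipd_w = base$ipd$w * agg_noise(dw, L, km$pass_noise_sd, config$aggregation),
      pw_w = base$pw$w * agg_noise(dw, L, km$pass_noise_sd, config$aggregation),
      ipd_c = base$ipd$c * agg_noise(dc, L, km$pass_noise_sd, config$aggregation),
      pw_c = base$pw$c * agg_noise(dc, L, km$pass_noise_sd, config$aggregation),
      depth_w = dw, depth_c = dc,
      adapter_left = if (config$adapters)
        sim_adapter(config$adapter_seq, km, dw, dc, config$aggregation) else NULL,
      adapter_right = if (config$adapters)
        sim_adapter(config$adapter_seq, km, dw, dc, config$aggregation) else NULL,
      chrom = if (!is.null(contig_len)) "sim_contig" else NA_character_,
      start = gstart)
    molecules[[i]] <- mol
    truths[[i]] <- truth
  }
  out <- list(molecules = molecules,
              truth = do.call(rbind, c(truths, list(empty_truth()))),
              config = config)
  if (!is.null(jags)) out$jags <- do.call(rbind, jags)
  if (identical(pl$rule, "periodic")) out$anchors <- pl$anchors
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d molecules, %d ground-truth modification sites (%s placement)\n",
              length(x$molecules), nrow(x$truth), x$config$placement$rule))
  invisible(x)
}

#' Simulate a jagged-end cell-free DNA library
#'
#' Each duplex molecule receives a 5' single-stranded overhang whose
#' fill-in (the last `J` nt at the 3' end of the opposite strand) carries
#' 6mA at every adenine, emulating end repair in the presence of
#' N6-methyl-dATP. Ground truth records the jag length per molecule end.
#'
#' @param jag Jag length: scalar or `c(min, max)` uniform integer draw.
#' @param ends Which ends carry an overhang: `"both"`, `"left"`, `"right"`.
#' @param ... Passed to [sim_config()].
#' @return A `"sim_dataset"` with an extra `jags` data frame.
#' @export
simulate_jagged_library <- function(jag = c(2L, 10L), ends = "both", ...) {
  simulate_dataset(sim_config(placement = list(rule = "jagged", jag = jag, ends = ends), ...))
}

#' Simulate Dam-treated (GATC) adenine methylation
#'
#' Every GATC occurrence is methylated at its adenine on both strands with
#' probability `p_motif`; every other adenine with probability `p_bg`.
#'
#' @param p_motif,p_bg Methylation probabilities at motif and background
#'   adenines.
#' @param ... Passed to [sim_config()].
#' @return A `"sim_dataset"`.
#' @export
simulate_dam_genome <- function(p_motif = 0.95, p_bg = 0.01, ...) {
  simulate_dataset(sim_config(placement = list(rule = "dam", p_motif = p_motif,
                                               p_bg = p_bg), ...))
}

#' Simulate accessibility-driven periodic adenine methylation
#'
#' Molecules are placed on a virtual contig; the probability that an
#' adenine at signed distance `d` from its nearest anchor carries 6mA is
#' `base + amplitude * (1 + cos(2 * pi * d / period)) / 2`, clipped to
#' `[0, 1]` -- a raised-cosine accessibility profile emulating phased
#' nucleosome arrays around anchor sites.
#'
#' @param period Period in bp (default 180, the nucleosomal repeat scale).
#' @param amplitude,base Amplitude and floor of the methylation probability.
#' @param anchors Anchor positions on the virtual contig.
#' @param contig_len Length of the virtual contig molecules are drawn from.
#' @param ... Passed to [sim_config()].
#' @return A `"sim_dataset"` with an `anchors` element.
#' @export
simulate_accessibility_track <- function(period = 180, amplitude = 0.4, base = 0.05,
                                         anchors = c(5000L, 15000L), contig_len = 20000L,
                                         ...) {
  simulate_dataset(sim_config(placement = list(rule = "periodic", period = period,
                                               amplitude = amplitude, base = base,
                                               anchors = anchors, contig_len = contig_len),
                              ...))
}

#' Synthetic oracle calls from ground truth
#'
#' Converts simulator ground truth into a per-adenine-site call table by
#' applying a fixed sensitivity and false-positive rate, emulating a caller
#' at a chosen operating point without training a network. Used for
#' desk-scale testing of the downstream applications; scores are set to
#' 0.95 for modified labels and 0.05 otherwise.
#'
#' @param sim A `"sim_dataset"`.
#' @param sensitivity Probability a true modified site is labelled modified.
#' @param fpr Probability an unmodified site is labelled modified.
#' @param mod_type Modification type of the produced calls.
#' @param strands Strands to emit calls for.
#' @return A calls data frame (`molecule_id`, `position`, `strand_mode`,
#'   `mod_type`, `score`, `label`, `depth`, `chrom`, `genome_pos`).
#' @export
truth_to_calls <- function(sim, sensitivity = 0.96, fpr = 0.01,
                           mod_type = "6mA", strands = c("watson", "crick")) {
  truth_key <- paste(sim$truth$molecule_id, sim$truth$position, sim$truth$strand)
  out <- lapply(sim$molecules, function(m) {
    sites <- a_sites(m$chars, strands)
    if (is.null(sites) || nrow(sites) == 0L) return(NULL)
    is_mod <- paste(m$molecule_id, sites$position, sites$strand) %in% truth_key
    called <- ifelse(is_mod, runif(nrow(sites)) < sensitivity,
                     runif(nrow(sites)) < fpr)
    data.frame(molecule_id = m$molecule_id, position = sites$position,
               strand_mode = sites$strand, mod_type = mod_type,
               score = ifelse(called, 0.95, 0.05),
               label = ifelse(called, "modified", "unmodified"),
               depth = ifelse(sites$strand == "watson", m$depth_w, m$depth_c),
               chrom = m$chrom,
               genome_pos = if (is.na(m$start)) NA_integer_ else m$start + sites$position,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
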