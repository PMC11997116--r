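#' Calling configuration
#'
#' @param cutoff Modification-score cutoff in (0, 1) separating
#'   modified from unmodified labels (default 0.5).
#' @param strand_mode Window mode for calling: `"duplex"`, `"watson"` or
#'   `"crick"`.
#' @param use_adapters Pad edge windows from adapter kinetics so sites near
#'   fragment ends stay callable.
#' @param width Window width.
#' @param max_6mA_iterations Maximum rounds of iterative 6mA confounder
#'   masking.
#' @return An object of class `"call_config"`.
#' @export
call_config <- function(cutoff = 0.5, strand_mode = c("duplex", "watson", "crick"),
                        use_adapters = TRUE, width = 21L, max_6mA_iterations = 3L) {
  strand_mode <- match.arg(strand_mode)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  structure(list(cutoff = cutoff, strand_mode = strand_mode,
                 use_adapters = isTRUE(use_adapters), width = as.integer(width),
                 max_6mA_iterations = as.integer(max_6mA_iterations)),
            class = "call_config")
}

new_calls <- function(mol, positions, strand_mode, mod_type, score, label, extra = NULL) {
  if (length(positions) == 0L) {
    df <- data.frame(molecule_id = character(0), position = integer(0),
                     strand_mode = character(0), mod_type = character(0),
                     score = numeric(0), label = character(0), depth = integer(0),
                     chrom = character(0), genome_pos = integer(0),
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df, extra[0, , drop = FALSE])
    return(df)
  }
  df <- data.frame(
    molecule_id = rep(mol$molecule_id, length(positions)),
    position = as.integer(positions), strand_mode = strand_mode,
    mod_type = mod_type, score = score, label = label,
    depth = switch(strand_mode, duplex = min(mol$depth_w, mol$depth_c),
                   watson = mol$depth_w, crick = mol$depth_c),
    chrom = mol$chrom,
    genome_pos = if (is.na(mol$start)) NA_integer_ else mol$start + as.integer(positions),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

check_model_task <- function(model, mod_type, cfg) {
  if (!inherits(model, "smrt_scorer") || !model$trained)
    stop("a trained smrt_scorer is required")
  if (!is.na(model$config$mod_type) && model$config$mod_type != mod_type)
    stop(sprintf("model was trained for %s, not %s", model$config$mod_type, mod_type))
  if (model$config$strand_mode != cfg$strand_mode)
    stop(sprintf("model expects %s windows but the calling configuration asks for %s",
                 model$config$strand_mode, cfg$strand_mode))
  if (model$config$width != cfg$width)
    stop("model window width does not match the calling configuration")
}

strand_depth_ok <- function(mol, strand_mode) {
  switch(strand_mode,
         duplex = mol$depth_w > 0L && mol$depth_c > 0L,
         watson = mol$depth_w > 0L,
         crick = mol$depth_c > 0L)
}

# score the CpG cytosines of one molecule with a median50-normalized model;
# shared by 5mC calling and the first stage of the 5hmC workflow
score_cpg_sites <- function(mol, model, cfg, mod_type) {
  sites <- target_sites(mol, mod_type, cfg$strand_mode)
  if (length(sites) == 0L)
    return(list(sites = integer(0), valid = logical(0), scores = numeric(0)))
  wins <- lapply(sites, function(p) {
    w <- extract_window(mol, p, mod_type, cfg$width, cfg$strand_mode, cfg$use_adapters)
    if (w$valid) normalize_median50(w, mol, norm_spec("median50")) else w
  })
  valid <- vapply(wins, `[[`, NA, "valid")
  scores <- rep(NA_real_, length(sites))
  if (any(valid))
    scores[valid] <- predict(model, windows_to_array(wins[valid]))
  list(sites = sites, valid = valid, scores = scores)
}

#' Call 5mC at the CpG sites of a molecule
#'
#' Scores every callable CpG cytosine with a 5mC-trained scorer on
#' median50-normalized windows and labels sites by the score cutoff.
#' Uncallable sites (windows falling off an end without adapter padding, or
#' a zero-depth strand in duplex mode) are emitted as `no_call` records.
#'
#' @param mol A [molecule_kinetics].
#' @param model A trained [fit_scorer()] model for 5mC with matching
#'   strand mode.
#' @param cfg A [call_config()].
#' @param fallback_model Optional single-strand model used when one strand
#'   of a duplex molecule has zero depth (its strand mode picks the strand).
#' @return A calls data frame; see [write_calls()] for the columns.
#' @export
call_5mC <- function(mol, model, cfg = call_config(), fallback_model = NULL) {
  check_model_task(model, "5mC", cfg)
  if (!strand_depth_ok(mol, cfg$strand_mode)) {
    if (!is.null(fallback_model) &&
        strand_depth_ok(mol, fallback_model$config$strand_mode)) {
      message(sprintf("molecule '%s': zero-depth strand; degrading to %s-only calling",
                      mol$molecule_id, fallback_model$config$strand_mode))
      cfg2 <- cfg
      cfg2$strand_mode <- fallback_model$config$strand_mode
      return(call_5mC(mol, fallback_model, cfg2))
    }
    message(sprintf("molecule '%s': zero subread depth on a required strand; emitting no_call",
                    mol$molecule_id))
    sites <- target_sites(mol, "5mC", cfg$strand_mode)
    return(new_calls(mol, sites, cfg$strand_mode, "5mC", NA_real_, "no_call"))
  }
  sc <- score_cpg_sites(mol, model, cfg, "5mC")
  new_calls(mol, sc$sites, cfg$strand_mode, "5mC", sc$scores,
            ifelse(!sc$valid, "no_call",
                   ifelse(sc$scores > cfg$cutoff, "modified", "unmodified")))
}

#' Two-stage 5hmC resolution at CpG sites
#'
#' Stage 1 scores each CpG with a uC-versus-5xC model (5xC = any modified
#' cytosine); sites at or below the cutoff are called `uC`. Stage 2 applies
#' a 5mC-versus-5hmC model to the remaining sites: scores above the cutoff
#' become `5hmC`, the rest `5mC`. Both stage scores are kept on the call
#' record.
#'
#' @param mol A [molecule_kinetics].
#' @param stage1_model Trained uC-vs-5xC scorer.
#' @param stage2_model Trained 5mC-vs-5hmC scorer (same layout and width).
#' @param cfg A [call_config()]; `cutoff` applies to both stages.
#' @return A calls data frame with `label` in
#'   `{uC, 5mC, 5hmC, no_call}` and columns `score1`, `score2`.
#' @export
call_5hmC_two_stage <- function(mol, stage1_model, stage2_model, cfg = call_config()) {
  check_model_task(stage1_model, "5xC", cfg)
  check_model_task(stage2_model, "5hmC", cfg)
  if (!identical(stage1_model$config$layout_id, stage2_model$config$layout_id))
    stop("stage models were trained on different window layouts")
  if (!strand_depth_ok(mol, cfg$strand_mode)) {
    message(sprintf("molecule '%s': zero subread depth on a required strand; emitting no_call",
                    mol$molecule_id))
    sites <- target_sites(mol, "5xC", cfg$strand_mode)
    return(new_calls(mol, sites, cfg$strand_mode, "5xC", NA_real_, "no_call",
                     extra = data.frame(score1 = rep(NA_real_, length(sites)),
                                        score2 = NA_real_)))
  }
  sc <- score_cpg_sites(mol, stage1_model, cfg, "5xC")
  s2 <- rep(NA_real_, length(sc$sites))
  modded <- which(sc$valid & sc$scores > cfg$cutoff)
  if (length(modded) > 0L) {
    wins <- lapply(sc$sites[modded], function(p) {
      w <- extract_window(mol, p, "5hmC", cfg$width, cfg$strand_mode, cfg$use_adapters)
      normalize_median50(w, mol, norm_spec("median50"))
    })
    s2[modded] <- predict(stage2_model, windows_to_array(wins))
  }
  label <- ifelse(!sc$valid, "no_call", two_stage_label(sc$scores, s2, cfg$cutoff))
  new_calls(mol, sc$sites, cfg$strand_mode,
            ifelse(label %in% c("5mC", "5hmC"), label, "5xC"),
            sc$scores, label,
            extra = data.frame(score1 = sc$scores, score2 = s2))
}

#' Iterative 6mA calling with confounder masking
#'
#' Neighboring 6mA sites inside a measurement window confound the target
#' site, so calling proceeds iteratively: the first round scores every
#' adenine with an empty confounder set; later rounds rebuild each window
#' with the previous round's above-cutoff sites (excluding the target
#' itself) declared as confounders, whose normalized kinetics are masked to
#' 1. Iteration stops when the label set is stable or after
#' `max_6mA_iterations` rounds.
#'
#' @param mol A [molecule_kinetics].
#' @param model Trained 6mA scorer (single-strand layout).
#' @param cfg A [call_config()] with `strand_mode` `"watson"` or `"crick"`
#'   selecting the strand whose adenines are called.
#' @return A calls data frame.
#' @export
call_6mA_iterative <- function(mol, model, cfg = call_config(strand_mode = "watson")) {
  if (cfg$strand_mode == "duplex")
    stop("6mA calling is strand-specific; call each strand separately")
  check_model_task(model, "6mA", cfg)
  sites <- target_sites(mol, "6mA", cfg$strand_mode)
  if (length(sites) == 0L)
    return(new_calls(mol, integer(0), cfg$strand_mode, "6mA", numeric(0), character(0)))
  if (!strand_depth_ok(mol, cfg$strand_mode)) {
    message(sprintf("molecule '%s': zero subread depth on the %s strand; emitting no_call",
                    mol$molecule_id, cfg$strand_mode))
    return(new_calls(mol, sites, cfg$strand_mode, "6mA", NA_real_, "no_call"))
  }
  raw <- lapply(sites, function(p)
    extract_window(mol, p, "6mA", cfg$width, cfg$strand_mode, cfg$use_adapters))
  valid <- vapply(raw, `[[`, NA, "valid")
  scores <- rep(NA_real_, length(sites))
  confounders <- integer(0)
  prev_called <- integer(0)   # empty confounder set in round 1
  for (iter in seq_len(cfg$max_6mA_iterations)) {
    wins <- lapply(which(valid), function(i) {
      spec <- norm_spec("thymine-median",
                        confounder_positions = setdiff(confounders, sites[i]))
      normalize_by_thymine(raw[[i]], mol, spec)
    })
    scores[valid] <- predict(model, windows_to_array(wins))
    called <- sites[valid & !is.na(scores) & scores > cfg$cutoff]
    if (identical(called, prev_called)) break
    prev_called <- called
    confounders <- called
  }
  new_calls(mol, sites, cfg$strand_mode, "6mA", scores,
            ifelse(!valid, "no_call",
                   ifelse(scores > cfg$cutoff, "modified", "unmodified")))
}

# stage-1 gate then stage-2 split; stage 2 is ignored for uC sites
two_stage_label <- function(s1, s2, cutoff) {
  ifelse(s1 <= cutoff, "uC", ifelse(s2 > cutoff, "5hmC", "5mC"))
}

read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L]))) ||
        as.integer(f[2L]) > as.integer(f[3L]))
      stop(sprintf("malformed BED region at line %d of %s", i, path))
    data.frame(chrom = f[1L], start = as.integer(f[2L]), end = as.integer(f[3L]),
               name = if (length(f) >= 4L) f[4L] else sprintf("region%d", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-region modification level
#'
#' The modification level of a region is `modified / (modified +
#' unmodified)` over the labelled calls it covers; `no_call` records are
#' excluded, and regions covering no labelled call are reported as `NA`
#' (missing), never 0. Calls are matched on reference coordinates when
#' present (`chrom`, `genome_pos`, 0-based half-open regions), otherwise on
#' `molecule_id` and molecule position.
#'
#' @param calls A calls data frame.
#' @param regions A BED file path or a data frame with `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `name`.
#' @return The regions with `n_modified`, `n_unmodified` and `level`.
#' @export
region_level <- function(calls, regions) {
  if (is.character(regions)) regions <- read_bed_regions(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  use_genome <- "genome_pos" %in% names(calls) && any(!is.na(calls$genome_pos))
  cchrom <- if (use_genome) calls$chrom else calls$molecule_id
  cpos <- if (use_genome) calls$genome_pos else calls$position
  labelled <- calls$label %in% c("modified", "unmodified")
  res <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- labelled & cchrom == regions$chrom[i] &
      cpos >= regions$start[i] & cpos < regions$end[i]
    nm <- sum(calls$label[sel] == "modified")
    nu <- sum(calls$label[sel] == "unmodified")
    data.frame(n_modified = nm, n_unmodified = nu,
               level = if (nm + nu == 0L) NA_real_ else nm / (nm + nu))
  })
  cbind(regions, do.call(rbind, res))
}

#' Per-molecule CpG methylation profiles
#'
#' Collapses 5mC calls into one ordered binary profile per molecule
#' (1 = methylated, 0 = unmethylated, NA = no_call); `n_cpg` counts called
#' sites only. Molecules whose sites are all `no_call` are excluded with a
#' message.
#'
#' @param calls A 5mC calls data frame.
#' @return A list of class `"methylation_profiles"`; each element has
#'   `molecule_id`, `positions`, `genome_pos`, `states`, `n_cpg`.
#' @export
molecule_profiles <- function(calls) {
  out <- lapply(split(calls, calls$molecule_id), function(cc) {
    cc <- cc[order(cc$position), , drop = FALSE]
    states <- ifelse(cc$label == "modified", 1L,
                     ifelse(cc$label == "unmodified", 0L, NA_integer_))
    if (all(is.na(states))) {
      message(sprintf("molecule '%s': all sites no_call; profile excluded",
                      cc$molecule_id[1L]))
      return(NULL)
    }
    list(molecule_id = cc$molecule_id[1L], positions = cc$position,
         genome_pos = cc$genome_pos, states = states,
         n_cpg = sum(!is.na(states)))
  })
  structure(Filter(Negate(is.null), unname(out)), class = "methylation_profiles")
}

#' @export
print.methylation_profiles <- function(x, ...) {
  cat(sprintf("<methylation_profiles> %d molecules, %d called CpGs\n",
              length(x), sum(vapply(x, `[[`, 0L, "n_cpg"))))
  invisible(x)
}
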