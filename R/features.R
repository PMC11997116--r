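# Measurement windows: the classifier input. A window covers the target
# site plus 10 nt of flanking context per side (21 rows by default); each
# row carries the normalized kinetics, the one-hot base identity, an
# adapter flag and the relative position. Channel layouts are versioned --
# trained scorers refuse windows from a different layout.

LAYOUTS <- list(
  `duplex-v1` = c("ipd_w", "pw_w", "ipd_c", "pw_c", "A", "C", "G", "T",
                  "adapter", "relpos"),
  `single-v1` = c("ipd", "pw", "A", "C", "G", "T", "adapter", "relpos")
)

#' Channel layout of a measurement window
#'
#' @param strand_mode `"duplex"` (both strands' kinetics, base-pair aligned
#'   in Watson coordinates) or `"watson"`/`"crick"` (single-strand).
#' @return Character vector of channel names; the layout id is its
#'   `"layout_id"` attribute.
#' @export
window_layout <- function(strand_mode = c("duplex", "watson", "crick")) {
  strand_mode <- match.arg(strand_mode)
  id <- if (strand_mode == "duplex") "duplex-v1" else "single-v1"
  structure(LAYOUTS[[id]], layout_id = id)
}

#' Normalization specification for measurement windows
#'
#' Two schemes are supported. `"median50"` (cytosine modifications): each
#' kinetic channel is divided by the median of that channel over a span of
#' `span` nt centred on the target (truncated at molecule+adapter
#' boundaries), making windows invariant to molecule-level kinetic scale.
#' `"thymine-median"` (6mA): every kinetic value is divided by the median
#' kinetic value of thymines of the same strand within the span (IPD and PW
#' divisors computed separately), so unmodified adenines normalize to a
#' distribution with mean 1; afterwards all kinetic values at declared
#' `confounder_positions` (known or provisionally called neighboring 6mA
#' sites) are set to exactly 1, maximally resembling the unmodified-adenine
#' distribution.
#'
#' @param mode `"median50"` or `"thymine-median"`.
#' @param span Normalization span in nt (default 50; must be >= the window
#'   width).
#' @param epsilon Positive floor for the divisor.
#' @param confounder_positions Integer vector of 0-based molecule positions
#'   to mask (thymine-median mode only).
#' @param clamp Upper bound applied to normalized kinetic values.
#' @return An object of class `"norm_spec"`.
#' @export
norm_spec <- function(mode = c("median50", "thymine-median"), span = 50L,
                      epsilon = 1e-3, confounder_positions = integer(0),
                      clamp = 10) {
  mode <- match.arg(mode)
  stopifnot(span >= 1, epsilon > 0, clamp > 0)
  structure(list(mode = mode, span = as.integer(span), epsilon = epsilon,
                 confounder_positions = as.integer(confounder_positions),
                 clamp = clamp),
            class = "norm_spec")
}

# gather per-position fields at 0-based indices idx, spilling into adapter
# flanks when present; returns ok = FALSE where no value is available
gather_positions <- function(mol, idx, use_adapters = TRUE) {
  L <- nchar(mol$sequence)
  s <- mol$chars
  n <- length(idx)
  out <- list(base = character(n), ipd_w = numeric(n), pw_w = numeric(n),
              ipd_c = numeric(n), pw_c = numeric(n),
              adapter = numeric(n), ok = rep(TRUE, n))
  inside <- idx >= 0L & idx < L
  ii <- idx[inside] + 1L
  out$base[inside] <- s[ii]
  for (f in c("ipd_w", "pw_w", "ipd_c", "pw_c")) out[[f]][inside] <- mol[[f]][ii]
  fill_side <- function(rows, ad, map_idx) {
    if (length(rows) == 0L) return()
    if (!use_adapters || is.null(ad)) {
      out$ok[rows] <<- FALSE
      return()
    }
    ai <- map_idx(idx[rows])
    bad <- ai < 1L | ai > nchar(ad$sequence)
    out$ok[rows[bad]] <<- FALSE
    rows <- rows[!bad]
    ai <- ai[!bad]
    out$base[rows] <<- seq_chars(ad$sequence)[ai]
    for (f in c("ipd_w", "pw_w", "ipd_c", "pw_c")) out[[f]][rows] <<- ad[[f]][ai]
    out$adapter[rows] <<- 1
  }
  fill_side(which(idx < 0L), mol$adapter_left,
            function(i) nchar(mol$adapter_left$sequence) + i + 1L)
  fill_side(which(idx >= L), mol$adapter_right, function(i) i - L + 1L)
  out
}

orient_molecule <- function(mol, position, strand_mode) {
  if (strand_mode == "crick") {
    list(mol = rc_molecule(mol), position = nchar(mol$sequence) - 1L - position)
  } else list(mol = mol, position = position)
}

check_target_base <- function(mol, position, mod_type) {
  s <- mol$chars
  L <- length(s)
  if (mod_type %in% c("5mC", "5xC", "5hmC")) {
    if (s[position + 1L] != "C" || position + 2L > L || s[position + 2L] != "G")
      stop(sprintf("position %d of molecule '%s' is '%s', not the C of a CpG",
                   position, mol$molecule_id, s[position + 1L]))
  } else if (mod_type == "6mA") {
    if (s[position + 1L] != "A")
      stop(sprintf("position %d of molecule '%s' is '%s', not an adenine",
                   position, mol$molecule_id, s[position + 1L]))
  } else stop("unknown mod_type: ", mod_type)
}

#' Extract a raw measurement window around a target site
#'
#' Builds the `width` x channels feature matrix spanning `position +/-
#' (width - 1) / 2`. Rows falling past a fragment end are completed from
#' the adapter flank kinetics when `use_adapters` is `TRUE` and the flank is
#' present (such rows carry `adapter = 1`); otherwise the window is
#' returned with `valid = FALSE` (a no-call: the site lacks flanking
#' context). Kinetic channels are raw; apply [normalize_window()] before
#' scoring.
#'
#' In `"crick"` mode the window is built in the Crick strand's 5'->3'
#' orientation (positions still refer to Watson coordinates). In
#' `"duplex"` mode Crick kinetics are base-pair aligned in Watson
#' coordinates and the one-hot channels encode the Watson base.
#'
#' @param mol A [molecule_kinetics].
#' @param position 0-based target position (Watson coordinates). Cytosine
#'   modification targets must be the C of a CpG (on the chosen strand);
#'   6mA targets an adenine.
#' @param mod_type `"5mC"`, `"5xC"`, `"5hmC"` or `"6mA"`.
#' @param width Odd window width (default 21).
#' @param strand_mode `"duplex"`, `"watson"` or `"crick"`.
#' @param use_adapters Complete edge windows from adapter kinetics.
#' @param check_base Validate the target base identity (default `TRUE`).
#' @return An object of class `"measurement_window"`: list with `target`,
#'   `width`, `strand_mode`, `layout_id`, `depth`, `valid` and (when valid)
#'   `matrix` plus the row-wise original molecule `positions`.
#' @export
extract_window <- function(mol, position, mod_type, width = 21L,
                           strand_mode = c("duplex", "watson", "crick"),
                           use_adapters = TRUE, check_base = TRUE) {
  strand_mode <- match.arg(strand_mode)
  if (width %% 2L != 1L || width < 3L) stop("width must be an odd integer >= 3")
  L <- nchar(mol$sequence)
  if (position < 0L || position >= L)
    stop(sprintf("position %d out of range for molecule '%s' (length %d)",
                 position, mol$molecule_id, L))
  need <- switch(strand_mode, duplex = c("depth_w", "depth_c"),
                 watson = "depth_w", crick = "depth_c")
  for (d in need) if (mol[[d]] == 0L)
    stop(sprintf("molecule '%s' has zero %s subread depth; use single-strand mode on the covered strand",
                 mol$molecule_id, if (d == "depth_w") "Watson" else "Crick"))
  ori <- orient_molecule(mol, position, strand_mode)
  if (check_base) check_target_base(ori$mol, ori$position, mod_type)
  half <- (width - 1L) %/% 2L
  idx <- ori$position + (-half:half)
  g <- gather_positions(ori$mol, idx, use_adapters)
  depth <- switch(strand_mode, duplex = min(mol$depth_w, mol$depth_c),
                  watson = mol$depth_w, crick = mol$depth_c)
  win <- structure(list(
    target = list(molecule_id = mol$molecule_id, position = as.integer(position),
                  mod_type = mod_type),
    width = as.integer(width), strand_mode = strand_mode,
    layout_id = attr(window_layout(strand_mode), "layout_id"),
    depth = depth, valid = all(g$ok)), class = "measurement_window")
  if (!win$valid) return(win)
  onehot <- matrix(0, width, 4L, dimnames = list(NULL, BASES))
  onehot[cbind(seq_len(width), match(g$base, BASES))] <- 1
  relpos <- (-half:half) / half
  m <- if (strand_mode == "duplex") {
    cbind(ipd_w = g$ipd_w, pw_w = g$pw_w, ipd_c = g$ipd_c, pw_c = g$pw_c,
          onehot, adapter = g$adapter, relpos = relpos)
  } else {
    cbind(ipd = g$ipd_w, pw = g$pw_w, onehot, adapter = g$adapter, relpos = relpos)
  }
  win$matrix <- m
  # original Watson-coordinate molecule position per row (adapter rows
  # fall outside [0, L-1])
  win$positions <- if (strand_mode == "crick") L - 1L - idx else idx
  win
}

#' @export
print.measurement_window <- function(x, ...) {
  cat(sprintf("<measurement_window> %s @ %d (%s, %s): %s\n",
              x$target$molecule_id, x$target$position, x$target$mod_type,
              x$strand_mode,
              if (x$valid) sprintf("%d x %d, %d adapter row(s)", x$width,
                                   ncol(x$matrix), sum(x$matrix[, "adapter"]))
              else "invalid (no-call)"))
  invisible(x)
}

kinetic_channels <- function(win) {
  if (win$strand_mode == "duplex") c("ipd_w", "pw_w", "ipd_c", "pw_c") else c("ipd", "pw")
}

# values of the molecule array feeding a given kinetic channel over the
# normalization span, in the window's orientation
span_values <- function(mol, win, spec) {
  ori <- orient_molecule(mol, win$target$position, win$strand_mode)
  start <- ori$position - spec$span %/% 2L
  idx <- start:(start + spec$span - 1L)
  g <- gather_positions(ori$mol, idx, use_adapters = TRUE)
  g$idx <- idx
  g
}

div_clamp <- function(x, med, spec, what) {
  if (!is.finite(med) || is.na(med)) med <- 0
  if (med < spec$epsilon) {
    if (med == 0 && all(x == 0)) {
      warning(sprintf("%s: all-zero channel over the normalization span; normalized values set to 0", what))
      return(x)
    }
    message(sprintf("%s: span median %.3g below epsilon; dividing by epsilon and capping at %g",
                    what, med, spec$clamp))
    med <- spec$epsilon
  }
  pmin(pmax(x / med, 0), spec$clamp)
}

#' Normalize a measurement window by the span median (cytosine mode)
#'
#' Divides each kinetic channel by the median of that channel over the
#' `spec$span`-nt span centred on the target (adapter flanks included,
#' truncated at boundaries), floors the divisor at `spec$epsilon`, and
#' clamps normalized values to `[0, spec$clamp]`. One-hot, adapter and
#' position channels are untouched.
#'
#' @param window A valid [extract_window()] result.
#' @param mol The molecule the window came from.
#' @param spec A [norm_spec()] with `mode = "median50"`.
#' @return The window with normalized kinetic channels.
#' @export
normalize_median50 <- function(window, mol, spec = norm_spec("median50")) {
  stopifnot(spec$mode == "median50")
  if (!window$valid) stop("cannot normalize an invalid (no-call) window")
  g <- span_values(mol, window, spec)
  src <- if (window$strand_mode == "duplex")
    c(ipd_w = "ipd_w", pw_w = "pw_w", ipd_c = "ipd_c", pw_c = "pw_c")
  else c(ipd = "ipd_w", pw = "pw_w")
  for (ch in names(src)) {
    vals <- g[[src[[ch]]]][g$ok]
    window$matrix[, ch] <- div_clamp(window$matrix[, ch], median(vals), spec,
                                     sprintf("%s @ %d channel %s",
                                             window$target$molecule_id,
                                             window$target$position, ch))
  }
  window
}

#' Normalize a 6mA measurement window by the thymine median
#'
#' Divides every kinetic value by the median kinetic value of thymines of
#' the same strand within the normalization span (IPD and PW divisors
#' computed separately), then sets all kinetic values at the declared
#' confounder positions to exactly 1 so neighboring 6mA sites maximally
#' resemble the unmodified-adenine distribution. Falls back to the
#' molecule-wide thymine median when the span contains no thymine
#' (an error if the molecule has none).
#'
#' @inheritParams normalize_median50
#' @param spec A [norm_spec()] with `mode = "thymine-median"`; its
#'   `confounder_positions` are 0-based molecule positions.
#' @return The window with normalized kinetic channels.
#' @export
normalize_by_thymine <- function(window, mol, spec = norm_spec("thymine-median")) {
  stopifnot(spec$mode == "thymine-median")
  if (!window$valid) stop("cannot normalize an invalid (no-call) window")
  if (window$target$mod_type != "6mA")
    stop("thymine-median normalization is specific to 6mA targets")
  g <- span_values(mol, window, spec)
  # thymines of the Watson-oriented view feed the *_w channels; Crick-strand
  # thymines pair Watson adenines and feed the *_c channels
  t_sel <- list(w = g$ok & g$base == "T", c = g$ok & g$base == "A")
  mol_chars <- mol$chars
  mol_t <- list(w = mol_chars == "T", c = mol_chars == "A")
  src <- if (window$strand_mode == "duplex")
    list(ipd_w = c("ipd_w", "w"), pw_w = c("pw_w", "w"),
         ipd_c = c("ipd_c", "c"), pw_c = c("pw_c", "c"))
  else list(ipd = c("ipd_w", "w"), pw = c("pw_w", "w"))
  ori_mol <- orient_molecule(mol, window$target$position, window$strand_mode)$mol
  for (ch in names(src)) {
    field <- src[[ch]][1L]; strand <- src[[ch]][2L]
    vals <- g[[field]][t_sel[[strand]]]
    if (length(vals) == 0L) {
      ori_chars <- ori_mol$chars
      sel <- if (strand == "w") ori_chars == "T" else ori_chars == "A"
      if (!any(sel))
        stop(sprintf("molecule '%s' contains no thymine on the %s strand; cannot thymine-normalize",
                     mol$molecule_id, if (strand == "w") "target" else "opposite"))
      message(sprintf("%s @ %d: no thymine in the normalization span for channel %s; using the molecule-wide median",
                      window$target$molecule_id, window$target$position, ch))
      vals <- ori_mol[[field]][sel]
    }
    window$matrix[, ch] <- div_clamp(window$matrix[, ch], median(vals), spec,
                                     sprintf("%s @ %d channel %s",
                                             window$target$molecule_id,
                                             window$target$position, ch))
  }
  if (length(spec$confounder_positions) > 0L) {
    rows <- which(window$positions %in% spec$confounder_positions)
    if (length(rows) > 0L)
      window$matrix[rows, kinetic_channels(window)] <- 1
  }
  window
}

#' Normalize a measurement window according to a specification
#'
#' Dispatches to [normalize_median50()] or [normalize_by_thymine()].
#'
#' @inheritParams normalize_median50
#' @param spec A [norm_spec()].
#' @return The normalized window.
#' @export
normalize_window <- function(window, mol, spec) {
  switch(spec$mode,
         median50 = normalize_median50(window, mol, spec),
         `thymine-median` = normalize_by_thymine(window, mol, spec))
}

#' Candidate target positions for a modification type
#'
#' 0-based positions of CpG cytosines (cytosine modifications) or adenines
#' (6mA) on the strand implied by `strand_mode`, before any callability
#' filtering.
#'
#' @inheritParams extract_window
#' @return Sorted integer vector of 0-based Watson-coordinate positions.
#' @export
target_sites <- function(mol, mod_type, strand_mode = c("duplex", "watson", "crick")) {
  strand_mode <- match.arg(strand_mode)
  s <- mol$chars
  if (mod_type %in% c("5mC", "5xC", "5hmC")) {
    cpg <- cpg_c_positions(s)
    if (strand_mode == "crick") cpg + 1L else cpg
  } else {
    if (strand_mode == "crick") which(s == "T") - 1L else which(s == "A") - 1L
  }
}

#' Positions whose measurement window is intact
#'
#' Returns the candidate target positions (per [target_sites()]) whose
#' window of the requested width can be fully assembled. With adapter
#' flanks present and `use_adapters = TRUE` every candidate position is
#' callable (the no-call region at fragment ends disappears); without
#' them, positions closer than half a window to either end are dropped.
#'
#' @inheritParams extract_window
#' @return Sorted integer vector of 0-based callable positions.
#' @export
callable_sites <- function(mol, mod_type, width = 21L,
                           strand_mode = c("duplex", "watson", "crick"),
                           use_adapters = TRUE) {
  strand_mode <- match.arg(strand_mode)
  pos <- target_sites(mol, mod_type, strand_mode)
  ok <- vapply(pos, function(p) {
    extract_window(mol, p, mod_type, width, strand_mode, use_adapters)$valid
  }, NA)
  pos[ok]
}

#' Combine two single-strand windows into a duplex window
#'
#' Takes the Watson-mode and Crick-mode windows of the same duplex site
#' (the Crick window extracted at the same Watson-coordinate position) and
#' assembles the duplex feature matrix: Crick kinetic rows are reversed
#' into Watson coordinates so that row i carries the Crick kinetics of the
#' base pairing Watson position i, and the one-hot channels encode the
#' Watson base.
#'
#' @param window_w A valid `"watson"`-mode [extract_window()] result.
#' @param window_c A valid `"crick"`-mode window at the same position.
#' @return A duplex `"measurement_window"`.
#' @export
encode_duplex <- function(window_w, window_c) {
  if (!window_w$valid || !window_c$valid)
    stop("encode_duplex requires two valid single-strand windows")
  if (window_w$strand_mode != "watson" || window_c$strand_mode != "crick")
    stop("encode_duplex expects a watson-mode and a crick-mode window")
  if (window_w$width != window_c$width)
    stop("encode_duplex: window widths differ")
  if (window_w$target$molecule_id != window_c$target$molecule_id ||
      window_w$target$position != window_c$target$position)
    stop("encode_duplex: windows target different sites")
  w <- window_w
  w$strand_mode <- "duplex"
  w$layout_id <- attr(window_layout("duplex"), "layout_id")
  w$depth <- min(window_w$depth, window_c$depth)
  n <- window_w$width
  w$matrix <- cbind(
    ipd_w = window_w$matrix[, "ipd"], pw_w = window_w$matrix[, "pw"],
    ipd_c = rev(window_c$matrix[, "ipd"]), pw_c = rev(window_c$matrix[, "pw"]),
    window_w$matrix[, BASES], adapter = window_w$matrix[, "adapter"],
    relpos = window_w$matrix[, "relpos"])
  w
}

#' Stack measurement windows into a 3-d feature array
#'
#' @param windows List of valid, normalized windows sharing one layout and
#'   width.
#' @return Numeric array `n x width x channels` with the layout id and the
#'   per-window subread depths as attributes.
#' @export
windows_to_array <- function(windows) {
  if (length(windows) == 0L) stop("windows_to_array: empty window list")
  if (!all(vapply(windows, function(w) isTRUE(w$valid), NA)))
    stop("windows_to_array: invalid (no-call) windows present; filter them first")
  ids <- unique(vapply(windows, `[[`, "", "layout_id"))
  wds <- unique(vapply(windows, `[[`, 0L, "width"))
  if (length(ids) != 1L || length(wds) != 1L)
    stop("windows_to_array: windows mix layouts or widths")
  ch <- LAYOUTS[[ids]]
  x <- array(0, dim = c(length(windows), wds, length(ch)),
             dimnames = list(NULL, NULL, ch))
  for (i in seq_along(windows)) x[i, , ] <- windows[[i]]$matrix
  attr(x, "layout_id") <- ids
  attr(x, "depth") <- vapply(windows, `[[`, 0L, "depth")
  x
}
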