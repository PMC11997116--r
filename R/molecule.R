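#' smrtcall: base modification calling from SMRT sequencing kinetics
#'
#' Detects 5mC, 5hmC and 6mA on single sequenced molecules from polymerase
#' kinetics (inter-pulse durations, IPD, and pulse widths, PW). The package
#' covers the full desk-scale workflow: reading per-molecule kinetics,
#' simulating synthetic libraries with ground truth, building normalized
#' 21-nt measurement windows, training and applying a convolutional +
#' transformer scoring network, per-molecule calling workflows, evaluation
#' statistics, and downstream applications (jagged-end profiles, nucleosome
#' periodicity, motif enrichment, molecule-origin scoring).
#'
#' All positions in the exported API are 0-based (half-open intervals on
#' output, BED convention). Human-readable messages use 1-based positions.
#'
#' @useDynLib smrtcall, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm rlnorm runif rbinom acf cor.test wilcox.test
#'   plogis pnorm quantile sd spec.pgram
#' @importFrom utils read.table write.table head tail
#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

revcomp <- function(sequence) {
  paste(rev(unname(COMPLEMENT[seq_chars(sequence)])), collapse = "")
}

#' One sequenced molecule with per-strand consensus kinetics
#'
#' Container for a single sequenced molecule: its consensus sequence (Watson
#' orientation) and, per strand, the per-position aggregated IPD and PW
#' values plus the subread depth (number of polymerase passes) that produced
#' them. Crick-strand arrays are stored in Watson coordinates with
#' base-paired indexing: `ipd_c[i]` is the kinetic value of the Crick base
#' paired with Watson position `i`.
#'
#' Optional adapter flanks hold the sequence and kinetics of the sequencing
#' adapters on either side, oriented so that
#' `adapter_left + molecule + adapter_right` is coordinate-continuous; they
#' are used to complete measurement windows that would otherwise fall off a
#' fragment end.
#'
#' @param molecule_id Character scalar identifying the molecule.
#' @param sequence Consensus sequence over A/C/G/T, Watson orientation.
#' @param ipd_w,pw_w,ipd_c,pw_c Numeric vectors of per-position aggregated
#'   kinetics, one value per consensus position, all non-negative.
#' @param depth_w,depth_c Subread depth (passes aggregated) per strand.
#' @param adapter_left,adapter_right Optional adapter flank, a list with
#'   elements `sequence`, `ipd_w`, `pw_w`, `ipd_c`, `pw_c` (lengths equal to
#'   the adapter length, which must be at least 10), or `NULL`.
#' @param chrom,start Optional reference placement (contig name and 0-based
#'   start of the molecule), used by genome-coordinate applications.
#' @return An object of class `"molecule_kinetics"`.
#' @export
molecule_kinetics <- function(molecule_id, sequence,
                              ipd_w, pw_w, ipd_c, pw_c,
                              depth_w, depth_c,
                              adapter_left = NULL, adapter_right = NULL,
                              chrom = NA_character_, start = NA_integer_) {
  n <- nchar(sequence)
  arrs <- list(ipd_w = ipd_w, pw_w = pw_w, ipd_c = ipd_c, pw_c = pw_c)
  for (nm in names(arrs)) {
    a <- arrs[[nm]]
    if (length(a) != n)
      stop(sprintf("molecule '%s': %s has length %d but sequence has length %d",
                   molecule_id, nm, length(a), n))
    if (any(!is.finite(a)) || any(a < 0))
      stop(sprintf("molecule '%s': %s contains negative or non-finite values",
                   molecule_id, nm))
  }
  if (!all(seq_chars(sequence) %in% BASES))
    stop(sprintf("molecule '%s': sequence contains characters outside A/C/G/T",
                 molecule_id))
  for (side in c("adapter_left", "adapter_right")) {
    ad <- get(side)
    if (!is.null(ad)) {
      la <- nchar(ad$sequence)
      if (la < 10L)
        stop(sprintf("molecule '%s': %s must be at least 10 nt", molecule_id, side))
      for (nm in c("ipd_w", "pw_w", "ipd_c", "pw_c"))
        if (length(ad[[nm]]) != la)
          stop(sprintf("molecule '%s': %s$%s length mismatch", molecule_id, side, nm))
    }
  }
  structure(list(
    molecule_id = as.character(molecule_id), sequence = sequence,
    chars = seq_chars(sequence),
    ipd_w = as.numeric(ipd_w), pw_w = as.numeric(pw_w),
    ipd_c = as.numeric(ipd_c), pw_c = as.numeric(pw_c),
    depth_w = as.integer(depth_w), depth_c = as.integer(depth_c),
    adapter_left = adapter_left, adapter_right = adapter_right,
    chrom = chrom, start = as.integer(start)
  ), class = "molecule_kinetics")
}

#' @export
print.molecule_kinetics <- function(x, ...) {
  cat(sprintf("<molecule_kinetics> %s: %d nt, depth %dx (Watson) / %dx (Crick)%s\n",
              x$molecule_id, nchar(x$sequence), x$depth_w, x$depth_c,
              if (!is.null(x$adapter_left) || !is.null(x$adapter_right))
                ", with adapter flanks" else ""))
  invisible(x)
}

#' @export
length.molecule_kinetics <- function(x) nchar(x$sequence)

rc_adapter <- function(ad) {
  if (is.null(ad)) return(NULL)
  list(sequence = revcomp(ad$sequence),
       ipd_w = rev(ad$ipd_c), pw_w = rev(ad$pw_c),
       ipd_c = rev(ad$ipd_w), pw_c = rev(ad$pw_w))
}

#' Reverse-complement a molecule, swapping strands
#'
#' Returns the same physical duplex viewed from the opposite strand: the
#' sequence is reverse-complemented, Watson/Crick kinetic arrays and depths
#' are swapped (and reversed, preserving the base-paired Watson-coordinate
#' storage convention), and the adapter flanks trade places. Applying the
#' transform twice restores the original object.
#'
#' @param mol A [molecule_kinetics] object.
#' @return A [molecule_kinetics] object.
#' @export
rc_molecule <- function(mol) {
  molecule_kinetics(
    molecule_id = mol$molecule_id, sequence = revcomp(mol$sequence),
    ipd_w = rev(mol$ipd_c), pw_w = rev(mol$pw_c),
    ipd_c = rev(mol$ipd_w), pw_c = rev(mol$pw_w),
    depth_w = mol$depth_c, depth_c = mol$depth_w,
    adapter_left = rc_adapter(mol$adapter_right),
    adapter_right = rc_adapter(mol$adapter_left),
    chrom = mol$chrom, start = mol$start
  )
}

#' One polymerase pass over a molecule
#'
#' A subread: the kinetics measured during a single pass of the polymerase
#' over one strand of the circular template, already aligned to consensus
#' coordinates. Crick passes are stored in Watson coordinates with
#' base-paired indexing, like [molecule_kinetics].
#'
#' @param molecule_id Molecule identifier shared by all passes of a molecule.
#' @param strand `"watson"` or `"crick"`.
#' @param pass_index Non-negative integer index of the pass.
#' @param ipd,pw Numeric vectors (equal length, non-negative), one value per
#'   consensus position.
#' @param aligned Logical; must be `TRUE` (subread-to-consensus alignment is
#'   upstream of this package).
#' @return An object of class `"subread_pass"`.
#' @export
subread_pass <- function(molecule_id, strand, pass_index, ipd, pw, aligned = TRUE) {
  strand <- match.arg(strand, c("watson", "crick"))
  if (length(ipd) != length(pw))
    stop(sprintf("pass %d of molecule '%s': ipd and pw lengths differ",
                 pass_index, molecule_id))
  if (any(ipd < 0, na.rm = TRUE) || any(pw < 0, na.rm = TRUE))
    stop(sprintf("pass %d of molecule '%s': negative kinetic values",
                 pass_index, molecule_id))
  if (pass_index < 0) stop("pass_index must be >= 0")
  structure(list(molecule_id = as.character(molecule_id), strand = strand,
                 pass_index = as.integer(pass_index),
                 ipd = as.numeric(ipd), pw = as.numeric(pw),
                 aligned = isTRUE(aligned)),
            class = "subread_pass")
}
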