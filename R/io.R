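#' Aggregate subread passes onto consensus coordinates
#'
#' Collapses the per-pass kinetics of one molecule into per-position,
#' per-strand consensus kinetics. The subread depth per strand is the
#' number of passes aggregated for that strand. Missing single-position
#' values (`NA` dropouts within a pass) are imputed as the median of that
#' pass's strand before aggregation, with a message.
#'
#' @param passes List of [subread_pass] objects sharing one `molecule_id`
#'   and length, all aligned to consensus coordinates.
#' @param method Aggregation statistic across passes: `"mean"` (default) or
#'   `"median"` (robust to single-pass outliers).
#' @param sequence Optional consensus sequence; when supplied a full
#'   [molecule_kinetics] object is returned, otherwise a bare list of the
#'   kinetics fields.
#' @return A [molecule_kinetics] object (if `sequence` given) or a list with
#'   elements `ipd_w`, `pw_w`, `ipd_c`, `pw_c`, `depth_w`, `depth_c`.
#'   Zero-pass strands get all-zero kinetics and depth 0.
#' @export
aggregate_subreads <- function(passes, method = c("mean", "median"), sequence = NULL) {
  method <- match.arg(method)
  if (length(passes) == 0L) stop("aggregate_subreads: empty pass collection")
  ids <- vapply(passes, function(p) p$molecule_id, "")
  if (length(unique(ids)) != 1L)
    stop("aggregate_subreads: passes from multiple molecules: ",
         paste(unique(ids), collapse = ", "))
  lens <- vapply(passes, function(p) length(p$ipd), 0L)
  if (length(unique(lens)) != 1L)
    stop(sprintf("molecule '%s': passes have mixed lengths (%s)",
                 ids[1L], paste(unique(lens), collapse = ", ")))
  if (!all(vapply(passes, function(p) isTRUE(p$aligned), NA)))
    stop(sprintf("molecule '%s': unaligned passes; align subreads to the consensus first", ids[1L]))
  n <- lens[1L]
  agg_one <- function(strand, field) {
    sel <- Filter(function(p) p$strand == strand, passes)
    if (length(sel) == 0L) return(rep(0, n))
    m <- do.call(rbind, lapply(sel, function(p) {
      v <- p[[field]]
      if (anyNA(v)) {
        message(sprintf("molecule '%s': imputing %d missing %s value(s) in a %s pass with the pass median",
                        ids[1L], sum(is.na(v)), field, strand))
        v[is.na(v)] <- median(v, na.rm = TRUE)
      }
      v
    }))
    if (method == "mean") colMeans(m) else apply(m, 2L, median)
  }
  out <- list(
    ipd_w = agg_one("watson", "ipd"), pw_w = agg_one("watson", "pw"),
    ipd_c = agg_one("crick", "ipd"), pw_c = agg_one("crick", "pw"),
    depth_w = sum(vapply(passes, function(p) p$strand == "watson", NA)),
    depth_c = sum(vapply(passes, function(p) p$strand == "crick", NA))
  )
  if (is.null(sequence)) return(out)
  molecule_kinetics(ids[1L], sequence, out$ipd_w, out$pw_w, out$ipd_c, out$pw_c,
                    out$depth_w, out$depth_c)
}

fmt_nums <- function(x) paste(sprintf("%.6g", x), collapse = ",")
parse_nums <- function(s) if (identical(s, ".") || is.na(s)) numeric(0) else
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])

FIXTURE_COLS <- c("molecule_id", "sequence", "ipd_w", "pw_w", "ipd_c", "pw_c",
                  "depth_w", "depth_c", "chrom", "start",
                  "adapter_left_seq", "adapter_left_ipd_w", "adapter_left_pw_w",
                  "adapter_left_ipd_c", "adapter_left_pw_c",
                  "adapter_right_seq", "adapter_right_ipd_w", "adapter_right_pw_w",
                  "adapter_right_ipd_c", "adapter_right_pw_c")

#' Write molecules to the plain-text fixture format
#'
#' The canonical tab-separated interchange/test format: a header line, then
#' one line per molecule with comma-joined per-position kinetics printed
#' with 6 significant digits, and `.` for absent optional fields (adapters,
#' reference placement).
#'
#' @param molecules List of [molecule_kinetics] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  ad_fields <- function(ad, prefix) {
    if (is.null(ad)) return(stats::setNames(rep(".", 5L), paste0(prefix, c(
      "_seq", "_ipd_w", "_pw_w", "_ipd_c", "_pw_c"))))
    stats::setNames(c(ad$sequence, fmt_nums(ad$ipd_w), fmt_nums(ad$pw_w),
                      fmt_nums(ad$ipd_c), fmt_nums(ad$pw_c)),
                    paste0(prefix, c("_seq", "_ipd_w", "_pw_w", "_ipd_c", "_pw_c")))
  }
  rows <- vapply(molecules, function(m) {
    fields <- c(molecule_id = m$molecule_id, sequence = m$sequence,
                ipd_w = fmt_nums(m$ipd_w), pw_w = fmt_nums(m$pw_w),
                ipd_c = fmt_nums(m$ipd_c), pw_c = fmt_nums(m$pw_c),
                depth_w = as.character(m$depth_w), depth_c = as.character(m$depth_c),
                chrom = if (is.na(m$chrom)) "." else m$chrom,
                start = if (is.na(m$start)) "." else as.character(m$start),
                ad_fields(m$adapter_left, "adapter_left"),
                ad_fields(m$adapter_right, "adapter_right"))
    paste(fields[FIXTURE_COLS], collapse = "\t")
  }, "")
  writeLines(c(paste(FIXTURE_COLS, collapse = "\t"), rows), path)
  invisible(path)
}

read_fixture <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty fixture file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(FIXTURE_COLS[1:8] %in% header))
    stop("fixture file ", path, " lacks required columns")
  out <- list()
  for (i in seq_along(lines)[-1L]) {
    f <- stats::setNames(strsplit(lines[i], "\t", fixed = TRUE)[[1L]], header)
    read_ad <- function(prefix) {
      s <- f[paste0(prefix, "_seq")]
      if (is.na(s) || identical(unname(s), ".")) return(NULL)
      list(sequence = unname(s),
           ipd_w = parse_nums(f[paste0(prefix, "_ipd_w")]),
           pw_w = parse_nums(f[paste0(prefix, "_pw_w")]),
           ipd_c = parse_nums(f[paste0(prefix, "_ipd_c")]),
           pw_c = parse_nums(f[paste0(prefix, "_pw_c")]))
    }
    mol <- tryCatch(molecule_kinetics(
      f[["molecule_id"]], f[["sequence"]],
      parse_nums(f[["ipd_w"]]), parse_nums(f[["pw_w"]]),
      parse_nums(f[["ipd_c"]]), parse_nums(f[["pw_c"]]),
      as.integer(f[["depth_w"]]), as.integer(f[["depth_c"]]),
      adapter_left = read_ad("adapter_left"),
      adapter_right = read_ad("adapter_right"),
      chrom = if (identical(f[["chrom"]], ".") || is.na(f["chrom"])) NA_character_ else f[["chrom"]],
      start = if (identical(f[["start"]], ".") || is.na(f["start"])) NA_integer_ else as.integer(f[["start"]])
    ), error = function(e) stop(sprintf("fixture line %d: %s", i, conditionMessage(e)), call. = FALSE))
    out[[length(out) + 1L]] <- mol
  }
  out
}

read_bam_kinetics <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading bam-kinetics requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "seq"),
    tag = c("fi", "fp", "ri", "rp", "fn", "rn"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  out <- list()
  for (i in seq_along(b$qname)) {
    sq <- as.character(b$seq[i])
    n <- nchar(sq)
    tagv <- function(tg) {
      v <- b$tag[[tg]][[i]]
      if (is.null(v)) NULL else as.numeric(v)
    }
    fi <- tagv("fi"); fp <- tagv("fp"); ri <- tagv("ri"); rp <- tagv("rp")
    fn <- b$tag$fn[i]; rn <- b$tag$rn[i]
    if (is.null(fn) || is.na(fn)) fn <- if (is.null(fi)) 0L else 1L
    if (is.null(rn) || is.na(rn)) rn <- if (is.null(ri)) 0L else 1L
    for (nm in c("fi", "fp", "ri", "rp")) {
      v <- get(nm)
      if (!is.null(v) && length(v) != n)
        stop(sprintf("bam record '%s': tag %s has length %d but sequence has length %d",
                     b$qname[i], nm, length(v), n))
    }
    zero <- rep(0, n)
    # reverse-strand kinetics are stored 5'->3' of the reverse strand in the
    # tags; flip them into Watson-coordinate, base-paired indexing
    out[[length(out) + 1L]] <- molecule_kinetics(
      b$qname[i], sq,
      ipd_w = if (is.null(fi)) zero else fi,
      pw_w = if (is.null(fp)) zero else fp,
      ipd_c = if (is.null(ri)) zero else rev(ri),
      pw_c = if (is.null(rp)) zero else rev(rp),
      depth_w = as.integer(fn), depth_c = as.integer(rn))
  }
  out
}

#' Read molecule kinetics from a file
#'
#' Reads per-molecule consensus kinetics either from the plain-text
#' tab-separated fixture format written by [write_molecules()] or from a
#' BAM file carrying PacBio-style per-base CCS kinetics tags (`fi`/`fp`
#' forward IPD/PW, `ri`/`rp` reverse IPD/PW, `fn`/`rn` pass counts; reverse
#' arrays are re-oriented into Watson coordinates). Molecules with zero
#' passes on both strands are skipped with a warning.
#'
#' @param path Input file.
#' @param format `"tsv-fixture"` or `"bam-kinetics"`.
#' @return List of [molecule_kinetics] objects.
#' @export
read_molecules <- function(path, format = c("tsv-fixture", "bam-kinetics")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  mols <- switch(format,
                 "tsv-fixture" = read_fixture(path),
                 "bam-kinetics" = read_bam_kinetics(path))
  keep <- vapply(mols, function(m) m$depth_w + m$depth_c > 0L, NA)
  if (any(!keep))
    warning(sprintf("skipping %d molecule(s) with zero passes on both strands: %s",
                    sum(!keep),
                    paste(vapply(mols[!keep], `[[`, "", "molecule_id"), collapse = ", ")))
  mols[keep]
}

#' Write modification calls to BED or TSV
#'
#' BED output is 0-based half-open, BED6+2: chrom (the reference contig if
#' the calls carry one, otherwise the molecule id), start, end, name
#' (modification type), score (1000 x modification score, rounded), strand,
#' then the raw score and the subread depth. Rows are sorted by
#' (molecule_id, position, strand_mode); `no_call` records are written with
#' `.` in the score columns. TSV output keeps full precision and all
#' columns.
#'
#' @param calls A calls data frame as returned by the calling functions.
#' @param path Output path.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (nrow(calls) > 0L)
    calls <- calls[order(calls$molecule_id, calls$position, calls$strand_mode), ,
                   drop = FALSE]
  if (format == "tsv") {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  strand_sym <- c(watson = "+", crick = "-", duplex = ".")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(calls) > 0L) {
    chrom <- if ("chrom" %in% names(calls) && !all(is.na(calls$chrom)))
      ifelse(is.na(calls$chrom), calls$molecule_id, calls$chrom) else calls$molecule_id
    pos <- if ("genome_pos" %in% names(calls) && !all(is.na(calls$genome_pos)))
      ifelse(is.na(calls$genome_pos), calls$position, calls$genome_pos) else calls$position
    nc <- calls$label == "no_call"
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%d",
                       chrom, pos, pos + 1L, calls$mod_type,
                       ifelse(nc, ".", as.character(round(1000 * calls$score))),
                       strand_sym[calls$strand_mode],
                       ifelse(nc, ".", sprintf("%.6g", calls$score)),
                       calls$depth), con)
  }
  invisible(path)
}
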