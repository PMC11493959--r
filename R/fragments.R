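# Fragment-level input: BED3+ reading and per-bin short/long tallies.

autosome_names <- paste0("chr", 1:22)

# length windows for the short/long ratio features and the mixture window
SHORT_RANGE <- c(100L, 150L)
LONG_RANGE <- c(151L, 220L)
LENGTH_WINDOW <- c(50L, 400L)

#' Read cfDNA fragments from a BED file or text
#'
#' Reads a BED3+ file (plain or gzip; extra columns are ignored), computes
#' fragment lengths as `end - start`, and drops non-autosomal records with a
#' logged count. Coordinates are 0-based half-open.
#'
#' @param path path to a BED file, or a character vector of BED lines via
#'   `text`.
#' @param text optional character vector of BED lines (overrides `path`).
#' @return tibble with columns `chrom`, `start`, `end`, `length`, in file
#'   order, with attribute `n_dropped_nonautosomal`.
#' @export
read_fragments <- function(path = NULL, text = NULL) {
  if (!is.null(text)) {
    df <- tryCatch(data.table::fread(text = paste(text, collapse = "\n"),
                                     header = FALSE, fill = TRUE, data.table = FALSE),
                   error = function(e) delfi_error(
                     paste("malformed BED input:", conditionMessage(e)),
                     "delfi_parse_error"))
  } else {
    if (!file.exists(path))
      delfi_error(paste("BED file not found:", path), "delfi_io_error")
    df <- tryCatch(data.table::fread(path, header = FALSE, fill = TRUE, data.table = FALSE),
                   error = function(e) delfi_error(
                     paste("malformed BED input:", conditionMessage(e)),
                     "delfi_parse_error"))
  }
  if (ncol(df) < 3L)
    delfi_error("BED input needs at least 3 columns", "delfi_parse_error")
  chrom <- as.character(df[[1L]])
  start <- suppressWarnings(as.numeric(df[[2L]]))
  end <- suppressWarnings(as.numeric(df[[3L]]))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    delfi_error(sprintf("non-integer coordinates at line %d", bad[1L]),
                "delfi_parse_error")
  bad <- which(start >= end)
  if (length(bad))
    delfi_error(sprintf("invalid interval (start >= end) at line %d", bad[1L]),
                "delfi_parse_error")
  keep <- chrom %in% autosome_names
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(sprintf("read_fragments: dropped %d non-autosomal record(s)", n_dropped))
  out <- tibble::tibble(chrom = chrom[keep], start = start[keep], end = end[keep],
                        length = end[keep] - start[keep])
  attr(out, "n_dropped_nonautosomal") <- n_dropped
  out
}

#' Construct a per-bin counts container
#'
#' Low-level constructor used by both [bin_fragments()] and the cohort
#' simulator. `lengths` is a histogram of retained fragment lengths over the
#' integer grid 50..400 bp.
#'
#' @param sample_id sample identifier.
#' @param short,long integer count vectors, one element per tiling bin.
#' @param length_hist integer vector of counts named/aligned to 50:400 bp.
#' @param total_fragments number of fragments assigned to bins.
#' @return a `binned_counts` object.
#' @export
new_binned_counts <- function(sample_id, short, long, length_hist,
                              total_fragments = sum(length_hist)) {
  stopifnot(length(short) == length(long),
            length(length_hist) == diff(LENGTH_WINDOW) + 1L,
            all(short >= 0), all(long >= 0))
  structure(list(sample_id = sample_id, short = as.numeric(short),
                 long = as.numeric(long),
                 length_hist = as.numeric(length_hist),
                 total_fragments = total_fragments),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %s: %d bins, %.0f short / %.0f long fragments\n",
              x$sample_id, length(x$short), sum(x$short), sum(x$long)))
  invisible(x)
}

#' Tally fragments into tiling bins
#'
#' Each fragment is assigned to the unique bin containing its midpoint
#' (`floor((start + end) / 2)`); fragments whose midpoint falls in no bin
#' (excluded or untiled regions) are dropped. Assigned fragments are counted
#' as short (100-150 bp) or long (151-220 bp) per bin; other lengths count in
#' neither class. Lengths of all assigned fragments within 50-400 bp are
#' retained as a histogram for mixture fitting.
#'
#' @param fragments tibble from [read_fragments()].
#' @param tiling a `delfi_tiling`.
#' @param sample_id sample identifier stored in the result.
#' @return a `binned_counts` object.
#' @export
bin_fragments <- function(fragments, tiling, sample_id = "sample") {
  nb <- nrow(tiling)
  short <- integer(nb)
  long <- integer(nb)
  hist <- integer(diff(LENGTH_WINDOW) + 1L)
  assigned <- 0L
  mid <- floor((fragments$start + fragments$end) / 2)
  for (ch in unique(fragments$chrom)) {
    bsel <- which(tiling$chrom == ch)
    fsel <- which(fragments$chrom == ch)
    if (!length(bsel) || !length(fsel)) next
    starts <- tiling$start[bsel]
    ends <- tiling$end[bsel]
    idx <- findInterval(mid[fsel], starts)
    ok <- idx >= 1L & mid[fsel] < ends[pmax(idx, 1L)]
    bin <- bsel[idx[ok]]
    len <- fragments$length[fsel][ok]
    assigned <- assigned + sum(ok)
    s <- len >= SHORT_RANGE[1L] & len <= SHORT_RANGE[2L]
    l <- len >= LONG_RANGE[1L] & len <= LONG_RANGE[2L]
    if (any(s)) short <- short + tabulate(bin[s], nbins = nb)
    if (any(l)) long <- long + tabulate(bin[l], nbins = nb)
    w <- len >= LENGTH_WINDOW[1L] & len <= LENGTH_WINDOW[2L]
    if (any(w)) hist <- hist + tabulate(len[w] - LENGTH_WINDOW[1L] + 1L,
                                        nbins = length(hist))
  }
  new_binned_counts(sample_id, short, long, hist, total_fragments = assigned)
}

#' Write per-bin counts and the length histogram to TSV files
#'
#' @param counts a `binned_counts`.
#' @param counts_path TSV `bin_id short long`.
#' @param lengths_path TSV `length count` over 50-400 bp (zero rows omitted).
#' @return invisibly, the two paths.
#' @export
write_counts <- function(counts, counts_path, lengths_path = NULL) {
  data.table::fwrite(data.frame(bin_id = seq_along(counts$short),
                                short = counts$short, long = counts$long),
                     counts_path, sep = "\t")
  if (!is.null(lengths_path)) {
    grid <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
    nz <- counts$length_hist > 0
    data.table::fwrite(data.frame(length = grid[nz], count = counts$length_hist[nz]),
                       lengths_path, sep = "\t")
  }
  invisible(c(counts_path, lengths_path))
}

#' Read per-bin counts written by [write_counts()]
#'
#' @param counts_path,lengths_path TSV paths; `lengths_path` may be `NULL`
#'   (empty histogram).
#' @param sample_id sample identifier.
#' @return a `binned_counts`.
#' @export
read_counts <- function(counts_path, lengths_path = NULL, sample_id = "sample") {
  df <- data.table::fread(counts_path, data.table = FALSE)
  hist <- numeric(diff(LENGTH_WINDOW) + 1L)
  if (!is.null(lengths_path) && file.exists(lengths_path)) {
    lh <- data.table::fread(lengths_path, data.table = FALSE)
    keep <- lh$length >= LENGTH_WINDOW[1L] & lh$length <= LENGTH_WINDOW[2L]
    hist[lh$length[keep] - LENGTH_WINDOW[1L] + 1L] <- lh$count[keep]
  }
  new_binned_counts(sample_id, df$short, df$long, hist)
}

# lengths histogram helpers: tabulate raw lengths / expand histogram
lengths_to_hist <- function(lengths) {
  lengths <- round(lengths)
  keep <- lengths >= LENGTH_WINDOW[1L] & lengths <= LENGTH_WINDOW[2L]
  tabulate(lengths[keep] - LENGTH_WINDOW[1L] + 1L, nbins = diff(LENGTH_WINDOW) + 1L)
}
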