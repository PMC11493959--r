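#' @importFrom stats approx dnorm lowess median predict pt rbeta rbinom
#'   rmultinom rnorm rpois runif sd cor setNames ave filter
#' @importFrom utils head tail
NULL

# package-local cache (memoizes the canonical tiling)
.delfi_cache <- new.env(parent = emptyenv())

delfi_error <- function(msg, class) {
  stop(structure(class = c(class, "delfi_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Build a reference tiling of fixed-width genomic bins
#'
#' Tiles each autosome given in `chrom_sizes` into adjacent, non-overlapping
#' `bin_width`-bp bins (0-based, half-open BED coordinates), removes every bin
#' that intersects an exclusion interval, assigns each surviving bin to a
#' chromosome arm, and groups runs of `bins_per_group` consecutive bins on the
#' same arm into larger regions (5-Mb groups at the defaults). Bins left over
#' at the end of an arm that cannot complete a full group carry `group5mb = NA`.
#'
#' @param chrom_sizes data.frame with columns `chrom`, `size` (bp).
#' @param exclusions data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), sorted by start within chromosome and non-overlapping, or
#'   `NULL` for no exclusions.
#' @param gc per-bin GC fractions: `NULL` (a smooth deterministic synthetic
#'   surrogate is used), a function of `(chrom, start, end)` returning a
#'   fraction per bin, or a data.frame with columns `chrom`, `start`, `gc`.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`, or
#'   `NULL`, in which case each chromosome is a single arm named after it.
#' @param bin_width bin width in bp (default 100 kb).
#' @param bins_per_group number of consecutive bins per group (default 50,
#'   i.e. 5 Mb of retained sequence).
#' @return A `delfi_tiling`: a tibble of bins with columns `bin_id`, `chrom`,
#'   `start`, `end`, `gc`, `arm`, `group5mb`, with attributes `arms` (arm
#'   labels in order) and `exclusions`.
#' @export
build_tiling <- function(chrom_sizes, exclusions = NULL, gc = NULL,
                         centromeres = NULL, bin_width = 100000L,
                         bins_per_group = 50L) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "size") %in% names(chrom_sizes)))
  chrom_sizes$chrom <- as.character(chrom_sizes$chrom)
  if (anyDuplicated(chrom_sizes$chrom))
    delfi_error("duplicate chromosomes in chrom_sizes", "delfi_validation_error")

  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    exclusions <- as.data.frame(exclusions)[, c("chrom", "start", "end")]
    exclusions$chrom <- as.character(exclusions$chrom)
    if (any(!exclusions$chrom %in% chrom_sizes$chrom))
      delfi_error("exclusion interval on a chromosome absent from chrom_sizes",
                  "delfi_validation_error")
    if (any(exclusions$start >= exclusions$end))
      delfi_error("exclusion interval with start >= end", "delfi_validation_error")
    for (ch in unique(exclusions$chrom)) {
      e <- exclusions[exclusions$chrom == ch, ]
      if (is.unsorted(e$start, strictly = TRUE) && nrow(e) > 1L)
        delfi_error(sprintf("exclusions on %s are not sorted", ch),
                    "delfi_validation_error")
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        delfi_error(sprintf("overlapping exclusions on %s", ch),
                    "delfi_validation_error")
    }
  } else {
    exclusions <- data.frame(chrom = character(), start = integer(), end = integer())
  }

  bins <- do.call(rbind, lapply(seq_len(nrow(chrom_sizes)), function(i) {
    ch <- chrom_sizes$chrom[i]
    n_full <- chrom_sizes$size[i] %/% bin_width
    if (n_full == 0L) return(NULL)
    start <- as.numeric(seq_len(n_full) - 1L) * bin_width
    data.frame(chrom = ch, start = start, end = start + bin_width)
  }))
  if (is.null(bins) || nrow(bins) == 0L)
    delfi_error("no bins: every chromosome shorter than one bin", "delfi_validation_error")

  # drop bins intersecting an exclusion (merged+sorted intervals per chrom)
  keep <- rep(TRUE, nrow(bins))
  for (ch in unique(exclusions$chrom)) {
    e <- exclusions[exclusions$chrom == ch, ]
    sel <- bins$chrom == ch
    idx <- findInterval(bins$start[sel], e$start)
    hit <- (idx >= 1L & bins$start[sel] < e$end[pmax(idx, 1L)]) |
           (idx < nrow(e) & e$start[pmin(idx + 1L, nrow(e))] < bins$end[sel])
    keep[sel][hit] <- FALSE
  }
  bins <- bins[keep, , drop = FALSE]
  if (nrow(bins) == 0L) delfi_error("no bins survive the exclusions", "delfi_validation_error")

  # arm assignment by bin midpoint relative to the centromere
  mid <- (bins$start + bins$end) / 2
  base <- sub("^chr", "", bins$chrom)
  if (!is.null(centromeres)) {
    centromeres <- as.data.frame(centromeres)
    cs <- setNames(centromeres$start, as.character(centromeres$chrom))
    ce <- setNames(centromeres$end, as.character(centromeres$chrom))
    has_cen <- bins$chrom %in% names(cs)
    arm <- base
    cenmid <- (cs[bins$chrom] + ce[bins$chrom]) / 2
    arm[has_cen] <- paste0(base, ifelse(mid < cenmid, "p", "q"))[has_cen]
  } else {
    arm <- base
  }
  bins$arm <- arm

  # gc fractions
  if (is.null(gc)) {
    bins$gc <- synthetic_gc(bins$chrom, bins$start, bins$end)
  } else if (is.function(gc)) {
    bins$gc <- gc(bins$chrom, bins$start, bins$end)
  } else {
    gdf <- as.data.frame(gc)
    key <- paste(bins$chrom, bins$start)
    m <- match(key, paste(gdf$chrom, gdf$start))
    if (anyNA(m))
      delfi_error("gc table is missing values for some bins", "delfi_validation_error")
    bins$gc <- gdf$gc[m]
  }
  if (any(!is.finite(bins$gc)) || any(bins$gc < 0 | bins$gc > 1))
    delfi_error("gc fractions must lie in [0, 1]", "delfi_validation_error")

  # order, ids, grouping: runs of bins_per_group consecutive retained bins per arm
  ord <- order(match(bins$chrom, chrom_sizes$chrom), bins$start)
  bins <- bins[ord, , drop = FALSE]
  bins$bin_id <- seq_len(nrow(bins))
  arm_rle <- factor(bins$arm, levels = unique(bins$arm))
  within_arm <- stats::ave(seq_len(nrow(bins)), arm_rle, FUN = seq_along)
  n_arm <- stats::ave(seq_len(nrow(bins)), arm_rle, FUN = length)
  local_grp <- ifelse(within_arm <= (n_arm %/% bins_per_group) * bins_per_group,
                      (within_arm - 1L) %/% bins_per_group + 1L, NA_integer_)
  # sequential global group ids in bin order
  gkey <- ifelse(is.na(local_grp), NA, paste(bins$arm, local_grp))
  ug <- unique(gkey[!is.na(gkey)])
  bins$group5mb <- match(gkey, ug)

  out <- tibble::as_tibble(bins[, c("bin_id", "chrom", "start", "end", "gc", "arm", "group5mb")])
  attr(out, "arms") <- unique(bins$arm)
  attr(out, "exclusions") <- tibble::as_tibble(exclusions)
  attr(out, "bin_width") <- as.integer(bin_width)
  attr(out, "bins_per_group") <- as.integer(bins_per_group)
  class(out) <- c("delfi_tiling", class(out))
  validate_tiling(out)
}

#' Validate a reference tiling
#'
#' Checks the structural invariants: fixed bin width, sorted non-overlapping
#' bins, GC fractions in \[0, 1\], and complete single-arm groups of
#' `bins_per_group` consecutive bins. Returns the tiling invisibly on success
#' and raises a classed validation error otherwise.
#'
#' @param tiling a `delfi_tiling`.
#' @return the tiling, invisibly.
#' @export
validate_tiling <- function(tiling) {
  bw <- attr(tiling, "bin_width") %||% 100000L
  bpg <- attr(tiling, "bins_per_group") %||% 50L
  if (nrow(tiling) == 0L) delfi_error("no bins", "delfi_validation_error")
  if (!identical(tiling$bin_id, seq_len(nrow(tiling))))
    delfi_error("bin_id must be 1..n in order", "delfi_validation_error")
  if (any(tiling$end - tiling$start != bw))
    delfi_error(sprintf("every bin must span exactly %d bp", bw), "delfi_validation_error")
  for (ch in unique(tiling$chrom)) {
    s <- tiling$start[tiling$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      delfi_error(sprintf("bins on %s are unsorted or overlapping", ch),
                  "delfi_validation_error")
  }
  if (any(!is.finite(tiling$gc)) || any(tiling$gc < 0 | tiling$gc > 1))
    delfi_error("gc fractions must lie in [0, 1]", "delfi_validation_error")
  grp <- tiling$group5mb[!is.na(tiling$group5mb)]
  if (length(grp)) {
    tab <- table(grp)
    if (any(tab != bpg))
      delfi_error(sprintf("every group must contain exactly %d bins", bpg),
                  "delfi_validation_error")
    arms_per_group <- tapply(tiling$arm[!is.na(tiling$group5mb)], grp,
                             function(a) length(unique(a)))
    if (any(arms_per_group != 1L))
      delfi_error("a group spans more than one arm", "delfi_validation_error")
    # contiguity: a group's bins are consecutive among retained bins of its arm
    for (a in unique(tiling$arm)) {
      g <- tiling$group5mb[tiling$arm == a]
      gg <- g[!is.na(g)]
      if (length(gg) && any(diff(which(!is.na(g))) != 1L))
        delfi_error(sprintf("grouped bins on arm %s are not contiguous", a),
                    "delfi_validation_error")
    }
  }
  invisible(tiling)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of 5-Mb groups in a tiling
#' @param tiling a `delfi_tiling`.
#' @return integer count of distinct groups.
#' @export
n_groups <- function(tiling) length(unique(tiling$group5mb[!is.na(tiling$group5mb)]))

#' Deterministic synthetic per-bin GC fractions
#'
#' A smooth, fully deterministic surrogate for precomputed per-bin GC content:
#' a sum of sinusoids of the bin midpoint with chromosome-specific phases,
#' clamped to \[0.30, 0.62\]. It emulates the megabase-scale autocorrelation of
#' real GC content so that GC-correction has realistic structure to remove;
#' it is synthetic and carries no sequence information.
#'
#' @param chrom,start,end vectors of bin coordinates.
#' @return numeric vector of GC fractions.
#' @export
synthetic_gc <- function(chrom, start, end) {
  ci <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  ci[is.na(ci)] <- 23
  mid <- (start + end) / 2
  gc <- 0.42 + 0.06 * sin(2 * pi * mid / 2.3e7 + ci) +
    0.035 * sin(2 * pi * mid / 3.1e6 + 2 * ci) +
    0.015 * sin(mid / 9.0e4 + 3 * ci)
  pmin(pmax(gc, 0.30), 0.62)
}

#' Write a tiling to a tab-separated file
#'
#' Columns `bin_id chrom start end gc arm group5mb`; GC is printed with 17
#' significant digits so that a write/load round trip is bit-exact.
#'
#' @param tiling a `delfi_tiling`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiling <- function(tiling, path) {
  df <- as.data.frame(tiling)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$gc <- sprintf("%.17g", df$gc)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Load and validate a tiling file
#'
#' Reads the tab-separated format written by [write_tiling()] and validates
#' every tiling invariant before returning.
#'
#' @param path tiling file path.
#' @param bin_width,bins_per_group expected geometry (defaults 100 kb / 50).
#' @return a validated `delfi_tiling`.
#' @export
load_tiling <- function(path, bin_width = 100000L, bins_per_group = 50L) {
  if (!file.exists(path)) delfi_error(paste("tiling file not found:", path),
                                      "delfi_io_error")
  df <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      colClasses = list(character = c("chrom", "arm"))),
    error = function(e) delfi_error(paste("malformed tiling file:", conditionMessage(e)),
                                    "delfi_parse_error"))
  need <- c("bin_id", "chrom", "start", "end", "gc", "arm", "group5mb")
  if (nrow(df) == 0L) delfi_error("no bins", "delfi_parse_error")
  if (!all(need %in% names(df)))
    delfi_error("tiling file lacks required columns", "delfi_parse_error")
  if (anyDuplicated(df$bin_id))
    delfi_error("duplicate bin_ids in tiling file", "delfi_parse_error")
  out <- tibble::as_tibble(df[, need])
  out$group5mb <- as.integer(out$group5mb)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  attr(out, "arms") <- unique(out$arm)
  attr(out, "exclusions") <- tibble::tibble(chrom = character(), start = integer(),
                                            end = integer())
  attr(out, "bin_width") <- as.integer(bin_width)
  attr(out, "bins_per_group") <- as.integer(bins_per_group)
  class(out) <- c("delfi_tiling", class(out))
  validate_tiling(out)
  out
}

#' Miniature synthetic tiling for fast tests and examples
#'
#' Two synthetic 51-Mb chromosomes with a 1-Mb excluded centromere each:
#' 1,000 bins of 100 kb on 4 arms, forming 20 complete 5-Mb groups.
#'
#' @return a `delfi_tiling` with 1,000 bins.
#' @export
mini_tiling <- function() {
  if (!is.null(.delfi_cache$mini)) return(.delfi_cache$mini)
  sizes <- data.frame(chrom = c("chr1", "chr2"), size = c(51e6, 51e6))
  cen <- data.frame(chrom = c("chr1", "chr2"), start = c(25e6, 25e6), end = c(26e6, 26e6))
  t <- build_tiling(sizes, exclusions = cen, centromeres = cen)
  .delfi_cache$mini <- t
  t
}
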