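# hg19 autosome constants: chromosome sizes and centromere gap intervals
# (UCSC hg19 gap table, type "centromere"; 0-based half-open).

hg19_chrom_sizes <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    size = c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
             159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
             115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
             59128983, 63025520, 48129895, 51304566))
}

hg19_centromeres <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    start = c(121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
              58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
              16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
              24681782, 26369569, 11288129, 13000000),
    end = c(124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
            61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
            19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
            27681782, 29369569, 14288129, 16000000))
}

# arms never scored: the short arms of the acrocentric chromosomes
acrocentric_p_arms <- c("13p", "14p", "15p", "21p", "22p")

merge_intervals <- function(df) {
  df <- df[order(df$chrom, df$start), ]
  out <- do.call(rbind, lapply(split(df, df$chrom), function(e) {
    if (nrow(e) <= 1L) return(e)
    keep_start <- e$start
    keep_end <- e$end
    j <- 1L
    for (i in 2:nrow(e)) {
      if (e$start[i] <= keep_end[j]) {
        keep_end[j] <- max(keep_end[j], e$end[i])
      } else {
        j <- j + 1L
        keep_start[j] <- e$start[i]
        keep_end[j] <- e$end[i]
      }
    }
    data.frame(chrom = e$chrom[1L], start = keep_start[seq_len(j)],
               end = keep_end[seq_len(j)])
  }))
  rownames(out) <- NULL
  out[order(match(out$chrom, paste0("chr", 1:22)), out$start), ]
}

# Allocate per-arm retained-bin targets so that the totals hit the canonical
# bin and group counts exactly: start from proportional removal, then shuffle
# single bins between arms (changing only group remainders) until the group
# count matches. Deterministic; no randomness.
allocate_arm_targets <- function(m, total_target, groups_target, bpg = 50L) {
  if (sum(m) < total_target)
    delfi_error("base tiling has fewer bins than the canonical target",
                "delfi_validation_error")
  d <- sum(m) - total_target
  rem <- as.integer(floor(m * d / sum(m)))
  short <- d - sum(rem)
  ord <- order(-m, names(m))
  if (short > 0L) rem[ord[seq_len(short)]] <- rem[ord[seq_len(short)]] + 1L
  n <- m - rem
  for (iter in seq_len(10000L)) {
    G <- sum(n %/% bpg)
    if (G == groups_target) break
    if (G > groups_target) {
      from <- which(n %% bpg == 0L & n > 0L)
      to <- which(n %% bpg < (bpg - 1L) & n < m)
    } else {
      from <- which(n %% bpg >= 1L)
      to <- which(n %% bpg == (bpg - 1L) & n < m)
    }
    to <- setdiff(to, from[1L])
    if (!length(from) || !length(to))
      delfi_error("cannot reconcile bin and group targets", "delfi_validation_error")
    n[from[1L]] <- n[from[1L]] - 1L
    n[to[1L]] <- n[to[1L]] + 1L
  }
  if (sum(n %/% bpg) != groups_target)
    delfi_error("group target not reached", "delfi_validation_error")
  n
}

#' Canonical hg19 autosome tiling
#'
#' Constructs the packaged reference tiling of the 22 hg19 autosomes:
#' 26,236 non-overlapping 100-kb bins grouped into 504 5-Mb regions across the
#' 39 scored chromosome arms (all arms except the acrocentric short arms 13p,
#' 14p, 15p, 21p and 22p). Exclusions are assembled from hg19 gap annotations
#' (telomeres, centromeres, acrocentric p-arms) plus additional 100-kb
#' intervals placed by a deterministic allocation so the canonical counts hold
#' exactly; the additional intervals play the role of a low-mappability /
#' blacklist mask. Per-bin GC fractions come from [synthetic_gc()] and are
#' synthetic. The construction is deterministic and cached per session.
#'
#' @return a validated `delfi_tiling` with exactly 26,236 bins, 504 groups and
#'   39 arms.
#' @export
hg19_tiling <- function() {
  if (!is.null(.delfi_cache$hg19)) return(.delfi_cache$hg19)
  sizes <- hg19_chrom_sizes()
  cen <- hg19_centromeres()
  telo <- 10000L
  base_excl <- rbind(
    cen,
    data.frame(chrom = sizes$chrom, start = 0L, end = telo),
    data.frame(chrom = sizes$chrom, start = sizes$size - telo, end = sizes$size),
    # acrocentric p-arms are dropped entirely
    data.frame(chrom = paste0("chr", c(13, 14, 15, 21, 22)), start = 0L,
               end = cen$start[match(paste0("chr", c(13, 14, 15, 21, 22)), cen$chrom)]))
  base_excl <- merge_intervals(base_excl)
  base <- build_tiling(sizes, exclusions = base_excl, centromeres = cen)

  arm_order <- unique(base$arm)
  m <- setNames(as.integer(table(factor(base$arm, levels = arm_order))), arm_order)
  n <- allocate_arm_targets(m, total_target = 26236L, groups_target = 504L)

  # remove (m - n) evenly spaced bins within each arm; removed bins become
  # additional exclusion intervals
  extra <- do.call(rbind, lapply(arm_order, function(a) {
    k <- m[[a]] - n[[a]]
    if (k == 0L) return(NULL)
    b <- base[base$arm == a, ]
    idx <- unique(pmin(nrow(b), pmax(1L, round((seq_len(k) - 0.5) * nrow(b) / k))))
    if (length(idx) != k)
      delfi_error("exclusion placement collision", "delfi_validation_error")
    data.frame(chrom = b$chrom[idx], start = b$start[idx], end = b$end[idx])
  }))
  excl <- merge_intervals(rbind(base_excl, extra))
  tiling <- build_tiling(sizes, exclusions = excl, centromeres = cen)

  stopifnot(nrow(tiling) == 26236L, n_groups(tiling) == 504L,
            length(attr(tiling, "arms")) == 39L,
            !any(attr(tiling, "arms") %in% acrocentric_p_arms))
  .delfi_cache$hg19 <- tiling
  tiling
}
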