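#' Pairwise linkage disequilibrium (r-squared)
#'
#' Composite LD: the squared Pearson correlation of genotype dosage codes.
#' Invariant to allele relabeling (2 - x).
#'
#' @param g1,g2 numeric dosage vectors of equal length >= 3.
#' @return r^2 in \[0, 1\].
#' @export
pairwise_ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2), length(g1) >= 3L)
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("monomorphic marker: LD undefined")
  stats::cor(g1, g2)^2
}

#' LD decay profile and decay distance
#'
#' Mean r^2 per physical-distance bin over all intra-chromosomal marker pairs
#' within `max_dist`, plus the decay distance: the smallest bin midpoint at
#' which the monotone-smoothed (cumulative-minimum) mean r^2 falls below
#' `threshold`.
#'
#' @param G `GenotypeMatrix`.
#' @param max_dist maximum pair distance in bp (default 500000, i.e. a 500-kb
#'   window).
#' @param bin bin width in bp (default 1000).
#' @param threshold decay threshold on mean r^2 (default 0.1).
#' @return list with `profile` (data.frame `dist_mid`, `mean_r2`, `n_pairs`)
#'   and `decay_distance` (bp, NA if the profile never drops below the
#'   threshold).
#' @export
ld_decay_profile <- function(G, max_dist = 500000, bin = 1000, threshold = 0.1) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(G$map$chrom)) {
    sel <- which(G$map$chrom == ch)
    if (length(sel) < 2L) next
    pos <- G$map$pos[sel]
    codes <- G$codes[, sel, drop = FALSE]
    cc <- suppressWarnings(stats::cor(codes))
    pd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(pd)
    keep <- ut & pd <= max_dist & is.finite(cc)
    dists <- c(dists, pd[keep])
    r2s <- c(r2s, cc[keep]^2)
  }
  if (!length(dists)) return(list(profile = data.frame(dist_mid = numeric(0),
                                                       mean_r2 = numeric(0),
                                                       n_pairs = integer(0)),
                                  decay_distance = NA_real_))
  b <- pmin(floor(dists / bin), floor(max_dist / bin) - 1)
  mean_r2 <- tapply(r2s, b, mean)
  n_pairs <- tapply(r2s, b, length)
  mids <- (as.numeric(names(mean_r2)) + 0.5) * bin
  smoothed <- cummin(as.numeric(mean_r2))
  below <- which(smoothed < threshold)
  decay <- if (length(below)) mids[below[1]] else NA_real_
  list(profile = data.frame(dist_mid = mids, mean_r2 = as.numeric(mean_r2),
                            n_pairs = as.integer(n_pairs)),
       decay_distance = decay)
}

#' LD boundaries of a focal SNP
#'
#' Scans outward from the focal SNP over neighboring markers on the same
#' chromosome; in each direction the boundary is the position of the last
#' marker before r^2 with the focal SNP first drops below `threshold`
#' (one-pass: LD recovering above the threshold further out is not
#' re-entered). If r^2 never drops, the boundary is the chromosome's terminal
#' marker position.
#'
#' @param G `GenotypeMatrix`.
#' @param snp_id focal marker id.
#' @param threshold r^2 threshold (default 0.1).
#' @return numeric `c(start, end)` in bp; always contains the focal position.
#' @export
ld_boundaries <- function(G, snp_id, threshold = 0.1) {
  i <- match(snp_id, G$map$marker)
  if (is.na(i)) stop("unknown SNP: ", snp_id)
  ch <- G$map$chrom[i]
  sel <- which(G$map$chrom == ch)
  j <- match(i, sel)
  pos <- G$map$pos[sel]
  focal <- G$codes[, sel[j]]
  if (stats::var(focal) == 0) stop("focal SNP is monomorphic")
  scan_dir <- function(idx_seq) {
    last <- pos[j]
    for (jj in idx_seq) {
      v <- G$codes[, sel[jj]]
      r2 <- if (stats::var(v) == 0) 0 else stats::cor(focal, v)^2
      if (r2 < threshold) return(last)
      last <- pos[jj]
    }
    last  # never dropped: chromosome terminal marker
  }
  up <- if (j > 1L) scan_dir((j - 1L):1L) else pos[j]
  down <- if (j < length(sel)) scan_dir((j + 1L):length(sel)) else pos[j]
  c(start = up, end = down)
}

#' Merge per-SNP LD intervals into independent QTL regions
#'
#' Single-linkage merge, within each chromosome, of significant-SNP intervals
#' that overlap or whose peak SNP positions are less than `merge_dist` apart
#' (strict <). The merged interval is the union span; the lead SNP is the
#' member with the smallest p (ties broken by smaller position).
#'
#' @param significant data.frame with columns `snp`, `chrom`, `pos`, `p`,
#'   `start`, `end` (per-SNP LD interval from [ld_boundaries()]).
#' @param merge_dist peak-SNP merge distance in bp (default 50000).
#' @return data.frame of QTL intervals: `chrom`, `start`, `end`, `lead_snp`,
#'   `lead_p`, `n_snps`, `member_snps` (comma-joined).
#' @export
merge_qtl_intervals <- function(significant, merge_dist = 50000) {
  if (nrow(significant) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      lead_snp = character(0), lead_p = numeric(0),
                      n_snps = integer(0), member_snps = character(0),
                      stringsAsFactors = FALSE))
  stopifnot(all(c("snp", "chrom", "pos", "p", "start", "end") %in% names(significant)))
  out <- list()
  for (ch in unique(significant$chrom)) {
    d <- significant[significant$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    n <- nrow(d)
    # union-find over the linkage relation
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
      overlap <- d$start[a] <= d$end[b] && d$start[b] <= d$end[a]
      near <- abs(d$pos[a] - d$pos[b]) < merge_dist
      if (overlap || near) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    comp <- vapply(seq_len(n), find, 1L)
    for (g in unique(comp)) {
      m <- d[comp == g, , drop = FALSE]
      lead <- m[order(m$p, m$pos), ][1, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(m$start), end = max(m$end),
        lead_snp = lead$snp, lead_p = lead$p, n_snps = nrow(m),
        member_snps = paste(m$snp[order(m$pos)], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Build QTL intervals from a significant-SNP association table
#'
#' Convenience wrapper: per-SNP LD boundaries then interval merging.
#'
#' @param assoc data.frame with columns `feature` (SNP id) and `p`,
#'   significant rows only.
#' @param G `GenotypeMatrix` supplying map and LD.
#' @param ld_threshold r^2 boundary threshold (default 0.1).
#' @param merge_dist peak merge distance (default 50000).
#' @return QTL interval table as from [merge_qtl_intervals()].
#' @export
qtl_intervals <- function(assoc, G, ld_threshold = 0.1, merge_dist = 50000) {
  if (nrow(assoc) == 0L) {
    return(merge_qtl_intervals(data.frame(snp = character(0), chrom = character(0),
                                          pos = integer(0), p = numeric(0),
                                          start = integer(0), end = integer(0))))
  }
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    snp <- assoc$feature[i]
    j <- match(snp, G$map$marker)
    bb <- ld_boundaries(G, snp, threshold = ld_threshold)
    data.frame(snp = snp, chrom = G$map$chrom[j], pos = G$map$pos[j],
               p = assoc$p[i], start = bb[["start"]], end = bb[["end"]],
               stringsAsFactors = FALSE)
  })
  merge_qtl_intervals(do.call(rbind, rows), merge_dist = merge_dist)
}

#' Classify an eQTL as local or distant
#'
#' Local iff the eQTL and the gene are on the same chromosome and either
#' overlap or the gap between the eQTL interval and the gene interval is at
#' most `window` bp (inclusive); otherwise distant.
#'
#' @param eqtl list/row with `chrom`, `start`, `end` (1-based inclusive).
#' @param gene list/row with `chrom`, `start`, `end`.
#' @param window proximity window in bp (default 50000).
#' @return `"local"` or `"distant"`.
#' @export
classify_eqtl <- function(eqtl, gene, window = 50000) {
  if (eqtl$chrom != gene$chrom) return("distant")
  if (eqtl$start <= gene$end && gene$start <= eqtl$end) return("local")  # overlap
  # distance between the facing interval ends ("end within 50 kb upstream",
  # "start within 50 kb downstream")
  gap <- if (eqtl$end < gene$start) gene$start - eqtl$end
         else eqtl$start - gene$end
  if (gap <= window) "local" else "distant"
}

#' Distant-eQTL hotspot scan
#'
#' Sliding windows of width `window` (step `window/2`) along each chromosome;
#' each window's event count is tested against a Poisson null with rate equal
#' to the genome-wide event density times the window width. Window p values
#' are BH-adjusted and significant overlapping windows are merged into maximal
#' hotspot regions.
#'
#' @param events data.frame with columns `chrom`, `pos` (distant-eQTL lead
#'   positions).
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window window width in bp (default 100000).
#' @param signif significance level on the adjusted p (default 0.01).
#' @return data.frame of hotspot regions: `chrom`, `start`, `end`,
#'   `event_count`, `min_p_adj`.
#' @export
detect_hotspots <- function(events, chrom_sizes, window = 100000,
                            signif = 0.01) {
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      event_count = integer(0), min_p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0L) return(empty)
  stopifnot(all(events$chrom %in% names(chrom_sizes)))
  total_len <- sum(chrom_sizes[unique(events$chrom)])
  rate <- nrow(events) / total_len  # events per bp, genome-wide background
  wins <- list()
  for (ch in unique(events$chrom)) {
    L <- chrom_sizes[[ch]]
    starts <- seq(1, max(1, L - window + 1), by = window / 2)
    pos <- events$pos[events$chrom == ch]
    cnt <- vapply(starts, function(s) sum(pos >= s & pos <= s + window - 1), 1L)
    wins[[ch]] <- data.frame(chrom = ch, start = starts,
                             end = pmin(starts + window - 1, L),
                             count = cnt, stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, wins)
  w$p <- stats::ppois(w$count - 1, lambda = rate * window, lower.tail = FALSE)
  w$p_adj <- stats::p.adjust(w$p, method = "BH")
  sig <- w[w$p_adj < signif & w$count > 0, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    d <- sig[sig$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cur <- d[1, ]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur$end + 1) {
        cur$end <- max(cur$end, d$end[i])
        cur$p_adj <- min(cur$p_adj, d$p_adj[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- d[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  reg <- do.call(rbind, out)
  pos_all <- events
  reg$event_count <- vapply(seq_len(nrow(reg)), function(i) {
    sum(pos_all$chrom == reg$chrom[i] &
          pos_all$pos >= reg$start[i] & pos_all$pos <= reg$end[i])
  }, 1L)
  data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
             event_count = reg$event_count, min_p_adj = reg$p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}
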