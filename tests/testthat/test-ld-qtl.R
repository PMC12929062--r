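test_that("pairwise r2 is a squared correlation, flip-invariant", {
  set.seed(17)
  g1 <- rbinom(8, 2, 0.5)
  while (var(g1) == 0) g1 <- rbinom(8, 2, 0.5)
  expect_equal(pairwise_ld_r2(g1, g1), 1)
  expect_equal(pairwise_ld_r2(g1, 2 - g1), 1)
  g2 <- c(0, 1, 2, 0, 1, 2, 0, 2)
  expect_equal(pairwise_ld_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  expect_error(pairwise_ld_r2(g1, rep(1, 8)), "monomorphic")
})

test_that("LD decay distance tracks the simulated block length", {
  decays <- sapply(1:10, function(i) {
    G <- simulate_genotypes(n_genotypes = 120, n_markers = 300, n_chrom = 1,
                            chrom_len = 1e6, ld_block_len = 10000, seed = 20 + i)
    ld_decay_profile(G, max_dist = 100000, bin = 2500)$decay_distance
  })
  expect_true(all(decays >= 5000 & decays <= 20000))
})

test_that("unlinked markers show the 1/(n-1) null r2 and immediate decay", {
  G <- unlinked_panel(n = 60, m = 150, seed = 23)
  prof <- ld_decay_profile(G, max_dist = 2e6, bin = 2e5)
  expect_lt(abs(mean(prof$profile$mean_r2) - 1 / 59), 0.01)
  expect_equal(prof$decay_distance, prof$profile$dist_mid[1])
  # two markers -> one pair, one bin
  G2 <- G; G2$codes <- G$codes[, 1:2]; G2$map <- G$map[1:2, ]
  p2 <- ld_decay_profile(G2, max_dist = 1e8, bin = 1e8)
  expect_equal(sum(p2$profile$n_pairs), 1L)
})

test_that("LD boundaries follow the one-pass first-drop rule", {
  # 7-marker chromosome engineered around the focal SNP (index 4):
  # left r2 pattern (0.9, 0.5, 0.05), right (0.8, 0.09, 0.9): the later
  # high-LD markers must NOT re-open the interval
  set.seed(24)
  n <- 400
  focal <- rbinom(n, 2, 0.5)
  mk <- function(rho, s) corr_neighbor(focal, rho, s)
  codes <- cbind(m1 = mk(0.12, 1), m2 = mk(0.75, 2), m3 = mk(0.95, 3),
                 focal = focal, m5 = mk(0.9, 5), m6 = mk(0.12, 6),
                 m7 = mk(0.95, 7))
  rownames(codes) <- paste0("s", seq_len(n))
  r2 <- apply(codes, 2, function(v) cor(focal, v)^2)
  # the engineered pattern must bracket the 0.1 threshold as intended:
  # high LD adjacent (m3, m2 | m5), sub-threshold beyond (m1 | m6), and a
  # high-LD marker (m7) beyond the first drop that must NOT re-open
  expect_true(all(r2[c("m2", "m3", "m5", "m7")] > 0.1))
  expect_true(all(r2[c("m1", "m6")] < 0.1))
  map <- data.frame(marker = colnames(codes), chrom = "A01",
                    pos = seq(1000, by = 1000, length.out = 7))
  G <- new_genotype_matrix(codes, map, recode_minor = FALSE)
  b <- ld_boundaries(G, "focal", threshold = 0.1)
  # hand enumeration: left walk stops at m1 -> boundary m2 (2000);
  # right walk stops at m6 -> boundary m5 (5000), despite m7's high LD
  expect_equal(unname(b["start"]), 2000)
  expect_equal(unname(b["end"]), 5000)
  expect_true(b["start"] <= map$pos[4] && b["end"] >= map$pos[4])

  # immediate drop on both sides pins the interval to the focal position
  codes2 <- cbind(lo1 = mk(0.01, 11), focal = focal, lo2 = mk(0.02, 12))
  rownames(codes2) <- paste0("s", seq_len(n))
  G2 <- new_genotype_matrix(codes2, data.frame(marker = colnames(codes2),
                                               chrom = "A01",
                                               pos = c(100, 200, 300)),
                            recode_minor = FALSE)
  if (cor(codes2[, 1], focal)^2 < 0.1 && cor(codes2[, 3], focal)^2 < 0.1) {
    b2 <- ld_boundaries(G2, "focal")
    expect_equal(unname(b2), c(200, 200))
  }
  # perfect LD throughout -> chromosome-terminal boundaries
  codes3 <- cbind(a = focal, focal = focal, b = 2 - focal)
  rownames(codes3) <- paste0("s", seq_len(n))
  G3 <- new_genotype_matrix(codes3, data.frame(marker = colnames(codes3),
                                               chrom = "A01",
                                               pos = c(100, 200, 300)),
                            recode_minor = FALSE)
  expect_equal(unname(ld_boundaries(G3, "focal")), c(100, 300))
})

test_that("QTL merging reproduces the hand-enumerated 12-SNP partition", {
  snps <- data.frame(
    snp = paste0("S", 1:12),
    chrom = rep(c("chr1", "chr2"), each = 6),
    pos = c(100000, 130000, 200000, 205000, 300000, 349000,
            100000, 149999, 210000, 260000, 320000, 365000),
    p = c(1e-8, 1e-6, 1e-7, 1e-9, 1e-5, 1e-5,
          1e-4, 1e-5, 1e-6, 1e-3, 1e-2, 1e-7),
    start = c(90000, 120000, 190000, 195000, 250000, 340000,
              95000, 145000, 200000, 215000, 310000, 325000),
    end = c(110000, 140000, 210000, 215000, 310000, 360000,
            105000, 155000, 220000, 265000, 330000, 370000),
    stringsAsFactors = FALSE)
  q <- merge_qtl_intervals(snps, merge_dist = 50000)
  expect_equal(nrow(q), 6)
  expect_equal(q$lead_snp, c("S1", "S4", "S5", "S8", "S9", "S12"))
  expect_equal(q$start, c(90000, 190000, 250000, 95000, 200000, 310000))
  expect_equal(q$end, c(140000, 215000, 360000, 155000, 265000, 370000))
  expect_equal(q$n_snps, rep(2L, 6))
  # lead tie (S5/S6 both 1e-5) broken by smaller position
  expect_equal(q$lead_snp[3], "S5")

  # trivial distance rules
  two <- data.frame(snp = c("a", "b"), chrom = "c1", pos = c(100000, 140000),
                    p = c(1e-4, 1e-5), start = c(95000, 135000),
                    end = c(105000, 145000))
  expect_equal(nrow(merge_qtl_intervals(two)), 1)       # 40 kb apart
  two$pos[2] <- 160000; two$start[2] <- 155000; two$end[2] <- 165000
  expect_equal(nrow(merge_qtl_intervals(two)), 2)       # 60 kb apart
})

test_that("QTL merging is idempotent and order-invariant", {
  set.seed(25)
  for (rep_i in 1:10) {
    n <- 15
    pos <- sort(sample.int(2e6, n))
    snps <- data.frame(snp = paste0("x", 1:n), chrom = "c1", pos = pos,
                       p = runif(n, 1e-10, 1e-3),
                       start = pmax(1, pos - sample(1e4:8e4, n, TRUE)),
                       end = pos + sample(1e4:8e4, n, TRUE))
    q1 <- merge_qtl_intervals(snps)
    # idempotence: feed the merged intervals back through (as their lead SNPs)
    again <- data.frame(snp = q1$lead_snp, chrom = q1$chrom,
                        pos = snps$pos[match(q1$lead_snp, snps$snp)],
                        p = q1$lead_p, start = q1$start, end = q1$end)
    # order invariance
    q2 <- merge_qtl_intervals(snps[sample(n), ])
    expect_equal(q1$start, q2$start)
    expect_equal(q1$lead_snp, q2$lead_snp)
    # independent oracle: iterate pairwise merging until fixpoint
    merged <- split(seq_len(n), seq_len(n))
    repeat {
      changed <- FALSE
      for (a in seq_along(merged)) {
        if (changed) break
        for (b in seq_along(merged)) {
          if (a >= b) next
          ia <- merged[[a]]; ib <- merged[[b]]
          sa <- min(snps$start[ia]); ea <- max(snps$end[ia])
          sb <- min(snps$start[ib]); eb <- max(snps$end[ib])
          link <- (sa <= eb && sb <= ea) ||
            any(abs(outer(snps$pos[ia], snps$pos[ib], "-")) < 50000)
          if (link) {
            merged[[a]] <- c(ia, ib); merged[[b]] <- NULL; changed <- TRUE
            break
          }
        }
      }
      if (!changed) break
    }
    expect_equal(nrow(q1), length(merged))
  }
})

test_that("local/distant classification matches the 50-kb truth table", {
  W <- 50000
  gene <- list(chrom = "c1", start = 500000, end = 510000)
  cases <- list(
    list(e = list(chrom = "c2", start = 500000, end = 510000), want = "distant"),
    list(e = list(chrom = "c1", start = 505000, end = 520000), want = "local"),   # overlap
    list(e = list(chrom = "c1", start = 400000, end = 450001), want = "local"),   # 49,999 gap
    list(e = list(chrom = "c1", start = 400000, end = 449999), want = "distant"), # 50,001 gap
    list(e = list(chrom = "c1", start = 400000, end = 450000), want = "local"),   # exactly 50 kb
    list(e = list(chrom = "c1", start = 502000, end = 508000), want = "local"),   # nested
    list(e = list(chrom = "c1", start = 540000, end = 600000), want = "local"),   # 30 kb downstream
    list(e = list(chrom = "c1", start = 560001, end = 600000), want = "distant")  # 50,001 downstream
  )
  for (cs in cases) {
    expect_equal(classify_eqtl(cs$e, gene, window = W), cs$want)
    # orientation symmetry: swapping which interval is "gene" cannot matter
    expect_equal(classify_eqtl(cs$e, gene, window = W) == "local",
                 classify_eqtl(gene, cs$e, window = W) == "local")
  }
})

test_that("hotspot scan flags dense windows and stays quiet under the null", {
  expect_equal(nrow(detect_hotspots(data.frame(chrom = character(0),
                                               pos = numeric(0)),
                                    c(chr1 = 1e7))), 0)
  # 100 events packed in one 100-kb window over 20 background events
  set.seed(26)
  ev <- data.frame(chrom = "chr1",
                   pos = c(round(runif(100, 5e6, 5e6 + 99999)),
                           sample.int(1e7, 20)))
  h <- detect_hotspots(ev, c(chr1 = 1e7))
  expect_gte(nrow(h), 1)
  expect_true(any(h$start <= 5e6 & h$end >= 5e6 + 99999))
  # Poisson tail oracle for that window's raw p
  lam <- 120 / 1e7 * 1e5
  expect_lt(ppois(99, lam, lower.tail = FALSE), 1e-100)

  # uniform null: no hotspot in >= 95% of seeded runs
  quiet <- sapply(1:100, function(i) {
    set.seed(1200 + i)
    evn <- data.frame(chrom = "chr1", pos = sample.int(1e7, 200))
    nrow(detect_hotspots(evn, c(chr1 = 1e7))) == 0
  })
  expect_gte(mean(quiet), 0.95)
})

test_that("a planted trans hub is recovered across seeds", {
  found <- sapply(1:100, function(i) {
    set.seed(1300 + i)
    hub_start <- 4e6
    ev <- data.frame(chrom = "chr1",
                     pos = c(round(runif(50, hub_start, hub_start + 99999)),
                             sample.int(1e7, 50)))
    h <- detect_hotspots(ev, c(chr1 = 1e7))
    nrow(h) > 0 && any(h$start <= hub_start + 99999 & h$end >= hub_start)
  })
  expect_gte(mean(found), 0.95)
})
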