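# Quartiles, metaprofiles, distances, proximity tables, site overlap.

classified_fixture <- function(n, layout, seed = 1) {
  set.seed(seed)
  chrom <- sample(layout$chromosomes$name, n, replace = TRUE)
  len <- layout$chromosomes$length[match(chrom, layout$chromosomes$name)]
  mid <- floor(runif(n, 500, len - 500))
  data.frame(name = sprintf("o%03d", seq_len(n)), chrom = chrom,
             start = mid - 100, end = mid + 100,
             trep = runif(n, 5, 45),
             count_wt = 0, count_mut = 0, log2fc = 0, pvalue = 1, qvalue = 1,
             class = sample(c("Rif1-repressed", "Rif1-unregulated",
                              "Rif1-activated"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("quartile assignment follows rank order and the remainder rule", {
  origins <- data.frame(name = letters[1:8], chrom = "chrA",
                        start = 1:8 * 1000, end = 1:8 * 1000 + 100,
                        trep = c(30, 10, 20, 40, 5, 35, 15, 25),
                        stringsAsFactors = FALSE)
  q <- assign_trep_quartiles(origins)
  expect_equal(q[order(origins$trep)], rep(1:4, each = 2))

  nine <- data.frame(name = letters[1:9], chrom = "chrA",
                     start = 1:9, end = 2:10, trep = 9:1,
                     stringsAsFactors = FALSE)
  q9 <- assign_trep_quartiles(nine)
  expect_equal(as.integer(table(q9)), c(3L, 2L, 2L, 2L))  # extras go early
  expect_equal(q9[nine$trep == 1], 1L)

  # ties broken by name, verified against an explicit sort oracle
  tied <- data.frame(name = sprintf("n%02d", c(5, 3, 8, 1, 7, 2, 6, 4)),
                     chrom = "chrA", start = 1:8, end = 2:9,
                     trep = c(10, 10, 10, 10, 20, 20, 20, 20),
                     stringsAsFactors = FALSE)
  qt <- assign_trep_quartiles(tied)
  o <- order(tied$trep, tied$name)
  want <- integer(8); want[o] <- rep(1:4, each = 2)
  expect_equal(qt, want)

  expect_error(assign_trep_quartiles(origins[1:3, ]), "at least 4")
})

test_that("metaprofiles average per offset with edge-aware n", {
  layout <- tiny_layout(c(chrA = 100000))
  flat <- make_track(layout, list(chrA = rep(3.5, 2000)))
  one <- data.frame(name = "o1", chrom = "chrA", start = 49900, end = 50100,
                    stringsAsFactors = FALSE)
  prof <- metaprofile(flat, one, 5000)
  expect_equal(prof$mean, rep(3.5, 101))
  expect_equal(prof$offset_bp, seq(-2500, 2500, by = 50))
  expect_equal(prof$n, rep(1L, 101))

  # an origin 1 kb from the chromosome start loses left offsets only
  near_edge <- data.frame(name = c("e", "i"), chrom = "chrA",
                          start = c(900, 49900), end = c(1100, 50100),
                          stringsAsFactors = FALSE)
  prof2 <- metaprofile(flat, near_edge, 40000)
  expect_equal(prof2$n[prof2$offset_bp < -1000], rep(1L, sum(prof2$offset_bp < -1000)))
  expect_equal(prof2$n[prof2$offset_bp >= -1000], rep(2L, sum(prof2$offset_bp >= -1000)))

  # random group vs loop-and-average oracle
  set.seed(151)
  vals <- runif(2000)
  track <- make_track(layout, list(chrA = vals))
  grp <- data.frame(name = sprintf("g%d", 1:12), chrom = "chrA",
                    start = sort(floor(runif(12, 3000, 95000))),
                    stringsAsFactors = FALSE)
  grp$end <- grp$start + 200
  prof3 <- metaprofile(track, grp, 5000)
  offs <- -50:50
  want <- sapply(offs, function(o) {
    v <- sapply(seq_len(12), function(i) {
      b <- (floor((grp$start[i] + grp$end[i]) / 2)) %/% 50 + 1 + o
      if (b >= 1 && b <= 2000) vals[b] else NA
    })
    mean(v, na.rm = TRUE)
  })
  expect_equal(prof3$mean, want)
  expect_error(metaprofile(track, grp[0, ], 5000), "empty")
})

test_that("nearest distance uses edge-gap semantics and flags orphans", {
  q <- data.frame(chrom = "chrA", start = 99500, end = 100500)
  cen <- data.frame(chrom = "chrA", start = 150000, end = 150120)
  expect_equal(distance_to_nearest(q, cen), 49500)

  overlapping <- data.frame(chrom = "chrA", start = 100000, end = 100100)
  expect_equal(distance_to_nearest(q, overlapping), 0)

  orphan <- data.frame(chrom = "chrB", start = 1, end = 2)
  expect_true(is.na(distance_to_nearest(orphan, cen)))

  set.seed(161)
  qs <- random_intervals(c("chrA", "chrB"), 60, 2e5, 162)
  ls <- random_intervals(c("chrA", "chrC"), 25, 2e5, 163)
  expect_equal(distance_to_nearest(qs, ls), oracle_nearest_distance(qs, ls))
})

test_that("proximity counts apply the <= threshold boundary per class", {
  cen <- data.frame(chrom = "chrA", start = 150000, end = 150120)
  layout <- tiny_layout(c(chrA = 500000), centromeres = cen)
  # midpoints exactly 20 kb, just beyond, and far from the CEN edge
  classified <- data.frame(
    name = c("at", "past", "far"), chrom = "chrA",
    start = c(129999, 129998, 20000) - 100,
    end = c(129999, 129998, 20000) + 100,
    class = c("Rif1-repressed", "Rif1-repressed", "Rif1-activated"),
    stringsAsFactors = FALSE)
  # distance from midpoint m to CEN start s (half-open, 1 bp midpoint
  # interval): s - m - 1 = 20000 for m = 129999
  tab <- proximity_class_counts(classified, layout, "CEN", 20000)
  expect_equal(tab$within[tab$class == "Rif1-repressed"], 1)
  expect_equal(tab$beyond[tab$class == "Rif1-repressed"], 1)
  expect_equal(tab$within[tab$class == "Rif1-activated"], 0)
  expect_equal(tab$within + tab$beyond,
               unname(sapply(tab$class, function(k)
                 sum(classified$class == k))))

  # seeded random instance against a brute-force classification oracle
  layout2 <- genome_layout(
    data.frame(name = c("chrA", "chrB"), length = c(4e5, 3e5)),
    centromeres = data.frame(chrom = c("chrA", "chrB"),
                             start = c(2e5, 1e5), end = c(2e5, 1e5) + 120))
  cls <- classified_fixture(80, layout2, seed = 164)
  for (lm in c("CEN", "TEL")) {
    tab2 <- proximity_class_counts(cls, layout2, lm, 20000)
    lms <- if (lm == "CEN") layout2$centromeres else
      data.frame(chrom = rep(c("chrA", "chrB"), each = 2),
                 start = c(0, 4e5 - 1, 0, 3e5 - 1),
                 end = c(1, 4e5, 1, 3e5))
    mid <- floor((cls$start + cls$end) / 2)
    d <- oracle_nearest_distance(
      data.frame(chrom = cls$chrom, start = mid, end = mid + 1), lms)
    for (k in tab2$class) {
      expect_equal(tab2$within[tab2$class == k],
                   sum(d <= 20000 & cls$class == k))
    }
  }
})

test_that("class mean distances exclude landmark-proximal origins first", {
  cen <- data.frame(chrom = "chrA", start = 200000, end = 200120)
  layout <- tiny_layout(c(chrA = 500000), centromeres = cen)
  classified <- data.frame(
    name = sprintf("o%d", 1:6), chrom = "chrA",
    start = c(100000, 300000, 80000, 320000, 201000, 100) - 100,
    end = c(100000, 300000, 80000, 320000, 201000, 100) + 100,
    class = c("Rif1-repressed", "Rif1-repressed", "Rif1-unregulated",
              "Rif1-unregulated", "Rif1-unregulated", "Rif1-activated"),
    stringsAsFactors = FALSE)
  # o5 is pericentric, o6 subtelomeric: both excluded
  res <- mean_distance_by_class(classified, layout, 20000)
  expect_equal(res$n_excluded, 2L)
  s <- res$summary
  expect_equal(s$n[s$class == "Rif1-repressed"], 2L)
  expect_equal(s$n[s$class == "Rif1-unregulated"], 2L)
  expect_equal(s$n[s$class == "Rif1-activated"], 0L)
  expect_equal(s$mean_bp[s$class == "Rif1-repressed"],
               mean(c(200000 - 100000 - 1, 300000 - 200120 + 1 - 1)))

  # Welch t-test against a hand-set two-class case
  cls2 <- data.frame(
    name = sprintf("h%d", 1:4), chrom = "chrA",
    start = c(100000, 170000, 320120, 420120) - 100,
    end = c(100000, 170000, 320120, 420120) + 100,
    class = rep(c("Rif1-repressed", "Rif1-activated"), each = 2),
    stringsAsFactors = FALSE)
  res2 <- mean_distance_by_class(cls2, layout, 20000)
  d <- c(200000 - 100001, 200000 - 170001, 320120 - 200120, 420120 - 200120)
  # direct Welch computation as the oracle
  va <- d[1:2]; vb <- d[3:4]
  tstat <- (mean(va) - mean(vb)) /
    sqrt(var(va) / 2 + var(vb) / 2)
  df <- (var(va) / 2 + var(vb) / 2)^2 /
    ((var(va) / 2)^2 + (var(vb) / 2)^2)
  want_p <- 2 * pt(-abs(tstat), df)
  got <- res2$tests$p_value[res2$tests$class_a == "Rif1-repressed" &
                              res2$tests$class_b == "Rif1-activated"]
  expect_equal(got, want_p, tolerance = 1e-12)

  # degenerate equal constant samples give p = 1
  cls3 <- cls2
  cls3$start <- c(100000, 100000, 300240, 300240) - 100
  cls3$end <- cls3$start + 200
  res3 <- mean_distance_by_class(cls3, layout, 20000)
  expect_true(all(is.na(res3$tests$p_value) | res3$tests$p_value %in% c(0, 1)))
})

test_that("excluding a pericentric origin leaves other classes untouched", {
  cen <- data.frame(chrom = "chrA", start = 200000, end = 200120)
  layout <- tiny_layout(c(chrA = 500000), centromeres = cen)
  cls <- classified_fixture(40, layout, seed = 171)
  res_all <- mean_distance_by_class(cls, layout, 20000)
  extra <- cls[1, ]
  extra$name <- "peri"; extra$class <- "Rif1-repressed"
  extra$start <- 200500 - 100; extra$end <- 200500 + 100
  res_extra <- mean_distance_by_class(rbind(cls, extra), layout, 20000)
  for (k in c("Rif1-unregulated", "Rif1-activated")) {
    expect_equal(res_extra$summary$mean_bp[res_extra$summary$class == k],
                 res_all$summary$mean_bp[res_all$summary$class == k])
  }
  expect_equal(res_extra$n_excluded, res_all$n_excluded + 1L)
})

test_that("site overlap applies half-open >=1 bp and the intergenic 1 kb rule", {
  layout <- tiny_layout(c(chrA = 200000))
  sites_path <- write_tsv_fixture(data.frame(
    name = c("YAL001C", "iYAL001C", "iYAL002W"),
    type = c("ORF", "intergenic", "intergenic"),
    chrom = "chrA",
    start = c(10001, 30001, 60001),
    end = c(12000, 33000, 63000),
    gene_side = c(NA, "left", "right")), withr::local_tempfile())
  sites <- read_sites_table(sites_path, layout)
  expect_equal(sites$start, c(10000, 30000, 62000))
  expect_equal(sites$end, c(12000, 31000, 63000))

  bad <- write_tsv_fixture(data.frame(
    name = "x", type = "promoter", chrom = "chrA", start = 1, end = 10),
    withr::local_tempfile())
  expect_error(read_sites_table(bad, layout), "feature type")

  classified <- data.frame(
    name = c("abut", "one_bp", "inside"), chrom = "chrA",
    # 1 kb origin windows: [12000,13000), [11999,12999), [10400,11400);
    # the ORF window ends at 12000 (half-open)
    start = c(12500 - 100, 12499 - 100, 10900 - 100),
    end = c(12500 + 100, 12499 + 100, 10900 + 100),
    class = c("Rif1-repressed", "Rif1-unregulated", "Rif1-activated"),
    stringsAsFactors = FALSE)
  res <- overlap_with_sites(classified, sites, layout)
  expect_equal(res$total, 2)
  expect_equal(res$per_class$proximal[res$per_class$class == "Rif1-repressed"], 0)
  expect_equal(res$per_class$proximal[res$per_class$class == "Rif1-unregulated"], 1)

  # subtelomeric exclusion drops origins near chromosome ends
  layout_big <- tiny_layout(c(chrA = 400000))
  internal <- data.frame(
    name = c("tel", "mid1", "mid2"), chrom = "chrA",
    start = c(500, 200000, 210000) - 100, end = c(500, 200000, 210000) + 100,
    class = "Rif1-repressed", stringsAsFactors = FALSE)
  res2 <- overlap_with_sites(internal, sites, layout_big,
                             exclude_subtelomeric = TRUE)
  expect_equal(res2$n_origins, 2L)

  # randomized sites against the quadratic overlap oracle
  set.seed(181)
  cls <- classified_fixture(50, layout, seed = 182)
  rnd_sites <- random_intervals("chrA", 30, 2e5, 183)
  rnd_sites$name <- sprintf("s%d", 1:30); rnd_sites$type <- "ORF"
  res3 <- overlap_with_sites(cls, rnd_sites, layout)
  mid <- floor((cls$start + cls$end) / 2)
  win <- data.frame(chrom = cls$chrom, start = pmax(0, mid - 500),
                    end = pmin(2e5, mid + 500))
  want_total <- sum(oracle_overlaps_any(win, rnd_sites))
  expect_equal(res3$total, want_total)
})

test_that("the landscape report is internally consistent on R64 coordinates", {
  layout <- read_chrom_sizes(system.file("extdata", "sacCer3.chrom.sizes",
                                         package = "repliscape"))
  layout <- read_centromeres(system.file("extdata", "sacCer3_centromeres.tsv",
                                         package = "repliscape"), layout)
  cls <- classified_fixture(300, layout, seed = 191)
  rep <- landscape_report(cls, layout)
  expect_equal(sum(rep$class_counts$n), 300)
  expect_equal(rep$cen_proximity$within + rep$cen_proximity$beyond,
               rep$class_counts$n)
  expect_equal(rep$tel_proximity$within + rep$tel_proximity$beyond,
               rep$class_counts$n)
  expect_equal(sum(rep$cen_distance$summary$n) + rep$cen_distance$n_excluded,
               300L)
})
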